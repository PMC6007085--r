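---
title: "Modelling, curating and validating MEG-BIDS datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling, curating and validating MEG-BIDS datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megbids)
```

## The problem this package addresses

Magnetoencephalography has no common raw file format: CTF/VSM,
Elekta/Neuromag/MEGIN, Yokogawa/KIT and other vendors each ship their own
binary containers, some of which are whole directories rather than single
files. The Brain Imaging Data Structure (BIDS) solves the organisational
half of this problem: raw recordings stay in their native vendor format,
while a fixed folder hierarchy (study → subject → session → modality →
run) and text-based metadata — JSON sidecars and tab-separated tables —
make a dataset self-describing, searchable and exchangeable between
analysis tools.

`megbids` implements that standard for MEG as a self-contained R toolkit:

* a **bidirectional filename grammar** between names such as
  `sub-01_ses-01_task-rest_run-01_meg.fif` and typed entity sets;
* a **tree scanner** building an indexed, queryable model of a dataset
  directory;
* **typed readers and writers** for every metadata artifact (MEG sidecar,
  coordinate-system document, channels/events/scans/participants tables,
  dataset description, and the anatomical-MRI fiducial field);
* **inheritance resolution** — the effective metadata of a recording
  merged across hierarchy levels, with the file closer to the data
  prevailing field by field;
* **fiducial-defined coordinate frames** with rigid transforms and unit
  conversion;
* a **conformance validator** emitting a severity-graded, stably coded
  report;
* a **curator** that builds a conformant tree from a declarative manifest;
* a **synthetic fixture generator** with named mutation operators, so
  every behaviour above is testable without any real MEG recording.

Raw payloads are opaque throughout: the package records their presence,
name and directory-ness but never opens vendor binaries. Metadata enters
through the manifest or through an extraction plugin.

## The filename grammar

A filename is a sequence of `key-value` entities in the fixed order
`sub < ses < task < acq < run < proc`, a suffix naming the file's role
(`meg`, `channels`, `events`, `coordsystem`, `headshape`, `photo`,
`scans`, `T1w`, plus the study-level `participants` and
`dataset_description`), and an extension. Labels are ASCII alphanumerics;
`run` is numeric, zero-padded to two digits on writing but accepted at any
width on reading (tolerant reader, canonical writer). The grammar table
ships as a machine-readable JSON document
(`system.file("extdata", "grammar.json", package = "megbids")`), the
single source of truth for the parser, validator and curator.

```{r}
parse_name("sub-01_ses-01_task-rest_run-01_meg.json")
parse_name("sub-01_run-01_task-rest_meg.fif")
```

Rejections are structured, never errors, and carry exactly one reason
code from `no-match`, `bad-key`, `bad-label`, `bad-order`, `bad-suffix`,
assigned in that precedence. Two reading-vs-writing asymmetries are
deliberate:

* The parser accepts any canonical-order *subset* of entities, because
  inheritance sidecars higher in the tree legitimately drop entities
  (a root-level `task-rest_meg.json` has no `sub-`). Required-entity
  enforcement happens when *building* a data filename and in the
  validator.
* `headshape` accepts any extension — scalp digitisation files are
  manufacturer-specific — while other suffixes carry a closed extension
  list whose violation is only a warning (vendors vary legitimately).

Placement follows a fixed table: run-item files under
`sub-<L>[/ses-<L>]/meg/`, anatomical files under `anat/`, session-specific
files (`coordsystem`, `headshape`, `photo`, `scans`) at the
`sub-<L>[/ses-<L>]` level, study files at the root. Session folders are
optional: a single-session study may omit `ses-` entirely, and the
validator then applies session-level rules at the subject level.

## Inheritance

The effective metadata of a recording is resolved by collecting every
sidecar of the right suffix whose entity set is a submap of the target's
and whose directory lies on the path from the root to the target, ordering
them by (directory depth, then entity count, both ascending), and merging
key by key so that later — deeper, more specific — files override earlier
ones. The merge is field-wise, not whole-file, because conflicts are
defined per field. Two design points were genuinely open:

* **Ties.** Two distinct applicable sidecars at the same depth with the
  same entity count (say, a root `task-rest_meg.json` and a root
  `run-01_meg.json` both applying to one run) have no defensible order;
  resolution refuses with an ambiguity error rather than picking silently,
  and the validator reports `MEG-E016`.
* **Tables.** Row-level merging of TSV tables is undefined, so for
  `channels`/`events` tables the deepest applicable file wins outright.

`resolve_sidecar()` returns full provenance: which file contributed each
surviving key.

## Coordinate frames

MEG systems disagree on head coordinate conventions and units, so the
package carries a closed registry of `MEGCoordinateSystem` tokens — `CTF`
and `KIT` (ALS axes), `ElektaNeuromag` (RAS), and `Other`, which requires
a free-text description and has no canonical construction. Frames are
built from the three anatomical fiducials:

* **ALS**: origin at the midpoint of LPA and RPA; \(\hat{x}\) towards the
  nasion; \(\hat{z} = \widehat{\hat{x} \times (\mathrm{LPA} -
  \mathrm{RPA})}\) (superior); \(\hat{y} = \hat{z} \times \hat{x}\)
  (left).
* **RAS**: \(\hat{x}\) from LPA to RPA; origin at the orthogonal
  projection of the nasion onto that line; \(\hat{y}\) towards the
  nasion; \(\hat{z} = \hat{x} \times \hat{y}\).

These formulas are this package's documented choice, following the
de-facto vendor conventions; the standard names the problem but fixes no
mathematics. All rotations are proper (determinant +1, orthonormal within
1e-9); fiducial triangles with area at or below 1e-12 m² are refused as
degenerate. The canonical internal unit is metres — conversion happens at
ingest — and unit conversion scales one decade at a time so that chained
conversions (m → cm → mm) perform the identical floating-point operation
sequence as the direct one and therefore compose bit-exactly, not merely
closely.

## The validator

`validate_dataset()` applies independent rule families — filename grammar
and placement, root metadata, per-file JSON/TSV schemas, sidecar
resolution, coordinate-system checks, and referential cross-checks
(channel counts against the channels table, `scans.tsv` targets,
participants against subject folders, event onsets against the recording
duration, empty-room links) — and always returns a report; I/O failures
become issues, never crashes. Codes are stable and severity-graded:
structural, grammar and required-metadata failures are ERRORs;
cross-count mismatches and best-practice deviations are WARNINGs, because
vendors differ legitimately; unknown metadata keys are INFO. A dataset is
invalid iff at least one ERROR is present; `--strict` (or
`strict_report()`) promotes warnings. Each check is owned by exactly one
family, so a single defect yields a single code. The registry
(`issue_registry()`) is an explicit reconstruction and superset of the
checks a conformance checker for this standard needs; it is documented as
such rather than claimed to mirror any particular external tool.

## The synthetic fixture generator

`fixture_spec()` + `generate_dataset()` expand a seed deterministically
into a complete valid dataset. The defaults describe a small
resting-state study of the kind the standard's example datasets contain:
a CTF-class axial-gradiometer system (274 gradiometers + 28 reference
channels + EOG/ECG/trigger, sampled at 2400 Hz), 5-minute (300 s)
continuous runs,
one empty-room run per subject recorded as an ordinary run with task
label `noise` and linked from task runs via `AssociatedEmptyRoom`, an
anatomical T1w JSON carrying the `NAS`/`LPA`/`RPA` fiducial field, and
fiducial triangles sampled as plausible head geometry (nasion ~9.5 cm
anterior, pre-auricular points ±7.5 cm lateral, millimetre-scale jitter).
Event onsets are uniform over the recording at 0.5 events/s by default.
All randomness flows from one seed through per-subject substreams, so the
same spec is byte-identical on every run and partial regeneration is
stable.

Two generator choices deserve emphasis:

* Run-level sidecars deliberately omit `PowerLineFrequency`; only a
  root-level `task-<label>_meg.json` carries it. Every fixture therefore
  *requires* inheritance to resolve, keeping that machinery load-bearing
  in all tests. Empty-room runs have no root-level sidecar and are
  self-sufficient.
* Raw payloads are a synthetic format, labelled as such: a 64-byte header
  (magic `MEGSYN01`, channel count, sampling frequency, duration) plus a
  small pseudorandom body. The body size is deliberately *not*
  `duration × rate × channels` — payloads exercise opaque-file handling
  and the extraction-plugin interface, nothing else. The shipped
  `"synthetic"` plugin reads exactly this header; readers for real vendor
  formats would be registered through the same `register_plugin()`
  interface.

What the fixtures do **not** emulate: physiological signal content, real
vendor binary internals, stimulus files, derivatives, multi-modality
studies beyond the anatomical sidecar, and pathological file-system
states (permissions, symlink cycles). A green test suite therefore
demonstrates correctness of the organisational and metadata machinery,
not of anything signal-level.

`mutate_dataset()` applies one of 22 named, minimal defects (one file
touched each) with a known expected issue code — from entity-order breaks
through stringified booleans to collinear fiducials — forming a
mutation-kill matrix in which every ERROR code of the registry is killed
by at least one operator and no operator provokes spurious errors.

## Numerical and serialisation choices

* JSON writes are canonical: schema key order then byte-sorted extras,
  4-space indent, UTF-8, LF, trailing newline; repeated writes are
  byte-identical and read-write-read is a fixed point.
* In TSV, the exact lowercase string `n/a` is the sole missing-value
  sentinel; ragged rows are padded/truncated with a violation recorded.
* Orthonormality tolerance 1e-9; collinearity threshold 1e-12 m²;
  datetime fields must be ISO 8601 to the second.
* Scanning sorts with byte-order (locale-independent) collation, so trees
  enumerate identically everywhere.

## Problem sizes used in the checks

The package's own test suite and the `scripts/acceptance.R` summary use
500 random names for the grammar round-trip, 20 random fixture specs for
generator validity, the full 22-operator mutation matrix, 200 layered
random trees against a brute-force sort-and-fold inheritance oracle, 100
fiducial triangles for the frame properties, and a 2-subject end-to-end
curation. These sizes were chosen as the point where adding cases stopped
changing the observed pass rates; all complete in well under two minutes
on one CPU.

## Known limitations

* Only the six entities above are supported; additional BIDS entities
  (`echo`, `space`, ...) are out of scope.
* MRI support is limited to recognising anatomical filenames and the
  fiducial field of the T1w JSON; no volume data is read.
* Derivatives are ignored, not modelled.
* Event annotation beyond the standard events table (hierarchical event
  descriptors, stimulus files) is not supported.
* The `coordsystem`/`scans`/`headshape`/`photo` placement at the
  subject/session level follows this package's placement table; tools
  following other readings of the standard's folder layout may place
  them one level deeper.
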