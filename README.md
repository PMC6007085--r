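# megbids

Model, curate and validate MEG-BIDS dataset trees in R.

Magnetoencephalography (MEG) has no common raw data format — CTF/VSM,
Elekta/Neuromag/MEGIN, Yokogawa/KIT and other systems each use their own
containers, some of them whole directories. The Brain Imaging Data
Structure (BIDS) standardises the *organisation* instead: raw recordings
stay in their native vendor format inside a fixed study → subject →
session → modality → run hierarchy, described by text metadata — JSON
sidecars (`*_meg.json`, `*_coordsystem.json`) and TSV tables
(`*_channels.tsv`, `*_events.tsv`, `scans.tsv`, `participants.tsv`) —
with the **inheritance principle**: a metadata file higher in the tree
applies to all compatible data below it, and the file closer to the data
prevails field by field.

`megbids` is a self-contained toolkit for that standard, for MEG lab data
managers, methods developers and pipeline authors:

* **Filename grammar** — bidirectional mapping between names like
  `sub-01_ses-01_task-rest_run-01_meg.fif` and typed entity sets
  (`parse_name()`, `build_name()`, `expected_location()`), with
  structured one-reason rejections.
* **Tree model** — a deterministic scanner/indexer (`scan_tree()`,
  `query()`); raw payloads (including CTF `.ds` directories) are opaque
  leaves, never opened.
* **Sidecar I/O** — schema-checked readers and byte-deterministic writers
  for every metadata artifact (`read_json_sidecar()`,
  `read_tsv_table()`, `write_json_sidecar()`, `write_tsv_table()`).
* **Inheritance** — effective-metadata resolution with full provenance
  (`resolve_sidecar()`, `applicable_sidecars()`).
* **Coordinates** — fiducial-defined head frames (ALS for CTF/KIT, RAS
  for Elekta/Neuromag), rigid transforms and exact unit conversion
  (`frame_from_fiducials()`, `between_frames()`, `convert_units()`).
* **Validator** — a rule engine with a stable registry of coded,
  severity-graded findings (`validate_dataset()`, `render_report()`).
* **Curator** — builds a conformant tree from a declarative YAML manifest
  (`curate()`, `read_manifest()`), with a plugin interface for metadata
  extraction from raw files.
* **Fixtures** — a seeded generator of valid synthetic datasets and 22
  named mutation operators with known expected issue codes
  (`generate_dataset()`, `mutate_dataset()`).

A command-line entry point ships as `exec/megbids` (subcommands
`validate`, `convert`, `inspect`, `fixture`; exit status 0 = valid,
1 = invalid, 2 = usage error, 3 = internal error).

## Worked example

```r
library(megbids)

out <- file.path(tempdir(), "demo")
res <- generate_dataset(fixture_spec(seed = 7, n_sub = 2, n_run = 2), out)
res$tree
#> <megbids_tree> /tmp/Rtmp8TPZEE/demo
#>   subjects:     2
#>   artifacts:    33
#>   unclassified: 0
res$report
#> valid: 0 errors, 0 warnings
```

The generated study has 2 subjects with 2 resting-state runs plus one
empty-room (`task-noise`) run each, CTF-style directory payloads, channel
and event tables, per-session coordinate-system documents and an
anatomical fiducial sidecar — 33 artifacts, all conformant.

Metadata resolution shows the inheritance principle at work: the
run-level sidecar deliberately carries no `PowerLineFrequency`; it is
inherited from the root-level task sidecar, while everything else comes
from the run-level file:

```r
raw <- query(res$tree, sub = "01", task = "rest", run = "01",
             suffix = "meg", extension = "ds")
resolve_sidecar(res$tree, raw$relative_path)
#> <resolution_trace> sub-01/meg/sub-01_task-rest_run-01_meg.ds (suffix meg)
#>   [1] depth 0, 1 entities: task-rest_meg.json
#>   [2] depth 2, 3 entities: sub-01/meg/sub-01_task-rest_run-01_meg.json
#>   effective keys: PowerLineFrequency, InstitutionName, TaskName, ...
```

Breaking the dataset on purpose and re-validating:

```r
mutate_dataset(out, "drop-required-meg-key")
validate_dataset(out)
#> invalid: 1 errors, 0 warnings
#> [ERROR] MEG-E011 sub-01/meg/sub-01_task-rest_run-01_meg.ds -
#>   effective sidecar lacks required key 'DewarPosition'
```

The report says the effective (inherited) metadata of that recording no
longer contains one of the seven required MEG sidecar keys; the code
`MEG-E011` is stable and machine-checkable (`issue_registry()` lists all
codes and severities).

## Scope

Raw vendor binaries are never parsed (the extraction-plugin interface
exists; the package ships one plugin for its own synthetic fixture
format). Derivatives folders are ignored, not modelled. Only the six
standard entities (`sub`, `ses`, `task`, `acq`, `run`, `proc`) are
supported. See the methods vignette
(`vignettes/megbids-methods.Rmd`) for the model, design decisions,
numerical tolerances and limitations.
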