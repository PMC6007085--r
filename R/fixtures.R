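# --- manufacturer profiles ---------------------------------------------------

manufacturer_profiles <- function() {
  list(
    CTF = list(extension = "ds", directory_payload = TRUE,
               sfreq = 2400, units = "cm", convention = "CTF",
               channels = c(MEGGRADAXIAL = 274, MEGREFMAG = 28,
                            EOG = 2, ECG = 1, TRIG = 1)),
    Neuromag = list(extension = "fif", directory_payload = FALSE,
                    sfreq = 1000, units = "m",
                    convention = "ElektaNeuromag",
                    channels = c(MEGMAG = 102, MEGGRADPLANAR = 204,
                                 EOG = 2, ECG = 1, TRIG = 1)),
    KIT = list(extension = "con", directory_payload = FALSE,
               sfreq = 2000, units = "mm", convention = "KIT",
               channels = c(MEGGRADAXIAL = 157, MEGREFMAG = 3, TRIG = 1)))
}

#' Describe a synthetic fixture dataset
#'
#' A fixture spec plus a seed deterministically expands to one dataset
#' tree. Defaults emulate a small resting-state study on a CTF-class
#' 275-channel system: 5-minute continuous recordings at 2400 Hz, one
#' empty-room (task `noise`) run per subject, an anatomical T1w sidecar
#' carrying the fiducial field, and a root-level task sidecar so that the
#' inheritance principle is exercised in every fixture (run-level sidecars
#' deliberately omit `PowerLineFrequency`, which only the root file
#' carries).
#'
#' @param seed Integer master seed; all randomness flows from it through
#'   per-subject substreams.
#' @param n_sub,n_ses,n_task,n_run Tree dimensions. `n_ses = 1` produces a
#'   session-less layout (no `ses-*` folders), which the standard allows.
#' @param include_emptyroom Add one task-`noise` run per subject/session?
#' @param include_anat Add an anatomical T1w JSON (+ tiny payload) with
#'   the `AnatomicalLandmarkCoordinates` fiducial field?
#' @param manufacturer `"CTF"`, `"Neuromag"` or `"KIT"` — sets raw payload
#'   style (CTF datasets are directories), sampling rate, channel profile,
#'   coordinate convention and units.
#' @param event_rate Mean events per second for task runs.
#' @param duration Recording duration in seconds.
#' @param subject_sidecars Also write a subject-level partial sidecar
#'   (a third inheritance layer)?
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_sub = 3L, n_ses = 1L, n_task = 1L,
                         n_run = 2L, include_emptyroom = TRUE,
                         include_anat = TRUE, manufacturer = "CTF",
                         event_rate = 0.5, duration = 300,
                         subject_sidecars = FALSE) {
  stopifnot(n_sub >= 1, n_ses >= 1, n_task >= 1, n_run >= 1,
            event_rate > 0, duration > 0)
  prof <- manufacturer_profiles()[[manufacturer]]
  if (is.null(prof)) {
    stop("unknown manufacturer profile '", manufacturer, "'",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_sub = as.integer(n_sub),
                 n_ses = as.integer(n_ses), n_task = as.integer(n_task),
                 n_run = as.integer(n_run),
                 include_emptyroom = isTRUE(include_emptyroom),
                 include_anat = isTRUE(include_anat),
                 manufacturer = manufacturer, profile = prof,
                 event_rate = event_rate, duration = duration,
                 subject_sidecars = isTRUE(subject_sidecars)),
            class = "fixture_spec")
}

task_names <- function(n) {
  base <- c("rest", "faces", "motor", "auditory", "visual")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("cog%02d", seq_len(n - length(base))))
}

sub_labels <- function(n) sprintf("%02d", seq_len(n))
ses_labels <- function(n) if (n == 1L) list(NULL) else
  as.list(sprintf("%02d", seq_len(n)))

channel_rows <- function(profile) {
  rows <- list()
  counters <- c(MEG = 0L, REF = 0L, EOG = 0L, ECG = 0L, TRIG = 0L,
                MISC = 0L, EEG = 0L, EMG = 0L)
  unit_for <- c(MEGMAG = "T", MEGGRADAXIAL = "T", MEGGRADPLANAR = "T/m",
                MEGREFMAG = "T", MEGREFGRADAXIAL = "T",
                EEG = "V", EOG = "V", ECG = "V", EMG = "V", TRIG = "V",
                MISC = "V")
  prefix_for <- c(MEGMAG = "MEG", MEGGRADAXIAL = "MEG",
                  MEGGRADPLANAR = "MEG", MEGREFMAG = "REF",
                  MEGREFGRADAXIAL = "REF", EEG = "EEG", EOG = "EOG",
                  ECG = "ECG", EMG = "EMG", TRIG = "TRIG", MISC = "MISC")
  for (type in names(profile$channels)) {
    n <- profile$channels[[type]]
    pre <- prefix_for[[type]]
    start <- counters[[pre]]
    counters[[pre]] <- start + n
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <- list(
        name = sprintf("%s%04d", pre, start + i),
        type = type, units = unit_for[[type]],
        low_cutoff = 0.03, high_cutoff = profile$sfreq / 4,
        status = "good")
    }
  }
  rows
}

count_fields <- function(profile) {
  ch <- profile$channels
  grp <- list(MEGChannelCount = c("MEGMAG", "MEGGRADAXIAL",
                                  "MEGGRADPLANAR"),
              MEGREFChannelCount = c("MEGREFMAG", "MEGREFGRADAXIAL"),
              EEGChannelCount = "EEG", EOGChannelCount = "EOG",
              ECGChannelCount = "ECG", EMGChannelCount = "EMG",
              MiscChannelCount = "MISC", TriggerChannelCount = "TRIG")
  out <- lapply(grp, function(types) sum(ch[names(ch) %in% types]))
  out
}

sample_fiducials <- function(units) {
  # plausible head geometry: nasion anterior, pre-auricular points lateral
  # at roughly +/- 7.5 cm; jitter keeps every fixture distinct
  nas_m <- c(stats::rnorm(1, 0, 0.004), 0.095 + stats::rnorm(1, 0, 0.004),
             stats::rnorm(1, 0, 0.004))
  lpa_m <- c(-0.075 + stats::rnorm(1, 0, 0.003),
             stats::rnorm(1, 0, 0.003), stats::rnorm(1, 0, 0.003))
  rpa_m <- c(0.075 + stats::rnorm(1, 0, 0.003),
             stats::rnorm(1, 0, 0.003), stats::rnorm(1, 0, 0.003))
  f <- 1 / unit_factor(units)
  list(NAS = round(nas_m * f, 4), LPA = round(lpa_m * f, 4),
       RPA = round(rpa_m * f, 4))
}

event_rows <- function(n_events, duration, task) {
  if (n_events < 1L) n_events <- 1L
  onsets <- sort(round(stats::runif(n_events, 0, max(duration - 2, 1)), 3))
  types <- sample(c("stimulus", "response", "target"), n_events,
                  replace = TRUE)
  lapply(seq_len(n_events), function(i) {
    list(onset = onsets[i], duration = 0.5, trial_type = types[i],
         value = match(types[i], c("stimulus", "response", "target")),
         sample = NA)
  })
}

acq_time_for <- function(day_index, slot) {
  sprintf("2018-06-%02dT%02d:%02d:00", 1 + (day_index %% 27),
          9 + (slot %% 8), 5 * (slot %% 12))
}

#' Build a curation manifest (plus synthetic payloads) for a fixture spec
#'
#' Expands a [fixture_spec()] into a full [curate()] manifest, writing the
#' synthetic raw payloads into `staging`. Also returns the expected
#' relative file list of the curated tree, enumerated independently of the
#' curator's own bookkeeping, and a log of the payload header parameters.
#'
#' @param spec A [fixture_spec()].
#' @param staging Directory for the synthetic raw payloads.
#' @return List with `manifest`, `expected_files`, `payload_log`.
#' @export
build_fixture_manifest <- function(spec, staging) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  prof <- spec$profile
  tasks <- task_names(spec$n_task)
  subs <- sub_labels(spec$n_sub)
  sess <- ses_labels(spec$n_ses)
  n_channels <- as.integer(sum(prof$channels))
  counts <- count_fields(prof)

  power_line <- with_seed(derive_seed(spec$seed, 0),
                          sample(c(50, 60), 1))
  dewar <- with_seed(derive_seed(spec$seed, 1),
                     sample(c("upright", "supine"), 1))

  recordings <- list()
  anatomy <- list()
  expected <- c("dataset_description.json", "participants.tsv")
  extra_sidecars <- lapply(tasks, function(t) {
    list(path = paste0("task-", t, "_meg.json"),
         content = list(PowerLineFrequency = power_line,
                        InstitutionName = "Synthetic Imaging Centre"))
  })
  expected <- c(expected, vapply(extra_sidecars, `[[`, "", "path"))

  participants <- list()
  chan_rows <- channel_rows(prof)

  for (si in seq_along(subs)) {
    sub <- subs[si]
    sseed <- derive_seed(spec$seed, 100 + si)
    participants[[si]] <- with_seed(sseed, list(
      participant_id = paste0("sub-", sub),
      age = sample(20:45, 1),
      sex = sample(c("M", "F"), 1)))
    if (spec$subject_sidecars) {
      for (t in tasks) {
        nm <- paste0("sub-", sub, "_task-", t, "_meg.json")
        extra_sidecars[[length(extra_sidecars) + 1L]] <-
          list(path = paste0("sub-", sub, "/", nm),
               content = list(DewarPosition = dewar))
        expected <- c(expected, paste0("sub-", sub, "/", nm))
      }
    }
    for (ssi in seq_along(sess)) {
      ses <- sess[[ssi]]
      base_dir <- paste0("sub-", sub,
                         if (!is.null(ses)) paste0("/ses-", ses))
      fid <- with_seed(derive_seed(sseed, ssi),
                       sample_fiducials(prof$units))
      coordsys <- list(MEGCoordinateSystem = prof$convention,
                       MEGCoordinateUnits = prof$units,
                       AnatomicalLandmarkCoordinates = fid)
      expected <- c(expected,
                    paste0(base_dir, "/",
                           build_name(entity_set(sub = sub, ses = ses,
                                                 suffix = "scans",
                                                 extension = "tsv"))),
                    paste0(base_dir, "/",
                           build_name(entity_set(sub = sub, ses = ses,
                                                 suffix = "coordsystem",
                                                 extension = "json"))))
      run_slots <- list()
      for (t in tasks) for (r in seq_len(spec$n_run)) {
        run_slots[[length(run_slots) + 1L]] <- list(task = t, run = r)
      }
      if (spec$include_emptyroom) {
        run_slots[[length(run_slots) + 1L]] <- list(task = "noise",
                                                    run = 1L)
      }
      noise_rel <- NULL
      if (spec$include_emptyroom) {
        es_noise <- entity_set(sub = sub, ses = ses, task = "noise",
                               run = 1L, suffix = "meg",
                               extension = prof$extension)
        noise_rel <- paste0(expected_location(es_noise), "/",
                            build_name(es_noise))
      }
      slot_i <- 0L
      for (slot in run_slots) {
        slot_i <- slot_i + 1L
        t <- slot$task; r <- slot$run
        is_noise <- identical(t, "noise")
        rseed <- derive_seed(sseed, 1000 * ssi + slot_i)
        payload_name <- sprintf("raw_%s_%s_%s_%02d", sub,
                                if (is.null(ses)) "0" else ses, t, r)
        if (prof$directory_payload) {
          pdir <- file.path(staging, paste0(payload_name, ".ds"))
          dir.create(pdir, showWarnings = FALSE)
          write_synthetic_raw(file.path(pdir, "payload.dat"),
                              n_channels, prof$sfreq, spec$duration,
                              seed = rseed)
          raw_path <- pdir
        } else {
          raw_path <- file.path(staging,
                                paste0(payload_name, ".",
                                       prof$extension))
          write_synthetic_raw(raw_path, n_channels, prof$sfreq,
                              spec$duration, seed = rseed)
        }
        meta <- c(list(TaskName = t,
                       SamplingFrequency = prof$sfreq,
                       DewarPosition = dewar,
                       SoftwareFilters = "n/a",
                       DigitizedLandmarks = TRUE,
                       DigitizedHeadPoints = !is_noise,
                       Manufacturer = spec$manufacturer,
                       RecordingDuration = spec$duration,
                       RecordingType = "continuous"),
                  counts)
        if (is_noise) {
          # no root-level noise sidecar exists, so the run-level file
          # must be self-sufficient
          meta$PowerLineFrequency <- power_line
        } else if (!is.null(noise_rel)) {
          meta$AssociatedEmptyRoom <- noise_rel
        }
        ev <- NULL
        if (!is_noise) {
          n_ev <- with_seed(rseed + 1,
                            stats::rpois(1, spec$event_rate *
                                           spec$duration))
          ev <- with_seed(rseed + 2,
                          event_rows(n_ev, spec$duration, t))
        }
        recordings[[length(recordings) + 1L]] <- list(
          subject = sub, session = ses, task = t, run = r,
          raw_path = raw_path,
          raw_extension = prof$extension,
          meg_metadata = meta,
          channels = chan_rows,
          events = ev,
          coordsystem = coordsys,
          acq_time = acq_time_for(si * 3 + ssi, slot_i))
        es_raw <- entity_set(sub = sub, ses = ses, task = t, run = r,
                             suffix = "meg", extension = prof$extension)
        stem_dir <- expected_location(es_raw)
        expected <- c(expected,
                      paste0(stem_dir, "/", build_name(es_raw)),
                      paste0(stem_dir, "/", build_name(local({
                        e <- es_raw; e$extension <- "json"; e
                      }))),
                      paste0(stem_dir, "/", build_name(local({
                        e <- es_raw; e$suffix <- "channels"
                        e$extension <- "tsv"; e
                      }))))
        if (!is_noise) {
          expected <- c(expected,
                        paste0(stem_dir, "/", build_name(local({
                          e <- es_raw; e$suffix <- "events"
                          e$extension <- "tsv"; e
                        }))))
        }
      }
      if (spec$include_anat && ssi == 1L) {
        mri_fid <- with_seed(derive_seed(sseed, 77),
                             sample_fiducials("mm"))
        nii_path <- file.path(staging, paste0("anat_", sub, ".nii"))
        write_synthetic_raw(nii_path, 1L, 0, 0,
                            seed = derive_seed(sseed, 78))
        anatomy[[length(anatomy) + 1L]] <-
          list(subject = sub, session = ses, landmarks = mri_fid,
               units = "mm", raw_path = nii_path)
        anat_dir <- paste0(base_dir, "/anat")
        es_t1 <- entity_set(sub = sub, ses = ses, suffix = "T1w",
                            extension = "json")
        expected <- c(expected,
                      paste0(anat_dir, "/", build_name(es_t1)),
                      paste0(anat_dir, "/", build_name(local({
                        e <- es_t1; e$extension <- "nii"; e
                      }))))
      }
    }
  }

  manifest <- structure(list(
    dataset = list(name = sprintf("Synthetic MEG study (seed %d)",
                                  spec$seed),
                   bids_version = "1.1.0",
                   authors = list("Fixture Generator")),
    participants = participants,
    extra_sidecars = extra_sidecars,
    recordings = recordings,
    anatomy = anatomy), class = "curation_manifest")
  list(manifest = manifest,
       expected_files = sort_c(unique(expected)),
       payload_log = list(n_channels = n_channels, sfreq = prof$sfreq,
                          duration = spec$duration))
}

#' Generate a valid synthetic MEG-BIDS tree
#'
#' Deterministically expands a [fixture_spec()] into a dataset on disk by
#' building its manifest and curating it. The same spec and seed always
#' produce a byte-identical tree.
#'
#' @param spec A [fixture_spec()].
#' @param out Output directory (must be absent or empty).
#' @param staging Where the intermediate synthetic payloads go; a
#'   temporary directory by default, removed afterwards.
#' @return List with `tree`, `report` (self-validation), `files` (what the
#'   curator wrote), `expected_files` (the generator's own enumeration),
#'   `manifest`, `payload_log`.
#' @export
generate_dataset <- function(spec, out, staging = NULL) {
  cleanup <- is.null(staging)
  if (is.null(staging)) staging <- tempfile("megbids-staging-")
  fx <- build_fixture_manifest(spec, staging)
  res <- curate(fx$manifest, out, mode = "copy")
  if (cleanup) unlink(staging, recursive = TRUE)
  c(res, list(expected_files = fx$expected_files,
              manifest = fx$manifest, payload_log = fx$payload_log))
}
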