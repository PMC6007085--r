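# --- synthetic raw payload format -------------------------------------------

SYNTH_MAGIC <- "MEGSYN01"

#' Write a synthetic raw MEG payload
#'
#' The package's stand-in for a vendor raw recording, labelled synthetic:
#' a 64-byte header (8-byte magic `"MEGSYN01"`, little-endian uint32
#' channel count, float64 sampling frequency in Hz, float64 duration in
#' seconds, zero padding) followed by a seeded pseudorandom byte body. The
#' body is opaque noise of fixed small size — payload content is
#' deliberately not modelled.
#'
#' @param path Output file.
#' @param n_channels,sfreq,duration Header fields.
#' @param seed Integer seed for the body bytes.
#' @param body_bytes Body size in bytes.
#' @return `path`, invisibly.
#' @export
write_synthetic_raw <- function(path, n_channels, sfreq, duration,
                                seed = 1L, body_bytes = 256L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(SYNTH_MAGIC), con)
  writeBin(as.integer(n_channels), con, size = 4L, endian = "little")
  writeBin(as.double(sfreq), con, size = 8L, endian = "little")
  writeBin(as.double(duration), con, size = 8L, endian = "little")
  writeBin(raw(64L - 8L - 4L - 8L - 8L), con)
  body <- with_seed(seed, as.raw(sample.int(256L, body_bytes,
                                            replace = TRUE) - 1L))
  writeBin(body, con)
  invisible(path)
}

#' Read the header of a synthetic raw payload
#' @param path A file written by [write_synthetic_raw()], or a
#'   directory-style payload containing one.
#' @return List with `n_channels`, `sfreq`, `duration`.
#' @export
read_synthetic_raw <- function(path) {
  if (dir.exists(path)) {
    inner <- sort_c(list.files(path, full.names = TRUE))
    inner <- inner[!dir.exists(inner)]
    if (!length(inner)) {
      stop("directory payload '", path, "' contains no files",
           call. = FALSE)
    }
    path <- inner[1]
  }
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, SYNTH_MAGIC)) {
    stop("'", path, "' is not a synthetic raw payload (bad magic)",
         call. = FALSE)
  }
  n_channels <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sfreq <- readBin(con, "double", 1L, size = 8L, endian = "little")
  duration <- readBin(con, "double", 1L, size = 8L, endian = "little")
  list(n_channels = n_channels, sfreq = sfreq, duration = duration)
}

# --- metadata extraction plugins --------------------------------------------

.megbids_plugins <- new.env(parent = emptyenv())

#' Register a metadata extraction plugin
#'
#' A plugin is a function `raw_path -> named list of MEG sidecar fields`.
#' Values from the curation manifest always override plugin values. The
#' package ships exactly one plugin, `"synthetic"`, for its own synthetic
#' raw format; readers for real vendor formats can be registered the same
#' way.
#'
#' @param id Plugin identifier.
#' @param fun Extraction function.
#' @export
register_plugin <- function(id, fun) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fun))
  .megbids_plugins[[id]] <- fun
  invisible(id)
}

#' Extract partial MEG sidecar metadata from a raw payload
#'
#' @param raw_path Path to a raw recording (file or directory payload).
#' @param plugin_id Plugin identifier.
#' @return Named list of sidecar fields. When no plugin is registered
#'   under `plugin_id`, an empty list with attribute `note` (an INFO
#'   message) is returned; a plugin parse failure is an error.
#' @export
extract_metadata <- function(raw_path, plugin_id = "synthetic") {
  fun <- .megbids_plugins[[plugin_id]]
  if (is.null(fun)) {
    out <- list()
    attr(out, "note") <- paste0("no extraction plugin registered for '",
                                plugin_id, "'; manifest must supply all ",
                                "metadata")
    return(out)
  }
  fun(raw_path)
}

synthetic_plugin <- function(raw_path) {
  h <- read_synthetic_raw(raw_path)
  list(MEGChannelCount = h$n_channels,
       SamplingFrequency = h$sfreq,
       RecordingDuration = h$duration)
}

# --- manifest ----------------------------------------------------------------

#' Read a curation manifest
#'
#' The manifest is a YAML mapping describing the dataset, its participants
#' and one entry per raw recording (subject/session/task/run labels, path
#' to the native payload, MEG sidecar fields, optional channels/events
#' rows, coordinate-system fields and acquisition time). See the package
#' vignette for the full layout.
#'
#' @param path YAML file.
#' @return The manifest as a list (class `curation_manifest`).
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  structure(m, class = "curation_manifest")
}

recording_key <- function(rec) {
  # [[ not $: "acq" must not partial-match "acq_time"
  paste(rec[["subject"]], rec[["session"]] %||% "", rec[["task"]],
        rec[["acq"]] %||% "", rec[["run"]] %||% "", rec[["proc"]] %||% "",
        sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_manifest <- function(manifest, plugin = NULL) {
  if (is.null(manifest$dataset$name) ||
        is.null(manifest$dataset$bids_version)) {
    stop("manifest error: dataset.name and dataset.bids_version are ",
         "required", call. = FALSE)
  }
  recs <- manifest$recordings %||% list()
  keys <- vapply(recs, recording_key, character(1))
  if (anyDuplicated(keys)) {
    stop("manifest error: duplicate recording key (subject/session/task/",
         "acq/run/proc must be unique): ", keys[duplicated(keys)][1],
         call. = FALSE)
  }
  req <- required_meg_keys()
  # keys a recording may legitimately inherit from a manifest-declared
  # upper-level sidecar rather than carry itself
  inherited_for <- function(rec) {
    keys <- character(0)
    for (xs in manifest$extra_sidecars %||% list()) {
      es <- parse_name(basename(xs$path))
      if (!is_entity_set(es) || es$suffix != "meg") next
      ents <- es$entities
      rec_ents <- c(sub = rec[["subject"]], ses = rec[["session"]],
                    task = rec[["task"]], acq = rec[["acq"]],
                    run = rec[["run"]], proc = rec[["proc"]])
      ok <- all(vapply(names(ents), function(k) {
        !is.null(rec_ents[[k]]) &&
          as.character(rec_ents[[k]]) == ents[[k]]
      }, logical(1)))
      if (ok) keys <- c(keys, names(xs$content))
    }
    keys
  }
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    for (f in c("subject", "task", "raw_path")) {
      if (is.null(rec[[f]])) {
        stop("manifest error: recording ", i, " lacks '", f, "'",
             call. = FALSE)
      }
    }
    if (!file.exists(rec$raw_path) && !dir.exists(rec$raw_path)) {
      stop("manifest error: recording ", i, ": raw_path '", rec$raw_path,
           "' does not exist", call. = FALSE)
    }
    meta <- rec$meg_metadata %||% list()
    if (!is.null(plugin)) {
      extracted <- extract_metadata(rec$raw_path, plugin)
      meta <- utils::modifyList(as.list(extracted), meta)
    }
    missing <- setdiff(req, c(names(meta), inherited_for(rec)))
    if (length(missing)) {
      stop("manifest error: recording ", i, " (", recording_key(rec),
           "): missing required MEG metadata key '", missing[1], "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

copy_payload <- function(from, to, mode = "copy") {
  if (mode == "link") {
    ok <- suppressWarnings(file.symlink(normalizePath(from), to))
    if (ok) return(invisible(to))
  }
  if (dir.exists(from)) {
    dir.create(to, recursive = TRUE)
    inner <- list.files(from, all.files = TRUE, no.. = TRUE,
                        full.names = TRUE)
    if (length(inner)) file.copy(inner, to, recursive = TRUE)
  } else {
    file.copy(from, to, copy.date = FALSE)
  }
  invisible(to)
}

list_to_df <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  out <- lapply(cols, function(cn) {
    vals <- lapply(rows, function(r) r[[cn]] %||% NA)
    unlist(vals)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Curate raw recordings into a conformant MEG-BIDS tree
#'
#' Builds a dataset tree from a [read_manifest()]-style manifest: writes
#' `dataset_description.json` and `participants.tsv`, places every raw
#' payload at its canonical name and location (native extension preserved;
#' directory payloads copied intact, never opened), writes all sidecars
#' through the typed writers, accumulates per-session `scans.tsv` with
#' acquisition times, then self-validates. The whole manifest is checked
#' before anything is written, so a refused manifest leaves no partial
#' tree.
#'
#' @param manifest A manifest list (see [read_manifest()]).
#' @param out_root Output directory; must be absent or empty.
#' @param mode `"copy"` (default, portable) or `"link"` (symlink payloads).
#' @param plugin Optional extraction plugin id; manifest values override
#'   extracted ones.
#' @return List with `tree` (the scanned result), `report` (the
#'   self-validation [validate_dataset()] report) and `files` (sorted
#'   relative paths written, payloads included).
#' @export
curate <- function(manifest, out_root, mode = c("copy", "link"),
                   plugin = NULL) {
  mode <- match.arg(mode)
  if (dir.exists(out_root) && length(list.files(out_root,
                                                all.files = TRUE,
                                                no.. = TRUE))) {
    stop("output directory '", out_root, "' is not empty", call. = FALSE)
  }
  validate_manifest(manifest, plugin = plugin)
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(rel) written <<- c(written, rel)
  ensure_dir <- function(rel) {
    d <- file.path(out_root, rel)
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }

  dd <- list(Name = manifest$dataset$name,
             BIDSVersion = manifest$dataset$bids_version)
  if (!is.null(manifest$dataset$authors)) {
    dd$Authors <- as.character(unlist(manifest$dataset$authors))
  }
  write_json_sidecar(dd, file.path(out_root, "dataset_description.json"),
                     schema = "dataset_description")
  emit("dataset_description.json")

  recs <- manifest$recordings %||% list()
  subjects <- sort_c(unique(vapply(recs, function(r)
    as.character(r$subject), character(1))))
  participants <- manifest$participants %||%
    lapply(subjects, function(s) list(participant_id = paste0("sub-", s)))
  write_tsv_table(list_to_df(participants),
                  file.path(out_root, "participants.tsv"),
                  schema = "participants")
  emit("participants.tsv")

  for (xs in manifest$extra_sidecars %||% list()) {
    es <- parse_name(basename(xs$path))
    if (!is_entity_set(es)) {
      stop("extra sidecar '", xs$path, "' does not parse: ", es$reason,
           call. = FALSE)
    }
    dir <- path_dir(xs$path)
    expected <- expected_location(es)
    if (dir != expected && dir != "" &&
          !startsWith(expected, paste0(dir, "/"))) {
      stop("extra sidecar '", xs$path, "' is neither at its expected ",
           "location nor at an ancestor level", call. = FALSE)
    }
    if (nzchar(dir)) ensure_dir(dir)
    write_json_sidecar(xs$content, file.path(out_root, xs$path),
                       schema = if (es$suffix %in% c("meg", "coordsystem"))
                         es$suffix else NULL,
                       partial = TRUE)
    emit(xs$path)
  }

  scans_rows <- list()     # key -> list of rows
  coord_docs <- list()     # key -> doc (first one wins; later must agree)
  for (rec in recs) {
    ext <- rec$raw_extension %||% {
      b <- basename(rec$raw_path)
      if (grepl("\\.", b)) sub("^.*\\.", "", b) else NA_character_
    }
    es_raw <- entity_set(sub = rec$subject, ses = rec$session,
                         task = rec$task, acq = rec[["acq"]],
                         run = rec$run, proc = rec[["proc"]],
                         suffix = "meg", extension = ext)
    meg_dir <- expected_location(es_raw)
    ensure_dir(meg_dir)
    raw_name <- build_name(es_raw)
    raw_rel <- paste(meg_dir, raw_name, sep = "/")
    copy_payload(rec$raw_path, file.path(out_root, raw_rel), mode = mode)
    emit(raw_rel)

    meta <- rec$meg_metadata %||% list()
    if (!is.null(plugin)) {
      meta <- utils::modifyList(as.list(extract_metadata(rec$raw_path,
                                                         plugin)), meta)
    }
    es_json <- es_raw; es_json$extension <- "json"
    json_rel <- paste(meg_dir, build_name(es_json), sep = "/")
    write_json_sidecar(meta, file.path(out_root, json_rel), schema = "meg",
                       partial = TRUE)
    emit(json_rel)

    if (!is.null(rec$channels)) {
      es_ch <- es_raw; es_ch$suffix <- "channels"; es_ch$extension <- "tsv"
      ch_rel <- paste(meg_dir, build_name(es_ch), sep = "/")
      tab <- if (is.data.frame(rec$channels)) rec$channels
             else list_to_df(rec$channels)
      write_tsv_table(tab, file.path(out_root, ch_rel), schema = "channels")
      emit(ch_rel)
    }
    if (!is.null(rec$events)) {
      es_ev <- es_raw; es_ev$suffix <- "events"; es_ev$extension <- "tsv"
      ev_rel <- paste(meg_dir, build_name(es_ev), sep = "/")
      tab <- if (is.data.frame(rec$events)) rec$events
             else list_to_df(rec$events)
      write_tsv_table(tab, file.path(out_root, ev_rel), schema = "events")
      emit(ev_rel)
    }

    ses_key <- paste(rec$subject, rec$session %||% "", sep = "|")
    scans_rows[[ses_key]] <- c(scans_rows[[ses_key]],
                               list(list(filename = paste0("meg/", raw_name),
                                         acq_time = rec$acq_time %||%
                                           "n/a")))
    if (!is.null(rec$coordsystem) && is.null(coord_docs[[ses_key]])) {
      coord_docs[[ses_key]] <- rec$coordsystem
    }
  }

  for (key in names(scans_rows)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sub <- parts[1]; ses <- if (length(parts) > 1 && nzchar(parts[2]))
      parts[2] else NULL
    es_sc <- entity_set(sub = sub, ses = ses, suffix = "scans",
                        extension = "tsv")
    loc <- expected_location(es_sc)
    sc_rel <- paste(loc, build_name(es_sc), sep = "/")
    rows <- list_to_df(scans_rows[[key]])
    rows <- rows[order(rows$filename, method = "radix"), , drop = FALSE]
    write_tsv_table(rows, file.path(out_root, sc_rel), schema = "scans")
    emit(sc_rel)
    cd <- coord_docs[[key]]
    if (!is.null(cd)) {
      es_co <- entity_set(sub = sub, ses = ses, suffix = "coordsystem",
                          extension = "json")
      co_rel <- paste(loc, build_name(es_co), sep = "/")
      write_json_sidecar(cd, file.path(out_root, co_rel),
                         schema = "coordsystem")
      emit(co_rel)
    }
  }

  for (an in manifest$anatomy %||% list()) {
    es_t1 <- entity_set(sub = an$subject, ses = an$session, suffix = "T1w",
                        extension = "json")
    loc <- expected_location(es_t1)
    ensure_dir(loc)
    t1_rel <- paste(loc, build_name(es_t1), sep = "/")
    doc <- list(AnatomicalLandmarkCoordinates = an$landmarks,
                CoordinateUnits = an$units %||% "mm")
    write_json_sidecar(doc, file.path(out_root, t1_rel), schema = "T1w")
    emit(t1_rel)
    if (!is.null(an$raw_path)) {
      es_nii <- es_t1; es_nii$extension <- "nii"
      nii_rel <- paste(loc, build_name(es_nii), sep = "/")
      copy_payload(an$raw_path, file.path(out_root, nii_rel), mode = mode)
      emit(nii_rel)
    }
  }

  tree <- scan_tree(out_root)
  report <- validate_dataset(tree)
  list(tree = tree, report = report, files = sort_c(written))
}
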