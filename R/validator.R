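#' Registry of validation issue codes
#'
#' Stable code-to-severity mapping for every finding the validator can
#' emit. Structural, grammar and required-metadata failures are ERRORs;
#' cross-count mismatches and best-practice deviations are WARNINGs
#' (vendors differ legitimately); unknown metadata keys are INFO.
#'
#' @return Data frame with columns `code`, `severity`, `title`.
#' @export
issue_registry <- function() {
  reg <- rbind(
    c("MEG-E001", "ERROR", "path matches no recognised filename pattern"),
    c("MEG-E002", "ERROR", "dataset_description.json is missing"),
    c("MEG-E003", "ERROR", "dataset description lacks a required field"),
    c("MEG-E004", "ERROR", "artifact is not in its expected directory"),
    c("MEG-E010", "ERROR", "MEG recording resolves no *_meg.json sidecar"),
    c("MEG-E011", "ERROR", "effective MEG sidecar misses a required key"),
    c("MEG-E012", "ERROR", "malformed JSON file"),
    c("MEG-E013", "ERROR", "metadata value of wrong type or vocabulary"),
    c("MEG-E014", "ERROR", "malformed TSV table structure"),
    c("MEG-E015", "ERROR", "duplicate identifier within a table"),
    c("MEG-E016", "ERROR", "ambiguous sidecars at equal specificity"),
    c("MEG-E020", "ERROR",
      "coordsystem missing although landmarks were digitised"),
    c("MEG-E021", "ERROR", "MEG coordinate system token not in registry"),
    c("MEG-E022", "ERROR", "invalid coordinate units"),
    c("MEG-E023", "ERROR", "anatomical landmarks are collinear"),
    c("MEG-E031", "ERROR", "scans.tsv references a missing file"),
    c("MEG-W005", "WARNING", "unexpected extension for suffix"),
    c("MEG-W011", "WARNING", "MEG recording has no channels table"),
    c("MEG-W030", "WARNING",
      "channel count fields disagree with channels table"),
    c("MEG-W032", "WARNING",
      "participants.tsv and subject folders disagree"),
    c("MEG-W033", "WARNING", "event onset beyond recording duration"),
    c("MEG-W034", "WARNING", "associated empty-room recording not found"),
    c("MEG-I001", "INFO", "unknown metadata key"))
  data.frame(code = reg[, 1], severity = reg[, 2], title = reg[, 3],
             stringsAsFactors = FALSE)
}

issue_severity <- function(code) {
  reg <- issue_registry()
  s <- reg$severity[match(code, reg$code)]
  if (is.na(s)) stop("unknown issue code '", code, "'", call. = FALSE)
  s
}

# map reader violation codes onto validator issue codes
violation_issue_code <- function(vcode) {
  switch(vcode,
         "JSON-PARSE" = "MEG-E012",
         "TYPE" = "MEG-E013",
         "VOCAB" = "MEG-E013",
         "RANGE" = "MEG-E013",
         "PATTERN" = "MEG-E013",
         "MISSING-COLUMN" = "MEG-E014",
         "DUP-COLUMN" = "MEG-E014",
         "RAGGED-ROW" = "MEG-E014",
         "EMPTY-TABLE" = "MEG-E014",
         "DUP-VALUE" = "MEG-E015",
         "UNKNOWN-KEY" = "MEG-I001",
         "MISSING-KEY" = "MEG-E011",
         NA_character_)
}

required_meg_keys <- function() {
  names(sidecar_schema("meg")$required)
}

#' Validate a dataset tree for MEG-BIDS conformance
#'
#' Applies the full rule set — filename grammar and placement, root
#' metadata, sidecar resolution and schemas, coordinate-system checks, and
#' referential cross-checks — and always returns a report; I/O failures
#' become issues, never crashes. Raw payload contents are never opened:
#' only presence, naming and directory-ness are checked.
#'
#' @param x A `megbids_tree` from [scan_tree()] or a directory path.
#' @param ignore Passed to [scan_tree()] when `x` is a path.
#' @return Object of class `validation_report`: `issues` data frame
#'   (`code`, `severity`, `path`, `message`), `counts`, and `verdict`
#'   (`"invalid"` iff at least one ERROR).
#' @export
validate_dataset <- function(x, ignore = c("derivatives", "sourcedata",
                                           "code", "stimuli")) {
  tree <- if (is_megbids_tree(x)) x else scan_tree(x, ignore = ignore)
  issues <- list()
  add <- function(code, path, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, severity = issue_severity(code), path = path,
      message = message, stringsAsFactors = FALSE)
  }
  add_violations <- function(v, path, drop = character(0)) {
    for (i in seq_len(nrow(v))) {
      code <- violation_issue_code(v$code[i])
      if (is.na(code) || code %in% drop) next
      add(code, path, v$message[i])
    }
  }
  a <- tree$artifacts
  g <- bids_grammar()

  # (F) filename grammar and placement -------------------------------------
  for (i in seq_len(nrow(tree$unclassified))) {
    add("MEG-E001", tree$unclassified$relative_path[i],
        paste("unrecognised name:", tree$unclassified$note[i]))
  }
  for (i in seq_len(nrow(a))) {
    es <- artifact_entities(a[i, ])
    expected <- expected_location(es)
    actual <- path_dir(a$relative_path[i])
    # metadata sidecars may sit at an ancestor level (inheritance files)
    is_meta <- !a$is_directory_payload[i] && !is.na(a$extension[i]) &&
      a$extension[i] %in% c("json", "tsv")
    ancestor_ok <- is_meta &&
      (actual == "" || startsWith(expected, paste0(actual, "/")))
    if (actual != expected && !ancestor_ok) {
      add("MEG-E004", a$relative_path[i],
          paste0("expected under '",
                 if (nzchar(expected)) expected else "<root>",
                 "', found under '",
                 if (nzchar(actual)) actual else "<root>", "'"))
    }
    rule <- g$suffixes[[a$suffix[i]]]
    allowed <- unlist(rule$extensions)
    if (!is.null(allowed) &&
        (is.na(a$extension[i]) || !a$extension[i] %in% allowed)) {
      add("MEG-W005", a$relative_path[i],
          paste0("extension '", a$extension[i], "' unusual for suffix '",
                 a$suffix[i], "'"))
    }
  }

  # (D) dataset description -------------------------------------------------
  dd <- a[a$suffix == "dataset_description" & a$relative_path ==
            "dataset_description.json", , drop = FALSE]
  if (!nrow(dd)) {
    add("MEG-E002", "<dataset>", "dataset_description.json not found at root")
  } else {
    r <- read_json_sidecar(file.path(tree$root, "dataset_description.json"),
                           schema = "dataset_description")
    miss <- r$violations[r$violations$code == "MISSING-KEY", , drop = FALSE]
    for (i in seq_len(nrow(miss))) {
      add("MEG-E003", "dataset_description.json", miss$message[i])
    }
    add_violations(r$violations[r$violations$code != "MISSING-KEY", ,
                                drop = FALSE],
                   "dataset_description.json")
  }

  # (T) per-file schema checks ----------------------------------------------
  json_schema_for <- c(meg = "meg", coordsystem = "coordsystem",
                       T1w = "T1w")
  tsv_schema_for <- c(channels = "channels", events = "events",
                      scans = "scans", participants = "participants")
  parse_failed <- character(0)
  for (i in seq_len(nrow(a))) {
    sfx <- a$suffix[i]; ext <- a$extension[i]; rel <- a$relative_path[i]
    if (!is.na(ext) && ext == "json" && sfx %in% names(json_schema_for)) {
      r <- read_json_sidecar(file.path(tree$root, rel),
                             schema = json_schema_for[[sfx]],
                             check_required = FALSE)
      if (is.null(r$document)) parse_failed <- c(parse_failed, rel)
      drop <- if (sfx == "coordsystem") "MEG-E013" else character(0)
      if (sfx == "coordsystem") {
        # units/system vocabulary is owned by the C-family checks below;
        # still surface genuine type errors
        vv <- r$violations
        vv <- vv[!(vv$code %in% c("VOCAB")), , drop = FALSE]
        add_violations(vv, rel)
      } else {
        add_violations(r$violations, rel)
      }
    }
    if (!is.na(ext) && ext == "tsv" && sfx %in% names(tsv_schema_for)) {
      r <- read_tsv_table(file.path(tree$root, rel),
                          schema = tsv_schema_for[[sfx]])
      add_violations(r$violations, rel)
    }
  }

  # (M) sidecar resolution for every raw recording --------------------------
  raw_idx <- which(a$suffix == "meg" &
                     (a$is_directory_payload |
                        is.na(a$extension) | a$extension != "json"))
  effective <- vector("list", length(raw_idx))
  names(effective) <- a$relative_path[raw_idx]
  for (j in seq_along(raw_idx)) {
    i <- raw_idx[j]
    rel <- a$relative_path[i]
    res <- tryCatch(resolve_sidecar(tree, rel, suffix = "meg"),
                    megbids_ambiguity = function(e) e,
                    megbids_resolution_error = function(e) e)
    if (inherits(res, "megbids_ambiguity")) {
      add("MEG-E016", rel, conditionMessage(res))
      next
    }
    if (inherits(res, "megbids_resolution_error")) {
      # the parse failure itself is already reported as MEG-E012
      next
    }
    if (!nrow(res$applied)) {
      add("MEG-E010", rel, "no applicable *_meg.json sidecar found")
      next
    }
    missing <- setdiff(required_meg_keys(), names(res$effective))
    for (k in missing) {
      add("MEG-E011", rel,
          paste0("effective sidecar lacks required key '", k, "'"))
    }
    effective[[rel]] <- res$effective
  }

  # (C) coordinate system per session ---------------------------------------
  sess_key <- function(sub, ses) paste(sub, ses, sep = "\r")
  raws <- a[raw_idx, , drop = FALSE]
  groups <- unique(raws[, c("sub", "ses"), drop = FALSE])
  registry <- frame_conventions()$name
  for (gi in seq_len(nrow(groups))) {
    sub <- groups$sub[gi]; ses <- groups$ses[gi]
    if (is.na(sub)) next
    in_group <- raws$sub == sub & (is.na(raws$ses) == is.na(ses)) &
      (is.na(ses) | raws$ses %in% ses)
    digitised <- any(vapply(raws$relative_path[in_group], function(rel) {
      isTRUE(effective[[rel]]$DigitizedLandmarks)
    }, logical(1)))
    cs <- a[a$suffix == "coordsystem" & !is.na(a$sub) & a$sub == sub &
              (is.na(a$ses) == is.na(ses)) &
              (is.na(ses) | (!is.na(a$ses) & a$ses == ses)), ,
            drop = FALSE]
    where <- paste0("sub-", sub, if (!is.na(ses)) paste0("/ses-", ses))
    if (!nrow(cs)) {
      if (digitised) {
        add("MEG-E020", where,
            "DigitizedLandmarks is true but no *_coordsystem.json present")
      }
      next
    }
    for (ci in seq_len(nrow(cs))) {
      rel <- cs$relative_path[ci]
      r <- read_json_sidecar(file.path(tree$root, rel),
                             schema = "coordsystem",
                             check_required = FALSE)
      if (is.null(r$document)) next  # MEG-E012 already reported
      doc <- r$document
      sys <- doc$MEGCoordinateSystem
      sys_ok <- is.character(sys) && length(sys) == 1L && sys %in% registry
      if (!sys_ok) {
        add("MEG-E021", rel,
            paste0("MEGCoordinateSystem '",
                   if (is.null(sys)) "<missing>" else sys,
                   "' is not a registered token"))
      } else if (sys == "Other" &&
                 !(is.character(doc$MEGCoordinateSystemDescription) &&
                     nzchar(doc$MEGCoordinateSystemDescription[1]))) {
        add("MEG-E021", rel,
            "system 'Other' requires MEGCoordinateSystemDescription")
      }
      units <- doc$MEGCoordinateUnits
      if (!(is.character(units) && length(units) == 1L &&
              units %in% names(.unit_factors))) {
        add("MEG-E022", rel,
            paste0("MEGCoordinateUnits '",
                   if (is.null(units)) "<missing>" else units,
                   "' is not one of m, cm, mm"))
      }
      alc <- doc$AnatomicalLandmarkCoordinates
      if (!is.null(alc) && is.null(json_type_error(alc, "landmarks"))) {
        u <- if (is.character(units) && units %in% names(.unit_factors))
          units else "m"
        ok <- tryCatch({
          fiducials(unlist(alc$NAS), unlist(alc$LPA), unlist(alc$RPA),
                    units = u)
          TRUE
        }, error = function(e) FALSE)
        if (!ok) {
          add("MEG-E023", rel,
              "anatomical landmarks NAS/LPA/RPA are collinear")
        }
      }
    }
  }

  # (X) cross-checks ---------------------------------------------------------
  channel_count_map <- list(
    MEGChannelCount = c("MEGMAG", "MEGGRADAXIAL", "MEGGRADPLANAR"),
    MEGREFChannelCount = c("MEGREFMAG", "MEGREFGRADAXIAL"),
    EEGChannelCount = "EEG", EOGChannelCount = "EOG",
    ECGChannelCount = "ECG", EMGChannelCount = "EMG",
    MiscChannelCount = "MISC", TriggerChannelCount = "TRIG")
  for (rel in names(effective)) {
    eff <- effective[[rel]]
    if (is.null(eff)) next
    ch <- tryCatch(resolve_table(tree, rel, suffix = "channels"),
                   megbids_ambiguity = function(e) e)
    if (inherits(ch, "megbids_ambiguity")) {
      add("MEG-E016", rel, conditionMessage(ch))
      ch <- list(path = NULL)
    }
    if (is.null(ch$path)) {
      add("MEG-W011", rel, "no applicable *_channels.tsv for this recording")
    } else if (!is.null(ch$result$table) &&
                 "type" %in% names(ch$result$table)) {
      types <- ch$result$table$type
      for (field in names(channel_count_map)) {
        declared <- eff[[field]]
        if (is.null(declared) || !is_scalar_number(declared)) next
        actual <- sum(types %in% channel_count_map[[field]], na.rm = TRUE)
        if (actual != declared) {
          add("MEG-W030", rel,
              paste0(field, " is ", declared, " but ", ch$path,
                     " has ", actual, " such channels"))
        }
      }
    }
    dur <- eff$RecordingDuration
    if (is_scalar_number(dur)) {
      ev <- tryCatch(resolve_table(tree, rel, suffix = "events"),
                     megbids_ambiguity = function(e) NULL)
      if (!is.null(ev) && !is.null(ev$path) &&
            !is.null(ev$result$table) &&
            "onset" %in% names(ev$result$table)) {
        onsets <- ev$result$table$onset
        over <- which(!is.na(onsets) & onsets > dur)
        if (length(over)) {
          add("MEG-W033", ev$path,
              paste0(length(over), " event onset(s) exceed ",
                     "RecordingDuration (", dur, " s)"))
        }
      }
    }
    aer <- eff$AssociatedEmptyRoom
    if (is.character(aer) && length(aer) == 1L) {
      target <- sub("^/+", "", aer)
      if (!file.exists(file.path(tree$root, target)) &&
            !dir.exists(file.path(tree$root, target))) {
        add("MEG-W034", rel,
            paste0("AssociatedEmptyRoom '", aer, "' does not exist"))
      }
    }
  }
  # scans.tsv referential integrity
  scans_idx <- which(a$suffix == "scans" & !is.na(a$extension) &
                       a$extension == "tsv")
  for (i in scans_idx) {
    rel <- a$relative_path[i]
    r <- read_tsv_table(file.path(tree$root, rel), schema = "scans")
    if (is.null(r$table) || !"filename" %in% names(r$table)) next
    base <- path_dir(rel)
    for (fn in r$table$filename) {
      if (is.na(fn)) next
      target <- if (nzchar(base)) file.path(tree$root, base, fn)
                else file.path(tree$root, fn)
      if (!file.exists(target) && !dir.exists(target)) {
        add("MEG-E031", rel,
            paste0("scans.tsv references missing file '", fn, "'"))
      }
    }
  }
  # participants vs subject folders, both directions
  pt <- a[a$relative_path == "participants.tsv", , drop = FALSE]
  if (nrow(pt)) {
    r <- read_tsv_table(file.path(tree$root, "participants.tsv"),
                        schema = "participants")
    if (!is.null(r$table) && "participant_id" %in% names(r$table)) {
      ids <- sub("^sub-", "", r$table$participant_id[
        !is.na(r$table$participant_id)])
      for (orphan in setdiff(ids, tree$subjects)) {
        add("MEG-W032", "participants.tsv",
            paste0("participant 'sub-", orphan,
                   "' has no subject folder"))
      }
      for (missing in setdiff(tree$subjects, ids)) {
        add("MEG-W032", "participants.tsv",
            paste0("subject folder 'sub-", missing,
                   "' is not listed in participants.tsv"))
      }
    }
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(code = character(0), severity = character(0),
               path = character(0), message = character(0),
               stringsAsFactors = FALSE)
  issues <- unique(issues)
  ord <- order(issues$path, issues$code, issues$message, method = "radix")
  issues <- issues[ord, , drop = FALSE]
  rownames(issues) <- NULL
  new_report(issues)
}

new_report <- function(issues) {
  counts <- c(error = sum(issues$severity == "ERROR"),
              warning = sum(issues$severity == "WARNING"),
              info = sum(issues$severity == "INFO"))
  structure(list(issues = issues, counts = counts,
                 verdict = if (counts[["error"]] > 0) "invalid" else "valid"),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' Render a validation report
#'
#' Deterministic ordering (path, then code). The JSON rendering
#' round-trips through [parse_report()] to an equal report and re-renders
#' byte-identically.
#'
#' @param report A `validation_report`.
#' @param format One of `"text"`, `"json"`, `"tsv"`.
#' @return Character vector of lines (`text`, `tsv`) or a single JSON
#'   string.
#' @export
render_report <- function(report, format = c("text", "json", "tsv")) {
  stopifnot(inherits(report, "validation_report"))
  format <- match.arg(format)
  issues <- report$issues
  if (format == "text") {
    head <- sprintf("%s: %d errors, %d warnings", report$verdict,
                    report$counts[["error"]], report$counts[["warning"]])
    body <- if (nrow(issues)) {
      sprintf("[%s] %s %s - %s", issues$severity, issues$code,
              issues$path, issues$message)
    } else character(0)
    c(head, body)
  } else if (format == "tsv") {
    body <- if (nrow(issues)) {
      sprintf("%s\t%s\t%s\t%s", issues$severity, issues$code, issues$path,
              issues$message)
    } else character(0)
    c("severity\tcode\tpath\tmessage", body)
  } else {
    payload <- list(schema_version = "1.0",
                    verdict = report$verdict,
                    counts = as.list(report$counts),
                    issues = issues)
    paste0(jsonlite::toJSON(payload, pretty = 4, auto_unbox = TRUE,
                            digits = NA, dataframe = "rows"), "\n")
  }
}

#' Parse a JSON-rendered report back into a `validation_report`
#' @param json JSON string produced by [render_report()].
#' @return A `validation_report`.
#' @export
parse_report <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = TRUE)
  issues <- if (is.data.frame(p$issues) && nrow(p$issues)) {
    p$issues[, c("code", "severity", "path", "message"), drop = FALSE]
  } else {
    data.frame(code = character(0), severity = character(0),
               path = character(0), message = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(issues) <- NULL
  new_report(issues)
}

#' Promote warnings to errors (strict mode)
#' @param report A `validation_report`.
#' @return A new report in which every WARNING is an ERROR.
#' @export
strict_report <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  issues <- report$issues
  issues$severity[issues$severity == "WARNING"] <- "ERROR"
  new_report(issues)
}
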