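# package-level cache for the grammar table and sidecar schemas
.megbids_cache <- new.env(parent = emptyenv())

#' The filename grammar table
#'
#' Returns the machine-readable grammar shipped with the package: the
#' canonical entity order (`sub < ses < task < acq < run < proc`), label
#' patterns, and one rule per filename suffix (required/optional entities,
#' allowed extensions, expected placement in the tree). The same table
#' drives [parse_name()], [build_name()], [expected_location()], the
#' validator and the curator.
#'
#' @return A list mirroring `inst/extdata/grammar.json`.
#' @export
#' @examples
#' names(bids_grammar()$suffixes)
bids_grammar <- function() {
  if (is.null(.megbids_cache$grammar)) {
    path <- system.file("extdata", "grammar.json", package = "megbids",
                        mustWork = TRUE)
    .megbids_cache$grammar <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                                 simplifyDataFrame = FALSE,
                                                 simplifyMatrix = FALSE)
  }
  .megbids_cache$grammar
}

#' Entity keys in canonical order
#' @return Character vector `c("sub", "ses", "task", "acq", "run", "proc")`.
#' @export
entity_keys <- function() bids_grammar()$entity_order

#' Construct an entity set
#'
#' An entity set is the parsed identity of one file in a BIDS tree: an
#' ordered map of entity key-value pairs (the `sub-01_task-rest_...` part of
#' a filename), a suffix naming the file's role (`meg`, `channels`, ...),
#' and an extension. Entities are stored in canonical order regardless of
#' the order given.
#'
#' @param ... Entity values named by key, e.g. `sub = "01", task = "rest"`.
#'   `run` may be given as an integer; it is stored as digits.
#' @param suffix File-role token; must be one of the grammar's suffixes.
#' @param extension Extension without the leading dot, or `NA` for
#'   extension-less directory payloads.
#' @return An object of class `entity_set` with fields `entities` (named
#'   character vector in canonical order), `suffix`, `extension`.
#' @export
#' @examples
#' entity_set(sub = "01", task = "rest", run = 1, suffix = "meg",
#'            extension = "fif")
entity_set <- function(..., suffix, extension = NA_character_) {
  ents <- list(...)
  ents <- ents[!vapply(ents, is.null, logical(1))]
  g <- bids_grammar()
  keys <- names(ents)
  if (length(ents) && (is.null(keys) || any(!nzchar(keys)))) {
    stop("all entities must be named", call. = FALSE)
  }
  bad <- setdiff(keys, g$entity_order)
  if (length(bad)) {
    stop("unknown entity key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(keys)) stop("duplicate entity keys", call. = FALSE)
  vals <- vapply(ents, function(v) {
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE)
    else as.character(v)
  }, character(1))
  ord <- order(match(keys, g$entity_order))
  keys <- keys[ord]; vals <- vals[ord]
  for (i in seq_along(keys)) {
    pat <- if (keys[i] == "run") g$run_pattern else g$label_pattern
    if (!grepl(pat, vals[i])) {
      stop("invalid label '", vals[i], "' for entity '", keys[i], "'",
           call. = FALSE)
    }
  }
  if (missing(suffix) || !is.character(suffix) || length(suffix) != 1L) {
    stop("suffix is required", call. = FALSE)
  }
  if (!suffix %in% names(g$suffixes)) {
    stop("unknown suffix '", suffix, "'", call. = FALSE)
  }
  ents_out <- stats::setNames(vals, keys)
  structure(list(entities = ents_out, suffix = suffix,
                 extension = as.character(extension)),
            class = "entity_set")
}

#' @export
print.entity_set <- function(x, ...) {
  cat("<entity_set> ", build_name(x, partial = TRUE), "\n", sep = "")
  invisible(x)
}

#' @export
format.entity_set <- function(x, ...) build_name(x, partial = TRUE)

is_entity_set <- function(x) inherits(x, "entity_set")

reject_name <- function(reason, filename, detail = "") {
  structure(list(reason = reason, filename = filename, detail = detail),
            class = "name_rejection")
}

#' Test for a rejected filename parse
#' @param x Result of [parse_name()].
#' @return `TRUE` if `x` is a structured rejection (with a `$reason` code).
#' @export
is_rejection <- function(x) inherits(x, "name_rejection")

#' @export
print.name_rejection <- function(x, ...) {
  cat("<name_rejection> '", x$filename, "': ", x$reason,
      if (nzchar(x$detail)) paste0(" (", x$detail, ")") else "", "\n",
      sep = "")
  invisible(x)
}

#' Parse a BIDS filename into an entity set
#'
#' Accepts names of the form
#' `[sub-<L>][_ses-<L>][_task-<L>][_acq-<L>][_run-<D>][_proc-<L>]_<suffix>[.<ext>]`
#' with entities in canonical order, plus the study-level literals
#' `participants.tsv`, `participants.json` and `dataset_description.json`.
#' Names with a subset of entities (e.g. a root-level `task-rest_meg.json`
#' inheritance sidecar) are accepted; whether required entities are present
#' for a *data* file is checked by [build_name()] and the validator, not by
#' the parser.
#'
#' Non-matching names are never an error: a structured rejection is returned
#' carrying exactly one reason code from `no-match`, `bad-key`, `bad-label`,
#' `bad-order`, `bad-suffix`.
#'
#' @param filename A final path component (no directory separators).
#' @return An [entity_set()] on success, otherwise a `name_rejection` with
#'   fields `reason`, `filename`, `detail`.
#' @export
#' @examples
#' parse_name("sub-01_ses-01_task-rest_run-01_meg.json")
#' parse_name("sub-01_run-01_task-rest_meg.fif")$reason  # "bad-order"
parse_name <- function(filename) {
  stopifnot(is.character(filename), length(filename) == 1L, !is.na(filename))
  if (grepl("[/\\\\]", filename)) {
    stop("filename must be a final path component, not a path", call. = FALSE)
  }
  g <- bids_grammar()
  lit <- g$study_level_names[[filename]]
  if (!is.null(lit)) {
    return(structure(list(entities = stats::setNames(character(0),
                                                     character(0)),
                          suffix = lit$suffix, extension = lit$extension),
                     class = "entity_set"))
  }
  tokens <- strsplit(filename, "_", fixed = TRUE)[[1]]
  if (length(tokens) < 2L || any(!nzchar(tokens))) {
    return(reject_name("no-match", filename,
                       "expected <entities>_<suffix>[.<ext>]"))
  }
  last <- tokens[length(tokens)]
  m <- regmatches(last, regexec("^([A-Za-z0-9]+)(?:\\.([A-Za-z0-9.]+))?$",
                                last))[[1]]
  if (!length(m)) {
    return(reject_name("no-match", filename, "malformed suffix component"))
  }
  suffix <- m[2]
  extension <- if (nzchar(m[3])) m[3] else NA_character_
  ent_tok <- tokens[-length(tokens)]
  km <- regmatches(ent_tok, regexec("^([a-zA-Z0-9]+)-(.*)$", ent_tok))
  if (any(vapply(km, length, integer(1)) == 0L)) {
    return(reject_name("no-match", filename,
                       "entity component without key-value hyphen"))
  }
  keys <- vapply(km, `[`, character(1), 2L)
  vals <- vapply(km, `[`, character(1), 3L)
  unknown <- setdiff(keys, g$entity_order)
  if (length(unknown)) {
    return(reject_name("bad-key", filename,
                       paste("unknown key:", paste(unknown, collapse = ", "))))
  }
  for (i in seq_along(keys)) {
    pat <- if (keys[i] == "run") g$run_pattern else g$label_pattern
    if (!grepl(pat, vals[i])) {
      return(reject_name("bad-label", filename,
                         paste0("invalid label '", vals[i], "' for key '",
                                keys[i], "'")))
    }
  }
  idx <- match(keys, g$entity_order)
  if (anyDuplicated(keys) || is.unsorted(idx, strictly = TRUE)) {
    return(reject_name("bad-order", filename,
                       paste("canonical order is",
                             paste(g$entity_order, collapse = " < "))))
  }
  if (!suffix %in% names(g$suffixes)) {
    return(reject_name("bad-suffix", filename,
                       paste0("unknown suffix '", suffix, "'")))
  }
  structure(list(entities = stats::setNames(vals, keys), suffix = suffix,
                 extension = extension),
            class = "entity_set")
}

#' Build the canonical filename for an entity set
#'
#' Inverse of [parse_name()]: entities are emitted in canonical order,
#' `run` zero-padded to `run_width` digits (tolerant reader, canonical
#' writer: any digit count parses, the writer pads).
#'
#' @param x An [entity_set()].
#' @param run_width Zero-pad width for the run index (default 2).
#' @param partial If `TRUE`, do not enforce the suffix's required entities
#'   (used for inheritance sidecars higher in the tree, which drop
#'   entities on purpose).
#' @return The filename string.
#' @export
#' @examples
#' build_name(entity_set(sub = "01", task = "noise", run = 1,
#'                       suffix = "meg", extension = "ds"))
build_name <- function(x, run_width = NULL, partial = FALSE) {
  stopifnot(is_entity_set(x))
  g <- bids_grammar()
  if (is.null(run_width)) run_width <- g$run_pad_width
  rule <- g$suffixes[[x$suffix]]
  if (is.null(rule)) stop("unknown suffix '", x$suffix, "'", call. = FALSE)
  if (!partial) {
    missing_req <- setdiff(unlist(rule$required), names(x$entities))
    if (length(missing_req)) {
      stop("missing required entity '", missing_req[1], "' for suffix '",
           x$suffix, "'", call. = FALSE)
    }
  }
  vals <- x$entities
  if ("run" %in% names(vals)) {
    r <- vals[["run"]]
    if (nchar(r) < run_width) {
      vals[["run"]] <- paste0(strrep("0", run_width - nchar(r)), r)
    }
  }
  parts <- if (length(vals)) paste0(names(vals), "-", vals) else character(0)
  stem <- paste(c(parts, x$suffix), collapse = "_")
  if (!is.na(x$extension) && nzchar(x$extension)) {
    paste0(stem, ".", x$extension)
  } else {
    stem
  }
}

#' Expected directory for an entity set
#'
#' Placement rules: run-item MEG artifacts (`meg`, `channels`, `events`) go
#' under `sub-<L>[/ses-<L>]/meg`; anatomical files under
#' `sub-<L>[/ses-<L>]/anat`; session-specific files (`coordsystem`,
#' `headshape`, `photo`, `scans`) at the `sub-<L>[/ses-<L>]` level; study
#' files and entity sets without a `sub` entity (root-level inheritance
#' sidecars) at the dataset root.
#'
#' @param x An [entity_set()].
#' @return Relative directory path (`""` for the dataset root), using
#'   forward slashes, no trailing slash.
#' @export
#' @examples
#' expected_location(entity_set(sub = "01", ses = "02",
#'                              suffix = "coordsystem", extension = "json"))
expected_location <- function(x) {
  stopifnot(is_entity_set(x))
  g <- bids_grammar()
  rule <- g$suffixes[[x$suffix]]
  if (is.null(rule)) stop("unknown suffix '", x$suffix, "'", call. = FALSE)
  has_sub <- "sub" %in% names(x$entities)
  if (rule$placement == "root" || !has_sub) return("")
  sub <- x$entities[["sub"]]
  base <- paste0("sub-", sub)
  ses <- if ("ses" %in% names(x$entities)) x$entities[["ses"]] else NULL
  if (!is.null(ses)) base <- paste0(base, "/ses-", ses)
  switch(rule$placement,
         session = base,
         meg = paste0(base, "/meg"),
         anat = paste0(base, "/anat"),
         stop("unknown placement '", rule$placement, "'", call. = FALSE))
}

# TRUE when a name parses as a directory-style raw payload (e.g. CTF .ds)
is_directory_payload_name <- function(es) {
  if (!is_entity_set(es)) return(FALSE)
  rule <- bids_grammar()$suffixes[[es$suffix]]
  !is.na(es$extension) &&
    es$extension %in% unlist(rule$directory_extensions)
}
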