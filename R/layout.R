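# sort with a locale-independent collation so scans are deterministic
sort_c <- function(x) sort(x, method = "radix")

artifact_level <- function(es) {
  rule <- bids_grammar()$suffixes[[es$suffix]]
  switch(rule$placement,
         root = "study",
         session = if ("ses" %in% names(es$entities)) "session" else "subject",
         "run-item")
}

empty_artifacts <- function() {
  data.frame(relative_path = character(0), sub = character(0),
             ses = character(0), task = character(0), acq = character(0),
             run = character(0), proc = character(0), suffix = character(0),
             extension = character(0), level = character(0),
             is_directory_payload = logical(0), stringsAsFactors = FALSE)
}

artifact_row <- function(relpath, es, is_dir) {
  e <- function(k) {
    if (k %in% names(es$entities)) es$entities[[k]] else NA_character_
  }
  data.frame(relative_path = relpath, sub = e("sub"), ses = e("ses"),
             task = e("task"), acq = e("acq"), run = e("run"),
             proc = e("proc"), suffix = es$suffix,
             extension = es$extension, level = artifact_level(es),
             is_directory_payload = is_dir, stringsAsFactors = FALSE)
}

#' Rebuild the entity set of an artifact row
#'
#' @param artifact One row of a tree's `artifacts` table (or a list with the
#'   same fields).
#' @return An [entity_set()].
#' @export
artifact_entities <- function(artifact) {
  ents <- list()
  for (k in entity_keys()) {
    v <- artifact[[k]]
    if (length(v) == 1L && !is.na(v)) ents[[k]] <- v
  }
  do.call(entity_set, c(ents, list(suffix = artifact[["suffix"]],
                                   extension = artifact[["extension"]])))
}

#' Scan a directory into a dataset tree model
#'
#' Walks the directory recursively with deterministic (byte-order sorted)
#' enumeration and classifies every path against the filename grammar.
#' Directory-style raw payloads (e.g. CTF `*_meg.ds` folders) are recorded
#' as single leaf artifacts and never descended into — raw vendor payloads
#' are opaque. Paths that match no pattern land in `unclassified` together
#' with the parser's rejection reason; nothing is silently dropped.
#'
#' By default `derivatives/`, `sourcedata/`, `code/`, `stimuli/` and hidden
#' files are ignored.
#'
#' @param root Dataset root directory.
#' @param ignore Top-level directory names to skip.
#' @return An object of class `megbids_tree`: list with `root`, `artifacts`
#'   (data frame, one row per artifact, lexicographically sorted by
#'   `relative_path`), `subjects`, `sessions` (named list sub -> ses
#'   labels), `unclassified` (data frame `relative_path`, `note`).
#' @export
scan_tree <- function(root,
                      ignore = c("derivatives", "sourcedata", "code",
                                 "stimuli")) {
  if (length(root) != 1L || !dir.exists(root)) {
    stop("dataset root '", root, "' is not an existing directory",
         call. = FALSE)
  }
  arts <- list()
  uncl_path <- character(0)
  uncl_note <- character(0)
  subjects <- character(0)
  sessions <- list()

  walk <- function(rel, depth) {
    abs <- if (nzchar(rel)) file.path(root, rel) else root
    entries <- tryCatch(sort_c(list.files(abs, all.files = FALSE)),
                        error = function(e) e)
    if (inherits(entries, "error")) {
      uncl_path <<- c(uncl_path, rel)
      uncl_note <<- c(uncl_note,
                      paste("read failure:", conditionMessage(entries)))
      return(invisible())
    }
    for (name in entries) {
      relpath <- if (nzchar(rel)) paste(rel, name, sep = "/") else name
      abspath <- file.path(root, relpath)
      isdir <- dir.exists(abspath)
      if (depth == 0L && isdir && name %in% ignore) next
      if (isdir) {
        es <- parse_name(name)
        if (is_entity_set(es) && is_directory_payload_name(es)) {
          arts[[length(arts) + 1L]] <<- artifact_row(relpath, es, TRUE)
          next
        }
        if (depth == 0L && grepl("^sub-[A-Za-z0-9]+$", name)) {
          lab <- sub("^sub-", "", name)
          subjects <<- c(subjects, lab)
          if (is.null(sessions[[lab]])) sessions[[lab]] <<- character(0)
        }
        if (depth == 1L && grepl("^ses-[A-Za-z0-9]+$", name) &&
            grepl("^sub-", rel)) {
          lab <- sub("^sub-", "", rel)
          sessions[[lab]] <<- c(sessions[[lab]], sub("^ses-", "", name))
        }
        walk(relpath, depth + 1L)
      } else {
        es <- parse_name(name)
        if (is_entity_set(es)) {
          arts[[length(arts) + 1L]] <<- artifact_row(relpath, es, FALSE)
        } else {
          uncl_path <<- c(uncl_path, relpath)
          uncl_note <<- c(uncl_note,
                          paste0("reason=", es$reason,
                                 if (nzchar(es$detail)) paste0("; ", es$detail)
                                 else ""))
        }
      }
    }
    invisible()
  }
  walk("", 0L)

  artifacts <- if (length(arts)) do.call(rbind, arts) else empty_artifacts()
  ord <- order(artifacts$relative_path, method = "radix")
  artifacts <- artifacts[ord, , drop = FALSE]
  rownames(artifacts) <- NULL
  uncl <- data.frame(relative_path = uncl_path, note = uncl_note,
                     stringsAsFactors = FALSE)
  uncl <- uncl[order(uncl$relative_path, method = "radix"), , drop = FALSE]
  rownames(uncl) <- NULL
  structure(list(root = normalizePath(root, winslash = "/"),
                 artifacts = artifacts,
                 subjects = sort_c(unique(subjects)),
                 sessions = lapply(sessions, function(s) sort_c(unique(s))),
                 unclassified = uncl,
                 ignore = ignore),
            class = "megbids_tree")
}

#' @export
print.megbids_tree <- function(x, ...) {
  cat("<megbids_tree> ", x$root, "\n",
      "  subjects:     ", length(x$subjects), "\n",
      "  artifacts:    ", nrow(x$artifacts), "\n",
      "  unclassified: ", nrow(x$unclassified), "\n", sep = "")
  invisible(x)
}

is_megbids_tree <- function(x) inherits(x, "megbids_tree")

#' Query artifacts of a dataset tree
#'
#' Returns exactly the artifacts whose entity sets contain the filter as a
#' submap, in stable (lexicographic by `relative_path`) order.
#'
#' @param tree A `megbids_tree` from [scan_tree()].
#' @param ... Entity filters by key (e.g. `sub = "01"`, `task = "rest"`).
#' @param suffix,extension Optional suffix / extension filters.
#' @return Subset of `tree$artifacts` (data frame).
#' @export
#' @examples
#' \dontrun{query(tree, sub = "01", suffix = "meg")}
query <- function(tree, ..., suffix = NULL, extension = NULL) {
  stopifnot(is_megbids_tree(tree))
  filt <- list(...)
  bad <- setdiff(names(filt), entity_keys())
  if (length(filt) && (is.null(names(filt)) || any(!nzchar(names(filt))) ||
                       length(bad))) {
    stop("unknown filter key(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         call. = FALSE)
  }
  a <- tree$artifacts
  keep <- rep(TRUE, nrow(a))
  for (k in names(filt)) {
    keep <- keep & !is.na(a[[k]]) & a[[k]] == as.character(filt[[k]])
  }
  if (!is.null(suffix)) keep <- keep & a$suffix == suffix
  if (!is.null(extension)) keep <- keep & !is.na(a$extension) &
      a$extension == extension
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a tree inventory as TSV
#'
#' One row per artifact with columns `relative_path`, the six entity keys,
#' `suffix` and `extension`; missing entities encoded as `n/a`.
#'
#' @param tree A `megbids_tree`.
#' @param path Output file, or `NULL` to return the lines invisibly.
#' @return The TSV lines, invisibly.
#' @export
write_inventory <- function(tree, path = NULL) {
  stopifnot(is_megbids_tree(tree))
  cols <- c("relative_path", entity_keys(), "suffix", "extension")
  a <- tree$artifacts[, cols, drop = FALSE]
  for (j in seq_along(a)) a[[j]][is.na(a[[j]])] <- "n/a"
  body <- if (nrow(a)) apply(a, 1L, paste, collapse = "\t") else character(0)
  lines <- c(paste(cols, collapse = "\t"), body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
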