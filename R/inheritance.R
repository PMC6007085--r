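path_depth <- function(relpath) {
  d <- dirname(relpath)
  if (d == ".") 0L else length(strsplit(d, "/", fixed = TRUE)[[1]])
}

path_dir <- function(relpath) {
  d <- dirname(relpath)
  if (d == ".") "" else d
}

# is `dir` the dataset root or an ancestor-or-self of `target_dir`?
dir_on_path <- function(dir, target_dir) {
  if (dir == "") return(TRUE)
  if (dir == target_dir) return(TRUE)
  startsWith(target_dir, paste0(dir, "/"))
}

n_entities_row <- function(row) {
  sum(!is.na(unlist(row[entity_keys()])))
}

resolve_target_row <- function(tree, target) {
  if (is.character(target)) {
    hit <- tree$artifacts[tree$artifacts$relative_path == target, ,
                          drop = FALSE]
    if (nrow(hit) != 1L) {
      stop("target '", target, "' is not an artifact of this tree",
           call. = FALSE)
    }
    hit
  } else {
    as.data.frame(target, stringsAsFactors = FALSE)
  }
}

megbids_ambiguity <- function(paths, target) {
  structure(class = c("megbids_ambiguity", "error", "condition"),
            list(message = paste0("ambiguous sidecars for '", target,
                                  "' at equal depth and specificity: ",
                                  paste(paths, collapse = ", ")),
                 call = NULL, paths = paths))
}

#' Sidecars applicable to a data artifact
#'
#' A sidecar applies to a target when its entity set is a submap of the
#' target's (every entity it carries is present in the target with the same
#' value) and it lives at the dataset root or in a directory on the path
#' down to the target. The result is ordered shallowest-first, then by
#' entity count ascending, i.e. least to most specific — the order in which
#' the inheritance merge applies them. Two distinct applicable sidecars at
#' the same depth with the same entity count are refused as ambiguous
#' (condition class `megbids_ambiguity`) rather than silently ordered.
#'
#' @param tree A `megbids_tree`.
#' @param target Relative path of a data artifact (or its row).
#' @param suffix Sidecar suffix to collect (default `"meg"`).
#' @param extension Sidecar extensions considered metadata (default
#'   `"json"`; use `"tsv"` for table sidecars).
#' @return Subset of `tree$artifacts` with extra columns `depth` and
#'   `n_entities`, in application order.
#' @export
applicable_sidecars <- function(tree, target, suffix = "meg",
                                extension = "json") {
  stopifnot(is_megbids_tree(tree))
  trow <- resolve_target_row(tree, target)
  tdir <- path_dir(trow$relative_path)
  a <- tree$artifacts
  cand <- a[a$suffix == suffix & !is.na(a$extension) &
              a$extension %in% extension &
              a$relative_path != trow$relative_path, , drop = FALSE]
  if (!nrow(cand)) {
    cand$depth <- integer(0); cand$n_entities <- integer(0)
    return(cand)
  }
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!dir_on_path(path_dir(cand$relative_path[i]), tdir)) next
    ok <- TRUE
    for (k in entity_keys()) {
      cv <- cand[[k]][i]
      if (!is.na(cv) && (is.na(trow[[k]]) || trow[[k]] != cv)) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) {
    cand$depth <- integer(0); cand$n_entities <- integer(0)
    return(cand)
  }
  cand$depth <- vapply(cand$relative_path, path_depth, integer(1),
                       USE.NAMES = FALSE)
  cand$n_entities <- vapply(seq_len(nrow(cand)),
                            function(i) n_entities_row(cand[i, ]),
                            integer(1))
  ord <- order(cand$depth, cand$n_entities, cand$relative_path,
               method = "radix")
  cand <- cand[ord, , drop = FALSE]
  dup <- duplicated(cand[, c("depth", "n_entities")])
  if (any(dup)) {
    i <- which(dup)[1]
    tied <- cand$relative_path[cand$depth == cand$depth[i] &
                                 cand$n_entities == cand$n_entities[i]]
    stop(megbids_ambiguity(tied, trow$relative_path))
  }
  rownames(cand) <- NULL
  cand
}

megbids_resolution_error <- function(path, why) {
  structure(class = c("megbids_resolution_error", "error", "condition"),
            list(message = paste0("cannot resolve: applicable sidecar '",
                                  path, "' ", why),
                 call = NULL, path = path))
}

#' Resolve effective metadata under the inheritance principle
#'
#' Applies every applicable JSON sidecar in order (shallowest and least
#' specific first), merging key-by-key so that the file closer to the data
#' prevails field-wise. Returns the effective map plus full provenance:
#' which file contributed each surviving key.
#'
#' @inheritParams applicable_sidecars
#' @return Object of class `resolution_trace`: list with `target`,
#'   `applied` (data frame `path`, `depth`, `n_entities`,
#'   `keys_contributed`), `effective` (named list).
#' @export
resolve_sidecar <- function(tree, target, suffix = "meg") {
  trow <- resolve_target_row(tree, target)
  app <- applicable_sidecars(tree, target, suffix = suffix,
                             extension = "json")
  effective <- list()
  docs <- vector("list", nrow(app))
  for (i in seq_len(nrow(app))) {
    p <- file.path(tree$root, app$relative_path[i])
    r <- read_json_sidecar(p)
    if (is.null(r$document)) {
      stop(megbids_resolution_error(app$relative_path[i],
                                    "is not readable as JSON"))
    }
    docs[[i]] <- r$document
    effective[names(r$document)] <- r$document
  }
  contributed <- character(nrow(app))
  for (i in seq_len(nrow(app))) {
    keys <- names(docs[[i]])
    final <- vapply(keys, function(k) {
      later <- seq_len(nrow(app)) > i
      !any(vapply(which(later), function(j) k %in% names(docs[[j]]),
                  logical(1)))
    }, logical(1))
    contributed[i] <- paste(keys[final], collapse = ",")
  }
  applied <- data.frame(path = app$relative_path, depth = app$depth,
                        n_entities = app$n_entities,
                        keys_contributed = contributed,
                        stringsAsFactors = FALSE)
  structure(list(target = trow$relative_path, suffix = suffix,
                 applied = applied, effective = effective),
            class = "resolution_trace")
}

#' @export
print.resolution_trace <- function(x, ...) {
  cat("<resolution_trace> ", x$target, " (suffix ", x$suffix, ")\n",
      sep = "")
  for (i in seq_len(nrow(x$applied))) {
    cat("  [", i, "] depth ", x$applied$depth[i], ", ",
        x$applied$n_entities[i], " entities: ", x$applied$path[i], "\n",
        sep = "")
  }
  cat("  effective keys: ", paste(names(x$effective), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Render a resolution trace as JSON
#' @param trace A `resolution_trace`.
#' @return JSON string (pretty-printed, trailing newline).
#' @export
trace_to_json <- function(trace) {
  stopifnot(inherits(trace, "resolution_trace"))
  payload <- list(target = trace$target, suffix = trace$suffix,
                  applied = trace$applied, effective = trace$effective)
  paste0(jsonlite::toJSON(payload, pretty = 4, auto_unbox = TRUE,
                          digits = NA, dataframe = "rows"), "\n")
}

#' Resolve an inherited TSV table (whole-file precedence)
#'
#' Row-level merging of tables is undefined, so for TSV sidecars the
#' deepest (most specific) applicable table wins outright.
#'
#' @inheritParams applicable_sidecars
#' @param schema Schema id passed to [read_tsv_table()].
#' @return List with `path` (relative path of the winning table, or `NULL`
#'   when none applies) and the winning [read_tsv_table()] result.
#' @export
resolve_table <- function(tree, target, suffix = "channels",
                          schema = suffix) {
  app <- applicable_sidecars(tree, target, suffix = suffix,
                             extension = "tsv")
  if (!nrow(app)) return(list(path = NULL, result = NULL))
  winner <- app$relative_path[nrow(app)]
  list(path = winner,
       result = read_tsv_table(file.path(tree$root, winner),
                               schema = schema))
}
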