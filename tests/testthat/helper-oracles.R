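# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (enumeration, brute force, string pasting) so that the
# package's own grammar/merge logic is never used to produce its own
# expected values.

rand_label <- function(n = 1, min_len = 1, max_len = 6) {
  alphabet <- c(letters, LETTERS, 0:9)
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# A random valid entity set, returned as plain pieces plus the hand-pasted
# canonical filename (independent of build_name()).
random_valid_name <- function() {
  g <- list(
    meg = list(req = c("sub", "task"), opt = c("ses", "acq", "run", "proc"),
               ext = c("json", "fif", "ds", "con", "sqd")),
    channels = list(req = c("sub", "task"),
                    opt = c("ses", "acq", "run", "proc"), ext = "tsv"),
    events = list(req = c("sub", "task"),
                  opt = c("ses", "acq", "run", "proc"), ext = "tsv"),
    coordsystem = list(req = "sub", opt = c("ses", "acq"), ext = "json"),
    scans = list(req = "sub", opt = "ses", ext = "tsv"),
    photo = list(req = "sub", opt = c("ses", "acq"), ext = "jpg"),
    headshape = list(req = "sub", opt = c("ses", "acq"), ext = "pos"),
    T1w = list(req = "sub", opt = c("ses", "acq", "run"),
               ext = c("json", "nii")))
  order <- c("sub", "ses", "task", "acq", "run", "proc")
  suffix <- sample(names(g), 1)
  rule <- g[[suffix]]
  keys <- union(rule$req, rule$opt[stats::runif(length(rule$opt)) < 0.5])
  keys <- order[order %in% keys]
  vals <- stats::setNames(rand_label(length(keys)), keys)
  if ("run" %in% keys) {
    vals[["run"]] <- sprintf("%02d", sample(1:99, 1))
  }
  ext <- sample(rule$ext, 1)
  name <- paste0(paste(paste0(keys, "-", vals), collapse = "_"), "_",
                 suffix, ".", ext)
  list(name = name, entities = vals, suffix = suffix, extension = ext)
}

# Corrupt a valid name so that it must be rejected.
corrupt_name <- function(valid) {
  kind <- sample(c("swap", "bad-key", "bad-label", "bad-suffix",
                   "no-match"), 1)
  name <- valid$name
  switch(kind,
    swap = {
      # reversing all entities breaks canonical order when >= 2 entities;
      # otherwise fall through to a bad key
      ks <- names(valid$entities)
      if (length(ks) >= 2) {
        parts <- paste0(rev(ks), "-", rev(valid$entities))
        paste0(paste(parts, collapse = "_"), "_", valid$suffix, ".",
               valid$extension)
      } else paste0("zzz-9_", name)
    },
    `bad-key` = paste0("qqq-7_", sub("^sub-", "xub-", name)),
    `bad-label` = sub("^sub-([A-Za-z0-9])", "sub-\\1%", name),
    `bad-suffix` = sub(paste0("_", valid$suffix, "\\."), "_nonsuffix.",
                       name),
    `no-match` = gsub("_", "", name, fixed = TRUE))
}

# Brute-force inheritance oracle: membership by subset test over every
# sidecar, order by (depth, entity count), left fold of key-level merges.
oracle_applicable <- function(tree, target_rel, suffix, extension = "json") {
  a <- tree$artifacts
  trow <- a[a$relative_path == target_rel, , drop = FALSE]
  tdir <- dirname(target_rel)
  if (tdir == ".") tdir <- ""
  keys <- c("sub", "ses", "task", "acq", "run", "proc")
  hits <- list()
  for (i in seq_len(nrow(a))) {
    if (a$suffix[i] != suffix) next
    if (is.na(a$extension[i]) || !a$extension[i] %in% extension) next
    if (a$relative_path[i] == target_rel) next
    cdir <- dirname(a$relative_path[i])
    if (cdir == ".") cdir <- ""
    on_path <- cdir == "" || cdir == tdir ||
      startsWith(tdir, paste0(cdir, "/"))
    if (!on_path) next
    submap <- TRUE
    for (k in keys) {
      if (!is.na(a[[k]][i]) &&
            (is.na(trow[[k]]) || trow[[k]] != a[[k]][i])) {
        submap <- FALSE
        break
      }
    }
    if (!submap) next
    depth <- if (cdir == "") 0L else
      length(strsplit(cdir, "/", fixed = TRUE)[[1]])
    hits[[length(hits) + 1L]] <- list(path = a$relative_path[i],
                                      depth = depth,
                                      count = sum(!is.na(unlist(
                                        a[i, keys]))))
  }
  if (!length(hits)) return(list(paths = character(0), effective = list()))
  depths <- vapply(hits, `[[`, 0L, "depth")
  counts <- vapply(hits, `[[`, 0L, "count")
  paths <- vapply(hits, `[[`, "", "path")
  ord <- order(depths, counts, paths)
  paths <- paths[ord]
  eff <- list()
  for (p in paths) {
    doc <- jsonlite::fromJSON(file.path(tree$root, p),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
    eff <- utils::modifyList(eff, doc)
  }
  list(paths = paths, effective = eff)
}

# A tiny on-disk tree with layered meg.json sidecars and one raw target,
# written with plain file primitives (not the curator).
layered_tree <- function(dir, seed) {
  set.seed(seed)
  dir.create(file.path(dir, "sub-01", "meg"), recursive = TRUE)
  task <- sample(c("rest", "faces"), 1)
  raw <- sprintf("sub-01_task-%s_run-01_meg.fif", task)
  writeBin(as.raw(1:16), file.path(dir, "sub-01", "meg", raw))
  keypool <- c("PowerLineFrequency", "DewarPosition", "InstitutionName",
               "RecordingType", "Manufacturer")
  rand_doc <- function() {
    ks <- sample(keypool, sample(1:3, 1))
    stats::setNames(as.list(paste0("v", sample(1:9, length(ks)))), ks)
  }
  wj <- function(path, doc) {
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE),
               path)
  }
  if (stats::runif(1) < 0.8) {
    wj(file.path(dir, sprintf("task-%s_meg.json", task)), rand_doc())
  }
  if (stats::runif(1) < 0.5) {
    wj(file.path(dir, "sub-01",
                 sprintf("sub-01_task-%s_meg.json", task)), rand_doc())
  }
  if (stats::runif(1) < 0.9) {
    wj(file.path(dir, "sub-01", "meg",
                 sprintf("sub-01_task-%s_run-01_meg.json", task)),
       rand_doc())
  }
  # a sidecar for another task: applicable to nothing here
  if (stats::runif(1) < 0.4) {
    wj(file.path(dir, "task-nap_meg.json"), rand_doc())
  }
  file.path("sub-01", "meg", raw)
}

sorted_keys <- function(l) if (length(l)) l[order(names(l))] else l

copy_tree <- function(from, to) {
  dir.create(to, recursive = TRUE, showWarnings = FALSE)
  file.copy(list.files(from, full.names = TRUE), to, recursive = TRUE)
}

small_spec <- function(seed = 1L, ...) {
  fixture_spec(seed = seed, n_sub = 1L, n_ses = 1L, n_task = 1L,
               n_run = 2L, ...)
}

tree_md5 <- function(root) {
  files <- sort(list.files(root, recursive = TRUE))
  structure(as.character(tools::md5sum(file.path(root, files))),
            names = files)
}
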