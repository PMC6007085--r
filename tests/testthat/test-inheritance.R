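test_that("the file closer to the data prevails, key by key", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "sub-01", "meg"), recursive = TRUE)
  writeBin(as.raw(1:8), file.path(root, "sub-01", "meg",
                                  "sub-01_task-rest_run-01_meg.fif"))
  writeLines(jsonlite::toJSON(list(PowerLineFrequency = 60),
                              auto_unbox = TRUE),
             file.path(root, "task-rest_meg.json"))
  writeLines(jsonlite::toJSON(list(PowerLineFrequency = 50,
                                   DewarPosition = "upright"),
                              auto_unbox = TRUE),
             file.path(root, "sub-01", "meg",
                       "sub-01_task-rest_run-01_meg.json"))
  tree <- scan_tree(root)
  target <- "sub-01/meg/sub-01_task-rest_run-01_meg.fif"

  app <- applicable_sidecars(tree, target, suffix = "meg")
  expect_identical(app$relative_path,
                   c("task-rest_meg.json",
                     "sub-01/meg/sub-01_task-rest_run-01_meg.json"))

  trace <- resolve_sidecar(tree, target)
  expect_identical(trace$effective$PowerLineFrequency, 50L)
  expect_identical(trace$effective$DewarPosition, "upright")
  # provenance: the run-level file is the final contributor of both keys
  expect_identical(trace$applied$keys_contributed[2],
                   "PowerLineFrequency,DewarPosition")
  expect_identical(trace$applied$keys_contributed[1], "")
})

test_that("sidecars with mismatching entities never apply", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "sub-01", "meg"), recursive = TRUE)
  writeBin(as.raw(1:8), file.path(root, "sub-01", "meg",
                                  "sub-01_task-rest_run-01_meg.fif"))
  writeLines(jsonlite::toJSON(list(DewarPosition = "supine"),
                              auto_unbox = TRUE),
             file.path(root, "task-faces_meg.json"))
  tree <- scan_tree(root)
  app <- applicable_sidecars(tree,
                             "sub-01/meg/sub-01_task-rest_run-01_meg.fif")
  expect_equal(nrow(app), 0L)
  # single applicable file: effective equals its content
  writeLines(jsonlite::toJSON(list(DewarPosition = "upright"),
                              auto_unbox = TRUE),
             file.path(root, "sub-01", "meg",
                       "sub-01_task-rest_run-01_meg.json"))
  tree <- scan_tree(root)
  trace <- resolve_sidecar(tree,
                           "sub-01/meg/sub-01_task-rest_run-01_meg.fif")
  expect_identical(trace$effective, list(DewarPosition = "upright"))
})

test_that("equal depth and specificity is refused as ambiguous", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "sub-01", "meg"), recursive = TRUE)
  writeBin(as.raw(1:8), file.path(root, "sub-01", "meg",
                                  "sub-01_task-rest_run-01_meg.fif"))
  writeLines("{}", file.path(root, "task-rest_meg.json"))
  writeLines("{}", file.path(root, "run-01_meg.json"))
  tree <- scan_tree(root)
  expect_error(
    applicable_sidecars(tree,
                        "sub-01/meg/sub-01_task-rest_run-01_meg.fif"),
    class = "megbids_ambiguity")
})

test_that("adding an inapplicable sidecar never changes resolution", {
  root <- withr::local_tempdir()
  target <- layered_tree(root, seed = 31)
  before <- resolve_sidecar(scan_tree(root), target)$effective
  writeLines(jsonlite::toJSON(list(DewarPosition = "tilted"),
                              auto_unbox = TRUE),
             file.path(root, "task-zzz_meg.json"))
  after <- resolve_sidecar(scan_tree(root), target)$effective
  expect_identical(before, after)
})

test_that("resolution equals the sort-and-fold oracle on random trees", {
  for (seed in 1:60) {
    root <- withr::local_tempdir()
    target <- layered_tree(root, seed = 1000 + seed)
    tree <- scan_tree(root)
    oracle <- oracle_applicable(tree, target, "meg")
    got <- tryCatch(resolve_sidecar(tree, target),
                    megbids_ambiguity = function(e) e)
    expect_false(inherits(got, "megbids_ambiguity"), info = seed)
    expect_identical(got$applied$path, oracle$paths, info = seed)
    expect_identical(sorted_keys(got$effective),
                     sorted_keys(oracle$effective), info = seed)
    unlink(root, recursive = TRUE)
  }
})

path_depth_public <- function(p) length(strsplit(dirname(p), "/")[[1]])
manufacturer_channel_total <- function() {
  c(MEGGRADAXIAL = 274, MEGREFMAG = 28, EOG = 2, ECG = 1, TRIG = 1)
}

test_that("TSV inheritance is whole-file: the deepest table wins", {
  out <- withr::local_tempdir("tsvinh")
  unlink(out, recursive = TRUE)
  res <- generate_dataset(small_spec(21), out)
  tree <- res$tree
  raw <- query(tree, task = "rest", suffix = "meg", extension = "ds")
  ch <- resolve_table(tree, raw$relative_path[1], suffix = "channels")
  expect_identical(path_depth_public(ch$path),
                   path_depth_public(raw$relative_path[1]))
  expect_equal(nrow(ch$result$table),
               sum(manufacturer_channel_total()))
})
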