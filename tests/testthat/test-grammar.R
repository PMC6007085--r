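test_that("canonical names parse into their entity sets", {
  es <- parse_name("sub-01_ses-01_task-rest_run-01_meg.json")
  expect_s3_class(es, "entity_set")
  expect_identical(es$entities,
                   c(sub = "01", ses = "01", task = "rest", run = "01"))
  expect_identical(es$suffix, "meg")
  expect_identical(es$extension, "json")

  es2 <- parse_name("sub-01_task-rest_run-01_meg.ds")
  expect_identical(es2$extension, "ds")

  lit <- parse_name("participants.tsv")
  expect_identical(lit$suffix, "participants")
  expect_length(lit$entities, 0L)

  root_sidecar <- parse_name("task-rest_meg.json")
  expect_identical(root_sidecar$entities, c(task = "rest"))
})

test_that("every malformed name gets exactly one reason code", {
  cases <- list(
    list("sub-01_run-01_task-rest_meg.fif", "bad-order"),
    list("sub-01_sub-02_task-rest_meg.fif", "bad-order"),
    list("sub-01_space-x_task-rest_meg.fif", "bad-key"),
    list("sub-01_task-re.st_meg.fif", "bad-label"),
    list("sub-01_run-0a_meg.fif", "bad-label"),
    list("sub-01_task-rest_banana.fif", "bad-suffix"),
    list("README", "no-match"),
    list("sub-01", "no-match"),
    list("task_meg.json", "no-match"))
  codes <- c("no-match", "bad-key", "bad-label", "bad-order", "bad-suffix")
  for (case in cases) {
    r <- parse_name(case[[1]])
    expect_true(is_rejection(r), info = case[[1]])
    expect_identical(r$reason, case[[2]], info = case[[1]])
    expect_true(r$reason %in% codes && length(r$reason) == 1L)
  }
})

test_that("build_name writes the canonical form", {
  expect_identical(
    build_name(entity_set(sub = "01", task = "noise", run = 1,
                          suffix = "meg", extension = "ds")),
    "sub-01_task-noise_run-01_meg.ds")
  expect_identical(
    build_name(entity_set(suffix = "participants", extension = "tsv")),
    "participants.tsv")
  expect_identical(
    build_name(entity_set(sub = "01", ses = "01", suffix = "coordsystem",
                          extension = "json")),
    "sub-01_ses-01_coordsystem.json")
  # entities given out of order are still emitted canonically
  expect_identical(
    build_name(entity_set(run = 2, sub = "01", task = "rest",
                          suffix = "meg", extension = "fif")),
    "sub-01_task-rest_run-02_meg.fif")
})

test_that("missing required entities are refused by name", {
  expect_error(build_name(entity_set(sub = "01", suffix = "meg",
                                     extension = "fif")),
               "task")
  expect_error(build_name(entity_set(task = "rest", suffix = "meg",
                                     extension = "fif")),
               "sub")
  # partial mode admits inheritance sidecars
  expect_identical(build_name(entity_set(task = "rest", suffix = "meg",
                                         extension = "json"),
                              partial = TRUE),
                   "task-rest_meg.json")
})

test_that("expected_location follows the placement table", {
  expect_identical(
    expected_location(entity_set(sub = "01", ses = "02",
                                 suffix = "coordsystem",
                                 extension = "json")),
    "sub-01/ses-02")
  expect_identical(
    expected_location(entity_set(sub = "01", task = "faces", run = 2,
                                 suffix = "events", extension = "tsv")),
    "sub-01/meg")
  expect_identical(
    expected_location(entity_set(sub = "01", suffix = "T1w",
                                 extension = "json")),
    "sub-01/anat")
  expect_identical(
    expected_location(entity_set(suffix = "dataset_description",
                                 extension = "json")),
    "")
  # root-level inheritance sidecar: no sub entity, lives at the root
  expect_identical(
    expected_location(entity_set(task = "rest", suffix = "meg",
                                 extension = "json")),
    "")
})

test_that("parse and build are mutually inverse on random entity sets", {
  set.seed(401)
  for (i in 1:200) {
    v <- random_valid_name()
    es <- parse_name(v$name)
    expect_s3_class(es, "entity_set")
    expect_identical(es$entities, v$entities, info = v$name)
    expect_identical(es$suffix, v$suffix, info = v$name)
    # build o parse is the identity on accepted names
    expect_identical(build_name(es), v$name, info = v$name)
  }
})

test_that("random corruptions are rejected with exactly one reason", {
  set.seed(402)
  codes <- c("no-match", "bad-key", "bad-label", "bad-order", "bad-suffix")
  for (i in 1:200) {
    bad <- corrupt_name(random_valid_name())
    r <- parse_name(bad)
    expect_true(is_rejection(r), info = bad)
    expect_true(length(r$reason) == 1L && r$reason %in% codes, info = bad)
  }
})
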