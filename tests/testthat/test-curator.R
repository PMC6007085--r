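one_rec_manifest <- function(staging) {
  raw <- file.path(staging, "native.fif")
  write_synthetic_raw(raw, 306, 1000, 120, seed = 9)
  list(
    dataset = list(name = "Tiny auditory study", bids_version = "1.1.0"),
    recordings = list(list(
      subject = "01", task = "rest", run = 1, raw_path = raw,
      meg_metadata = list(TaskName = "rest", SamplingFrequency = 1000,
                          PowerLineFrequency = 50,
                          DewarPosition = "upright",
                          SoftwareFilters = "n/a",
                          DigitizedLandmarks = FALSE,
                          DigitizedHeadPoints = FALSE),
      channels = list(list(name = "MEG0001", type = "MEGMAG",
                           units = "T")),
      events = list(list(onset = 1.5, duration = 0.5,
                         trial_type = "tone")),
      acq_time = "2018-06-19T10:00:00")))
}

test_that("a one-recording manifest curates into a valid canonical tree", {
  staging <- withr::local_tempdir("stage")
  out <- withr::local_tempdir("out")
  unlink(out, recursive = TRUE)
  res <- curate(one_rec_manifest(staging), out)
  expect_identical(res$report$verdict, "valid")
  expect_equal(res$report$counts[["error"]], 0L)
  expect_true(file.exists(
    file.path(out, "sub-01", "meg", "sub-01_task-rest_run-01_meg.fif")))
  expect_setequal(res$files, c(
    "dataset_description.json", "participants.tsv",
    "sub-01/meg/sub-01_task-rest_run-01_meg.fif",
    "sub-01/meg/sub-01_task-rest_run-01_meg.json",
    "sub-01/meg/sub-01_task-rest_run-01_channels.tsv",
    "sub-01/meg/sub-01_task-rest_run-01_events.tsv",
    "sub-01/sub-01_scans.tsv"))
  # the payload is copied byte-for-byte, never interpreted
  expect_identical(read_synthetic_raw(
    file.path(out, "sub-01", "meg",
              "sub-01_task-rest_run-01_meg.fif"))$n_channels, 306L)
})

test_that("duplicate recording keys and missing metadata are refused", {
  staging <- withr::local_tempdir("dup")
  m <- one_rec_manifest(staging)
  m$recordings[[2]] <- m$recordings[[1]]
  out <- withr::local_tempdir("dupout")
  unlink(out, recursive = TRUE)
  expect_error(curate(m, out), "duplicate recording key")
  expect_false(dir.exists(out))  # refusal leaves nothing behind

  m2 <- one_rec_manifest(staging)
  m2$recordings[[1]]$meg_metadata$DewarPosition <- NULL
  expect_error(curate(m2, out), "DewarPosition")
  expect_false(dir.exists(out))

  m3 <- one_rec_manifest(staging)
  res <- curate(m3, out)
  expect_error(curate(m3, out), "not empty")
})

test_that("the synthetic plugin echoes the payload header", {
  staging <- withr::local_tempdir("plug")
  raw <- file.path(staging, "rec.fif")
  write_synthetic_raw(raw, 274, 2400, 300, seed = 5)
  got <- extract_metadata(raw, "synthetic")
  expect_identical(got, list(MEGChannelCount = 274L,
                             SamplingFrequency = 2400,
                             RecordingDuration = 300))
  # unknown plugin: empty partial plus an informational note
  none <- extract_metadata(raw, "ctf-res4")
  expect_length(none, 0L)
  expect_match(attr(none, "note"), "no extraction plugin")
  # corrupt payload is a parse error
  writeBin(as.raw(1:64), raw)
  expect_error(extract_metadata(raw, "synthetic"), "bad magic")
})

test_that("manifest values override plugin-extracted fields", {
  staging <- withr::local_tempdir("ovr")
  out <- withr::local_tempdir("ovrout")
  unlink(out, recursive = TRUE)
  m <- one_rec_manifest(staging)
  m$recordings[[1]]$meg_metadata$SamplingFrequency <- 999
  res <- curate(m, out, plugin = "synthetic")
  doc <- read_json_sidecar(
    file.path(out, "sub-01", "meg",
              "sub-01_task-rest_run-01_meg.json"))$document
  expect_identical(doc$SamplingFrequency, 999L)    # manifest wins
  expect_identical(doc$RecordingDuration, 120L)    # plugin fills the gap
})

test_that("YAML manifests round-trip through the reader into curate", {
  staging <- withr::local_tempdir("yml")
  raw <- file.path(staging, "native.fif")
  write_synthetic_raw(raw, 10, 500, 60, seed = 2)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "dataset:",
    "  name: YAML study",
    "  bids_version: 1.1.0",
    "recordings:",
    "  - subject: '01'",
    "    task: rest",
    "    run: 1",
    paste0("    raw_path: ", raw),
    "    meg_metadata:",
    "      TaskName: rest",
    "      SamplingFrequency: 500",
    "      PowerLineFrequency: 50",
    "      DewarPosition: upright",
    "      SoftwareFilters: n/a",
    "      DigitizedLandmarks: false",
    "      DigitizedHeadPoints: false"), yml)
  m <- read_manifest(yml)
  expect_s3_class(m, "curation_manifest")
  out <- withr::local_tempdir("ymlout")
  unlink(out, recursive = TRUE)
  res <- curate(m, out)
  expect_identical(res$report$verdict, "valid")
})

test_that("curating the same manifest twice is byte-identical", {
  a <- withr::local_tempdir("rep1")
  b <- withr::local_tempdir("rep2")
  unlink(c(a, b), recursive = TRUE)
  staging <- withr::local_tempdir("repstage")
  fx <- build_fixture_manifest(small_spec(77), staging)
  curate(fx$manifest, a)
  curate(fx$manifest, b)
  ha <- tree_md5(a); hb <- tree_md5(b)
  expect_identical(names(ha), names(hb))
  expect_identical(unname(ha), unname(hb))
})
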