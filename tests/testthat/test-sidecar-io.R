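minimal_meg_doc <- function() {
  list(TaskName = "rest", SamplingFrequency = 2400,
       PowerLineFrequency = 60, DewarPosition = "upright",
       SoftwareFilters = "n/a", DigitizedLandmarks = TRUE,
       DigitizedHeadPoints = TRUE)
}

test_that("a minimal conformant MEG sidecar reads with zero violations", {
  p <- withr::local_tempfile(fileext = ".json")
  write_json_sidecar(minimal_meg_doc(), p, schema = "meg")
  r <- read_json_sidecar(p, schema = "meg")
  expect_equal(nrow(r$violations), 0L)
  expect_identical(r$document$TaskName, "rest")
  expect_true(isTRUE(r$document$DigitizedLandmarks))
})

test_that("type, vocabulary and parse defects are reported, not thrown", {
  p <- withr::local_tempfile(fileext = ".json")
  doc <- minimal_meg_doc()
  doc$SamplingFrequency <- "fast"
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), p)
  r <- read_json_sidecar(p, schema = "meg")
  bad <- r$violations[r$violations$code == "TYPE", ]
  expect_equal(nrow(bad), 1L)
  expect_identical(bad$field, "SamplingFrequency")

  doc2 <- minimal_meg_doc()
  doc2$PowerLineFrequency <- 55
  writeLines(jsonlite::toJSON(doc2, auto_unbox = TRUE), p)
  r2 <- read_json_sidecar(p, schema = "meg")
  expect_true("VOCAB" %in% r2$violations$code)

  writeLines("{ this is not json", p)
  r3 <- read_json_sidecar(p, schema = "meg")
  expect_identical(r3$violations$code, "JSON-PARSE")
  expect_null(r3$document)
})

test_that("k deleted required keys yield exactly k missing-key violations", {
  set.seed(77)
  req <- names(sidecar_schema("meg")$required)
  for (k in c(1, 3, 7)) {
    p <- withr::local_tempfile(fileext = ".json")
    doc <- minimal_meg_doc()
    drop <- sample(req, k)
    doc[drop] <- NULL
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), p)
    r <- read_json_sidecar(p, schema = "meg")
    miss <- r$violations[r$violations$code == "MISSING-KEY", ]
    expect_equal(nrow(miss), k)
    expect_setequal(miss$field, drop)
    # and none when the same file is read as a partial inheritance layer
    rp <- read_json_sidecar(p, schema = "meg", check_required = FALSE)
    expect_false("MISSING-KEY" %in% rp$violations$code)
  }
})

test_that("unknown keys are preserved verbatim and reported as info", {
  p <- withr::local_tempfile(fileext = ".json")
  doc <- c(minimal_meg_doc(), list(VendorQuirk = "keepme"))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), p)
  r <- read_json_sidecar(p, schema = "meg")
  expect_identical(r$document$VendorQuirk, "keepme")
  info <- r$violations[r$violations$severity == "INFO", ]
  expect_identical(info$field, "VendorQuirk")
})

test_that("TSV reading: sentinel, ragged rows, missing columns", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\ttype\tunits", "MLC11\tMEGGRADAXIAL\tT"), p)
  r <- read_tsv_table(p, schema = "channels")
  expect_equal(nrow(r$table), 1L)
  expect_equal(nrow(r$violations), 0L)

  writeLines(c("onset\ttrial_type", "0.5\tstim"), p)
  r2 <- read_tsv_table(p, schema = "events")
  miss <- r2$violations[r2$violations$code == "MISSING-COLUMN", ]
  expect_identical(miss$field, "duration")

  writeLines(c("onset\tduration", "0.5\tn/a", "1.2\t0.5\tstray"), p)
  r3 <- read_tsv_table(p, schema = "events")
  expect_true("RAGGED-ROW" %in% r3$violations$code)
  expect_true(is.na(r3$table$duration[1]))  # "n/a" decodes to missing
  expect_identical(r3$table$onset, c(0.5, 1.2))

  writeLines(c("name\tname\tunits", "a\tb\tT"), p)
  r4 <- read_tsv_table(p, schema = "channels")
  expect_true("DUP-COLUMN" %in% r4$violations$code)
})

test_that("writers are deterministic and refuse invariant violations", {
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  doc <- minimal_meg_doc()
  write_json_sidecar(doc, p1, schema = "meg")
  write_json_sidecar(doc, p2, schema = "meg")
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  bad <- doc
  bad$TaskName <- NULL
  expect_error(write_json_sidecar(bad, p1, schema = "meg"), "TaskName")

  tab <- data.frame(onset = c(0.25, 1.5), duration = c(0.5, NA),
                    trial_type = c("a", "b"))
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(tab, t1, schema = "events")
  write_tsv_table(tab, t2, schema = "events")
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(readLines(t1)[3], "1.5\tn/a\tb")
  expect_error(write_tsv_table(data.frame(onset = 1), t1,
                               schema = "events"),
               "duration")
})

test_that("read-write-read is a fixed point for JSON and TSV", {
  p <- withr::local_tempfile(fileext = ".json")
  doc <- c(minimal_meg_doc(),
           list(RecordingDuration = 300.5, MEGChannelCount = 274L))
  write_json_sidecar(doc, p, schema = "meg")
  r1 <- read_json_sidecar(p, schema = "meg")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_json_sidecar(r1$document, p2, schema = "meg")
  expect_identical(readLines(p), readLines(p2))
  r2 <- read_json_sidecar(p2, schema = "meg")
  expect_identical(r1$document, r2$document)

  t1 <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(name = c("MEG0001", "EOG0001"),
                    type = c("MEGMAG", "EOG"), units = c("T", "V"),
                    low_cutoff = c(0.03, NA), high_cutoff = c(600, 600))
  write_tsv_table(tab, t1, schema = "channels")
  rt <- read_tsv_table(t1, schema = "channels")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_table(rt$table, t2, schema = "channels")
  expect_identical(readLines(t1), readLines(t2))
})
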