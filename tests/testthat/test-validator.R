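test_that("generated fixtures validate with zero errors", {
  out <- withr::local_tempdir("val")
  unlink(out, recursive = TRUE)
  res <- generate_dataset(small_spec(42), out)
  expect_identical(res$report$verdict, "valid")
  expect_equal(res$report$counts[["error"]], 0L)
})

test_that("one renamed file yields exactly one grammar error at its path", {
  out <- withr::local_tempdir("ren")
  unlink(out, recursive = TRUE)
  res <- generate_dataset(small_spec(43), out)
  ch <- query(res$tree, suffix = "channels")$relative_path[1]
  bad_name <- "sub-01_meg_task-rest.json"
  file.rename(file.path(out, ch),
              file.path(out, dirname(ch), bad_name))
  report <- validate_dataset(out)
  e001 <- report$issues[report$issues$code == "MEG-E001", ]
  expect_equal(nrow(e001), 1L)
  expect_identical(e001$path, file.path(dirname(ch), bad_name))
})

test_that("validation is deterministic and monotone under additions", {
  out <- withr::local_tempdir("mono")
  unlink(out, recursive = TRUE)
  res <- generate_dataset(small_spec(44), out)
  mutate_dataset(out, "drop-required-meg-key")
  r1 <- validate_dataset(out)
  r2 <- validate_dataset(out)
  expect_identical(r1$issues, r2$issues)
  # adding an unrelated valid artifact removes no existing issue
  writeBin(as.raw(1:32),
           file.path(out, "sub-01", "sub-01_headshape.pos"))
  r3 <- validate_dataset(out)
  expect_true(all(paste(r1$issues$code, r1$issues$path) %in%
                    paste(r3$issues$code, r3$issues$path)))
})

test_that("issue codes map to fixed severities and a consistent verdict", {
  reg <- issue_registry()
  expect_false(anyDuplicated(reg$code) > 0)
  expect_true(all(reg$severity %in% c("ERROR", "WARNING", "INFO")))
  out <- withr::local_tempdir("sev")
  unlink(out, recursive = TRUE)
  generate_dataset(small_spec(45), out)
  mutate_dataset(out, "mismatch-channel-count")
  rep <- validate_dataset(out)
  # a warning-only report is still a valid dataset...
  expect_identical(rep$verdict, "valid")
  expect_gt(rep$counts[["warning"]], 0)
  # ...until strict mode promotes warnings
  expect_identical(strict_report(rep)$verdict, "invalid")
})

test_that("reports render deterministically in all three formats", {
  out <- withr::local_tempdir("rep")
  unlink(out, recursive = TRUE)
  generate_dataset(small_spec(46), out)
  empty <- validate_dataset(out)
  expect_identical(render_report(empty, "text")[1],
                   "valid: 0 errors, 0 warnings")

  mutate_dataset(out, "drop-required-meg-key")
  mutate_dataset(out, "delete-dataset-description")
  mutate_dataset(out, "mismatch-channel-count")
  rep <- validate_dataset(out)
  expect_equal(rep$counts[["error"]], 2L)
  expect_equal(rep$counts[["warning"]], 1L)
  expect_identical(render_report(rep, "text")[1],
                   "invalid: 2 errors, 1 warnings")
  tsv <- render_report(rep, "tsv")
  expect_identical(tsv[1], "severity\tcode\tpath\tmessage")
  expect_length(tsv, nrow(rep$issues) + 1L)

  js <- render_report(rep, "json")
  back <- parse_report(js)
  expect_identical(back$issues, rep$issues)
  expect_identical(back$verdict, rep$verdict)
  expect_identical(render_report(back, "json"), js)
})

test_that("every mutation operator is killed with no spurious errors", {
  base <- withr::local_tempdir("kill")
  unlink(base, recursive = TRUE)
  res <- generate_dataset(small_spec(47), base)
  expect_identical(res$report$verdict, "valid")
  ops <- mutation_operators()
  reg <- issue_registry()
  expect_true(all(ops$expected_code %in% reg$code))
  killed <- character(0)
  for (i in seq_len(nrow(ops))) {
    work <- withr::local_tempdir(paste0("m", i))
    copy_tree(base, work)
    rec <- mutate_dataset(work, ops$id[i])
    rep <- validate_dataset(work)
    expect_true(rec$expected_code %in% rep$issues$code,
                info = ops$id[i])
    spurious <- setdiff(
      rep$issues$code[rep$issues$severity == "ERROR"],
      rec$expected_code)
    expect_length(spurious, 0)
    killed <- c(killed, rec$expected_code)
    unlink(work, recursive = TRUE)
  }
  # surjectivity: every ERROR code in the registry is killed
  expect_length(setdiff(reg$code[reg$severity == "ERROR"], killed), 0)
})

test_that("mutations are minimal: exactly one path differs", {
  base <- withr::local_tempdir("min")
  unlink(base, recursive = TRUE)
  generate_dataset(small_spec(48), base)
  before <- tree_md5(base)
  for (op in c("drop-required-meg-key", "invalid-units",
               "scans-references-missing-file", "break-entity-order",
               "add-conflicting-sidecar")) {
    work <- withr::local_tempdir(substr(op, 1, 4))
    copy_tree(base, work)
    mutate_dataset(work, op)
    after <- tree_md5(work)
    changed <- union(setdiff(names(before), names(after)),
                     setdiff(names(after), names(before)))
    common <- intersect(names(before), names(after))
    changed <- union(changed, common[before[common] != after[common]])
    expect_length(changed, if (op == "break-entity-order") 2L else 1L)
    unlink(work, recursive = TRUE)
  }
})
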