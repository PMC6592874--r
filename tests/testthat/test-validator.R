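test_that("all five generated archetypes validate with zero errors", {
  for (a in ieeg_archetypes()$archetype_id) {
    report <- validate_dataset(clean_dataset(a))
    expect_true(report$valid, info = a)
    expect_equal(report$summary[["error"]], 0L, info = a)
  }
})

test_that("validation reports are deterministic for identical trees", {
  root <- clean_dataset("seizure_seeg")
  j1 <- validation_json(validate_dataset(root))
  j2 <- validation_json(validate_dataset(root))
  expect_identical(j1, j2)
  # and across a regenerated byte-identical tree at another location
  other <- tempfile()
  generate_dataset("seizure_seeg", other, seed = 42L)
  expect_identical(validation_json(validate_dataset(other)), j1)
  unlink(other, recursive = TRUE)
})

test_that("scaffold rules: dataset description and per-subject iEEG data", {
  d <- fresh_copy("motor_movement")
  unlink(file.path(d, "dataset_description.json"))
  report <- validate_dataset(d)
  expect_true("E_NO_DATASET_DESCRIPTION" %in% report$issues$code)
  expect_false(report$valid)
  unlink(d, recursive = TRUE)

  # a subject with /anat/ but no /ieeg/ is not an iEEG subject
  d <- fresh_copy("multimodal_ecog_mri")
  unlink(file.path(d, "sub-01", "ieeg"), recursive = TRUE)
  report <- validate_dataset(d)
  expect_equal(report$issues$code[report$issues$severity == "error"],
               "E_NO_IEEG_DATA")
  expect_equal(report$issues$path[report$issues$code == "E_NO_IEEG_DATA"],
               "sub-01")
  unlink(d, recursive = TRUE)
})

test_that("unofficial formats pass the validator with a warning", {
  d <- fresh_copy("motor_movement")
  edf <- list.files(d, pattern = "_ieeg\\.edf$", recursive = TRUE)
  for (f in edf) {
    file.rename(file.path(d, f),
                file.path(d, sub("\\.edf$", ".nwb", f)))
  }
  report <- validate_dataset(d)
  expect_true(report$valid)
  expect_true("W_UNOFFICIAL_FORMAT" %in% report$issues$code)
  expect_true("W_UNCHECKED" %in% report$issues$code)
  expect_gt(report$summary[["warning"]], 0)
  unlink(d, recursive = TRUE)
})

test_that("renaming a data file to an unknown extension is an error", {
  d <- fresh_copy("motor_movement")
  f <- list.files(d, pattern = "_ieeg\\.edf$", recursive = TRUE)[1]
  file.rename(file.path(d, f), file.path(d, sub("\\.edf$", ".xyz", f)))
  report <- validate_dataset(d)
  expect_false(report$valid)
  expect_true("E_UNKNOWN_FORMAT" %in% report$issues$code)
  unlink(d, recursive = TRUE)
})

test_that("electrode tables must pair with a coordinate system; IntendedFor must resolve", {
  d <- fresh_copy("motor_movement")
  cs <- list.files(d, pattern = "_coordsystem\\.json$", recursive = TRUE)[1]
  unlink(file.path(d, cs))
  issues <- check_coordsystem_pairing(d)
  expect_true("E_COORDSYS_MISSING" %in% issues$code)
  unlink(d, recursive = TRUE)

  d <- fresh_copy("multimodal_ecog_mri")
  # two resolvable pairs in two spaces is fine
  el <- list.files(d, pattern = "_electrodes\\.tsv$", recursive = TRUE)[1]
  cs <- list.files(d, pattern = "_coordsystem\\.json$", recursive = TRUE)[1]
  file.copy(file.path(d, el),
            file.path(d, sub("_electrodes", "_space-talairach_electrodes", el)))
  file.copy(file.path(d, cs),
            file.path(d, sub("_coordsystem", "_space-talairach_coordsystem", cs)))
  expect_equal(nrow(check_coordsystem_pairing(d)), 0L)

  # dangling IntendedFor
  unlink(file.path(d, "sub-01", "anat"), recursive = TRUE)
  issues <- check_coordsystem_pairing(d)
  expect_equal(unique(issues$code), "E_INTENDEDFOR_DANGLING")
  unlink(d, recursive = TRUE)
})

test_that("channel/electrode cross-checks compare table against payload", {
  d <- fresh_copy("seizure_seeg")
  data_rel <- list.files(d, pattern = "_ieeg\\.edf$", recursive = TRUE)
  expect_equal(nrow(check_channel_electrode_consistency(d, data_rel[1])), 0L)

  # drop one channels row -> count mismatch with both counts in context
  ch <- list.files(d, pattern = "_channels\\.tsv$", recursive = TRUE)[1]
  lines <- readLines(file.path(d, ch))
  writeLines(lines[-length(lines)], file.path(d, ch))
  issues <- check_channel_electrode_consistency(d, data_rel[1])
  expect_equal(issues$code, "E_CHANNEL_COUNT_MISMATCH")
  expect_equal(issues$context[[1]]$table, 11)
  expect_equal(issues$context[[1]]$file, 12)
  unlink(d, recursive = TRUE)

  # an iEEG channel absent from every electrode table warns
  d <- fresh_copy("motor_movement")
  el <- list.files(d, pattern = "_electrodes\\.tsv$", recursive = TRUE)[1]
  lines <- readLines(file.path(d, el))
  writeLines(lines[-2], file.path(d, el))
  data_rel <- list.files(d, pattern = "_ieeg\\.edf$", recursive = TRUE)[1]
  issues <- check_channel_electrode_consistency(d, data_rel)
  expect_equal(issues$code, "W_ELECTRODE_UNLOCATED")
  expect_equal(issues$severity, "warning")
  unlink(d, recursive = TRUE)
})

test_that("adding a defect never removes issues already present", {
  d <- fresh_copy("motor_movement")
  corrupt_dataset(d, "E_MISSING_KEY")
  first <- validate_dataset(d)$issues
  corrupt_dataset(d, "E_COORDSYS_MISSING")
  second <- validate_dataset(d)$issues
  key <- function(x) paste(x$code, x$path)
  expect_true(all(key(first) %in% key(second)))
  expect_true(all(c("E_MISSING_KEY", "E_COORDSYS_MISSING") %in% second$code))
  unlink(d, recursive = TRUE)
})

test_that("issues are ordered by path then code and valid tracks error count", {
  d <- fresh_copy("motor_movement")
  corrupt_dataset(d, "E_MISSING_KEY")
  report <- validate_dataset(d)
  ord <- order(report$issues$path, report$issues$code, method = "radix")
  expect_equal(ord, seq_len(nrow(report$issues)))
  expect_identical(report$valid, report$summary[["error"]] == 0L)
  expect_s3_class(tidy(report), "tbl_df")
  g <- glance(report)
  expect_equal(g$n_errors, report$summary[["error"]])
  unlink(d, recursive = TRUE)
})
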