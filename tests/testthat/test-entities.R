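test_that("paths from the standard layout parse into their entity sets", {
  p <- parse_bids_path("sub-01/ieeg/sub-01_task-visual_ieeg.json")
  expect_equal(p$subject, "01")
  expect_equal(p$task, "visual")
  expect_equal(p$suffix, "ieeg")
  expect_equal(p$extension, ".json")
  expect_equal(p$datatype, "ieeg")

  p <- parse_bids_path("sub-01/anat/sub-01_T1w.nii.gz")
  expect_equal(p$subject, "01")
  expect_equal(p$suffix, "T1w")
  expect_equal(p$extension, ".nii.gz")
  expect_equal(p$datatype, "anat")

  p <- parse_bids_path("sub-01/ses-02/ieeg/sub-01_ses-02_task-x_run-003_ieeg.edf")
  expect_equal(p$session, "02")
  expect_equal(p$run, 3L)
  expect_equal(p$run_width, 3L)
})

test_that("malformed names are rejected, not silently repaired", {
  # entity after the suffix
  expect_error(parse_bids_path("sub-01/ieeg/sub-01_ieeg_task-x.json"),
               class = "ieegbids_malformed_name")
  # missing hyphen
  expect_error(parse_bids_path("sub-01/ieeg/sub01_task-x_ieeg.edf"),
               class = "ieegbids_malformed_name")
  # duplicated entity
  expect_error(parse_bids_path("sub-01/ieeg/sub-01_task-a_task-b_ieeg.edf"),
               class = "ieegbids_malformed_name")
  # unknown entity key
  expect_error(parse_bids_path("sub-01/ieeg/sub-01_flavor-x_task-a_ieeg.edf"),
               class = "ieegbids_malformed_name")
  # folder/filename subject mismatch
  expect_error(parse_bids_path("sub-02/ieeg/sub-01_task-a_ieeg.edf"),
               class = "ieegbids_malformed_name")
  # unknown suffix is a distinct failure
  expect_error(parse_bids_path("sub-01/ieeg/sub-01_task-a_wibble.tsv"),
               class = "ieegbids_unknown_suffix")
})

test_that("rendering uses the fixed entity order with zero-padded runs", {
  p <- bids_path(subject = "01", task = "motor", run = 1, suffix = "ieeg",
                 extension = ".vhdr")
  expect_equal(build_bids_path(p),
               "sub-01/ieeg/sub-01_task-motor_run-01_ieeg.vhdr")
  expect_error(build_bids_path(bids_path(task = "motor", suffix = "ieeg",
                                         extension = ".edf")),
               class = "ieegbids_missing_entity")
  expect_error(build_bids_path(bids_path(subject = "01", suffix = "ieeg",
                                         extension = ".edf")),
               class = "ieegbids_missing_entity")
})

test_that("parse and build are mutually inverse over generated entity sets", {
  set.seed(101)
  labels <- function() paste(sample(c(letters, 0:9), 4, TRUE), collapse = "")
  for (i in 1:60) {
    p <- bids_path(
      subject = labels(),
      session = if (runif(1) < 0.4) labels() else NULL,
      task = labels(),
      acquisition = if (runif(1) < 0.3) labels() else NULL,
      run = if (runif(1) < 0.5) sample(1:120, 1) else NULL,
      space = if (runif(1) < 0.2) labels() else NULL,
      suffix = "ieeg",
      extension = sample(c(".edf", ".vhdr", ".json"), 1))
    q <- parse_bids_path(build_bids_path(p))
    for (f in c("subject", "session", "task", "acquisition", "run",
                "space", "suffix", "extension", "datatype")) {
      expect_identical(q[[f]], p[[f]], info = f)
    }
    # fixed point: a second render/parse cycle changes nothing
    expect_identical(build_bids_path(q), build_bids_path(p))
  }
})

test_that("enumeration classifies every file and is deterministic", {
  root <- clean_dataset("auditory_speech")
  files <- enumerate_dataset(root)
  expect_true(all(files$category %in% c("bids", "passthrough")))
  expect_equal(sum(grepl("^stimuli/", files$path)),
               sum(files$category == "passthrough" &
                     grepl("^stimuli/", files$path)))
  expect_identical(files, enumerate_dataset(root))

  empty <- tempfile(); dir.create(empty)
  expect_equal(nrow(enumerate_dataset(empty)), 0L)
  expect_error(enumerate_dataset(file.path(empty, "nope")),
               class = "ieegbids_not_a_directory")

  writeLines("hello", file.path(empty, "README"))
  en <- enumerate_dataset(empty)
  expect_equal(en$category, "passthrough")
})

test_that("sidecar resolution orders root-level before local and flags ties", {
  root <- tempfile(); dir.create(file.path(root, "sub-01", "ieeg"),
                                 recursive = TRUE)
  writeLines("{}", file.path(root, "task-visual_ieeg.json"))
  writeLines("{}", file.path(root, "sub-01", "ieeg",
                             "sub-01_task-visual_ieeg.json"))
  files <- enumerate_dataset(root)
  p <- bids_path(subject = "01", task = "visual", suffix = "ieeg",
                 extension = ".edf")
  sc <- resolve_sidecars(p, files)
  expect_equal(sc$path, c("task-visual_ieeg.json",
                          "sub-01/ieeg/sub-01_task-visual_ieeg.json"))

  expect_equal(nrow(resolve_sidecars(
    bids_path(subject = "02", task = "other", suffix = "ieeg",
              extension = ".edf"), files)), 0L)

  # a second root-level sidecar at the same specificity level is ambiguous
  writeLines("{}", file.path(root, "acq-x_ieeg.json"))
  files <- enumerate_dataset(root)
  p2 <- bids_path(subject = "01", task = "visual", acquisition = "x",
                  suffix = "ieeg", extension = ".edf")
  expect_error(resolve_sidecars(p2, files),
               class = "ieegbids_ambiguous_sidecar")
})
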