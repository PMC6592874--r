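MICRO_V <- "\u00b5V"

test_that("write then load is the identity for tabular sidecars", {
  channels <- tibble::tibble(
    name = c("G1", "G2", "T1"), type = c("ECOG", "ECOG", "TRIG"),
    units = c(MICRO_V, MICRO_V, NA), low_cutoff = c(0.1, 0.1, NA),
    high_cutoff = c(100, 100, NA), sampling_frequency = c(512, 512, 512),
    group = c("G", "G", NA), status = c("good", "bad", "good"))
  f <- tempfile(fileext = ".tsv")
  write_bids_table(channels, f, "channels")
  got <- load_bids_table(f, "channels")
  expect_equal(got$rows, channels)
  expect_equal(nrow(got$issues), 0L)

  electrodes <- tibble::tibble(
    name = c("G1", "G2"), x = c(-41.2, -38.75), y = c(12, 14.5),
    z = c(55.01, 56.2), size = c(4.15, 4.15), group = c("G", "G"))
  f2 <- tempfile(fileext = ".tsv")
  write_bids_table(electrodes, f2, "electrodes")
  got2 <- load_bids_table(f2, "electrodes")
  expect_equal(got2$rows, electrodes)
  expect_equal(nrow(got2$issues), 0L)

  events <- tibble::tibble(onset = c(0.5, 1.25, 3), duration = c(0.5, 0, 1),
                           trial_type = c("a", "b", "a"),
                           sample = c(256, 640, 1536))
  f3 <- tempfile(fileext = ".tsv")
  write_bids_table(events, f3, "events")
  got3 <- load_bids_table(f3, "events")
  expect_equal(got3$rows, events)
})

test_that("a 2-D electrode table (z uniformly n/a) loads cleanly", {
  tab <- tibble::tibble(name = c("G1", "G2"), x = c(200, 260),
                        y = c(150, 150), z = c(NA_real_, NA_real_))
  f <- tempfile(fileext = ".tsv")
  write_bids_table(tab, f, "electrodes")
  got <- load_bids_table(f, "electrodes")
  expect_equal(nrow(got$issues), 0L)
  expect_true(all(is.na(got$rows$z)))
})

test_that("content defects accumulate as issues instead of throwing", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("name\ttype", "G1\tECOG"), f)   # units column missing
  got <- load_bids_table(f, "channels")
  expect_equal(got$issues$code, "E_MISSING_COLUMN")
  expect_equal(got$issues$severity, "error")

  writeLines(c("name\tx\ty\tz", "A\t1\t2\t3", "A\t4\t5\tn/a"), f)
  got <- load_bids_table(f, "electrodes")
  expect_setequal(got$issues$code,
                  c("E_DUPLICATE_NAME", "E_MIXED_DIMENSIONALITY"))

  writeLines(c("onset\tduration", "2\t0.5", "1\t0.5"), f)
  got <- load_bids_table(f, "events")
  expect_true("E_UNSORTED_EVENTS" %in% got$issues$code)

  writeLines(c("name\ttype\tunits", "G1\tLASER\tfurlongs"), f)
  got <- load_bids_table(f, "channels")
  expect_setequal(got$issues$code,
                  c("W_UNKNOWN_CHANNEL_TYPE", "W_UNIT_UNRECOGNIZED"))
  expect_true(all(got$issues$severity == "warning"))
})

test_that("events are emitted sorted by onset and invariants are enforced on write", {
  ev <- tibble::tibble(onset = c(3, 1, 2), duration = c(1, 1, 1),
                       trial_type = c("c", "a", "b"))
  f <- tempfile(fileext = ".tsv")
  write_bids_table(ev, f, "events")
  got <- load_bids_table(f, "events")
  expect_equal(got$rows$onset, c(1, 2, 3))
  expect_equal(got$rows$trial_type, c("a", "b", "c"))

  expect_error(write_bids_table(
    tibble::tibble(name = c("A", "A"), x = 1:2, y = 1:2, z = 1:2),
    tempfile(), "electrodes"), class = "ieegbids_invariant_violation")
  expect_error(write_bids_table(
    tibble::tibble(name = c("A", "B"), x = 1:2, y = 1:2,
                   z = c(1, NA)),
    tempfile(), "electrodes"), class = "ieegbids_invariant_violation")
})

test_that("the acquisition sidecar roundtrips with unknown keys preserved", {
  m <- list(TaskName = "visual", SamplingFrequency = 500,
            PowerLineFrequency = 50, SoftwareFilters = "n/a",
            iEEGReference = "common average", Manufacturer = "synthetic",
            CustomLabNote = "kept verbatim")
  f <- tempfile(fileext = ".json")
  write_ieeg_sidecar(m, f)
  got <- load_ieeg_sidecar(f)
  expect_equal(unclass(got$model)[names(m)], m)
  expect_equal(got$issues$code, "W_UNKNOWN_KEY")
  expect_equal(got$issues$severity, "warning")
})

test_that("acquisition sidecar key and value rules fire", {
  f <- tempfile(fileext = ".json")
  write_ieeg_sidecar(list(TaskName = "x", SamplingFrequency = 100,
                          PowerLineFrequency = 50,
                          SoftwareFilters = "n/a"), f)
  got <- load_ieeg_sidecar(f)
  expect_equal(got$issues$code, "E_MISSING_KEY")
  expect_match(got$issues$message, "iEEGReference")

  write_ieeg_sidecar(list(TaskName = "x", SamplingFrequency = 100,
                          PowerLineFrequency = 43, SoftwareFilters = "n/a",
                          iEEGReference = "mastoid"), f)
  expect_true("E_BAD_VALUE" %in% load_ieeg_sidecar(f)$issues$code)

  writeLines("{", f)
  got <- load_ieeg_sidecar(f)
  expect_null(got$model)
  expect_equal(got$issues$code, "E_JSON_SYNTAX")
})

test_that("coordinate system rules follow the Other/description contract", {
  f <- tempfile(fileext = ".json")
  write_coordsystem(list(iEEGCoordinateSystem = "Other",
                         iEEGCoordinateUnits = "mm",
                         iEEGCoordinateSystemDescription = "clinical schema"),
                    f)
  expect_equal(nrow(load_coordsystem(f)$issues), 0L)

  write_coordsystem(list(iEEGCoordinateSystem = "Other",
                         iEEGCoordinateUnits = "mm"), f)
  iss <- load_coordsystem(f)$issues
  expect_equal(iss$code, "E_MISSING_KEY")
  expect_match(iss$message, "Description")

  write_coordsystem(list(iEEGCoordinateSystem = "ACPC",
                         iEEGCoordinateUnits = "furlongs"), f)
  expect_equal(load_coordsystem(f)$issues$code, "E_BAD_VALUE")
})
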