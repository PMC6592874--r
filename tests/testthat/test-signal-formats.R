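test_that("the format registry holds two compliant and three unofficial formats", {
  reg <- format_registry()
  expect_equal(sum(reg$tier == "compliant"), 2L)
  expect_equal(sum(reg$tier == "unofficial"), 3L)
  expect_equal(classify_format(".edf")$tier, "compliant")
  expect_equal(classify_format(".vhdr")$tier, "compliant")
  expect_equal(classify_format(".nwb")$tier, "unofficial")
  expect_equal(classify_format(".set")$tier, "unofficial")
  expect_equal(classify_format(".mefd")$tier, "unofficial")
  expect_equal(classify_format(".xyz")$format_id, "unknown")
})

test_that("EDF preserves distinct per-channel sampling rates", {
  set.seed(7)
  data <- list(slow = round(runif(200, -100, 100), 1),
               fast = round(runif(400, -100, 100), 1))
  rec <- ieeg_recording(data, sampling_frequency = c(100, 200),
                        physical_range = c(-500, 500))
  f <- tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  expect_equal(back$channels$sampling_frequency, c(100, 200))
  expect_equal(lengths(back$data), c(slow = 200L, fast = 400L))
})

test_that("a constant zero signal with symmetric range maps to midpoint codes", {
  rec <- ieeg_recording(list(flat = rep(0, 50)), sampling_frequency = 50,
                        physical_range = c(-100, 100))
  f <- tempfile(fileext = ".edf")
  write_edf(rec, f)
  # midpoint of [-32768, 32767] under the linear map is -0.5 -> rounds to 0
  con <- file(f, "rb"); on.exit(close(con))
  invisible(readBin(con, "raw", 512L))
  codes <- readBin(con, "integer", 50, size = 2L, endian = "little")
  expect_true(all(codes %in% c(0L, -1L)))
  back <- read_edf(f)
  expect_lt(max(abs(back$data$flat)), 200 / 65535)  # one quantization step
})

test_that("EDF scaling agrees with an independently built file and brute-force map", {
  set.seed(11)
  for (rep in 1:5) {
    ns <- sample(1:3, 1)
    pmin <- round(runif(ns, -5000, -10))
    pmax <- round(runif(ns, 10, 5000))
    dmin <- rep(-32768L, ns); dmax <- rep(32767L, ns)
    spr <- sample(c(10L, 20L, 50L), ns, TRUE)
    n_rec <- 3L
    codes <- lapply(seq_len(ns), function(i) {
      as.integer(sample(-32768:32767, spr[i] * n_rec, TRUE))
    })
    f <- build_edf_bytes(paste0("s", seq_len(ns)), rep("uV", ns),
                         pmin, pmax, dmin, dmax, spr, codes, n_rec)
    rec <- read_edf(f)
    for (i in seq_len(ns)) {
      # brute-force scaler applied sample-wise
      expected <- vapply(codes[[i]], function(D) {
        pmin[i] + (D - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      }, numeric(1))
      expect_equal(rec$data[[i]], expected)
    }
    unlink(f)
  }
})

test_that("EDF roundtrip reproduces the digital payload byte-for-byte", {
  rec <- random_recording(n_channels = 4, fs = 128, seconds = 2, seed = 3)
  f1 <- tempfile(fileext = ".edf"); f2 <- tempfile(fileext = ".edf")
  write_edf(rec, f1)
  write_edf(read_edf(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("EDF file size follows the header arithmetic", {
  rec <- ieeg_recording(list(a = 0), sampling_frequency = 1,
                        physical_range = c(-1, 1))
  f <- tempfile(fileext = ".edf")
  write_edf(rec, f)
  expect_equal(file.size(f), 256 * 2 + 2)
})

test_that("EDF writer and reader reject bad inputs", {
  rec <- ieeg_recording(list(a = c(0, 150)), sampling_frequency = 2,
                        physical_range = c(-100, 100))
  expect_error(write_edf(rec, tempfile()), class = "ieegbids_range_overflow")

  rec2 <- ieeg_recording(stats::setNames(list(c(0, 1)),
                                         strrep("x", 20)),
                         sampling_frequency = 2,
                         physical_range = c(-10, 10))
  expect_error(write_edf(rec2, tempfile()), class = "ieegbids_label_too_long")

  f <- tempfile()
  ok <- random_recording(1, 10, 1)
  write_edf(ok, f)
  raw <- readBin(f, "raw", file.size(f))
  writeBin(raw[1:(length(raw) - 4)], f)
  expect_error(read_edf(f), class = "ieegbids_truncated_data")

  writeBin(charToRaw(strrep("9", 300)), f)
  expect_error(read_edf(f), class = "ieegbids_bad_header")
})

test_that("BrainVision float32 roundtrip is bit-exact", {
  set.seed(5)
  data <- lapply(1:3, function(i) snap_float32(rnorm(500, sd = 50)))
  names(data) <- paste0("ch", 1:3)
  rec <- ieeg_recording(data, sampling_frequency = 250)
  base <- tempfile()
  write_brainvision(rec, base, encoding = "float32")
  back <- read_brainvision(paste0(base, ".vhdr"))
  expect_identical(back$data[["ch1"]], data[["ch1"]])
  expect_equal(max(abs(unlist(back$data) - unlist(data))), 0)
  expect_equal(back$binary_encoding, "float32")
})

test_that("BrainVision int16 roundtrip error is bounded by half the resolution", {
  set.seed(6)
  data <- list(a = runif(400, -3000, 3000), b = runif(400, -3000, 3000))
  rec <- ieeg_recording(data, sampling_frequency = 200)
  base <- tempfile()
  write_brainvision(rec, base, encoding = "int16", resolution = 0.1)
  back <- read_brainvision(paste0(base, ".vhdr"))
  err <- max(abs(unlist(back$data) - unlist(data)))
  expect_lte(err, 0.05 + 1e-12)
})

test_that("BrainVision derives the rate from the sampling interval", {
  rec <- ieeg_recording(list(a = snap_float32(sin(1:100))),
                        sampling_frequency = 500)
  base <- tempfile()
  write_brainvision(rec, base)
  lines <- readLines(paste0(base, ".vhdr"))
  expect_true("SamplingInterval=2000" %in% lines)
  expect_equal(read_brainvision(paste0(base, ".vhdr"))
               $channels$sampling_frequency, 500)
})

test_that("BrainVision enforces its format constraints", {
  rec <- ieeg_recording(list(a = 1:100 / 10, b = 1:200 / 10),
                        sampling_frequency = c(100, 200))
  expect_error(write_brainvision(rec, tempfile()),
               class = "ieegbids_mixed_rates")

  ok <- ieeg_recording(list(a = rep(5000, 10)), sampling_frequency = 10)
  expect_error(write_brainvision(ok, tempfile(), encoding = "int16",
                                 resolution = 0.1),
               class = "ieegbids_resolution_overflow")

  base <- tempfile()
  write_brainvision(ieeg_recording(list(a = snap_float32(1:10 / 2)),
                                   sampling_frequency = 10), base)
  unlink(paste0(base, ".eeg"))
  expect_error(read_brainvision(paste0(base, ".vhdr")),
               class = "ieegbids_missing_companion")

  base2 <- tempfile()
  write_brainvision(ieeg_recording(list(a = snap_float32(1:10 / 2)),
                                   sampling_frequency = 10), base2)
  vhdr <- paste0(base2, ".vhdr")
  txt <- readLines(vhdr)
  txt[txt == "DataOrientation=MULTIPLEXED"] <- "DataOrientation=VECTORIZED"
  writeLines(txt, vhdr)
  expect_error(read_brainvision(vhdr), class = "ieegbids_unsupported_encoding")
})
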