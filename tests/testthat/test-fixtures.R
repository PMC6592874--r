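test_that("generation is a pure function of archetype and seed", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_dataset("visual_stimulus", d1, seed = 9L)
  generate_dataset("visual_stimulus", d2, seed = 9L)
  m1 <- tree_md5(d1); m2 <- tree_md5(d2)
  expect_identical(names(m1), names(m2))
  expect_identical(unname(m1), unname(m2))
  # a different seed must change the signal payload
  d3 <- tempfile()
  generate_dataset("visual_stimulus", d3, seed = 10L)
  m3 <- tree_md5(d3)
  eeg <- grep("\\.eeg$", names(m1))
  expect_false(identical(m1[eeg], m3[eeg]))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("generation refuses a non-empty target", {
  d <- tempfile(); dir.create(d)
  writeLines("x", file.path(d, "occupied.txt"))
  expect_error(generate_dataset("motor_movement", d),
               class = "ieegbids_target_not_empty")
  expect_error(generate_dataset("no_such_archetype", tempfile()),
               class = "ieegbids_unknown_archetype")
})

test_that("synthesized signals carry a mains peak at the power-line frequency", {
  rec <- synthesize_signal("motor_movement", seed = 4L)
  x <- rec$data[["G1"]]
  n <- length(x)                       # 8 s at 256 Hz -> 0.125 Hz bins
  mag <- Mod(stats::fft(x))[1:(n / 2)]
  hz <- (seq_len(n / 2) - 1) / 8
  mains <- mag[hz == 60]
  neighbors <- mag[abs(hz - 60) <= 1 & hz != 60]
  expect_gt(mains, 5 * max(neighbors))
  # determinism of synthesis
  rec2 <- synthesize_signal("motor_movement", seed = 4L)
  expect_identical(rec$data, rec2$data)
})

test_that("the seizure archetype exercises two EDF sampling rates", {
  root <- clean_dataset("seizure_seeg")
  edf <- list.files(root, pattern = "_ieeg\\.edf$", recursive = TRUE,
                    full.names = TRUE)[1]
  rec <- read_edf(edf)
  expect_setequal(unique(rec$channels$sampling_frequency), c(512, 256))
  expect_equal(recording_duration(rec), 8)
})

test_that("the multimodal archetype links electrodes to a readable volume", {
  root <- clean_dataset("multimodal_ecog_mri")
  nii <- list.files(root, pattern = "\\.nii\\.gz$", recursive = TRUE,
                    full.names = TRUE)
  expect_length(nii, 1L)
  img <- RNifti::readNifti(nii)
  expect_equal(dim(img), c(8L, 8L, 8L))
  cs <- list.files(root, pattern = "_coordsystem\\.json$", recursive = TRUE,
                   full.names = TRUE)[1]
  model <- load_coordsystem(cs)$model
  expect_true(file.exists(file.path(root, model$IntendedFor)))
})

test_that("the auditory archetype ships playable stimuli referenced by events", {
  root <- clean_dataset("auditory_speech")
  wavs <- list.files(file.path(root, "stimuli"), pattern = "\\.wav$")
  expect_length(wavs, 2L)
  ev <- list.files(root, pattern = "_events\\.tsv$", recursive = TRUE,
                   full.names = TRUE)[1]
  rows <- load_bids_table(ev, "events")$rows
  expect_true(all(rows$stim_file %in% wavs))
  # RIFF/WAVE magic in the generated audio
  raw <- readBin(file.path(root, "stimuli", wavs[1]), "raw", 12)
  expect_identical(rawToChar(raw[1:4]), "RIFF")
  expect_identical(rawToChar(raw[9:12]), "WAVE")
})

test_that("every corruption operator injects exactly its target code", {
  reg <- corruption_registry()
  error_codes <- reg$code[startsWith(reg$code, "E_")]
  registry_errors <- issue_registry()
  registry_errors <- registry_errors$code[registry_errors$severity == "error"]
  # full negative coverage: an operator exists for every error code
  expect_setequal(error_codes, registry_errors)

  for (i in seq_len(nrow(reg))) {
    code <- reg$code[i]
    d <- fresh_copy(reg$archetype[i])
    expect_identical(corrupt_dataset(d, code), code)
    report <- validate_dataset(d)
    if (startsWith(code, "E_")) {
      errs <- unique(report$issues$code[report$issues$severity == "error"])
      expect_identical(errs, code, info = code)
      expect_false(report$valid, info = code)
    } else {
      expect_true(code %in% report$issues$code, info = code)
      expect_true(report$valid, info = code)
    }
    unlink(d, recursive = TRUE)
  }

  expect_error(corrupt_dataset(tempdir(), "E_TOTALLY_MADE_UP"),
               class = "ieegbids_unknown_defect")
})
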