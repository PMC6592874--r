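# Shared test fixtures: memoized clean archetype datasets (generated once
# per session, copied per test so corruption operators never touch the
# originals) and an independent byte-level EDF builder used as the
# scaling oracle.

.fixture_cache <- new.env(parent = emptyenv())

clean_dataset <- function(archetype, seed = 42L) {
  key <- paste0(archetype, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    d <- file.path(tempdir(), paste0("ieegbids_fix_", key))
    unlink(d, recursive = TRUE)
    generate_dataset(archetype, d, seed = seed)
    .fixture_cache[[key]] <- d
  }
  .fixture_cache[[key]]
}

fresh_copy <- function(archetype, seed = 42L) {
  src <- clean_dataset(archetype, seed)
  dst <- tempfile(pattern = "ieegbids_copy_")
  dir.create(dst)
  for (f in list.files(src, recursive = TRUE)) {
    dir.create(dirname(file.path(dst, f)), recursive = TRUE,
               showWarnings = FALSE)
    file.copy(file.path(src, f), file.path(dst, f))
  }
  dst
}

tree_md5 <- function(root) {
  f <- sort(list.files(root, recursive = TRUE))
  out <- unname(tools::md5sum(file.path(root, f)))
  names(out) <- f
  out
}

# Independent EDF byte builder: constructs the file directly from field
# strings and an int16 payload, sharing no code with write_edf().
build_edf_bytes <- function(labels, units, pmin, pmax, dmin, dmax, spr,
                            codes, n_records, duration = 1) {
  ns <- length(labels)
  pad <- function(s, w) sprintf(paste0("%-", w, "s"), s)
  hdr <- paste0(pad("0", 8), pad("t", 80), pad("t", 80), pad("02.02.02", 8),
                pad("10.00.00", 8), pad(256 * (ns + 1), 8), pad("", 44),
                pad(n_records, 8), pad(format(duration), 8), pad(ns, 4))
  blk <- function(vals, w) paste(vapply(vals, pad, character(1), w = w),
                                 collapse = "")
  shdr <- paste0(blk(labels, 16), blk(rep("", ns), 80), blk(units, 8),
                 blk(format(pmin, trim = TRUE), 8),
                 blk(format(pmax, trim = TRUE), 8),
                 blk(format(dmin), 8), blk(format(dmax), 8),
                 blk(rep("", ns), 80), blk(spr, 8), blk(rep("", ns), 32))
  payload <- integer(0)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      payload <- c(payload, codes[[i]][((r - 1) * spr[i] + 1):(r * spr[i])])
    }
  }
  f <- tempfile(fileext = ".edf")
  con <- file(f, "wb")
  writeBin(charToRaw(paste0(hdr, shdr)), con)
  writeBin(as.integer(payload), con, size = 2L, endian = "little")
  close(con)
  f
}

# Evaluate a CLI call, swallowing its printed output, returning the status.
capture_status <- function(expr) {
  status <- NULL
  invisible(utils::capture.output(status <- expr))
  status
}

random_recording <- function(n_channels = 3, fs = 100, seconds = 2,
                             seed = 1) {
  set.seed(seed)
  data <- lapply(seq_len(n_channels), function(i) {
    round(runif(fs * seconds, -400, 400), 1)
  })
  names(data) <- paste0("ch", seq_len(n_channels))
  ieeg_recording(data, sampling_frequency = fs,
                 physical_range = c(-3276.8, 3276.7))
}
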