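# Minimal deterministic media writers for fixture datasets: a NIfTI-1
# anatomical volume (via RNifti, gzipped with a fixed-header deflate so
# repeated generation is byte-identical) and a 16-bit PCM WAV stimulus.

#' Write a minimal synthetic anatomical volume
#'
#' An 8x8x8 voxel NIfTI-1 image with 1 mm isotropic voxels and a smooth
#' deterministic intensity pattern: enough to exercise `IntendedFor`
#' resolution and anat-folder handling without real imaging data. The
#' gzip stream is produced with a zero modification time so output is
#' byte-identical across runs.
#'
#' @param path Output path ending in `.nii.gz` (or `.nii` for an
#'   uncompressed volume).
#' @param seed Integer seed for the intensity pattern.
#' @param dim Volume dimensions (default `c(8, 8, 8)`).
#' @return `path`, invisibly.
#' @export
write_minimal_nifti <- function(path, seed = 1L, dim = c(8L, 8L, 8L)) {
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                   z = seq_len(dim[3]))
  phase <- (seed %% 97) / 97 * 2 * pi
  vox <- array(
    as.integer(round(500 + 400 * sin(g$x / 2 + phase) * cos(g$y / 2) +
                       100 * sin(g$z / 2))),
    dim = dim)
  img <- RNifti::asNifti(vox)
  if (endsWith(path, ".gz")) {
    tmp <- tempfile(fileext = ".nii")
    on.exit(unlink(tmp))
    RNifti::writeNifti(img, tmp)
    raw_nii <- readBin(tmp, "raw", n = file.size(tmp))
    con <- gzfile(path, open = "wb")   # R's gzip header carries mtime 0
    writeBin(raw_nii, con)
    close(con)
  } else {
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

# Amplitude envelope tone; "filtered" variant removes the upper partials,
# mimicking the low-pass filtered speech condition.
synth_tone <- function(freq, duration, rate, filtered = FALSE) {
  t <- seq(0, duration, by = 1 / rate)[-1]
  env <- pmin(1, 10 * t) * pmin(1, 10 * (duration - t))
  x <- sin(2 * pi * freq * t)
  if (!filtered) {
    x <- x + 0.4 * sin(2 * pi * 2 * freq * t) +
      0.2 * sin(2 * pi * 3 * freq * t)
  }
  env * x / max(abs(x * env), 1e-9) * 0.8
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param x Numeric samples in `[-1, 1]`.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, rate, path) {
  pcm <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  n <- length(pcm)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw("RIFF"), con)
  writeBin(as.integer(36L + 2L * n), con, size = 4L, endian = "little")
  writeBin(charToRaw("WAVEfmt "), con)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")   # block align
  writeBin(16L, con, size = 2L, endian = "little")  # bits per sample
  writeBin(charToRaw("data"), con)
  writeBin(as.integer(2L * n), con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
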