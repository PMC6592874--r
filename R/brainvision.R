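# BrainVision Core Data Format: .vhdr (INI-style header), .vmrk (markers),
# .eeg (raw multiplexed binary, little-endian). Supported binary encodings
# are INT_16 and IEEE_FLOAT_32; orientation MULTIPLEXED only.

bv_escape <- function(x) {
  if (any(grepl(",", x, fixed = TRUE))) {
    stop_ieeg("bad_recording", "commas are not allowed in BrainVision fields")
  }
  x
}

#' Write a recording as a BrainVision triplet
#'
#' Emits `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg`. All channels must
#' share one sampling frequency (a BrainVision format constraint). Stored
#' values are `physical / resolution`; with `encoding = "float32"` and the
#' default resolution of 1 the roundtrip is bit-exact at 32-bit precision,
#' with `encoding = "int16"` the roundtrip error is bounded by half the
#' per-channel resolution.
#'
#' @param rec An [ieeg_recording()] with a single sampling rate.
#' @param base_path Output path without extension.
#' @param encoding `"float32"` (default) or `"int16"`.
#' @param resolution Per-channel scaling step in physical units (recycled).
#'   Defaults to 1. For `int16`, scaled samples must fit the int16 range.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_brainvision <- function(rec, base_path,
                              encoding = c("float32", "int16"),
                              resolution = 1) {
  stopifnot(inherits(rec, "ieeg_recording"))
  encoding <- match.arg(encoding)
  ch <- rec$channels
  if (length(unique(ch$sampling_frequency)) != 1L) {
    stop_ieeg("mixed_rates",
              "BrainVision requires a single sampling frequency across channels")
  }
  fs <- ch$sampling_frequency[1]
  nch <- nrow(ch)
  n <- ch$n_samples[1]
  resolution <- rep_len(as.numeric(resolution), nch)
  base <- basename(base_path)
  paths <- c(vhdr = paste0(base_path, ".vhdr"),
             vmrk = paste0(base_path, ".vmrk"),
             eeg  = paste0(base_path, ".eeg"))

  vhdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", fmt_num(1e6 / fs)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=",
           if (encoding == "float32") "IEEE_FLOAT_32" else "INT_16"),
    "",
    "[Channel Infos]",
    vapply(seq_len(nch), function(i) {
      sprintf("Ch%d=%s,,%s,%s", i, bv_escape(ch$name[i]),
              fmt_num(resolution[i]), bv_escape(ch$units[i]))
    }, character(1)))
  write_utf8_lines(vhdr, paths[["vhdr"]])

  mk <- rec$markers
  vmrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (!is.null(mk) && nrow(mk) > 0L) {
    vmrk <- c(vmrk, vapply(seq_len(nrow(mk)), function(i) {
      sprintf("Mk%d=%s,%s,%d,%d,0", i + 1L,
              bv_escape(mk$type[i]), bv_escape(mk$description[i]),
              as.integer(mk$onset_sample[i]) + 1L,
              max(1L, as.integer(mk$duration[i])))
    }, character(1)))
  }
  write_utf8_lines(vmrk, paths[["vmrk"]])

  m <- do.call(rbind, rec$data)            # nch x n, column-major => multiplexed
  stored <- sweep(m, 1, resolution, "/")
  con <- file(paths[["eeg"]], open = "wb")
  on.exit(close(con))
  if (encoding == "float32") {
    writeBin(as.numeric(stored), con, size = 4L, endian = "little")
  } else {
    codes <- round(stored)
    if (any(abs(codes) > 32767)) {
      stop_ieeg("resolution_overflow",
                "scaled samples exceed the int16 range; increase resolution")
    }
    writeBin(as.integer(codes), con, size = 2L, endian = "little")
  }
  invisible(paths)
}

parse_ini <- function(lines) {
  out <- list()
  section <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- out[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE) && !is.null(section)) {
      key <- sub("=.*$", "", ln)
      out[[section]][[key]] <- sub("^[^=]*=", "", ln)
    }
  }
  out
}

ini_get <- function(ini, section, key, default = NULL) {
  v <- ini[[section]][[key]]
  v %||% default
}

#' Read a BrainVision triplet into a recording
#'
#' Parses the INI-style header, scales the binary payload by each
#' channel's resolution, derives the sampling frequency from the sampling
#' interval in microseconds, and parses the marker file into a tibble of
#' `(type, description, onset_sample, duration)`.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return An [ieeg_recording()] with `source_format = "brainvision"`.
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) {
    stop_ieeg("unreadable_file",
              sprintf("%s does not exist", dQuote(vhdr_path)))
  }
  ini <- parse_ini(read_utf8_lines(vhdr_path))
  dir <- dirname(vhdr_path)
  data_file <- ini_get(ini, "Common Infos", "DataFile")
  marker_file <- ini_get(ini, "Common Infos", "MarkerFile")
  if (is.null(data_file) || !file.exists(file.path(dir, data_file))) {
    stop_ieeg("missing_companion",
              sprintf("binary data file %s is missing",
                      dQuote(data_file %||% "<unset>")))
  }
  if (!is.null(marker_file) && !file.exists(file.path(dir, marker_file))) {
    stop_ieeg("missing_companion",
              sprintf("marker file %s is missing", dQuote(marker_file)))
  }
  orientation <- ini_get(ini, "Common Infos", "DataOrientation", "MULTIPLEXED")
  if (!identical(orientation, "MULTIPLEXED")) {
    stop_ieeg("unsupported_encoding",
              sprintf("unsupported data orientation %s", dQuote(orientation)))
  }
  binfmt <- ini_get(ini, "Binary Infos", "BinaryFormat")
  if (is.null(binfmt) || !binfmt %in% c("IEEE_FLOAT_32", "INT_16")) {
    stop_ieeg("unsupported_encoding",
              sprintf("unsupported binary format %s",
                      dQuote(binfmt %||% "<unset>")))
  }
  nch <- as.integer(ini_get(ini, "Common Infos", "NumberOfChannels", "0"))
  interval <- as.numeric(ini_get(ini, "Common Infos", "SamplingInterval"))
  if (!is.finite(interval) || interval <= 0) {
    stop_ieeg("bad_header", "SamplingInterval missing or not positive")
  }
  fs <- 1e6 / interval

  ch_entries <- ini[["Channel Infos"]]
  ch_keys <- grep("^Ch[0-9]+$", names(ch_entries), value = TRUE)
  ch_keys <- ch_keys[order(as.integer(sub("^Ch", "", ch_keys)))]
  if (length(ch_keys) != nch) {
    stop_ieeg("inconsistent_channel_count",
              sprintf("NumberOfChannels is %d but %d channels are declared",
                      nch, length(ch_keys)))
  }
  info <- strsplit(unlist(ch_entries[ch_keys], use.names = FALSE), ",")
  nm <- vapply(info, function(f) f[1], character(1))
  res <- vapply(info, function(f) {
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))
  units <- vapply(info, function(f) if (length(f) >= 4) f[4] else "\u00b5V",
                  character(1))

  eeg_path <- file.path(dir, data_file)
  bytes <- file.size(eeg_path)
  word <- if (binfmt == "IEEE_FLOAT_32") 4L else 2L
  if (bytes %% (word * nch) != 0) {
    stop_ieeg("truncated_data",
              "binary payload size is not a whole number of sample frames")
  }
  n <- bytes / (word * nch)
  con <- file(eeg_path, open = "rb")
  on.exit(close(con))
  raw_vals <- if (binfmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = n * nch, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = n * nch, size = 2L, signed = TRUE,
            endian = "little")
  }
  m <- matrix(raw_vals, nrow = nch)      # multiplexed: channel index fastest
  data <- lapply(seq_len(nch), function(i) m[i, ] * res[i])
  names(data) <- nm

  markers <- NULL
  if (!is.null(marker_file)) {
    mk_ini <- parse_ini(read_utf8_lines(file.path(dir, marker_file)))
    mk_entries <- mk_ini[["Marker Infos"]]
    mk_keys <- grep("^Mk[0-9]+$", names(mk_entries), value = TRUE)
    mk_keys <- mk_keys[order(as.integer(sub("^Mk", "", mk_keys)))]
    if (length(mk_keys) > 0L) {
      f <- strsplit(unlist(mk_entries[mk_keys], use.names = FALSE), ",")
      markers <- tibble::tibble(
        type = vapply(f, function(x) x[1], character(1)),
        description = vapply(f, function(x) if (length(x) >= 2) x[2] else "",
                             character(1)),
        onset_sample = vapply(f, function(x) as.integer(x[3]) - 1L,
                              integer(1)),
        duration = vapply(f, function(x) as.integer(x[4]), integer(1)))
      markers <- dplyr::filter(markers, .data$type != "New Segment")
    }
  }

  ieeg_recording(data, sampling_frequency = fs, units = units,
                 markers = markers, source_format = "brainvision",
                 binary_encoding = if (binfmt == "IEEE_FLOAT_32")
                   "float32" else "int16")
}
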