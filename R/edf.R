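# European Data Format (classic EDF) reader and writer.
#
# Layout: 256-byte fixed ASCII header, then 256 bytes of ASCII header per
# signal, then data records of interleaved little-endian int16 samples.
# Records are written with a 1 s duration so samples-per-record equals the
# per-channel sampling rate, which is how EDF expresses variable rates.

EDF_DIG_MIN <- -32768L
EDF_DIG_MAX <- 32767L

pad_ascii <- function(x, width) {
  x <- as.character(x)
  # header fields are ASCII; transliterate the micro sign, then strip
  x <- gsub("\u00b5", "u", x, fixed = TRUE)
  x <- iconv(x, to = "ASCII", sub = "?")
  if (nchar(x) > width) {
    stop_ieeg("label_too_long",
              sprintf("field value %s exceeds %d bytes", dQuote(x), width))
  }
  formatC(x, width = -width, flag = "-")
}

# Render a number into an 8-byte ASCII header field, losslessly for the
# magnitudes EDF carries.
fmt_edf_num <- function(x, width = 8L) {
  s <- format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE,
              digits = 15)
  if (nchar(s) > width) {
    s <- formatC(x, format = "g", digits = width - 2L)
  }
  if (nchar(s) > width) {
    stop_ieeg("bad_header",
              sprintf("numeric value %s does not fit an EDF header field", s))
  }
  s
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit digital codes via the per-channel linear
#' map defined by (`physical_min`, `physical_max`, -32768, 32767). Records
#' span 1 s, so each channel contributes `sampling_frequency` samples per
#' record; channels may differ in rate. Duration must therefore be a whole
#' number of seconds and rates whole numbers of samples per second.
#'
#' @param rec An [ieeg_recording()]; every sample must lie within its
#'   channel's physical range and labels must fit EDF's 16-byte field.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ieeg_recording"))
  ch <- rec$channels
  spr <- ch$sampling_frequency          # samples per 1 s record
  if (any(abs(spr - round(spr)) > 1e-9)) {
    stop_ieeg("bad_recording",
              "EDF writing requires integer sampling rates (1 s records)")
  }
  spr <- as.integer(round(spr))
  n_records <- ch$n_samples[1] / spr[1]
  if (abs(n_records - round(n_records)) > 1e-9) {
    stop_ieeg("bad_recording",
              "EDF writing requires a whole number of 1 s records")
  }
  n_records <- as.integer(round(n_records))

  codes <- vector("list", nrow(ch))
  for (i in seq_len(nrow(ch))) {
    x <- rec$data[[i]]
    pmin <- ch$physical_min[i]; pmax <- ch$physical_max[i]
    if (any(x < pmin) || any(x > pmax)) {
      stop_ieeg("range_overflow",
                sprintf("channel %s has samples outside its physical range",
                        dQuote(ch$name[i])))
    }
    d <- round(EDF_DIG_MIN +
                 (x - pmin) * (EDF_DIG_MAX - EDF_DIG_MIN) / (pmax - pmin))
    codes[[i]] <- as.integer(pmin(pmax(d, EDF_DIG_MIN), EDF_DIG_MAX))
  }

  ns <- nrow(ch)
  header <- paste0(
    pad_ascii("0", 8),
    pad_ascii("X X X X", 80),
    pad_ascii("Startdate 01-JAN-2000 X X X", 80),
    pad_ascii("01.01.00", 8),
    pad_ascii("00.00.00", 8),
    pad_ascii(as.character(256L * (ns + 1L)), 8),
    pad_ascii("", 44),
    pad_ascii(as.character(n_records), 8),
    pad_ascii("1", 8),
    pad_ascii(as.character(ns), 4))
  sig_field <- function(vals, width) {
    paste(vapply(vals, pad_ascii, character(1), width = width),
          collapse = "")
  }
  sig_header <- paste0(
    sig_field(ch$name, 16),
    sig_field(rep("", ns), 80),                     # transducer
    sig_field(ch$units, 8),
    sig_field(vapply(ch$physical_min, fmt_edf_num, character(1)), 8),
    sig_field(vapply(ch$physical_max, fmt_edf_num, character(1)), 8),
    sig_field(rep(as.character(EDF_DIG_MIN), ns), 8),
    sig_field(rep(as.character(EDF_DIG_MAX), ns), 8),
    sig_field(rep("", ns), 80),                     # prefiltering
    sig_field(as.character(spr), 8),
    sig_field(rep("", ns), 32))                     # reserved

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, sig_header)), con)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(codes[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

edf_num <- function(s, what) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (any(is.na(v))) {
    stop_ieeg("bad_header", sprintf("EDF header field %s is not numeric", what))
  }
  v
}

#' Read an EDF file into a recording
#'
#' Digital 16-bit two's-complement samples are mapped to physical values
#' with the per-channel linear map
#' `P = pmin + (D - dmin) * (pmax - pmin) / (dmax - dmin)`; the per-channel
#' sampling frequency is samples-per-record divided by the record duration.
#'
#' @param path EDF file.
#' @return An [ieeg_recording()] with `source_format = "edf"`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) {
    stop_ieeg("unreadable_file", sprintf("%s does not exist", dQuote(path)))
  }
  sz <- file.size(path)
  if (sz < 256L) stop_ieeg("bad_header", "file shorter than an EDF header")
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  fld <- function(from, len) substr(hdr, from, from + len - 1L)
  if (trimws(fld(1, 8)) != "0") {
    stop_ieeg("bad_header", "unsupported EDF version field")
  }
  header_bytes <- edf_num(fld(185, 8), "header bytes")
  n_records <- edf_num(fld(237, 8), "number of records")
  duration <- edf_num(fld(245, 8), "record duration")
  ns <- as.integer(edf_num(fld(253, 4), "signal count"))
  n_records <- as.integer(n_records)
  if (ns < 1L || header_bytes != 256L * (ns + 1L)) {
    stop_ieeg("bad_header", "EDF header size inconsistent with signal count")
  }
  if (n_records < 0 || duration <= 0) {
    stop_ieeg("bad_header", "EDF record count/duration not usable")
  }
  shdr <- rawToChar(readBin(con, "raw", 256L * ns))
  if (nchar(shdr) < 256L * ns) stop_ieeg("bad_header", "truncated signal header")
  sfld <- function(offset, width) {
    vapply(seq_len(ns) - 1L, function(i) {
      substr(shdr, offset * ns + i * width + 1L, offset * ns + (i + 1L) * width)
    }, character(1))
  }
  labels <- trimws(sfld(0, 16))
  units <- vapply(seq_len(ns) - 1L, function(i) {
    trimws(substr(shdr, 96L * ns + i * 8L + 1L, 96L * ns + (i + 1L) * 8L))
  }, character(1))
  at <- function(byte_offset, width) {
    vapply(seq_len(ns) - 1L, function(i) {
      substr(shdr, byte_offset * ns + i * width + 1L,
             byte_offset * ns + (i + 1L) * width)
    }, character(1))
  }
  pmin <- edf_num(at(104, 8), "physical minimum")
  pmax <- edf_num(at(112, 8), "physical maximum")
  dmin <- edf_num(at(120, 8), "digital minimum")
  dmax <- edf_num(at(128, 8), "digital maximum")
  spr  <- as.integer(edf_num(at(216, 8), "samples per record"))
  if (any(dmin == dmax)) {
    stop_ieeg("degenerate_scaling", "digital min equals digital max")
  }
  payload_n <- n_records * sum(spr)
  expected <- 256L * (ns + 1L) + 2 * payload_n
  if (sz < expected) {
    stop_ieeg("truncated_data",
              sprintf("file holds %s bytes but the header promises %s",
                      format(sz), format(expected)))
  }
  raw_codes <- readBin(con, "integer", n = payload_n, size = 2L,
                       signed = TRUE, endian = "little")
  data <- lapply(seq_len(ns), function(i) numeric(n_records * spr[i]))
  pos <- 0L
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      d <- raw_codes[(pos + 1L):(pos + spr[i])]
      pos <- pos + spr[i]
      data[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    }
  }
  names(data) <- labels
  ieeg_recording(data,
                 sampling_frequency = spr / duration,
                 units = units,
                 physical_range = cbind(pmin, pmax),
                 source_format = "edf",
                 binary_encoding = "int16")
}

# Digital codes an EDF writer would emit for one channel; exposed for the
# scaling oracle in tests.
edf_digital_codes <- function(x, pmin, pmax,
                              dmin = EDF_DIG_MIN, dmax = EDF_DIG_MAX) {
  as.integer(round(dmin + (x - pmin) * (dmax - dmin) / (pmax - pmin)))
}
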