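# Internal helpers shared across modules.

# Classed conditions: every user-facing failure mode gets a stable condition
# class "ieegbids_<snake>" so callers (and the validator) can catch precisely.
stop_ieeg <- function(class, msg, ...) {
  rlang::abort(msg, class = c(paste0("ieegbids_", class), "ieegbids_error"), ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` with the RNG seeded, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# UTF-8 text written with "\n" newlines regardless of platform.
write_utf8_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  txt <- paste0(paste(enc2utf8(as.character(lines)), collapse = "\n"), "\n")
  writeBin(charToRaw(txt), con)
  invisible(path)
}

read_utf8_lines <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  if (!validUTF8(txt)) {
    # Latin-1 fallback for legacy headers
    txt <- iconv(txt, from = "latin1", to = "UTF-8")
  } else {
    Encoding(txt) <- "UTF-8"
  }
  strsplit(gsub("\r\n?", "\n", txt), "\n", fixed = TRUE)[[1]]
}

# Deterministic decimal rendering for TSV/INI output: plain notation, no
# trailing zeros, locale-independent.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("n/a")
    s <- format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE,
                nsmall = 0, digits = 15)
    s
  }, character(1))
}

# Byte-order-based lexicographic sort, independent of locale.
sort_c <- function(x) sort(x, method = "radix")

# Round-trip a double vector through IEEE-754 single precision. Useful when
# preparing data destined for a 32-bit binary payload so that the write/read
# cycle is bit-exact.
#' Snap doubles to 32-bit float precision
#'
#' Rounds each value to the nearest IEEE-754 single-precision float and
#' returns it as a double. Data passed through this function round-trips
#' bit-exactly through a `float32` BrainVision payload.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
snap_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "numeric", n = length(x), size = 4L, endian = "little")
}
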