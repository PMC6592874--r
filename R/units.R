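# Electrophysiology unit normalization: SI symbol with optional prefix,
# micro written as the micro sign U+00B5 (never Greek mu U+03BC or ASCII
# "u").

UNIT_PREFIXES <- c("p", "n", "\u00b5", "m", "k", "M")
UNIT_BASES <- c("V", "A", "\u03a9", "Hz", "s", "T", "\u00b0C")
UNIT_BASE_ALIASES <- c("Ohm" = "\u03a9", "ohm" = "\u03a9",
                       "degC" = "\u00b0C")

unit_candidates <- function() {
  c(UNIT_BASES,
    as.vector(outer(UNIT_PREFIXES, UNIT_BASES, paste0)))
}

# Non-throwing core: list(ok, value, suggestion).
unit_info <- function(raw) {
  x <- trimws(raw)
  # Greek mu and ASCII "u" both denote micro; rewrite to U+00B5
  x <- gsub("\u03bc", "\u00b5", x, fixed = TRUE)
  if (x %in% names(UNIT_BASE_ALIASES)) x <- UNIT_BASE_ALIASES[[x]]
  for (al in names(UNIT_BASE_ALIASES)) {
    # prefixed alias, e.g. "kOhm"
    if (nchar(x) > nchar(al) && endsWith(x, al)) {
      pre <- substr(x, 1, nchar(x) - nchar(al))
      if (pre %in% UNIT_PREFIXES || pre == "u") {
        x <- paste0(pre, UNIT_BASE_ALIASES[[al]])
        break
      }
    }
  }
  if (startsWith(x, "u") && substr(x, 2, nchar(x)) %in% UNIT_BASES) {
    x <- paste0("\u00b5", substr(x, 2, nchar(x)))
  }
  cands <- unit_candidates()
  if (x %in% cands) {
    return(list(ok = TRUE, value = x, suggestion = NULL))
  }
  # obvious rewrite: unique case-insensitive match
  lower_hit <- cands[tolower(cands) == tolower(x)]
  sugg <- if (length(lower_hit) == 1L) lower_hit else NULL
  list(ok = FALSE, value = NA_character_, suggestion = sugg)
}

#' Normalize an electrophysiology unit string
#'
#' Physical units in iEEG-BIDS are SI unit symbols with an optional prefix
#' symbol (e.g. `mV`, `µV`), with micro written as the micro sign,
#' Unicode U+00B5. This function canonicalizes common variants: Greek mu
#' (U+03BC) and the ASCII fallback `u` prefix are rewritten to U+00B5, and
#' `Ohm`/`degC` spellings map to their symbols. Normalization is
#' idempotent.
#'
#' @param raw Character vector of unit strings.
#' @return Character vector of canonical unit strings (one-character
#'   prefix from `p, n, µ, m, k, M` plus a base symbol from
#'   `V, A, Ω, Hz, s, T, °C`).
#' @export
normalize_unit <- function(raw) {
  if (any(!nzchar(trimws(raw)))) {
    stop_ieeg("unknown_unit", "unit string must be non-empty")
  }
  vapply(raw, function(r) {
    info <- unit_info(r)
    if (!info$ok) {
      msg <- sprintf("unrecognized unit %s", dQuote(r))
      if (!is.null(info$suggestion)) {
        msg <- paste0(msg, sprintf("; did you mean %s?",
                                   dQuote(info$suggestion)))
      }
      stop_ieeg("unknown_unit", msg, suggestion = info$suggestion)
    }
    info$value
  }, character(1), USE.NAMES = FALSE)
}
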