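# Signal-format compliance registry: two compliant formats, three
# unofficially-supported formats recognized by extension only.

#' Signal format registry
#'
#' iEEG-BIDS accepts two tiers of signal formats: *compliant* formats,
#' which tooling reads and writes (European Data Format and the
#' BrainVision Core triplet), and *unofficially-supported* formats, which
#' are recognized and tolerated but never parsed (Neurodata Without
#' Borders `.nwb`, EEGLAB `.set`, and Multiscale Electrophysiology Format
#' version 3 `.mefd`).
#'
#' @return A tibble with columns `format_id`, `extensions` (list-column),
#'   `tier` (`"compliant"` or `"unofficial"`), and `readable`.
#' @export
format_registry <- function() {
  tibble::tibble(
    format_id = c("edf", "brainvision", "nwb", "eeglab", "mef3"),
    extensions = list(".edf", c(".vhdr", ".vmrk", ".eeg"),
                      ".nwb", ".set", ".mefd"),
    tier = c("compliant", "compliant", "unofficial", "unofficial",
             "unofficial"),
    readable = c(TRUE, TRUE, FALSE, FALSE, FALSE))
}

#' Classify a file's signal format by extension
#'
#' @param x A [bids_path()] object, or a filename/extension string.
#' @return A one-row tibble with `format_id`, `tier`, `readable`, and
#'   `extension`. An unrecognized extension is a classified outcome, not
#'   an error: `format_id = "unknown"`, `tier = "unknown"`; the dataset
#'   validator reports it at error severity.
#' @export
classify_format <- function(x) {
  ext <- if (inherits(x, "bids_path")) {
    x$extension
  } else {
    se <- tryCatch(split_extension(basename(as.character(x))),
                   ieegbids_error = function(e) list(extension = ""))
    if (startsWith(as.character(x), ".")) as.character(x) else se$extension
  }
  reg <- format_registry()
  hit <- which(vapply(reg$extensions, function(e) ext %in% e, logical(1)))
  if (length(hit) == 0L) {
    return(tibble::tibble(format_id = "unknown", tier = "unknown",
                          readable = FALSE, extension = ext))
  }
  tibble::tibble(format_id = reg$format_id[hit[1]], tier = reg$tier[hit[1]],
                 readable = reg$readable[hit[1]], extension = ext)
}
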