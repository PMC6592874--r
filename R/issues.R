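# Validation issue registry: stable codes with a fixed code->severity
# mapping. E_* issues make a dataset invalid; W_* issues mark reduced
# quality but leave it valid (notably unofficially-supported signal
# formats, which pass validation with a warning).

ISSUE_REGISTRY <- tibble::tibble(
  code = c(
    "E_MALFORMED_NAME", "E_UNKNOWN_SUFFIX", "E_UNKNOWN_FORMAT",
    "E_NO_DATASET_DESCRIPTION", "E_NO_IEEG_DATA", "E_MISSING_TASK",
    "E_SESSION_MISMATCH", "E_SIDECAR_MISSING", "E_MISSING_COLUMN",
    "E_MISSING_KEY", "E_JSON_SYNTAX", "E_BAD_VALUE", "E_DUPLICATE_NAME",
    "E_MIXED_DIMENSIONALITY", "E_UNSORTED_EVENTS", "E_COORDSYS_MISSING",
    "E_INTENDEDFOR_DANGLING", "E_CHANNEL_COUNT_MISMATCH",
    "E_CHANNEL_ORDER", "E_CHANNEL_NAME_MISMATCH",
    "E_SAMPLING_FREQUENCY_MISMATCH", "E_MISSING_COMPANION",
    "W_UNOFFICIAL_FORMAT", "W_UNCHECKED", "W_ELECTRODE_UNLOCATED",
    "W_UNKNOWN_KEY", "W_UNKNOWN_CHANNEL_TYPE", "W_UNIT_UNRECOGNIZED",
    "W_NO_CHANNELS_TSV", "W_COLUMN_ORDER"),
  title = c(
    "filename does not follow the entity grammar",
    "filename suffix is not registered",
    "data file extension matches no registered signal format",
    "dataset_description.json is missing at the dataset root",
    "subject has no iEEG recording",
    "iEEG data file lacks the task entity",
    "session folder and ses- entity disagree",
    "recording has no _ieeg.json sidecar",
    "required table column missing",
    "required JSON key missing",
    "file is not well-formed JSON",
    "value outside its controlled vocabulary or range",
    "duplicated name within a table",
    "electrode table mixes 2-D and 3-D rows",
    "event rows not sorted by onset",
    "electrode positions lack a paired coordinate system",
    "IntendedFor points at a file that does not exist",
    "channels table row count differs from the data file",
    "channel names match as a set but not in order",
    "channel names differ between table and data file",
    "channel sampling frequency differs from the data file",
    "BrainVision companion file missing",
    "data file uses an unofficially-supported format",
    "cross-file content checks skipped for this recording",
    "iEEG channel has no electrode position",
    "JSON key outside the sidecar vocabulary",
    "channel type outside the controlled vocabulary",
    "unit string does not normalize",
    "recording has no _channels.tsv",
    "required table columns not in leading order")
)
ISSUE_REGISTRY$severity <- ifelse(startsWith(ISSUE_REGISTRY$code, "E_"),
                                  "error", "warning")

#' Validation issue registry
#'
#' Every finding the validator can emit, with its stable code, severity,
#' and a short description. The code-to-severity mapping is fixed here:
#' structural absences an analyst cannot work around are errors;
#' vocabulary deviations and unofficial formats are warnings.
#'
#' @return A tibble with columns `code`, `title`, `severity`.
#' @export
issue_registry <- function() ISSUE_REGISTRY

issue_severity <- function(code) {
  i <- match(code, ISSUE_REGISTRY$code)
  if (anyNA(i)) {
    stop_ieeg("unknown_issue_code",
              sprintf("unregistered issue code %s",
                      paste(code[is.na(i)], collapse = ", ")))
  }
  ISSUE_REGISTRY$severity[i]
}
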