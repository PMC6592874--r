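# Typed models, readers, writers and single-file validation for the iEEG
# sidecar files: _ieeg.json, _channels.tsv, _electrodes.tsv,
# _coordsystem.json, _events.tsv.
#
# Content problems never throw: loaders return (model, issues) so the
# dataset validator can accumulate findings across files.

CHANNEL_TYPES <- c("ECOG", "SEEG", "DBS", "EEG", "ECG", "EMG", "EOG",
                   "TRIG", "MISC")
IEEG_CHANNEL_TYPES <- c("ECOG", "SEEG", "DBS")
COORD_UNITS <- c("mm", "cm", "m", "pixels")
POWER_LINE_VALUES <- c(50, 60)

TABLE_SCHEMAS <- list(
  channels = list(
    required = c("name", "type", "units"),
    known = c("name", "type", "units", "low_cutoff", "high_cutoff",
              "sampling_frequency", "group", "status", "reference"),
    numeric = c("low_cutoff", "high_cutoff", "sampling_frequency")),
  electrodes = list(
    required = c("name", "x", "y", "z"),
    known = c("name", "x", "y", "z", "size", "group", "material",
              "manufacturer", "hemisphere"),
    numeric = c("x", "y", "z", "size")),
  events = list(
    required = c("onset", "duration"),
    known = c("onset", "duration", "trial_type", "value", "sample",
              "stim_file"),
    numeric = c("onset", "duration", "sample"))
)

# One validation issue as a one-row tibble (registry-checked in issues.R).
issue_row <- function(code, path, message, context = NULL) {
  tibble::tibble(code = code, severity = issue_severity(code), path = path,
                 message = message, context = list(context))
}

no_issues <- function() {
  tibble::tibble(code = character(), severity = character(),
                 path = character(), message = character(),
                 context = list())
}

#' Load a BIDS tabular sidecar file
#'
#' Reads a tab-delimited table with a header row into a typed tibble.
#' `"n/a"` is the sole missing-value token and maps to `NA`. Content
#' problems (missing required columns, non-numeric values, duplicate
#' names, mixed 2-D/3-D electrode coordinates, unsorted events, unknown
#' channel types, unrecognized units) are accumulated as issues, never
#' thrown.
#'
#' @param path TSV file path.
#' @param schema One of `"channels"`, `"electrodes"`, `"events"`.
#' @param relpath Dataset-relative path recorded in issues (defaults to
#'   `path`).
#' @return A list with `rows` (tibble) and `issues` (tibble).
#' @export
load_bids_table <- function(path, schema = c("channels", "electrodes",
                                             "events"),
                            relpath = path) {
  schema <- match.arg(schema)
  sch <- TABLE_SCHEMAS[[schema]]
  if (!file.exists(path)) {
    stop_ieeg("unreadable_file", sprintf("%s does not exist", dQuote(path)))
  }
  issues <- no_issues()
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = character(), progress = FALSE,
                        show_col_types = FALSE)
  df <- tibble::as_tibble(df)
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  # "n/a" -> NA everywhere
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(),
                                        ~ dplyr::na_if(.x, "n/a")))

  missing <- setdiff(sch$required, names(df))
  for (col in missing) {
    issues <- dplyr::bind_rows(issues, issue_row(
      "E_MISSING_COLUMN", relpath,
      sprintf("required column %s is missing from the %s table",
              dQuote(col), schema), list(column = col)))
  }
  lead <- intersect(sch$required, names(df))
  if (length(missing) == 0L &&
      !identical(names(df)[seq_along(sch$required)], sch$required)) {
    issues <- dplyr::bind_rows(issues, issue_row(
      "W_COLUMN_ORDER", relpath,
      sprintf("leading columns should be %s",
              paste(sch$required, collapse = ", "))))
  }

  for (col in intersect(sch$numeric, names(df))) {
    vals <- df[[col]]
    conv <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(conv))
    if (length(bad) > 0L) {
      issues <- dplyr::bind_rows(issues, issue_row(
        "E_BAD_VALUE", relpath,
        sprintf("column %s has non-numeric values (rows %s)", dQuote(col),
                paste(utils::head(bad, 5), collapse = ", ")),
        list(column = col)))
    }
    df[[col]] <- conv
  }

  if ("name" %in% names(df) && anyDuplicated(stats::na.omit(df$name))) {
    dup <- unique(df$name[duplicated(df$name) & !is.na(df$name)])
    issues <- dplyr::bind_rows(issues, issue_row(
      "E_DUPLICATE_NAME", relpath,
      sprintf("duplicated name(s): %s", paste(dup, collapse = ", ")),
      list(names = dup)))
  }

  if (schema == "channels") {
    if ("type" %in% names(df)) {
      unknown <- setdiff(stats::na.omit(unique(df$type)), CHANNEL_TYPES)
      for (tp in unknown) {
        issues <- dplyr::bind_rows(issues, issue_row(
          "W_UNKNOWN_CHANNEL_TYPE", relpath,
          sprintf("channel type %s is not in the controlled vocabulary",
                  dQuote(tp)), list(type = tp)))
      }
    }
    if ("units" %in% names(df)) {
      for (i in seq_len(nrow(df))) {
        u <- df$units[i]
        if (is.na(u)) next
        info <- unit_info(u)
        if (!info$ok) {
          issues <- dplyr::bind_rows(issues, issue_row(
            "W_UNIT_UNRECOGNIZED", relpath,
            sprintf("unit %s on channel %s does not normalize%s", dQuote(u),
                    dQuote(df$name[i] %||% as.character(i)),
                    if (!is.null(info$suggestion))
                      sprintf(" (did you mean %s?)", dQuote(info$suggestion))
                    else ""),
            list(unit = u, suggestion = info$suggestion)))
        }
      }
    }
    if ("sampling_frequency" %in% names(df)) {
      bad <- which(!is.na(df$sampling_frequency) & df$sampling_frequency <= 0)
      if (length(bad) > 0L) {
        issues <- dplyr::bind_rows(issues, issue_row(
          "E_BAD_VALUE", relpath, "sampling_frequency must be positive",
          list(column = "sampling_frequency")))
      }
    }
  }

  if (schema == "electrodes" && "z" %in% names(df) && nrow(df) > 0L) {
    n_na <- sum(is.na(df$z))
    if (n_na != 0L && n_na != nrow(df)) {
      issues <- dplyr::bind_rows(issues, issue_row(
        "E_MIXED_DIMENSIONALITY", relpath,
        "z must be n/a for all rows (2-D table) or for none (3-D table)"))
    }
  }

  if (schema == "events" && all(c("onset", "duration") %in% names(df)) &&
      nrow(df) > 0L) {
    if (any(df$onset < 0, na.rm = TRUE) ||
        any(df$duration < 0, na.rm = TRUE)) {
      issues <- dplyr::bind_rows(issues, issue_row(
        "E_BAD_VALUE", relpath, "onset and duration must be non-negative"))
    }
    if (is.unsorted(df$onset, na.rm = TRUE)) {
      issues <- dplyr::bind_rows(issues, issue_row(
        "E_UNSORTED_EVENTS", relpath,
        "event rows must be sorted by onset (non-decreasing)"))
    }
  }

  list(rows = df, issues = issues)
}

# ---- JSON sidecars ---------------------------------------------------------

IEEG_SIDECAR_REQUIRED <- c("TaskName", "SamplingFrequency",
                           "PowerLineFrequency", "SoftwareFilters",
                           "iEEGReference")
IEEG_SIDECAR_KNOWN <- c(IEEG_SIDECAR_REQUIRED, "Manufacturer",
                        "ManufacturersModelName", "RecordingDuration",
                        "RecordingType", "HardwareFilters",
                        "ElectrodeManufacturer", "ElectricalStimulation",
                        "ECOGChannelCount", "SEEGChannelCount",
                        "EEGChannelCount", "EOGChannelCount",
                        "ECGChannelCount", "EMGChannelCount",
                        "TriggerChannelCount", "MiscChannelCount",
                        "InstitutionName", "TaskDescription", "Instructions")
COUNT_KEYS <- grep("ChannelCount$", IEEG_SIDECAR_KNOWN, value = TRUE)

read_json_object <- function(path, relpath) {
  if (!file.exists(path)) {
    stop_ieeg("unreadable_file", sprintf("%s does not exist", dQuote(path)))
  }
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) e)
  if (inherits(obj, "error") || !is.list(obj)) {
    return(list(ok = FALSE, issues = issue_row(
      "E_JSON_SYNTAX", relpath, "file is not a well-formed JSON object")))
  }
  list(ok = TRUE, obj = obj, issues = no_issues())
}

#' Load an _ieeg.json acquisition sidecar
#'
#' Checks the required keys (task name, sampling frequency, power line
#' frequency, software filters, and the reference scheme used prior to
#' digitization). Unknown keys are warnings and are preserved verbatim so
#' that a write/load cycle is lossless.
#'
#' @param path JSON file path.
#' @param relpath Dataset-relative path recorded in issues.
#' @return A list with `model` (class `ieeg_sidecar`, or `NULL` on syntax
#'   failure) and `issues`.
#' @export
load_ieeg_sidecar <- function(path, relpath = path) {
  r <- read_json_object(path, relpath)
  if (!r$ok) return(list(model = NULL, issues = r$issues))
  obj <- r$obj
  issues <- no_issues()
  for (key in IEEG_SIDECAR_REQUIRED) {
    if (is.null(obj[[key]])) {
      issues <- dplyr::bind_rows(issues, issue_row(
        "E_MISSING_KEY", relpath,
        sprintf("required key %s is missing", dQuote(key)),
        list(key = key)))
    }
  }
  sf <- obj$SamplingFrequency
  if (!is.null(sf) && (!is.numeric(sf) || sf <= 0)) {
    issues <- dplyr::bind_rows(issues, issue_row(
      "E_BAD_VALUE", relpath, "SamplingFrequency must be a positive number",
      list(key = "SamplingFrequency")))
  }
  plf <- obj$PowerLineFrequency
  if (!is.null(plf) && !identical(plf, "n/a") &&
      !(is.numeric(plf) && plf %in% POWER_LINE_VALUES)) {
    issues <- dplyr::bind_rows(issues, issue_row(
      "E_BAD_VALUE", relpath,
      "PowerLineFrequency must be 50, 60, or \"n/a\"",
      list(key = "PowerLineFrequency")))
  }
  for (key in intersect(COUNT_KEYS, names(obj))) {
    v <- obj[[key]]
    if (!is.numeric(v) || v < 0 || v != round(v)) {
      issues <- dplyr::bind_rows(issues, issue_row(
        "E_BAD_VALUE", relpath,
        sprintf("%s must be a non-negative integer", key), list(key = key)))
    }
  }
  for (key in setdiff(names(obj), IEEG_SIDECAR_KNOWN)) {
    issues <- dplyr::bind_rows(issues, issue_row(
      "W_UNKNOWN_KEY", relpath,
      sprintf("key %s is not part of the iEEG sidecar vocabulary (preserved)",
              dQuote(key)), list(key = key)))
  }
  model <- structure(obj, class = "ieeg_sidecar")
  list(model = model, issues = issues)
}

#' Load a _coordsystem.json sidecar
#'
#' `iEEGCoordinateSystem` and `iEEGCoordinateUnits` are mandatory;
#' `iEEGCoordinateSystemDescription` becomes mandatory when the system is
#' the catch-all `"Other"`. Units are restricted to mm, cm, m, pixels.
#'
#' @inheritParams load_ieeg_sidecar
#' @return A list with `model` (class `ieeg_coordsystem`) and `issues`.
#' @export
load_coordsystem <- function(path, relpath = path) {
  r <- read_json_object(path, relpath)
  if (!r$ok) return(list(model = NULL, issues = r$issues))
  obj <- r$obj
  issues <- no_issues()
  for (key in c("iEEGCoordinateSystem", "iEEGCoordinateUnits")) {
    if (is.null(obj[[key]])) {
      issues <- dplyr::bind_rows(issues, issue_row(
        "E_MISSING_KEY", relpath,
        sprintf("required key %s is missing", dQuote(key)),
        list(key = key)))
    }
  }
  if (identical(obj$iEEGCoordinateSystem, "Other") &&
      is.null(obj$iEEGCoordinateSystemDescription)) {
    issues <- dplyr::bind_rows(issues, issue_row(
      "E_MISSING_KEY", relpath,
      "iEEGCoordinateSystemDescription is required when the system is \"Other\"",
      list(key = "iEEGCoordinateSystemDescription")))
  }
  un <- obj$iEEGCoordinateUnits
  if (!is.null(un) && !un %in% COORD_UNITS) {
    issues <- dplyr::bind_rows(issues, issue_row(
      "E_BAD_VALUE", relpath,
      sprintf("iEEGCoordinateUnits %s is not one of %s", dQuote(un),
              paste(COORD_UNITS, collapse = ", ")),
      list(key = "iEEGCoordinateUnits")))
  }
  model <- structure(obj, class = "ieeg_coordsystem")
  list(model = model, issues = issues)
}

# ---- Writers ---------------------------------------------------------------

json_canonical_order <- function(obj, known) {
  c(obj[intersect(known, names(obj))],
    obj[setdiff(names(obj), known)])
}

write_json_sidecar <- function(obj, path, known) {
  obj <- json_canonical_order(obj, known)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = 4, digits = NA,
                          null = "null")
  write_utf8_lines(txt, path)
}

#' Write an _ieeg.json sidecar
#'
#' Keys are emitted in a fixed canonical order (required keys first, then
#' known optional keys, then preserved unknown keys), UTF-8, 4-space
#' indentation; `load_ieeg_sidecar(write_ieeg_sidecar(m))` reproduces `m`.
#'
#' @param model Named list or `ieeg_sidecar` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ieeg_sidecar <- function(model, path) {
  write_json_sidecar(unclass(model), path, IEEG_SIDECAR_KNOWN)
  invisible(path)
}

#' Write a _coordsystem.json sidecar
#' @inheritParams write_ieeg_sidecar
#' @return `path`, invisibly.
#' @export
write_coordsystem <- function(model, path) {
  write_json_sidecar(unclass(model), path,
                     c("iEEGCoordinateSystem", "iEEGCoordinateUnits",
                       "iEEGCoordinateSystemDescription", "IntendedFor"))
  invisible(path)
}

#' Write a BIDS tabular sidecar file
#'
#' Tab delimiter, `"n/a"` for missing values, `"\n"` newlines, columns in
#' canonical order (required columns first). Event tables are emitted
#' sorted by onset. Writing a table that violates its invariants
#' (duplicate names, mixed 2-D/3-D electrode coordinates) is an error.
#'
#' @param rows Tibble of rows (typed; `NA` marks missing).
#' @param path Output path.
#' @param schema One of `"channels"`, `"electrodes"`, `"events"`.
#' @return `path`, invisibly.
#' @export
write_bids_table <- function(rows, path, schema = c("channels", "electrodes",
                                                    "events")) {
  schema <- match.arg(schema)
  sch <- TABLE_SCHEMAS[[schema]]
  missing <- setdiff(sch$required, names(rows))
  if (length(missing) > 0L) {
    stop_ieeg("invariant_violation",
              sprintf("missing required column(s): %s",
                      paste(missing, collapse = ", ")))
  }
  if ("name" %in% names(rows) && anyDuplicated(rows$name)) {
    stop_ieeg("invariant_violation", "names must be unique")
  }
  if (schema == "electrodes" && nrow(rows) > 0L) {
    n_na <- sum(is.na(rows$z))
    if (n_na != 0L && n_na != nrow(rows)) {
      stop_ieeg("invariant_violation",
                "electrode table must be uniformly 2-D or 3-D")
    }
  }
  if (schema == "events" && nrow(rows) > 0L) {
    rows <- rows[order(rows$onset, method = "radix"), , drop = FALSE]
  }
  cols <- c(intersect(sch$known, names(rows)),
            setdiff(names(rows), sch$known))
  rows <- rows[, cols, drop = FALSE]
  rendered <- vapply(cols, function(col) {
    v <- rows[[col]]
    if (is.numeric(v)) fmt_num(v) else ifelse(is.na(v), "n/a", as.character(v))
  }, character(nrow(rows)))
  if (nrow(rows) == 1L) rendered <- matrix(rendered, nrow = 1L)
  if (nrow(rows) == 0L) rendered <- matrix(character(0), ncol = length(cols))
  lines <- c(paste(cols, collapse = "\t"),
             apply(rendered, 1L, paste, collapse = "\t"))
  write_utf8_lines(lines, path)
  invisible(path)
}
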