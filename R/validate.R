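# Whole-dataset validation: tree and name checks, per-file sidecar
# checks, signal-format tier checks, then the cross-file consistency
# rules that tie channels, electrodes, coordinate systems and images
# together. Reports are deterministic: issues sorted by (path, code).

#' Validate an iEEG-BIDS dataset tree
#'
#' Runs, in order: filename/tree checks (entity grammar, session
#' consistency, dataset scaffold), per-file sidecar content checks,
#' signal-format tier checks, and cross-file checks (coordinate-system
#' pairing, channel/electrode agreement). Everything found is an issue in
#' the report; the only hard error is a nonexistent root.
#'
#' A dataset is *valid* iff it has no error-severity issues. Datasets
#' whose only deviation is an unofficially-supported signal format are
#' valid with warnings.
#'
#' @param root Dataset root directory.
#' @return An object of class `ieeg_validation` with fields `issues`
#'   (tibble: `code`, `severity`, `path`, `message`, `context`),
#'   `summary` (named counts), `valid` (logical), `root`, and `n_files`.
#' @export
validate_dataset <- function(root) {
  if (!dir.exists(root)) {
    stop_ieeg("not_a_directory", sprintf("%s is not a directory", dQuote(root)))
  }
  files <- enumerate_dataset(root)
  issues <- no_issues()
  add <- function(...) issues <<- dplyr::bind_rows(issues, issue_row(...))

  # 1. name checks -----------------------------------------------------------
  for (i in which(files$category == "invalid")) {
    code <- if (identical(files$error_class[i], "ieegbids_unknown_suffix"))
      "E_UNKNOWN_SUFFIX" else "E_MALFORMED_NAME"
    add(code, files$path[i], files$message[i])
  }

  bids <- dplyr::filter(files, .data$category == "bids")

  # session folder vs ses- entity: jointly optional, but if either is
  # present both are required and equal
  for (i in seq_len(nrow(bids))) {
    ds <- bids$dir_session[i]
    fs <- bids$session[i]
    if (!identical(is.na(ds), is.na(fs)) ||
        (!is.na(ds) && !identical(ds, fs))) {
      add("E_SESSION_MISMATCH", bids$path[i], sprintf(
        "session folder (%s) and ses- entity (%s) disagree",
        if (is.na(ds)) "absent" else ds, if (is.na(fs)) "absent" else fs))
    }
  }

  # 2. dataset scaffold -------------------------------------------------------
  issues <- dplyr::bind_rows(issues, check_dataset_scaffold(root, files))

  # 3. per-file checks --------------------------------------------------------
  anchors <- dplyr::filter(bids, .data$suffix == "ieeg",
                           !.data$extension %in% c(".json", ".tsv",
                                                   ".eeg", ".vmrk"))
  loaded <- new.env(parent = emptyenv())   # cache of parsed sidecars
  load_cached <- function(row, loader, schema = NULL) {
    key <- row$path
    if (!is.null(loaded[[key]])) return(loaded[[key]])
    res <- if (is.null(schema)) loader(file.path(root, key), relpath = key)
           else loader(file.path(root, key), schema, relpath = key)
    loaded[[key]] <- res
    res
  }

  for (i in seq_len(nrow(bids))) {
    row <- bids[i, ]
    res <- switch(
      row$suffix,
      channels   = load_cached(row, load_bids_table, "channels"),
      electrodes = load_cached(row, load_bids_table, "electrodes"),
      events     = load_cached(row, load_bids_table, "events"),
      coordsystem = load_cached(row, load_coordsystem),
      ieeg = if (row$extension == ".json")
        load_cached(row, load_ieeg_sidecar) else NULL,
      NULL)
    if (!is.null(res)) issues <- dplyr::bind_rows(issues, res$issues)
  }

  # 4. signal format tier + cross-file checks --------------------------------
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    fmt <- classify_format(a$parsed[[1]])
    if (fmt$tier == "unknown") {
      add("E_UNKNOWN_FORMAT", a$path, sprintf(
        "extension %s matches no registered iEEG signal format",
        dQuote(a$extension)))
    } else if (fmt$tier == "unofficial") {
      add("W_UNOFFICIAL_FORMAT", a$path, sprintf(
        "%s is unofficially supported; its payload is not checked",
        fmt$format_id))
    }
    if (is.na(a$task)) {
      add("E_MISSING_TASK", a$path, "iEEG data files require a task entity")
    }
    issues <- dplyr::bind_rows(
      issues,
      check_recording(root, a, files, fmt, load_cached))
  }

  # 5. coordinate-system pairing ---------------------------------------------
  issues <- dplyr::bind_rows(issues,
                             check_coordsystem_pairing(root, files, load_cached))

  finalize_report(root, files, issues)
}

finalize_report <- function(root, files, issues) {
  ord <- order(issues$path, issues$code, method = "radix")
  issues <- issues[ord, , drop = FALSE]
  n_err <- sum(issues$severity == "error")
  n_warn <- sum(issues$severity == "warning")
  structure(
    list(issues = issues,
         summary = c(error = n_err, warning = n_warn),
         valid = n_err == 0L,
         root = root,
         n_files = sum(files$category != "invalid")),
    class = "ieeg_validation")
}

#' Check the dataset scaffold
#'
#' Requires `dataset_description.json` at the root and, for every subject
#' folder, an `ieeg` datatype directory holding at least one data file.
#' An iEEG-BIDS dataset must contain iEEG recordings: a subject with only
#' anatomical data is an error.
#'
#' @param root Dataset root.
#' @param files Enumeration tibble (computed from `root` if omitted).
#' @return Issues tibble.
#' @export
check_dataset_scaffold <- function(root, files = enumerate_dataset(root)) {
  issues <- no_issues()
  top <- vapply(strsplit(files$path, "/", fixed = TRUE),
                function(p) p[1], character(1))
  if (!"dataset_description.json" %in% files$path) {
    issues <- dplyr::bind_rows(issues, issue_row(
      "E_NO_DATASET_DESCRIPTION", ".",
      "dataset_description.json is required at the dataset root"))
  }
  subjects <- sort_c(unique(top[grepl("^sub-[A-Za-z0-9]+$", top)]))
  if (length(subjects) == 0L) {
    issues <- dplyr::bind_rows(issues, issue_row(
      "E_NO_IEEG_DATA", ".",
      "dataset contains no subject folders with iEEG recordings"))
    return(issues)
  }
  bids <- dplyr::filter(files, .data$category == "bids")
  for (s in subjects) {
    label <- sub("^sub-", "", s)
    has_data <- any(bids$subject == label & bids$suffix == "ieeg" &
                      !bids$extension %in% c(".json", ".tsv", ".eeg", ".vmrk"),
                    na.rm = TRUE)
    if (!has_data) {
      issues <- dplyr::bind_rows(issues, issue_row(
        "E_NO_IEEG_DATA", s,
        sprintf("%s has no iEEG data file under an ieeg/ directory", s)))
    }
  }
  issues
}

# Cross-file checks for one recording anchor (a data file row).
check_recording <- function(root, a, files, fmt, load_cached) {
  issues <- no_issues()
  add <- function(...) issues <<- dplyr::bind_rows(issues, issue_row(...))
  p <- a$parsed[[1]]

  sidecars <- tryCatch(resolve_sidecars(p, files),
                       ieegbids_ambiguous_sidecar = function(e) NULL)
  if (is.null(sidecars)) {
    # ambiguity is reported as a bad-value issue on the data file
    add("E_BAD_VALUE", a$path,
        "two sidecars apply at the same specificity level")
    return(issues)
  }
  js <- dplyr::filter(sidecars, .data$suffix == "ieeg",
                      .data$extension == ".json")
  if (nrow(js) == 0L) {
    add("E_SIDECAR_MISSING", a$path,
        "no _ieeg.json sidecar applies to this recording")
  }
  ch_rows <- dplyr::filter(sidecars, .data$suffix == "channels")
  if (nrow(ch_rows) == 0L) {
    add("W_NO_CHANNELS_TSV", a$path,
        "no _channels.tsv applies to this recording")
    return(issues)
  }
  ch_row <- ch_rows[nrow(ch_rows), ]      # most specific wins
  tab <- load_cached(ch_row, load_bids_table, "channels")$rows
  if (!all(c("name", "type") %in% names(tab))) return(issues)

  # electrode coverage: every iEEG-type channel should appear in some
  # electrode table of this subject(/session); spare electrodes that were
  # never recorded from are fine
  el_rows <- dplyr::filter(files, .data$category == "bids",
                           .data$suffix == "electrodes")
  keep <- purrr::map_lgl(el_rows$parsed, function(s)
    entities_subset_of(s, p, ignore = "space"))
  el_rows <- el_rows[keep, , drop = FALSE]
  el_names <- unique(unlist(purrr::map(seq_len(nrow(el_rows)), function(j) {
    load_cached(el_rows[j, ], load_bids_table, "electrodes")$rows$name
  })))
  ieeg_ch <- tab$name[!is.na(tab$type) & tab$type %in% IEEG_CHANNEL_TYPES]
  for (nm in setdiff(ieeg_ch, el_names)) {
    add("W_ELECTRODE_UNLOCATED", ch_row$path, sprintf(
      "iEEG channel %s appears in no electrode table", dQuote(nm)),
      list(channel = nm))
  }

  # content checks need a readable payload
  if (!fmt$readable) {
    add("W_UNCHECKED", a$path, sprintf(
      "channel count and sampling-rate checks skipped (%s payload not parsed)",
      fmt$format_id))
    return(issues)
  }
  rec <- tryCatch({
    if (fmt$format_id == "edf") read_edf(file.path(root, a$path))
    else read_brainvision(file.path(root, a$path))
  }, ieegbids_missing_companion = function(e) e,
     ieegbids_error = function(e) e)
  if (inherits(rec, "ieegbids_missing_companion")) {
    add("E_MISSING_COMPANION", a$path, conditionMessage(rec))
    return(issues)
  }
  if (!inherits(rec, "ieeg_recording")) {
    add("W_UNCHECKED", a$path, sprintf(
      "data file could not be read (%s); content checks skipped",
      conditionMessage(rec)))
    return(issues)
  }

  file_names <- rec$channels$name
  if (nrow(tab) != length(file_names)) {
    add("E_CHANNEL_COUNT_MISMATCH", ch_row$path, sprintf(
      "channels table lists %d channels but the data file has %d",
      nrow(tab), length(file_names)),
      list(table = nrow(tab), file = length(file_names)))
    return(issues)
  }
  if (!identical(tab$name, file_names)) {
    if (setequal(tab$name, file_names)) {
      add("E_CHANNEL_ORDER", ch_row$path,
          "channel names match the data file as a set but not in order")
    } else {
      add("E_CHANNEL_NAME_MISMATCH", ch_row$path, sprintf(
        "channel names differ from the data file (e.g. %s vs %s)",
        dQuote(setdiff(tab$name, file_names)[1] %||% "?"),
        dQuote(setdiff(file_names, tab$name)[1] %||% "?")))
    }
    return(issues)
  }
  if ("sampling_frequency" %in% names(tab)) {
    tf <- tab$sampling_frequency
    bad <- which(!is.na(tf) &
                   abs(tf - rec$channels$sampling_frequency) > 1e-6)
    if (length(bad) > 0L) {
      add("E_SAMPLING_FREQUENCY_MISMATCH", ch_row$path, sprintf(
        "sampling_frequency disagrees with the data file for channel(s) %s",
        paste(tab$name[utils::head(bad, 5)], collapse = ", ")))
    }
  }
  issues
}

#' Check electrode/coordinate-system pairing
#'
#' Every `_electrodes.tsv` must be paired with a `_coordsystem.json`
#' carrying the same entity set (including the `space` entity, so
#' electrodes localized in multiple spaces pair space-by-space). When a
#' coordinate system declares `IntendedFor`, the referenced image must
#' exist in the dataset.
#'
#' @param root Dataset root.
#' @param files Enumeration tibble (computed from `root` if omitted).
#' @param load_cached Internal loader cache (optional).
#' @return Issues tibble.
#' @export
check_coordsystem_pairing <- function(root, files = enumerate_dataset(root),
                                      load_cached = NULL) {
  issues <- no_issues()
  add <- function(...) issues <<- dplyr::bind_rows(issues, issue_row(...))
  if (is.null(load_cached)) {
    load_cached <- function(row, loader, schema = NULL) {
      if (is.null(schema)) loader(file.path(root, row$path), relpath = row$path)
      else loader(file.path(root, row$path), schema, relpath = row$path)
    }
  }
  bids <- dplyr::filter(files, .data$category == "bids")
  el <- dplyr::filter(bids, .data$suffix == "electrodes")
  cs <- dplyr::filter(bids, .data$suffix == "coordsystem")
  key_of <- function(p) {
    ents <- entity_set(p)
    paste(names(ents), unlist(lapply(ents, as.character)),
          sep = "=", collapse = ";")
  }
  cs_keys <- vapply(cs$parsed, key_of, character(1))
  for (i in seq_len(nrow(el))) {
    k <- key_of(el$parsed[[i]])
    if (!k %in% cs_keys) {
      add("E_COORDSYS_MISSING", el$path[i],
          "electrode positions must be paired with an explicit coordinate system")
    }
  }
  for (i in seq_len(nrow(cs))) {
    model <- load_cached(cs[i, ], load_coordsystem)$model
    if (is.null(model)) next
    intended <- model$IntendedFor
    if (!is.null(intended)) {
      target <- sub("^bids::", "", intended)
      if (!file.exists(file.path(root, target))) {
        add("E_INTENDEDFOR_DANGLING", cs$path[i], sprintf(
          "IntendedFor target %s does not exist in the dataset",
          dQuote(intended)), list(intended_for = intended))
      }
    }
    # pixels are only meaningful for 2-D electrode tables
    if (identical(model$iEEGCoordinateUnits, "pixels")) {
      j <- which(cs_keys[i] == vapply(el$parsed, key_of, character(1)))
      for (jj in j) {
        rows <- load_cached(el[jj, ], load_bids_table, "electrodes")$rows
        if ("z" %in% names(rows) && nrow(rows) > 0L && !all(is.na(rows$z))) {
          add("E_BAD_VALUE", cs$path[i],
              "iEEGCoordinateUnits \"pixels\" requires a 2-D electrode table")
        }
      }
    }
  }
  issues
}

#' Check channel/electrode consistency for one recording
#'
#' Convenience wrapper that runs the per-recording cross-file checks
#' (channel count and order against the data file, electrode coverage of
#' iEEG channels, sampling-frequency agreement, unit normalization) for a
#' single data file path.
#'
#' @param root Dataset root.
#' @param data_path Dataset-relative path of the data file.
#' @return Issues tibble.
#' @export
check_channel_electrode_consistency <- function(root, data_path) {
  files <- enumerate_dataset(root)
  a <- dplyr::filter(files, .data$path == data_path)
  if (nrow(a) != 1L || a$category != "bids") {
    stop_ieeg("unreadable_file",
              sprintf("%s is not a parsed data file in the dataset",
                      dQuote(data_path)))
  }
  fmt <- classify_format(a$parsed[[1]])
  load_cached <- function(row, loader, schema = NULL) {
    if (is.null(schema)) loader(file.path(root, row$path), relpath = row$path)
    else loader(file.path(root, row$path), schema, relpath = row$path)
  }
  check_recording(root, a, files, fmt, load_cached)
}

# ---- report methods --------------------------------------------------------

#' @export
print.ieeg_validation <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.ieeg_validation <- function(x, ...) {
  head <- sprintf("iEEG-BIDS validation of %s: %s (%d error(s), %d warning(s), %d file(s))",
                  x$root, if (x$valid) "VALID" else "INVALID",
                  x$summary[["error"]], x$summary[["warning"]], x$n_files)
  if (nrow(x$issues) == 0L) return(c(head, "  no issues"))
  c(head, sprintf("  [%s] %s %s: %s",
                  ifelse(x$issues$severity == "error", "ERROR", "WARN "),
                  x$issues$code, x$issues$path, x$issues$message))
}

#' Serialize a validation report to JSON
#'
#' Machine-readable form: `{"issues": [...], "summary": {...}, "valid":
#' ...}`, deterministic for identical datasets (no timestamps).
#'
#' @param x An `ieeg_validation` report.
#' @return A JSON string.
#' @export
validation_json <- function(x) {
  stopifnot(inherits(x, "ieeg_validation"))
  issues <- purrr::map(seq_len(nrow(x$issues)), function(i) {
    out <- list(code = x$issues$code[i], severity = x$issues$severity[i],
                path = x$issues$path[i], message = x$issues$message[i])
    ctx <- x$issues$context[[i]]
    if (!is.null(ctx)) out$context <- ctx
    out
  })
  jsonlite::toJSON(list(issues = issues,
                        summary = as.list(x$summary),
                        valid = x$valid),
                   auto_unbox = TRUE, pretty = 2, digits = NA, null = "null")
}

#' Tidy the issues of a validation report
#' @param x An `ieeg_validation` report.
#' @param ... Unused.
#' @return The issues tibble.
#' @export
tidy.ieeg_validation <- function(x, ...) x$issues

#' One-row summary of a validation report
#' @param x An `ieeg_validation` report.
#' @param ... Unused.
#' @return A one-row tibble with `valid`, `n_errors`, `n_warnings`,
#'   `n_files`.
#' @export
glance.ieeg_validation <- function(x, ...) {
  tibble::tibble(valid = x$valid, n_errors = x$summary[["error"]],
                 n_warnings = x$summary[["warning"]], n_files = x$n_files)
}

#' Issue count plot for a validation report
#' @param object An `ieeg_validation` report.
#' @param ... Unused.
#' @return A ggplot object (bar chart of issue counts per code, colored
#'   by severity).
#' @export
autoplot.ieeg_validation <- function(object, ...) {
  df <- dplyr::count(object$issues, .data$code, .data$severity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$code,
                                   fill = .data$severity)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "issues", y = NULL, fill = "severity")
}
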