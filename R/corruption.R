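# Corruption operators for negative testing: one operator per
# error-severity code in the validator registry, each applying exactly
# one logical mutation to a clean generated dataset so that validating
# the corrupted tree yields exactly the targeted code among its errors.

find_one <- function(root, pattern) {
  hits <- sort_c(list.files(root, pattern = pattern, recursive = TRUE))
  if (length(hits) == 0L) {
    stop_ieeg("unknown_defect",
              sprintf("no file matching %s in %s to corrupt", pattern,
                      dQuote(root)))
  }
  hits[1]
}

edit_tsv <- function(root, rel, fn) {
  path <- file.path(root, rel)
  lines <- read_utf8_lines(path)
  write_utf8_lines(fn(lines), path)
}

edit_json <- function(root, rel, fn) {
  path <- file.path(root, rel)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  write_json_sidecar(fn(obj), path, known = names(obj))
}

# Strip one entity (e.g. "task" or "ses") from every filename of the
# first recording's file set: one logical mutation, keeps sidecar
# resolution intact.
strip_entity_everywhere <- function(root, key) {
  files <- sort_c(list.files(root, recursive = TRUE))
  targets <- files[grepl(paste0("(^|/|_)", key, "-[A-Za-z0-9]+_"),
                         basename(files))]
  if (length(targets) == 0L) {
    stop_ieeg("unknown_defect",
              sprintf("no filenames carry the %s entity", key))
  }
  for (f in targets) {
    new_name <- file.path(dirname(f),
                          sub(paste0(key, "-[A-Za-z0-9]+_"), "",
                              basename(f)))
    file.rename(file.path(root, f), file.path(root, new_name))
  }
  invisible(NULL)
}

CORRUPTIONS <- list(
  E_NO_DATASET_DESCRIPTION = list(
    archetype = "motor_movement",
    apply = function(root) unlink(file.path(root,
                                            "dataset_description.json"))),
  E_NO_IEEG_DATA = list(
    archetype = "multimodal_ecog_mri",
    apply = function(root) {
      ieeg_dirs <- list.dirs(root, recursive = TRUE, full.names = TRUE)
      unlink(ieeg_dirs[basename(ieeg_dirs) == "ieeg"], recursive = TRUE)
    }),
  E_MALFORMED_NAME = list(
    archetype = "motor_movement",
    apply = function(root) {
      f <- find_one(root, "_events\\.tsv$")
      file.rename(file.path(root, f),
                  file.path(root, dirname(f),
                            sub("task-", "task", basename(f), fixed = TRUE)))
    }),
  E_UNKNOWN_SUFFIX = list(
    archetype = "motor_movement",
    apply = function(root) {
      f <- find_one(root, "_events\\.tsv$")
      file.rename(file.path(root, f),
                  file.path(root, dirname(f),
                            sub("_events\\.tsv$", "_bogus.tsv", basename(f))))
    }),
  E_UNKNOWN_FORMAT = list(
    archetype = "motor_movement",
    apply = function(root) {
      f <- find_one(root, "_ieeg\\.edf$")
      file.rename(file.path(root, f),
                  file.path(root, sub("\\.edf$", ".xyz", f)))
    }),
  E_MISSING_TASK = list(
    archetype = "motor_movement",
    apply = function(root) strip_entity_everywhere(root, "task")),
  E_SESSION_MISMATCH = list(
    archetype = "seizure_seeg",
    apply = function(root) strip_entity_everywhere(root, "ses")),
  E_SIDECAR_MISSING = list(
    archetype = "motor_movement",
    apply = function(root) unlink(file.path(root,
                                            find_one(root, "_ieeg\\.json$")))),
  E_MISSING_COLUMN = list(
    archetype = "motor_movement",
    apply = function(root) {
      edit_tsv(root, find_one(root, "_channels\\.tsv$"), function(lines) {
        cells <- strsplit(lines, "\t", fixed = TRUE)
        drop <- match("units", cells[[1]])
        vapply(cells, function(r) paste(r[-drop], collapse = "\t"),
               character(1))
      })
    }),
  E_MISSING_KEY = list(
    archetype = "motor_movement",
    apply = function(root) {
      edit_json(root, find_one(root, "_ieeg\\.json$"), function(obj) {
        obj$iEEGReference <- NULL
        obj
      })
    }),
  E_JSON_SYNTAX = list(
    archetype = "motor_movement",
    apply = function(root) {
      write_utf8_lines("{", file.path(root, find_one(root, "_ieeg\\.json$")))
    }),
  E_BAD_VALUE = list(
    archetype = "motor_movement",
    apply = function(root) {
      edit_json(root, find_one(root, "_coordsystem\\.json$"), function(obj) {
        obj$iEEGCoordinateUnits <- "furlongs"
        obj
      })
    }),
  E_DUPLICATE_NAME = list(
    archetype = "motor_movement",
    apply = function(root) {
      edit_tsv(root, find_one(root, "_electrodes\\.tsv$"), function(lines) {
        r2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
        r3 <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
        r3[1] <- r2[1]
        lines[3] <- paste(r3, collapse = "\t")
        lines
      })
    }),
  E_MIXED_DIMENSIONALITY = list(
    archetype = "motor_movement",
    apply = function(root) {
      edit_tsv(root, find_one(root, "_electrodes\\.tsv$"), function(lines) {
        hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
        zi <- match("z", hdr)
        r2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
        r2[zi] <- "n/a"
        lines[2] <- paste(r2, collapse = "\t")
        lines
      })
    }),
  E_UNSORTED_EVENTS = list(
    archetype = "motor_movement",
    apply = function(root) {
      edit_tsv(root, find_one(root, "_events\\.tsv$"), function(lines) {
        c(lines[1], rev(lines[-1]))
      })
    }),
  E_COORDSYS_MISSING = list(
    archetype = "motor_movement",
    apply = function(root) {
      unlink(file.path(root, find_one(root, "_coordsystem\\.json$")))
    }),
  E_INTENDEDFOR_DANGLING = list(
    archetype = "multimodal_ecog_mri",
    apply = function(root) {
      edit_json(root, find_one(root, "_coordsystem\\.json$"), function(obj) {
        obj$IntendedFor <- "sub-01/anat/sub-01_acq-missing_T1w.nii.gz"
        obj
      })
    }),
  E_CHANNEL_COUNT_MISMATCH = list(
    archetype = "motor_movement",
    apply = function(root) {
      edit_tsv(root, find_one(root, "_channels\\.tsv$"),
               function(lines) lines[-length(lines)])
    }),
  E_CHANNEL_ORDER = list(
    archetype = "motor_movement",
    apply = function(root) {
      edit_tsv(root, find_one(root, "_channels\\.tsv$"), function(lines) {
        c(lines[1], lines[3], lines[2], lines[-(1:3)])
      })
    }),
  E_CHANNEL_NAME_MISMATCH = list(
    archetype = "motor_movement",
    apply = function(root) {
      edit_tsv(root, find_one(root, "_channels\\.tsv$"), function(lines) {
        r2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
        r2[1] <- "BOGUS"
        lines[2] <- paste(r2, collapse = "\t")
        lines
      })
    }),
  E_SAMPLING_FREQUENCY_MISMATCH = list(
    archetype = "motor_movement",
    apply = function(root) {
      edit_tsv(root, find_one(root, "_channels\\.tsv$"), function(lines) {
        hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
        si <- match("sampling_frequency", hdr)
        r2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
        r2[si] <- "9999"
        lines[2] <- paste(r2, collapse = "\t")
        lines
      })
    }),
  E_MISSING_COMPANION = list(
    archetype = "visual_stimulus",
    apply = function(root) {
      unlink(file.path(root, find_one(root, "_ieeg\\.eeg$")))
    }),
  W_UNOFFICIAL_FORMAT = list(
    archetype = "motor_movement",
    apply = function(root) {
      f <- find_one(root, "_ieeg\\.edf$")
      file.rename(file.path(root, f),
                  file.path(root, sub("\\.edf$", ".nwb", f)))
    })
)

#' Corruption operator registry
#'
#' One operator per error code in [issue_registry()] (plus the
#' unofficial-format warning), with the archetype each operator is
#' designed to run on.
#'
#' @return A tibble with columns `code` and `archetype`.
#' @export
corruption_registry <- function() {
  tibble::tibble(code = names(CORRUPTIONS),
                 archetype = vapply(CORRUPTIONS, function(x) x$archetype,
                                    character(1)))
}

#' Inject one defect into a clean generated dataset
#'
#' Applies exactly one mutation chosen by `defect_code`, designed so that
#' [validate_dataset()] on the mutated tree reports the targeted code
#' among its error-severity issues (and, for single-file defects, only
#' that code).
#'
#' @param root A clean generated dataset (ideally of the archetype listed
#'   in [corruption_registry()] for that code).
#' @param defect_code One of the codes in [corruption_registry()].
#' @return `defect_code`, invisibly.
#' @export
corrupt_dataset <- function(root, defect_code) {
  op <- CORRUPTIONS[[defect_code]]
  if (is.null(op)) {
    stop_ieeg("unknown_defect",
              sprintf("unknown defect code %s; known codes: %s",
                      dQuote(defect_code),
                      paste(names(CORRUPTIONS), collapse = ", ")))
  }
  op$apply(root)
  invisible(defect_code)
}
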