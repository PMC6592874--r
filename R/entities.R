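# BIDS filename grammar for iEEG datasets: entity parsing, canonical
# rendering, dataset enumeration, and sidecar resolution.

# Entity keys in their fixed filename order, mapped to field names.
ENTITY_KEYS <- c(sub = "subject", ses = "session", task = "task",
                 acq = "acquisition", run = "run", space = "space")

# Known suffixes, their datatype directory, and allowed extensions.
SUFFIX_REGISTRY <- list(
  ieeg = list(datatype = "ieeg",
              extensions = c(".edf", ".vhdr", ".vmrk", ".eeg", ".nwb",
                             ".set", ".mefd", ".json", ".tsv")),
  channels    = list(datatype = "ieeg", extensions = ".tsv"),
  electrodes  = list(datatype = "ieeg", extensions = ".tsv"),
  coordsystem = list(datatype = "ieeg", extensions = ".json"),
  events      = list(datatype = "ieeg", extensions = ".tsv"),
  photo       = list(datatype = "ieeg", extensions = c(".jpg", ".png")),
  T1w         = list(datatype = "anat", extensions = c(".nii", ".nii.gz")),
  dataset_description = list(datatype = "", extensions = ".json")
)

# Extensions recognised anywhere in the grammar (multi-dot first so that
# ".nii.gz" wins over ".gz").
KNOWN_EXTENSIONS <- c(".nii.gz", ".edf", ".vhdr", ".vmrk", ".eeg", ".nwb",
                      ".set", ".mefd", ".json", ".tsv", ".nii", ".jpg",
                      ".png", ".wav")

# Extensions that anchor a recording (one data file per recording).  The
# BrainVision companions .eeg/.vmrk belong to their .vhdr anchor.
DATA_ANCHOR_EXTENSIONS <- c(".edf", ".vhdr", ".nwb", ".set", ".mefd")

is_valid_label <- function(x) grepl("^[A-Za-z0-9]+$", x)

#' Construct a BIDS path object
#'
#' A `bids_path` captures the parsed identity of one file in an iEEG-BIDS
#' dataset: its entities (`subject`, `session`, `task`, `acquisition`,
#' `run`, `space`), its `suffix`, its `extension`, and the datatype
#' directory it lives in.
#'
#' @param subject,session,task,acquisition,space Optional entity labels,
#'   alphanumeric only (hyphen and underscore are filename delimiters and
#'   therefore excluded from labels).
#' @param run Optional positive integer run index. Rendered zero-padded to
#'   at least two digits; any parsed width is preserved for re-rendering.
#' @param suffix Filename suffix, one of the registered iEEG-BIDS suffixes
#'   (`ieeg`, `channels`, `electrodes`, `coordsystem`, `events`, `T1w`,
#'   `dataset_description`, ...).
#' @param extension File extension including the leading dot (`.edf`,
#'   `.vhdr`, `.tsv`, `.json`, `.nii.gz`, ...).
#' @param datatype Datatype directory (`"ieeg"`, `"anat"`, or `""` for
#'   root-level files). Defaults to the suffix's registered datatype.
#' @param run_width Rendering width for `run` (kept on parse so that
#'   build-then-parse is the identity).
#' @return An object of class `bids_path`.
#' @seealso [parse_bids_path()], [build_bids_path()]
#' @export
bids_path <- function(subject = NULL, session = NULL, task = NULL,
                      acquisition = NULL, run = NULL, space = NULL,
                      suffix, extension, datatype = NULL, run_width = 2L) {
  for (f in list(subject = subject, session = session, task = task,
                 acquisition = acquisition, space = space)) {
    if (!is.null(f) && !is_valid_label(f)) {
      stop_ieeg("malformed_name",
                sprintf("entity label %s is not alphanumeric", dQuote(f)))
    }
  }
  if (!is.null(run)) {
    run <- as.integer(run)
    if (is.na(run) || run < 1L) {
      stop_ieeg("malformed_name", "run must be a positive integer")
    }
  }
  if (!suffix %in% names(SUFFIX_REGISTRY)) {
    stop_ieeg("unknown_suffix", sprintf("unknown suffix %s", dQuote(suffix)))
  }
  if (!is.character(extension) || !startsWith(extension, ".")) {
    stop_ieeg("malformed_name", "extension must start with '.'")
  }
  structure(
    list(subject = subject, session = session, task = task,
         acquisition = acquisition, run = run, space = space,
         suffix = suffix, extension = extension,
         datatype = datatype %||% SUFFIX_REGISTRY[[suffix]]$datatype,
         run_width = max(2L, as.integer(run_width))),
    class = "bids_path")
}

#' @export
print.bids_path <- function(x, ...) {
  cat("<bids_path> ", build_bids_path(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bids_path <- function(x, ...) build_bids_path(x)

entity_set <- function(p) {
  ents <- p[c("subject", "session", "task", "acquisition", "run", "space")]
  ents[!vapply(ents, is.null, logical(1))]
}

split_extension <- function(filename) {
  for (ext in KNOWN_EXTENSIONS) {
    if (endsWith(filename, ext)) {
      return(list(stem = substr(filename, 1L, nchar(filename) - nchar(ext)),
                  extension = ext))
    }
  }
  m <- regexpr("\\.[^.]+$", filename)
  if (m == -1L) {
    stop_ieeg("malformed_name",
              sprintf("%s has no extension", dQuote(filename)))
  }
  list(stem = substr(filename, 1L, m - 1L),
       extension = substr(filename, m, nchar(filename)))
}

#' Parse a relative path into a BIDS path object
#'
#' Splits a dataset-relative path into its entities, suffix, extension and
#' datatype directory. Unknown entity keys, malformed key-value segments,
#' duplicated entities, and entities placed after the suffix are rejected,
#' never silently dropped.
#'
#' @param path Relative path within a dataset root, e.g.
#'   `"sub-01/ieeg/sub-01_task-visual_ieeg.json"`.
#' @return A [bids_path()] object. The directory-level session label (if
#'   any) is attached as attribute `"dir_session"` so the validator can
#'   cross-check it against the filename's `ses-` entity.
#' @export
parse_bids_path <- function(path) {
  path <- gsub("\\\\", "/", path)
  if (startsWith(path, "/")) {
    stop_ieeg("malformed_name", "path must be relative to the dataset root")
  }
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  filename <- parts[length(parts)]
  dirs <- parts[-length(parts)]

  se <- split_extension(filename)
  if (se$stem %in% names(SUFFIX_REGISTRY)) {
    # suffix-only root files (the dataset_description suffix itself
    # contains an underscore, so it must not go through entity splitting)
    return(bids_path(suffix = se$stem, extension = se$extension,
                     datatype = ""))
  }
  segments <- strsplit(se$stem, "_", fixed = TRUE)[[1]]
  if (length(segments) == 0L || any(!nzchar(segments))) {
    stop_ieeg("malformed_name",
              sprintf("%s: empty filename segment", dQuote(filename)))
  }
  suffix <- segments[length(segments)]
  if (grepl("-", suffix, fixed = TRUE)) {
    stop_ieeg("malformed_name",
              sprintf("%s: filename ends in an entity, suffix is missing",
                      dQuote(filename)))
  }
  ent_segments <- segments[-length(segments)]

  ents <- list()
  run_width <- 2L
  for (seg in ent_segments) {
    if (!grepl("-", seg, fixed = TRUE)) {
      stop_ieeg("malformed_name",
                sprintf("%s: segment %s has no hyphen (entities appearing after the suffix are also reported here)",
                        dQuote(filename), dQuote(seg)))
    }
    key <- sub("-.*$", "", seg)
    value <- sub("^[^-]*-", "", seg)
    if (!key %in% names(ENTITY_KEYS)) {
      stop_ieeg("malformed_name",
                sprintf("%s: unknown entity key %s", dQuote(filename),
                        dQuote(key)))
    }
    field <- ENTITY_KEYS[[key]]
    if (field %in% names(ents)) {
      stop_ieeg("malformed_name",
                sprintf("%s: duplicated entity %s", dQuote(filename),
                        dQuote(key)))
    }
    if (!is_valid_label(value)) {
      stop_ieeg("malformed_name",
                sprintf("%s: entity value %s is not alphanumeric",
                        dQuote(filename), dQuote(value)))
    }
    if (field == "run") {
      if (!grepl("^[0-9]+$", value)) {
        stop_ieeg("malformed_name",
                  sprintf("%s: run index %s is not numeric",
                          dQuote(filename), dQuote(value)))
      }
      run_width <- nchar(value)
      value <- as.integer(value)
    }
    ents[[field]] <- value
  }

  if (!suffix %in% names(SUFFIX_REGISTRY)) {
    stop_ieeg("unknown_suffix",
              sprintf("%s: unknown suffix %s", dQuote(filename),
                      dQuote(suffix)))
  }

  # Directory structure: [sub-XX [ses-YY] <datatype>] / filename
  datatype <- ""
  dir_session <- NULL
  if (length(dirs) > 0L) {
    if (!grepl("^sub-[A-Za-z0-9]+$", dirs[1])) {
      stop_ieeg("malformed_name",
                sprintf("%s: first directory %s is not a sub- folder",
                        dQuote(path), dQuote(dirs[1])))
    }
    dir_subject <- sub("^sub-", "", dirs[1])
    if (is.null(ents$subject) || !identical(ents$subject, dir_subject)) {
      stop_ieeg("malformed_name",
                sprintf("%s: subject folder %s does not match filename entities",
                        dQuote(path), dQuote(dirs[1])))
    }
    rest <- dirs[-1]
    if (length(rest) > 0L && grepl("^ses-[A-Za-z0-9]+$", rest[1])) {
      dir_session <- sub("^ses-", "", rest[1])
      rest <- rest[-1]
    }
    if (length(rest) > 1L) {
      stop_ieeg("malformed_name",
                sprintf("%s: too many directory levels", dQuote(path)))
    }
    if (length(rest) == 1L) {
      if (!rest[1] %in% c("ieeg", "anat")) {
        stop_ieeg("malformed_name",
                  sprintf("%s: unknown datatype directory %s",
                          dQuote(path), dQuote(rest[1])))
      }
      datatype <- rest[1]
    }
  }

  p <- bids_path(subject = ents$subject, session = ents$session,
                 task = ents$task, acquisition = ents$acquisition,
                 run = ents$run, space = ents$space,
                 suffix = suffix, extension = se$extension,
                 datatype = datatype, run_width = run_width)
  attr(p, "dir_session") <- dir_session
  p
}

render_filename <- function(p) {
  segs <- character(0)
  ents <- entity_set(p)
  for (key in names(ENTITY_KEYS)) {
    field <- ENTITY_KEYS[[key]]
    if (!is.null(ents[[field]])) {
      value <- ents[[field]]
      if (field == "run") {
        value <- formatC(value, width = p$run_width %||% 2L, flag = "0")
      }
      segs <- c(segs, paste0(key, "-", value))
    }
  }
  paste0(paste(c(segs, p$suffix), collapse = "_"), p$extension)
}

#' Render a BIDS path object to its canonical relative path
#'
#' The inverse of [parse_bids_path()]: entities are rendered in the fixed
#' order `sub`, `ses`, `task`, `acq`, `run`, `space`, followed by the
#' suffix and extension, inside the `sub-<label>/[ses-<label>/]<datatype>/`
#' directory chain. `parse_bids_path(build_bids_path(p))` reproduces `p`'s
#' entity set exactly.
#'
#' @param p A [bids_path()] object.
#' @return Relative path string.
#' @export
build_bids_path <- function(p) {
  stopifnot(inherits(p, "bids_path"))
  if (is.null(p$subject) && !p$suffix %in% c("dataset_description")) {
    # Root-level sidecars (inheritance) are allowed for .json/.tsv; data
    # files require a subject.
    if (!p$extension %in% c(".json", ".tsv")) {
      stop_ieeg("missing_entity",
                sprintf("suffix %s data files require a subject entity",
                        dQuote(p$suffix)))
    }
  }
  if (p$suffix == "ieeg" && p$extension %in% DATA_ANCHOR_EXTENSIONS &&
      is.null(p$task)) {
    stop_ieeg("missing_entity", "iEEG data files require a task entity")
  }
  filename <- render_filename(p)
  if (is.null(p$subject) || identical(p$datatype, "")) {
    dirs <- if (is.null(p$subject)) character(0) else
      c(paste0("sub-", p$subject),
        if (!is.null(p$session)) paste0("ses-", p$session))
  } else {
    dirs <- c(paste0("sub-", p$subject),
              if (!is.null(p$session)) paste0("ses-", p$session),
              p$datatype)
  }
  paste(c(dirs, filename), collapse = "/")
}

# Root-level files that are BIDS-legal but not entity-named.
PASSTHROUGH_PATTERNS <- c("^README(\\.md|\\.txt)?$", "^CHANGES$", "^LICENSE$",
                          "^participants\\.(tsv|json)$")

is_passthrough <- function(relpath) {
  parts <- strsplit(relpath, "/", fixed = TRUE)[[1]]
  if (parts[1] %in% c("stimuli", "sourcedata")) return(TRUE)
  if (any(startsWith(parts, "."))) return(TRUE)
  if (length(parts) == 1L &&
      any(vapply(PASSTHROUGH_PATTERNS, grepl, logical(1), x = parts[1]))) {
    return(TRUE)
  }
  FALSE
}

#' Enumerate an iEEG-BIDS dataset tree
#'
#' Walks `root` and classifies every file: entity-named files are parsed
#' with [parse_bids_path()]; files on the root-level allowlist (`README`,
#' `CHANGES`, `LICENSE`, `participants.tsv/.json`), everything under
#' `/stimuli/` or `/sourcedata/`, and hidden files pass through unparsed;
#' unparseable names are recorded with their error, never dropped. The
#' result is a pure function of directory content, in byte-lexicographic
#' path order.
#'
#' @param root Dataset root directory.
#' @return A tibble with one row per file: `path` (dataset-relative),
#'   `category` (`"bids"`, `"passthrough"`, or `"invalid"`), the entity
#'   columns, `suffix`, `extension`, `datatype`, `dir_session`,
#'   `error_class`/`message` for invalid names, and a `parsed` list-column
#'   of `bids_path` objects.
#' @export
enumerate_dataset <- function(root) {
  if (!dir.exists(root)) {
    stop_ieeg("not_a_directory", sprintf("%s is not a directory", dQuote(root)))
  }
  rel <- list.files(root, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  rel <- sort_c(rel)
  rows <- purrr::map(rel, function(rp) {
    if (is_passthrough(rp)) {
      return(tibble::tibble(path = rp, category = "passthrough",
                            subject = NA_character_, session = NA_character_,
                            task = NA_character_, acquisition = NA_character_,
                            run = NA_integer_, space = NA_character_,
                            suffix = NA_character_, extension = NA_character_,
                            datatype = NA_character_,
                            dir_session = NA_character_,
                            error_class = NA_character_,
                            message = NA_character_, parsed = list(NULL)))
    }
    p <- tryCatch(parse_bids_path(rp), ieegbids_error = function(e) e)
    if (inherits(p, "bids_path")) {
      tibble::tibble(path = rp, category = "bids",
                     subject = p$subject %||% NA_character_,
                     session = p$session %||% NA_character_,
                     task = p$task %||% NA_character_,
                     acquisition = p$acquisition %||% NA_character_,
                     run = p$run %||% NA_integer_,
                     space = p$space %||% NA_character_,
                     suffix = p$suffix, extension = p$extension,
                     datatype = p$datatype,
                     dir_session = attr(p, "dir_session") %||% NA_character_,
                     error_class = NA_character_, message = NA_character_,
                     parsed = list(p))
    } else {
      cls <- intersect(class(p), c("ieegbids_malformed_name",
                                   "ieegbids_unknown_suffix"))
      tibble::tibble(path = rp, category = "invalid",
                     subject = NA_character_, session = NA_character_,
                     task = NA_character_, acquisition = NA_character_,
                     run = NA_integer_, space = NA_character_,
                     suffix = NA_character_, extension = NA_character_,
                     datatype = NA_character_, dir_session = NA_character_,
                     error_class = if (length(cls)) cls[1] else "ieegbids_error",
                     message = conditionMessage(p), parsed = list(NULL))
    }
  })
  dplyr::bind_rows(rows)
}

# Sidecar suffixes applicable to an ieeg data file, with their extensions.
SIDECAR_SUFFIXES <- list(ieeg = ".json", channels = ".tsv",
                         electrodes = ".tsv", coordsystem = ".json",
                         events = ".tsv")

entities_subset_of <- function(sidecar, target, ignore = character(0)) {
  se <- entity_set(sidecar)
  te <- entity_set(target)
  se <- se[setdiff(names(se), ignore)]
  all(vapply(names(se), function(n) {
    !is.null(te[[n]]) && identical(te[[n]], se[[n]])
  }, logical(1)))
}

#' Resolve the metadata sidecars applicable to a data file
#'
#' Implements BIDS inheritance: a sidecar applies to a data file when its
#' entities are a subset of the data file's entities and its suffix is one
#' of the sidecar suffixes (`ieeg.json`, `channels.tsv`, `electrodes.tsv`,
#' `coordsystem.json`, `events.tsv`). Results are ordered from most
#' general (dataset root, fewest entities) to most specific, so later
#' entries override earlier ones.
#'
#' @param p A `bids_path` for an `ieeg` data file.
#' @param files Enumeration tibble from [enumerate_dataset()].
#' @param suffixes Restrict to these sidecar suffixes (default: all five).
#' @return Tibble of matching rows from `files`, in override order.
#' @export
resolve_sidecars <- function(p, files,
                             suffixes = names(SIDECAR_SUFFIXES)) {
  stopifnot(inherits(p, "bids_path"))
  cand <- dplyr::filter(files, .data$category == "bids",
                        .data$suffix %in% suffixes,
                        .data$extension %in% c(".json", ".tsv"))
  # The data file's own .json/.tsv twin is a sidecar of itself only for the
  # ieeg suffix; exclude the data file proper.
  keep <- purrr::map_lgl(cand$parsed, function(s) {
    ext_ok <- identical(s$extension,
                        SIDECAR_SUFFIXES[[s$suffix]] %||% "")
    ext_ok && entities_subset_of(s, p)
  })
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  spec_level <- purrr::map_int(cand$parsed,
                               function(s) length(entity_set(s)))
  ord <- order(spec_level, cand$path, method = "radix")
  cand <- cand[ord, , drop = FALSE]
  spec_level <- spec_level[ord]
  # Two sidecars of the same suffix at the same specificity level cannot be
  # ordered: ambiguous.
  key <- paste(cand$suffix, spec_level)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_ieeg("ambiguous_sidecar",
              sprintf("multiple %s sidecars at the same specificity level",
                      dQuote(sub(" .*", "", dup))))
  }
  cand
}
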