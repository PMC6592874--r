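# Seeded synthetic dataset generation: five canonical iEEG study
# archetypes (auditory filtered speech, motor movement, visual stimulus,
# seizure sEEG, multimodal ECoG+MRI), each emitted as a complete
# iEEG-BIDS tree that passes validation with zero errors, plus corruption
# operators that inject exactly one defect for negative testing.
#
# Scale is deliberately tiny (1-2 subjects, <= 16 channels, <= 10 s at
# <= 512 Hz) so that a full corpus regenerates in seconds.

ARCHETYPES <- list(
  auditory_speech = list(
    task = "auditory", n_subjects = 1L, data_format = "brainvision",
    encoding = "int16", resolution = 0.1, coordinate_mode = "3d_mm",
    power_line = 60, duration = 6,
    layout = list(list(group = "G", kind = "grid", n = 8L, type = "ECOG",
                       rate = 512)),
    events = list(clear = 3L, filtered = 3L),
    stimuli = c(clear = "stimuli/tone_clear.wav",
                filtered = "stimuli/tone_filtered.wav"),
    coordsystem = list(iEEGCoordinateSystem = "ACPC",
                       iEEGCoordinateUnits = "mm")),
  motor_movement = list(
    task = "motor", n_subjects = 2L, data_format = "edf",
    coordinate_mode = "3d_mm", power_line = 60, duration = 8, run = 1L,
    layout = list(list(group = "G", kind = "grid", n = 8L, type = "ECOG",
                       rate = 256),
                  list(group = "S", kind = "strip", n = 4L, type = "ECOG",
                       rate = 256),
                  list(group = "TRIG", kind = "misc", n = 1L, type = "TRIG",
                       rate = 256)),
    events = list(move = 4L, rest = 4L),
    coordsystem = list(iEEGCoordinateSystem = "ACPC",
                       iEEGCoordinateUnits = "mm")),
  visual_stimulus = list(
    task = "visual", n_subjects = 1L, data_format = "brainvision",
    encoding = "float32", coordinate_mode = "2d_pixels",
    power_line = 50, duration = 6,
    layout = list(list(group = "G", kind = "grid", n = 10L, type = "ECOG",
                       rate = 500)),
    events = list(stim = 5L),
    coordsystem = list(
      iEEGCoordinateSystem = "Other",
      iEEGCoordinateUnits = "pixels",
      iEEGCoordinateSystemDescription =
        "2-D grid positions on an intraoperative photograph")),
  seizure_seeg = list(
    task = "seizure", n_subjects = 1L, session = "01",
    data_format = "edf", coordinate_mode = "3d_mm", power_line = 50,
    duration = 8,
    layout = list(list(group = "A", kind = "depth", n = 6L, type = "SEEG",
                       rate = 512),
                  list(group = "B", kind = "depth", n = 6L, type = "SEEG",
                       rate = 256)),
    events = list(spike = 4L, seizure = 1L),
    coordsystem = list(iEEGCoordinateSystem = "ACPC",
                       iEEGCoordinateUnits = "mm")),
  multimodal_ecog_mri = list(
    task = "rest", n_subjects = 1L, data_format = "edf",
    coordinate_mode = "3d_mm", power_line = 60, duration = 6,
    anat = TRUE,
    layout = list(list(group = "G", kind = "grid", n = 8L, type = "ECOG",
                       rate = 256)),
    events = list(rest = 2L),
    coordsystem = list(
      iEEGCoordinateSystem = "Other",
      iEEGCoordinateUnits = "mm",
      iEEGCoordinateSystemDescription =
        "scanner-native space of the subject's T1-weighted image"))
)

#' The five synthetic dataset archetypes
#'
#' @return A tibble describing each archetype: id, task, number of
#'   subjects, signal format/encoding, coordinate mode, sampling rates,
#'   and duration.
#' @export
ieeg_archetypes <- function() {
  tibble::tibble(
    archetype_id = names(ARCHETYPES),
    task = vapply(ARCHETYPES, function(a) a$task, character(1)),
    n_subjects = vapply(ARCHETYPES, function(a) a$n_subjects, integer(1)),
    data_format = vapply(ARCHETYPES, function(a) a$data_format, character(1)),
    encoding = vapply(ARCHETYPES, function(a)
      a$encoding %||% "int16", character(1)),
    coordinate_mode = vapply(ARCHETYPES, function(a) a$coordinate_mode,
                             character(1)),
    rates = vapply(ARCHETYPES, function(a)
      paste(sort_c(fmt_num(unique(vapply(a$layout, function(l) l$rate,
                                         numeric(1))))), collapse = "/"),
      character(1)),
    duration = vapply(ARCHETYPES, function(a) a$duration, numeric(1)))
}

archetype_channels <- function(a) {
  purrr::map_dfr(a$layout, function(l) {
    nm <- if (l$n == 1L) l$group else paste0(l$group, seq_len(l$n))
    tibble::tibble(name = nm, group = l$group, kind = l$kind,
                   type = l$type, rate = l$rate)
  })
}

# Deterministic event plan: onsets on a 0.25 s grid, trial types cycled.
plan_events <- function(a, seed) {
  with_seed(seed, {
    types <- rep(names(a$events), unlist(a$events))
    n <- length(types)
    grid <- seq(0.5, a$duration - 1, by = 0.25)
    onsets <- sort(sample(grid, n))
    tibble::tibble(onset = onsets, duration = 0.5,
                   trial_type = sample(types))
  })
}

#' Synthesize a multi-channel iEEG signal
#'
#' Per channel: pink-ish background (a 1/f-weighted sum of sinusoids with
#' random phases), a mains component at the archetype's power-line
#' frequency, and event-locked amplitude bumps at the planned event
#' onsets. Fully determined by `(archetype_id, seed)`.
#'
#' @param archetype_id One of the ids in [ieeg_archetypes()].
#' @param seed Integer seed.
#' @param events Optional event plan (tibble with `onset`); defaults to
#'   the archetype's own plan.
#' @return An [ieeg_recording()].
#' @export
synthesize_signal <- function(archetype_id, seed, events = NULL) {
  a <- ARCHETYPES[[archetype_id]]
  if (is.null(a)) {
    stop_ieeg("unknown_archetype",
              sprintf("unknown archetype %s", dQuote(archetype_id)))
  }
  if (a$duration <= 0) {
    stop_ieeg("bad_recording", "archetype duration must be positive")
  }
  ch <- archetype_channels(a)
  events <- events %||% plan_events(a, seed + 17L)
  data <- vector("list", nrow(ch))
  with_seed(seed, {
    for (i in seq_len(nrow(ch))) {
      fs <- ch$rate[i]
      n <- as.integer(round(a$duration * fs))
      t <- (seq_len(n) - 1) / fs
      if (ch$type[i] == "TRIG") {
        x <- numeric(n)
        for (o in events$onset) {
          x[t >= o & t < o + 0.1] <- 100
        }
      } else {
        freqs <- exp(seq(log(1), log(min(80, fs / 3)), length.out = 20))
        x <- numeric(n)
        for (f in freqs) {
          x <- x + (30 / sqrt(f)) * sin(2 * pi * f * t +
                                          stats::runif(1, 0, 2 * pi))
        }
        x <- x + 5 * sin(2 * pi * a$power_line * t +
                           stats::runif(1, 0, 2 * pi))
        for (o in events$onset) {
          x <- x + 40 * exp(-(t - o - 0.15)^2 / (2 * 0.05^2)) *
            sin(2 * pi * 10 * t)
        }
        x <- x + stats::rnorm(n, sd = 2)
      }
      data[[i]] <- round(x, 1)      # 0.1 microvolt quantum, EDF/int16 friendly
    }
  })
  names(data) <- ch$name
  if (identical(a$data_format, "brainvision") &&
      identical(a$encoding %||% "int16", "float32")) {
    data <- lapply(data, snap_float32)
  }
  ieeg_recording(data, sampling_frequency = ch$rate,
                 units = ifelse(ch$type == "TRIG", "n/a", "\u00b5V"),
                 physical_range = c(-3276.8, 3276.7),
                 markers = tibble::tibble(
                   type = "Stimulus",
                   description = events$trial_type,
                   onset_sample = as.integer(round(events$onset * ch$rate[1])),
                   duration = 1L))
}

# Schematic electrode geometry in mm: grids/strips on a hemisphere
# surface of radius 70 mm, depth leads along straight trajectories with
# 3.5 mm contact spacing.
electrode_coords <- function(ch, mode, seed) {
  with_seed(seed, {
    groups <- unique(ch$group[ch$kind != "misc"])
    out <- purrr::map_dfr(groups, function(g) {
      rows <- ch[ch$group == g, ]
      n <- nrow(rows)
      if (mode == "2d_pixels") {
        col <- (seq_len(n) - 1) %% 5
        rw <- (seq_len(n) - 1) %/% 5
        return(tibble::tibble(name = rows$name,
                              x = 200 + 60 * col + round(stats::runif(n, -3, 3)),
                              y = 150 + 60 * rw + round(stats::runif(n, -3, 3)),
                              z = NA_real_))
      }
      if (rows$kind[1] == "depth") {
        entry <- c(stats::runif(1, -60, -40), stats::runif(1, -40, -20),
                   stats::runif(1, -10, 10))
        dirv <- c(1, stats::runif(1, -0.2, 0.2), stats::runif(1, -0.2, 0.2))
        dirv <- dirv / sqrt(sum(dirv^2))
        k <- seq_len(n) - 1
        tibble::tibble(name = rows$name,
                       x = round(entry[1] + 3.5 * k * dirv[1], 2),
                       y = round(entry[2] + 3.5 * k * dirv[2], 2),
                       z = round(entry[3] + 3.5 * k * dirv[3], 2))
      } else {
        az0 <- stats::runif(1, -0.6, 0.6)
        el0 <- stats::runif(1, 0.2, 0.8)
        ncol <- if (rows$kind[1] == "grid") 4L else n
        col <- (seq_len(n) - 1) %% ncol
        rw <- (seq_len(n) - 1) %/% ncol
        az <- az0 + 0.14 * col
        el <- el0 + 0.14 * rw
        tibble::tibble(name = rows$name,
                       x = round(70 * cos(el) * sin(az), 2),
                       y = round(70 * cos(el) * cos(az), 2),
                       z = round(70 * sin(el), 2))
      }
    })
    out
  })
}

#' Generate a complete synthetic iEEG-BIDS dataset
#'
#' Writes one of the five archetype datasets under `root`:
#' `dataset_description.json`, a participants table, per-subject `ieeg/`
#' files (signal data plus all five sidecar types, electrodes and
#' coordinate system per the archetype's coordinate mode), a `/stimuli/`
#' folder with generated audio for the auditory archetype, and a minimal
#' anatomical volume for the multimodal archetype. Generation is a pure
#' function of `(archetype_id, seed)`: trees are byte-identical across
#' runs. Every generated tree passes [validate_dataset()] with zero
#' errors.
#'
#' @param archetype_id One of the ids in [ieeg_archetypes()].
#' @param root Target directory (must be empty or absent).
#' @param seed Integer seed (default 1).
#' @return `root`, invisibly.
#' @export
generate_dataset <- function(archetype_id, root, seed = 1L) {
  a <- ARCHETYPES[[archetype_id]]
  if (is.null(a)) {
    stop_ieeg("unknown_archetype",
              sprintf("unknown archetype %s; valid ids: %s",
                      dQuote(archetype_id),
                      paste(names(ARCHETYPES), collapse = ", ")))
  }
  if (dir.exists(root) && length(list.files(root, all.files = TRUE,
                                            no.. = TRUE)) > 0L) {
    stop_ieeg("target_not_empty",
              sprintf("%s exists and is not empty", dQuote(root)))
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  write_json_sidecar(list(
    Name = paste0("Synthetic iEEG dataset (", archetype_id, ")"),
    BIDSVersion = "1.4.0",
    DatasetType = "raw",
    Authors = list("ieegbids fixture generator")),
    file.path(root, "dataset_description.json"),
    known = c("Name", "BIDSVersion", "DatasetType", "Authors"))

  subjects <- sprintf("%02d", seq_len(a$n_subjects))
  write_utf8_lines(c("participant_id\tage\tsex",
                     vapply(seq_along(subjects), function(i) {
                       sprintf("sub-%s\t%d\t%s", subjects[i],
                               25L + ((seed + 7L * i) %% 40L),
                               c("M", "F")[1L + (seed + i) %% 2L])
                     }, character(1))),
                   file.path(root, "participants.tsv"))

  if (!is.null(a$stimuli)) {
    dir.create(file.path(root, "stimuli"), showWarnings = FALSE)
    write_wav(synth_tone(440, 0.4, 8000, filtered = FALSE),
              8000, file.path(root, a$stimuli[["clear"]]))
    write_wav(synth_tone(440, 0.4, 8000, filtered = TRUE),
              8000, file.path(root, a$stimuli[["filtered"]]))
  }

  for (si in seq_along(subjects)) {
    generate_subject(a, archetype_id, root, subjects[si],
                     seed + 1000L * si)
  }
  invisible(root)
}

generate_subject <- function(a, archetype_id, root, sub, seed) {
  ch <- archetype_channels(a)
  events <- plan_events(a, seed + 17L)
  rec <- synthesize_signal(archetype_id, seed, events = events)

  data_ext <- if (a$data_format == "edf") ".edf" else ".vhdr"
  data_p <- bids_path(subject = sub, session = a$session, task = a$task,
                      run = a$run, suffix = "ieeg", extension = data_ext)
  rel <- build_bids_path(data_p)
  dir.create(dirname(file.path(root, rel)), recursive = TRUE,
             showWarnings = FALSE)

  if (a$data_format == "edf") {
    write_edf(rec, file.path(root, rel))
  } else {
    base <- sub("\\.vhdr$", "", file.path(root, rel))
    enc <- a$encoding %||% "int16"
    write_brainvision(rec, base, encoding = enc,
                      resolution = if (enc == "int16")
                        a$resolution %||% 0.1 else 1)
  }

  # _ieeg.json
  counts <- table(ch$type)
  sidecar <- c(list(
    TaskName = a$task,
    SamplingFrequency = max(ch$rate),
    PowerLineFrequency = a$power_line,
    SoftwareFilters = "n/a",
    iEEGReference =
      "common average of all intracranial channels, referenced prior to digitization",
    Manufacturer = "synthetic",
    RecordingDuration = a$duration),
    stats::setNames(as.list(as.integer(counts)),
                    paste0(sub("^ECOG$", "ECOG", names(counts)),
                           "ChannelCount")))
  names(sidecar) <- sub("^TRIGChannelCount$", "TriggerChannelCount",
                        names(sidecar))
  write_ieeg_sidecar(sidecar, file.path(root, build_bids_path(
    bids_path(subject = sub, session = a$session, task = a$task,
              run = a$run, suffix = "ieeg", extension = ".json"))))

  # _channels.tsv — order matches the data file exactly
  channels <- tibble::tibble(
    name = ch$name, type = ch$type,
    units = ifelse(ch$type == "TRIG", NA_character_, "\u00b5V"),
    low_cutoff = 0.1, high_cutoff = ch$rate / 4,
    sampling_frequency = ch$rate,
    group = ch$group, status = "good")
  write_bids_table(channels, file.path(root, build_bids_path(
    bids_path(subject = sub, session = a$session, task = a$task,
              run = a$run, suffix = "channels", extension = ".tsv"))),
    schema = "channels")

  # _events.tsv
  ev <- dplyr::mutate(events,
                      sample = as.integer(round(.data$onset * max(ch$rate))))
  if (!is.null(a$stimuli)) {
    ev$stim_file <- sub("^stimuli/", "",
                        unname(a$stimuli[ev$trial_type]))
  }
  write_bids_table(ev, file.path(root, build_bids_path(
    bids_path(subject = sub, session = a$session, task = a$task,
              run = a$run, suffix = "events", extension = ".tsv"))),
    schema = "events")

  # _electrodes.tsv + _coordsystem.json
  coords <- electrode_coords(ch, a$coordinate_mode, seed + 29L)
  electrodes <- dplyr::mutate(
    coords,
    size = ifelse(ch$kind[match(coords$name, ch$name)] == "depth", 5, 4.15),
    group = ch$group[match(coords$name, ch$name)])
  write_bids_table(electrodes, file.path(root, build_bids_path(
    bids_path(subject = sub, session = a$session, suffix = "electrodes",
              extension = ".tsv"))), schema = "electrodes")

  coordsystem <- a$coordsystem
  if (isTRUE(a$anat)) {
    anat_p <- build_bids_path(bids_path(subject = sub, suffix = "T1w",
                                        extension = ".nii.gz"))
    coordsystem$IntendedFor <- anat_p
    dir.create(dirname(file.path(root, anat_p)), recursive = TRUE,
               showWarnings = FALSE)
    write_minimal_nifti(file.path(root, anat_p), seed = seed + 31L)
  }
  write_coordsystem(coordsystem, file.path(root, build_bids_path(
    bids_path(subject = sub, session = a$session, suffix = "coordsystem",
              extension = ".json"))))
  invisible(NULL)
}
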