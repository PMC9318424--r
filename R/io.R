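# Readers and writers for the package's plain-text interchange formats
# (kinematics, events, EEG matrices, montages, synergy sets) and a minimal
# continuous-recording EDF implementation for EEG exchange.

#' Write / read joint-angle recordings as delimited text
#'
#' One row per sample: `time_s` followed by the joint columns in session
#' order. The reader rebuilds a [new_kin_session()] session from the angle table plus an
#' events table, optionally applying a per-sensor linear calibration
#' (`angle = gain * raw + offset`, from the flat/fist calibration postures).
#'
#' @param session A `kin_session`.
#' @param path Output file (tab-separated).
#' @export
write_kinematics <- function(session, path) {
  stopifnot(inherits(session, "kin_session"))
  df <- as_tibble(session$angles)
  df <- dplyr::bind_cols(
    tibble(time_s = (seq_len(nrow(session$angles)) - 1) / session$rate), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_kinematics
#' @param angles_path,events_path Input files.
#' @param rate Sampling rate in Hz.
#' @param calibration Optional tibble with columns `joint`, `gain`, `offset`.
#' @export
read_kinematics <- function(angles_path, events_path, rate = 125,
                            calibration = NULL) {
  df <- readr::read_tsv(angles_path, show_col_types = FALSE)
  joints <- setdiff(names(df), "time_s")
  angles <- as.matrix(df[, joints])
  if (!is.null(calibration)) {
    stopifnot(all(c("joint", "gain", "offset") %in% names(calibration)))
    for (i in seq_len(nrow(calibration))) {
      j <- match(calibration$joint[i], joints)
      if (!is.na(j)) {
        angles[, j] <- calibration$gain[i] * angles[, j] + calibration$offset[i]
      }
    }
  }
  events <- read_events(events_path)
  new_kin_session(angles, rate, events, joint_labels = joints)
}

#' Write / read the trial event table
#'
#' Columns: `trial_id`, `grasp_type` (1-6), `cue_on_s`, `cue_off_s`,
#' `excluded` (logical artifact-exclusion flag).
#'
#' @param events Events tibble.
#' @param path File path (tab-separated).
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE)
  ev$excluded <- as.logical(ev$excluded)
  ev
}

#' Write / read EEG as a delimited matrix
#'
#' One row per sample, `time_s` plus one column per channel (channel names
#' from the montage).
#'
#' @param session An `eeg_session`.
#' @param path File path (tab-separated).
#' @export
write_eeg_matrix <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  df <- as_tibble(session$data)
  df <- dplyr::bind_cols(
    tibble(time_s = (seq_len(nrow(session$data)) - 1) / session$rate), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_eeg_matrix
#' @param events_path Events table path.
#' @param montage Montage tibble; must cover the file's channel columns.
#' @param rate Sampling rate (Hz).
#' @param resting_s Length-2 numeric, start/end of the resting segment in
#'   seconds, or `NULL`.
#' @export
read_eeg_matrix <- function(path, events_path, montage = gamma_montage_32(),
                            rate = 256, resting_s = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  chans <- setdiff(names(df), "time_s")
  montage <- montage[match(chans, montage$channel), ]
  if (anyNA(montage$channel)) abort("montage lacks some file channels")
  resting <- if (!is.null(resting_s)) {
    c(round(resting_s[1] * rate) + 1L, round(resting_s[2] * rate))
  }
  new_eeg_session(as.matrix(df[, chans]), rate, montage,
                  read_events(events_path), resting)
}

#' Write / read a montage file
#'
#' Tab-separated `channel`, `x`, `y` scalp coordinates.
#' @param montage Montage tibble.
#' @param path File path.
#' @export
write_montage <- function(montage, path) {
  validate_montage(montage)
  readr::write_tsv(montage, path)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  validate_montage(m)
  m
}

#' Serialize a synergy set as a delimited matrix plus metadata sidecar
#'
#' The synergy matrix goes to `<prefix>.tsv` (one row per synergy, joint-major
#' columns) and the layout, variance fractions and threshold to
#' `<prefix>.yml`.
#'
#' @param set A `synergy_set`.
#' @param prefix Path prefix (without extension).
#' @export
write_synergies <- function(set, prefix) {
  stopifnot(inherits(set, "synergy_set"))
  utils::write.table(set$S, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(layout = set$layout,
                        variance_fractions = set$variance_fractions,
                        threshold = set$threshold, n_syn = set$n_syn),
                   paste0(prefix, ".yml"), precision = 12)
  invisible(prefix)
}

#' @rdname write_synergies
#' @export
read_synergies <- function(prefix) {
  S <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(S) <- NULL
  meta <- yaml::read_yaml(paste0(prefix, ".yml"))
  structure(list(S = S,
                 variance_fractions = as.numeric(meta$variance_fractions),
                 layout = meta$layout, threshold = meta$threshold,
                 n_syn = meta$n_syn),
            class = "synergy_set")
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Per subject: `subject<i>_kinematics.tsv`, `subject<i>_eeg.tsv` (or `.edf`)
#' and `subject<i>_events.tsv`, plus a shared `montage.tsv`.
#'
#' @param cohort A `grasp_cohort`.
#' @param dir Output directory (created if needed).
#' @param eeg_format `"tsv"` or `"edf"`.
#' @export
write_cohort <- function(cohort, dir, eeg_format = c("tsv", "edf")) {
  stopifnot(inherits(cohort, "grasp_cohort"))
  eeg_format <- match.arg(eeg_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_montage(cohort$subjects[[1]]$eeg$montage, file.path(dir, "montage.tsv"))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    write_kinematics(s$kinematics,
                     file.path(dir, sprintf("subject%d_kinematics.tsv", i)))
    write_events(s$kinematics$events,
                 file.path(dir, sprintf("subject%d_events.tsv", i)))
    if (eeg_format == "tsv") {
      write_eeg_matrix(s$eeg, file.path(dir, sprintf("subject%d_eeg.tsv", i)))
    } else {
      write_edf(s$eeg, file.path(dir, sprintf("subject%d_eeg.edf", i)))
    }
  }
  invisible(dir)
}

# --- Minimal European Data Format (EDF) support -----------------------------
# Continuous recordings only, 1 s data records, 16-bit samples. Sufficient for
# exchanging the EEG matrices this package works with; trial events travel in
# the separate events table.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

# Most precise decimal representation of x that fits an 8-character field.
edf_num8 <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, digits = d, format = "g")
      if (nchar(s) <= 8) return(s)
    }
    s
  }, "")
}

#' Write / read EEG in European Data Format
#'
#' A minimal EDF implementation for continuous multichannel recordings:
#' 16-bit samples, one-second data records, physical range taken from the
#' data. Quantization error is bounded by (physical range) / 65535 per
#' sample. Events are not embedded; pair the file with an events table.
#'
#' @param session An `eeg_session` whose length is a whole number of seconds.
#' @param path Output `.edf` path.
#' @export
write_edf <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  data <- session$data
  rate <- session$rate
  ns <- ncol(data)
  n_rec <- nrow(data) %/% rate
  if (n_rec * rate != nrow(data)) {
    abort("EDF writer requires a whole number of 1 s records")
  }
  pmin <- apply(data, 2, min)
  pmax <- apply(data, 2, max)
  pad <- pmax == pmin
  pmax[pad] <- pmin[pad] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                        # patient id (anonymous)
  wr("Startdate X X X X", 80)              # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(1, 8)
  wr(ns, 4)
  for (f in list(list(colnames(data), 16), list(rep("", ns), 80),
                 list(rep("uV", ns), 8),
                 list(edf_num8(pmin), 8),
                 list(edf_num8(pmax), 8),
                 list(rep(dmin, ns), 8), list(rep(dmax, ns), 8),
                 list(rep("", ns), 80), list(rep(rate, ns), 8),
                 list(rep("", ns), 32))) {
    for (v in f[[1]]) wr(v, f[[2]])
  }
  # re-read the 8-char physical limits so the scaling matches exactly
  pmin_hdr <- as.numeric(edf_num8(pmin))
  pmax_hdr <- as.numeric(edf_num8(pmax))
  scale <- (dmax - dmin) / (pmax_hdr - pmin_hdr)
  for (r in seq_len(n_rec)) {
    rows <- (r - 1) * rate + seq_len(rate)
    block <- vapply(seq_len(ns), function(e) {
      as.integer(pmin(pmax(round((data[rows, e] - pmin_hdr[e]) * scale[e]
                                 + dmin), dmin), dmax))
    }, integer(rate))
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_edf
#' @return `read_edf()` returns a list with `data` (samples x channels,
#'   physical units), `rate` and `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    abort("reader supports equal sampling rates across signals only")
  }
  rate <- spr[1] / rec_dur
  data <- matrix(0, n_rec * spr[1], ns, dimnames = list(NULL, labels))
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, spr[1], ns)
    rows <- (r - 1) * spr[1] + seq_len(spr[1])
    data[rows, ] <- sweep(sweep(block, 2, dmin),
                          2, (pmax - pmin) / (dmax - dmin), `*`) +
      matrix(pmin, spr[1], ns, byrow = TRUE)
  }
  list(data = data, rate = rate, labels = labels)
}
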