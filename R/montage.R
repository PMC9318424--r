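#' 32-channel scalp montage over the sensorimotor strip
#'
#' Returns the electrode layout used throughout the package: 24 denominative
#' 10/20-system positions covering frontal (F), fronto-central (FC), central
#' (C), centro-parietal (CP), parietal (P) and occipital (O) areas, plus eight
#' intermediate 10/5-style positions interleaved over the hand sensorimotor
#' area. Coordinates are 2-D projected scalp positions on a unit head disk
#' (x: left negative / right positive; y: anterior positive).
#'
#' @return A tibble with columns `channel`, `x`, `y`.
#' @examples
#' gamma_montage_32()
#' @export
gamma_montage_32 <- function() {
  tibble::tribble(
    ~channel, ~x, ~y,
    "F3",   -0.4,  0.6,
    "Fz",    0.0,  0.6,
    "F4",    0.4,  0.6,
    "FC3",  -0.4,  0.3,
    "FC1",  -0.2,  0.3,
    "FCz",   0.0,  0.3,
    "FC2",   0.2,  0.3,
    "FC4",   0.4,  0.3,
    "FCC3h", -0.3, 0.15,
    "FCC1h", -0.1, 0.15,
    "FCC2h",  0.1, 0.15,
    "FCC4h",  0.3, 0.15,
    "C5",   -0.6,  0.0,
    "C3",   -0.4,  0.0,
    "C1",   -0.2,  0.0,
    "Cz",    0.0,  0.0,
    "C2",    0.2,  0.0,
    "C4",    0.4,  0.0,
    "C6",    0.6,  0.0,
    "CCP3h", -0.3, -0.15,
    "CCP1h", -0.1, -0.15,
    "CCP2h",  0.1, -0.15,
    "CCP4h",  0.3, -0.15,
    "CP3",  -0.4, -0.3,
    "CP1",  -0.2, -0.3,
    "CPz",   0.0, -0.3,
    "CP2",   0.2, -0.3,
    "CP4",   0.4, -0.3,
    "P3",   -0.4, -0.6,
    "Pz",    0.0, -0.6,
    "P4",    0.4, -0.6,
    "Oz",    0.0, -0.9
  )
}

#' Electrode neighborhoods by scalp distance
#'
#' For every electrode, lists the electrode itself plus all montage electrodes
#' within `radius` (Euclidean distance in montage coordinates). The default
#' radius captures the immediate grid neighbors of the standard montage.
#'
#' @param montage Tibble with `channel`, `x`, `y` columns.
#' @param radius Neighborhood radius in montage units.
#' @return A named list; element `e` is a character vector of channel names.
#' @export
electrode_neighborhoods <- function(montage = gamma_montage_32(), radius = 0.25) {
  stopifnot(is_number(radius), radius >= 0)
  xy <- as.matrix(montage[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  out <- lapply(seq_len(nrow(montage)), function(i) {
    montage$channel[d[i, ] <= radius + 1e-12]
  })
  stats::setNames(out, montage$channel)
}

validate_montage <- function(montage) {
  if (!all(c("channel", "x", "y") %in% names(montage))) {
    abort("montage must have columns channel, x, y")
  }
  if (anyDuplicated(montage$channel)) abort("montage channel names must be unique")
  invisible(montage)
}
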