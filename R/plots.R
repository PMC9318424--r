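# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   facet_wrap labs theme_minimal scale_size_area coord_fixed
#' @export
ggplot2::autoplot

#' Plot variance fractions and the reconstruction-error curve
#'
#' @param object A `synergy_decomposition`.
#' @param max_components How many leading components to show.
#' @param ... Unused.
#' @return A ggplot: per-component variance fraction (bars) with the
#'   cumulative fraction and the complementary reconstruction error (lines).
#' @method autoplot synergy_decomposition
#' @export
autoplot.synergy_decomposition <- function(object, max_components = 15, ...) {
  df <- tidy(object)
  df <- df[seq_len(min(nrow(df), max_components)), ]
  ggplot(df, aes(x = .data$component)) +
    geom_col(aes(y = .data$variance_fraction), fill = "grey70") +
    geom_line(aes(y = .data$cumulative_variance), colour = "steelblue") +
    geom_line(aes(y = 1 - .data$cumulative_variance), colour = "firebrick") +
    labs(x = "component", y = "fraction of variance",
         title = "Variance captured and reconstruction error by synergy count") +
    theme_minimal()
}

#' Plot the selected synergies as per-joint velocity curves
#'
#' @param object A `synergy_set`.
#' @param rate Kinematic sampling rate (Hz) for the time axis.
#' @param ... Unused.
#' @return A ggplot, one facet per synergy, one line per joint.
#' @method autoplot synergy_set
#' @export
autoplot.synergy_set <- function(object, rate = 125, ...) {
  df <- tidy(object, rate = rate)
  ggplot(df, aes(x = .data$time_s, y = .data$value, colour = .data$joint)) +
    geom_line(linewidth = 0.4) +
    facet_wrap(~synergy, labeller = ggplot2::label_both) +
    labs(x = "time (s)", y = "velocity component (a.u.)",
         title = "Kinematic synergies") +
    theme_minimal()
}

#' Plot decoding accuracy or error by group
#'
#' @param object A `synergy_cv`.
#' @param by Grouping passed to [aggregate_accuracy()] (`"joint"`, `"grasp"`,
#'   `"subject"`).
#' @param what `"error"` (1 - |rho|) or `"accuracy"` (percent).
#' @param ... Unused.
#' @return A ggplot bar chart with the grouped mean and an sd error bar.
#' @method autoplot synergy_cv
#' @export
autoplot.synergy_cv <- function(object, by = "joint", what = c("error", "accuracy"),
                                ...) {
  what <- match.arg(what)
  agg <- aggregate_accuracy(object, by)
  gcol <- names(agg)[1]
  ycol <- if (what == "error") "error_mean" else "accuracy_mean"
  scol <- if (what == "error") "error_sd" else "accuracy_sd"
  ggplot(agg, aes(x = factor(.data[[gcol]]), y = .data[[ycol]])) +
    geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(aes(ymin = .data[[ycol]] - .data[[scol]],
                               ymax = .data[[ycol]] + .data[[scol]]),
                           width = 0.25) +
    labs(x = by,
         y = if (what == "error") "decoding error (1 - |rho|)"
             else "decoding accuracy (%)") +
    theme_minimal()
}

#' Topographic map of synergy independency densities
#'
#' A simple scalp scatter map: electrodes at their montage positions, point
#' size/colour proportional to the density, one facet per synergy (and per
#' band when the map carries a `band` column).
#'
#' @param object An `independency_map`.
#' @param statistic Column to display (`"density"` or `"mean_sq_corr"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot independency_map
#' @export
autoplot.independency_map <- function(object, statistic = "density", ...) {
  stopifnot(statistic %in% names(object))
  p <- ggplot(object, aes(x = .data$x, y = .data$y,
                          size = .data[[statistic]],
                          colour = .data[[statistic]])) +
    ggplot2::annotate("path",
                      x = cos(seq(0, 2 * pi, length.out = 100)),
                      y = sin(seq(0, 2 * pi, length.out = 100)),
                      colour = "grey70") +
    geom_point() +
    scale_size_area(max_size = 6) +
    ggplot2::scale_colour_viridis_c() +
    coord_fixed() +
    labs(title = "Neural independency density", x = NULL, y = NULL) +
    theme_minimal()
  if ("band" %in% names(object)) {
    p + facet_wrap(band ~ synergy, labeller = ggplot2::label_both)
  } else {
    p + facet_wrap(~synergy, labeller = ggplot2::label_both)
  }
}
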