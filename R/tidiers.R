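# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a synergy decomposition
#'
#' @param x A `synergy_decomposition`.
#' @param ... Unused.
#' @return One row per component: singular value, variance fraction,
#'   cumulative variance.
#' @method tidy synergy_decomposition
#' @export
tidy.synergy_decomposition <- function(x, ...) {
  tibble(component = seq_along(x$d),
         singular_value = x$d,
         variance_fraction = x$variance_fractions,
         cumulative_variance = cumsum(x$variance_fractions))
}

#' @rdname tidy.synergy_decomposition
#' @method glance synergy_decomposition
#' @export
glance.synergy_decomposition <- function(x, ...) {
  tibble(n_components = length(x$d),
         rank = sum(x$d > 1e-10 * max(x$d, .Machine$double.eps)),
         total_energy = sum(x$d^2),
         centered = x$center)
}

#' Tidy a synergy set into long per-joint curves
#'
#' @param x A `synergy_set` with layout information.
#' @param rate Kinematic sampling rate used to express time in seconds.
#' @param ... Unused.
#' @return Long tibble: synergy, joint, sample, time_s, value.
#' @method tidy synergy_set
#' @export
tidy.synergy_set <- function(x, rate = 125, ...) {
  lay <- x$layout
  if (is.null(lay)) abort("synergy set has no layout information")
  E <- lay$epoch_samples
  purrr::map_dfr(seq_len(x$n_syn), function(i) {
    m <- unflatten_epoch(x$S[i, ], E)
    tibble(synergy = i,
           joint = rep(lay$joint_labels, each = E),
           sample = rep(seq_len(E), lay$n_joints),
           time_s = rep((seq_len(E) - 1) / rate, lay$n_joints),
           value = as.numeric(m))
  })
}

#' @rdname tidy.synergy_set
#' @method glance synergy_set
#' @export
glance.synergy_set <- function(x, ...) {
  tibble(n_syn = x$n_syn, threshold = x$threshold,
         cumulative_variance = sum(x$variance_fractions))
}

#' Tidy a fitted decoder
#'
#' @param x A `synergy_decoder`.
#' @param ... Unused.
#' @return Long coefficient tibble: task, feature component, synergy,
#'   estimate.
#' @method tidy synergy_decoder
#' @export
tidy.synergy_decoder <- function(x, ...) {
  purrr::imap_dfr(x$beta, function(B, nm) {
    tibble(task = nm,
           component = rep(seq_len(nrow(B)), ncol(B)),
           synergy = rep(seq_len(ncol(B)), each = nrow(B)),
           estimate = as.numeric(B))
  })
}

#' @rdname tidy.synergy_decoder
#' @method glance synergy_decoder
#' @export
glance.synergy_decoder <- function(x, ...) {
  tibble(n_tasks = length(x$beta),
         per_task = x$per_task,
         n_features = nrow(x$beta[[1]]),
         n_syn = x$n_syn,
         max_cond = max(x$diagnostics$cond))
}

#' Tidy cross-validation results
#'
#' @param x A `synergy_cv`.
#' @param ... Unused.
#' @return The per-trial-per-joint results tibble.
#' @method tidy synergy_cv
#' @export
tidy.synergy_cv <- function(x, ...) x$results

#' @rdname tidy.synergy_cv
#' @method glance synergy_cv
#' @export
glance.synergy_cv <- function(x, ...) {
  ok <- x$results$rho[!x$results$flagged]
  tibble(n_folds = nrow(x$folds),
         n_scores = length(ok),
         n_flagged = sum(x$results$flagged),
         accuracy_mean = 100 * mean(ok),
         accuracy_sd = 100 * sd(ok),
         error_mean = mean(1 - abs(ok)),
         mean_n_syn = mean(x$folds$n_syn),
         mean_pca_components = mean(x$folds$pca_components))
}
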