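#' Plot cross-cycle predictive abilities
#'
#' Predictive ability against the number of training cycles, faceted by
#' direction, coloured by common-genotype scenario.
#'
#' @param object A `cyclegp_validation` tibble from [evaluate_scenarios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyclegp_validation <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_trn_trials, y = .data$pa,
                               colour = .data$scenario, group = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(
      rows = if ("trait" %in% names(object)) ggplot2::vars(.data$trait),
      cols = if ("direction" %in% names(object)) ggplot2::vars(.data$direction)) +
    ggplot2::labs(x = "training cycles averaged", y = "predictive ability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fitted LD decay
#'
#' Observed pairwise r2 against distance with the fitted Hill-Weir curve and
#' threshold crossings.
#'
#' @param object An `ld_decay_fit` from [fit_ld_decay()].
#' @param max_points Subsample cap on plotted pairs.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ld_decay_fit <- function(object, max_points = 5000, ...) {
  dat <- object$data
  if (nrow(dat) > max_points) dat <- dat[seq(1, nrow(dat), length.out = max_points), ]
  grid <- tibble(dist_mb = seq(1e-6, max(dat$dist_mb), length.out = 300))
  grid$r2 <- object$curve(grid$dist_mb)
  cross <- dplyr::filter(object$threshold_crossings, is.finite(.data$dist_mb))
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$dist_mb, .data$r2)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.9) +
    ggplot2::labs(x = "distance (Mb)", y = expression(r^2)) +
    ggplot2::theme_minimal()
  if (nrow(cross)) {
    p <- p +
      ggplot2::geom_hline(data = cross, ggplot2::aes(yintercept = .data$threshold),
                          linetype = "dotted") +
      ggplot2::geom_vline(data = cross, ggplot2::aes(xintercept = .data$dist_mb),
                          linetype = "dotted")
  }
  p
}

#' Plot Bayes B residual-variance traces
#'
#' Post-burn-in residual-variance samples per chain, the standard convergence
#' diagnostic for the sampler.
#'
#' @param object A `bayesb_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bayesb_model <- function(object, ...) {
  tr <- dplyr::bind_rows(lapply(seq_along(object$residual_variance_chain),
                                function(ch) {
    tibble(chain = factor(ch),
           sample = seq_along(object$residual_variance_chain[[ch]]),
           sigma2_e = object$residual_variance_chain[[ch]])
  }))
  ggplot2::ggplot(tr, ggplot2::aes(.data$sample, .data$sigma2_e,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "kept sample", y = expression(sigma[e]^2), colour = "chain") +
    ggplot2::theme_minimal()
}

#' Marker density of a map
#'
#' Average markers per centimorgan, the coverage summary quoted for elite
#' breeding panels.
#'
#' @param n_markers Number of markers.
#' @param map_length_cm Total map length in cM.
#' @return Markers per cM.
#' @export
marker_density <- function(n_markers, map_length_cm) {
  assert_that(map_length_cm > 0, "map length must be positive")
  n_markers / map_length_cm
}
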