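#' Simulate a sparse additive trait architecture
#'
#' Marker effects follow the spike-and-slab architecture assumed by Bayes B:
#' each marker has a zero effect with probability `pi_zero` and otherwise a
#' heavy-tailed scaled-t draw (5 df). Year-to-year instability of genotypic
#' values is modelled by realising, per trial, a year-specific effect vector
#' `b_year = sqrt(ry) * b_shared + sqrt(1 - ry) * b_dev` with `b_dev` an
#' independent draw over the same non-zero marker set, so the additive
#' correlation of true genotypic values between two years is `ry_target` in
#' expectation (identical vectors when `ry_target = 1`).
#'
#' @param map A [as_genetic_map()] object.
#' @param pi_zero Proportion of zero-effect markers, in `[0, 1)`.
#' @param h2_target Per-trait narrow-sense heritability of clonal means, each
#'   in `(0, 1]`; recycled to `n_traits`.
#' @param ry_target Target additive correlation between year realisations,
#'   in `[-1, 1]`.
#' @param n_traits Number of traits.
#' @param trait_names Optional trait names (default `trait1..`).
#' @param seed Integer seed.
#' @return A `trait_architecture` object: the shared effect matrix
#'   (markers x traits), the non-zero marker mask, and the targets.
#' @export
#' @examples
#' map <- make_genetic_map(200, n_lg = 4, total_length_cm = 400, seed = 1)
#' arch <- simulate_trait_architecture(map, pi_zero = 0.95,
#'                                     h2_target = c(0.3, 0.5),
#'                                     ry_target = 0.95, n_traits = 2, seed = 7)
simulate_trait_architecture <- function(map, pi_zero = 0.95, h2_target = 0.4,
                                        ry_target = 0.95, n_traits = 1,
                                        trait_names = NULL, seed = NULL) {
  assert_that(pi_zero >= 0 && pi_zero < 1, "pi_zero must be in [0, 1)")
  assert_that(all(h2_target > 0 & h2_target <= 1), "h2_target must be in (0, 1]")
  assert_that(ry_target >= -1 && ry_target <= 1, "ry_target must be in [-1, 1]")
  m <- nrow(map)
  h2 <- rep_len(h2_target, n_traits)
  trait_names <- trait_names %||% sprintf("trait%d", seq_len(n_traits))
  assert_that(length(trait_names) == n_traits, "one name per trait")
  slab_df <- 5
  with_seed(seed, {
    nonzero <- matrix(stats::runif(m * n_traits) > pi_zero, m, n_traits)
    effects <- matrix(0, m, n_traits)
    n_nz <- sum(nonzero)
    if (n_nz > 0) effects[nonzero] <- stats::rt(n_nz, df = slab_df)
  })
  colnames(effects) <- trait_names
  structure(list(effects = effects, nonzero = nonzero, pi_zero = pi_zero,
                 h2_target = stats::setNames(h2, trait_names),
                 ry_target = ry_target, slab_df = slab_df,
                 n_traits = n_traits, trait_names = trait_names,
                 marker_ids = map$marker_id),
            class = "trait_architecture")
}

#' @exportS3Method base::print
print.trait_architecture <- function(x, ...) {
  cat(sprintf("<trait_architecture> %d markers x %d traits, pi0=%.3g, ry=%.2f\n",
              nrow(x$effects), x$n_traits, x$pi_zero, x$ry_target))
  invisible(x)
}

# Year-specific marker effects for one trial: same QTL positions, effect sizes
# wobbling between years with correlation ry_target. Drawn under the caller's
# RNG state (simulate_trial seeds it).
realize_year_effects <- function(arch, n_traits = arch$n_traits) {
  ry <- arch$ry_target
  if (ry == 1) return(arch$effects)
  dev <- matrix(0, nrow(arch$effects), arch$n_traits)
  n_nz <- sum(arch$nonzero)
  if (n_nz > 0) dev[arch$nonzero] <- stats::rt(n_nz, df = arch$slab_df)
  s <- sign(ry)
  sqrt(abs(ry)) * s * arch$effects + sqrt(1 - abs(ry)) * dev
}
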