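#' Simulate a replicated clonal field trial
#'
#' Lays the population out as a randomized complete block design: every
#' genotype appears once per replicate, replicates are stacked blocks of
#' raised beds, each bed holds `plots_per_bed` single-plant plots of which one
#' is the common control genotype. Plot phenotypes are
#' `trait mean + year-specific true breeding value + replicate effect +
#' optional separable AR1xAR1 spatial surface + iid residual`. The residual
#' variance per trait is calibrated so the narrow-sense heritability of clonal
#' means matches the architecture's `h2_target` given the realised genetic
#' variance in this roster.
#'
#' @param pop A `breeding_pop`; its full roster is trialled.
#' @param architecture A [simulate_trait_architecture()] object.
#' @param trial_id Trial label, e.g. `"T2"`.
#' @param n_reps Replicates, 5 or 6.
#' @param plots_per_bed Plots per bed, 5 to 9 (one is the control plot).
#' @param control_id Id of the control genotype; must be in the population.
#' @param spatial Either `"none"` or a list
#'   `list(rho_r =, rho_c =, s2 =)` describing a separable AR1(row) x
#'   AR1(col) Gaussian surface with marginal variance `s2`.
#' @param missing_rate Probability each genotype call is masked missing.
#' @param s2_rep Replicate effect variance, as a fraction of the mean realised
#'   genetic variance across traits (default 0.25).
#' @param trait_means Numeric vector of trait intercepts (recycled).
#' @param seed Integer seed.
#' @return A list with elements `trial` (long tibble: `trial`, `genotype`,
#'   `rep`, `bed`, `plot`, `row`, `col`, `is_control`, `trait`, `value`),
#'   `genotypes` (a [geno_matrix()] for the roster, with missing calls),
#'   `truth` (tibble of per-genotype year-specific true breeding values) and
#'   `sigma` (per-trait residual and genetic variances used).
#' @export
simulate_trial <- function(pop, architecture, trial_id, n_reps = 5,
                           plots_per_bed = 7, control_id = NULL,
                           spatial = "none", missing_rate = 0,
                           s2_rep = 0.25, trait_means = 0, seed = NULL) {
  assert_that(n_reps %in% c(5L, 6L), "n_reps must be 5 or 6")
  assert_that(plots_per_bed >= 5 && plots_per_bed <= 9,
              "plots_per_bed must be in 5..9")
  assert_that(missing_rate >= 0 && missing_rate <= 0.2,
              "missing_rate must be in [0, 0.2]")
  ids <- pop$pedigree$id
  control_id <- control_id %||% ids[1]
  assert_that(control_id %in% ids, "control genotype absent from population")
  test_ids <- setdiff(ids, control_id)
  n_test <- length(test_ids)
  per_bed <- plots_per_bed - 1L               # non-control plots per bed
  n_beds <- ceiling(n_test / per_bed)
  traits <- architecture$trait_names
  means <- rep_len(trait_means, length(traits))

  dos <- pop_dosages(pop)

  with_seed(seed, {
    b_year <- realize_year_effects(architecture)
    g <- dos %*% b_year                      # true BVs, individuals x traits
    var_g <- apply(g, 2, stats::var)
    var_g[var_g == 0] <- 1e-12
    h2 <- architecture$h2_target
    # clonal-mean error = sigma2_plot / n_reps; solve for sigma2_plot
    sigma2_plot <- n_reps * var_g * (1 - h2) / h2
    rep_sd <- sqrt(s2_rep * mean(var_g))
    rep_eff <- stats::rnorm(n_reps, 0, rep_sd)

    layout <- lapply(seq_len(n_reps), function(r) {
      ord <- sample(test_ids)
      bed <- rep(seq_len(n_beds), each = per_bed)[seq_len(n_test)]
      slot <- stats::ave(seq_len(n_test), bed, FUN = seq_along)
      ctrl_col <- sample.int(plots_per_bed, n_beds, replace = TRUE)
      # shift test slots to leave the control column free within each bed
      col <- slot + (slot >= ctrl_col[bed])
      dplyr::bind_rows(
        tibble(genotype = ord, rep = r, bed = bed,
               row = (r - 1L) * n_beds + bed, col = col, is_control = FALSE),
        tibble(genotype = control_id, rep = r, bed = seq_len(n_beds),
               row = (r - 1L) * n_beds + seq_len(n_beds), col = ctrl_col,
               is_control = TRUE)
      )
    })
    plan <- dplyr::bind_rows(layout)
    plan$plot <- (plan$bed - 1L) * plots_per_bed + plan$col
    n_plot <- nrow(plan)

    surf <- matrix(0, n_reps * n_beds, plots_per_bed)
    if (!identical(spatial, "none")) {
      assert_that(is.list(spatial) && all(c("rho_r", "rho_c", "s2") %in% names(spatial)),
                  "spatial must be \"none\" or list(rho_r=, rho_c=, s2=)")
      surf <- ar1_surface(n_reps * n_beds, plots_per_bed,
                          spatial$rho_r, spatial$rho_c, spatial$s2)
    }
    gi <- match(plan$genotype, ids)
    records <- lapply(seq_along(traits), function(k) {
      e <- stats::rnorm(n_plot, 0, sqrt(sigma2_plot[k]))
      tibble(trial = trial_id, genotype = plan$genotype, rep = plan$rep,
             bed = plan$bed, plot = plan$plot, row = plan$row, col = plan$col,
             is_control = plan$is_control, trait = traits[k],
             value = means[k] + g[gi, k] + rep_eff[plan$rep] +
               surf[cbind(plan$row, plan$col)] + e)
    })
    trial <- dplyr::arrange(dplyr::bind_rows(records),
                            .data$trait, .data$rep, .data$bed, .data$col)

    calls <- dos
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(calls)) < missing_rate, nrow(calls))
      calls[mask] <- NA_integer_
    }
  })

  truth <- tibble(genotype = rep(ids, length(traits)),
                  trait = rep(traits, each = length(ids)),
                  true_bv = as.vector(g))
  list(trial = trial,
       genotypes = geno_matrix(calls, map = pop$map),
       truth = truth,
       sigma = tibble(trait = traits, var_g = var_g,
                      sigma2_plot = sigma2_plot, rep_sd = rep_sd))
}

# Draw a separable AR1(rho_r) x AR1(rho_c) Gaussian surface with marginal
# variance s2 on an nr x nc grid, via the Kronecker-Cholesky identity.
ar1_surface <- function(nr, nc, rho_r, rho_c, s2) {
  Lr <- t(chol(ar1_corr(nr, rho_r)))
  Lc <- t(chol(ar1_corr(nc, rho_c)))
  sqrt(s2) * (Lr %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% t(Lc))
}

ar1_corr <- function(n, rho) {
  assert_that(abs(rho) < 1, "AR1 correlation must have |rho| < 1")
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}
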