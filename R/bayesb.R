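#' Bayes B sampler specification
#'
#' Hyper-parameters and chain settings for [bayesb_fit()]. Defaults follow
#' common whole-genome-regression practice: prior inclusion probability 0.5
#' updated under a weak Beta prior (pseudo-count 10), a scaled-t slab with
#' 5 degrees of freedom whose scale attributes `r2_prior` of the phenotypic
#' variance to markers a priori, and a 50,000-iteration chain with 10,000
#' burn-in run five times.
#'
#' @param pi_zero Prior probability a marker effect is exactly zero.
#' @param slab_df Degrees of freedom of the scaled-t slab.
#' @param r2_prior Prior proportion of phenotypic variance attributed to
#'   markers (sets the slab scale).
#' @param n_iter Total MCMC iterations per chain.
#' @param burn_in Burn-in iterations discarded.
#' @param thin Thinning interval for stored samples.
#' @param n_chains Independent chains (each gets a distinct sub-seed).
#' @param update_pi Update `pi_zero` from the data (default TRUE)?
#' @param pi_counts Beta pseudo-count weight on the `pi_zero` prior.
#' @param seed Integer seed.
#' @return A `bayesb_spec` list.
#' @export
bayesb_spec <- function(pi_zero = 0.5, slab_df = 5, r2_prior = 0.5,
                        n_iter = 50000, burn_in = 10000, thin = 5,
                        n_chains = 5, update_pi = TRUE, pi_counts = 10,
                        seed = 1) {
  assert_that(pi_zero >= 0 && pi_zero < 1, "pi_zero must be in [0, 1)")
  assert_that(burn_in < n_iter, "burn_in must be smaller than n_iter")
  assert_that(n_chains >= 1, "need at least one chain")
  structure(list(pi_zero = pi_zero, slab_df = slab_df, r2_prior = r2_prior,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 update_pi = update_pi, pi_counts = pi_counts,
                 seed = as.integer(seed)),
            class = "bayesb_spec")
}

#' Fit a Bayes B whole-genome regression
#'
#' Gibbs sampler for `y = 1 mu + Z beta + e` where each marker effect is zero
#' with probability `pi` and otherwise follows a scaled-t slab (implemented as
#' a normal with a marker-specific variance carrying a scaled-inverse-chi2
#' prior). Phenotypes are per-genotype BLUEs; marker covariates are centred
#' dosages. Multiple chains run under distinct derived sub-seeds and the
#' returned effects are the across-chain posterior means; per-chain summaries
#' and the post-burn-in residual-variance traces are retained, with a
#' Geweke-style z-score on each trace (|z| > 3 warns).
#'
#' @param blues A BLUE table slice (columns `genotype_id`, `blue`; one trait),
#'   e.g. one [tidy()] result of [fit_trial_model()], or any tibble with those
#'   columns.
#' @param genotypes An imputed [geno_matrix()] covering the phenotyped
#'   individuals.
#' @param spec A [bayesb_spec()].
#' @param trait,trials Optional provenance labels stored on the model.
#' @return A `bayesb_model`: `intercept_mean`, `marker_effect_means`,
#'   `inclusion_probs`, `pi_mean`, `residual_variance_chain` (list per chain),
#'   `chains`, `provenance`, `spec`. [tidy()] gives per-marker effects and
#'   inclusion probabilities; [glance()] chain-level summaries.
#' @export
bayesb_fit <- function(blues, genotypes, spec = bayesb_spec(),
                       trait = NULL, trials = NULL) {
  assert_that(is.data.frame(blues) && all(c("genotype_id", "blue") %in% names(blues)),
              "blues must have columns genotype_id, blue")
  if ("trait" %in% names(blues)) {
    assert_that(length(unique(blues$trait)) == 1L,
                "blues slice must contain a single trait")
    trait <- trait %||% blues$trait[1]
  }
  assert_that(!anyNA(genotypes$calls), "genotypes must be imputed first")
  ids <- intersect(blues$genotype_id, rownames(genotypes$calls))
  assert_that(length(ids) >= 30, "need at least 30 phenotyped, genotyped individuals")
  b <- blues[match(ids, blues$genotype_id), ]
  y <- b$blue
  assert_that(all(is.finite(y)), "non-finite phenotypes")
  assert_that(stats::var(y) > 0, "phenotypes are constant; nothing to fit")
  W <- genotypes$calls[ids, , drop = FALSE]
  W <- scale(W, center = TRUE, scale = FALSE)
  msx <- sum(apply(W, 2, stats::var))
  vy <- stats::var(y)
  prob_in <- 1 - spec$pi_zero
  S0_beta <- vy * spec$r2_prior * (spec$slab_df + 2) / (msx * prob_in)
  df_e <- 5
  S0_e <- vy * (1 - spec$r2_prior) * (df_e + 2)

  chains <- lapply(seq_len(spec$n_chains), function(ch) {
    with_seed(derive_seed(spec$seed, paste0("chain", ch)), {
      .bayesb_mcmc(y, W, spec$n_iter, spec$burn_in, spec$thin,
                   spec$slab_df, S0_beta, df_e, S0_e,
                   prob_in, spec$pi_counts, spec$update_pi)
    })
  })
  beta_mat <- vapply(chains, function(c) as.numeric(c$beta),
                     numeric(ncol(W)))
  incl_mat <- vapply(chains, function(c) as.numeric(c$inclusion),
                     numeric(ncol(W)))
  gz <- vapply(chains, function(c) geweke_z(c$sigma2_e_chain), numeric(1))
  if (any(abs(gz) > 3, na.rm = TRUE)) {
    warn(sprintf("residual-variance trace Geweke |z| > 3 in chain(s) %s; consider longer chains",
                 paste(which(abs(gz) > 3), collapse = ", ")))
  }
  structure(list(
    intercept_mean = mean(vapply(chains, function(c) c$mu, numeric(1))),
    marker_effect_means = stats::setNames(rowMeans(beta_mat), colnames(genotypes$calls)),
    inclusion_probs = stats::setNames(rowMeans(incl_mat), colnames(genotypes$calls)),
    pi_mean = mean(vapply(chains, function(c) mean(c$pi_chain), numeric(1))),
    residual_variance_chain = lapply(chains, function(c) as.numeric(c$sigma2_e_chain)),
    geweke_z = gz,
    chains = lapply(seq_along(chains), function(ch) list(
      mu = chains[[ch]]$mu,
      beta = stats::setNames(beta_mat[, ch], colnames(genotypes$calls)),
      inclusion = incl_mat[, ch])),
    marker_means = attr(W, "scaled:center"),
    provenance = list(trait = trait, trials = trials, n = length(ids)),
    spec = spec), class = "bayesb_model")
}

geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 20) return(NA_real_)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq.int(n - floor(frac2 * n) + 1, n)]
  (mean(a) - mean(b)) / sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}

#' @exportS3Method base::print
print.bayesb_model <- function(x, ...) {
  cat(sprintf("<bayesb_model> %d markers, %d chain(s), pi %.3f, mean incl %.4f\n",
              length(x$marker_effect_means), length(x$chains), x$pi_mean,
              mean(x$inclusion_probs)))
  invisible(x)
}

#' @export
tidy.bayesb_model <- function(x, ...) {
  tibble(marker_id = names(x$marker_effect_means),
         effect = as.numeric(x$marker_effect_means),
         inclusion_prob = as.numeric(x$inclusion_probs))
}

#' @export
glance.bayesb_model <- function(x, ...) {
  tibble(n_chains = length(x$chains),
         n = x$provenance$n,
         pi_mean = x$pi_mean,
         residual_variance = mean(unlist(x$residual_variance_chain)),
         max_abs_geweke_z = max(abs(x$geweke_z), na.rm = TRUE))
}

#' Predict genomic breeding values from Bayes B models
#'
#' `GEBV_i = mu + sum_j w_ij beta_j` with dosages centred on the training
#' marker means. When several models are supplied their marker sets are
#' intersected (with a warning if they disagree) and one prediction set per
#' model is returned; averaging across cycles is a separate step
#' ([average_predictions()]).
#'
#' @param models A `bayesb_model` or list of them.
#' @param genotypes An imputed [geno_matrix()] for the individuals to score.
#' @return A [prediction_set()] (or list of them, one per model).
#' @export
bayesb_predict <- function(models, genotypes) {
  single <- inherits(models, "bayesb_model")
  if (single) models <- list(models)
  assert_that(!anyNA(genotypes$calls), "genotypes must be imputed first")
  marker_sets <- lapply(models, function(m) names(m$marker_effect_means))
  common <- Reduce(intersect, c(marker_sets, list(colnames(genotypes$calls))))
  assert_that(length(common) > 0, "no markers shared between models and genotypes")
  if (any(vapply(marker_sets, length, integer(1)) != length(common)) ||
      length(common) != ncol(genotypes$calls)) {
    warn(sprintf("marker sets differ; using the %d-marker intersection", length(common)))
  }
  out <- lapply(models, function(m) {
    W <- sweep(genotypes$calls[, common, drop = FALSE], 2, m$marker_means[common])
    gebv <- as.numeric(m$intercept_mean + W %*% m$marker_effect_means[common])
    prediction_set(tibble(individual_id = rownames(genotypes$calls),
                          trait = m$provenance$trait %||% NA_character_,
                          gebv = gebv),
                   training_trials = m$provenance$trials %||% "unknown")
  })
  if (single) out[[1]] else out
}

#' Prediction sets
#'
#' A tibble of per-individual genomic estimated breeding values with
#' training-set provenance carried in attributes.
#'
#' @param x Tibble with columns `individual_id`, `trait`, `gebv`.
#' @param training_trials Character vector of training trial labels.
#' @param scenario `"include_common"` or `"exclude_common"` (set during
#'   validation).
#' @return A `prediction_set` tibble.
#' @export
prediction_set <- function(x, training_trials = character(),
                           scenario = "include_common") {
  assert_that(all(c("individual_id", "trait", "gebv") %in% names(x)),
              "prediction set needs individual_id, trait, gebv")
  assert_that(all(is.finite(x$gebv)), "non-finite GEBVs")
  assert_that(length(training_trials) >= 1, "training provenance must be non-empty")
  out <- as_tibble(x)
  attr(out, "training_trials") <- training_trials
  attr(out, "scenario") <- scenario
  class(out) <- c("prediction_set", class(out))
  out
}

#' @exportS3Method base::print
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d individuals, TRN {%s}, %s\n", nrow(x),
              paste(attr(x, "training_trials"), collapse = ","),
              attr(x, "scenario")))
  NextMethod()
}
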