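fake_bayesb_model <- function(mu, beta, centers = NULL, trait = "y",
                              trials = "T2") {
  centers <- centers %||% stats::setNames(rep(0, length(beta)), names(beta))
  structure(list(intercept_mean = mu, marker_effect_means = beta,
                 inclusion_probs = stats::setNames(rep(0.5, length(beta)),
                                                   names(beta)),
                 residual_variance_chain = list(rep(1, 50)),
                 chains = list(list()), marker_means = centers,
                 provenance = list(trait = trait, trials = trials, n = 10)),
            class = "bayesb_model")
}

test_that("GEBV prediction is the exact dot product of effects and dosages", {
  calls <- matrix(c(0, 1, 2, 1,
                    2, 0, 1, 1,
                    1, 2, 0, 2), 3, 4, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), paste0("m", 1:4)))
  beta <- stats::setNames(c(0.5, -1, 0.25, 2), paste0("m", 1:4))
  mod <- fake_bayesb_model(mu = 3, beta = beta)
  ps <- bayesb_predict(mod, geno_matrix(calls))
  # hand oracle: explicit sums
  expected <- vapply(1:3, function(i) {
    s <- 3
    for (j in 1:4) s <- s + calls[i, j] * beta[j]
    s
  }, numeric(1))
  expect_lt(max(abs(ps$gebv - expected)), 1e-12)

  # all-zero effects: GEBV = intercept for everyone
  mod0 <- fake_bayesb_model(mu = 7, beta = stats::setNames(rep(0, 4), paste0("m", 1:4)))
  ps0 <- bayesb_predict(mod0, geno_matrix(calls))
  expect_true(all(ps0$gebv == 7))

  # duplicated individuals get identical GEBVs
  calls2 <- rbind(calls, d = calls["a", ])
  ps2 <- bayesb_predict(mod, geno_matrix(calls2))
  expect_equal(ps2$gebv[ps2$individual_id == "d"],
               ps2$gebv[ps2$individual_id == "a"])

  # disjoint marker sets are rejected
  bad <- geno_matrix(matrix(1, 2, 2, dimnames = list(c("x", "y"), c("q1", "q2"))))
  expect_error(bayesb_predict(mod, bad), "no markers shared")
})

test_that("a planted large-effect marker is recovered with high inclusion", {
  set.seed(2)
  n <- 400; m <- 200
  W <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("i%03d", 1:n), sprintf("m%03d", 1:m)))
  beta_true <- 2
  y <- as.numeric(W[, 50] * beta_true + rnorm(n, 0, 1))
  bl <- tibble::tibble(genotype_id = rownames(W), blue = y)
  bm <- bayesb_fit(bl, geno_matrix(W), quick_spec(seed = 1, n_iter = 2000,
                                                  burn_in = 500))
  expect_gt(bm$inclusion_probs[50], 0.95)
  expect_lt(abs(bm$marker_effect_means[50] - beta_true) / beta_true, 0.10)
})

test_that("pure-noise phenotypes yield near-zero out-of-sample ability", {
  pas <- vapply(1:5, function(s) {
    set.seed(s + 400)
    n <- 120; m <- 150
    W <- matrix(rbinom(n * m, 2, 0.4), n, m,
                dimnames = list(sprintf("i%03d", 1:n), sprintf("m%03d", 1:m)))
    y <- rnorm(n)
    bl <- tibble::tibble(genotype_id = rownames(W), blue = y)
    bm <- suppressWarnings(bayesb_fit(bl, geno_matrix(W), quick_spec(seed = s)))
    ps <- bayesb_predict(bm, geno_matrix(W))
    stats::cor(ps$gebv, rnorm(n))   # against fresh noise
  }, numeric(1))
  expect_lt(abs(mean(pas)), 3 * stats::sd(pas) / sqrt(length(pas)) + 0.1)
})

test_that("the no-spike wide-slab limit reproduces GBLUP rankings", {
  set.seed(77)
  panel <- sim_h2_panel(n = 200, m = 300, h2 = 0.5, seed = 55)
  spec <- bayesb_spec(pi_zero = 1e-6, slab_df = 1e5, n_iter = 1500,
                      burn_in = 300, thin = 2, n_chains = 1,
                      update_pi = FALSE, seed = 4)
  bm <- suppressWarnings(bayesb_fit(panel$blues, panel$geno, spec))
  ps <- bayesb_predict(bm, panel$geno)
  gb <- gblup_fit(panel$blues, vanraden_grm(panel$geno), blend = 0.001)
  shared <- intersect(ps$individual_id, gb$gebv$individual_id)
  rc <- stats::cor(ps$gebv[match(shared, ps$individual_id)],
                   gb$gebv$gebv[match(shared, gb$gebv$individual_id)],
                   method = "spearman")
  expect_gt(rc, 0.98)
})

test_that("degenerate inputs are rejected with informative errors", {
  W <- matrix(rbinom(40 * 20, 2, 0.4), 40, 20,
              dimnames = list(sprintf("i%02d", 1:40), sprintf("m%02d", 1:20)))
  g <- geno_matrix(W)
  bl_const <- tibble::tibble(genotype_id = rownames(W), blue = 1)
  expect_error(bayesb_fit(bl_const, g, quick_spec()), "constant")
  bl_nan <- tibble::tibble(genotype_id = rownames(W), blue = c(NaN, rnorm(39)))
  expect_error(bayesb_fit(bl_nan, g, quick_spec()), "non-finite")
  bl_few <- tibble::tibble(genotype_id = rownames(W)[1:5], blue = rnorm(5))
  expect_error(bayesb_fit(bl_few, g, quick_spec()), "at least 30")
  gm_na <- g; gm_na$calls[1, 1] <- NA
  expect_error(bayesb_fit(tibble::tibble(genotype_id = rownames(W),
                                         blue = rnorm(40)), gm_na, quick_spec()),
               "imputed")
  expect_error(bayesb_spec(burn_in = 10, n_iter = 5), "burn_in")
})
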