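test_that("noise-free balanced trials give BLUE = raw genotype mean", {
  pop <- tiny_pop(15, 60)
  arch <- simulate_trait_architecture(pop$map, pi_zero = 0.8, h2_target = 1,
                                      ry_target = 1, n_traits = 1, seed = 3)
  st <- simulate_trial(pop, arch, "T2", n_reps = 5, s2_rep = 0, seed = 21)
  b <- tidy(fit_trial_model(st$trial, "trait1", "base"))
  raw <- tapply(st$trial$value, st$trial$genotype, mean)
  centred <- raw - mean(raw[b$genotype_id])
  expect_lt(max(abs(b$blue - centred[b$genotype_id])), 1e-8)
})

test_that("BLUEs recover true genotype values under known replicate effects", {
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    genos <- sprintf("g%02d", 1:20)
    truth <- stats::rnorm(20, 0, 2)
    rep_eff <- c(5, -5, 2, -2, 0)
    dat <- expand.grid(genotype = genos, rep = 1:5, stringsAsFactors = FALSE)
    dat$bed <- rep(1:4, length.out = nrow(dat))
    dat$row <- dat$rep; dat$col <- dat$bed
    dat$trial <- "TX"; dat$is_control <- FALSE; dat$trait <- "y"
    dat$plot <- seq_len(nrow(dat))
    dat$value <- truth[match(dat$genotype, genos)] + rep_eff[dat$rep] +
      stats::rnorm(nrow(dat), 0, 1)
    b <- tidy(fit_trial_model(tibble::as_tibble(dat), "y", "base"))
    mean(b$blue - (truth[match(b$genotype_id, genos)] - mean(truth)))
  }, numeric(1))
  # unbiased: mean deviation ~ N(0, sigma^2/(n_rep * n_geno)) per seed
  expect_lt(abs(mean(errs)), 3 * (1 / sqrt(100)) / sqrt(10) + 0.05)
})

test_that("the REML engine agrees with lme4 on an iid-residual model", {
  skip_if_not_installed("lme4")
  prog <- small_program(seed = 2, n_cycles = 1, h2 = 0.4)
  tr <- prog$phenotypes[prog$phenotypes$trait == "trait1", ]
  fit <- fit_trial_model(prog$phenotypes, "trait1", "base")
  tr$bedf <- factor(paste(tr$rep, tr$bed, sep = ":"))
  lf <- lme4::lmer(value ~ 0 + genotype + (1 | rep) + (1 | bedf), data = tr,
                   REML = TRUE)
  fe <- lme4::fixef(lf)
  names(fe) <- sub("^genotype", "", names(fe))
  ours <- fit$blues$blue
  theirs <- fe[fit$blues$genotype_id] - mean(fe[fit$blues$genotype_id])
  expect_lt(max(abs(ours - theirs)), 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  ours_vc <- fit$varcomps
  expect_equal(ours_vc$variance[ours_vc$term == "residual"],
               vc$vcov[vc$grp == "Residual"], tolerance = 1e-3)
  expect_equal(ours_vc$variance[ours_vc$term == "rep"],
               vc$vcov[vc$grp == "rep"], tolerance = 1e-2)
})

test_that("AR1 residuals with zero correlation reduce to the iid model", {
  prog <- small_program(seed = 11, n_cycles = 1, h2 = 0.4)
  m_rc <- fit_trial_model(prog$phenotypes, "trait1", "spatial_rc")
  m_ar0 <- fit_trial_model(prog$phenotypes, "trait1", "spatial_rc_ar1",
                           fix_rho = c(0, 0))
  expect_lt(abs(m_rc$log_likelihood - m_ar0$log_likelihood), 1e-6)
})

test_that("BLUEs are invariant to a constant phenotype shift", {
  prog <- small_program(seed = 3, n_cycles = 1, h2 = 0.5)
  ph <- prog$phenotypes
  b1 <- tidy(fit_trial_model(ph, "trait1", "base"))
  ph2 <- dplyr::mutate(ph, value = value + 100)
  b2 <- tidy(fit_trial_model(ph2, "trait1", "base"))
  expect_lt(max(abs(b1$blue - b2$blue)), 1e-6)
})

test_that("model selection minimises AIC with parameter and BIC tie-breaks", {
  fake <- function(tag, ll, k, n = 100, ck = "x") {
    structure(list(blues = tibble::tibble(), model_tag = tag,
                   log_likelihood = ll, n_params = k, n_obs = n,
                   aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
                   varcomps = NULL, data_checksum = ck, center = "grand_mean"),
              class = "trial_model")
  }
  one <- fake("only", -50, 3)
  expect_identical(select_model(list(one))$model_tag, "only")
  # equal likelihoods: fewer parameters wins
  sel <- select_model(list(fake("big", -100, 5), fake("small", -100, 3)))
  expect_identical(sel$model_tag, "small")
  # AIC arithmetic: (-100, k=4) -> 208 vs (-97, k=6) -> 206
  a <- fake("a", -100, 4); b <- fake("b", -97, 6)
  expect_equal(a$aic, 208); expect_equal(b$aic, 206)
  expect_identical(select_model(list(a, b))$model_tag, "b")
  expect_error(select_model(list(fake("a", -1, 2, ck = "x"),
                                 fake("b", -1, 2, ck = "y"))),
               "differing data")
})

test_that("centring on the control genotype anchors the control at zero", {
  prog <- small_program(seed = 9, n_cycles = 1, h2 = 0.5)
  b <- tidy(fit_trial_model(prog$phenotypes, "trait1", "base",
                            center = "control"))
  expect_equal(b$blue[b$genotype_id == prog$control_id], 0)
})

test_that("a single-replicate fixed-only fit returns the observations", {
  dat <- tibble::tibble(trial = "T0", genotype = c("a", "b", "c"), rep = 1L,
                        bed = 1L, plot = 1:3, row = 1L, col = 1:3,
                        is_control = FALSE, trait = "y", value = c(1.5, 2.5, 9))
  b <- tidy(fit_trial_model(dat, "y", "base"))
  expect_equal(b$blue + mean(dat$value), dat$value[match(b$genotype_id, dat$genotype)])
})
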