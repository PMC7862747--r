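trials5 <- paste0("T", seq(2, 10, 2))

test_that("scenario compositions grow forward and backward as labelled", {
  fwd <- assign_scenarios(trials5, "T10", "forward")
  expect_equal(fwd$label, c("T2", "T24", "T246", "T2468"))
  expect_equal(fwd$trn_trials[[3]], c("T2", "T4", "T6"))
  bwd <- assign_scenarios(trials5, "T10", "backward")
  expect_equal(bwd$label, c("T8", "T86", "T864", "T8642"))
  expect_equal(bwd$trn_trials[[4]], c("T8", "T6", "T4", "T2"))
  # backward with a single trial equals forward with that trial
  f1 <- assign_scenarios(c("T2", "T4"), "T4", "forward")
  b1 <- assign_scenarios(c("T2", "T4"), "T4", "backward")
  expect_equal(f1$trn_trials, b1$trn_trials)
  expect_error(assign_scenarios(trials5, "T2", "forward"), "precede")
  expect_error(assign_scenarios(trials5, "T99"), "must be one of")
})

test_that("prediction averaging is an equal-weight mean with union provenance", {
  mk <- function(ids, vals, trn) {
    prediction_set(tibble::tibble(individual_id = ids, trait = "y", gebv = vals),
                   training_trials = trn)
  }
  a <- mk(c("i1", "i2"), c(1, 10), "T2")
  b <- mk(c("i1", "i2"), c(3, 20), "T4")
  avg <- average_predictions(list(a, b))
  expect_equal(avg$gebv[avg$individual_id == "i1"], 2)
  expect_equal(avg$gebv[avg$individual_id == "i2"], 15)
  expect_setequal(attr(avg, "training_trials"), c("T2", "T4"))
  # idempotence
  self <- average_predictions(list(a, a))
  expect_equal(self$gebv, a$gebv)
  # three sets, hand mean on a 10-individual fixture
  ids <- sprintf("i%02d", 1:10)
  set.seed(3)
  v1 <- rnorm(10); v2 <- rnorm(10); v3 <- rnorm(10)
  avg3 <- average_predictions(list(mk(ids, v1, "T2"), mk(ids, v2, "T4"),
                                   mk(ids, v3, "T6")))
  expect_lt(max(abs(avg3$gebv - (v1 + v2 + v3) / 3)), 1e-12)
  # individuals outside the overlap are averaged over their own sets
  d <- mk(c("i1", "zz"), c(5, 7), "T8")
  avg2 <- average_predictions(list(a, d))
  expect_equal(avg2$gebv[avg2$individual_id == "zz"], 7)
  expect_error(average_predictions(list()), "no prediction sets")
})

test_that("predictive ability is the Pearson correlation over matched ids", {
  ids <- sprintf("i%02d", 1:5)
  obs <- tibble::tibble(genotype_id = ids, blue = c(1.2, -0.5, 2.2, 0.3, 1.0))
  perfect <- prediction_set(tibble::tibble(individual_id = ids, trait = "y",
                                           gebv = obs$blue), "T2")
  expect_equal(predictive_ability(perfect, obs)$pa, 1)
  flipped <- prediction_set(tibble::tibble(individual_id = ids, trait = "y",
                                           gebv = -obs$blue), "T2")
  expect_equal(predictive_ability(flipped, obs)$pa, -1)

  # 5-point fixture scored by the explicit correlation formula
  x <- c(0.2, 1.4, -0.8, 2.1, 0.9)
  y <- c(0.5, 1.1, -0.2, 1.3, 1.6)
  sx <- x - sum(x) / 5; sy <- y - sum(y) / 5
  r_hand <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  ps <- prediction_set(tibble::tibble(individual_id = ids, trait = "y",
                                      gebv = x), "T2")
  pa <- predictive_ability(ps, tibble::tibble(genotype_id = ids, blue = y))
  expect_lt(abs(pa$pa - r_hand), 1e-12)
  expect_equal(pa$n_tst, 5L)

  # affine invariance with positive slope
  ps2 <- prediction_set(tibble::tibble(individual_id = ids, trait = "y",
                                       gebv = 3 + 2 * x), "T2")
  expect_equal(predictive_ability(ps2,
                                  tibble::tibble(genotype_id = ids, blue = y))$pa,
               pa$pa)

  # zero-variance vectors reported as missing with a reason
  flat <- prediction_set(tibble::tibble(individual_id = ids, trait = "y",
                                        gebv = rep(1, 5)), "T2")
  out <- predictive_ability(flat, obs)
  expect_true(is.na(out$pa))
  expect_match(out$reason, "zero variance")
  expect_error(predictive_ability(perfect, obs[1:2, ]), "at least 3")
})

test_that("the published incidence matrix yields the published derived averages", {
  pub <- strawberry_trial_incidence()
  avg <- incidence_averages(pub$matrix)
  expect_equal(avg$avg_common_genotypes, c(31L, 44L, 61L, 66L, 62L))
  expect_equal(avg$avg_shared_parents, c(4L, 5L, 8L, 8L, 7L))
})

test_that("incidence summaries count overlaps, families and shared parents", {
  ped <- tibble::tibble(
    id = c("c1", "c2", paste0("k", 1:8)),
    dam = c(NA, NA, "c1", "c1", "c1", "c2", "c2", "c1", "c2", "c2"),
    sire = c(NA, NA, "c2", "c2", "x1", "x1", "x1", "x2", "x2", "x2"))
  rosters <- list(
    TA = c("c1", "k1", "k2", "k3"),          # families: c1/c2, c1/x1
    TB = c("c1", "k1", "k4", "k5", "k6"),    # overlap with TA: c1,k1 (2)
    TC = c("k7", "k8"))
  expect_warning(inc <- incidence_summary(rosters, ped), "parentless")
  M <- inc$matrix
  expect_equal(unname(M["TA", "TB"]), 2L)
  expect_equal(unname(M["TA", "TC"]), 0L)
  expect_equal(unname(M["TB", "TC"]), 0L)
  # TA families: {c1|c2, c1|x1}; TB first-seen k4(c1/x1 already? k4 dam c1 sire x1)...
  expect_equal(unname(diag(M)), c(2L, 2L, 1L))
  # shared parents between family sets
  expect_equal(unname(M["TB", "TA"]), length(intersect(c("c1", "c2", "x1"),
                                                       c("c1", "c2", "x1", "x2"))))
  # identical rosters overlap completely
  same <- list(T1 = c("k1", "k2", "k3"), T2 = c("k1", "k2", "k3"))
  inc2 <- incidence_summary(same, ped)
  expect_equal(unname(inc2$matrix["T1", "T2"]), 3L)
})

test_that("excluding common genotypes removes exactly the roster overlap", {
  prog <- small_program(seed = 13)
  traits <- prog$architecture$trait_names
  geno <- lapply(prog$genotypes, function(g) impute_mean(qc_filter(g)$genotypes))
  blues <- dplyr::bind_rows(lapply(prog$trials, function(tr) {
    tidy(fit_trial_model(prog$phenotypes[prog$phenotypes$trial == tr, ],
                         traits[1], "base"))
  }))
  tst <- utils::tail(prog$trials, 1)
  spec <- quick_spec(seed = 3)
  preds <- lapply(stats::setNames(prog$trials[1:2], prog$trials[1:2]),
                  function(tr) {
    bm <- suppressWarnings(
      bayesb_fit(blues[blues$trial_id == tr, ], geno[[tr]], spec,
                 trait = traits[1], trials = tr))
    suppressWarnings(bayesb_predict(bm, geno[[tst]]))
  })
  tstb <- blues[blues$trial_id == tst, ]
  sc_inc <- assign_scenarios(prog$trials, tst, "forward", include_common = TRUE)[1, ]
  sc_exc <- assign_scenarios(prog$trials, tst, "forward", include_common = FALSE)[1, ]
  v_inc <- evaluate_scenarios(preds, tstb, prog$rosters, sc_inc)
  v_exc <- evaluate_scenarios(preds, tstb, prog$rosters, sc_exc)
  overlap <- length(intersect(prog$rosters[[tst]], prog$rosters[[prog$trials[1]]]))
  expect_equal(v_inc$n_tst - v_exc$n_tst, overlap)
  expect_equal(v_exc$scenario, "exclude_common")
})
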