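test_that("pairwise r2 matches the explicit correlation formula", {
  # six individuals, two markers, computed by the definitional sums
  calls <- cbind(m1 = c(0, 1, 2, 1, 0, 2), m2 = c(0, 2, 2, 1, 1, 2))
  rownames(calls) <- sprintf("i%d", 1:6)
  map <- as_genetic_map(tibble::tibble(marker_id = c("m1", "m2"),
                                       linkage_group = 1L, pos_cm = c(0, 5)))
  g <- geno_matrix(calls, map = map)
  ld <- pairwise_r2(g, "within_lg")
  x <- calls[, 1] - mean(calls[, 1]); y <- calls[, 2] - mean(calls[, 2])
  r2_hand <- (sum(x * y))^2 / (sum(x^2) * sum(y^2))
  expect_lt(abs(ld$r2 - r2_hand), 1e-12)
  expect_equal(ld$dist_mb, 5 * 0.4)

  # a marker against its own copy: r2 exactly 1
  calls2 <- cbind(calls, m3 = calls[, 1])
  map2 <- as_genetic_map(tibble::tibble(marker_id = c("m1", "m2", "m3"),
                                        linkage_group = 1L, pos_cm = c(0, 5, 9)))
  ld2 <- pairwise_r2(geno_matrix(calls2, map = map2), "within_lg")
  expect_equal(ld2$r2[ld2$m1 == "m1" & ld2$m2 == "m3"], 1)

  # monomorphic markers are skipped and counted
  calls3 <- cbind(calls, m3 = rep(2, 6))
  ld3 <- pairwise_r2(geno_matrix(calls3, map = map2), "within_lg")
  expect_equal(attr(ld3, "n_monomorphic_skipped"), 2L)
  expect_equal(nrow(ld3), 1L)
})

test_that("independent markers show near-zero r2 at large n", {
  set.seed(17)
  n <- 10000
  calls <- cbind(m1 = rbinom(n, 2, 0.4), m2 = rbinom(n, 2, 0.35))
  rownames(calls) <- sprintf("i%05d", 1:n)
  map <- as_genetic_map(tibble::tibble(marker_id = c("m1", "m2"),
                                       linkage_group = 1:2, pos_cm = c(0, 0)))
  ld <- pairwise_r2(geno_matrix(calls, map = map), "between_lg")
  expect_lt(ld$r2, 0.002)
})

test_that("whitening by an identity kinship leaves r2 unchanged", {
  set.seed(23)
  n <- 80
  calls <- matrix(rbinom(n * 12, 2, 0.4), n, 12,
                  dimnames = list(sprintf("i%02d", 1:n), sprintf("m%02d", 1:12)))
  map <- make_genetic_map(12, n_lg = 2, total_length_cm = 50, seed = 2)
  colnames(calls) <- map$marker_id
  g <- geno_matrix(calls, map = map)
  ld <- pairwise_r2(g, "within_lg")
  K <- diag(n); dimnames(K) <- list(rownames(calls), rownames(calls))
  ldv <- r2v_corrected(g, K, ld)
  expect_lt(max(abs(ldv$r2v - ldv$r2)), 1e-10)
})

test_that("relatedness inflates r2 relative to the corrected measure", {
  # family-structured panel: close relatives duplicate haplotype stretches
  pop <- make_founders(20, tiny_map(120, n_lg = 3, len = 300, seed = 5), seed = 6)
  plan <- partial_circular_mating(pop$pedigree$id[1:8], 4, n_offspring = 10)
  fam <- advance_cycle(pop, plan, n_select_per_family = 10, seed = 7)
  calls <- pop_dosages(fam)
  q <- qc_filter(geno_matrix(calls, map = pop$map), maf_min = 0.05,
                 max_missing = 1)
  g <- impute_mean(q$genotypes)
  K <- vanraden_grm(g)
  ld <- pairwise_r2(g, "within_lg", max_pairs = 400, seed = 8)
  ldv <- r2v_corrected(g, K, ld, blend = 0.05)
  ok <- is.finite(ldv$r2v)
  expect_gt(mean(ld$r2[ok]), mean(ldv$r2v[ok]))
  expect_gt(mean(ld$r2[ok] > ldv$r2v[ok]), 0.6)
})

test_that("LD decay fitting is self-consistent and handles degenerate inputs", {
  n <- 100; rho_true <- 2.5
  d <- seq(0.05, 10, length.out = 300)
  mk_ld <- function(r2) {
    out <- tibble::tibble(lg1 = 1L, lg2 = 1L, m1 = paste0("a", seq_along(d)),
                          m2 = paste0("b", seq_along(d)), dist_mb = d, r2 = r2)
    class(out) <- c("ld_table", class(out))
    attr(out, "n_ind") <- n
    out
  }
  fit <- fit_ld_decay(mk_ld(cyclegp:::hill_weir_er2(rho_true * d, n)))
  expect_lt(abs(fit$rho - rho_true) / rho_true, 0.01)
  # the curve evaluated at a reported crossing returns the threshold
  cr <- fit$threshold_crossings
  expect_lt(abs(fit$curve(cr$dist_mb[cr$threshold == 0.2]) - 0.2), 1e-6)
  # fitted curve is monotone non-increasing
  grid <- fit$curve(seq(0.01, 10, length.out = 200))
  expect_true(all(diff(grid) <= 1e-12))
  # flat high r2 (no decay): thresholds never reached, reported as NA
  flat <- fit_ld_decay(mk_ld(rep(0.4, length(d))))
  expect_true(all(is.na(flat$threshold_crossings$dist_mb)))
  expect_error(fit_ld_decay(mk_ld(rep(0.05, length(d)))[1:10, ]), "at least 50")
})

test_that("the sample-size correction always lowers mean r2", {
  g <- sim_wright_fisher(ne = 40, n_loci = 120, n_gen = 10, n_sample = 35,
                         seed = 3)
  q <- qc_filter(g, maf_min = 0.05, max_missing = 0)
  ne <- ne_ld(impute_mean(q$genotypes), seed = 4)
  expect_lt(ne$r2_corrected, ne$r2_mean)
  expect_gt(ne$ne, 0)
  expect_true(all(is.finite(ne$ci)) || all(is.na(ne$ci)))
})

test_that("smaller effective size extends LD further along the genome", {
  # within-group decay crossings move outward as Ne shrinks
  cross_of <- function(ne, seed) {
    g <- sim_wright_fisher(ne = ne, n_loci = 400, n_gen = 4 * ne,
                           n_sample = ne, n_lg = 4, seed = seed)
    q <- qc_filter(g, 0.05, 0)
    ld <- pairwise_r2(impute_mean(q$genotypes), "between_lg",
                      max_pairs = 3000, seed = seed)
    mean(ld$r2)
  }
  r_small <- mean(vapply(1:3, function(s) cross_of(25, s), numeric(1)))
  r_large <- mean(vapply(1:3, function(s) cross_of(100, s + 10), numeric(1)))
  expect_gt(r_small, r_large)
})
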