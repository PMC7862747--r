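#' Pairwise linkage disequilibrium (r-squared) between marker dosages
#'
#' Composite (unphased) LD: the squared Pearson correlation between dosage
#' vectors. Within-linkage-group pairs carry their distance in Mb for decay
#' fitting; between-group pairs (distance undefined) are the unlinked set used
#' for Ne estimation. Pairs involving a monomorphic marker are skipped and
#' counted.
#'
#' @param g A complete (imputed) [geno_matrix()] with a map attached for
#'   `within_lg` scope.
#' @param scope `"within_lg"` or `"between_lg"`.
#' @param max_pairs Uniform seeded subsample cap on the number of pairs.
#' @param seed Seed for the pair subsample.
#' @return An `ld_table` tibble: `lg1`, `lg2`, `m1`, `m2`, `dist_mb` (NA
#'   between groups), `r2`; skipped-pair count in attribute
#'   `"n_monomorphic_skipped"`.
#' @export
pairwise_r2 <- function(g, scope = c("within_lg", "between_lg"),
                        max_pairs = 50000, seed = 1) {
  scope <- match.arg(scope)
  assert_that(!anyNA(g$calls), "genotypes must be complete (impute first)")
  assert_that(!is.null(g$map), "pairwise_r2 needs a genetic map")
  map <- g$map
  m <- ncol(g$calls)
  lg <- map$linkage_group
  pairs <- if (scope == "within_lg") {
    do.call(rbind, lapply(split(seq_len(m), lg), function(ix) {
      if (length(ix) < 2) return(NULL)
      t(utils::combn(ix, 2))
    }))
  } else if (m <= 2500) {
    idx <- t(utils::combn(seq_len(m), 2))
    idx[lg[idx[, 1]] != lg[idx[, 2]], , drop = FALSE]
  } else {
    # too many pairs to enumerate: draw a seeded uniform sample directly
    with_seed(seed, {
      i <- sample.int(m, 6L * max_pairs, replace = TRUE)
      j <- sample.int(m, 6L * max_pairs, replace = TRUE)
    })
    ok <- i < j & lg[i] != lg[j]
    idx <- unique(cbind(i[ok], j[ok]))
    idx[seq_len(min(nrow(idx), max_pairs)), , drop = FALSE]
  }
  assert_that(!is.null(pairs) && nrow(pairs) > 0, "no marker pairs in scope")
  if (nrow(pairs) > max_pairs) {
    with_seed(seed, pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE])
  }
  sds <- apply(g$calls, 2, stats::sd)
  mono <- sds == 0
  skip <- mono[pairs[, 1]] | mono[pairs[, 2]]
  n_skip <- sum(skip)
  pairs <- pairs[!skip, , drop = FALSE]
  assert_that(nrow(pairs) > 0, "all pairs involve monomorphic markers")
  r2 <- vapply(seq_len(nrow(pairs)), function(k) {
    stats::cor(g$calls[, pairs[k, 1]], g$calls[, pairs[k, 2]])^2
  }, numeric(1))
  out <- tibble(lg1 = lg[pairs[, 1]], lg2 = lg[pairs[, 2]],
                m1 = map$marker_id[pairs[, 1]], m2 = map$marker_id[pairs[, 2]],
                dist_mb = ifelse(lg[pairs[, 1]] == lg[pairs[, 2]],
                                 abs(map$pos_mb[pairs[, 1]] - map$pos_mb[pairs[, 2]]),
                                 NA_real_),
                r2 = r2)
  class(out) <- c("ld_table", class(out))
  attr(out, "n_monomorphic_skipped") <- n_skip
  attr(out, "n_ind") <- nrow(g$calls)
  out
}

#' Relatedness-corrected LD (r-squared-V)
#'
#' Re-estimates pairwise LD after whitening the dosage vectors by the inverse
#' symmetric square root of the kinship-implied sample covariance
#' `(1 - blend) * K + blend * I`, so correlation induced purely by sample
#' relatedness is removed; with `K = I` the measure equals plain r-squared.
#'
#' @param g A complete [geno_matrix()].
#' @param kinship A [vanraden_grm()] (or symmetric id-named matrix) covering
#'   the individuals of `g`.
#' @param pairs An `ld_table` from [pairwise_r2()] giving the pairs to
#'   correct (its `r2` column is retained).
#' @param blend Identity blend making the kinship positive definite.
#' @return The `ld_table` with an added `r2v` column.
#' @export
r2v_corrected <- function(g, kinship, pairs, blend = 0.01) {
  K <- if (inherits(kinship, "grm")) kinship$values else as.matrix(kinship)
  ids <- rownames(g$calls)
  assert_that(all(ids %in% rownames(K)), "kinship must cover all individuals")
  S <- grm_blend(K[ids, ids], blend)
  eg <- eigen(S, symmetric = TRUE)
  assert_that(min(eg$values) > 1e-10,
              "kinship not positive definite; increase blend")
  Wm <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))   # S^(-1/2)
  markers <- unique(c(pairs$m1, pairs$m2))
  Xw <- Wm %*% g$calls[, markers, drop = FALSE]
  colnames(Xw) <- markers
  sds <- apply(Xw, 2, stats::sd)
  r2v <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs$m1[k]; b <- pairs$m2[k]
    if (sds[a] == 0 || sds[b] == 0) return(NA_real_)
    stats::cor(Xw[, a], Xw[, b])^2
  }, numeric(1))
  out <- dplyr::mutate(pairs, r2v = r2v)
  class(out) <- unique(c("ld_table", class(out)))
  out
}

# Hill-Weir expected r2 as a function of the population recombination
# parameter C, with the sample-size (n individuals) small-sample term.
hill_weir_er2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit LD decay over physical distance
#'
#' Nonlinear least squares of the Hill-Weir expectation of r-squared against
#' distance, `E[r2] = f(C = rho * d_Mb; n)`, where `rho` is the
#' recombination-scale parameter per Mb and `n` the number of sampled
#' individuals. Reports the distances at which the fitted curve crosses the
#' requested thresholds (NA when a threshold is never reached on the observed
#' range).
#'
#' @param ld An `ld_table` of within-group pairs (`dist_mb`, `r2`).
#' @param n_ind Number of individuals behind the r2 estimates (defaults to
#'   the table's attribute).
#' @param thresholds r2 levels at which to report crossing distances.
#' @return An `ld_decay_fit`: `rho`, `curve` (function of distance),
#'   `threshold_crossings` tibble, `n_pairs`, `n_ind`.
#' @export
fit_ld_decay <- function(ld, n_ind = NULL, thresholds = c(0.2, 0.1)) {
  dat <- dplyr::filter(ld, is.finite(.data$dist_mb), is.finite(.data$r2))
  assert_that(nrow(dat) >= 50, "need at least 50 within-group pairs")
  assert_that(diff(range(dat$dist_mb)) > 0, "pairs must span a distance range")
  n <- n_ind %||% attr(ld, "n_ind")
  assert_that(!is.null(n) && n >= 2, "supply n_ind (individuals behind r2)")
  # multi-start grid then Levenberg-Marquardt refinement
  grid <- 10^seq(-3, 3, length.out = 25)
  sse <- vapply(grid, function(r) {
    sum((dat$r2 - hill_weir_er2(r * dat$dist_mb, n))^2)
  }, numeric(1))
  start <- grid[which.min(sse)]
  fit <- tryCatch(
    minpack.lm::nlsLM(r2 ~ hill_weir_er2(rho * dist_mb, n),
                      data = dat, start = list(rho = start),
                      lower = 1e-8, upper = 1e8,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  rho <- if (is.null(fit)) start else stats::coef(fit)[["rho"]]
  assert_that(is.finite(rho) && rho > 0,
              "LD decay fit failed to converge after multi-start")
  curve_fun <- function(d) hill_weir_er2(rho * d, n)
  dmax <- max(dat$dist_mb)
  crossings <- tibble(
    threshold = thresholds,
    dist_mb = vapply(thresholds, function(th) {
      lo <- curve_fun(1e-9); hi <- curve_fun(dmax)
      if (th > lo || th < hi) return(NA_real_)  # never reached on range
      stats::uniroot(function(d) curve_fun(d) - th, c(1e-9, dmax),
                     tol = 1e-10)$root
    }, numeric(1)))
  structure(list(rho = rho, curve = curve_fun,
                 threshold_crossings = crossings,
                 n_pairs = nrow(dat), n_ind = n,
                 data = dat[, c("dist_mb", "r2")]),
            class = "ld_decay_fit")
}

#' @exportS3Method base::print
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("<ld_decay_fit> rho=%.4g /Mb over %d pairs (n=%d)\n",
              x$rho, x$n_pairs, x$n_ind))
  print(x$threshold_crossings)
  invisible(x)
}

#' @export
tidy.ld_decay_fit <- function(x, ...) x$threshold_crossings

#' @export
glance.ld_decay_fit <- function(x, ...) {
  tibble(rho = x$rho, n_pairs = x$n_pairs, n_ind = x$n_ind)
}

#' LD-based effective population size
#'
#' The bias-corrected LD method for random mating: markers below the MAF
#' threshold are dropped, mean r2 is taken over between-linkage-group
#' (effectively unlinked) pairs, the sample-size expectation is subtracted
#' (`1/S + 3.19/S^2` for S >= 30, `0.0018 + 0.907/S + 4.44/S^2` otherwise)
#' and Ne solves the corresponding quadratic
#' (`Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')`, small-sample variant with
#' constants 0.308 and 2.08). A delete-one-locus jackknife gives the
#' confidence interval.
#'
#' @param g A complete [geno_matrix()] with map.
#' @param maf_threshold Minimum minor-allele frequency retained (default 0.05).
#' @param max_pairs Cap on unlinked pairs (seeded subsample).
#' @param conf Jackknife confidence level.
#' @param seed Seed for pair subsampling.
#' @return An `ne_estimate`: `ne` (Inf when the corrected mean r2 is
#'   non-positive), `r2_mean`, `r2_corrected`, `n_pairs`, `s_size`, `ci`.
#' @export
ne_ld <- function(g, maf_threshold = 0.05, max_pairs = 50000, conf = 0.95,
                  seed = 1) {
  assert_that(!is.null(g$map), "ne_ld needs a genetic map to find unlinked pairs")
  S <- nrow(g$calls)
  assert_that(S >= 10, "need at least 10 individuals")
  st <- marker_stats(g)
  keep <- !is.na(st$maf) & st$maf >= maf_threshold
  assert_that(sum(keep) >= 2, "fewer than 2 markers pass the MAF threshold")
  gk <- geno_matrix(g$calls[, keep, drop = FALSE], map = g$map[keep, ])
  ld <- pairwise_r2(gk, scope = "between_lg", max_pairs = max_pairs, seed = seed)
  assert_that(nrow(ld) >= 10, "too few unlinked marker pairs")
  samp_exp <- ld_sample_expectation(S)
  r2_mean <- mean(ld$r2)
  r2p <- r2_mean - samp_exp
  ne_point <- ne_from_r2prime(r2p, S)
  # jackknife over loci: drop each marker's pairs in turn
  loci <- unique(c(ld$m1, ld$m2))
  ne_jk <- vapply(loci, function(l) {
    r2m <- mean(ld$r2[ld$m1 != l & ld$m2 != l])
    ne_from_r2prime(r2m - samp_exp, S)
  }, numeric(1))
  ne_jk <- ne_jk[is.finite(ne_jk)]
  ci <- if (length(ne_jk) >= 10) {
    nl <- length(ne_jk)
    jse <- sqrt((nl - 1) / nl * sum((ne_jk - mean(ne_jk))^2))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    c(lower = max(ne_point - z * jse, 0), upper = ne_point + z * jse)
  } else c(lower = NA_real_, upper = NA_real_)
  structure(list(ne = ne_point, r2_mean = r2_mean, r2_corrected = r2p,
                 n_pairs = nrow(ld), s_size = S,
                 maf_threshold = maf_threshold, ci = ci),
            class = "ne_estimate")
}

ld_sample_expectation <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

ne_from_r2prime <- function(r2p, S) {
  if (!is.finite(r2p) || r2p <= 0) return(Inf)
  if (S >= 30) {
    disc <- 1 / 9 - 2.76 * r2p
    if (disc < 0) disc <- 0
    (1 / 3 + sqrt(disc)) / (2 * r2p)
  } else {
    disc <- 0.308^2 - 2.08 * r2p
    if (disc < 0) disc <- 0
    (0.308 + sqrt(disc)) / (2 * r2p)
  }
}

#' @exportS3Method base::print
print.ne_estimate <- function(x, ...) {
  cat(sprintf("<ne_estimate> Ne=%.1f (mean r2 %.4f, corrected %.4f, %d pairs, S=%d)\n",
              x$ne, x$r2_mean, x$r2_corrected, x$n_pairs, x$s_size))
  invisible(x)
}

#' Simulate a Wright-Fisher population of unlinked SNPs
#'
#' Discrete-generation random-mating diploid population of constant size with
#' free recombination between loci, used to check LD-based Ne recovery.
#' Synthetic by construction.
#'
#' @param ne Census (= effective) size of the random-mating population.
#' @param n_loci Number of unlinked biallelic loci.
#' @param n_gen Generations of drift before sampling.
#' @param n_sample Individuals sampled (without replacement when possible).
#' @param init_freq_range Initial allele-frequency range.
#' @param n_lg Linkage groups the loci are spread over (so [ne_ld()] treats
#'   them as unlinked between groups).
#' @param seed Integer seed.
#' @return A complete [geno_matrix()] of the sampled individuals.
#' @export
sim_wright_fisher <- function(ne, n_loci, n_gen = 15, n_sample = ne,
                              init_freq_range = c(0.2, 0.8), n_lg = 20,
                              seed = 1) {
  with_seed(seed, {
    p0 <- stats::runif(n_loci, init_freq_range[1], init_freq_range[2])
    H1 <- matrix(stats::rbinom(ne * n_loci, 1, rep(p0, each = ne)), ne, n_loci)
    H2 <- matrix(stats::rbinom(ne * n_loci, 1, rep(p0, each = ne)), ne, n_loci)
    for (gen in seq_len(n_gen)) {
      dam <- sample.int(ne, ne, replace = TRUE)
      sire <- sample.int(ne, ne, replace = TRUE)
      pick1 <- matrix(stats::runif(ne * n_loci) < 0.5, ne, n_loci)
      pick2 <- matrix(stats::runif(ne * n_loci) < 0.5, ne, n_loci)
      N1 <- ifelse(pick1, H1[dam, ], H2[dam, ])
      N2 <- ifelse(pick2, H1[sire, ], H2[sire, ])
      H1 <- N1; H2 <- N2
    }
    idx <- sample.int(ne, min(n_sample, ne))
  })
  calls <- (H1 + H2)[idx, , drop = FALSE]
  rownames(calls) <- sprintf("I%04d", seq_len(nrow(calls)))
  colnames(calls) <- sprintf("L%05d", seq_len(n_loci))
  map <- tibble(marker_id = colnames(calls),
                linkage_group = rep_len(seq_len(n_lg), n_loci),
                pos_cm = stats::ave(rep(1, n_loci),
                                    rep_len(seq_len(n_lg), n_loci),
                                    FUN = function(x) seq_along(x) * 10))
  geno_matrix(calls, map = as_genetic_map(dplyr::arrange(map, .data$linkage_group, .data$pos_cm)))
}
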