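#' GBLUP: genomic REML variance components, heritability and GEBVs
#'
#' Fits `y = 1 mu + u + e` with `var(u) = G sigma2_a`, `var(e) = I sigma2_e`
#' by REML on the eigen-rotated scale (a single variance ratio is profiled,
#' so the fit is exact and fast). Heritability is
#' `h2 = sigma2_a / (sigma2_a + sigma2_e)`, with a delta-method standard
#' error from the curvature of the profile REML log-likelihood. GEBVs are the
#' BLUPs of `u`.
#'
#' @param blues A BLUE table slice (columns `genotype_id`, `blue`, single
#'   trait) or any tibble with those columns.
#' @param grm A [vanraden_grm()] object (or symmetric matrix with ids)
#'   covering all phenotyped individuals.
#' @param blend Identity blend applied to G before fitting (use > 0 when the
#'   panel contains duplicated genotypes).
#' @return A `gblup_fit`: `varcomps` (`sigma2_a`, `sigma2_e`, `h2`, `se_h2`),
#'   `gebv` tibble, `loglik`, `n`. [tidy()] returns the GEBVs, [glance()] the
#'   variance components.
#' @export
gblup_fit <- function(blues, grm, blend = 0) {
  assert_that(all(c("genotype_id", "blue") %in% names(blues)),
              "blues must have columns genotype_id, blue")
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  ids <- blues$genotype_id
  assert_that(all(ids %in% rownames(G)),
              "grm must cover all phenotyped individuals")
  y <- blues$blue
  assert_that(all(is.finite(y)), "non-finite phenotypes")
  n <- length(y)
  Gs <- G[ids, ids]
  if (blend > 0) Gs <- (1 - blend) * Gs + blend * diag(n)

  if (stats::var(y) == 0) {
    # degenerate: no phenotypic variance, additive variance at the boundary
    vc <- tibble(sigma2_a = 0, sigma2_e = 0, h2 = 0, se_h2 = NA_real_)
    return(structure(list(varcomps = vc,
                          gebv = tibble(individual_id = ids, gebv = 0),
                          loglik = NA_real_, n = n, lambda = 0),
                     class = "gblup_fit"))
  }

  eg <- eigen(Gs, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-6 * max(d)) {
    abort("G is not positive semi-definite; blend towards the identity")
  }
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  xs <- drop(crossprod(U, rep(1, n)))
  p <- 1L

  neg2ll <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * d + 1
    xtvx <- sum(xs^2 / w)
    mu <- sum(xs * ys / w) / xtvx
    r <- sum((ys - xs * mu)^2 / w)
    sigma2e <- r / (n - p)
    (n - p) * log(sigma2e) + sum(log(w)) + log(xtvx) +
      (n - p) * (1 + log(2 * pi))
  }
  opt <- stats::optimize(neg2ll, c(-25, 25), tol = 1e-10)
  lam <- exp(opt$minimum)
  w <- lam * d + 1
  xtvx <- sum(xs^2 / w)
  mu <- sum(xs * ys / w) / xtvx
  r <- sum((ys - xs * mu)^2 / w)
  sigma2e <- r / (n - p)
  sigma2a <- lam * sigma2e
  h2 <- lam / (1 + lam)
  # curvature of the profile in log(lambda); delta method to h2
  eps <- 1e-3
  hess <- (neg2ll(opt$minimum + eps) - 2 * opt$objective +
             neg2ll(opt$minimum - eps)) / eps^2
  se_h2 <- if (is.finite(hess) && hess > 0) {
    sqrt(2 / hess) * lam / (1 + lam)^2
  } else NA_real_
  # BLUP(u) = lam G (lam G + I)^-1 (y - mu)
  shrink <- lam * d / w
  u <- drop(U %*% (shrink * (ys - xs * mu)))
  structure(list(
    varcomps = tibble(sigma2_a = sigma2a, sigma2_e = sigma2e, h2 = h2,
                      se_h2 = se_h2),
    gebv = tibble(individual_id = ids, gebv = u),
    mu = mu, loglik = -0.5 * opt$objective, n = n, lambda = lam),
    class = "gblup_fit")
}

#' @exportS3Method base::print
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> n=%d, sigma2_a=%.4g, sigma2_e=%.4g, h2=%.3f\n",
              x$n, x$varcomps$sigma2_a, x$varcomps$sigma2_e, x$varcomps$h2))
  invisible(x)
}

#' @export
tidy.gblup_fit <- function(x, ...) x$gebv

#' @export
glance.gblup_fit <- function(x, ...) {
  dplyr::mutate(x$varcomps, log_likelihood = x$loglik, n = x$n)
}
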