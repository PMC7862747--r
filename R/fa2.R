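#' Factor-analytic multi-year genomic model
#'
#' Fits the multivariate genomic model for genotype-by-year effects
#' `u_g = (Gamma %x% I) f + delta`, i.e. an FA(K) structure on the
#' across-year genetic covariance `Sigma_g = Gamma Gamma' + Psi`, with the
#' genomic relationship matrix G describing covariance among genotypes and a
#' heterogeneous independent residual per year (different plots in different
#' years). Estimation is REML: with a complete genotype x year table the
#' likelihood factorises over the eigenvectors of G into independent t-variate
#' normals (fast path); unbalanced data fall back to the dense
#' observed-cell covariance. The rotation indeterminacy of `Gamma` is resolved
#' by a lower-triangular constraint.
#'
#' @param multi_trial_blues Tibble with columns `trial_id`, `genotype_id`,
#'   `blue` (one trait; pass one trait slice at a time).
#' @param grm A [vanraden_grm()] (or symmetric id-named matrix) covering all
#'   genotypes.
#' @param K Number of factors (default 2).
#' @param blend Identity blend applied to G (default 0.01; clonal panels with
#'   repeated genotypes make G singular).
#' @param max_iter Optimiser iteration cap.
#' @return An `fa_fit`: `loadings` (years x K), `specific_variances`,
#'   `residual_variances`, `genetic_covariance` (`Gamma Gamma' + Psi`),
#'   `genetic_correlations`, `ve_percent`
#'   (`100 * tr(Gamma Gamma') / tr(Sigma_g)`), `scores` (factor-score BLUPs,
#'   complete data only), `loglik`. [tidy()] returns the per-year loadings
#'   and variances; [glance()] the summary.
#' @export
fa_multiyear_fit <- function(multi_trial_blues, grm, K = 2, blend = 0.01,
                             max_iter = 400) {
  dat <- multi_trial_blues
  assert_that(all(c("trial_id", "genotype_id", "blue") %in% names(dat)),
              "need columns trial_id, genotype_id, blue")
  if ("trait" %in% names(dat)) {
    assert_that(length(unique(dat$trait)) == 1L, "pass a single-trait slice")
  }
  years <- sort(unique(dat$trial_id))
  t_y <- length(years)
  assert_that(t_y >= 3, "need at least 3 trials")
  assert_that(K >= 1 && K < t_y, "K must be in 1..(n_years - 1)")
  check_connectivity(dat, years)

  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  ids <- sort(unique(dat$genotype_id))
  assert_that(all(ids %in% rownames(G)), "grm must cover all genotypes")
  Gs <- grm_blend(G[ids, ids], blend)

  # genotype x year response matrix (NA where untested)
  Y <- matrix(NA_real_, length(ids), t_y, dimnames = list(ids, years))
  Y[cbind(match(dat$genotype_id, ids), match(dat$trial_id, years))] <- dat$blue
  complete <- !anyNA(Y)

  # start values from the phenotypic covariance, split between genetics and error
  S <- stats::cov(Y, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  diag(S)[diag(S) <= 0] <- stats::var(dat$blue)
  Sg0 <- 0.6 * S
  es <- eigen((Sg0 + t(Sg0)) / 2, symmetric = TRUE)
  L0 <- es$vectors[, seq_len(K), drop = FALSE] %*%
    diag(sqrt(pmax(es$values[seq_len(K)], 1e-4)), K)
  # rotate to lower-triangular form (QR of the leading KxK block)
  L0 <- rotate_lower(L0)
  psi0 <- pmax(diag(Sg0) - rowSums(L0^2), 0.05 * diag(S))
  se0 <- pmax(0.4 * diag(S), 1e-4)
  par0 <- c(L0[lower_tri_mask(t_y, K)], log(psi0), log(se0))

  obj <- if (complete) {
    fa_negll_complete_factory(Y, Gs, K)
  } else {
    fa_negll_dense_factory(dat, years, ids, Gs, K)
  }
  opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                      lower = c(rep(-Inf, sum(lower_tri_mask(t_y, K))),
                                rep(log(1e-8), 2 * t_y)),
                      upper = c(rep(Inf, sum(lower_tri_mask(t_y, K))),
                                rep(log(1e8), 2 * t_y)),
                      control = list(maxit = max_iter, factr = 1e7))
  pars <- unpack_fa(opt$par, t_y, K)
  Gamma <- rotate_lower(pars$Gamma)
  Sigma_g <- Gamma %*% t(Gamma) + diag(pars$psi, t_y)
  dimnames(Sigma_g) <- list(years, years)
  corr <- stats::cov2cor(Sigma_g)
  ve <- 100 * sum(diag(Gamma %*% t(Gamma))) / sum(diag(Sigma_g))

  scores <- NULL
  if (complete) {
    scores <- fa_scores(Y, Gs, Gamma, pars$psi, pars$se, K)
  }
  structure(list(loadings = Gamma, specific_variances = stats::setNames(pars$psi, years),
                 residual_variances = stats::setNames(pars$se, years),
                 genetic_covariance = Sigma_g, genetic_correlations = corr,
                 ve_percent = ve, scores = scores, K = K, years = years,
                 loglik = -0.5 * opt$value, convergence = opt$convergence),
            class = "fa_fit")
}

lower_tri_mask <- function(t_y, K) {
  m <- matrix(TRUE, t_y, K)
  m[upper.tri(matrix(0, t_y, K))[, seq_len(K), drop = FALSE]] <- FALSE
  for (i in seq_len(K)) for (j in seq_len(K)) if (j > i) m[i, j] <- FALSE
  m
}

unpack_fa <- function(par, t_y, K) {
  mask <- lower_tri_mask(t_y, K)
  Gamma <- matrix(0, t_y, K)
  nl <- sum(mask)
  Gamma[mask] <- par[seq_len(nl)]
  psi <- exp(par[nl + seq_len(t_y)])
  se <- exp(par[nl + t_y + seq_len(t_y)])
  list(Gamma = Gamma, psi = psi, se = se)
}

# rotate loadings so the upper KxK corner is lower triangular with positive diag
rotate_lower <- function(L) {
  K <- ncol(L)
  qr_ <- qr(t(L[seq_len(K), , drop = FALSE]))
  Q <- qr.Q(qr_, complete = TRUE)[, seq_len(K), drop = FALSE]
  out <- L %*% Q
  s <- sign(diag(out[seq_len(K), , drop = FALSE]))
  s[s == 0] <- 1
  out %*% diag(s, K)
}

# Complete-data REML: rotate rows by the eigenvectors of G; row i is
# t-variate normal with covariance d_i * Sigma_g + diag(se).
fa_negll_complete_factory <- function(Y, Gs, K) {
  t_y <- ncol(Y); m <- nrow(Y)
  eg <- eigen(Gs, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10); U <- eg$vectors
  Yt <- crossprod(U, Y)                   # m x t
  xt <- drop(crossprod(U, rep(1, m)))     # rotated intercept design
  function(par) {
    p <- unpack_fa(par, t_y, K)
    Sg <- p$Gamma %*% t(p$Gamma) + diag(p$psi, t_y)
    logdet <- 0
    XtVX <- matrix(0, t_y, t_y); XtVy <- numeric(t_y); yVy <- 0
    for (i in seq_len(m)) {
      Vi <- d[i] * Sg + diag(p$se, t_y)
      cV <- tryCatch(chol(Vi), error = function(e) NULL)
      if (is.null(cV)) return(1e10)
      logdet <- logdet + 2 * sum(log(diag(cV)))
      Bi <- chol2inv(cV)
      XtVX <- XtVX + xt[i]^2 * Bi
      XtVy <- XtVy + xt[i] * drop(Bi %*% Yt[i, ])
      yVy <- yVy + drop(Yt[i, ] %*% Bi %*% Yt[i, ])
    }
    cX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cX)) return(1e10)
    mu <- backsolve(cX, forwardsolve(t(cX), XtVy))
    r <- yVy - sum(XtVy * mu)
    N <- m * t_y
    val <- logdet + 2 * sum(log(diag(cX))) + r + (N - t_y) * log(2 * pi)
    if (!is.finite(val)) 1e10 else val
  }
}

# Unbalanced REML: dense covariance over observed (genotype, year) cells.
fa_negll_dense_factory <- function(dat, years, ids, Gs, K) {
  t_y <- length(years)
  gi <- match(dat$genotype_id, ids)
  yi <- match(dat$trial_id, years)
  y <- dat$blue
  N <- length(y)
  X <- stats::model.matrix(~ 0 + factor(yi, levels = seq_len(t_y)))
  Gobs <- Gs[gi, gi]
  function(par) {
    p <- unpack_fa(par, t_y, K)
    Sg <- p$Gamma %*% t(p$Gamma) + diag(p$psi, t_y)
    V <- Sg[yi, yi] * Gobs + diag(p$se[yi], N)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(1e10)
    ViX <- backsolve(cV, forwardsolve(t(cV), X))
    Viy <- backsolve(cV, forwardsolve(t(cV), y))
    XtVX <- crossprod(X, ViX); XtVy <- crossprod(X, Viy)
    cX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cX)) return(1e10)
    mu <- backsolve(cX, forwardsolve(t(cX), XtVy))
    r <- sum(y * Viy) - sum(XtVy * mu)
    val <- 2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) + r +
      (N - t_y) * log(2 * pi)
    if (!is.finite(val)) 1e10 else val
  }
}

# Factor-score BLUPs for complete data: u BLUP per rotated row, then
# f_i = Gamma' Sigma_g^-1 u_i.
fa_scores <- function(Y, Gs, Gamma, psi, se, K) {
  t_y <- ncol(Y); m <- nrow(Y)
  eg <- eigen(Gs, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10); U <- eg$vectors
  Sg <- Gamma %*% t(Gamma) + diag(psi, t_y)
  mu <- colMeans(Y)
  R <- sweep(Y, 2, mu)
  Rt <- crossprod(U, R)
  Ut <- matrix(0, m, t_y)
  for (i in seq_len(m)) {
    Vi <- d[i] * Sg + diag(se, t_y)
    Ut[i, ] <- drop(d[i] * Sg %*% solve(Vi, Rt[i, ]))
  }
  u <- U %*% Ut
  f <- u %*% solve(Sg, Gamma)
  rownames(f) <- rownames(Y)
  colnames(f) <- paste0("factor", seq_len(K))
  f
}

check_connectivity <- function(dat, years) {
  rosters <- split(dat$genotype_id, dat$trial_id)[years]
  t_y <- length(years)
  adj <- matrix(FALSE, t_y, t_y)
  for (i in seq_len(t_y)) for (j in seq_len(t_y)) {
    adj[i, j] <- i == j || length(intersect(rosters[[i]], rosters[[j]])) > 0
  }
  seen <- logical(t_y); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE; queue <- c(queue, nb)
  }
  if (!all(seen)) {
    abort(paste0("trials are not connected by shared genotypes; components: {",
                 paste(years[seen], collapse = ","), "} vs {",
                 paste(years[!seen], collapse = ","), "}"))
  }
  invisible(TRUE)
}

#' @exportS3Method base::print
print.fa_fit <- function(x, ...) {
  off <- x$genetic_correlations[lower.tri(x$genetic_correlations)]
  cat(sprintf("<fa_fit> FA%d over %d years, mean r_a %.3f, VE%% %.1f\n",
              x$K, length(x$years), mean(off), x$ve_percent))
  invisible(x)
}

#' @export
tidy.fa_fit <- function(x, ...) {
  tibble(trial_id = x$years,
         loading1 = x$loadings[, 1],
         loading2 = if (x$K >= 2) x$loadings[, 2] else NA_real_,
         specific_variance = as.numeric(x$specific_variances),
         residual_variance = as.numeric(x$residual_variances))
}

#' @export
glance.fa_fit <- function(x, ...) {
  off <- x$genetic_correlations[lower.tri(x$genetic_correlations)]
  tibble(K = x$K, n_years = length(x$years),
         mean_genetic_correlation = mean(off),
         min_genetic_correlation = min(off),
         ve_percent = x$ve_percent,
         log_likelihood = x$loglik,
         converged = x$convergence == 0)
}
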