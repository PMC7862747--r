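#' Adjust plot phenotypes to per-genotype BLUEs
#'
#' One-stage REML analysis of a single trial and trait. Genotypes are fixed
#' effects (their estimates are the BLUEs); replicates and beds within
#' replicates are random. Three candidate models are available:
#'
#' * `base` — random replicate + bed-within-replicate, iid residual.
#' * `spatial_rc` — `base` plus random row and column effects.
#' * `spatial_rc_ar1` — `spatial_rc` with the iid residual replaced by a
#'   separable AR1(row) x AR1(col) correlated residual.
#'
#' Variance parameters are estimated by restricted maximum likelihood with
#' variance ratios bounded below at 1e-8 of the phenotypic variance; the
#' iid-residual models profile the residual variance and solve the mixed-model
#' equations in the random-effect dimension, the AR1 model maximises the dense
#' REML likelihood over the two autocorrelations as well. BLUEs are centred on
#' the grand mean (default) or on the control genotype.
#'
#' @param trial Long-format trial tibble (columns `trial`, `genotype`, `rep`,
#'   `bed`, `row`, `col`, `is_control`, `trait`, `value`), as produced by
#'   [simulate_trial()].
#' @param trait Trait name to adjust.
#' @param model One of `"base"`, `"spatial_rc"`, `"spatial_rc_ar1"`.
#' @param center `"grand_mean"` or `"control"`.
#' @param control_id Control genotype id (defaults to the flagged control).
#' @param fix_rho Optional length-2 numeric to fix `(rho_row, rho_col)` in the
#'   AR1 model instead of estimating them.
#' @return A `trial_model` object; [tidy()] returns the BLUE table
#'   (`trial_id`, `genotype_id`, `trait`, `blue`, `se`, `model_tag`),
#'   [glance()] the fit summary (`model_tag`, `log_likelihood`, `n_params`,
#'   `aic`, `bic`).
#' @export
fit_trial_model <- function(trial, trait,
                            model = c("base", "spatial_rc", "spatial_rc_ar1"),
                            center = c("grand_mean", "control"),
                            control_id = NULL, fix_rho = NULL) {
  model <- match.arg(model)
  center <- match.arg(center)
  dat <- dplyr::filter(trial, .data$trait == !!trait)
  assert_that(nrow(dat) > 0, paste("no records for trait", trait))
  assert_that(all(is.finite(dat$value)), "non-finite phenotypes")
  if (model != "base") {
    assert_that(all(c("row", "col") %in% names(dat)) && !anyNA(dat$row) &&
                  !anyNA(dat$col), "spatial models need row/col coordinates")
  }
  n_rep <- length(unique(dat$rep))
  assert_that(n_rep >= 2 || model == "base",
              "need at least 2 replicates")
  y <- dat$value
  n <- length(y)
  geno <- factor(dat$genotype)
  X <- stats::model.matrix(~ 0 + geno)
  colnames(X) <- levels(geno)

  Zs <- list()
  if (n_rep > 1) Zs$rep <- indicator(factor(dat$rep))
  bed_f <- factor(paste(dat$rep, dat$bed, sep = ":"))
  if (nlevels(bed_f) > 1 && nlevels(bed_f) < n) Zs$bed <- indicator(bed_f)
  if (model %in% c("spatial_rc", "spatial_rc_ar1")) {
    if (length(unique(dat$row)) > 1) Zs$row <- indicator(factor(dat$row))
    if (length(unique(dat$col)) > 1) Zs$col <- indicator(factor(dat$col))
  }

  fit <- if (model == "spatial_rc_ar1") {
    reml_dense_ar1(y, X, Zs, dat$row, dat$col, fix_rho = fix_rho)
  } else {
    reml_woodbury(y, X, Zs)
  }

  beta <- fit$beta
  se <- fit$se_beta
  offset <- if (center == "grand_mean") {
    mean(beta)
  } else {
    control_id <- control_id %||% unique(dat$genotype[dat$is_control])[1]
    assert_that(!is.na(control_id) && control_id %in% names(beta),
                "control genotype not found for centring")
    beta[[control_id]]
  }
  blues <- tibble(trial_id = dat$trial[1], genotype_id = names(beta),
                  trait = trait, blue = as.numeric(beta - offset),
                  se = as.numeric(se), model_tag = model)
  k <- fit$n_varpar + ncol(X)
  structure(list(blues = blues, model_tag = model,
                 log_likelihood = fit$loglik, n_params = k, n_obs = n,
                 aic = -2 * fit$loglik + 2 * k,
                 bic = -2 * fit$loglik + k * log(n),
                 varcomps = fit$varcomps,
                 data_checksum = checksum_y(y),
                 center = center),
            class = "trial_model")
}

#' @exportS3Method base::print
print.trial_model <- function(x, ...) {
  cat(sprintf("<trial_model:%s> %d BLUEs, logLik %.2f, AIC %.1f\n",
              x$model_tag, nrow(x$blues), x$log_likelihood, x$aic))
  invisible(x)
}

#' @export
tidy.trial_model <- function(x, ...) x$blues

#' @export
glance.trial_model <- function(x, ...) {
  tibble(model_tag = x$model_tag, log_likelihood = x$log_likelihood,
         n_params = x$n_params, n_obs = x$n_obs, aic = x$aic, bic = x$bic)
}

#' Select among candidate trial models
#'
#' Minimum-AIC selection with ties broken by fewer parameters, then by BIC.
#' Candidates must have been fitted on identical data.
#'
#' @param fits List of `trial_model` objects (or a single one).
#' @return The winning `trial_model`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "trial_model")) fits <- list(fits)
  assert_that(length(fits) >= 1, "no candidate models")
  assert_that(all(vapply(fits, inherits, logical(1), "trial_model")),
              "candidates must be trial_model objects")
  cks <- vapply(fits, function(f) f$data_checksum, character(1))
  assert_that(length(unique(cks)) == 1L,
              "candidates were fitted on differing data")
  tab <- dplyr::bind_rows(lapply(fits, glance))
  ord <- order(tab$aic, tab$n_params, tab$bic)
  fits[[ord[1]]]
}

indicator <- function(f) {
  Z <- stats::model.matrix(~ 0 + f)
  colnames(Z) <- levels(f)
  Z
}

checksum_y <- function(y) sprintf("%d|%.10e|%.10e", length(y), sum(y), sum(y^2))

# --- REML engines -----------------------------------------------------------

# Profiled REML for V = sigma2_e (I + sum_k gamma_k Z_k Z_k'), worked in the
# random-effect dimension (Woodbury), so cost per evaluation is O(q^3 + p^2 q)
# not O(n^3). Returns estimates, BLUEs and the REML log-likelihood including
# all constants (comparable across candidate models on the same data).
reml_woodbury <- function(y, X, Zs, lower_log_gamma = log(1e-8),
                          upper_log_gamma = log(1e8)) {
  n <- length(y); p <- qr(X)$rank
  if (length(Zs) == 0L) return(reml_fixed_only(y, X))
  Z <- do.call(cbind, Zs)
  q <- ncol(Z)
  term <- rep(seq_along(Zs), vapply(Zs, ncol, integer(1)))
  ZtZ <- crossprod(Z); XtZ <- crossprod(X, Z); Zty <- crossprod(Z, y)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y * y)

  crit <- function(log_gamma) {
    s <- sqrt(exp(log_gamma))[term]
    K <- diag(q) + (s %o% s) * ZtZ
    cK <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(cK)) return(1e10)
    logdetV0 <- 2 * sum(log(diag(cK)))
    # V0^-1 A = A - Zs K^-1 Zs' A for any A, via cross-products
    ZtX_s <- XtZ * rep(s, each = nrow(XtZ))        # X'Z S
    Zty_s <- Zty * s
    Kinv_ZtX <- backsolve(cK, forwardsolve(t(cK), t(ZtX_s)))
    Kinv_Zty <- backsolve(cK, forwardsolve(t(cK), Zty_s))
    XtVX <- XtX - ZtX_s %*% Kinv_ZtX
    XtVy <- Xty - ZtX_s %*% Kinv_Zty
    yVy <- yty - sum(Zty_s * Kinv_Zty)
    cX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cX)) return(1e10)
    b <- backsolve(cX, forwardsolve(t(cX), XtVy))
    r <- max(yVy - sum(XtVy * b), 1e-300)
    sigma2 <- r / (n - p)
    val <- (n - p) * log(sigma2) + logdetV0 + 2 * sum(log(diag(cX))) +
      (n - p) * (1 + log(2 * pi))
    attr(val, "state") <- list(beta = b, sigma2 = sigma2, cX = cX,
                               gamma = exp(log_gamma))
    val
  }

  k <- length(Zs)
  opt <- NULL
  for (start in list(rep(log(0.1), k), rep(log(0.5), k))) {
    o <- stats::optim(start, function(par) as.numeric(crit(par)),
                      method = "L-BFGS-B",
                      lower = lower_log_gamma, upper = upper_log_gamma,
                      control = list(maxit = 200, factr = 1e4))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  if (k > 1) {
    # simplex polish: the profile surface flattens near variance boundaries
    o <- stats::optim(opt$par, function(par) as.numeric(crit(par)),
                      method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-13))
    if (is.finite(o$value) && o$value < opt$value) opt <- o
    opt$par <- pmin(pmax(opt$par, lower_log_gamma), upper_log_gamma)
  }
  final <- crit(opt$par)
  st <- attr(final, "state")
  se <- sqrt(pmax(diag(chol2inv(st$cX)), 0) * st$sigma2)
  beta <- stats::setNames(as.numeric(st$beta), colnames(X))
  list(beta = beta, se_beta = stats::setNames(se, colnames(X)),
       loglik = -0.5 * as.numeric(final),
       varcomps = tibble(term = c(names(Zs), "residual"),
                         variance = c(st$gamma * st$sigma2, st$sigma2)),
       n_varpar = k + 1L)
}

reml_fixed_only <- function(y, X) {
  n <- length(y); p <- qr(X)$rank
  fit <- stats::lm.fit(X, y)
  r <- sum(fit$residuals^2)
  sigma2 <- if (n > p) r / (n - p) else 0
  cXX <- chol(crossprod(X))
  XtXinv <- chol2inv(cXX)
  ll <- if (n > p && sigma2 > 0) {
    -0.5 * ((n - p) * log(sigma2) + 2 * sum(log(diag(cXX))) +
              (n - p) * (1 + log(2 * pi)))
  } else Inf
  list(beta = stats::setNames(fit$coefficients, colnames(X)),
       se_beta = stats::setNames(sqrt(diag(XtXinv) * sigma2), colnames(X)),
       loglik = ll, varcomps = tibble(term = "residual", variance = sigma2),
       n_varpar = 1L)
}

# Dense REML for V = sigma2_e (R(rho_r, rho_c) + sum_k gamma_k Z_k Z_k') with
# separable AR1 residual correlation built from plot coordinates. Suited to
# single-trial sizes (a few thousand plots).
reml_dense_ar1 <- function(y, X, Zs, row, col, fix_rho = NULL) {
  n <- length(y); p <- qr(X)$rank
  Z <- if (length(Zs)) do.call(cbind, Zs) else NULL
  term <- if (length(Zs)) rep(seq_along(Zs), vapply(Zs, ncol, integer(1))) else integer(0)
  dr <- abs(outer(row, row, "-")); dc <- abs(outer(col, col, "-"))

  crit <- function(par) {
    k <- length(Zs)
    # same variance-ratio floor/ceiling as the iid engine
    gam <- pmin(pmax(exp(par[seq_len(k)]), 1e-8), 1e8)
    rho <- if (is.null(fix_rho)) tanh(par[k + 1:2]) else fix_rho
    V0 <- rho[1]^dr * rho[2]^dc
    if (!is.null(Z)) {
      s2 <- gam[term]
      V0 <- V0 + Z %*% (t(Z) * s2)
    }
    cV <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(cV)) return(1e10)
    Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    XtVX <- crossprod(X, Vi_X); XtVy <- crossprod(X, Vi_y)
    cX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cX)) return(1e10)
    b <- backsolve(cX, forwardsolve(t(cX), XtVy))
    r <- max(sum(y * Vi_y) - sum(XtVy * b), 1e-300)
    sigma2 <- r / (n - p)
    val <- (n - p) * log(sigma2) + 2 * sum(log(diag(cV))) +
      2 * sum(log(diag(cX))) + (n - p) * (1 + log(2 * pi))
    attr(val, "state") <- list(beta = b, sigma2 = sigma2, cX = cX,
                               gamma = gam, rho = rho)
    val
  }

  k <- length(Zs)
  npar <- k + if (is.null(fix_rho)) 2L else 0L
  start <- c(rep(log(0.1), k), if (is.null(fix_rho)) c(0.1, 0.1))
  opt <- stats::optim(start, function(par) as.numeric(crit(par)),
                      method = if (npar > 1) "Nelder-Mead" else "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  # alternate quasi-Newton / simplex polish: either alone can stall short of
  # the optimum on the nearly flat profile near variance boundaries
  for (method in c("BFGS", "Nelder-Mead", "BFGS")) {
    polish <- tryCatch(
      stats::optim(opt$par, function(par) as.numeric(crit(par)),
                   method = method,
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(polish) || !is.finite(polish$value)) next
    improved <- opt$value - polish$value
    if (polish$value < opt$value) opt <- polish
    if (improved < 1e-10) break
  }
  # perturbed restart if the surface misbehaved
  if (!is.finite(opt$value) || opt$value >= 1e10) {
    opt2 <- stats::optim(start + stats::rnorm(length(start), 0, 0.5),
                         function(par) as.numeric(crit(par)),
                         method = "Nelder-Mead", control = list(maxit = 500))
    if (opt2$value < opt$value) opt <- opt2
    assert_that(is.finite(opt$value) && opt$value < 1e10,
                "AR1 REML failed: fitted covariance not positive definite")
  }
  final <- crit(opt$par)
  st <- attr(final, "state")
  se <- sqrt(pmax(diag(chol2inv(st$cX)), 0) * st$sigma2)
  beta <- stats::setNames(as.numeric(st$beta), colnames(X))
  vc <- tibble(term = c(names(Zs), "residual", "rho_row", "rho_col"),
               variance = c(st$gamma * st$sigma2, st$sigma2, st$rho))
  list(beta = beta, se_beta = stats::setNames(se, colnames(X)),
       loglik = -0.5 * as.numeric(final), varcomps = vc,
       n_varpar = k + 1L + if (is.null(fix_rho)) 2L else 0L)
}
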