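#' Segmented (breakpoint) gamma GLMM for longitudinal diversity
#'
#' Models positive diversity values `y` of mouse `i` at time `t` as
#' Gamma-distributed with log-link mean
#' `log mu = beta0 + u_i + beta1 * t + beta2 * max(0, t - t_b)`,
#' with mouse random intercepts `u_i ~ N(0, sigma_u^2)`. The marginal
#' likelihood integrates each `u_i` by adaptive Gauss-Hermite quadrature
#' (nodes recentred and rescaled at each mouse's conditional mode) and is
#' maximized over the fixed effects, `sigma_u` and the gamma shape `nu`.
#' The breakpoint `t_b` is estimated by profiling the likelihood over a
#' time grid (stable for small designs); continuity of the mean at `t_b`
#' holds by construction. Technical replicates enter as repeated
#' observations.
#'
#' @param data Data frame with columns `mouse`, `t`, `y` (and optionally
#'   `replicate`); all `y > 0`.
#' @param breakpoint_grid Candidate breakpoints (months).
#' @param nAGQ Gauss-Hermite quadrature nodes (>= 9 recommended).
#' @return An object of class `breakpoint_fit`: coefficients (beta0, beta1,
#'   beta2), `t_b`, `sigma_u`, `shape`, `logLik`, `df` (including the
#'   profiled breakpoint), `AIC`, the grid `profile` and the training data.
#' @export
fit_breakpoint_glmm <- function(data, breakpoint_grid = seq(5, 10, by = 0.5),
                                nAGQ = 9L) {
  .check_obs(data)
  if (length(breakpoint_grid) < 1L || anyNA(breakpoint_grid))
    stop("degenerate breakpoint grid")
  if (length(unique(data$t)) < 3L) stop("need at least 3 timepoints")
  fits <- lapply(breakpoint_grid, function(tb)
    .fit_gamma_glmm(data, "breakpoint", t_b = tb, nAGQ = nAGQ))
  ll <- vapply(fits, function(f) if (is.null(f)) -Inf else f$logLik, numeric(1))
  if (all(!is.finite(ll))) stop("no breakpoint candidate produced a valid fit")
  best <- which.max(ll)
  fit <- fits[[best]]
  fit$profile <- data.frame(t_b = breakpoint_grid, logLik = ll)
  ## one extra effective parameter for the profiled breakpoint
  fit$df <- fit$df + 1L
  fit$AIC <- 2 * fit$df - 2 * fit$logLik
  fit$label <- "breakpoint"
  class(fit) <- c("breakpoint_fit", "diversity_glmm")
  fit
}

.check_obs <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("mouse", "t", "y") %in% names(data)))
  if (any(!is.finite(data$y)) || any(data$y <= 0))
    stop("gamma family requires strictly positive responses")
  if (length(unique(data$mouse)) < 2L) stop("need at least 2 mice")
}

## design matrix of a mean structure
.glmm_X <- function(t, mean_structure, t_b) {
  switch(mean_structure,
         intercept = cbind(`(Intercept)` = rep(1, length(t))),
         linear = cbind(`(Intercept)` = 1, t = t),
         breakpoint = cbind(`(Intercept)` = 1, t = t,
                            t_after = pmax(0, t - t_b)))
}

## negative marginal log-likelihood by adaptive Gauss-Hermite quadrature;
## par = (beta, log sigma_u, log nu)
.agq_negll <- function(par, X, y, mouse_idx, gh) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sigma_u <- exp(par[p + 1L])
  nu <- exp(par[p + 2L])
  if (!is.finite(sigma_u) || !is.finite(nu)) return(1e10)
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (i in seq_along(mouse_idx)) {
    ix <- mouse_idx[[i]]
    e <- eta[ix]; yy <- y[ix]
    ## g(u) = sum_j log Gamma(y_j; nu, nu / mu_j(u)) + log phi(u; 0, sigma_u)
    gfun <- function(u) {
      mu <- exp(e + u)
      sum(nu * log(nu) - nu * (e + u) + (nu - 1) * log(yy) -
            nu * yy / mu - lgamma(nu)) -
        0.5 * u^2 / sigma_u^2 - log(sigma_u) - 0.5 * log(2 * pi)
    }
    ## Newton search for the conditional mode (g is strictly concave)
    u <- 0
    for (it in 1:50) {
      r <- yy * exp(-(e + u))
      g1 <- sum(nu * (r - 1)) - u / sigma_u^2
      g2 <- -sum(nu * r) - 1 / sigma_u^2
      step <- g1 / g2
      u <- u - step
      if (abs(step) < 1e-10) break
    }
    h <- 1 / sqrt(-(-sum(nu * yy * exp(-(e + u))) - 1 / sigma_u^2))
    lg <- vapply(gh$x, function(z) gfun(u + h * z), numeric(1)) + gh$x^2 +
      log(gh$w)
    mx <- max(lg)
    ll <- ll + mx + log(sum(exp(lg - mx))) + log(h)
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

## fit one gamma GLMM with the requested fixed-effect structure
.fit_gamma_glmm <- function(data, mean_structure, t_b = NA_real_, nAGQ = 9L) {
  X <- .glmm_X(data$t, mean_structure, t_b)
  y <- data$y
  mouse_idx <- split(seq_along(y), data$mouse)
  gh <- pracma::gaussHermite(nAGQ)
  ## starting values from the fixed-effect gamma GLM
  g0 <- tryCatch(
    stats::glm.fit(X, y, family = stats::Gamma(link = "log")),
    error = function(e) NULL)
  if (is.null(g0) || !g0$converged) return(NULL)
  disp <- sum((y - g0$fitted.values)^2 / g0$fitted.values^2) / g0$df.residual
  resid_mouse <- vapply(mouse_idx, function(ix)
    mean(log(y[ix]) - log(g0$fitted.values[ix])), numeric(1))
  nu0 <- if (!is.finite(disp) || disp <= 0) 1e5 else 1 / disp
  par0 <- c(g0$coefficients,
            log(min(max(stats::sd(resid_mouse), 1e-3), 50)),
            log(min(max(nu0, 1e-2), 1e5)))
  opt <- tryCatch(
    stats::optim(par0, .agq_negll, X = X, y = y, mouse_idx = mouse_idx,
                 gh = gh, method = "L-BFGS-B",
                 lower = c(rep(-Inf, ncol(X)), log(1e-6), log(1e-4)),
                 upper = c(rep(Inf, ncol(X)), log(100), log(1e8)),
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0) {
    ## line-search failures near the boundary: fall back to Nelder-Mead
    opt <- tryCatch(
      stats::optim(par0, .agq_negll, X = X, y = y, mouse_idx = mouse_idx,
                   gh = gh, method = "Nelder-Mead",
                   control = list(maxit = 5000)),
      error = function(e) NULL)
  }
  if (is.null(opt) || opt$convergence != 0) return(NULL)
  hess <- tryCatch(
    stats::optimHess(opt$par, .agq_negll, X = X, y = y,
                     mouse_idx = mouse_idx, gh = gh),
    error = function(e) NULL)
  vcov_all <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  p <- ncol(X)
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  out <- list(
    beta = beta,
    beta0 = unname(beta[1L]),
    beta1 = if ("t" %in% names(beta)) unname(beta["t"]) else 0,
    beta2 = if ("t_after" %in% names(beta)) unname(beta["t_after"]) else 0,
    t_b = t_b,
    sigma_u = unname(exp(opt$par[p + 1L])),
    shape = unname(exp(opt$par[p + 2L])),
    logLik = -opt$value,
    df = p + 2L,
    AIC = 2 * (p + 2L) + 2 * opt$value,
    vcov_beta = if (!is.null(vcov_all))
      vcov_all[seq_len(p), seq_len(p), drop = FALSE] else NULL,
    n = length(y),
    y_sum = sum(y),
    t_range = range(data$t),
    nAGQ = nAGQ,
    data = data,
    label = mean_structure)
  class(out) <- "diversity_glmm"
  out
}

#' Null models for the diversity trajectory
#'
#' Fits the intercept-only and log-linear (no breakpoint) gamma GLMMs with
#' the same random-intercept structure as [fit_breakpoint_glmm()], for model
#' comparison.
#'
#' @inheritParams fit_breakpoint_glmm
#' @return Named list of `diversity_glmm` fits: `intercept`, `linear`.
#' @export
fit_null_models <- function(data, nAGQ = 9L) {
  .check_obs(data)
  fits <- list(
    intercept = .fit_gamma_glmm(data, "intercept", nAGQ = nAGQ),
    linear = .fit_gamma_glmm(data, "linear", nAGQ = nAGQ))
  if (any(vapply(fits, is.null, logical(1))))
    stop("null model fit failed")
  fits
}

#' Model-selection table over diversity-trajectory fits
#'
#' @param fits List of `diversity_glmm` / `breakpoint_fit` objects fitted on
#'   identical data.
#' @return Data frame sorted by AIC (ties broken by fewer parameters):
#'   model, k, logLik, AIC, dAIC.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L)
  n <- vapply(fits, `[[`, numeric(1), "n")
  ys <- vapply(fits, `[[`, numeric(1), "y_sum")
  if (length(unique(n)) > 1L || diff(range(ys)) > 1e-8 * max(abs(ys)))
    stop("fits were not computed on identical data")
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "label"),
    k = vapply(fits, `[[`, numeric(1), "df"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC, tab$k), , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1L]
  rownames(tab) <- NULL
  tab
}

#' Predicted mean diversity trajectory with 95\% confidence ribbon
#'
#' Returns the conditional mean for the median mouse (`u_i = 0`):
#' `exp(beta0 + beta1 t + beta2 (t - t_b)+)`, with a delta-method 95\%
#' confidence interval for the mean computed on the log scale from the
#' fixed-effect covariance. Times outside the training range by more than
#' 20\% of its span trigger an extrapolation warning.
#'
#' @param fit A `breakpoint_fit` (or any `diversity_glmm`).
#' @param times Prediction times (months).
#' @return Data frame: t, mean, lo, hi.
#' @export
predict_mean <- function(fit, times) {
  stopifnot(inherits(fit, "diversity_glmm"))
  rng <- fit$t_range
  tolr <- 0.2 * diff(rng)
  if (any(times < rng[1] - tolr | times > rng[2] + tolr))
    warning("prediction times extrapolate beyond 20% of the training range")
  X <- .glmm_X(times, fit$label, fit$t_b)
  eta <- as.vector(X %*% fit$beta)
  if (is.null(fit$vcov_beta))
    stop("fit has no fixed-effect covariance; cannot form the ribbon")
  se <- sqrt(rowSums((X %*% fit$vcov_beta) * X))
  data.frame(t = times, mean = exp(eta),
             lo = exp(eta - 1.96 * se), hi = exp(eta + 1.96 * se))
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("Segmented gamma GLMM (log link, mouse random intercept, AGQ",
      paste0(x$nAGQ, ")"), "\n")
  cat(sprintf("  breakpoint t_b = %.2f months (profiled over %d candidates)\n",
              x$t_b, nrow(x$profile)))
  cat(sprintf("  beta0 = %.3f, slope before = %.4f, slope after = %.4f\n",
              x$beta0, x$beta1, x$beta1 + x$beta2))
  cat(sprintf("  sigma_u = %.3f, gamma shape = %.2f\n", x$sigma_u, x$shape))
  cat(sprintf("  logLik = %.2f (df %d), AIC = %.2f\n",
              x$logLik, x$df, x$AIC))
  invisible(x)
}

#' @export
print.diversity_glmm <- function(x, ...) {
  cat(sprintf("Gamma GLMM (%s mean, log link): logLik %.2f, AIC %.2f\n",
              x$label, x$logLik, x$AIC))
  invisible(x)
}
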