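#' Design matrices for the two-part mixture model
#'
#' The model has a logistic component for metabolite presence,
#' `logit(p_i) = x_i' beta`, and a linear component for the mean of the
#' detected abundance, `mu_i = z_i' alpha`. The two components may use
#' different covariates; in practice `x` is often a subset of `z` (fewer
#' parameters are identifiable from detect/non-detect data than from
#' quantitative abundances).
#'
#' @param x_design numeric matrix (samples x logistic covariates, including
#'   an intercept column).
#' @param z_design numeric matrix (samples x linear covariates, including an
#'   intercept column).
#' @return object of class `mixture_design`.
#' @export
mixture_design <- function(x_design, z_design) {
  x_design <- as.matrix(x_design); z_design <- as.matrix(z_design)
  if (nrow(x_design) != nrow(z_design))
    stop("x_design and z_design must have the same number of rows", call. = FALSE)
  if (is.null(colnames(x_design)))
    colnames(x_design) <- paste0("x", seq_len(ncol(x_design)))
  if (is.null(colnames(z_design)))
    colnames(z_design) <- paste0("z", seq_len(ncol(z_design)))
  for (nm in c("x_design", "z_design")) {
    d <- get(nm)
    if (qr(d)$rank < ncol(d))
      stop(nm, " is rank deficient on the fitting samples", call. = FALSE)
  }
  structure(list(x = x_design, z = z_design), class = "mixture_design")
}

# log(exp(a) + exp(b)) elementwise, overflow-safe
.logspace_add <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

# packed-parameter negative log likelihood; used by the optimizer.
# par = c(beta, alpha, log_sigma); det is logical; thr per-sample T.
.nll_packed <- function(par, y, det, x, z, thr) {
  nb <- ncol(x); na_ <- ncol(z)
  beta <- par[seq_len(nb)]
  alpha <- par[nb + seq_len(na_)]
  sigma <- exp(par[nb + na_ + 1L])
  xb <- drop(x %*% beta)
  mu <- drop(z %*% alpha)
  if (any(!is.finite(xb)) || any(!is.finite(mu)) || !is.finite(sigma))
    return(.Machine$double.xmax / 1e6)
  logp <- stats::plogis(xb, log.p = TRUE)
  log1mp <- stats::plogis(-xb, log.p = TRUE)
  ll <- 0
  if (any(det))
    ll <- ll + sum(logp[det] + stats::dnorm(y[det], mu[det], sigma, log = TRUE))
  if (any(!det)) {
    u <- (thr[!det] - mu[!det]) / sigma
    logA <- .logspace_add(log1mp[!det],
                          logp[!det] + stats::pnorm(u, log.p = TRUE))
    ll <- ll + sum(logA)
  }
  if (!is.finite(ll)) return(.Machine$double.xmax / 1e6)
  -ll
}

# analytic gradient of .nll_packed
.nll_grad_packed <- function(par, y, det, x, z, thr) {
  nb <- ncol(x); na_ <- ncol(z)
  beta <- par[seq_len(nb)]
  alpha <- par[nb + seq_len(na_)]
  ls <- par[nb + na_ + 1L]
  sigma <- exp(ls)
  xb <- drop(x %*% beta)
  mu <- drop(z %*% alpha)
  logp <- stats::plogis(xb, log.p = TRUE)
  log1mp <- stats::plogis(-xb, log.p = TRUE)
  gb <- numeric(length(y))   # per-sample d(nll)/d(xb)
  ga <- numeric(length(y))   # per-sample d(nll)/d(mu)
  gl <- 0                    # d(nll)/d(log sigma)
  if (any(det)) {
    r <- y[det] - mu[det]
    gb[det] <- -exp(log1mp[det])
    ga[det] <- -r / sigma^2
    gl <- gl + sum(1 - r^2 / sigma^2)
  }
  if (any(!det)) {
    u <- (thr[!det] - mu[!det]) / sigma
    logPhi <- stats::pnorm(u, log.p = TRUE)
    log1mPhi <- stats::pnorm(u, lower.tail = FALSE, log.p = TRUE)
    logphi <- stats::dnorm(u, log = TRUE)
    logA <- .logspace_add(log1mp[!det], logp[!det] + logPhi)
    gb[!det] <- exp(logp[!det] + log1mp[!det] + log1mPhi - logA)
    w <- exp(logp[!det] + logphi - logA)
    ga[!det] <- w / sigma
    gl <- gl + sum(w * u)
  }
  c(drop(crossprod(x, gb)), drop(crossprod(z, ga)), gl)
}

#' Negative log-likelihood of the detectability/abundance mixture model
#'
#' For sample i the likelihood contribution is
#' \deqn{\left[(1-p_i) + p_i \Phi\!\left(\frac{T_i-\mu_i}{\sigma}\right)\right]^{1-\delta_i}
#'       \left[p_i \, \phi\!\left(\frac{y_i-\mu_i}{\sigma}\right)/\sigma\right]^{\delta_i}}
#' where \eqn{p_i = \mathrm{logit}^{-1}(x_i'\beta)} is the probability the
#' metabolite is present, \eqn{\mu_i = z_i'\alpha} its mean abundance,
#' \eqn{T_i} the batch detection threshold for the sample, and
#' \eqn{\delta_i} the detection indicator. The non-detected component sums
#' the probability of true absence and the probability of presence below
#' the threshold; the detected component is the normal density weighted by
#' presence. All terms are evaluated on the log scale with log-space
#' addition for the censored component.
#'
#' @param params list with elements `beta`, `alpha`, `log_sigma`.
#' @param y numeric vector of observed abundances (ignored where not detected).
#' @param detected logical vector, `TRUE` where the metabolite was detected.
#' @param design a [mixture_design()].
#' @param thresholds per-sample detection thresholds `T_i`.
#' @return the negative log-likelihood (a single number).
#' @export
neg_log_likelihood <- function(params, y, detected, design, thresholds) {
  stopifnot(inherits(design, "mixture_design"))
  par <- c(params$beta, params$alpha, params$log_sigma)
  if (any(!is.finite(par))) stop("non-finite parameter", call. = FALSE)
  if (length(params$beta) != ncol(design$x) ||
      length(params$alpha) != ncol(design$z))
    stop("parameter lengths do not match design columns", call. = FALSE)
  if (any(!detected) && any(!is.finite(thresholds[!detected])))
    stop("non-finite threshold for an undetected sample", call. = FALSE)
  .nll_packed(par, y, detected, design$x, design$z, thresholds)
}

# Gaussian MLE on z only (no undetected values, logistic bypassed: p = 1)
.fit_gaussian <- function(y, z, compute_se) {
  fit <- stats::lm.fit(z, y)
  n <- length(y)
  res <- fit$residuals
  s2 <- sum(res^2) / n
  sigma <- sqrt(s2)
  alpha <- fit$coefficients
  nll <- n / 2 * log(2 * pi * s2) + n / 2
  se_alpha <- rep(NA_real_, length(alpha))
  if (compute_se) {
    xtx_inv <- chol2inv(qr.R(fit$qr))
    # finite-sample (unbiased-variance) standard errors, the regression
    # convention, so downstream Wald tests match ordinary least squares
    se_alpha <- sqrt(diag(xtx_inv) * sum(res^2) / (n - fit$rank))
  }
  list(alpha = alpha, sigma = sigma, nll = nll, se_alpha = se_alpha)
}

#' Fit the mixture model for one metabolite by maximum likelihood
#'
#' Minimizes [neg_log_likelihood()] over `(beta, alpha, log sigma)` with
#' BFGS using the analytic gradient. Initialization: `alpha` from least
#' squares on the detected values (unidentified coefficients set to 0),
#' `beta` zero except an intercept at the logit of the observed detection
#' proportion (clipped to `[0.01, 0.99]`), and `log sigma` from the
#' complete-case residual standard deviation. On non-convergence one
#' jittered restart (seeded) is attempted. When every value is detected
#' the logistic component carries no information and is bypassed: `p` is
#' fixed at 1 and the fit reduces to Gaussian least squares on `z`.
#'
#' @param y numeric vector of abundances for the fitting samples.
#' @param detected logical detection indicator per sample.
#' @param design a [mixture_design()] whose rows align with `y`.
#' @param thresholds per-sample detection thresholds.
#' @param compute_se compute standard errors from the inverse observed
#'   information (numerical Jacobian of the analytic gradient)? Default
#'   `FALSE`; needed for [wald_test()].
#' @param bypass_logistic bypass the logistic component when all values are
#'   detected (default `TRUE`). Setting `FALSE` forces the full mixture
#'   optimization even then (the MLE for `beta` diverges towards `p = 1`;
#'   `alpha` and `sigma` are unaffected).
#' @param maxit,reltol optimizer settings (BFGS).
#' @param restart_seed seed for the jittered restart.
#' @param metabolite_id optional label stored in the result.
#' @return object of class `mixture_fit` with elements `beta`, `alpha`,
#'   `sigma`, `log_sigma`, `neg_log_lik`, `converged`, `n_detected`,
#'   `n_undetected`, `se_beta`, `se_alpha`, `bypassed`, `metabolite_id`.
#' @export
fit_mixture <- function(y, detected, design, thresholds = NULL,
                        compute_se = FALSE, bypass_logistic = TRUE,
                        maxit = 500L, reltol = 1e-10, restart_seed = 71L,
                        metabolite_id = NA_character_) {
  stopifnot(inherits(design, "mixture_design"))
  detected <- as.logical(detected)
  n <- length(y)
  if (nrow(design$x) != n) stop("design rows do not match length(y)", call. = FALSE)
  nd <- sum(detected)
  if (nd == 0L)
    stop("no detected values: metabolite not fittable", call. = FALSE)
  x <- design$x; z <- design$z
  nb <- ncol(x); na_ <- ncol(z)

  if (nd == n && bypass_logistic) {
    g <- .fit_gaussian(y, z, compute_se)
    out <- list(beta = stats::setNames(rep(NA_real_, nb), colnames(x)),
                alpha = stats::setNames(g$alpha, colnames(z)),
                sigma = g$sigma, log_sigma = log(g$sigma),
                neg_log_lik = g$nll, converged = TRUE,
                n_detected = nd, n_undetected = 0L,
                se_beta = stats::setNames(rep(NA_real_, nb), colnames(x)),
                se_alpha = stats::setNames(g$se_alpha, colnames(z)),
                bypassed = TRUE, metabolite_id = metabolite_id)
    class(out) <- "mixture_fit"
    return(out)
  }

  if (is.null(thresholds)) {
    if (nd < n) stop("thresholds required when undetected values are present",
                     call. = FALSE)
    thresholds <- rep(-Inf, n)
  }

  # initialization (see Details)
  a0 <- rep(0, na_)
  zd <- z[detected, , drop = FALSE]
  ls0 <- log(stats::sd(y[detected]) + 1e-3)
  if (nd >= 1L) {
    lf <- stats::lm.fit(zd, y[detected])
    cf <- lf$coefficients
    cf[is.na(cf)] <- 0
    a0 <- cf
    if (nd > ncol(zd)) {
      rsd <- sqrt(sum(lf$residuals^2) / nd)
      if (rsd > 0) ls0 <- log(rsd)
    }
  }
  pd <- min(max(nd / n, 0.01), 0.99)
  b0 <- rep(0, nb)
  ic <- which(apply(x, 2L, function(cc) all(cc == 1)))[1]
  if (!is.na(ic)) b0[ic] <- stats::qlogis(pd)
  par0 <- c(b0, a0, ls0)

  ctrl <- list(maxit = maxit, reltol = reltol)
  run <- function(p0) stats::optim(p0, .nll_packed, .nll_grad_packed,
                                   y = y, det = detected, x = x, z = z,
                                   thr = thresholds,
                                   method = "BFGS", control = ctrl)
  opt <- run(par0)
  grad_ok <- function(o)
    max(abs(.nll_grad_packed(o$par, y, detected, x, z, thresholds))) <= 1e-6
  converged <- opt$convergence == 0L || grad_ok(opt)
  if (!converged) {
    set.seed(restart_seed)
    opt2 <- run(par0 + stats::rnorm(length(par0), sd = 0.1))
    if (opt2$value < opt$value || opt2$convergence == 0L) opt <- opt2
    converged <- opt$convergence == 0L || grad_ok(opt)
  }

  par <- opt$par
  beta <- stats::setNames(par[seq_len(nb)], colnames(x))
  alpha <- stats::setNames(par[nb + seq_len(na_)], colnames(z))
  ls <- unname(par[nb + na_ + 1L])
  se_beta <- stats::setNames(rep(NA_real_, nb), colnames(x))
  se_alpha <- stats::setNames(rep(NA_real_, na_), colnames(z))
  vcov <- NULL
  if (compute_se) {
    H <- .observed_information(par, y, detected, x, z, thresholds)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc)) {
      dv <- diag(vc)
      dv[dv < 0] <- NA_real_
      se <- sqrt(dv)
      se_beta[] <- se[seq_len(nb)]
      se_alpha[] <- se[nb + seq_len(na_)]
      vcov <- vc
    }
  }
  out <- list(beta = beta, alpha = alpha, sigma = exp(ls), log_sigma = ls,
              neg_log_lik = opt$value, converged = converged,
              n_detected = nd, n_undetected = n - nd,
              se_beta = se_beta, se_alpha = se_alpha, vcov = vcov,
              bypassed = FALSE, metabolite_id = metabolite_id)
  class(out) <- "mixture_fit"
  out
}

# observed information as the central-difference Jacobian of the analytic
# gradient; symmetrized.
.observed_information <- function(par, y, det, x, z, thr, h = 1e-5) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    hp <- hm <- par
    step <- h * max(1, abs(par[j]))
    hp[j] <- hp[j] + step; hm[j] <- hm[j] - step
    H[, j] <- (.nll_grad_packed(hp, y, det, x, z, thr) -
               .nll_grad_packed(hm, y, det, x, z, thr)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit%s: nll = %.4f, sigma = %.4f, %d detected / %d undetected, %s\n",
              if (is.na(x$metabolite_id)) "" else paste0(" [", x$metabolite_id, "]"),
              x$neg_log_lik, x$sigma, x$n_detected, x$n_undetected,
              if (x$bypassed) "logistic bypassed"
              else if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Wald test for a fitted mixture-model coefficient
#'
#' Two-sided normal-theory Wald test for one coefficient of the linear
#' (abundance) or logistic (detectability) component, using standard errors
#' from the inverse observed information.
#'
#' @param fit a converged [fit_mixture()] result with `compute_se = TRUE`.
#' @param coefficient coefficient (column) name.
#' @param component `"linear"` or `"logistic"`.
#' @return list with `estimate`, `se`, `statistic` (z), `p_value`.
#' @export
wald_test <- function(fit, coefficient, component = c("linear", "logistic")) {
  component <- match.arg(component)
  est <- if (component == "linear") fit$alpha else fit$beta
  se <- if (component == "linear") fit$se_alpha else fit$se_beta
  if (!coefficient %in% names(est))
    stop("no coefficient '", coefficient, "' in the ", component, " component",
         call. = FALSE)
  e <- est[[coefficient]]; s <- se[[coefficient]]
  if (!is.finite(s) || s <= 0)
    stop("standard error unavailable for '", coefficient,
         "' (singular information or compute_se = FALSE)", call. = FALSE)
  zstat <- e / s
  list(estimate = e, se = s, statistic = zstat,
       p_value = 2 * stats::pnorm(-abs(zstat)))
}
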