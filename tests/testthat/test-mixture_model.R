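# naive, direct transcription of the per-sample likelihood used as an
# independent oracle: no log-space tricks, no shared code with the package
nll_naive <- function(beta, alpha, log_sigma, y, det, thr) {
  p <- 1 / (1 + exp(-beta))
  s <- exp(log_sigma)
  ll <- 0
  for (i in seq_along(y)) {
    li <- if (det[i])
      p * exp(-(y[i] - alpha)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
    else
      (1 - p) + p * pnorm((thr[i] - alpha) / s)
    ll <- ll + log(li)
  }
  -ll
}

test_that("negative log-likelihood matches hand-computed contributions", {
  des1 <- mixture_design(matrix(1, 1, 1), matrix(1, 1, 1))
  # detected sample at the mode of the normal, presence certain
  nll <- neg_log_likelihood(list(beta = 30, alpha = 14, log_sigma = 0),
                            y = 14, detected = TRUE, des1, thresholds = 13)
  expect_equal(nll, 0.5 * log(2 * pi), tolerance = 1e-6)
  # undetected sample with presence probability ~ 0: term ~ 1
  nll0 <- neg_log_likelihood(list(beta = -30, alpha = 14, log_sigma = 0),
                             y = NA_real_, detected = FALSE, des1, thresholds = 13)
  expect_equal(nll0, 0, tolerance = 1e-10)
  # undetected, p = 0.5 and T = mu: (1-p) + p*Phi(0) = 0.75
  nll5 <- neg_log_likelihood(list(beta = 0, alpha = 14, log_sigma = 0),
                             y = NA_real_, detected = FALSE, des1, thresholds = 14)
  expect_equal(nll5, -log(0.75), tolerance = 1e-9)
  expect_equal(-log(0.75), 0.2876821, tolerance = 1e-6)
  expect_error(
    neg_log_likelihood(list(beta = NaN, alpha = 14, log_sigma = 0),
                       y = 14, detected = TRUE, des1, thresholds = 13),
    "non-finite")
})

test_that("stable log-space evaluation agrees with the naive likelihood", {
  set.seed(42)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    y <- rnorm(n, 15, 1)
    det <- runif(n) < 0.7
    if (!any(det)) det[1] <- TRUE
    thr <- rep(14, n)
    beta <- rnorm(1, 0, 2); alpha <- rnorm(1, 15, 1); ls <- rnorm(1, -0.5, 0.5)
    des <- mixture_design(matrix(1, n, 1), matrix(1, n, 1))
    expect_equal(
      neg_log_likelihood(list(beta = beta, alpha = alpha, log_sigma = ls),
                         y, det, des, thr),
      nll_naive(beta, alpha, ls, y, det, thr), tolerance = 1e-8)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(7)
  n <- 30
  x <- cbind(1, rbinom(n, 1, 0.5))
  z <- cbind(1, x[, 2], rnorm(n))
  y <- rnorm(n, 15 + x[, 2], 0.7)
  det <- y > 14.3
  if (all(det)) det[1] <- FALSE
  thr <- rep(14.3, n)
  for (k in 1:10) {
    par <- c(rnorm(2, 0, 1), c(15, 1, 0) + rnorm(3, 0, 0.3), rnorm(1, -0.3, 0.2))
    ga <- mixnormr:::.nll_grad_packed(par, y, det, x, z, thr)
    gn <- numeric(length(par))
    h <- 1e-6
    for (j in seq_along(par)) {
      pp <- pm <- par; pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
      gn[j] <- (mixnormr:::.nll_packed(pp, y, det, x, z, thr) -
                mixnormr:::.nll_packed(pm, y, det, x, z, thr)) / (2 * h)
    }
    expect_equal(ga, gn, tolerance = 1e-4)
  }
})

test_that("BFGS fit lands on the brute-force grid-search minimum", {
  y <- c(14.1, 14.4, 13.9, 14.3, NA, NA)
  det <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  thr <- rep(13.8, 6)
  # exhaustive search on a 0.01 lattice, exploiting that the detected terms
  # depend only on (alpha, log sigma) and the presence probability only on
  # beta; assembled by broadcasting, so every lattice point is evaluated
  bs <- seq(-1, 3, 0.01); as_ <- seq(13.5, 15, 0.01); ls <- seq(-2.5, 0, 0.01)
  p <- 1 / (1 + exp(-bs))
  det_al <- outer(as_, ls, function(a, l)
    Reduce(`+`, lapply(y[det], function(yy)
      0.5 * log(2 * pi) + l + (yy - a)^2 / (2 * exp(2 * l)))))
  phi_al <- outer(as_, ls, function(a, l) pnorm((13.8 - a) / exp(l)))
  n_undet <- sum(!det)
  best <- c(val = Inf, b = NA, a = NA, l = NA)
  for (k in seq_along(bs)) {     # 401 slices of a (151 x 251) surface
    nll_k <- det_al - sum(det) * log(p[k]) -
      n_undet * log((1 - p[k]) + p[k] * phi_al)
    i <- arrayInd(which.min(nll_k), dim(nll_k))
    if (nll_k[i] < best["val"])
      best <- c(val = nll_k[i], b = bs[k], a = as_[i[1]], l = ls[i[2]])
  }
  # the broadcast assembly agrees with the naive per-sample likelihood
  expect_equal(unname(best["val"]),
               nll_naive(unname(best["b"]), unname(best["a"]),
                         unname(best["l"]), y, det, thr),
               tolerance = 1e-10)
  des <- mixture_design(matrix(1, 6, 1), matrix(1, 6, 1))
  fit <- fit_mixture(y, det, des, thr)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), unname(best["b"]), tolerance = 0.02)
  expect_equal(unname(fit$alpha), unname(best["a"]), tolerance = 0.02)
  expect_equal(fit$log_sigma, unname(best["l"]), tolerance = 0.02)
})

test_that("with no undetected values the fit is exactly Gaussian regression", {
  set.seed(11)
  n <- 40
  z <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  colnames(z) <- c("(Intercept)", "x1", "x2")
  y <- drop(z %*% c(16, 0.8, -1.2)) + rnorm(n, 0, 0.5)
  des <- mixture_design(z[, 1, drop = FALSE], z)
  fit <- fit_mixture(y, rep(TRUE, n), des)
  lmf <- lm.fit(z, y)
  expect_true(fit$bypassed)
  expect_equal(unname(fit$alpha), unname(lmf$coefficients), tolerance = 1e-6)
  expect_equal(fit$sigma, sqrt(sum(lmf$residuals^2) / n), tolerance = 1e-6)
  # intercept-only closed form: mean and MLE standard deviation (divisor n)
  des0 <- mixture_design(matrix(1, n, 1), matrix(1, n, 1))
  fit0 <- fit_mixture(y, rep(TRUE, n), des0)
  expect_equal(unname(fit0$alpha), mean(y), tolerance = 1e-8)
  expect_equal(fit0$sigma, sqrt(mean((y - mean(y))^2)), tolerance = 1e-8)
  # forcing the full mixture optimization changes nothing material:
  # p is driven to 1 and alpha, sigma agree with the bypass
  fitf <- fit_mixture(y, rep(TRUE, n), des, bypass_logistic = FALSE)
  expect_equal(unname(fitf$alpha), unname(fit$alpha), tolerance = 1e-4)
  expect_equal(fitf$sigma, fit$sigma, tolerance = 1e-4)
  expect_error(fit_mixture(y, rep(FALSE, n), des), "not fittable")
})

test_that("batch contrasts are recovered within sampling error on synthetic QCs", {
  set.seed(23)
  K <- 20; nq <- 3
  b_k <- rnorm(K, 0, 2)
  batch <- rep(seq_len(K), each = nq)
  sigma_true <- 0.03 * 18
  y <- 18 + b_k[batch] + rnorm(K * nq, 0, sigma_true)
  z <- cbind(1, outer(batch, 2:K, "==") + 0)
  colnames(z) <- c("(Intercept)", paste0("b", 2:K))
  des <- mixture_design(matrix(1, K * nq, 1), z)
  fit <- fit_mixture(y, rep(TRUE, K * nq), des, compute_se = TRUE)
  truth_contrast <- b_k[2:K] - b_k[1]
  est <- unname(fit$alpha[-1]); se <- unname(fit$se_alpha[-1])
  expect_true(all(abs(est - truth_contrast) <= 3 * se))
})

test_that("Wald tests give textbook p-values and flag unavailable errors", {
  fit <- structure(list(alpha = c("(Intercept)" = 10, slope = 0),
                        se_alpha = c("(Intercept)" = 1, slope = 0.5),
                        beta = c("(Intercept)" = 1),
                        se_beta = c("(Intercept)" = NA_real_)),
                   class = "mixture_fit")
  w0 <- wald_test(fit, "slope", "linear")
  expect_equal(w0$p_value, 1.0)
  fit$alpha[["slope"]] <- 1.959964
  fit$se_alpha[["slope"]] <- 1
  expect_equal(wald_test(fit, "slope", "linear")$p_value, 0.05, tolerance = 1e-5)
  expect_error(wald_test(fit, "(Intercept)", "logistic"), "standard error")
  expect_error(wald_test(fit, "nope", "linear"), "nope")
})
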