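test_that("the censored log-likelihood has the right limiting forms", {
  # no censoring: equals the ordinary normal-regression log-likelihood
  d <- generate_tobit_panel(n = 50, beta_true = c(0.5, 0.05),
                            sigma_true = 0.05, seed = 2)
  expect_equal(attr(d, "achieved_censoring"), 0)
  beta <- c(0.4, 0.1)
  sigma <- 0.07
  mu <- drop(d$X %*% beta)
  expect_equal(tobit_loglik(beta, sigma, d),
               sum(dnorm(d$y, mu, sigma, log = TRUE)))
  # one observation at the upper bound with the mean on the bound: log(1/2)
  d1 <- tobit_design(y = 1, X = matrix(1, 1, 1), lower = 0, upper = 1)
  expect_equal(tobit_loglik(1, 0.3, d1), log(0.5))
  expect_error(tobit_loglik(1, -1, d1), "positive")
})

test_that("the log-likelihood matches an independent numerical oracle", {
  # n = 5, p = 1 hand dataset; censored terms via numerical integration of
  # the latent normal density over the censored regions
  y <- c(0, 0.3, 0.8, 1, 1)
  X <- matrix(c(1, 1, 1, 1, 1), ncol = 1)
  beta <- 0.6
  sigma <- 0.4
  d <- tobit_design(y, X)
  dens <- function(t) dnorm(t, 0.6, sigma)
  expected <- log(integrate(dens, -Inf, 0)$value) +
    dnorm(0.3, 0.6, sigma, log = TRUE) +
    dnorm(0.8, 0.6, sigma, log = TRUE) +
    2 * log(integrate(dens, 1, Inf)$value)
  expect_equal(tobit_loglik(beta, sigma, d), expected, tolerance = 1e-8)
})

test_that("with no censoring the MLE equals least squares", {
  d <- generate_tobit_panel(n = 300, beta_true = c(0.5, 0.05, -0.04),
                            sigma_true = 0.05, censor_rate_target = 0,
                            seed = 4)
  fit <- fit_tobit(d)
  ols <- lm.fit(d$X, d$y)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(unname(fit$n_censored), c(0L, 0L))
})

test_that("seeded simulation recovers the true coefficients within 3 SEs", {
  truth <- c(0.8, 0.12, -0.08, 0.1)
  d <- generate_tobit_panel(n = 2000, beta_true = truth, sigma_true = 0.15,
                            censor_rate_target = 0.2, seed = 3)
  expect_gt(attr(d, "achieved_censoring"), 0.1)
  fit <- fit_tobit(d)
  expect_true(fit$converged)
  est <- c(fit$beta, fit$sigma)
  se <- fit$se
  expect_true(all(abs(est - c(truth, 0.15)) <= 3 * se))
  # the optimum improves on the least-squares start
  ols <- lm.fit(d$X, d$y)
  ll0 <- tobit_loglik(ols$coefficients, sd(ols$residuals), d)
  expect_gte(fit$loglik, ll0)
})

test_that("fit agrees with the interval-censored survival oracle", {
  skip_if_not_installed("survival")
  d <- generate_tobit_panel(n = 400, beta_true = c(0.8, 0.1, -0.05),
                            sigma_true = 0.12, seed = 6)
  fit <- fit_tobit(d)
  msk <- gsbup:::censor_masks(d)
  t1 <- ifelse(msk$hi, 1, ifelse(msk$lo, NA, d$y))
  t2 <- ifelse(msk$hi, NA, ifelse(msk$lo, 0, d$y))
  sv <- survival::survreg(survival::Surv(t1, t2, type = "interval2") ~
                            d$X[, -1], dist = "gaussian")
  expect_equal(unname(fit$beta), unname(sv$coefficients), tolerance = 1e-5)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-4)
  expect_equal(fit$loglik, sv$loglik[2], tolerance = 1e-6)
  expect_equal(unname(fit$se[seq_along(fit$beta)]),
               unname(sqrt(diag(sv$var))[seq_along(fit$beta)]),
               tolerance = 1e-3)
})

test_that("covariate rescaling is absorbed by the coefficient", {
  d <- generate_tobit_panel(n = 500, beta_true = c(0.8, 0.1), sigma_true = 0.1,
                            seed = 7)
  fit <- fit_tobit(d)
  X2 <- d$X
  X2[, 2] <- X2[, 2] * 100
  fit2 <- fit_tobit(tobit_design(d$y, X2, d$lower, d$upper))
  expect_equal(fit2$beta[2] * 100, fit$beta[2], tolerance = 1e-6)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(unname(fit2$z), unname(fit$z), tolerance = 1e-4)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_tobit(tobit_design(rep(1, 10), matrix(1, 10, 1))),
               "censored")
  X <- cbind(1, 1:20, 2 * (1:20))
  expect_error(fit_tobit(tobit_design(runif(20), X)), "rank deficient")
  expect_error(tobit_design(c(0.5, 1.2), matrix(1, 2, 1)), "within")
})

test_that("the report mirrors the conventional regression table", {
  d <- generate_tobit_panel(n = 300, beta_true = c(0.8, 0.1, -0.05),
                            sigma_true = 0.12, seed = 9)
  fit <- fit_tobit(d)
  rep_ <- tobit_report(fit)
  expect_equal(names(rep_), c("Variable", "Coefficient", "Std. Error",
                              "z-Statistic", "Prob."))
  expect_equal(nrow(rep_), length(fit$beta) + 1)  # coefficients + scale
  expect_true(all(rep_$Prob. >= 0 & rep_$Prob. <= 1))
  expect_true(is.finite(attr(rep_, "pseudo_r2_mcfadden")))
  # uncensored fit: p-values match the normal-approximation OLS p-values
  d0 <- generate_tobit_panel(n = 300, beta_true = c(0.5, 0.05),
                             sigma_true = 0.04, seed = 10)
  expect_equal(attr(d0, "achieved_censoring"), 0)
  f0 <- fit_tobit(d0)
  r0 <- tobit_report(f0)
  ols <- lm(d0$y ~ d0$X[, 2])
  # MLE sigma uses 1/n; z-statistics coincide up to that scaling at n = 300
  z_ols <- coef(summary(ols))[, "t value"] * sqrt((300 - 2) / 300)
  expect_equal(unname(r0$`z-Statistic`[1:2]), unname(z_ols),
               tolerance = 1e-2)
})

test_that("coefficient recovery is unbiased across repeated simulations", {
  truth <- c(0.85, 0.1, -0.07)
  est <- matrix(NA_real_, 50, 3)
  for (i in 1:50) {
    d <- generate_tobit_panel(n = 500, beta_true = truth, sigma_true = 0.12,
                              seed = 1000 + i)
    est[i, ] <- fit_tobit(d)$beta
  }
  bias <- colMeans(est) - truth
  expect_true(all(abs(bias) < 0.05 * abs(truth)))
})
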