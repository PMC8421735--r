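p4 <- table4_params()

# one moderately sized fitted model shared across diagnostics tests
fit_fixture <- local({
  coh <- sample_cohort(cohort_spec(), seed = 61)
  ds <- apply_blq(simulate_trial(coh, p4, trial_design(), seed = 62), "M1")
  f <- fit(ds, init = p4, fixed = c("ecrcl_slope", "sc"))
  list(ds = ds, fit = f)
})

test_that("CWRES are calibrated on data simulated from the fitted model", {
  g <- gof(fit_fixture$fit, fit_fixture$ds)
  cw <- g$CWRES[!g$censored]
  expect_gt(length(cw), 180)
  expect_true(all(is.finite(cw)))
  expect_lt(abs(mean(cw)), 0.1)
  expect_lt(abs(var(cw) - 1), 0.2)
})

test_that("IWRES vanishes for an observation equal to its individual prediction", {
  g <- gof(fit_fixture$fit, fit_fixture$ds)
  ds2 <- fit_fixture$ds
  i <- which(ds2$events$EVID == 0)[1]
  key <- which(g$ID == ds2$events$ID[i] & g$TIME == ds2$events$TIME[i] &
                 g$CMT == ds2$events$CMT[i])[1]
  ds2$events$DV[i] <- g$IPRED[key]
  g2 <- gof(fit_fixture$fit, ds2)
  expect_equal(g2$IWRES[key], 0, tolerance = 1e-9)
})

test_that("CWRES are invariant to a concentration unit rescaling", {
  ds2 <- fit_fixture$ds
  ds2$events$DV <- ds2$events$DV * 1000
  ds2$events$AMT <- ds2$events$AMT * 1000
  ds2$events$RATE <- ds2$events$RATE * 1000
  ds2$events$LLOQ <- ds2$events$LLOQ * 1000
  g1 <- gof(fit_fixture$fit, fit_fixture$ds)
  g2 <- gof(fit_fixture$fit, ds2)
  expect_equal(g2$CWRES, g1$CWRES, tolerance = 1e-8)
})

test_that("VPC brackets self-simulated data and is seed-reproducible", {
  v <- vpc(fit_fixture$fit, fit_fixture$ds, n_sim = 200, seed = 71)
  # structural invariants: ordered bands, bins spanning the observation times
  expect_true(all(v$bins$sim_lower <= v$bins$sim_median + 1e-12))
  expect_true(all(v$bins$sim_median <= v$bins$sim_upper + 1e-12))
  obs_t <- fit_fixture$ds$events$TIME[fit_fixture$ds$events$EVID == 0 &
                                        fit_fixture$ds$events$CMT == 1]
  expect_true(min(v$bins$bin_time) <= min(obs_t) + 1e-9)
  expect_true(max(v$bins$bin_time) >= max(obs_t) - 1e-9)
  inband <- with(v$bins, observed >= sim_lower & observed <= sim_upper)
  expect_gt(mean(inband, na.rm = TRUE), 0.8)
  v2 <- vpc(fit_fixture$fit, fit_fixture$ds, n_sim = 200, seed = 71)
  expect_identical(v$bins, v2$bins)
  expect_error(vpc(fit_fixture$fit, fit_fixture$ds, n_sim = 50, seed = 1),
               "n_sim")
})

test_that("categorical BLQ VPC has the right limits in the LLOQ", {
  res <- fit_fixture$fit
  # coverage is checked on a dataset that retains its censored records
  coh <- sample_cohort(cohort_spec(), seed = 61)
  ds <- apply_blq(simulate_trial(coh, p4, trial_design(), seed = 62), "M3")
  v0 <- categorical_vpc_blq(res, ds, n_sim = 100, seed = 5, lloq = 1e-12)
  expect_true(all(v0$bins$sim_median == 0))
  vinf <- categorical_vpc_blq(res, ds, n_sim = 100, seed = 5, lloq = 1e12)
  expect_true(all(vinf$bins$sim_lower == 1))
  expect_true(all(vinf$bins$observed == 1))
  v <- categorical_vpc_blq(res, ds, n_sim = 200, seed = 6)
  inband <- with(v$bins, observed >= sim_lower & observed <= sim_upper)
  expect_gt(mean(inband), 0.8)
})

test_that("SIR degenerates to the point estimate under a zero-covariance proposal", {
  est <- c(a = 1.5, b = -2)
  s <- sir(function(th) sum(th^2), est, matrix(0, 2, 2),
           n_samples = 200, n_resamples = 100, seed = 1)
  expect_true(all(s$resamples[, 1] == 1.5))
  expect_equal(s$summary$median, unname(est))
  expect_equal(s$summary$lower, s$summary$upper)
})

test_that("uniform importance weights reproduce the proposal distribution", {
  # OFV equal to -2 log proposal density makes all weights equal
  mu0 <- 3; s0 <- 0.5
  ofv_fun <- function(th) -2 * dnorm(th, mu0, s0, log = TRUE)
  s <- sir(ofv_fun, estimate = mu0, vcov = matrix(s0^2), n_samples = 4000,
           n_resamples = 2000, seed = 8, param_names = "mu")
  expect_gt(s$ess, 3800)  # near-uniform weights
  expect_equal(s$summary$median, mu0, tolerance = 0.05)
  expect_equal(s$summary$lower, mu0 - 1.96 * s0, tolerance = 0.08)
  expect_equal(s$summary$upper, mu0 + 1.96 * s0, tolerance = 0.08)
})

test_that("SIR matches the analytic posterior on a conjugate Gaussian toy", {
  set.seed(12)
  n <- 40; sigma <- 2; mu_true <- 10
  y <- rnorm(n, mu_true, sigma)
  ybar <- mean(y)
  ofv_fun <- function(mu) sum((y - mu)^2) / sigma^2
  post_sd <- sigma / sqrt(n)
  s <- sir(ofv_fun, estimate = ybar, vcov = matrix((1.5 * post_sd)^2),
           n_samples = 2000, n_resamples = 1000, seed = 13,
           param_names = "mu")
  expect_equal(s$summary$median, ybar, tolerance = 0.05 * abs(ybar))
  expect_equal(s$summary$lower, ybar - 1.96 * post_sd,
               tolerance = 0.05 * abs(ybar - 1.96 * post_sd))
  expect_equal(s$summary$upper, ybar + 1.96 * post_sd,
               tolerance = 0.05 * abs(ybar + 1.96 * post_sd))
})

test_that("SIR medians converge to the estimates as the proposal shrinks", {
  set.seed(3)
  y <- rnorm(30, 5, 1)
  ofv_fun <- function(mu) sum((y - mu)^2)
  for (scale in c(0.3, 0.03)) {
    s <- sir(ofv_fun, mean(y), matrix(scale^2), n_samples = 500,
             n_resamples = 250, seed = 4)
    expect_equal(s$summary$median, mean(y), tolerance = 3 * scale)
  }
})
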