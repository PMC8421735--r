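p4 <- table4_params()

test_that("BLQ policies M1/M3/M6 transform the dataset as specified", {
  # constructed trial-sized toy: 225 observations, 35 censored
  set.seed(2)
  n_obs <- 9
  ev <- list(); cov <- list()
  for (id in 1:25) {
    times <- seq(1, 9, length.out = n_obs)
    dv <- exp(rnorm(n_obs, log(5), 1))
    ev[[id]] <- data.frame(ID = id, TIME = c(0, times),
                           EVID = c(1L, rep(0L, n_obs)),
                           AMT = c(200, rep(NA, n_obs)),
                           RATE = c(200, rep(NA, n_obs)),
                           DV = c(NA, dv), CMT = 1L,
                           BLQ = 0L, LLOQ = 0.2)
    cov[[id]] <- data.frame(ID = id, BW = 10, ECRCL = 100, CRRT = 0L,
                            ECMO = 0L, AGE = 2, SEX = 0L)
  }
  ev <- do.call(rbind, ev)
  obs_rows <- which(ev$EVID == 0)
  flag <- sample(obs_rows, 35)
  ev$BLQ[flag] <- 1L
  ev$DV[flag] <- 0.1
  ds <- pk_dataset(ev, do.call(rbind, cov))
  expect_equal(sum(ds$events$EVID == 0), 225)

  m1 <- apply_blq(ds, "M1")
  expect_equal(sum(m1$events$EVID == 0), 190)
  m3 <- apply_blq(ds, "M3")
  expect_equal(sum(m3$events$BLQ_POLICY == "censored", na.rm = TRUE), 35)
  expect_equal(sum(m3$events$EVID == 0), 225)
  m6 <- apply_blq(ds, "M6")
  # one imputed record per subject with any BLQ; the rest dropped
  n_subj_blq <- length(unique(ev$ID[flag]))
  expect_equal(sum(m6$events$EVID == 0), 190 + n_subj_blq)
  expect_true(all(m6$events$BLQ[m6$events$EVID == 0] == 0))

  # no BLQ -> all three methods coincide
  ds0 <- pk_dataset(ev[ev$BLQ == 0 | ev$EVID == 1, ], do.call(rbind, cov))
  for (m in c("M1", "M3", "M6")) {
    expect_equal(apply_blq(ds0, m)$events$DV, ds0$events$DV)
  }
})

test_that("M6 imputes the first censored record per subject and drops the rest", {
  ev <- data.frame(ID = 1, TIME = c(0, 2, 6, 8), EVID = c(1L, 0L, 0L, 0L),
                   AMT = c(100, NA, NA, NA), RATE = c(100, NA, NA, NA),
                   DV = c(NA, 4, 0.15, 0.1), CMT = 1L,
                   BLQ = c(0L, 0L, 1L, 1L), LLOQ = 0.2)
  cov <- data.frame(ID = 1, BW = 10, ECRCL = 100, CRRT = 0L, ECMO = 0L)
  m6 <- apply_blq(pk_dataset(ev, cov), "M6")
  obs <- m6$events[m6$events$EVID == 0, ]
  expect_equal(nrow(obs), 2)
  expect_equal(obs$DV[obs$TIME == 6], 0.1)   # LLOQ/2
  expect_false(8 %in% obs$TIME)              # subsequent BLQ dropped
})

test_that("subject log-likelihood has the closed form at zero residual and uses kind-specific sigmas", {
  ds <- toy_dataset(n_subjects = 1, n_obs = 2, seed = 5)
  sub <- meropk:::compile_dataset(apply_blq(ds, "M1"))[[1]]
  # make the observation equal the model prediction
  p <- table4_params()
  pred <- meropk:::.subject_pred(sub, p,
                                 cl = typical_clearance(
                                   patient_covariates(sub$cov$bodyweight,
                                                      sub$cov$ecrcl), p),
                                 v1 = typical_volume(
                                   patient_covariates(sub$cov$bodyweight,
                                                      sub$cov$ecrcl), p))
  sub$obs_logdv <- log(pred)
  ll <- meropk:::subject_loglik(sub, p, 0, 0)
  expect_equal(ll, 2 * (-0.5 * log(2 * pi * p$sigma_plasma^2)))
  # effluent records must use sigma_effluent: swapping the labels changes it
  sub2 <- sub
  sub2$obs_kind <- c(1, 1)
  p_asym <- p; p_asym$sigma_effluent <- 1.3
  ll_pl <- meropk:::subject_loglik(sub2, p_asym, 0, 0)
  sub3 <- meropk:::compile_dataset(apply_blq(ds, "M1"))[[1]]
  expect_false(isTRUE(all.equal(ll_pl,
    -0.5 * 2 * log(2 * pi * 1.3^2) - sum((sub$obs_logdv - log(pred))^2))))
})

test_that("M3 censored contribution equals the numerically integrated censored mass", {
  p <- table4_params()
  ev <- data.frame(ID = 1, TIME = c(0, 2, 5), EVID = c(1L, 0L, 0L),
                   AMT = c(200, NA, NA), RATE = c(200, NA, NA),
                   DV = c(NA, 5, 0.1), CMT = 1L, BLQ = c(0L, 0L, 1L),
                   LLOQ = 0.2)
  cov <- data.frame(ID = 1, BW = 10, ECRCL = 90, CRRT = 0L, ECMO = 0L)
  ds <- apply_blq(pk_dataset(ev, cov), "M3")
  sub <- meropk:::compile_dataset(ds)[[1]]
  ll <- meropk:::subject_loglik(sub, p, 0.1, -0.2)
  # oracle: analytic part for the quantified record + quadrature for the
  # censored lognormal mass below LLOQ
  cl <- typical_clearance(patient_covariates(10, 90), p) * exp(0.1)
  v1 <- typical_volume(patient_covariates(10, 90), p) * exp(-0.2)
  pred <- meropk:::.subject_pred(sub, p, cl, v1)
  ll_quant <- dnorm(log(5), log(pred[1]), p$sigma_plasma, log = TRUE)
  mass <- stats::integrate(function(x)
    stats::dlnorm(x, log(pred[2]), p$sigma_plasma), 0, 0.2,
    rel.tol = 1e-12)$value
  expect_equal(ll, ll_quant + log(mass), tolerance = 1e-8)
})

test_that("degenerate IIV collapses the OFV to -2 sum of fixed-eta log-likelihoods", {
  p0 <- table4_params(); p0$omega_cl <- 0; p0$omega_v1 <- 0
  ds <- apply_blq(toy_dataset(n_subjects = 3, n_obs = 3, seed = 8), "M1")
  subs <- meropk:::compile_dataset(ds)
  direct <- -2 * sum(vapply(subs, function(s)
    meropk:::subject_loglik(s, p0, 0, 0), numeric(1)))
  expect_equal(ofv(ds, p0), direct, tolerance = 1e-10)
})

test_that("Laplace OFV agrees with Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  p <- table4_params()
  # deterministic 1-subject 2-observation toy: tight agreement
  ds1 <- apply_blq(toy_dataset(n_subjects = 1, n_obs = 2, seed = 3), "M1")
  expect_equal(ofv(ds1, p), ofv_ghq(ds1, p), tolerance = 0.1)
  # 10 randomized small datasets: within 0.5 OFV units
  for (r in 1:10) {
    ds <- apply_blq(toy_dataset(n_subjects = sample(2:5, 1),
                                n_obs = sample(2:4, 1), seed = 100 + r),
                    "M1")
    o_lap <- ofv(ds, p)
    o_ghq <- ofv_ghq(ds, p)
    expect_lt(abs(o_lap - o_ghq), 0.5)
  }
})

test_that("OFV is invariant to subject ordering and within-subject record shuffling", {
  p <- table4_params()
  coh <- sample_cohort(cohort_spec(n_subjects = 6, n_ecls = 3, n_two_step = 3, n_40mgkg = 1), seed = 31)
  ds <- apply_blq(simulate_trial(coh, p, trial_design(), seed = 32), "M1")
  ev <- ds$events
  o1 <- ofv(ds, p)
  # reverse subject blocks; keep time order within subject
  ids <- rev(unique(ev$ID))
  ev2 <- do.call(rbind, lapply(ids, function(id) ev[ev$ID == id, ]))
  ds2 <- ds; ds2$events <- ev2
  expect_equal(ofv(ds2, p), o1, tolerance = 1e-9)
})

test_that("likelihood-ratio thresholds implement the forward/backward criteria", {
  expect_true(lrt_decision(-3.85, 1, "forward"))
  expect_false(lrt_decision(-3.5, 1, "forward"))
  expect_false(lrt_decision(-3.84, 1, "forward") &&
                 -3.84 > -qchisq(0.95, 1))  # boundary just below 3.84
  # removal raising OFV by 5.466 does not meet the 10.83 backward criterion
  expect_false(lrt_decision(5.466, 1, "backward"))
  expect_true(lrt_decision(11, 1, "backward"))
  expect_error(lrt_decision(-4, 0, "forward"))
})

test_that("noiseless data identify the fixed effects to better than 1%", {
  p0 <- table4_params()
  p0$omega_cl <- 0; p0$omega_v1 <- 0
  p0$sigma_plasma <- 0.01; p0$sigma_effluent <- 0.01
  coh <- sample_cohort(cohort_spec(), seed = 3)
  ds <- apply_blq(simulate_trial(coh, p0, trial_design(), seed = 4), "M1")
  init <- table4_params()
  init$cl_typical <- 5; init$v1_typical <- 15
  init$omega_cl <- 0.2; init$omega_v1 <- 0.2
  f <- fit(ds, init = init, fixed = c("ecrcl_slope", "sc"))
  expect_lt(abs(f$params$cl_typical / 7.6 - 1), 0.01)
  expect_lt(abs(f$params$v1_typical / 21.4 - 1), 0.01)
})

test_that("refitting from the optimum is a fixed point", {
  p <- table4_params()
  coh <- sample_cohort(cohort_spec(n_subjects = 8, n_ecls = 4, n_two_step = 4, n_40mgkg = 1), seed = 21)
  ds <- apply_blq(simulate_trial(coh, p, trial_design(), seed = 22), "M6")
  f1 <- fit(ds, init = p, fixed = c("ecrcl_slope", "sc"))
  f2 <- fit(ds, init = f1$params, fixed = c("ecrcl_slope", "sc"))
  expect_lt(abs(f2$ofv - f1$ofv), 0.01)
})
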