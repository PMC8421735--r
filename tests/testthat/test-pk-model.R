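p4 <- table4_params()

test_that("clearance covariate model reproduces reference and hand-computed values", {
  expect_equal(typical_clearance(patient_covariates(12, 150), p4), 7.6)
  # BW 10, eCRCL 90, no CRRT: 7.6*(10/12)^0.75*0.79
  expect_equal(typical_clearance(patient_covariates(10, 90), p4),
               7.6 * (10 / 12)^0.75 * (1 + (90 - 150) * 0.0035),
               tolerance = 1e-12)
  expect_equal(typical_clearance(patient_covariates(10, 90), p4), 5.2367,
               tolerance = 1e-4)
  # CRRT adds SC * Flow with Flow = 0.045 L/h/kg * BW
  cl_crrt <- typical_clearance(patient_covariates(10, 30, on_crrt = TRUE), p4)
  expect_equal(cl_crrt,
               7.6 * (10 / 12)^0.75 * (1 + (30 - 150) * 0.0035) +
                 0.257 * 0.045 * 10, tolerance = 1e-12)
  expect_equal(cl_crrt, 3.96, tolerance = 0.01)
})

test_that("clearance is monotone in eCRCL and BW; CRRT adds exactly sc*Flow", {
  ecrcls <- seq(20, 250, by = 10)
  cls <- vapply(ecrcls, function(e)
    typical_clearance(patient_covariates(10, e), p4), numeric(1))
  expect_true(all(diff(cls) > 0))
  bws <- seq(3, 50, by = 1)
  clb <- vapply(bws, function(b)
    typical_clearance(patient_covariates(b, 90), p4), numeric(1))
  expect_true(all(diff(clb) > 0))
  for (bw in c(5, 12, 30)) {
    d <- typical_clearance(patient_covariates(bw, 60, on_crrt = TRUE), p4) -
      typical_clearance(patient_covariates(bw, 60, on_crrt = FALSE), p4)
    expect_equal(d, p4$sc * p4$flow_per_kg * bw, tolerance = 1e-12)
  }
})

test_that("out-of-domain covariates floor the eCRCL factor with a warning", {
  pbad <- pop_params(ecrcl_slope = 0.02)  # factor <= 0 at eCRCL 30
  expect_warning(cl <- typical_clearance(patient_covariates(10, 30), pbad),
                 "floored")
  expect_gt(cl, 0)
})

test_that("volume scales linearly with bodyweight", {
  expect_equal(typical_volume(patient_covariates(12, 150), p4), 21.4)
  expect_equal(typical_volume(patient_covariates(10, 90), p4), 21.4 * 10 / 12)
  expect_equal(typical_volume(patient_covariates(30, 90), p4), 53.5)
})

test_that("maturation factor follows age/(age + age50)", {
  expect_equal(maturation_factor(0.5, 0.5), 0.5)
  expect_equal(maturation_factor(2, 0.5), 0.8)
  expect_gt(maturation_factor(1e6, 0.5), 0.999999)
  expect_error(maturation_factor(1, 0), "age50")
})

test_that("individual parameters apply the exponential IIV model", {
  i0 <- individualize(7.6, 21.4)
  expect_equal(i0$cl, 7.6)
  expect_equal(individualize(7.6, 21.4, eta_cl = log(2))$cl, 15.2)
  expect_equal(individualize(7.6, 21.4, eta_cl = -0.5)$cl, 7.6 * exp(-0.5),
               tolerance = 1e-12)
})

test_that("regimen segments implement both infusion modes and conserve mass", {
  seg1 <- regimen_segments(dosing_regimen(20, 8, "infusion_1h"), 10)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$rate, 200)
  seg2 <- regimen_segments(dosing_regimen(20, 8, "two_step_3h"), 10)
  expect_equal(seg2$start, c(0, 0.5))
  expect_equal(seg2$end, c(0.5, 3))
  expect_equal(seg2$rate, c(200, 40))
  for (reg in list(dosing_regimen(20, 8, "infusion_1h", 5),
                   dosing_regimen(40, 8, "two_step_3h", 3),
                   dosing_regimen(35, 12, "two_step_3h", 7))) {
    for (bw in c(5, 11.5, 33)) {
      seg <- regimen_segments(reg, bw)
      expect_equal(sum(seg$rate * (seg$end - seg$start)),
                   reg$n_doses * reg$dose_per_kg * bw, tolerance = 1e-10)
    }
  }
})

test_that("closed-form concentration matches limits and the published worked case", {
  ind <- individualize(5.2367, 17.833)
  seg <- data.frame(start = 0, end = 1, rate = 200)
  expect_equal(concentration(0, seg, ind), 0)
  # end of a 1-h infusion
  expect_equal(concentration(1, seg, ind), 9.72, tolerance = 0.005)
  # constant-rate steady state -> R/CL
  seg_inf <- data.frame(start = 0, end = 1e5, rate = 200)
  expect_equal(concentration(1e4, seg_inf, ind), 200 / 5.2367,
               tolerance = 1e-9)
})

test_that("closed form agrees with adaptive ODE integration on randomized cases", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (r in 1:100) {
    cl <- runif(1, 1, 20); v1 <- runif(1, 5, 60)
    mode <- sample(c("infusion_1h", "two_step_3h"), 1)
    nd <- sample(1:3, 1)
    reg <- dosing_regimen(runif(1, 10, 45), 8, mode, nd)
    bw <- runif(1, 4, 40)
    seg <- regimen_segments(reg, bw)
    times <- sort(runif(4, 0.05, nd * 8))
    ref <- ode_conc(times, seg, cl, v1)
    got <- concentration(times, seg, list(cl = cl, v1 = v1))
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("concentration is continuous at segment boundaries and non-negative", {
  ind <- individualize(4, 20)
  seg <- regimen_segments(dosing_regimen(20, 8, "two_step_3h", 2), 10)
  eps <- 1e-9
  for (b in sort(unique(c(seg$start, seg$end)))) {
    if (b == 0) next
    expect_equal(concentration(b - eps, seg, ind),
                 concentration(b + eps, seg, ind), tolerance = 1e-6)
  }
  tt <- seq(0, 16, by = 0.05)
  expect_true(all(concentration(tt, seg, ind) >= 0))
})

test_that("analytic steady state equals many-dose superposition and is periodic", {
  cov <- patient_covariates(10, 90)
  ind <- individualize(5.2367, 17.833)
  reg <- dosing_regimen(20, 8, "infusion_1h")
  prof <- steady_state_profile(reg, cov, p4, ind)
  # worked value: end-of-infusion steady-state concentration
  expect_equal(prof$plasma_conc[prof$times == 1], 10.74, tolerance = 0.005)
  # N-dose fallback at N = 20
  seg20 <- regimen_segments(dosing_regimen(20, 8, "infusion_1h", 20), 10)
  t20 <- 19 * 8 + prof$times
  c20 <- concentration(t20, seg20, ind)
  expect_equal(prof$plasma_conc, c20, tolerance = 1e-6)
  # periodicity of the analytic solution
  expect_equal(prof$plasma_conc[1], prof$plasma_conc[length(prof$times)],
               tolerance = 1e-9)
  # tau*k >> 1: accumulation vanishes, single dose == steady state
  ind_fast <- individualize(60, 10)
  prof_fast <- steady_state_profile(reg, cov, p4, ind_fast)
  single <- concentration(prof_fast$times,
                          regimen_segments(reg, 10), ind_fast)
  expect_equal(max(abs(prof_fast$plasma_conc - single)) / max(single), 0,
               tolerance = 1e-3)
})

test_that("effluent compartment tracks SC*C1 and matches the stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  # quasi-steady state under a long constant-rate infusion: C2 -> SC * C1
  seg_inf <- data.frame(start = 0, end = 100, rate = 200)
  ind <- individualize(5, 18)
  c1 <- concentration(50, seg_inf, ind)
  c2 <- meropk:::effluent_at(50, seg_inf, ind, p4, 10)
  expect_equal(c2 / c1, p4$sc, tolerance = 1e-4)
  # SC = 0 -> identically zero
  p0 <- table4_params(); p0$sc <- 0
  expect_equal(meropk:::effluent_at(c(1, 3, 7), seg_inf, ind, p0, 10),
               c(0, 0, 0))
  # closed form vs stiff ODE on randomized cases
  set.seed(7)
  for (r in 1:10) {
    cl <- runif(1, 2, 12); v1 <- runif(1, 8, 40); bw <- runif(1, 5, 30)
    reg <- dosing_regimen(runif(1, 15, 40), 8,
                          sample(c("infusion_1h", "two_step_3h"), 1), 2)
    seg <- regimen_segments(reg, bw)
    times <- sort(runif(5, 0.2, 16))
    ref <- ode_effluent(times, seg, cl, v1, p4$sc, p4$flow_per_kg * bw, p4$v2)
    got <- meropk:::effluent_at(times, seg, list(cl = cl, v1 = v1), p4, bw)
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("steady-state effluent equals the many-dose effluent superposition", {
  ind <- individualize(4.2, 16)
  seg1 <- regimen_segments(dosing_regimen(20, 8, "two_step_3h"), 10)
  tt <- seq(0.1, 8, by = 0.5)
  ss <- meropk:::effluent_steady_state(tt, seg1, 8, ind, p4, 10)
  seg30 <- regimen_segments(dosing_regimen(20, 8, "two_step_3h", 30), 10)
  many <- meropk:::effluent_at(29 * 8 + tt, seg30, ind, p4, 10)
  expect_equal(ss, many, tolerance = 1e-6)
})

test_that("effluent_concentration requires CRRT and filters numeric profiles", {
  prof <- steady_state_profile(dosing_regimen(20), patient_covariates(10, 30),
                               p4)
  expect_error(effluent_concentration(prof, p4, 10, on_crrt = FALSE), "CRRT")
  # numeric-profile filter path approximates the closed form
  plain <- list(times = prof$times, plasma_conc = prof$plasma_conc)
  filt <- effluent_concentration(plain, p4, 10)
  exact <- effluent_concentration(prof, p4, 10)
  expect_equal(filt[-seq_len(50)], exact[-seq_len(50)], tolerance = 5e-3)
})

test_that("parameter containers validate and round-trip through config files", {
  expect_error(pop_params(sc = 1.4), "sc")
  expect_error(pop_params(cl_typical = -1))
  tmp <- tempfile(fileext = ".cfg")
  write_params(p4, tmp)
  p2 <- read_params(tmp)
  expect_equal(p2[names(p2)], p4[names(p4)], tolerance = 1e-9)
  expect_error(read_params({
    t2 <- tempfile(); writeLines("nonsense_key = 1", t2); t2
  }), "unknown parameter")
})
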