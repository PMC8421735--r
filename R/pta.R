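#' PK/PD target: fraction of the dosing interval above MIC
#'
#' @param fraction required fraction of the interval with free concentration
#'   above the MIC (0.5 or 1.0 in the study).
#' @param mic minimal inhibitory concentration, mg/L (> 0).
#' @param fu unbound drug fraction (meropenem protein binding < 2%, so 1.0 by
#'   default).
#' @return object of class `pta_target`.
#' @export
pta_target <- function(fraction, mic, fu = 1.0) {
  stopifnot(fraction > 0, fraction <= 1, mic > 0, fu > 0, fu <= 1)
  structure(list(fraction = fraction, mic = mic, fu = fu),
            class = "pta_target")
}

#' Simulation scenario
#'
#' One cell of the in-silico grid: a virtual child of given bodyweight and
#' renal function receiving a regimen.  Following the study's simulation
#' rules, scenarios with impaired renal function (eCRCL < 90 ml/min/1.73m2)
#' are simulated on CRRT (hemofilter clearance added); eCRCL 90 scenarios use
#' intrinsic clearance only.
#'
#' @param bodyweight kg.
#' @param ecrcl ml/min/1.73m2.
#' @param regimen a [dosing_regimen()].
#' @param on_crrt logical; defaults to the impaired-renal-function rule
#'   `ecrcl < 90`.
#' @return object of class `pta_scenario`.
#' @export
pta_scenario <- function(bodyweight, ecrcl, regimen, on_crrt = ecrcl < 90) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  structure(list(bodyweight = bodyweight, ecrcl = ecrcl, regimen = regimen,
                 on_crrt = on_crrt),
            class = "pta_scenario")
}

# ---- exact time-above-MIC ---------------------------------------------------
#
# At steady state the concentration on each inter-breakpoint piece is
# C(t) = A + B e^{-k t} (A = sum of active rates / CL; B collects the decay
# modes of current and prior infusions), hence monotone per piece with
# analytically solvable MIC crossings.  Vectorized over subjects.

# Time above `thresh` within one steady-state interval [0, tau].
# cl, v1: subject vectors; segments: one-dose segment table.
time_above_ss <- function(segments, tau, cl, v1, thresh) {
  stopifnot(max(segments$end) <= tau)
  k <- cl / v1
  brk <- sort(unique(c(0, segments$start, segments$end, tau)))
  gk <- 1 / (1 - exp(-k * tau))
  d_tau <- 0                                # single-dose concentration at tau
  for (j in seq_len(nrow(segments))) {
    d_tau <- d_tau + (segments$rate[j] / cl) *
      (exp(-k * (tau - segments$end[j])) - exp(-k * (tau - segments$start[j])))
  }
  t_above <- numeric(length(cl))
  for (i in seq_len(length(brk) - 1L)) {
    u0 <- brk[i]; u1 <- brk[i + 1L]
    a <- 0
    bcoef <- d_tau * gk          # steady-state tail, coefficient of e^{-k t}
    for (j in seq_len(nrow(segments))) {
      s0 <- segments$start[j]; s1 <- segments$end[j]; r <- segments$rate[j]
      if (s0 <= u0 && s1 >= u1) {          # active over this piece
        a <- a + r / cl
        bcoef <- bcoef - (r / cl) * exp(k * s0)
      } else if (s1 <= u0) {               # already ended
        bcoef <- bcoef + (r / cl) * (exp(k * s1) - exp(k * s0))
      }
    }
    c0 <- a + bcoef * exp(-k * u0)
    c1 <- a + bcoef * exp(-k * u1)
    above0 <- c0 >= thresh
    above1 <- c1 >= thresh
    piece <- numeric(length(cl))
    piece[above0 & above1] <- u1 - u0
    cross <- xor(above0, above1)
    if (any(cross)) {
      # A + B e^{-k t*} = thresh  =>  t* = -log((thresh - A)/B)/k
      aa <- if (length(a) > 1) a[cross] else rep_len(a, sum(cross))
      bb <- bcoef[cross]
      tstar <- -log((thresh - aa) / bb) / k[cross]
      tstar <- pmin(pmax(tstar, u0), u1)
      piece[cross] <- ifelse(above0[cross], tstar - u0, u1 - tstar)
    }
    t_above <- t_above + piece
  }
  t_above
}

# Steady-state concentration matrix (subjects x times) for one-dose segments.
conc_ss_matrix <- function(times, segments, tau, cl, v1) {
  k <- cl / v1
  n <- length(cl)
  d <- function(tt) {                       # single-dose, vector over subjects
    out <- numeric(n)
    for (j in seq_len(nrow(segments))) {
      if (tt > segments$start[j]) {
        out <- out + (segments$rate[j] / cl) *
          (exp(-k * max(0, tt - segments$end[j])) -
             exp(-k * (tt - segments$start[j])))
      }
    }
    out
  }
  d_tau <- d(tau)
  acc <- d_tau / (1 - exp(-k * tau))
  vapply(times, function(tt) d(tt) + acc * exp(-k * tt), numeric(n))
}

#' Fraction of the dosing interval with free concentration above MIC
#'
#' For profiles produced by [steady_state_profile()] the crossing times are
#' located analytically (the steady-state curve is piecewise
#' constant-plus-monoexponential, so each piece holds at most one crossing);
#' for plain numeric profiles, crossings are interpolated linearly between
#' grid points.
#'
#' @param profile a `concentration_profile` (or list with `times`,
#'   `plasma_conc` spanning exactly one dosing interval).
#' @param target a [pta_target()].
#' @return fraction of the interval in \[0, 1\].
#' @examples
#' p <- pop_params()
#' cov <- patient_covariates(10, 90)
#' prof <- steady_state_profile(dosing_regimen(20), cov, p)
#' fraction_time_above(prof, pta_target(0.5, mic = 2))
#' @export
fraction_time_above <- function(profile, target) {
  stopifnot(inherits(target, "pta_target"))
  thresh <- target$mic / target$fu
  if (!is.null(profile$segments)) {
    tau <- profile$tau
    return(time_above_ss(profile$segments, tau, profile$cl, profile$v1,
                         thresh) / tau)
  }
  tt <- profile$times
  cc <- profile$plasma_conc
  tau <- tt[length(tt)] - tt[1]
  above <- cc >= thresh
  t_above <- 0
  for (i in seq_len(length(tt) - 1L)) {
    dt <- tt[i + 1L] - tt[i]
    if (above[i] && above[i + 1L]) {
      t_above <- t_above + dt
    } else if (xor(above[i], above[i + 1L])) {
      frac <- (thresh - cc[i]) / (cc[i + 1L] - cc[i])
      t_above <- t_above + if (above[i]) frac * dt else (1 - frac) * dt
    }
  }
  t_above / tau
}

# Individual total clearances for a scenario: log-normal IIV on the intrinsic
# (renal + non-renal) clearance; the hemofilter clearance SC*Flow is a circuit
# property added without IIV.
.scenario_cl_v1 <- function(scn, p, eta_cl, eta_v1) {
  cov_nocrrt <- patient_covariates(scn$bodyweight, scn$ecrcl, on_crrt = FALSE)
  cl_int <- typical_clearance(cov_nocrrt, p)
  v1_typ <- typical_volume(cov_nocrrt, p)
  cl <- cl_int * exp(eta_cl)
  if (isTRUE(scn$on_crrt)) cl <- cl + p$sc * p$flow_per_kg * scn$bodyweight
  list(cl = cl, v1 = v1_typ * exp(eta_v1))
}

# Shared Monte-Carlo draws: IIV etas plus the residual-error deviate matrix
# used when ruv = TRUE.  Drawing once and reusing across scenario cells / MICs
# implements common random numbers (exact dose and MIC monotonicity).
.pta_draws <- function(p, n_subjects, seed, n_times) {
  with_seed(seed, list(
    eta_cl = stats::rnorm(n_subjects, 0, p$omega_cl),
    eta_v1 = stats::rnorm(n_subjects, 0, p$omega_v1),
    eps = matrix(stats::rnorm(n_subjects * n_times, 0, 1), n_subjects)))
}

# Per-subject fraction of the interval above `thresh` for one scenario cell.
# ruv = TRUE: stochastic-simulation convention — concentrations simulated at
# a sim_dt grid over the steady-state interval with log-additive residual
# error; fT>MIC is the fraction of simulated points above the threshold.
# ruv = FALSE: noise-free model curve with analytic crossings.
.cell_ft <- function(scn, p, draws, thresh, ruv, sim_dt) {
  ind <- .scenario_cl_v1(scn, p, draws$eta_cl, draws$eta_v1)
  reg1 <- dosing_regimen(scn$regimen$dose_per_kg, scn$regimen$interval,
                         scn$regimen$mode, 1L)
  seg <- regimen_segments(reg1, scn$bodyweight)
  tau <- scn$regimen$interval
  if (!ruv) {
    return(time_above_ss(seg, tau, ind$cl, ind$v1, thresh) / tau)
  }
  times <- seq(0, tau, by = sim_dt)
  cm <- conc_ss_matrix(times, seg, tau, ind$cl, ind$v1)
  dv <- exp(log(cm) + p$sigma_plasma * draws$eps[, seq_along(times), drop = FALSE])
  rowMeans(dv >= thresh)
}

#' Monte-Carlo probability of target attainment
#'
#' Draws a virtual population with log-normal inter-individual variability on
#' clearance and central volume and reports the percentage of subjects whose
#' steady-state fraction of the dosing interval above the MIC reaches the
#' target.  By default the simulation emulates a full stochastic simulation
#' from the model including its residual (assay) error: concentrations are
#' simulated on an hourly grid over the interval with log-additive residual
#' error and fT>MIC is the fraction of simulated points above the MIC.  Set
#' `ruv = FALSE` to evaluate noise-free model-predicted curves with analytic
#' MIC-crossing times instead.
#'
#' @param scenario a [pta_scenario()].
#' @param p a [pop_params()] object.
#' @param target a [pta_target()].
#' @param n_subjects virtual subjects (>= 100; study default 5000).
#' @param seed integer seed (required for reproducibility).
#' @param ruv include the residual-error model in the simulated
#'   concentrations (default `TRUE`).
#' @param sim_dt simulation grid step in h when `ruv = TRUE`.
#' @return object of class `pta_result`: list with `pta_percent`, `mc_se`
#'   (binomial Monte-Carlo standard error, percentage points), `n_subjects`,
#'   `seed`, `scenario`, `target`.
#' @export
simulate_pta <- function(scenario, p, target, n_subjects = 5000, seed,
                         ruv = TRUE, sim_dt = 1) {
  stopifnot(inherits(scenario, "pta_scenario"), n_subjects >= 100)
  tau <- scenario$regimen$interval
  draws <- .pta_draws(p, n_subjects, seed, length(seq(0, tau, by = sim_dt)))
  ft <- .cell_ft(scenario, p, draws, target$mic / target$fu, ruv, sim_dt)
  attained <- mean(ft >= target$fraction)
  structure(list(pta_percent = 100 * attained,
                 mc_se = 100 * sqrt(attained * (1 - attained) / n_subjects),
                 n_subjects = n_subjects, seed = seed,
                 scenario = scenario, target = target),
            class = "pta_result")
}

#' @export
print.pta_result <- function(x, ...) {
  cat(sprintf(
    "PTA %.1f%% (MC SE %.2f pp, n = %d)\n  BW %g kg, eCRCL %g%s, %g mg/kg q%gh %s, target %.0f%% fT > MIC %g mg/L\n",
    x$pta_percent, x$mc_se, x$n_subjects,
    x$scenario$bodyweight, x$scenario$ecrcl,
    if (x$scenario$on_crrt) " (CRRT)" else "",
    x$scenario$regimen$dose_per_kg, x$scenario$regimen$interval,
    x$scenario$regimen$mode, 100 * x$target$fraction, x$target$mic))
  invisible(x)
}

#' PTA as a function of MIC (common random numbers)
#'
#' Computes PTA over a doubling-dilution MIC grid using one set of subject
#' and residual-error draws for all MICs, which makes PTA exactly
#' non-increasing in MIC.
#'
#' @inheritParams simulate_pta
#' @param target_fraction required fraction of the interval (0.5 or 1.0).
#' @param mic_grid ascending positive MIC grid, mg/L; default doubling
#'   dilutions 0.125-16.
#' @param fu unbound fraction.
#' @return data.frame with columns `mic`, `pta`, `mc_se`, `n`, `seed`.
#' @export
pta_vs_mic <- function(scenario, p, target_fraction, n_subjects = 5000, seed,
                       mic_grid = 2^seq(-3, 4), fu = 1.0,
                       ruv = TRUE, sim_dt = 1) {
  stopifnot(all(mic_grid > 0), !is.unsorted(mic_grid))
  tau <- scenario$regimen$interval
  draws <- .pta_draws(p, n_subjects, seed, length(seq(0, tau, by = sim_dt)))
  pta <- vapply(mic_grid, function(mic) {
    ft <- .cell_ft(scenario, p, draws, mic / fu, ruv, sim_dt)
    100 * mean(ft >= target_fraction)
  }, numeric(1))
  data.frame(mic = mic_grid, pta = pta,
             mc_se = sqrt(pta / 100 * (1 - pta / 100) / n_subjects) * 100,
             n = n_subjects, seed = seed)
}

# canonical regimen grid in increasing order of intensity
.regimen_grid <- function(interval = 8) {
  list(
    list(dose = 20, mode = "infusion_1h", label = "20 mg/kg q8h 1 h"),
    list(dose = 20, mode = "two_step_3h", label = "20 mg/kg q8h 3 h"),
    list(dose = 40, mode = "infusion_1h", label = "40 mg/kg q8h 1 h"),
    list(dose = 40, mode = "two_step_3h", label = "40 mg/kg q8h 3 h")
  )
}

#' Scenario grid PTA tables
#'
#' Reproduces the study's PTA tables: for each bodyweight (5, 10, 20, 30 kg),
#' eCRCL (30, 60, 90 ml/min/1.73m2; CRRT added when impaired) and regimen
#' (20/40 mg/kg q8h, 1-h or two-step 3-h infusion), the PTA of the 50% and
#' 100% fT>MIC targets at the reference MIC.  One set of subject and
#' residual draws is shared across all cells (common random numbers), so
#' dose monotonicity holds exactly within a row.
#'
#' @inheritParams simulate_pta
#' @param bodyweights,ecrcls,targets,mic grid definition.
#' @param interval dosing interval, h.
#' @return long-format data.frame with columns `bodyweight`, `ecrcl`,
#'   `on_crrt`, `dose_per_kg`, `mode`, `regimen`, `target`, `mic`, `pta`,
#'   `mc_se`, `n`, `seed`.
#' @seealso [format_pta_table()], [recommend_regimen()]
#' @export
scenario_tables <- function(p, n_subjects = 5000, seed,
                            bodyweights = c(5, 10, 20, 30),
                            ecrcls = c(30, 60, 90),
                            targets = c(0.5, 1.0), mic = 2, interval = 8,
                            ruv = TRUE, sim_dt = 1) {
  draws <- .pta_draws(p, n_subjects, seed,
                      length(seq(0, interval, by = sim_dt)))
  rows <- list()
  for (bw in bodyweights) for (ec in ecrcls) {
    for (rg in .regimen_grid(interval)) {
      reg <- dosing_regimen(rg$dose, interval, rg$mode)
      scn <- pta_scenario(bw, ec, reg)
      ft <- .cell_ft(scn, p, draws, mic, ruv, sim_dt)
      for (tg in targets) {
        att <- mean(ft >= tg)
        rows[[length(rows) + 1L]] <- data.frame(
          bodyweight = bw, ecrcl = ec, on_crrt = scn$on_crrt,
          dose_per_kg = rg$dose, mode = rg$mode, regimen = rg$label,
          target = tg, mic = mic, pta = 100 * att,
          mc_se = 100 * sqrt(att * (1 - att) / n_subjects),
          n = n_subjects, seed = seed)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a PTA table in the published wide layout
#'
#' @param tables output of [scenario_tables()].
#' @param target which target fraction to format (0.5 or 1.0).
#' @return a wide data.frame: rows eCRCL x bodyweight, columns regimens.
#' @export
format_pta_table <- function(tables, target) {
  sub <- tables[tables$target == target, ]
  regs <- unique(sub$regimen)
  rows <- list()
  for (ec in unique(sub$ecrcl)) for (bw in unique(sub$bodyweight)) {
    cell <- sub[sub$ecrcl == ec & sub$bodyweight == bw, ]
    vals <- vapply(regs, function(r) cell$pta[cell$regimen == r], numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      ecrcl = ec, bodyweight = bw, t(round(vals, 1)), check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out) <- c("ecrcl", "bodyweight", regs)
  rownames(out) <- NULL
  out
}

#' Dosing-regimen recommendation
#'
#' For each scenario cell, the least-intensive regimen (ordered 20 mg/kg 1 h <
#' 20 mg/kg 3 h < 40 mg/kg 1 h < 40 mg/kg 3 h) whose PTA strictly exceeds the
#' threshold.
#'
#' @param tables output of [scenario_tables()].
#' @param pta_threshold percentage threshold (default 70, the study's rule).
#' @return data.frame with one row per (target, mic, ecrcl, bodyweight) cell:
#'   the recommended regimen label (`NA` if none attains the threshold) and
#'   its PTA.
#' @export
recommend_regimen <- function(tables, pta_threshold = 70) {
  order_labels <- vapply(.regimen_grid(), `[[`, "", "label")
  keys <- unique(tables[c("target", "mic", "ecrcl", "bodyweight")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    kk <- keys[i, ]
    cell <- tables[tables$target == kk$target & tables$mic == kk$mic &
                     tables$ecrcl == kk$ecrcl &
                     tables$bodyweight == kk$bodyweight, ]
    cell <- cell[match(order_labels, cell$regimen), ]
    cell <- cell[!is.na(cell$pta), , drop = FALSE]
    hit <- which(cell$pta > pta_threshold)
    rows[[i]] <- data.frame(
      kk,
      recommended = if (length(hit)) cell$regimen[hit[1]] else NA_character_,
      pta = if (length(hit)) cell$pta[hit[1]] else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
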