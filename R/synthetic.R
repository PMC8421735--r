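#' Bedside Schwartz estimated creatinine clearance
#'
#' `eCRCL = k * height / SCr`, with serum creatinine converted from umol/L to
#' mg/dL (factor 88.4) and `k` the Schwartz constant (0.413 for the bedside
#' formula; configurable since the constant used in any given clinical
#' dataset may differ).
#'
#' @param height_cm height in cm.
#' @param scr_umol serum creatinine in umol/L.
#' @param k Schwartz constant.
#' @return eCRCL in ml/min/1.73m2.
#' @export
schwartz_ecrcl <- function(height_cm, scr_umol, k = 0.413) {
  stopifnot(all(height_cm > 0), all(scr_umol > 0), k >= 0)
  k * height_cm / (scr_umol / 88.4)
}

#' Virtual cohort specification
#'
#' Distributional description of the study population used by
#' [sample_cohort()]: 25 septic children, 13 on extracorporeal life support
#' (ECLS), body size log-normal around a median bodyweight of 11.5 kg with
#' correlated height and age through a shared latent size factor, and serum
#' creatinine log-normal by ECLS stratum (ECLS children have markedly higher
#' creatinine, hence lower eCRCL).  Log-scale SDs are matched to the
#' reported interquartile ranges.
#'
#' @param n_subjects cohort size.
#' @param n_ecls subjects on ECLS.
#' @param fraction_crrt_among_ecls fraction of ECLS subjects on CRRT.
#' @param bw_median,bw_sdlog bodyweight distribution (kg).
#' @param height_median,height_sdlog height distribution (cm).
#' @param age_median,age_sdlog age distribution (years).
#' @param scr_median_ecls,scr_median_non,scr_sdlog_ecls,scr_sdlog_non serum
#'   creatinine by stratum (umol/L).
#' @param size_loading correlation loading of log BW/height/age on the shared
#'   latent size factor.
#' @param n_40mgkg subjects assigned the 40 mg/kg dose (the rest get
#'   20 mg/kg).
#' @param n_two_step subjects assigned the two-step 3-h infusion (the rest
#'   get the 1-h infusion).
#' @param schwartz_k Schwartz constant for [schwartz_ecrcl()].
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 25, n_ecls = 13,
                        fraction_crrt_among_ecls = 9 / 13,
                        bw_median = 11.5, bw_sdlog = 0.70,
                        height_median = 82, height_sdlog = 0.25,
                        age_median = 2.0, age_sdlog = 0.95,
                        scr_median_ecls = 46, scr_sdlog_ecls = 1.0,
                        scr_median_non = 20, scr_sdlog_non = 0.45,
                        size_loading = 0.85,
                        n_40mgkg = 3, n_two_step = 12,
                        schwartz_k = 0.413) {
  stopifnot(n_ecls <= n_subjects, n_40mgkg <= n_subjects,
            n_two_step <= n_subjects,
            fraction_crrt_among_ecls >= 0, fraction_crrt_among_ecls <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Sample a virtual cohort
#'
#' Draws per-subject covariates reproducibly: bodyweight, height and age from
#' correlated log-normals (shared latent size factor), serum creatinine by
#' ECLS stratum, eCRCL derived mechanistically from height and creatinine via
#' [schwartz_ecrcl()] (not drawn directly), sex balanced, and dose/infusion
#' assignments per the specification.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return data.frame with one row per subject: `ID`, `BW`, `HT`, `AGE`,
#'   `SEX` (0/1), `SCR`, `ECRCL`, `ECLS`, `CRRT`, `ECMO`, `DOSE_PER_KG`,
#'   `MODE`, plus placeholder lab covariates (`ALB`, `GLB`, `WAZ`, `LIZ`,
#'   `VANC`) drawn from neutral distributions for covariate-screen testing.
#' @export
sample_cohort <- function(spec = cohort_spec(), seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n_subjects
    ecls <- c(rep(TRUE, spec$n_ecls), rep(FALSE, n - spec$n_ecls))
    z_size <- stats::rnorm(n)
    lo <- spec$size_loading
    mix <- function(sdlog) sdlog * (lo * z_size +
                                      sqrt(1 - lo^2) * stats::rnorm(n))
    bw <- exp(log(spec$bw_median) + mix(spec$bw_sdlog))
    ht <- exp(log(spec$height_median) + mix(spec$height_sdlog))
    age <- exp(log(spec$age_median) + mix(spec$age_sdlog))
    scr <- ifelse(ecls,
                  exp(log(spec$scr_median_ecls) +
                        spec$scr_sdlog_ecls * stats::rnorm(n)),
                  exp(log(spec$scr_median_non) +
                        spec$scr_sdlog_non * stats::rnorm(n)))
    ecrcl <- schwartz_ecrcl(ht, scr, spec$schwartz_k)
    n_crrt <- round(spec$fraction_crrt_among_ecls * spec$n_ecls)
    crrt <- ecls & seq_len(n) %in% sample(which(ecls), n_crrt)
    dose <- rep(20, n)
    dose[sample.int(n, spec$n_40mgkg)] <- 40
    mode <- rep("infusion_1h", n)
    mode[sample.int(n, spec$n_two_step)] <- "two_step_3h"
    data.frame(
      ID = seq_len(n), BW = bw, HT = ht, AGE = age,
      SEX = stats::rbinom(n, 1, 0.48), SCR = scr, ECRCL = ecrcl,
      ECLS = as.integer(ecls), CRRT = as.integer(crrt),
      ECMO = as.integer(ecls),
      DOSE_PER_KG = dose, MODE = mode,
      ALB = stats::rnorm(n, 35.2, 6.8), GLB = stats::rnorm(n, 23.5, 6.3),
      WAZ = stats::rnorm(n, 0.04, 1.6),
      LIZ = stats::rbinom(n, 1, 0.3), VANC = stats::rbinom(n, 1, 0.3))
  })
}

#' Trial sampling design
#'
#' Intensive sampling after at least five doses: for children <= 30 kg,
#' samples at pre-dose and 5, 45, 90, 180, 360, 480 min after the end of
#' infusion; for children > 30 kg, pre-dose and 5, 15, 30, 60, 90, 120, 240,
#' 360, 480 min after the end of infusion.  CRRT subjects additionally have
#' effluent sampled at the same nominal times (excluding pre-dose).
#'
#' @param lloq lower limit of quantification, mg/L.
#' @param n_doses doses given before the sampled (terminal) interval.
#' @param schedule_light,schedule_heavy minutes after end of infusion for the
#'   two bodyweight strata.
#' @param heavy_cutoff_kg bodyweight cutoff between strata.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(lloq = 0.2, n_doses = 5L,
                         schedule_light = c(5, 45, 90, 180, 360, 480),
                         schedule_heavy = c(5, 15, 30, 60, 90, 120, 240, 360, 480),
                         heavy_cutoff_kg = 30) {
  stopifnot(lloq > 0, n_doses >= 1, length(schedule_light) > 0,
            length(schedule_heavy) > 0)
  structure(list(lloq = lloq, n_doses = as.integer(n_doses),
                 schedule_light = schedule_light,
                 schedule_heavy = schedule_heavy,
                 heavy_cutoff_kg = heavy_cutoff_kg),
            class = "trial_design")
}

#' Simulate a PK trial from a virtual cohort
#'
#' For each subject: draws log-normal random effects, builds the dose events
#' of the assigned regimen, evaluates plasma (and, for CRRT subjects,
#' effluent) concentrations at the design times around the final dose, adds
#' log-additive residual error with the record-kind sigma, and flags
#' observations below the LLOQ (value stored as measured, `BLQ = 1`).
#' The pre-dose sample is the trough of the interval preceding the final
#' dose.
#'
#' @param cohort a [sample_cohort()] data.frame.
#' @param p a [pop_params()] object (simulation truth).
#' @param design a [trial_design()].
#' @param seed integer seed.
#' @param effects optional list of [covariate_effect()]s (with explicit
#'   `ref` and `beta`) planted on top of the base model, for
#'   covariate-screen recovery experiments.
#' @return a validated [pk_dataset()].
#' @export
simulate_trial <- function(cohort, p, design = trial_design(), seed,
                           effects = list()) {
  stopifnot(inherits(design, "trial_design"))
  for (e in effects) {
    if (is.na(e$ref)) stop("planted covariate effects need an explicit ref")
  }
  rows <- with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(cohort))) {
      s <- cohort[i, ]
      eta_cl <- stats::rnorm(1, 0, p$omega_cl)
      eta_v1 <- stats::rnorm(1, 0, p$omega_v1)
      cov <- patient_covariates(s$BW, s$ECRCL, on_crrt = s$CRRT == 1)
      cl_int <- typical_clearance(
        patient_covariates(s$BW, s$ECRCL, on_crrt = FALSE), p)
      v1_typ <- typical_volume(cov, p)
      for (e in effects) {
        f <- .effect_factor(e, s[[e$covariate]])
        if (e$param == "cl") cl_int <- cl_int * f else v1_typ <- v1_typ * f
      }
      cl <- cl_int * exp(eta_cl) +
        if (s$CRRT == 1) p$sc * p$flow_per_kg * s$BW else 0
      v1 <- v1_typ * exp(eta_v1)
      reg <- dosing_regimen(s$DOSE_PER_KG, 8, s$MODE, design$n_doses)
      seg <- regimen_segments(reg, s$BW)
      last_dose <- (design$n_doses - 1L) * reg$interval
      inf_end <- max(seg$end) # end of final infusion
      sched <- if (s$BW > design$heavy_cutoff_kg) design$schedule_heavy
               else design$schedule_light
      times <- c(last_dose, inf_end + sched / 60)  # pre-dose trough + samples
      pred_pl <- concentration(times, seg, list(cl = cl, v1 = v1))
      dv_pl <- exp(log(pmax(pred_pl, 1e-12)) +
                     stats::rnorm(length(times), 0, p$sigma_plasma))
      ev <- data.frame(
        ID = s$ID,
        TIME = c(seg$start, times),
        EVID = c(rep(1L, nrow(seg)), rep(0L, length(times))),
        AMT = c(seg$rate * (seg$end - seg$start), rep(NA_real_, length(times))),
        RATE = c(seg$rate, rep(NA_real_, length(times))),
        DV = c(rep(NA_real_, nrow(seg)), dv_pl),
        CMT = c(rep(1L, nrow(seg)), rep(1L, length(times))),
        BLQ = c(rep(0L, nrow(seg)), as.integer(dv_pl < design$lloq)),
        LLOQ = design$lloq)
      if (s$CRRT == 1) {
        e_times <- inf_end + sched / 60
        pred_ef <- effluent_at(e_times, seg, list(cl = cl, v1 = v1), p, s$BW)
        dv_ef <- exp(log(pmax(pred_ef, 1e-12)) +
                       stats::rnorm(length(e_times), 0, p$sigma_effluent))
        ev <- rbind(ev, data.frame(
          ID = s$ID, TIME = e_times, EVID = 0L, AMT = NA_real_,
          RATE = NA_real_, DV = dv_ef, CMT = 2L,
          BLQ = as.integer(dv_ef < design$lloq), LLOQ = design$lloq))
      }
      out[[i]] <- ev[order(ev$TIME, -ev$EVID), ]
    }
    out
  })
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  cov_cols <- c("ID", "BW", "ECRCL", "CRRT", "ECMO", "AGE", "SEX",
                "HT", "WAZ", "ALB", "GLB", "LIZ", "VANC")
  pk_dataset(events, cohort[intersect(cov_cols, names(cohort))])
}
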