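# ---- compiled per-subject structures ---------------------------------------
#
# The estimation code flattens the event table once into plain vectors per
# subject; everything downstream works on these.

compile_dataset <- function(ds) {
  stopifnot(inherits(ds, "pk_dataset"))
  ev <- ds$events
  if (is.null(ev$BLQ_POLICY)) {
    ev$BLQ_POLICY <- ifelse(ev$EVID == 0, "obs", NA_character_)
    if (any(ev$EVID == 0 & ev$BLQ == 1))
      stop("dataset has unhandled BLQ records; call apply_blq() first")
  }
  ids <- unique(ev$ID)
  subjects <- lapply(ids, function(id) {
    sub <- ev[ev$ID == id, , drop = FALSE]
    dose <- sub[sub$EVID == 1, , drop = FALSE]
    obs <- sub[sub$EVID == 0, , drop = FALSE]
    cr <- ds$covariates[ds$covariates$ID == id, , drop = FALSE]
    labs <- as.list(cr[setdiff(names(cr), c("ID", "BW", "ECRCL", "CRRT",
                                            "ECMO", "AGE", "SEX"))])
    s0 <- dose$TIME
    s1 <- dose$TIME + dose$AMT / dose$RATE
    is_pl <- obs$CMT == 1
    t_pl <- obs$TIME[is_pl]
    t_ef <- obs$TIME[!is_pl]
    csub <- list(
      id = id,
      seg_start = s0, seg_end = s1, seg_rate = dose$RATE,
      obs_time = obs$TIME,
      obs_logdv = ifelse(obs$BLQ_POLICY == "censored", NA_real_, log(obs$DV)),
      obs_kind = obs$CMT,
      censored = obs$BLQ_POLICY == "censored",
      lloq = obs$LLOQ,
      idx_pl = which(is_pl), idx_ef = which(!is_pl),
      # precomputed time-offset matrices (obs x segments) for fast prediction
      pl_d0 = pmax(outer(t_pl, s0, "-"), 0),
      pl_d1 = pmax(outer(t_pl, s1, "-"), 0),
      pl_on = outer(t_pl, s0, "-") > 0,
      ef_u = outer(t_ef, s0, "-"),      # time since segment start
      ef_v = outer(t_ef, s1, "-"),      # time since segment end
      ef_u1 = s1 - s0,
      cov = c(list(bodyweight = cr$BW, ecrcl = cr$ECRCL,
                   on_crrt = cr$CRRT == 1, on_ecmo = cr$ECMO == 1,
                   age = if ("AGE" %in% names(cr)) cr$AGE else NA_real_,
                   sex = if ("SEX" %in% names(cr)) cr$SEX else NA),
              labs))
    csub
  })
  names(subjects) <- as.character(ids)
  subjects
}

# (e^{-k x} - e^{-lam x})/(lam - k) elementwise, with the lam -> k limit
.ratio_mat <- function(k, lam, x) {
  if (abs(lam - k) < 1e-9 * max(lam, k)) x * exp(-k * x)
  else (exp(-k * x) - exp(-lam * x)) / (lam - k)
}

# model predictions (natural scale) for one compiled subject at scalar cl, v1
.subject_pred <- function(csub, p, cl, v1) {
  k <- cl / v1
  rc <- csub$seg_rate / cl
  pred <- numeric(length(csub$obs_time))
  if (length(csub$idx_pl)) {
    m <- (exp(-k * csub$pl_d1) - exp(-k * csub$pl_d0)) * csub$pl_on
    pred[csub$idx_pl] <- as.vector(m %*% rc)
  }
  if (length(csub$idx_ef)) {
    lam <- p$flow_per_kg * csub$cov$bodyweight / p$v2
    u <- csub$ef_u; v <- csub$ef_v; u1 <- csub$ef_u1
    act <- u > 0 & v <= 0
    post <- v > 0
    m <- matrix(0, nrow(u), ncol(u))
    if (any(act)) {
      m[act] <- (1 - exp(-lam * u[act])) - lam * .ratio_mat(k, lam, u[act])
    }
    if (any(post)) {
      e1 <- (1 - exp(-lam * u1)) - lam * .ratio_mat(k, lam, u1)  # per segment
      f1 <- 1 - exp(-k * u1)
      e1m <- matrix(e1, nrow(u), ncol(u), byrow = TRUE)
      f1m <- matrix(f1, nrow(u), ncol(u), byrow = TRUE)
      m[post] <- exp(-lam * v[post]) * e1m[post] +
        lam * f1m[post] * .ratio_mat(k, lam, v[post])
    }
    pred[csub$idx_ef] <- p$sc * as.vector(m %*% rc)
  }
  pred
}

# ---- covariate-effect machinery (screening) --------------------------------

#' Covariate effect specification
#'
#' Describes one parameter-covariate relation for the stepwise screen.
#' Functional forms (centered at `ref`, by default the dataset median):
#' linear `1 + beta*(cov - ref)`, power `(cov/ref)^beta`, exponential
#' `exp(beta*(cov - ref))`.
#'
#' @param param `"cl"` or `"v1"`.
#' @param covariate covariate column name in the covariate table (e.g.
#'   `"ECRCL"`, `"ALB"`, `"LIZ"`).
#' @param form `"linear"`, `"power"` or `"exponential"`.
#' @param ref centering value; `NA` = dataset median.
#' @return list of class `covariate_effect`.
#' @export
covariate_effect <- function(param = c("cl", "v1"), covariate,
                             form = c("linear", "power", "exponential"),
                             ref = NA_real_) {
  structure(list(param = match.arg(param), covariate = covariate,
                 form = match.arg(form), ref = ref, beta = 0),
            class = "covariate_effect")
}

.effect_factor <- function(eff, value) {
  switch(eff$form,
    linear = max(1 + eff$beta * (value - eff$ref), .COV_FACTOR_FLOOR),
    power = (value / eff$ref)^eff$beta,
    exponential = exp(eff$beta * (value - eff$ref)))
}

.effect_ref <- function(eff, ds) {
  if (!is.na(eff$ref)) return(eff$ref)
  v <- ds$covariates[[eff$covariate]]
  if (is.null(v)) stop("unknown covariate: ", eff$covariate)
  stats::median(v, na.rm = TRUE)
}

# typical cl/v1 for one compiled subject under params + extra effects
.subject_typicals <- function(csub, p, effects) {
  cov <- csub$cov
  fac <- 1 + (cov$ecrcl - p$ecrcl_ref) * p$ecrcl_slope
  fac <- max(fac, .COV_FACTOR_FLOOR)
  cl <- p$cl_typical * (cov$bodyweight / p$bw_ref)^0.75 * fac
  v1 <- p$v1_typical * (cov$bodyweight / p$bw_ref)
  if (!is.na(p$age50) && !is.na(cov$age)) {
    cl <- cl * maturation_factor(cov$age, p$age50)
  }
  for (eff in effects) {
    value <- cov[[tolower(eff$covariate)]] %||% cov[[eff$covariate]]
    if (is.null(value) || is.na(value)) next
    f <- .effect_factor(eff, value)
    if (eff$param == "cl") cl <- cl * f else v1 <- v1 * f
  }
  list(cl_int = cl, v1 = v1,
       cl_crrt = if (isTRUE(cov$on_crrt)) p$sc * p$flow_per_kg * cov$bodyweight else 0)
}

# ---- subject log-likelihood -------------------------------------------------

#' Subject log-likelihood at fixed random effects
#'
#' Residual model: additive normal error on natural-log concentrations with
#' separate SDs for plasma and effluent records.  Quantified observations
#' contribute the normal log-density of `log(DV)` around `log(pred)`;
#' M3-censored observations contribute the censored-normal mass
#' `log Phi((log LLOQ - log pred)/sigma)`.
#'
#' @param csub one compiled subject (internal structure; see [ofv()] for the
#'   dataset-level entry point).
#' @param p a [pop_params()] object.
#' @param eta_cl,eta_v1 random effects (log scale).
#' @param effects list of [covariate_effect()]s beyond the base model.
#' @return the log-likelihood (numeric scalar; `-Inf` for inadmissible
#'   predictions).
#' @keywords internal
subject_loglik <- function(csub, p, eta_cl = 0, eta_v1 = 0, effects = list()) {
  typ <- .subject_typicals(csub, p, effects)
  cl <- typ$cl_int * exp(eta_cl) + typ$cl_crrt
  v1 <- typ$v1 * exp(eta_v1)
  if (!is.finite(cl) || !is.finite(v1) || cl <= 0 || v1 <= 0) return(-Inf)
  pred <- .subject_pred(csub, p, cl, v1)
  if (any(pred <= 0)) return(-Inf)  # model/data incompatibility (e.g. pre-input obs)
  sig <- ifelse(csub$obs_kind == 1, p$sigma_plasma, p$sigma_effluent)
  ll <- 0
  qn <- !csub$censored
  if (any(qn)) {
    ll <- ll + sum(stats::dnorm(csub$obs_logdv[qn], log(pred[qn]), sig[qn],
                                log = TRUE))
  }
  if (any(!qn)) {
    z <- (log(csub$lloq[!qn]) - log(pred[!qn])) / sig[!qn]
    ll <- ll + sum(stats::pnorm(z, log.p = TRUE))
  }
  ll
}

# ---- Laplace marginal likelihood (FOCE-I style mode expansion) --------------

# negative joint density in eta for one subject
.neg_joint <- function(eta, csub, p, effects, omega, active) {
  full <- c(0, 0)
  full[active] <- eta
  ll <- subject_loglik(csub, p, full[1], full[2], effects)
  if (!is.finite(ll)) return(1e10)
  -(ll + sum(stats::dnorm(eta, 0, omega[active], log = TRUE)))
}

# Deterministic damped-Newton minimizer with finite-difference stencils,
# for the 1- or 2-dimensional inner eta problem.  Returns the mode, the
# objective there, and the Hessian of the final stencil (reused by the
# Laplace approximation).
.inner_newton <- function(fn, start, h = 1e-4, tol_g = 1e-7, max_iter = 50) {
  d <- length(start)
  x <- start
  f0 <- fn(x)
  if (!is.finite(f0)) { x <- rep(0, d); f0 <- fn(x) }
  grad <- rep(Inf, d)
  hess <- diag(1, d)
  for (iter in seq_len(max_iter)) {
    fp <- fm <- numeric(d)
    for (i in seq_len(d)) {
      ei <- rep(0, d); ei[i] <- h
      fp[i] <- fn(x + ei); fm[i] <- fn(x - ei)
    }
    grad <- (fp - fm) / (2 * h)
    hess <- diag((fp + fm - 2 * f0) / h^2, d)
    if (d == 2) {
      hess[1, 2] <- hess[2, 1] <-
        (fn(x + c(h, h)) - fn(x + c(h, -h)) -
           fn(x + c(-h, h)) + fn(x + c(-h, -h))) / (4 * h^2)
    }
    if (max(abs(grad)) < tol_g) break
    hreg <- hess
    mineig <- if (d == 1) hreg[1, 1] else {
      tr <- hreg[1, 1] + hreg[2, 2]
      dt <- hreg[1, 1] * hreg[2, 2] - hreg[1, 2]^2
      (tr - sqrt(max(tr^2 - 4 * dt, 0))) / 2
    }
    if (!is.finite(mineig) || mineig <= 1e-8) {
      hreg <- hreg + diag(abs(mineig) + 0.1, d)
    }
    step <- -solve(hreg, grad)
    lam <- 1
    repeat {
      f1 <- fn(x + lam * step)
      if (is.finite(f1) && f1 <= f0 - 1e-4 * lam * sum(grad * step) + 1e-12)
        break
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) break
    x <- x + lam * step
    f0 <- fn(x)
  }
  list(par = x, objective = f0, hessian = hess, grad = grad)
}

# Laplace-approximate -2 log marginal likelihood contribution of one subject;
# returns list(ofv_i, eta) with the conditional mode.
.subject_laplace <- function(csub, p, effects, eta_start = c(0, 0)) {
  omega <- c(p$omega_cl, p$omega_v1)
  active <- which(omega > 1e-6)
  if (!length(active)) {
    ll <- subject_loglik(csub, p, 0, 0, effects)
    return(list(ofv_i = -2 * ll, eta = c(0, 0)))
  }
  fn <- function(e) .neg_joint(e, csub, p, effects, omega, active)
  opt <- .inner_newton(fn, eta_start[active])
  d <- length(active)
  det_h <- det(as.matrix(opt$hessian))
  eta_full <- c(0, 0)
  eta_full[active] <- opt$par
  if (!is.finite(det_h) || det_h <= 0) {
    return(list(ofv_i = Inf, eta = eta_full))
  }
  log_marg <- -opt$objective + (d / 2) * log(2 * pi) - 0.5 * log(det_h)
  list(ofv_i = -2 * log_marg, eta = eta_full)
}

#' Objective function value (-2 log marginal likelihood)
#'
#' Marginalizes the subject likelihood over the log-normal random effects on
#' CL and V1 by Laplace expansion about each subject's conditional mode (the
#' FOCE-I-style conditional estimation used throughout model building; with
#' a log-additive residual error the eta-epsilon interaction is carried by
#' the prediction entering the residual on the log scale).  An adaptive
#' Gauss-Hermite quadrature oracle arbitrates its accuracy in the test suite.
#'
#' @param ds a [pk_dataset()] (pass through [apply_blq()] first if it
#'   contains censored records).
#' @param p a [pop_params()] object.
#' @param effects list of [covariate_effect()]s beyond the base model.
#' @param approx likelihood approximation label; both map to the same
#'   conditional mode expansion (with a log-additive residual error the
#'   FOCE-I interaction term is carried by the prediction itself).
#' @param eta_cache optional environment carrying warm-start modes (internal).
#' @return the OFV (numeric). Infinite if any subject's inner mode search
#'   fails.
#' @export
ofv <- function(ds, p, effects = list(), approx = c("laplace", "foce_i"),
                eta_cache = NULL) {
  approx <- match.arg(approx)
  subjects <- if (is.list(ds) && is.null(ds$events)) ds else compile_dataset(ds)
  total <- 0
  for (nm in names(subjects)) {
    start <- if (!is.null(eta_cache) && !is.null(eta_cache[[nm]]))
      eta_cache[[nm]] else c(0, 0)
    res <- .subject_laplace(subjects[[nm]], p, effects, start)
    if (!is.null(eta_cache)) eta_cache[[nm]] <- res$eta
    total <- total + res$ofv_i
    if (!is.finite(total)) return(Inf)
  }
  total
}

# ---- parameter transforms for the outer optimizer ---------------------------

.FIT_PARS <- c("cl_typical", "v1_typical", "ecrcl_slope", "sc",
               "omega_cl", "omega_v1", "sigma_plasma", "sigma_effluent")

.to_trans <- function(name, value) {
  switch(name,
    ecrcl_slope = value * 100,
    sc = stats::qlogis(min(max(value, 1e-6), 1 - 1e-6)),
    log(max(value, 1e-12)))
}

.from_trans <- function(name, value) {
  switch(name,
    ecrcl_slope = value / 100,
    sc = stats::plogis(value),
    exp(value))
}

#' Population model fit by Laplacian estimation
#'
#' Minimizes the [ofv()] over the non-frozen fixed effects, IIV and residual
#' SDs (positivity enforced by log/logit transforms), returning empirical
#' Bayes eta estimates at the optimum.  The CRRT circuit constants
#' (`flow_per_kg`, `v2`) are frozen by default, as they are set by the CRRT
#' configuration rather than estimated.
#'
#' @param ds a [pk_dataset()]; censored records must have been resolved by
#'   [apply_blq()] (any method).
#' @param init initial [pop_params()]; see [initial_estimates()] for a
#'   data-driven heuristic.
#' @param fixed names of parameters to freeze at their `init` values
#'   (in addition to `flow_per_kg`, `v2`, `ecrcl_ref`, `bw_ref`, `age50`,
#'   which are always frozen).
#' @param effects list of [covariate_effect()]s whose coefficients are
#'   estimated alongside.
#' @param error_model `"two_sigma"` (separate plasma/effluent residual SDs,
#'   the final model) or `"one_sigma"` (shared SD, the base model).
#' @param n_starts number of optimizer starts; starts beyond the first jitter
#'   the transformed initials (the OFV surface proved unimodal for this model
#'   class in testing, so 1 is the default).
#' @param polish follow the quasi-Newton stage with Nelder-Mead escape
#'   rounds; rarely needed now that the quasi-Newton stage uses explicit
#'   central-difference gradients (default off).
#' @param control passed to [stats::nlminb()].
#' @return object of class `estimation_result`: `params` (fitted
#'   [pop_params()]), `effects` (with fitted `beta`s), `ofv`, `ebes`
#'   (subjects x 2 matrix), `converged`, `n_obs_used`, and internals used by
#'   [sir_from_fit()].
#' @export
fit <- function(ds, init = initial_estimates(ds), fixed = character(),
                effects = list(), error_model = c("two_sigma", "one_sigma"),
                n_starts = 1, polish = FALSE,
                control = list(rel.tol = 1e-8)) {
  error_model <- match.arg(error_model)
  subjects <- compile_dataset(ds)
  has_effl <- any(vapply(subjects, function(s) any(s$obs_kind == 2), TRUE))
  est_names <- setdiff(.FIT_PARS, fixed)
  if (error_model == "one_sigma") est_names <- setdiff(est_names, "sigma_effluent")
  if (!has_effl) est_names <- setdiff(est_names, c("sigma_effluent", "sc"))
  effects <- lapply(effects, function(e) {
    e$ref <- .effect_ref(e, ds)
    if (is.null(e$scale)) {
      v <- ds$covariates[[e$covariate]]
      e$scale <- max(stats::sd(v, na.rm = TRUE), 1e-8)
    }
    e
  })
  n_beta <- length(effects)
  # covariate coefficients are optimized on a per-SD scale so that all
  # outer parameters share comparable curvature
  par0 <- c(vapply(est_names, function(nm) .to_trans(nm, init[[nm]]),
                   numeric(1)),
            vapply(effects, function(e) e$beta * e$scale, numeric(1)))

  build <- function(par) {
    p <- init
    for (i in seq_along(est_names)) {
      p[[est_names[i]]] <- .from_trans(est_names[i], par[i])
    }
    if (error_model == "one_sigma") p$sigma_effluent <- p$sigma_plasma
    eff <- effects
    if (n_beta) {
      for (j in seq_len(n_beta)) {
        eff[[j]]$beta <- par[length(est_names) + j] / eff[[j]]$scale
      }
    }
    list(p = p, effects = eff)
  }

  cache <- new.env(parent = emptyenv())
  obj <- function(par) {
    b <- build(par)
    ofv(subjects, b$p, b$effects, eta_cache = cache)
  }
  # central-difference gradient: more reliable than the optimizer-internal
  # forward differences on this objective
  grad <- function(par, h = 1e-4) {
    vapply(seq_along(par), function(i) {
      ei <- rep(0, length(par)); ei[i] <- h
      (obj(par + ei) - obj(par - ei)) / (2 * h)
    }, numeric(1))
  }

  best <- NULL
  starts <- list(par0)
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- par0 + stats::rnorm(length(par0), 0, 0.3)
    }
  }
  for (st in starts) {
    opt <- stats::nlminb(st, obj, gradient = grad, control = control)
    # premature gradient-test stops happen on this objective; a short
    # Nelder-Mead round detects and escapes them, then nlminb re-polishes
    for (round in 1:3) {
      if (!polish || length(opt$par) < 2) break
      nm <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 250, reltol = 1e-8))
      if (nm$value < opt$objective - 0.1) {
        opt2 <- stats::nlminb(nm$par, obj, gradient = grad, control = control)
        opt <- if (opt2$objective < nm$value)
          opt2 else list(par = nm$par, objective = nm$value,
                         convergence = 0, message = "Nelder-Mead optimum")
      } else {
        if (nm$value < opt$objective) {
          opt <- list(par = nm$par, objective = nm$value, convergence = 0,
                      message = "Nelder-Mead optimum")
        }
        break
      }
    }
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  b <- build(best$par)
  final_ofv <- ofv(subjects, b$p, b$effects, eta_cache = cache)
  ebes <- do.call(rbind, lapply(names(subjects), function(nm) cache[[nm]]))
  dimnames(ebes) <- list(names(subjects), c("eta_cl", "eta_v1"))
  # nlminb's "false/singular convergence" codes flag failed gradient tests on
  # a noisy objective (the inner Laplace modes are themselves iterative);
  # treat a finite optimum at such a stop as converged, as the fixed-point
  # property test verifies stability of the optimum directly.
  ok_msg <- best$convergence == 0 ||
    grepl("relative convergence|false convergence|singular convergence",
          best$message %||% "")
  structure(list(
    params = b$p, effects = b$effects, ofv = final_ofv, ebes = ebes,
    converged = ok_msg && is.finite(final_ofv),
    optimizer_message = best$message,
    n_obs_used = sum(vapply(subjects, function(s) length(s$obs_time), 0L)),
    est_names = est_names, par = best$par, error_model = error_model,
    init = init, subjects = subjects
  ), class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("Population PK fit: OFV %.3f (%sconverged, %d observations)\n",
              x$ofv, if (x$converged) "" else "NOT ", x$n_obs_used))
  cat(sprintf("  CL %.3f L/h, V1 %.3f L, eCRCL slope %.3g, SC %.3f\n",
              x$params$cl_typical, x$params$v1_typical,
              x$params$ecrcl_slope, x$params$sc))
  cat(sprintf("  omega: %.3f / %.3f; sigma: %.3f / %.3f\n",
              x$params$omega_cl, x$params$omega_v1,
              x$params$sigma_plasma, x$params$sigma_effluent))
  for (e in x$effects) {
    cat(sprintf("  effect %s-%s (%s, ref %.3g): beta %.4g\n",
                toupper(e$param), e$covariate, e$form, e$ref, e$beta))
  }
  invisible(x)
}

#' Heuristic initial estimates
#'
#' Clearance from a naive pooled mono-exponential regression of
#' log-concentration on time since last dose; volume from dose / Cmax.
#'
#' @param ds a [pk_dataset()].
#' @return a [pop_params()] object with rough initials (omegas 0.3, sigmas
#'   0.5, slope 0, sc 0.25).
#' @export
initial_estimates <- function(ds) {
  ev <- ds$events
  obs <- ev[ev$EVID == 0 & ev$CMT == 1 & ev$BLQ == 0 & ev$DV > 0, ]
  v_est <- NULL
  tslds <- c(); lc <- c()
  for (id in unique(obs$ID)) {
    sub <- ev[ev$ID == id, ]
    dose <- sub[sub$EVID == 1, ]
    o <- obs[obs$ID == id, ]
    if (!nrow(o) || !nrow(dose)) next
    inf_dur <- max(dose$AMT / dose$RATE + dose$TIME) - max(dose$TIME)
    tsld <- vapply(o$TIME, function(t) {
      prior <- dose$TIME[dose$TIME <= t]
      if (length(prior)) t - max(prior) else NA_real_
    }, numeric(1))
    # elimination phase only: past the end of the (last) infusion
    el <- which(tsld > inf_dur + 0.1)
    tslds <- c(tslds, tsld[el]); lc <- c(lc, log(o$DV[el]))
    bw <- ds$covariates$BW[ds$covariates$ID == id]
    # rescale the subject-level dose/Cmax volume to the 12-kg reference
    v_est <- c(v_est, dose$AMT[1] / max(o$DV) * (12 / bw))
  }
  keep <- is.finite(tslds) & is.finite(lc)
  slope <- if (sum(keep) > 3) {
    stats::coef(stats::lm(lc[keep] ~ tslds[keep]))[2]
  } else -0.3
  k_hat <- min(2, max(0.05, -slope))
  v_hat <- max(1, stats::median(v_est, na.rm = TRUE))
  pop_params(cl_typical = k_hat * v_hat, v1_typical = v_hat,
             ecrcl_slope = 0, sc = 0.25,
             omega_cl = 0.3, omega_v1 = 0.3,
             sigma_plasma = 0.5, sigma_effluent = 0.5)
}

#' Likelihood-ratio decision for nested models
#'
#' Forward inclusion accepts a candidate if the OFV drop reaches the
#' chi-square quantile at p < 0.05 (3.84 for 1 df); backward elimination
#' retains a covariate only if its removal raises the OFV by at least the
#' p < 0.001 quantile (10.83 for 1 df).
#'
#' @param delta_ofv forward: OFV(extended) - OFV(base), negative if the
#'   candidate improves the fit; backward: OFV(reduced) - OFV(full), the
#'   increase caused by removal.
#' @param df degrees of freedom added/removed (>= 1).
#' @param stage `"forward"` or `"backward"`.
#' @return logical: forward — include the candidate; backward — retain the
#'   covariate.
#' @export
lrt_decision <- function(delta_ofv, df = 1, stage = c("forward", "backward")) {
  stage <- match.arg(stage)
  stopifnot(df >= 1)
  if (stage == "forward") {
    delta_ofv <= -stats::qchisq(0.95, df)
  } else {
    delta_ofv >= stats::qchisq(0.999, df)
  }
}

#' Stepwise covariate screen
#'
#' Forward additive inclusion (p < 0.05) followed by backward elimination
#' (p < 0.001): at each forward step every remaining candidate is added
#' singly to the current model, the most significant admissible candidate is
#' included, and the loop repeats; the backward stage then removes each
#' included covariate in turn and eliminates those whose removal raises the
#' OFV by less than 10.83 (1 df).
#'
#' @param ds a [pk_dataset()] (censoring already resolved).
#' @param base a fitted `estimation_result` for the base model.
#' @param candidates list of [covariate_effect()]s to screen.
#' @param ... passed to [fit()] (e.g. `fixed`, `error_model`).
#' @return list with `trace` (data.frame: model number, relation, form,
#'   stage, ofv, delta_ofv, significant, included) and `final` (the fitted
#'   model containing the surviving covariates).
#' @export
covariate_screen <- function(ds, base, candidates, ...) {
  stopifnot(inherits(base, "estimation_result"), base$converged)
  trace <- data.frame(model = 0L, relation = "base", form = "",
                      stage = "base", ofv = base$ofv, delta_ofv = NA_real_,
                      significant = NA, included = NA)
  included <- list()
  remaining <- candidates
  current <- base
  model_no <- 0L
  repeat {
    if (!length(remaining)) break
    fits <- vector("list", length(remaining))
    rows <- list()
    for (i in seq_along(remaining)) {
      model_no <- model_no + 1L
      cand <- remaining[[i]]
      f <- tryCatch(
        fit(ds, init = current$params, effects = c(included, list(cand)), ...),
        error = function(e) NULL)
      fits[[i]] <- f
      ok <- !is.null(f) && f$converged
      d_ofv <- if (ok) f$ofv - current$ofv else NA_real_
      rows[[i]] <- data.frame(
        model = model_no,
        relation = paste0(toupper(cand$param), "-", cand$covariate),
        form = cand$form, stage = "forward", ofv = if (ok) f$ofv else NA_real_,
        delta_ofv = d_ofv,
        significant = if (ok) lrt_decision(d_ofv, 1, "forward") else NA,
        included = FALSE)
    }
    step <- do.call(rbind, rows)
    sig <- which(!is.na(step$delta_ofv) & step$significant)
    if (!length(sig)) { trace <- rbind(trace, step); break }
    bestidx <- sig[which.min(step$delta_ofv[sig])]
    step$included[bestidx] <- TRUE
    trace <- rbind(trace, step)
    included <- c(included, list(remaining[[bestidx]]))
    current <- fits[[bestidx]]
    remaining <- remaining[-bestidx]
  }
  # backward elimination, least significant first
  repeat {
    if (!length(included)) break
    incs <- seq_along(included)
    rises <- numeric(length(incs))
    red_fits <- vector("list", length(incs))
    for (i in incs) {
      model_no <- model_no + 1L
      f <- tryCatch(
        fit(ds, init = current$params, effects = included[-i], ...),
        error = function(e) NULL)
      red_fits[[i]] <- f
      rises[i] <- if (!is.null(f) && f$converged) f$ofv - current$ofv else Inf
      cand <- included[[i]]
      trace <- rbind(trace, data.frame(
        model = model_no,
        relation = paste0(toupper(cand$param), "-", cand$covariate),
        form = cand$form, stage = "backward",
        ofv = if (is.finite(rises[i])) f$ofv else NA_real_,
        delta_ofv = rises[i],
        significant = lrt_decision(rises[i], 1, "backward"),
        included = lrt_decision(rises[i], 1, "backward")))
    }
    worst <- which.min(rises)
    if (lrt_decision(rises[worst], 1, "backward")) break  # all retained
    current <- red_fits[[worst]]
    included <- included[-worst]
  }
  list(trace = trace, final = current, included = included)
}
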