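# accept either a fitted model or bare population parameters as the
# simulation model for predictive checks
.as_model <- function(result) {
  if (inherits(result, "pop_params")) list(params = result, effects = list())
  else result
}

# predictions (log scale) for one compiled subject at given etas
.subject_logpred <- function(csub, p, effects, eta_cl, eta_v1) {
  typ <- .subject_typicals(csub, p, effects)
  cl <- typ$cl_int * exp(eta_cl) + typ$cl_crrt
  v1 <- typ$v1 * exp(eta_v1)
  log(pmax(.subject_pred(csub, p, cl, v1), 1e-300))
}

#' Goodness-of-fit residual table
#'
#' Per-observation population predictions (PRED, etas = 0), individual
#' predictions (IPRED, empirical Bayes etas), individual weighted residuals
#' (IWRES) and conditional weighted residuals (CWRES) from the first-order
#' expansion of the model about the empirical Bayes etas: with `f(eta)` the
#' log-scale prediction vector and `G = df/deta`, the marginal covariance is
#' approximated by `G Omega G' + Sigma` and
#' `CWRES = chol(cov)^-T (y - f(eta_hat) + G eta_hat)`.
#' Censored observations carry `NA` residuals (excluded, noted in the
#' `censored` column).
#'
#' @param result an `estimation_result` from [fit()].
#' @param ds the dataset used for the fit (after [apply_blq()]).
#' @return data.frame: `ID`, `TIME`, `CMT`, `DV`, `PRED`, `IPRED`, `IWRES`,
#'   `CWRES`, `censored`.
#' @export
gof <- function(result, ds) {
  stopifnot(inherits(result, "estimation_result"), result$converged)
  subjects <- compile_dataset(ds)
  p <- result$params
  omega <- diag(c(p$omega_cl, p$omega_v1)^2)
  out <- list()
  for (nm in names(subjects)) {
    csub <- subjects[[nm]]
    if (!length(csub$obs_time)) next
    eta <- result$ebes[nm, ]
    f_hat <- .subject_logpred(csub, p, result$effects, eta[1], eta[2])
    f_pop <- .subject_logpred(csub, p, result$effects, 0, 0)
    sig <- ifelse(csub$obs_kind == 1, p$sigma_plasma, p$sigma_effluent)
    h <- 1e-5
    g1 <- (.subject_logpred(csub, p, result$effects, eta[1] + h, eta[2]) -
             .subject_logpred(csub, p, result$effects, eta[1] - h, eta[2])) / (2 * h)
    g2 <- (.subject_logpred(csub, p, result$effects, eta[1], eta[2] + h) -
             .subject_logpred(csub, p, result$effects, eta[1], eta[2] - h)) / (2 * h)
    g <- cbind(g1, g2)
    covm <- g %*% omega %*% t(g) + diag(sig^2, length(sig))
    y <- csub$obs_logdv
    res <- y - f_hat + as.vector(g %*% eta)
    cw <- rep(NA_real_, length(y))
    qn <- !csub$censored
    if (any(qn)) {
      l <- chol(covm[qn, qn, drop = FALSE])
      cw[qn] <- backsolve(l, res[qn], transpose = TRUE)
    }
    iw <- (y - f_hat) / sig
    out[[nm]] <- data.frame(
      ID = csub$id, TIME = csub$obs_time, CMT = csub$obs_kind,
      DV = exp(y), PRED = exp(f_pop), IPRED = exp(f_hat),
      IWRES = ifelse(qn, iw, NA_real_), CWRES = cw,
      censored = csub$censored)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# assign observation times to bins; nominal times when few, quantile bins
# otherwise
.vpc_bins <- function(times, max_bins = 15) {
  ut <- sort(unique(times))
  if (length(ut) <= max_bins) {
    list(id = match(times, ut), mid = ut)
  } else {
    br <- unique(stats::quantile(times, probs = seq(0, 1, length.out = max_bins + 1)))
    id <- cut(times, br, include.lowest = TRUE, labels = FALSE)
    # ties in the quantile breaks can leave gaps; remap to contiguous bins
    id <- match(id, sort(unique(id)))
    mid <- as.numeric(tapply(times, factor(id, levels = sort(unique(id))),
                             stats::median))
    list(id = id, mid = mid)
  }
}

# simulate one replicate of DV values on the original design
.sim_replicate <- function(subjects, p, effects) {
  unlist(lapply(subjects, function(csub) {
    if (!length(csub$obs_time)) return(numeric(0))
    eta_cl <- stats::rnorm(1, 0, p$omega_cl)
    eta_v1 <- stats::rnorm(1, 0, p$omega_v1)
    lp <- .subject_logpred(csub, p, effects, eta_cl, eta_v1)
    sig <- ifelse(csub$obs_kind == 1, p$sigma_plasma, p$sigma_effluent)
    exp(lp + stats::rnorm(length(lp), 0, sig))
  }), use.names = FALSE)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets on the original design (doses,
#' sampling times, covariates), and per time bin compares the observed 5th,
#' 50th and 95th percentiles with the 95% confidence band of the same
#' percentiles across simulated replicates.
#'
#' @param result an `estimation_result`.
#' @param ds the dataset (after [apply_blq()]; censored records are excluded
#'   from the observed percentiles).
#' @param n_sim number of simulation replicates (>= 100; study setting 2000).
#' @param seed integer seed.
#' @param stratify `"plasma"` or `"effluent"` records.
#' @param percentiles observed/simulated percentiles.
#' @param max_bins cap on the number of time bins (nominal times are used
#'   when they number fewer).
#' @return object of class `vpc_result`: data.frame `bins` with, per bin and
#'   percentile, the observed value and the simulated lower/median/upper
#'   band, plus `n_simulations`.
#' @export
vpc <- function(result, ds, n_sim = 2000, seed, stratify = c("plasma", "effluent"),
                percentiles = c(5, 50, 95), max_bins = 15) {
  stratify <- match.arg(stratify)
  result <- .as_model(result)
  stopifnot(n_sim >= 100)
  subjects <- compile_dataset(ds)
  kind <- if (stratify == "plasma") 1 else 2
  all_time <- unlist(lapply(subjects, `[[`, "obs_time"), use.names = FALSE)
  all_kind <- unlist(lapply(subjects, `[[`, "obs_kind"), use.names = FALSE)
  all_cens <- unlist(lapply(subjects, `[[`, "censored"), use.names = FALSE)
  all_lloq <- unlist(lapply(subjects, `[[`, "lloq"), use.names = FALSE)
  all_dv <- exp(unlist(lapply(subjects, `[[`, "obs_logdv"), use.names = FALSE))
  sel <- all_kind == kind
  if (!any(sel)) stop("no ", stratify, " observations in the dataset")
  bins <- .vpc_bins(all_time[sel], max_bins)
  pr <- percentiles / 100
  obs_pct <- function(dv, keep) {
    vapply(seq_along(bins$mid), function(b) {
      v <- dv[bins$id == b & keep]
      if (length(v)) stats::quantile(v, pr, names = FALSE)
      else rep(NA_real_, length(pr))
    }, numeric(length(pr)))
  }
  # below-LLOQ values are excluded from BOTH the observed and the simulated
  # percentiles, so censoring affects the two sides identically (the
  # categorical VPC carries the censoring signal itself)
  lloq_sel <- all_lloq[sel]
  observed <- obs_pct(all_dv[sel],
                      !all_cens[sel] & !(all_dv[sel] < lloq_sel))
  sims <- with_seed(seed, {
    replicate(n_sim, {
      dv <- .sim_replicate(subjects, result$params, result$effects)
      obs_pct(dv[sel], dv[sel] >= lloq_sel)
    })
  }) # dims: percentile x bin x replicate
  rows <- list()
  for (ip in seq_along(percentiles)) for (b in seq_along(bins$mid)) {
    band <- stats::quantile(sims[ip, b, ], c(0.025, 0.5, 0.975),
                            na.rm = TRUE, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      bin_time = bins$mid[b], percentile = percentiles[ip],
      observed = observed[ip, b],
      sim_lower = band[1], sim_median = band[2], sim_upper = band[3])
  }
  structure(list(bins = do.call(rbind, rows), n_simulations = n_sim,
                 stratify = stratify, seed = seed),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  inband <- with(x$bins, observed >= sim_lower & observed <= sim_upper)
  cat(sprintf(
    "VPC (%s, %d simulations): %d/%d bin-percentiles inside the 95%% band\n",
    x$stratify, x$n_simulations, sum(inband, na.rm = TRUE),
    sum(!is.na(inband))))
  invisible(x)
}

#' Categorical visual predictive check for censored (BLQ) data
#'
#' Per time bin, the observed fraction of observations below the LLOQ
#' against the simulated 95% band of that fraction.
#'
#' @inheritParams vpc
#' @param lloq quantification limit; defaults to the dataset's LLOQ.
#' @return object of class `vpc_blq_result` with per-bin observed and
#'   simulated BLQ fractions.
#' @export
categorical_vpc_blq <- function(result, ds, n_sim = 2000, seed, lloq = NULL,
                                max_bins = 15) {
  result <- .as_model(result)
  subjects <- compile_dataset(ds)
  all_time <- unlist(lapply(subjects, `[[`, "obs_time"), use.names = FALSE)
  all_kind <- unlist(lapply(subjects, `[[`, "obs_kind"), use.names = FALSE)
  all_cens <- unlist(lapply(subjects, `[[`, "censored"), use.names = FALSE)
  all_lloq <- unlist(lapply(subjects, `[[`, "lloq"), use.names = FALSE)
  all_dv <- exp(unlist(lapply(subjects, `[[`, "obs_logdv"), use.names = FALSE))
  if (is.null(lloq)) lloq <- stats::median(all_lloq)
  sel <- all_kind == 1
  bins <- .vpc_bins(all_time[sel], max_bins)
  # observed BLQ: censored flag, or (M6-style imputation) value below lloq
  obs_blq <- all_cens[sel] | (all_dv[sel] < lloq)
  frac <- function(flag) {
    vapply(seq_along(bins$mid),
           function(b) mean(flag[bins$id == b]), numeric(1))
  }
  observed <- frac(obs_blq)
  sims <- with_seed(seed, {
    replicate(n_sim, {
      dv <- .sim_replicate(subjects, result$params, result$effects)
      frac(dv[sel] < lloq)
    })
  })
  sims <- matrix(sims, nrow = length(bins$mid))
  band <- t(apply(sims, 1, stats::quantile, c(0.025, 0.5, 0.975), names = FALSE))
  structure(list(
    bins = data.frame(bin_time = bins$mid, observed = observed,
                      sim_lower = band[, 1], sim_median = band[, 2],
                      sim_upper = band[, 3]),
    n_simulations = n_sim, lloq = lloq, seed = seed),
    class = "vpc_blq_result")
}

#' @export
print.vpc_blq_result <- function(x, ...) {
  inband <- with(x$bins, observed >= sim_lower & observed <= sim_upper)
  cat(sprintf(
    "Categorical BLQ VPC (LLOQ %g): %d/%d bins inside the 95%% band\n",
    x$lloq, sum(inband), length(inband)))
  invisible(x)
}

# ---- sampling importance resampling ----------------------------------------

.dmvnorm_log <- function(x, mean, sigma) {
  d <- length(mean)
  ch <- chol(sigma)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Sampling importance resampling (SIR)
#'
#' Draws proposal parameter vectors from a multivariate normal centred on the
#' estimates, weights each draw by the likelihood ratio
#' `exp(-1/2 (OFV(theta) - OFV_min))` over the proposal density, and
#' resamples without replacement.  One SIR iteration with a normal proposal,
#' matching the single-round setting used for the reported uncertainty
#' (2000 samples, 1000 resamples).
#'
#' @param ofv_fun function(theta vector) returning the OFV.
#' @param estimate parameter vector at the optimum.
#' @param vcov proposal covariance matrix (e.g. inverse-Hessian based); a
#'   zero matrix degenerates to all resamples equal to the estimate.
#' @param n_samples proposal draws.
#' @param n_resamples resamples (<= n_samples) drawn without replacement.
#' @param seed integer seed.
#' @param param_names optional names for reporting.
#' @return object of class `sir_result`: `resamples` matrix, `summary`
#'   data.frame (median and 2.5/97.5 percentiles per parameter), `ess`
#'   (effective sample size of the importance weights).
#' @export
sir <- function(ofv_fun, estimate, vcov, n_samples = 2000, n_resamples = 1000,
                seed, param_names = names(estimate)) {
  stopifnot(n_resamples <= n_samples)
  d <- length(estimate)
  vcov <- as.matrix(vcov)
  if (all(abs(vcov) < 1e-300)) {
    res <- matrix(rep(estimate, n_resamples), ncol = d, byrow = TRUE)
    colnames(res) <- param_names
    summ <- data.frame(parameter = param_names %||% paste0("p", seq_len(d)),
                       median = estimate, lower = estimate, upper = estimate)
    return(structure(list(resamples = res, summary = summ, ess = n_resamples,
                          n_samples = n_samples, n_resamples = n_resamples),
                     class = "sir_result"))
  }
  ev <- eigen(vcov, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    warning("singular proposal covariance; inflating diagonal")
    vcov <- vcov + diag(max(abs(ev$values)) * 1e-6 + 1e-12, d)
  }
  with_seed(seed, {
    samples <- MASS::mvrnorm(n_samples, mu = estimate, Sigma = vcov)
    if (d == 1) samples <- matrix(samples, ncol = 1)
    ofv0 <- ofv_fun(estimate)
    logw <- vapply(seq_len(n_samples), function(i) {
      th <- samples[i, ]
      o <- ofv_fun(th)
      if (!is.finite(o)) return(-Inf)
      -0.5 * (o - ofv0) - .dmvnorm_log(th, estimate, vcov)
    }, numeric(1))
    logw <- logw - max(logw[is.finite(logw)])
    w <- exp(logw)
    w[!is.finite(w)] <- 0
    ess <- sum(w)^2 / sum(w^2)
    idx <- sample.int(n_samples, n_resamples, replace = FALSE, prob = w)
    res <- samples[idx, , drop = FALSE]
    colnames(res) <- param_names
    qs <- apply(res, 2, stats::quantile, c(0.5, 0.025, 0.975), names = FALSE)
    summ <- data.frame(parameter = param_names %||% paste0("p", seq_len(d)),
                       median = qs[1, ], lower = qs[2, ], upper = qs[3, ])
    structure(list(resamples = res, summary = summ, ess = ess,
                   n_samples = n_samples, n_resamples = n_resamples),
              class = "sir_result")
  })
}

#' @export
print.sir_result <- function(x, ...) {
  cat(sprintf("SIR uncertainty (%d samples, %d resamples, ESS %.0f)\n",
              x$n_samples, x$n_resamples, x$ess))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %.4g (%.4g-%.4g)\n", s$parameter[i], s$median[i],
                s$lower[i], s$upper[i]))
  }
  invisible(x)
}

# rebuild pop_params/effects from a transformed parameter vector of a fit
.params_from_par <- function(result, par) {
  p <- result$init
  en <- result$est_names
  for (i in seq_along(en)) p[[en[i]]] <- .from_trans(en[i], par[i])
  if (result$error_model == "one_sigma") p$sigma_effluent <- p$sigma_plasma
  eff <- result$effects
  if (length(eff)) {
    for (j in seq_along(eff)) eff[[j]]$beta <- par[length(en) + j]
  }
  list(p = p, effects = eff)
}

#' Parameter uncertainty of a fitted model by SIR
#'
#' Builds the proposal from the numerical OFV Hessian at the optimum
#' (covariance `2 H^-1` on the transformed scale), runs [sir()], and
#' back-transforms the resamples to the natural scale (percentiles map
#' through the monotone component transforms).
#'
#' @param result a converged `estimation_result`.
#' @param n_samples,n_resamples,seed see [sir()].
#' @param hess_step relative finite-difference step for the Hessian.
#' @return a `sir_result` on the natural parameter scale.
#' @export
sir_from_fit <- function(result, n_samples = 2000, n_resamples = 1000, seed,
                         hess_step = 1e-3) {
  stopifnot(inherits(result, "estimation_result"), result$converged)
  cache <- new.env(parent = emptyenv())
  ofv_fun <- function(par) {
    b <- .params_from_par(result, par)
    tryCatch(ofv(result$subjects, b$p, b$effects, eta_cache = cache),
             error = function(e) Inf)
  }
  par <- result$par
  npar <- length(par)
  h <- pmax(abs(par), 1) * hess_step
  hess <- matrix(0, npar, npar)
  f0 <- ofv_fun(par)
  for (i in seq_len(npar)) {
    ei <- rep(0, npar); ei[i] <- h[i]
    hess[i, i] <- (ofv_fun(par + ei) + ofv_fun(par - ei) - 2 * f0) / h[i]^2
  }
  if (npar > 1) {
    for (i in seq_len(npar - 1)) for (j in (i + 1):npar) {
      ei <- rep(0, npar); ei[i] <- h[i]
      ej <- rep(0, npar); ej[j] <- h[j]
      hess[i, j] <- hess[j, i] <-
        (ofv_fun(par + ei + ej) - ofv_fun(par + ei - ej) -
           ofv_fun(par - ei + ej) + ofv_fun(par - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  vc <- tryCatch(2 * solve(hess), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(vc)) || any(diag(vc) <= 0)) {
    warning("singular OFV Hessian; using inflated diagonal proposal")
    vc <- diag(pmax(abs(par), 0.1)^2 * 0.01, npar)
  }
  nm <- c(result$est_names,
          vapply(result$effects, function(e)
            paste0(toupper(e$param), "-", e$covariate), character(1)))
  out <- sir(ofv_fun, par, vc, n_samples, n_resamples, seed, param_names = nm)
  # back-transform structural parameters to the natural scale
  for (i in seq_along(result$est_names)) {
    out$resamples[, i] <- .from_trans(result$est_names[i], out$resamples[, i])
  }
  qs <- apply(out$resamples, 2, stats::quantile, c(0.5, 0.025, 0.975),
              names = FALSE)
  out$summary <- data.frame(parameter = nm, median = qs[1, ],
                            lower = qs[2, ], upper = qs[3, ])
  out
}
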