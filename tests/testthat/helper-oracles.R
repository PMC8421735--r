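# Independent numerical oracles used across the suite.

# Plasma concentration by adaptive ODE integration (deSolve), one-compartment
# with piecewise-constant infusion input.
ode_conc <- function(times, segments, cl, v1, atol = 1e-12, rtol = 1e-10) {
  rate_fun <- function(t) {
    sum(segments$rate[segments$start < t & t <= segments$end])
  }
  rhs <- function(t, y, parms) list(rate_fun(t) - (cl / v1) * y)
  tcrit <- sort(unique(c(times, segments$start, segments$end)))
  out <- deSolve::lsoda(c(a = 0), sort(unique(c(0, tcrit))), rhs, NULL,
                        atol = atol, rtol = rtol, hmax = 0.05)
  amounts <- out[match(times, out[, "time"]), "a"]
  amounts / v1
}

# Effluent concentration by stiff ODE integration of the two-state system.
ode_effluent <- function(times, segments, cl, v1, sc, flow, v2,
                         atol = 1e-13, rtol = 1e-11) {
  rate_fun <- function(t) {
    sum(segments$rate[segments$start < t & t <= segments$end])
  }
  rhs <- function(t, y, parms) {
    c1 <- y[1] / v1
    list(c(rate_fun(t) - cl * c1,
           (flow / v2) * (sc * c1 - y[2])))
  }
  tt <- sort(unique(c(0, times, segments$start, segments$end)))
  out <- deSolve::lsoda(c(a = 0, c2 = 0), tt, rhs, NULL,
                        atol = atol, rtol = rtol, hmax = 0.02)
  out[match(times, out[, "time"]), "c2"]
}

# -2 log marginal likelihood by adaptive Gauss-Hermite quadrature (tensor
# grid centred and scaled at the conditional mode), independent of the
# Laplace path it checks.
ofv_ghq <- function(ds, p, n_nodes = 21) {
  subjects <- meropk:::compile_dataset(ds)
  gh <- pracma::gaussHermite(n_nodes)
  total <- 0
  for (csub in subjects) {
    omega <- c(p$omega_cl, p$omega_v1)
    nll <- function(e) {
      ll <- meropk:::subject_loglik(csub, p, e[1], e[2])
      -(ll + sum(stats::dnorm(e, 0, omega, log = TRUE)))
    }
    opt <- stats::optim(c(0, 0), nll, method = "BFGS")
    hh <- 1e-4
    hd <- vapply(1:2, function(i) {
      ei <- c(0, 0); ei[i] <- hh
      (nll(opt$par + ei) + nll(opt$par - ei) - 2 * opt$value) / hh^2
    }, numeric(1))
    scale <- 1 / sqrt(pmax(hd, 1e-8))
    # integrate exp(-nll) over eta with GH nodes x_i mapped through
    # mode + sqrt(2)*scale*x
    acc <- 0
    for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
      e <- opt$par + sqrt(2) * scale * c(gh$x[i], gh$x[j])
      f <- exp(-nll(e) + sum((c(gh$x[i], gh$x[j]))^2))
      acc <- acc + gh$w[i] * gh$w[j] * f
    }
    total <- total - 2 * (log(acc) + log(2) + sum(log(scale)))
  }
  total
}

# small deterministic two-subject dataset builder for likelihood tests
toy_dataset <- function(n_subjects = 2, n_obs = 3, seed = 1,
                        crrt = FALSE, blq_at = NULL, lloq = 0.2) {
  set.seed(seed)
  ev <- list(); cov <- list()
  for (id in seq_len(n_subjects)) {
    bw <- 8 + 4 * id
    dose <- 20 * bw
    times <- sort(sample(c(1.1, 2, 3, 4.5, 6, 7.5), n_obs))
    dv <- exp(rnorm(n_obs, log(8), 0.4))
    blq <- rep(0L, n_obs)
    if (!is.null(blq_at)) {
      dv[blq_at] <- lloq / 2
      blq[blq_at] <- 1L
    }
    ev[[id]] <- data.frame(
      ID = id, TIME = c(0, times), EVID = c(1L, rep(0L, n_obs)),
      AMT = c(dose, rep(NA, n_obs)), RATE = c(dose, rep(NA, n_obs)),
      DV = c(NA, dv), CMT = 1L, BLQ = c(0L, blq), LLOQ = lloq)
    cov[[id]] <- data.frame(ID = id, BW = bw, ECRCL = 80 + 20 * id,
                            CRRT = as.integer(crrt), ECMO = 0L,
                            AGE = 2, SEX = 0L)
  }
  pk_dataset(do.call(rbind, ev), do.call(rbind, cov))
}
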