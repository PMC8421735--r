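#' Population pharmacokinetic parameters
#'
#' Container for the fixed effects, inter-individual variability (IIV) and
#' residual-error magnitudes of the meropenem population model, together with
#' the fixed CRRT-circuit constants.  Defaults are the final-model estimates
#' for septic children on extracorporeal life support; use
#' [table4_params()] for the packaged published set.
#'
#' The clearance model is
#' \deqn{CL = \theta_{CL} (BW/BW_{ref})^{0.75}\,(1+(eCRCL-eCRCL_{ref})\theta_{CRCL})
#'   \;[+\; SC \cdot Q \;\mathrm{if\ on\ CRRT}]}
#' with \eqn{Q = flow\_per\_kg \cdot BW} the effluent (replacement + filtration)
#' flow.  The central volume scales linearly with bodyweight.  IIV enters
#' log-normally (`omega_*` are SDs of the log-scale random effects), and the
#' residual error is additive on log-concentrations with separate SDs for
#' plasma and CRRT-effluent observations.
#'
#' @param cl_typical typical clearance (L/h) at the reference covariates.
#' @param v1_typical typical central volume (L) at the reference bodyweight.
#' @param ecrcl_slope linear creatinine-clearance effect on clearance
#'   (per ml/min/1.73m2).
#' @param ecrcl_ref reference eCRCL (ml/min/1.73m2).
#' @param bw_ref reference bodyweight (kg).
#' @param sc sieving coefficient of the hemofilter (fraction in \[0, 1\]).
#' @param flow_per_kg CRRT effluent flow per kg bodyweight (L/h/kg).
#' @param v2 volume of the post-CRRT (effluent sampling) compartment (L).
#' @param omega_cl,omega_v1 IIV standard deviations (log scale) of CL and V1.
#' @param sigma_plasma,sigma_effluent residual SDs (log scale) for plasma and
#'   effluent observations.
#' @param age50 optional maturation half-age (years); `NA` disables the
#'   maturation term (it was screened but not retained in the final model).
#' @return An object of class `pop_params` (a named list).
#' @seealso [table4_params()], [read_params()], [typical_clearance()]
#' @examples
#' p <- pop_params()
#' p$cl_typical
#' @export
pop_params <- function(cl_typical = 7.6,
                       v1_typical = 21.4,
                       ecrcl_slope = 0.0035,
                       ecrcl_ref = 150,
                       bw_ref = 12,
                       sc = 0.257,
                       flow_per_kg = 0.045,
                       v2 = 0.025,
                       omega_cl = 0.557,
                       omega_v1 = 0.562,
                       sigma_plasma = 0.575,
                       sigma_effluent = 0.284,
                       age50 = NA_real_) {
  p <- list(
    cl_typical = cl_typical, v1_typical = v1_typical,
    ecrcl_slope = ecrcl_slope, ecrcl_ref = ecrcl_ref, bw_ref = bw_ref,
    sc = sc, flow_per_kg = flow_per_kg, v2 = v2,
    omega_cl = omega_cl, omega_v1 = omega_v1,
    sigma_plasma = sigma_plasma, sigma_effluent = sigma_effluent,
    age50 = age50
  )
  class(p) <- "pop_params"
  validate_pop_params(p)
  p
}

validate_pop_params <- function(p) {
  stopifnot(
    p$cl_typical > 0, p$v1_typical > 0, p$bw_ref > 0, p$v2 > 0,
    p$flow_per_kg >= 0,
    p$sc >= 0, p$sc <= 1,
    p$omega_cl >= 0, p$omega_v1 >= 0,
    p$sigma_plasma >= 0, p$sigma_effluent >= 0
  )
  if (!is.na(p$age50) && p$age50 <= 0) stop("age50 must be positive when set")
  invisible(p)
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population PK parameters (meropenem, one-compartment + post-CRRT)\n")
  cat(sprintf("  CL typical   %6.3f L/h   (BW ref %g kg, allometric 0.75)\n",
              x$cl_typical, x$bw_ref))
  cat(sprintf("  V1 typical   %6.3f L     (linear BW scaling)\n", x$v1_typical))
  cat(sprintf("  eCRCL slope  %8.5f per ml/min/1.73m2 (ref %g)\n",
              x$ecrcl_slope, x$ecrcl_ref))
  cat(sprintf("  SC %5.3f | flow %g L/h/kg | V2 %g L (fixed circuit constants)\n",
              x$sc, x$flow_per_kg, x$v2))
  cat(sprintf("  IIV omega: CL %5.3f, V1 %5.3f (log-scale SD)\n",
              x$omega_cl, x$omega_v1))
  cat(sprintf("  Residual sigma: plasma %5.3f, effluent %5.3f (log scale)\n",
              x$sigma_plasma, x$sigma_effluent))
  invisible(x)
}

#' Published final-model parameter estimates
#'
#' Reads the packaged parameter file holding the published final population
#' estimates (CL 7.6 L/h, V1 21.4 L, SC 0.257, eCRCL slope 0.0035, IIV CVs
#' 55.7/56.2%, residual SDs 0.575/0.284) used for simulation and as ground
#' truth in synthetic-data experiments.
#'
#' @param cv_as_sdlog how to map the printed IIV CV percentages to log-scale
#'   SDs: `"direct"` (omega = CV/100, the NONMEM reporting convention assumed
#'   by default) or `"lognormal"` (omega = sqrt(log(1 + (CV/100)^2))).
#' @return A [pop_params()] object.
#' @export
table4_params <- function(cv_as_sdlog = c("direct", "lognormal")) {
  cv_as_sdlog <- match.arg(cv_as_sdlog)
  p <- read_params(system.file("extdata", "final_model_params.cfg",
                               package = "meropk", mustWork = TRUE))
  if (cv_as_sdlog == "lognormal") {
    p$omega_cl <- sqrt(log(1 + p$omega_cl^2))
    p$omega_v1 <- sqrt(log(1 + p$omega_v1^2))
  }
  p
}

#' Read / write population parameters as a flat key-value file
#'
#' The on-disk format is plain text, one `key = value` pair per line, keys
#' matching the [pop_params()] argument names; `#` starts a comment.
#'
#' @param path file path.
#' @return `read_params()` returns a [pop_params()] object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed parameter line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals)) stop("non-numeric parameter value for key: ",
                        keys[is.na(vals)][1])
  known <- names(formals(pop_params))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown parameter key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pop_params, as.list(stats::setNames(vals, keys)))
}

#' @rdname read_params
#' @param p a [pop_params()] object.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "pop_params"))
  keys <- names(p)[!vapply(p, is.na, TRUE)]   # unset optionals are omitted
  lines <- sprintf("%s = %.10g", keys, unlist(p[keys]))
  writeLines(lines, path)
  invisible(path)
}
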