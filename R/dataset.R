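#' PK dataset of dosing and observation event records
#'
#' The estimation dataset couples an event table (one row per dose or
#' observation, NONMEM-style) with a per-subject covariate table.
#'
#' Event columns: `ID`, `TIME` (h), `EVID` (1 = dose, 0 = observation),
#' `AMT` (mg, doses), `RATE` (mg/h, doses), `DV` (mg/L, observations),
#' `CMT` (1 = plasma, 2 = CRRT effluent), `BLQ` (0/1), `LLOQ` (mg/L).
#' Covariate columns: `ID`, `BW`, `ECRCL`, `CRRT`, `ECMO`, `AGE`, `SEX`,
#' plus any screened covariates (`ALB`, `GLB`, `ALT`, `AST`, `TBIL`, `DBIL`,
#' `HT`, `WAZ`, `LIZ`, `VANC`, ...).
#'
#' @param events event data.frame.
#' @param covariates covariate data.frame (one row per subject).
#' @return validated object of class `pk_dataset`.
#' @export
pk_dataset <- function(events, covariates) {
  ds <- structure(list(events = as.data.frame(events),
                       covariates = as.data.frame(covariates)),
                  class = "pk_dataset")
  validate_pk_dataset(ds)
}

validate_pk_dataset <- function(ds) {
  ev <- ds$events
  cov <- ds$covariates
  need <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "CMT", "BLQ", "LLOQ")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event table is missing column(s): ",
                         paste(miss, collapse = ", "))
  need_cov <- c("ID", "BW", "ECRCL", "CRRT", "ECMO")
  miss <- setdiff(need_cov, names(cov))
  if (length(miss)) stop("covariate table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cov$ID)) stop("duplicated subject ID in covariate table")
  orphan <- setdiff(unique(ev$ID), cov$ID)
  if (length(orphan)) stop("observations without covariates for subject(s): ",
                           paste(orphan, collapse = ", "))
  if (any(ev$TIME < 0)) stop("negative event times (row ",
                             which(ev$TIME < 0)[1], ")")
  doses <- ev$EVID == 1
  if (any(doses & !(ev$AMT > 0)))
    stop("dose record with non-positive AMT (row ",
         which(doses & !(ev$AMT > 0))[1], ")")
  obs <- ev$EVID == 0
  bad_obs <- obs & !(ev$BLQ == 1) & !(ev$DV >= 0) # nolint
  if (any(bad_obs, na.rm = TRUE))
    stop("observation with negative/missing DV (row ", which(bad_obs)[1], ")")
  for (id in unique(ev$ID)) {
    sub <- ev[ev$ID == id, ]
    if (is.unsorted(sub$TIME))
      stop("times not sorted for subject ", id)
    first_obs <- suppressWarnings(min(sub$TIME[sub$EVID == 0]))
    first_dose <- suppressWarnings(min(sub$TIME[sub$EVID == 1]))
    if (is.finite(first_obs) &&
        (!is.finite(first_dose) || first_dose > first_obs))
      stop("subject ", id, " has an observation before any dose")
  }
  ds
}

#' @export
print.pk_dataset <- function(x, ...) {
  ev <- x$events
  nobs <- sum(ev$EVID == 0)
  cat(sprintf(
    "PK dataset: %d subjects, %d doses, %d observations (%d plasma, %d effluent), %d BLQ (%.1f%%)\n",
    length(unique(ev$ID)), sum(ev$EVID == 1), nobs,
    sum(ev$EVID == 0 & ev$CMT == 1), sum(ev$EVID == 0 & ev$CMT == 2),
    sum(ev$EVID == 0 & ev$BLQ == 1),
    if (nobs) 100 * sum(ev$EVID == 0 & ev$BLQ == 1) / nobs else 0))
  invisible(x)
}

#' Read / write the dataset CSV dialect
#'
#' One flat CSV with the event columns followed by the per-subject covariate
#' columns (repeated on every row of a subject).  `write_dataset()` then
#' `read_dataset()` round-trips to an identical dataset.
#'
#' @param path CSV file path.
#' @return `read_dataset()` returns a validated [pk_dataset()];
#'   `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ev_cols <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "CMT", "BLQ", "LLOQ")
  miss <- setdiff(ev_cols, names(df))
  if (length(miss)) stop("dataset ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  cov_cols <- setdiff(names(df), ev_cols)
  cov <- df[!duplicated(df$ID), c("ID", cov_cols), drop = FALSE]
  rownames(cov) <- NULL
  pk_dataset(df[ev_cols], cov)
}

#' @rdname read_dataset
#' @param ds a [pk_dataset()].
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "pk_dataset"))
  ev <- ds$events
  cov <- ds$covariates
  merged <- merge(ev, cov, by = "ID", sort = FALSE)
  merged <- merged[order(merged$ID, merged$TIME, -merged$EVID), ]
  utils::write.csv(merged, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply a below-LLOQ handling policy
#'
#' * **M1** — censored (BLQ) observations are discarded.
#' * **M3** — censored observations are kept and flagged for a
#'   censored-likelihood contribution (probability mass below the LLOQ).
#' * **M6** — the first censored observation of each subject (in time order)
#'   is imputed at LLOQ/2 and treated as quantified; subsequent censored
#'   observations are discarded.
#'
#' @param ds a [pk_dataset()].
#' @param method `"M1"`, `"M3"` or `"M6"`.
#' @return a `pk_dataset` whose events carry a `BLQ_POLICY` column
#'   (`"obs"`, `"censored"`) and, for M6, imputed DV values.
#' @export
apply_blq <- function(ds, method = c("M1", "M3", "M6")) {
  method <- match.arg(method)
  ev <- ds$events
  if (any(ev$EVID == 0 & is.na(ev$LLOQ)))
    stop("LLOQ must be set on all observation records")
  is_blq <- ev$EVID == 0 & ev$BLQ == 1
  ev$BLQ_POLICY <- ifelse(ev$EVID == 0, "obs", NA_character_)
  keep <- rep(TRUE, nrow(ev))
  if (method == "M1") {
    keep[is_blq] <- FALSE
  } else if (method == "M3") {
    ev$BLQ_POLICY[is_blq] <- "censored"
  } else {
    for (id in unique(ev$ID)) {
      idx <- which(ev$ID == id & is_blq)
      if (!length(idx)) next
      idx <- idx[order(ev$TIME[idx])]
      ev$DV[idx[1]] <- ev$LLOQ[idx[1]] / 2
      ev$BLQ[idx[1]] <- 0L
      if (length(idx) > 1) keep[idx[-1]] <- FALSE
    }
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  out <- ds
  out$events <- ev
  attr(out, "blq_method") <- method
  out
}
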