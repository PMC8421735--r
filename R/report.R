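#' Assemble an analysis report directory
#'
#' Writes the available results as a deterministic file set: a parameter
#' table with SIR medians and 95% CIs formatted as `median (lower-upper)`,
#' wide PTA tables per target, the regimen recommendations, VPC data, GOF
#' residuals, and PTA-vs-MIC curves.  Every figure's underlying numbers are
#' also written as CSV; figures are PNG (base graphics).
#'
#' @param results named list; any subset of `fit` (an `estimation_result`),
#'   `sir` (a `sir_result`), `pta_tables` (from [scenario_tables()]),
#'   `recommendations` (from [recommend_regimen()]), `vpc` (a `vpc_result`),
#'   `vpc_blq` (a `vpc_blq_result`), `gof` (from [gof()]), `pta_curves`
#'   (from [pta_vs_mic()]).
#' @param dir output directory (created if needed).
#' @param overwrite allow writing into a non-empty directory.
#' @param figures write PNG figures as well as CSVs.
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, dir, overwrite = FALSE, figures = TRUE) {
  stopifnot(is.list(results), length(results) > 0)
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    stop("output directory ", dir, " is not empty (use overwrite = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(df, name) {
    fp <- file.path(dir, name)
    utils::write.csv(df, fp, row.names = FALSE)
    paths <<- c(paths, fp)
  }
  if (!is.null(results$fit)) {
    p <- results$fit$params
    tab <- data.frame(
      parameter = c("CL (L/h)", "V1 (L)", "eCRCL slope", "SC",
                    "omega_CL", "omega_V1", "sigma_plasma", "sigma_effluent"),
      estimate = c(p$cl_typical, p$v1_typical, p$ecrcl_slope, p$sc,
                   p$omega_cl, p$omega_v1, p$sigma_plasma, p$sigma_effluent))
    if (!is.null(results$sir)) {
      s <- results$sir$summary
      m <- match(c("cl_typical", "v1_typical", "ecrcl_slope", "sc",
                   "omega_cl", "omega_v1", "sigma_plasma", "sigma_effluent"),
                 s$parameter)
      tab$sir <- ifelse(is.na(m), "",
                        sprintf("%.3g (%.3g-%.3g)", s$median[m],
                                s$lower[m], s$upper[m]))
    }
    tab$ofv <- results$fit$ofv
    put(tab, "parameter_table.csv")
  }
  if (!is.null(results$pta_tables)) {
    put(results$pta_tables, "pta_long.csv")
    for (tg in unique(results$pta_tables$target)) {
      put(format_pta_table(results$pta_tables, tg),
          sprintf("pta_table_target%.0f.csv", 100 * tg))
    }
  }
  if (!is.null(results$recommendations)) {
    put(results$recommendations, "recommendations.csv")
  }
  if (!is.null(results$gof)) {
    put(results$gof, "gof_residuals.csv")
    if (figures) {
      fp <- file.path(dir, "gof.png")
      grDevices::png(fp, width = 900, height = 900, res = 120)
      op <- graphics::par(mfrow = c(2, 2))
      g <- results$gof[!results$gof$censored, ]
      graphics::plot(g$PRED, g$CWRES, xlab = "Population prediction (mg/L)",
                     ylab = "CWRES", main = "CWRES vs PRED")
      graphics::abline(h = 0, col = 2)
      graphics::plot(g$TIME, g$CWRES, xlab = "Time (h)", ylab = "CWRES",
                     main = "CWRES vs time")
      graphics::abline(h = 0, col = 2)
      graphics::plot(g$PRED, g$DV, log = "xy", xlab = "PRED (mg/L)",
                     ylab = "Observed (mg/L)", main = "Observed vs PRED")
      graphics::abline(0, 1, col = 2)
      graphics::plot(g$IPRED, g$DV, log = "xy", xlab = "IPRED (mg/L)",
                     ylab = "Observed (mg/L)", main = "Observed vs IPRED")
      graphics::abline(0, 1, col = 2)
      graphics::par(op)
      grDevices::dev.off()
      paths <- c(paths, fp)
    }
  }
  for (nm in c("vpc", "vpc_blq")) {
    if (is.null(results[[nm]])) next
    put(results[[nm]]$bins, paste0(nm, ".csv"))
    if (figures) {
      fp <- file.path(dir, paste0(nm, ".png"))
      grDevices::png(fp, width = 800, height = 600, res = 120)
      b <- results[[nm]]$bins
      if (nm == "vpc") {
        graphics::matplot(unique(b$bin_time),
                          sapply(split(b$observed, b$percentile), identity),
                          type = "b", pch = 1, lty = 1, log = "y",
                          xlab = "Time (h)", ylab = "Concentration (mg/L)",
                          main = "Visual predictive check")
      } else {
        graphics::plot(b$bin_time, b$observed, type = "b", ylim = c(0, 1),
                       xlab = "Time (h)", ylab = "BLQ fraction",
                       main = "Categorical VPC (BLQ)")
        graphics::lines(b$bin_time, b$sim_lower, lty = 2)
        graphics::lines(b$bin_time, b$sim_upper, lty = 2)
      }
      grDevices::dev.off()
      paths <- c(paths, fp)
    }
  }
  if (!is.null(results$pta_curves)) {
    put(results$pta_curves, "pta_vs_mic.csv")
    if (figures) {
      fp <- file.path(dir, "pta_vs_mic.png")
      grDevices::png(fp, width = 800, height = 600, res = 120)
      cv <- results$pta_curves
      graphics::plot(cv$mic, cv$pta, log = "x", type = "b",
                     xlab = "MIC (mg/L)", ylab = "PTA (%)", ylim = c(0, 100),
                     main = "PTA vs MIC")
      graphics::abline(h = 70, lty = 2)
      grDevices::dev.off()
      paths <- c(paths, fp)
    }
  }
  invisible(paths)
}
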