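#' Run the full analysis chain on a station table
#'
#' Orchestrates the stages in analysis order: diel replicate QC ->
#' speciation -> delta-53Cr vs [Cr(III)] mass-balance fit -> delta-53Cr vs
#' ln[Cr] enrichment-factor fit -> mixed-layer deficit and export budgets ->
#' Cr(III)-NCP correlation. Each stage is a pure function of its inputs, so
#' rerunning with the same inputs reproduces the report exactly.
#'
#' The mass-balance fit selects diel-replicated depths above the winter mixed
#' layer and pairs the QC'd Cr(III) means with the station-depth delta-53Cr
#' values; the sample selection is recorded in the report.
#'
#' @param samples station table (see [read_station_table()]).
#' @param contexts station contexts (see [read_station_contexts()]).
#' @param constants a [cr_constants()] list.
#' @param alpha outlier-test significance level for the QC stage.
#' @param by_day split diel groups by day during QC.
#' @return list of class `"cr_run"` with elements `qc`, `speciation`,
#'   `fit_cr3` (a [cr_fractionation()] fit, or `NULL` if too few points),
#'   `fit_lncr`, `budgets`, `ncp_cr3` (euphotic-zone Cr(III) vs volumetric
#'   NCP regression summary), `selection` (station/depth pairs used in the
#'   mass-balance fit), `constants`.
#' @export
#' @examples
#' ocean <- simulate_ocean(seed = 7)
#' run <- run_all(ocean$samples, ocean$contexts)
#' run$fit_cr3$delta_cap
run_all <- function(samples, contexts, constants = cr_constants(),
                    alpha = 0.05, by_day = FALSE) {
  validate_station_table(samples)

  qc <- aggregate_diel(samples, value = "cr3_nmolkg", alpha = alpha,
                       by_day = by_day,
                       single_rel_unc = constants$cr3_default_unc)

  # station-depth [Cr] and delta means from the profile rows
  prof <- samples[!is.na(samples$cr_total_nmolkg), ]
  prof_agg <- stats::aggregate(
    cbind(cr_total_nmolkg, d53cr_permil) ~ station + depth_m,
    data = prof, FUN = mean, na.action = stats::na.pass)

  merged <- merge(prof_agg, qc[, c("station", "depth_m", "mean", "sd",
                                   "diel_replicated")],
                  by = c("station", "depth_m"), all.x = TRUE)
  names(merged)[names(merged) == "mean"] <- "cr3_mean"
  names(merged)[names(merged) == "sd"] <- "cr3_sd_qc"

  spec_rows <- !is.na(merged$cr3_mean) & !is.na(merged$cr_total_nmolkg)
  speciation <- cbind(
    merged[spec_rows, c("station", "depth_m")],
    speciate(merged$cr_total_nmolkg[spec_rows], merged$cr3_mean[spec_rows],
             merged$cr_total_nmolkg[spec_rows] * constants$rsd_cr,
             merged$cr3_sd_qc[spec_rows]))

  # mass-balance fit: diel-replicated depths above the winter mixed layer
  wml <- contexts$winter_ml_depth_m[match(merged$station, contexts$station)]
  wml[is.na(wml)] <- 100
  sel <- which(!is.na(merged$cr3_mean) & !is.na(merged$d53cr_permil) &
                 isTRUE_v(merged$diel_replicated) & merged$depth_m < wml)
  fit_cr3 <- if (length(sel) >= 3)
    cr_fractionation(merged$cr3_mean[sel], merged$d53cr_permil[sel],
                     mode = "cr3", cr6nr_const = constants$cr6nr_const)
  else NULL

  lnc <- which(!is.na(merged$cr_total_nmolkg) & !is.na(merged$d53cr_permil) &
                 merged$cr_total_nmolkg > 0)
  fit_lncr <- if (length(lnc) >= 3)
    cr_fractionation(merged$cr_total_nmolkg[lnc], merged$d53cr_permil[lnc],
                     mode = "lncr")
  else NULL

  budgets <- budget_table(samples, contexts, constants)

  # euphotic-zone Cr(III) means vs volumetric NCP
  ncp_cr3 <- NULL
  if ("ncp_vol_mmolc_m3_d" %in% names(contexts) &&
      any(is.finite(contexts$ncp_vol_mmolc_m3_d))) {
    zeu <- contexts$euphotic_depth_m[match(merged$station, contexts$station)]
    nv <- contexts$ncp_vol_mmolc_m3_d[match(merged$station, contexts$station)]
    eu <- which(!is.na(merged$cr3_mean) & isTRUE_v(merged$diel_replicated) &
                  merged$depth_m <= zeu & is.finite(nv))
    if (length(eu) >= 3) {
      f <- stats::lm(merged$cr3_mean[eu] ~ nv[eu])
      ncp_cr3 <- list(slope = unname(stats::coef(f)[2]),
                      intercept = unname(stats::coef(f)[1]),
                      r2 = summary(f)$r.squared,
                      p = stats::anova(f)[["Pr(>F)"]][1],
                      n = length(eu))
    }
  }

  structure(list(qc = qc, speciation = speciation,
                 fit_cr3 = fit_cr3, fit_lncr = fit_lncr,
                 budgets = budgets, ncp_cr3 = ncp_cr3,
                 selection = merged[sel, c("station", "depth_m")],
                 constants = constants),
            class = "cr_run")
}

isTRUE_v <- function(x) !is.na(x) & x

#' @export
print.cr_run <- function(x, ...) {
  cat("crseawater analysis run\n")
  cat("  QC groups:", nrow(x$qc), " (outliers rejected:",
      sum(x$qc$n_outliers), "of", sum(x$qc$n), "replicates)\n")
  cat("  speciation rows:", nrow(x$speciation),
      sprintf(" (median Cr(III) %% of total: %.1f)\n",
              stats::median(x$speciation$pct_cr3)))
  if (!is.null(x$fit_cr3))
    cat(sprintf("  Delta53Cr = %+.3f permil (intercept %.3f, r2 %.2f, n %d)\n",
                x$fit_cr3$delta_cap, x$fit_cr3$intercept, x$fit_cr3$r2,
                x$fit_cr3$n))
  if (!is.null(x$fit_lncr))
    cat(sprintf("  epsilon = %+.3f permil (r2 %.2f, n %d)\n",
                x$fit_lncr$epsilon, x$fit_lncr$r2, x$fit_lncr$n))
  if (!is.null(x$ncp_cr3))
    cat(sprintf("  euphotic Cr(III) ~ NCP: r2 %.2f (n %d)\n",
                x$ncp_cr3$r2, x$ncp_cr3$n))
  sig <- sum(isTRUE_v(x$budgets$significant))
  cat("  stations with significant Cr deficit:", sig, "of",
      nrow(x$budgets), "\n")
  invisible(x)
}

#' Write a machine-readable run report
#'
#' Serializes a [run_all()] result to a directory: `report.json` with the
#' fitted quantities and selections at full precision plus `qc.csv`,
#' `speciation.csv`, `budgets.csv`.
#'
#' @param run a `"cr_run"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fitj <- function(f) if (is.null(f)) NULL else
    f[c("slope", "intercept", "ci95_slope", "ci95_intercept", "r2", "n",
        "mode", if (f$mode == "cr3") c("delta_vi_nr", "delta_cap",
                                       "delta_cap_ci") else
          c("epsilon", "epsilon_ci"))]
  report <- list(fit_cr3 = fitj(run$fit_cr3), fit_lncr = fitj(run$fit_lncr),
                 ncp_cr3 = run$ncp_cr3, selection = run$selection,
                 constants = unclass(run$constants))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  qc <- run$qc; qc$outlier_mask <- NULL
  utils::write.csv(qc, file.path(dir, "qc.csv"), row.names = FALSE)
  utils::write.csv(run$speciation, file.path(dir, "speciation.csv"),
                   row.names = FALSE)
  utils::write.csv(run$budgets, file.path(dir, "budgets.csv"),
                   row.names = FALSE)
  invisible(dir)
}
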