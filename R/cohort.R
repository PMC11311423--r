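#' Analysis configuration
#'
#' Bundles the tunables of the cohort analysis. Defaults follow head-and-neck
#' contour-QA convention: a 2 mm surface-Dice tolerance, a 200 cGy absolute
#' clinical-objective difference to flag a pair (about 3 percent, or one
#' fraction, of a 69.96 Gy prescription), a 25 mm (2.5 cm) proximity cutoff
#' with 30 mm used in tabulations, 0.1-wide DSC/sDSC bins and 2 mm HD bins,
#' and D0.01cc as the near-maximum statistic.
#'
#' @param tolerance_mm sDSC tolerance (mm).
#' @param flag_threshold_cgy absolute flagging threshold on the
#'   clinical-objective difference (cGy).
#' @param proximity_cutoff_mm PTV proximity cutoff (mm).
#' @param table_cutoff_mm proximity cutoff used in per-organ tables (mm).
#' @param dsc_bin_width,sdsc_bin_width bin widths for flag-proportion curves.
#' @param hd_bin_width_mm HD bin width (mm).
#' @param dmax_volume_cc hot-volume criterion for D0.01cc (cc).
#' @param min_plan_dose_cgy optional inclusion filter: keep only patients
#'   prescribed at least this dose (e.g. 4000 cGy).
#' @param relative_threshold_pct optional: replace the absolute flag
#'   threshold with this percentage of each patient's prescription (e.g. 3
#'   or 5). At most one of the absolute/relative modes is active; setting
#'   this switches flagging to the relative rule.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(tolerance_mm = 2,
                            flag_threshold_cgy = 200,
                            proximity_cutoff_mm = 25,
                            table_cutoff_mm = 30,
                            dsc_bin_width = 0.1,
                            sdsc_bin_width = 0.1,
                            hd_bin_width_mm = 2,
                            dmax_volume_cc = 0.01,
                            min_plan_dose_cgy = NULL,
                            relative_threshold_pct = NULL) {
  stopifnot(tolerance_mm >= 0, flag_threshold_cgy > 0,
            proximity_cutoff_mm > 0, table_cutoff_mm > 0,
            dsc_bin_width > 0, sdsc_bin_width > 0, hd_bin_width_mm > 0,
            dmax_volume_cc > 0)
  if (!is.null(relative_threshold_pct) && relative_threshold_pct <= 0)
    stop("`relative_threshold_pct` must be positive")
  if (!is.null(min_plan_dose_cgy) && min_plan_dose_cgy <= 0)
    stop("`min_plan_dose_cgy` must be positive")
  structure(list(tolerance_mm = tolerance_mm,
                 flag_threshold_cgy = flag_threshold_cgy,
                 proximity_cutoff_mm = proximity_cutoff_mm,
                 table_cutoff_mm = table_cutoff_mm,
                 dsc_bin_width = dsc_bin_width,
                 sdsc_bin_width = sdsc_bin_width,
                 hd_bin_width_mm = hd_bin_width_mm,
                 dmax_volume_cc = dmax_volume_cc,
                 min_plan_dose_cgy = min_plan_dose_cgy,
                 relative_threshold_pct = relative_threshold_pct),
            class = "analysis_config")
}

evaluable_records <- function(records) {
  if (!"evaluable" %in% names(records)) return(records)
  records[records$evaluable %in% TRUE, , drop = FALSE]
}

#' Flag records exceeding the clinical-objective difference threshold
#'
#' A record is flagged when its absolute clinical-objective difference meets
#' the threshold (inclusive: a difference exactly at the threshold flags).
#' In absolute mode the threshold is `flag_threshold_cgy` for every record;
#' in relative mode it is `relative_threshold_pct`/100 of that record's
#' patient prescription, which must then be present.
#'
#' @param records record data.frame with `delta_dco_cgy` (and
#'   `prescription_cgy` for relative mode).
#' @param config an [analysis_config()].
#' @return `records` with `flagged` (logical; NA for unevaluable records) and
#'   `flag_threshold_used_cgy` columns set.
#' @export
flag_records <- function(records, config = analysis_config()) {
  stopifnot(is.data.frame(records), "delta_dco_cgy" %in% names(records))
  if (!is.null(config$relative_threshold_pct)) {
    if (!"prescription_cgy" %in% names(records) ||
        any(!is.finite(records$prescription_cgy[records$evaluable %in% TRUE])))
      stop("relative flagging mode requires a prescription for every patient")
    thr <- config$relative_threshold_pct / 100 * records$prescription_cgy
  } else {
    thr <- rep(config$flag_threshold_cgy, nrow(records))
  }
  records$flag_threshold_used_cgy <- thr
  records$flagged <- records$delta_dco_cgy >= thr
  records
}

q_linear <- function(x, p) {
  # linear interpolation between order statistics (R type 7), stated once
  # and used for every quantile in the package
  unname(stats::quantile(x, p, type = 7, na.rm = TRUE, names = FALSE))
}

#' Cohort summary: per-organ and pooled aggregates
#'
#' Produces the per-organ table (N; mean/SD of DSC, sDSC, HD; median and 90
#' percent quantile of the absolute Dmax and Dmean differences; flagged
#' count and fraction; fraction of flagged pairs within the table proximity
#' cutoff; min-max of flagged clinical-objective differences) and pooled
#' aggregates (coverage thresholds — the 10th percentile of DSC and sDSC and
#' the 90th of HD; fractions of pairs below the dose threshold; two-sided
#' Wilcoxon signed-rank p-values on the signed deltas; the identical-pair
#' fraction; and pooled plus per-organ R-squared for each geometric metric
#' against each absolute dose difference). All quantiles interpolate
#' linearly between order statistics; all dose quantiles are taken on
#' absolute differences.
#'
#' @param records flagged record data.frame (see [flag_records()]).
#' @param config an [analysis_config()].
#' @param organs organ labels to tabulate; organs absent from the cohort get
#'   an N = 0 row. Defaults to the organs present.
#' @return list of class `cohort_summary` with `organ_table` (data.frame),
#'   `pooled` (list), and `r2` (data.frame of pooled and per-organ fits).
#' @export
summarize_cohort <- function(records, config = analysis_config(),
                             organs = NULL) {
  ev <- evaluable_records(records)
  if (nrow(ev) == 0L) stop("no evaluable records to summarize")
  if (!"flagged" %in% names(ev)) ev <- flag_records(ev, config)
  if (is.null(organs)) organs <- sort(unique(ev$organ))

  one_organ <- function(org) {
    r <- ev[ev$organ == org, , drop = FALSE]
    n <- nrow(r)
    if (n == 0L)
      return(data.frame(organ = org, n = 0L, dco_kind = NA_character_,
                        dsc_mean = NA_real_, dsc_sd = NA_real_,
                        sdsc_mean = NA_real_, sdsc_sd = NA_real_,
                        hd_mean_mm = NA_real_, hd_sd_mm = NA_real_,
                        abs_ddmax_median_cgy = NA_real_, abs_ddmax_q90_cgy = NA_real_,
                        abs_ddmean_median_cgy = NA_real_, abs_ddmean_q90_cgy = NA_real_,
                        n_flagged = 0L, flagged_fraction = NA_real_,
                        n_flagged_within_table_cutoff = 0L,
                        flagged_within_table_cutoff_fraction = NA_real_,
                        flagged_dco_min_cgy = NA_real_,
                        flagged_dco_max_cgy = NA_real_))
    fl <- r[r$flagged %in% TRUE, , drop = FALSE]
    data.frame(
      organ = org, n = n, dco_kind = r$dco_kind[1],
      dsc_mean = mean(r$dsc), dsc_sd = stats::sd(r$dsc),
      sdsc_mean = mean(r$sdsc), sdsc_sd = stats::sd(r$sdsc),
      hd_mean_mm = mean(r$hd_mm), hd_sd_mm = stats::sd(r$hd_mm),
      abs_ddmax_median_cgy = q_linear(r$abs_delta_dmax_cgy, 0.5),
      abs_ddmax_q90_cgy = q_linear(r$abs_delta_dmax_cgy, 0.9),
      abs_ddmean_median_cgy = q_linear(r$abs_delta_dmean_cgy, 0.5),
      abs_ddmean_q90_cgy = q_linear(r$abs_delta_dmean_cgy, 0.9),
      n_flagged = nrow(fl), flagged_fraction = nrow(fl) / n,
      n_flagged_within_table_cutoff =
        sum(fl$distance_to_ptv_mm <= config$table_cutoff_mm),
      flagged_within_table_cutoff_fraction =
        if (nrow(fl) > 0)
          sum(fl$distance_to_ptv_mm <= config$table_cutoff_mm) / nrow(fl)
        else NA_real_,
      flagged_dco_min_cgy = if (nrow(fl) > 0) min(fl$delta_dco_cgy) else NA_real_,
      flagged_dco_max_cgy = if (nrow(fl) > 0) max(fl$delta_dco_cgy) else NA_real_)
  }
  organ_table <- do.call(rbind, lapply(organs, one_organ))
  rownames(organ_table) <- NULL

  thr <- config$flag_threshold_cgy
  is_max <- ev$dco_kind == "max"
  pooled <- list(
    n = nrow(ev),
    identical_fraction = mean(ev$identical_pair),
    dsc_p10 = q_linear(ev$dsc, 0.10),
    sdsc_p10 = q_linear(ev$sdsc, 0.10),
    hd_p90_mm = q_linear(ev$hd_mm, 0.90),
    frac_abs_ddmax_below_threshold = mean(ev$abs_delta_dmax_cgy < thr),
    frac_abs_ddmean_below_threshold = mean(ev$abs_delta_dmean_cgy < thr),
    frac_dco_max_below_threshold =
      if (any(is_max)) mean(ev$delta_dco_cgy[is_max] < thr) else NA_real_,
    frac_dco_mean_below_threshold =
      if (any(!is_max)) mean(ev$delta_dco_cgy[!is_max] < thr) else NA_real_,
    n_flagged = sum(ev$flagged),
    flagged_fraction = mean(ev$flagged),
    wilcoxon_p_dmax = wilcoxon_signed(ev$delta_dmax_cgy)$p,
    wilcoxon_p_dmean = wilcoxon_signed(ev$delta_dmean_cgy)$p)

  metrics <- c(dsc = "dsc", sdsc = "sdsc", hd = "hd_mm")
  deltas <- c(abs_ddmax = "abs_delta_dmax_cgy", abs_ddmean = "abs_delta_dmean_cgy")
  r2_rows <- list()
  for (org in c("(pooled)", organs)) {
    r <- if (org == "(pooled)") ev else ev[ev$organ == org, , drop = FALSE]
    for (mi in seq_along(metrics)) for (di in seq_along(deltas)) {
      val <- if (nrow(r) >= 3L)
        suppressMessages(linear_r2(r[[metrics[mi]]], r[[deltas[di]]]))
      else NA_real_
      r2_rows[[length(r2_rows) + 1L]] <-
        data.frame(organ = org, metric = names(metrics)[mi],
                   delta = names(deltas)[di], n = nrow(r), r2 = val)
    }
  }
  r2 <- do.call(rbind, r2_rows)
  rownames(r2) <- NULL

  structure(list(organ_table = organ_table, pooled = pooled, r2 = r2,
                 config = config),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("<cohort_summary> %d pairs (%.0f%% identical), %d flagged (%.1f%%)\n",
              p$n, 100 * p$identical_fraction, p$n_flagged,
              100 * p$flagged_fraction))
  cat(sprintf("  coverage: DSC p10 %.3f | sDSC p10 %.3f | HD p90 %.2f mm\n",
              p$dsc_p10, p$sdsc_p10, p$hd_p90_mm))
  cat(sprintf("  |dDmax| < thr: %.1f%% | |dDmean| < thr: %.1f%% | Wilcoxon p: %.3g / %.3g\n",
              100 * p$frac_abs_ddmax_below_threshold,
              100 * p$frac_abs_ddmean_below_threshold,
              p$wilcoxon_p_dmax, p$wilcoxon_p_dmean))
  cat(sprintf("  organs tabulated: %d\n", nrow(x$organ_table)))
  invisible(x)
}

#' Flag-proportion curve over binned geometric agreement
#'
#' Bins records by one geometric metric — DSC and sDSC at every 0.1, HD at
#' every 2 mm by default — and reports the flagged fraction per bin. Bins
#' are half-open `[lo, lo + w)`; the final DSC/sDSC bin is closed at 1.0 so
#' perfect agreement lands in the top bin. Empty bins are kept with an NA
#' fraction so curves from different cohorts align.
#'
#' @param records flagged record data.frame.
#' @param metric `"dsc"`, `"sdsc"` or `"hd"`.
#' @param config an [analysis_config()].
#' @return data.frame with `bin_lo`, `bin_hi`, `bin_mid`, `n`, `n_flagged`,
#'   `flagged_fraction` (NA for empty bins).
#' @export
binned_flag_proportions <- function(records, metric = c("dsc", "sdsc", "hd"),
                                    config = analysis_config()) {
  metric <- match.arg(metric)
  ev <- evaluable_records(records)
  stopifnot("flagged" %in% names(ev))
  if (metric == "hd") {
    x <- ev$hd_mm
    w <- config$hd_bin_width_mm
    lo <- seq(0, floor(max(x) / w) * w, by = w)
    edges <- c(lo, max(lo) + w)
    idx <- findInterval(x, edges, rightmost.closed = FALSE)
  } else {
    x <- ev[[metric]]
    w <- if (metric == "dsc") config$dsc_bin_width else config$sdsc_bin_width
    edges <- round(seq(0, 1, by = w), 12)
    if (abs(edges[length(edges)] - 1) > 1e-12) edges <- c(edges, 1)
    # [lo, hi) bins, final bin closed at 1.0
    idx <- findInterval(x, edges, rightmost.closed = TRUE)
  }
  nb <- length(edges) - 1L
  idx <- pmin(pmax(idx, 1L), nb)
  n <- tabulate(idx, nbins = nb)
  nf <- tabulate(idx[ev$flagged %in% TRUE], nbins = nb)
  data.frame(metric = metric,
             bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
             n = n, n_flagged = nf,
             flagged_fraction = ifelse(n > 0, nf / n, NA_real_))
}

#' Proximity stratification of flagged records
#'
#' Among flagged records: the fraction within the proximity cutoff of the
#' nearest PTV, plus the same breakdown restricted to high-geometric-
#' agreement subsets (DSC > 0.90; and sDSC > 0.90 or HD < 5 mm) — the
#' regimes where geometric indices alone would *not* have raised concern.
#'
#' @param records flagged record data.frame with distances computed.
#' @param config an [analysis_config()].
#' @return list of class `proximity_stratification`: `cutoff_mm`,
#'   `n_flagged`, overall `n_within`/`fraction_within`, and `high_dsc` /
#'   `high_sdsc_or_low_hd` sublists (`n`, `n_within`, `fraction_within`,
#'   NA fractions when the stratum is empty).
#' @export
proximity_stratified_flags <- function(records, config = analysis_config()) {
  ev <- evaluable_records(records)
  stopifnot(all(c("flagged", "distance_to_ptv_mm") %in% names(ev)))
  fl <- ev[ev$flagged %in% TRUE, , drop = FALSE]
  cutoff <- config$proximity_cutoff_mm
  stratum <- function(r) {
    n <- nrow(r)
    nw <- sum(r$distance_to_ptv_mm <= cutoff)
    list(n = n, n_within = nw,
         fraction_within = if (n > 0) nw / n else NA_real_)
  }
  structure(list(cutoff_mm = cutoff,
                 n_flagged = nrow(fl),
                 n_within = stratum(fl)$n_within,
                 fraction_within = stratum(fl)$fraction_within,
                 high_dsc = stratum(fl[fl$dsc > 0.90, , drop = FALSE]),
                 high_sdsc_or_low_hd =
                   stratum(fl[fl$sdsc > 0.90 | fl$hd_mm < 5, , drop = FALSE])),
            class = "proximity_stratification")
}

#' @export
print.proximity_stratification <- function(x, ...) {
  cat(sprintf("<proximity_stratification> %d flagged; %s within %.0f mm\n",
              x$n_flagged,
              if (x$n_flagged > 0)
                sprintf("%d (%.0f%%)", x$n_within, 100 * x$fraction_within)
              else "none",
              x$cutoff_mm))
  invisible(x)
}

#' Sensitivity scenarios: inclusion filter and prescription-relative thresholds
#'
#' Re-runs flagging and summaries under (a) an inclusion filter keeping only
#' patients prescribed at least `min_plan_dose_cgy` (default 4000 cGy, i.e.
#' 40 Gy) with the absolute threshold, and (b) prescription-relative
#' thresholds of 3 and 5 percent, alongside the baseline absolute rule.
#'
#' @param records record data.frame with prescriptions present.
#' @param config baseline [analysis_config()].
#' @param min_plan_dose_cgy inclusion filter for scenario (a).
#' @param relative_pcts relative thresholds for scenario family (b).
#' @return list of class `sensitivity_result`: `scenarios` (named list, each
#'   with `config`, `summary`, `n`, `flagged_fraction`) and `comparison`
#'   (data.frame of scenario, n, n_flagged, flagged_fraction).
#' @export
sensitivity_run <- function(records, config = analysis_config(),
                            min_plan_dose_cgy = 4000,
                            relative_pcts = c(3, 5)) {
  ev <- evaluable_records(records)
  if (any(!is.finite(ev$prescription_cgy)))
    stop("sensitivity analysis requires prescriptions for all patients")
  organs <- sort(unique(ev$organ))

  run_one <- function(recs, cfg) {
    recs <- flag_records(recs, cfg)
    list(config = cfg, summary = summarize_cohort(recs, cfg, organs = organs),
         n = nrow(recs), n_flagged = sum(recs$flagged),
         flagged_fraction = mean(recs$flagged))
  }
  scenarios <- list(baseline = run_one(ev, config))
  cfg_incl <- config
  cfg_incl$min_plan_dose_cgy <- min_plan_dose_cgy
  scenarios$min_plan_dose <-
    run_one(ev[ev$prescription_cgy >= min_plan_dose_cgy, , drop = FALSE],
            cfg_incl)
  for (pct in relative_pcts) {
    cfg_rel <- config
    cfg_rel$relative_threshold_pct <- pct
    scenarios[[sprintf("relative_%gpct", pct)]] <- run_one(ev, cfg_rel)
  }
  comparison <- do.call(rbind, lapply(names(scenarios), function(nm)
    data.frame(scenario = nm, n = scenarios[[nm]]$n,
               n_flagged = scenarios[[nm]]$n_flagged,
               flagged_fraction = scenarios[[nm]]$flagged_fraction)))
  rownames(comparison) <- NULL
  structure(list(scenarios = scenarios, comparison = comparison),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result>\n")
  print(x$comparison)
  invisible(x)
}
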