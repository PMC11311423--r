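## End-to-end pipeline: manifest -> per-pair records -> flags -> summaries.

record_row_skeleton <- function(patient, organ, rx) {
  data.frame(patient = patient, organ = organ,
             dsc = NA_real_, sdsc = NA_real_, hd_mm = NA_real_,
             tolerance_mm = NA_real_, identical_pair = NA,
             auto_dmax_cgy = NA_real_, auto_dmean_cgy = NA_real_,
             auto_volume_cc = NA_real_,
             clinical_dmax_cgy = NA_real_, clinical_dmean_cgy = NA_real_,
             clinical_volume_cc = NA_real_,
             delta_dmax_cgy = NA_real_, delta_dmean_cgy = NA_real_,
             abs_delta_dmax_cgy = NA_real_, abs_delta_dmean_cgy = NA_real_,
             dco_kind = NA_character_, delta_dco_cgy = NA_real_,
             distance_to_ptv_mm = NA_real_, nearest_ptv = NA_character_,
             within_cutoff = NA, flagged = NA,
             prescription_cgy = rx, evaluable = FALSE,
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Evaluate one auto/clinical contour pair against a dose grid and PTVs
#'
#' Computes the geometric agreement, dose statistics under the shared dose
#' grid, and PTV proximity for a single pair, returning one record row.
#' Pairs with an empty mask are returned unevaluable (with the reason) rather
#' than erroring, so a cohort run survives degenerate structures.
#'
#' @param patient patient id.
#' @param organ organ label.
#' @param auto,clinical [structure_mask()] objects on one grid.
#' @param dose [dose_grid()] already resampled to the mask grid.
#' @param ptvs list of PTV [structure_mask()] objects on the same grid.
#' @param prescription_cgy plan prescription (cGy; NA allowed).
#' @param config an [analysis_config()].
#' @param policy organ-to-D_CO mapping.
#' @return one-row data.frame (see [write_records()] for the schema).
#' @export
evaluate_oar_pair <- function(patient, organ, auto, clinical, dose, ptvs,
                              prescription_cgy = NA_real_,
                              config = analysis_config(),
                              policy = organ_policy()) {
  row <- record_row_skeleton(patient, organ, prescription_cgy)
  dm <- evaluate_pair(dose, auto, clinical, policy = policy,
                      volume_cc = config$dmax_volume_cc)
  if (!isTRUE(dm$evaluable)) {
    row$reason <- dm$reason
    return(row)
  }
  geo <- compare_pair(auto, clinical, tolerance_mm = config$tolerance_mm)
  prox <- distance_to_ptv(clinical, ptvs)
  row$dsc <- geo$dsc; row$sdsc <- geo$sdsc; row$hd_mm <- geo$hd_mm
  row$tolerance_mm <- geo$tolerance_mm; row$identical_pair <- geo$identical
  row$auto_dmax_cgy <- dm$auto$dmax_cgy
  row$auto_dmean_cgy <- dm$auto$dmean_cgy
  row$auto_volume_cc <- dm$auto$volume_cc
  row$clinical_dmax_cgy <- dm$clinical$dmax_cgy
  row$clinical_dmean_cgy <- dm$clinical$dmean_cgy
  row$clinical_volume_cc <- dm$clinical$volume_cc
  row$delta_dmax_cgy <- dm$delta_dmax_cgy
  row$delta_dmean_cgy <- dm$delta_dmean_cgy
  row$abs_delta_dmax_cgy <- dm$abs_delta_dmax_cgy
  row$abs_delta_dmean_cgy <- dm$abs_delta_dmean_cgy
  row$dco_kind <- dm$dco_kind; row$delta_dco_cgy <- dm$delta_dco_cgy
  row$distance_to_ptv_mm <- prox$distance_mm
  row$nearest_ptv <- prox$nearest_ptv
  row$within_cutoff <- prox$distance_mm <= config$proximity_cutoff_mm
  row$evaluable <- TRUE
  row
}

#' Run the full cohort analysis from a manifest
#'
#' For each patient: reads the dose grid and masks, resamples the dose to
#' the contour grid once (shared by both contour sets), evaluates every
#' auto/clinical pair geometrically and dosimetrically, measures PTV
#' proximity, applies the flagging rule, and assembles the cohort summaries,
#' the binned flag-proportion curves for DSC/sDSC/HD, and the proximity
#' stratification of flagged records.
#'
#' @param manifest a `cohort_manifest` or path to a manifest JSON.
#' @param config an [analysis_config()].
#' @param verbose print per-patient progress.
#' @return list of class `cohort_results`: `records` (data.frame), `summary`
#'   ([summarize_cohort()]), `curves` (named list of
#'   [binned_flag_proportions()] frames), `stratification`
#'   ([proximity_stratified_flags()]), `config`, and `n_unevaluable`.
#' @export
run_cohort <- function(manifest, config = analysis_config(), verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "cohort_manifest"))
  policy <- organ_policy()
  rows <- list()
  for (p in manifest$patients) {
    if (verbose)
      message(sprintf("patient %s: %d OAR pair(s)", p$id, length(p$oars)))
    if (!is.null(config$min_plan_dose_cgy) &&
        (!is.finite(p$prescription_cgy) ||
         p$prescription_cgy < config$min_plan_dose_cgy)) {
      if (verbose)
        message(sprintf("  excluded (prescription %s < %s cGy)",
                        p$prescription_cgy, config$min_plan_dose_cgy))
      next
    }
    dose <- read_dose(p$dose)
    ptvs <- lapply(names(p$ptvs), function(nm) read_mask(p$ptvs[[nm]], nm))
    # one dose resampling per contour lattice, shared by both contour sets
    dose_cache <- list()
    grid_key <- function(g) paste(c(g$dims, signif(g$spacing, 12),
                                    signif(g$origin, 12)), collapse = ",")
    for (organ in names(p$oars)) {
      auto <- read_mask(p$oars[[organ]]$auto, organ)
      clinical <- read_mask(p$oars[[organ]]$clinical, organ)
      key <- grid_key(clinical$grid)
      if (is.null(dose_cache[[key]]))
        dose_cache[[key]] <- interpolate_dose_to_grid(dose, clinical$grid)
      dose_on_grid <- dose_cache[[key]]
      row <- evaluate_oar_pair(p$id, organ, auto, clinical, dose_on_grid,
                               ptvs, p$prescription_cgy, config, policy)
      if (verbose && !isTRUE(row$evaluable))
        message(sprintf("  unevaluable %s: %s", organ, row$reason))
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) stop("no contour pairs evaluated")
  records <- do.call(rbind, rows)
  records <- flag_records(records, config)
  records <- classify_proximity_keep_na(records, config$proximity_cutoff_mm)
  summary <- summarize_cohort(records, config)
  curves <- list(dsc = binned_flag_proportions(records, "dsc", config),
                 sdsc = binned_flag_proportions(records, "sdsc", config),
                 hd = binned_flag_proportions(records, "hd", config))
  strat <- proximity_stratified_flags(records, config)
  structure(list(records = records, summary = summary, curves = curves,
                 stratification = strat, config = config,
                 n_unevaluable = sum(!records$evaluable)),
            class = "cohort_results")
}

classify_proximity_keep_na <- function(records, cutoff_mm) {
  records$within_cutoff <-
    ifelse(is.na(records$distance_to_ptv_mm), NA,
           records$distance_to_ptv_mm <= cutoff_mm)
  records
}

#' @export
print.cohort_results <- function(x, ...) {
  cat(sprintf("<cohort_results> %d records (%d unevaluable)\n",
              nrow(x$records), x$n_unevaluable))
  print(x$summary)
  invisible(x)
}

#' Write cohort results to a directory
#'
#' Writes `records.csv` (per-pair rows), `summary.json` (organ table, pooled
#' aggregates, R-squared fits, stratification), and one
#' `curve_<metric>.csv` per binned flag-proportion curve.
#'
#' @param results a `cohort_results` from [run_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_results <- function(results, out_dir) {
  stopifnot(inherits(results, "cohort_results"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_records(results$records, file.path(out_dir, "records.csv"))
  s <- results$summary
  jsonlite::write_json(
    list(pooled = s$pooled,
         organ_table = s$organ_table,
         r2 = s$r2,
         stratification = unclass(results$stratification),
         n_unevaluable = results$n_unevaluable,
         config = unclass(results$config)),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  for (nm in names(results$curves))
    utils::write.csv(results$curves[[nm]],
                     file.path(out_dir, sprintf("curve_%s.csv", nm)),
                     row.names = FALSE)
  invisible(out_dir)
}
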