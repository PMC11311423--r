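#' The controlled vocabulary of head-and-neck organs-at-risk
#'
#' Nineteen OARs: brain, brainstem, cochleas, esophagus, eyes, submandibular
#' glands, larynx, lenses, optic chiasm, optic nerves, parotids, spinal cord
#' and vertebral column, with `_l`/`_r` laterality suffixes where the organ
#' is paired.
#'
#' @return character vector of the 19 organ labels.
#' @export
oar_vocabulary <- function() {
  c("brain", "brainstem", "cochlea_l", "cochlea_r", "esophagus",
    "eye_l", "eye_r", "glnd_submand_l", "glnd_submand_r", "larynx",
    "lens_l", "lens_r", "optic_chiasm", "optic_nerve_l", "optic_nerve_r",
    "parotid_l", "parotid_r", "spinal_cord", "vertebral_column")
}

#' Organ-specific clinical-objective dose kind
#'
#' Clinical objective criteria for head-and-neck plans constrain most OARs by
#' the near-maximum dose D0.01cc ("max") and the larynx, submandibular glands
#' and parotids by the mean dose ("mean"). `organ_policy()` returns that
#' mapping; unknown organ names default to "max" with a warning, so synthetic
#' or nonstandard labels still evaluate.
#'
#' @return named character vector mapping organ label to `"max"` or `"mean"`.
#' @export
organ_policy <- function() {
  vocab <- oar_vocabulary()
  kind <- rep("max", length(vocab))
  names(kind) <- vocab
  kind[c("larynx", "glnd_submand_l", "glnd_submand_r",
         "parotid_l", "parotid_r")] <- "mean"
  kind
}

#' Look up the D_CO kind for one organ
#'
#' @param organ organ label.
#' @param policy a mapping as returned by [organ_policy()].
#' @return `"max"` or `"mean"`.
#' @export
dco_kind_for <- function(organ, policy = organ_policy()) {
  if (organ %in% names(policy)) return(unname(policy[[organ]]))
  warning(sprintf("organ '%s' not in policy; defaulting its clinical objective to D0.01cc (max)",
                  organ))
  "max"
}

#' Read a cohort manifest from JSON
#'
#' The manifest lists, per patient: an id, the plan prescription in cGy, the
#' dose-grid path, one or more named PTV mask paths, and per-OAR pairs of
#' auto/clinical mask paths. Relative paths are resolved against the manifest
#' file's directory.
#'
#' @param path path to the manifest JSON.
#' @return a `cohort_manifest`: list with element `patients`, each entry a
#'   list with `id`, `prescription_cgy`, `dose`, `ptvs` (named list of
#'   paths), and `oars` (named list of `list(auto=, clinical=)` paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$patients) || length(raw$patients) == 0L)
    stop("manifest has no patients")
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    p <- as.character(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  vocab <- oar_vocabulary()
  patients <- lapply(raw$patients, function(p) {
    if (is.null(p$id) || is.null(p$dose) || is.null(p$ptvs) ||
        is.null(p$oars))
      stop("each manifest patient needs id, dose, ptvs and oars")
    rx <- if (is.null(p$prescription_cgy)) NA_real_ else
      as.numeric(p$prescription_cgy)
    oars <- lapply(p$oars, function(o) {
      if (is.null(o$auto) || is.null(o$clinical))
        stop(sprintf("patient '%s': every OAR entry needs both an auto and a clinical mask path",
                     p$id))
      list(auto = resolve(o$auto), clinical = resolve(o$clinical))
    })
    unknown <- setdiff(names(oars), vocab)
    if (length(unknown))
      warning(sprintf("patient '%s': organ name(s) outside the 19-OAR vocabulary: %s",
                      p$id, paste(unknown, collapse = ", ")))
    list(id = as.character(p$id), prescription_cgy = rx,
         dose = resolve(p$dose),
         ptvs = lapply(p$ptvs, resolve),
         oars = oars)
  })
  structure(list(patients = patients), class = "cohort_manifest")
}

#' Write a cohort manifest to JSON
#'
#' @param manifest a `cohort_manifest` (see [read_manifest()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(list(patients = manifest$patients), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

## Canonical column order of the per-pair record table.
record_columns <- function() {
  c("patient", "organ", "dsc", "sdsc", "hd_mm", "tolerance_mm",
    "identical_pair",
    "auto_dmax_cgy", "auto_dmean_cgy", "auto_volume_cc",
    "clinical_dmax_cgy", "clinical_dmean_cgy", "clinical_volume_cc",
    "delta_dmax_cgy", "delta_dmean_cgy",
    "abs_delta_dmax_cgy", "abs_delta_dmean_cgy",
    "dco_kind", "delta_dco_cgy",
    "distance_to_ptv_mm", "nearest_ptv", "within_cutoff",
    "flagged", "prescription_cgy", "evaluable", "reason")
}

#' Write per-pair OAR records to CSV
#'
#' One row per auto/clinical contour pair: patient and organ, the geometric
#' agreement (DSC, sDSC, HD), dose statistics for both contours, signed and
#' absolute dose deltas, the clinical-objective delta and its kind, distance
#' to the closest PTV, and the flag state. Numeric fields are written at
#' full double precision so a read-back reproduces them exactly.
#'
#' @param records a data.frame of records as produced by [run_cohort()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_records <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame")
  cols <- intersect(record_columns(), names(records))
  out <- records[, c(cols, setdiff(names(records), cols)), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read per-pair OAR records back from CSV
#'
#' @param path CSV written by [write_records()].
#' @return data.frame of records with numeric/logical types restored.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  logical_cols <- intersect(c("identical_pair", "within_cutoff", "flagged",
                              "evaluable"), names(df))
  for (cl in logical_cols) df[[cl]] <- as.logical(df[[cl]])
  df
}
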