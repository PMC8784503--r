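#' Process one PET/CT scan end to end
#'
#' Runs the full quantification sequence: Poisson denoising, CT-based (or
#' manual) LV localization, ellipsoidal VOI segmentation, reorientation to
#' the standard cardiac axes, short-axis ring extraction and polar-map
#' assembly, AHA-17 aggregation, and the scalar LV metrics. Every default
#' and manual override that affects the numbers is recorded in the
#' provenance log.
#'
#' @param pet a `scalar_volume` (SUV or Bq/mL), or a NIfTI path readable by
#'   [read_pet_scan()].
#' @param ct optional `scalar_volume` in HU (or NIfTI path) for automatic
#'   localization; may be omitted when `center` or `ellipsoid` is given.
#' @param meta an `acquisition_meta`, required when `pet` is in Bq/mL and
#'   not read from a sidecar.
#' @param center optional numeric(3) manual LV centre (mm); bypasses CT
#'   localization.
#' @param ellipsoid optional [ellipsoid_voi()]; default built from the
#'   localized/manual centre and `voi_semi_axes`.
#' @param voi_semi_axes default VOI semi-axes (mm) when `ellipsoid` is not
#'   given; generous enough to enclose a dilated LV while excluding distant
#'   structures.
#' @param angles optional numeric(2) `c(theta_hla, theta_vla)` in degrees;
#'   `NULL` uses the principal-axis initializer ([estimate_orientation()]).
#' @param smoothing_mm denoising scale; 0 disables.
#' @param lung_hu_threshold,pad_mm passed to [localize_lv()].
#' @param masks optional per-slice manual myocardial masks for
#'   [build_polar_map()].
#' @param territory_metric,apex_in_lad passed to the metrics layer.
#' @param patient_id,stage identifiers copied into the metrics row
#'   (`stage` should be one of `"staging"`, `"interim"`, `"eot"`).
#' @param out_dir optional output directory; when given, writes
#'   `metrics.csv`, `segments.csv`, `polar_map.csv`, `polar_map.png` and
#'   `provenance.log`.
#' @return A list of class `lv_scan_result`: `metrics` (one-row
#'   data.frame), `segments`, `polar_map`, `oriented`, `localization`,
#'   `provenance` (character vector).
#' @export
process_scan <- function(pet, ct = NULL, meta = NULL,
                         center = NULL, ellipsoid = NULL,
                         voi_semi_axes = c(55, 55, 75),
                         angles = NULL, smoothing_mm = 2,
                         lung_hu_threshold = -400, pad_mm = 20,
                         masks = NULL,
                         territory_metric = "mean", apex_in_lad = TRUE,
                         patient_id = "anon", stage = NA_character_,
                         out_dir = NULL) {
  prov <- character()
  note <- function(...) prov <<- c(prov, paste0(format(Sys.time(),
                                                       "%Y-%m-%d %H:%M:%S "),
                                                paste0(...)))
  stage_try <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  if (is.character(pet)) {
    sc <- stage_try("load", read_pet_scan(pet))
    note("loaded PET from ", pet)
    meta <- sc$meta
    pet <- sc$volume
  }
  if (is.character(ct)) {
    ct <- stage_try("load", read_ct_scan(ct))
    note("loaded CT")
  }
  stopifnot(inherits(pet, "scalar_volume"))
  if (pet$unit != "SUV") {
    if (is.null(meta))
      stop("[suv] PET is not in SUV and no acquisition metadata was given")
    pet <- stage_try("suv", compute_suv(pet, meta))
    note("converted activity to body-weight SUV (decay-corrected dose)")
  }
  if (smoothing_mm > 0) {
    pet <- stage_try("denoise", denoise_poisson(pet, smoothing_mm))
    note("Poisson denoising, smoothing scale ", smoothing_mm, " mm")
  } else note("denoising disabled")
  loc <- NULL
  if (is.null(ellipsoid)) {
    if (!is.null(center)) {
      loc <- localize_lv(if (is.null(ct)) pet else ct,
                         center_override = center, pad_mm = pad_mm)
      note("manual LV centre override: ",
           paste(signif(center, 5), collapse = ", "), " mm")
    } else {
      if (is.null(ct))
        stop("[localize] no CT and no manual centre: cannot localize the LV")
      loc <- stage_try("localize",
                       localize_lv(ct, lung_hu_threshold, pad_mm))
      note("automatic CT localization, centre ",
           paste(signif(loc$center_mm, 5), collapse = ", "), " mm")
    }
    ellipsoid <- ellipsoid_voi(loc$center_mm, voi_semi_axes)
    note("VOI ellipsoid semi-axes ",
         paste(voi_semi_axes, collapse = ", "), " mm")
  } else {
    note("user-supplied VOI ellipsoid")
  }
  mv <- stage_try("voi", apply_voi(pet, ellipsoid))
  if (is.null(angles)) {
    angles <- stage_try("orient", estimate_orientation(mv))
    note("principal-axis orientation estimate: theta_hla=",
         signif(angles[1], 4), " deg, theta_vla=", signif(angles[2], 4),
         " deg")
  } else {
    note("user-supplied angles: ", paste(signif(angles, 4), collapse = ", "),
         " deg")
  }
  olv <- stage_try("orient", orient_lv(mv, angles[1], angles[2]))
  pm <- stage_try("polar_map", build_polar_map(olv, masks = masks))
  if (length(pm$provenance$manual_masks))
    note("manual myocardial masks on slice(s) ",
         paste(pm$provenance$manual_masks, collapse = ", "))
  note("polar map: ", pm$n_rings, " rings + ", pm$n_cap,
       " apex-cap bins; basal slices truncated: ",
       pm$provenance$truncated_slices)
  segs <- stage_try("segments", aggregate_segments(pm))
  met <- stage_try("metrics",
                   lv_metrics(segs, territory_metric = territory_metric,
                              apex_in_lad = apex_in_lad))
  note("territory metric: ", territory_metric, "; apex in LAD: ",
       apex_in_lad)
  metrics <- cbind(data.frame(patient_id = patient_id, stage = stage,
                              stringsAsFactors = FALSE),
                   seg_table_wide(segs), met)
  res <- structure(list(metrics = metrics, segments = segs, polar_map = pm,
                        oriented = olv, localization = loc,
                        provenance = prov),
                   class = "lv_scan_result")
  if (!is.null(out_dir)) write_scan_outputs(res, out_dir)
  res
}

seg_table_wide <- function(segs) {
  w <- as.data.frame(as.list(c(
    setNames(segs$suv_mean, paste0("seg", segs$segment, "_mean")),
    setNames(segs$suv_max, paste0("seg", segs$segment, "_max")))))
  w
}

write_scan_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(res$segments, file.path(out_dir, "segments.csv"),
            row.names = FALSE)
  export_polar_map(res$polar_map, file.path(out_dir, "polar_map.csv"))
  grDevices::png(file.path(out_dir, "polar_map.png"), width = 600,
                 height = 600)
  plot_polar_map(res$polar_map)
  grDevices::dev.off()
  writeLines(res$provenance, file.path(out_dir, "provenance.log"))
  invisible(out_dir)
}

#' Longitudinal cohort statistics over per-scan LV metrics
#'
#' For each chemotherapy regimen with enough complete patients, and for the
#' combined (`"Both"`) group, runs per metric: the Friedman test across the
#' three scan stages, Bonferroni-adjusted Wilcoxon signed-rank post-hoc
#' pairs, and point-biserial correlations for the staging-to-interim and
#' interim-to-EOT transitions (later scan coded 1, so positive r = higher
#' at the later scan). Patients missing any stage are dropped with a
#' warning (the design requires all three scans); groups with fewer than 2
#' complete patients are skipped with a warning.
#'
#' @param records data.frame with columns `patient_id`, `regimen`, `stage`
#'   (values `staging`, `interim`, `eot`) and numeric metric columns.
#' @param metrics metric column names; default = all numeric columns.
#' @param alpha familywise level for the post-hoc flags.
#' @param exact_friedman use the exact Friedman permutation p (small n).
#' @param out_dir optional directory; writes `cohort_summary.csv`,
#'   `cohort_tests.csv`, `cohort_posthoc.csv`, `cohort_correlations.csv`
#'   and `cohort_report.json`.
#' @return A list of class `cohort_report`: `summary`, `tests`, `posthoc`,
#'   `correlations` (tibbles).
#' @export
run_cohort <- function(records, metrics = NULL, alpha = 0.05,
                       exact_friedman = FALSE, out_dir = NULL) {
  stopifnot(all(c("patient_id", "regimen", "stage") %in% names(records)))
  stages <- c("staging", "interim", "eot")
  if (!all(records$stage %in% stages))
    stop("`stage` must be one of: ", paste(stages, collapse = ", "))
  if (is.null(metrics))
    metrics <- names(records)[vapply(records, is.numeric, TRUE)]
  if (!length(metrics)) stop("no metric columns")
  groups <- c(as.list(unique(as.character(records$regimen))), list("Both"))
  tests <- list(); posthoc <- list(); cors <- list()
  for (g in groups) {
    sub <- if (identical(g, "Both")) records
           else records[records$regimen == g, ]
    complete <- names(which(table(sub$patient_id) == 3))
    dropped <- setdiff(unique(sub$patient_id), complete)
    if (length(dropped))
      warning("group ", g, ": dropping patient(s) without all three scans: ",
              paste(dropped, collapse = ", "))
    sub <- sub[sub$patient_id %in% complete, ]
    n <- length(complete)
    if (n < 2) {
      warning("group ", g, ": fewer than 2 complete patients; skipped")
      next
    }
    for (mname in metrics) {
      X <- sapply(stages, function(s) {
        v <- sub[sub$stage == s, ]
        v[[mname]][match(complete, v$patient_id)]
      })
      ft <- friedman_test(X, exact = exact_friedman)
      tests[[length(tests) + 1]] <- tibble::tibble(
        group = g, metric = mname, n = n,
        friedman_chisq = unname(ft$statistic),
        friedman_df = unname(ft$parameter),
        friedman_p = ft$p.value)
      ph <- posthoc_pairwise(X, alpha = alpha)
      posthoc[[length(posthoc) + 1]] <-
        tibble::tibble(group = g, metric = mname, ph)
      for (tr in list(c("staging", "interim"), c("interim", "eot"))) {
        vals <- c(X[, tr[1]], X[, tr[2]])
        labs <- factor(rep(tr, each = n), levels = tr)
        pb <- tryCatch(point_biserial(vals, labs), error = function(e) NULL)
        cors[[length(cors) + 1]] <- tibble::tibble(
          group = g, metric = mname,
          transition = paste(tr, collapse = " -> "),
          r = if (is.null(pb)) NA_real_ else unname(pb$estimate),
          p = if (is.null(pb)) NA_real_ else pb$p.value)
      }
    }
  }
  if (!length(tests)) stop("no group had at least 2 complete patients")
  rep_ <- structure(list(summary = summarize_cohort(records,
                                                    metrics = metrics),
                         tests = dplyr::bind_rows(tests),
                         posthoc = dplyr::bind_rows(posthoc),
                         correlations = dplyr::bind_rows(cors)),
                    class = "cohort_report")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(rep_$summary, file.path(out_dir, "cohort_summary.csv"),
              row.names = FALSE)
    write.csv(rep_$tests, file.path(out_dir, "cohort_tests.csv"),
              row.names = FALSE)
    write.csv(rep_$posthoc, file.path(out_dir, "cohort_posthoc.csv"),
              row.names = FALSE)
    write.csv(rep_$correlations,
              file.path(out_dir, "cohort_correlations.csv"),
              row.names = FALSE)
    jsonlite::write_json(lapply(rep_[c("tests", "posthoc", "correlations")],
                                as.data.frame),
                         file.path(out_dir, "cohort_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  rep_
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat("Friedman tests:\n"); print(x$tests)
  cat("Point-biserial correlations:\n"); print(x$correlations)
  invisible(x)
}
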