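check_segments <- function(segs, ids) {
  bad <- ids[!is.finite(segs$suv_mean[match(ids, segs$segment)]) |
               segs$n_cells[match(ids, segs$segment)] == 0]
  if (length(bad))
    stop("segment(s) without valid cells: ", paste(bad, collapse = ", "))
}

weighted_segment_mean <- function(segs, ids) {
  i <- match(ids, segs$segment)
  sum(segs$n_cells[i] * segs$suv_mean[i]) / sum(segs$n_cells[i])
}

#' Global myocardial SUVmean
#'
#' Count-weighted average of the segmental SUVmean over segments 1-16; the
#' apex (segment 17) is excluded because its polar-map construction differs
#' from the wall segments. Equivalent to the direct mean over all valid
#' non-apex polar-map cells.
#'
#' @param segs an `aha_segments` table.
#' @return A single dimensionless SUV value.
#' @export
global_suvmean <- function(segs) {
  check_segments(segs, 1:16)
  weighted_segment_mean(segs, 1:16)
}

#' Septal and lateral regional SUVmax
#'
#' Septal region = segments 2, 3, 8, 9; lateral region = segments
#' 5, 6, 11, 12.
#'
#' @param segs an `aha_segments` table.
#' @return Named numeric(2): `septal_suv_max`, `lateral_suv_max`.
#' @export
regional_suvmax <- function(segs) {
  check_segments(segs, c(SEPTAL_SEGMENTS, LATERAL_SEGMENTS))
  c(septal_suv_max =
      max(segs$suv_max[match(SEPTAL_SEGMENTS, segs$segment)]),
    lateral_suv_max =
      max(segs$suv_max[match(LATERAL_SEGMENTS, segs$segment)]))
}

territory_segments <- function(apex_in_lad = TRUE) {
  lad <- LAD_SEGMENTS
  if (!apex_in_lad) lad <- setdiff(lad, 17)
  list(LAD = lad, RCA = RCA_SEGMENTS, LCX = LCX_SEGMENTS)
}

#' Vascular territory uptake ratios
#'
#' Each coronary territory value is the count-weighted mean of the
#' segmental SUVmean over its AHA segments (LAD = 1, 2, 7, 8, 13, 14, 17;
#' RCA = 3, 4, 9, 10, 15; LCX = 5, 6, 11, 12, 16); the reported ratios are
#' `100 * LAD / LCX` and `100 * RCA / LCX` in percent. SUVmax-based
#' territory values are available via `metric = "max"`.
#'
#' @param segs an `aha_segments` table.
#' @param metric `"mean"` (count-weighted SUVmean, default) or `"max"`.
#' @param apex_in_lad assign the apex (17) to the LAD territory (default)
#'   or exclude it.
#' @return Named numeric(2): `lad_lcx_pct`, `rca_lcx_pct`.
#' @export
territory_ratios <- function(segs, metric = c("mean", "max"),
                             apex_in_lad = TRUE) {
  metric <- match.arg(metric)
  terr <- territory_segments(apex_in_lad)
  check_segments(segs, unlist(terr))
  tval <- vapply(terr, function(ids) {
    if (metric == "mean") weighted_segment_mean(segs, ids)
    else max(segs$suv_max[match(ids, segs$segment)])
  }, 0)
  if (tval[["LCX"]] <= 0)
    stop("LCX territory uptake is zero: territory ratios undefined")
  c(lad_lcx_pct = 100 * tval[["LAD"]] / tval[["LCX"]],
    rca_lcx_pct = 100 * tval[["RCA"]] / tval[["LCX"]])
}

#' Septal-lateral uptake ratio (SLUR)
#'
#' `100 *` the count-weighted mean segmental SUVmean of the septal segments
#' (2, 3, 8, 9) over that of the lateral segments (5, 6, 11, 12), in
#' percent. Healthy myocardium typically shows about 20% lower septal than
#' lateral uptake, i.e. SLUR around 80%.
#'
#' @param segs an `aha_segments` table.
#' @return SLUR in percent.
#' @export
compute_slur <- function(segs) {
  check_segments(segs, c(SEPTAL_SEGMENTS, LATERAL_SEGMENTS))
  lat <- weighted_segment_mean(segs, LATERAL_SEGMENTS)
  if (lat <= 0) stop("lateral mean uptake is zero: SLUR undefined")
  100 * weighted_segment_mean(segs, SEPTAL_SEGMENTS) / lat
}

#' All scalar LV metrics from a segment table
#'
#' @param segs an `aha_segments` table.
#' @param territory_metric passed to [territory_ratios()].
#' @param apex_in_lad passed to [territory_ratios()].
#' @return A one-row data.frame with `global_suvmean`, `septal_suvmax`,
#'   `lateral_suvmax`, `lad_lcx_pct`, `rca_lcx_pct`, `slur_pct`.
#' @export
lv_metrics <- function(segs, territory_metric = "mean",
                       apex_in_lad = TRUE) {
  rm_ <- regional_suvmax(segs)
  tr <- territory_ratios(segs, metric = territory_metric,
                         apex_in_lad = apex_in_lad)
  data.frame(global_suvmean = global_suvmean(segs),
             septal_suvmax = rm_[["septal_suv_max"]],
             lateral_suvmax = rm_[["lateral_suv_max"]],
             lad_lcx_pct = tr[["lad_lcx_pct"]],
             rca_lcx_pct = tr[["rca_lcx_pct"]],
             slur_pct = compute_slur(segs))
}
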