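# Otsu threshold of a numeric sample via EBImage (between-class variance
# maximization on a 256-bin histogram), mapped back to the data scale.
otsu_threshold <- function(vals, levels = 256) {
  vals <- vals[is.finite(vals)]
  r <- range(vals)
  if (length(vals) < 2 || diff(r) == 0)
    stop("cannot threshold: values are constant")
  norm <- (vals - r[1]) / diff(r)
  img <- EBImage::Image(norm, dim = c(length(norm), 1))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  r[1] + thr * diff(r)
}

#' Automatic myocardial mask for one short-axis slice
#'
#' Thresholds the slice by Otsu's method (between-class variance
#' maximization over the histogram of VOI-restricted values); the mask is
#' the set of above-threshold voxels inside the VOI. Slices with (near-)
#' constant uptake — e.g. myocardial uptake too low to distinguish from the
#' blood pool — cannot be thresholded and raise an error, which is the cue
#' for a manual mask via [override_mask()].
#'
#' @param slice numeric matrix of SUV values.
#' @param included logical matrix: which pixels belong to the VOI.
#' @return Logical matrix (TRUE = myocardium candidate).
#' @export
myocardium_mask <- function(slice, included = NULL) {
  if (is.null(included)) included <- array(TRUE, dim(slice))
  stopifnot(identical(dim(slice), dim(included)))
  vals <- slice[included]
  if (length(vals) < 2 || diff(range(vals)) == 0)
    stop("unprocessable slice: uptake is uniform (cannot separate ",
         "myocardium from blood pool/background)")
  thr <- otsu_threshold(vals)
  included & slice > thr
}

#' Replace the automatic myocardial mask with a user-drawn one
#'
#' Covers the manual-correction scenarios: tumour tissue adjacent to the
#' myocardium, low myocardial uptake defeating automatic thresholding, and
#' segmented papillary muscles.
#'
#' @param slice numeric matrix (used only for shape validation).
#' @param user_mask logical matrix of the same shape, non-empty.
#' @return The user mask, with attribute `provenance = "manual_mask"`.
#' @export
override_mask <- function(slice, user_mask) {
  if (!identical(dim(slice), dim(user_mask)))
    stop("user mask shape ", paste(dim(user_mask), collapse = "x"),
         " does not match slice shape ", paste(dim(slice), collapse = "x"))
  user_mask <- user_mask & TRUE
  if (!any(user_mask))
    stop("user mask is empty: no myocardium selected")
  attr(user_mask, "provenance") <- "manual_mask"
  user_mask
}

# direction of polar angle theta (degrees): 0 = anterior ("up", -y),
# increasing toward the septum (+x). Returns c(dx, dy) in voxel axes.
angle_dir <- function(deg) {
  t <- deg * pi / 180
  cbind(dx = sin(t), dy = -cos(t))
}

#' Extract the myocardial ring of one short-axis slice
#'
#' For each integer degree 0..359 a ray is cast from the centre and the SUV
#' profile is sampled at sub-pixel steps by bilinear interpolation; the
#' sample with maximum SUV within the masked radial support defines the
#' ring at that angle (ties broken toward the smaller radius, so an
#' adjacent hot structure further out cannot capture the ray). The centre
#' is then recalculated as the centroid of the 360 maximizing points, one
#' recalculation per slice.
#'
#' @param slice numeric matrix (x = first index, y = second).
#' @param mask logical matrix restricting the radial support.
#' @param center numeric(2) starting centre in (fractional) pixel indices.
#' @param step_px radial sampling step in pixels.
#' @param values_fn optional function(px, py) returning interpolated values
#'   at fractional pixel positions; defaults to bilinear interpolation of
#'   `slice`. Used to sample an un-resampled source volume through a
#'   composed transform.
#' @return A list of class `radial_ring`: `samples` (data.frame with
#'   `angle`, `radius` in px, `value`), `center` (the input),
#'   `center_updated`, and `open` (logical(360), TRUE where the ray found
#'   no masked support).
#' @export
extract_ring <- function(slice, mask, center, step_px = 0.5,
                         values_fn = NULL) {
  stopifnot(identical(dim(slice), dim(mask)))
  d <- dim(slice)
  if (!any(mask)) stop("empty myocardial mask")
  if (center[1] < 1 || center[1] > d[1] || center[2] < 1 || center[2] > d[2])
    stop("ring centre lies outside the slice")
  r_max <- sqrt(max((c(1, d[1]) - center[1])^2)) +
    sqrt(max((c(1, d[2]) - center[2])^2))
  radii <- seq(0, r_max, by = step_px)
  dirs <- angle_dir(0:359)
  px <- outer(dirs[, 1], radii) + center[1]  # 360 x nr
  py <- outer(dirs[, 2], radii) + center[2]
  inb <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2]
  sup <- matrix(FALSE, 360, length(radii))
  ri <- pmin(pmax(round(px[inb]), 1), d[1])
  ci <- pmin(pmax(round(py[inb]), 1), d[2])
  sup[inb] <- mask[cbind(ri, ci)]
  vals <- matrix(NA_real_, 360, length(radii))
  vals[inb] <- if (is.null(values_fn)) {
    pracma::interp2(x = seq_len(d[2]), y = seq_len(d[1]),
                    Z = slice, xp = py[inb], yp = px[inb])
  } else {
    values_fn(px[inb], py[inb])
  }
  vals[!sup] <- NA_real_
  open <- rowSums(sup) == 0
  best <- rep(NA_integer_, 360)
  best[!open] <- apply(vals[!open, , drop = FALSE], 1, which.max)
  radius <- ifelse(open, NA_real_, radii[best])
  value <- vals[cbind(1:360, best)]
  pts_x <- center[1] + dirs[, 1] * radius
  pts_y <- center[2] + dirs[, 2] * radius
  newc <- if (all(open)) center else
    c(mean(pts_x[!open]), mean(pts_y[!open]))
  structure(list(samples = data.frame(angle = 0:359, radius = radius,
                                      value = value),
                 center = center, center_updated = newc, open = open),
            class = "radial_ring")
}

# sector tests in degrees on [0, 360)
in_sector <- function(deg, lo, hi) {
  deg <- deg %% 360
  if (lo <= hi) deg >= lo & deg < hi else deg >= lo | deg < hi
}

SEPTAL_SEGMENTS <- c(2, 3, 8, 9)
LATERAL_SEGMENTS <- c(5, 6, 11, 12)
LAD_SEGMENTS <- c(1, 2, 7, 8, 13, 14, 17)
RCA_SEGMENTS <- c(3, 4, 9, 10, 15)
LCX_SEGMENTS <- c(5, 6, 11, 12, 16)

AHA_SEGMENT_NAMES <- c(
  "basal anterior", "basal anteroseptal", "basal inferoseptal",
  "basal inferior", "basal inferolateral", "basal anterolateral",
  "mid anterior", "mid anteroseptal", "mid inferoseptal",
  "mid inferior", "mid inferolateral", "mid anterolateral",
  "apical anterior", "apical septal", "apical inferior", "apical lateral",
  "apex")

# AHA segment id for a polar angle (deg) and zone
# ("basal"/"mid"/"apical"/"apex"). Angle origin: anterior wall, increasing
# toward the septum.
aha_segment_id <- function(deg, zone) {
  base6 <- function(d) {
    ifelse(in_sector(d, 330, 30), 1L,
      ifelse(in_sector(d, 30, 90), 2L,
        ifelse(in_sector(d, 90, 150), 3L,
          ifelse(in_sector(d, 150, 210), 4L,
            ifelse(in_sector(d, 210, 270), 5L, 6L)))))
  }
  apical4 <- function(d) {
    ifelse(in_sector(d, 315, 45), 13L,
      ifelse(in_sector(d, 45, 135), 14L,
        ifelse(in_sector(d, 135, 225), 15L, 16L)))
  }
  out <- integer(length(deg))
  out[zone == "basal"] <- base6(deg[zone == "basal"])
  out[zone == "mid"] <- base6(deg[zone == "mid"]) + 6L
  out[zone == "apical"] <- apical4(deg[zone == "apical"])
  out[zone == "apex"] <- 17L
  out
}

# decide which z end is the apex: the apical cap is a compact disc while
# the open base is a wide annulus (or arc), so the mean distance of mask
# pixels from their centroid separates the two ends robustly.
mask_spread <- function(mask) {
  if (!any(mask)) return(NA_real_)
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  mean(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
}

#' Build the LV polar map from an oriented subvolume
#'
#' On every processable short-axis slice an Otsu myocardial mask is taken
#' and the maximum-SUV ring extracted, apex to base, with the ring centre
#' propagated and recalculated slice by slice. Following the
#' Michigan-standard construction, the first and last rings are the first
#' and last slices with nonzero mask elements, and the basal limit is
#' truncated so the septal and lateral walls end on the same slice. The map
#' centre (apex) is filled by maximum sampling along rays fanning out from
#' the apex point through the apical cap; ring k of K occupies normalized
#' radius ((A + k) - 0.5) / (A + K) where A is the number of apex-cap bins
#' (A = round(K/3), placing the cap/ring boundary at one quarter of the
#' map radius).
#'
#' @param olv an `oriented_lv` with at least 3 processable slices.
#' @param masks optional list of per-slice logical masks (indexed by slice)
#'   overriding the automatic Otsu mask; entries may be `NULL` to keep the
#'   automatic one.
#' @param step_px radial sampling step in pixels for ring extraction.
#' @return An object of class `polar_map`: `values` (360 x R matrix),
#'   `valid` (same shape), `n_cap`, `n_rings`, `ring_zone`
#'   (character(K)), `segment` (360 x R integer matrix), plus provenance.
#' @export
build_polar_map <- function(olv, masks = NULL, step_px = 0.5) {
  stopifnot(inherits(olv, "oriented_lv"))
  d <- dim(olv$values)
  nz <- d[3]
  # a slice is processable only if it actually contains myocardium;
  # otherwise per-slice Otsu on background- or blood-pool-only slices
  # (including sub-slice remnants created by resampling) fabricates rings.
  # Myocardial presence = at least 8 voxels reaching 40% of the volume's
  # near-maximum uptake: blood pool sits near 30% of myocardium in FDG
  # studies, while even a severe (half-intensity) regional defect is at 50%.
  vox <- olv$values[olv$mask]
  thr3 <- 0.4 * stats::quantile(vox, 0.99)
  slice_masks <- vector("list", nz)
  manual <- logical(nz)
  for (k in seq_len(nz)) {
    um <- if (!is.null(masks) && length(masks) >= k) masks[[k]] else NULL
    if (!is.null(um)) {
      slice_masks[[k]] <- override_mask(olv$values[, , k], um)
      manual[k] <- TRUE
    } else if (sum(olv$values[, , k][olv$mask[, , k]] > thr3) >= 8) {
      slice_masks[[k]] <- tryCatch(
        myocardium_mask(olv$values[, , k], olv$mask[, , k]),
        error = function(e) array(FALSE, d[1:2]))
    } else {
      slice_masks[[k]] <- array(FALSE, d[1:2])
    }
  }
  nzslices <- which(vapply(slice_masks, any, TRUE))
  if (length(nzslices) < 3)
    stop("fewer than 3 processable short-axis slices")
  lo <- min(nzslices); hi <- max(nzslices)
  # apex side: the cap slice is a compact disc, the base a wide annulus
  f_lo <- mean(vapply(lo:min(lo + 1, hi), function(k)
    mask_spread(slice_masks[[k]]), 0), na.rm = TRUE)
  f_hi <- mean(vapply(max(lo, hi - 1):hi, function(k)
    mask_spread(slice_masks[[k]]), 0), na.rm = TRUE)
  apex_first <- f_lo <= f_hi
  order_k <- if (apex_first) lo:hi else hi:lo
  # ring extraction apex -> base, centre carried forward; values sampled
  # from the source volume through the composed transform when available
  smp <- if (!is.null(olv$source)) oriented_sampler(olv) else NULL
  ctr <- colMeans(which(slice_masks[[order_k[1]]], arr.ind = TRUE))
  rings <- vector("list", length(order_k))
  for (i in seq_along(order_k)) {
    k <- order_k[i]
    vfn <- if (is.null(smp)) NULL else
      local({kk <- k; function(px, py) smp(px, py, rep(kk, length(px)))})
    rings[[i]] <- extract_ring(olv$values[, , k], slice_masks[[k]], ctr,
                               step_px = step_px, values_fn = vfn)
    ctr <- rings[[i]]$center_updated
  }
  closed_frac <- function(ring, lo_deg, hi_deg) {
    sel <- in_sector(0:359, lo_deg, hi_deg)
    mean(!ring$open[sel])
  }
  # basal truncation: septal and lateral walls must end on the same slice.
  # The myocardium is contiguous, so rings stop at the first slice where
  # either wall opens (e.g. a septal wall extending basally past the
  # lateral wall); anything beyond is discarded even if ring extraction
  # from a drifted centre reports support there.
  ok <- vapply(rings, closed_frac, 0, 30, 150) >= 0.5 &
    vapply(rings, closed_frac, 0, 210, 330) >= 0.5
  if (!ok[1]) stop("apical ring has an open wall; manual masks required")
  K <- rle(ok)$lengths[1]
  # basal count-threshold stop: trailing rings whose median sample drops
  # below 75% of the best ring median are partial-volume remnants of the open
  # base (oblique cut smeared by resampling), not myocardium
  med <- vapply(rings, function(r) stats::median(r$samples$value,
                                                 na.rm = TRUE), 0)
  while (K > 3 && med[K] < 0.75 * max(med[seq_len(K)])) K <- K - 1L
  if (K < 3) stop("fewer than 3 processable short-axis slices after ",
                  "basal truncation")
  rings <- rings[seq_len(K)]
  # apex cap: rays from the apex point through the cap, max sampling
  A <- max(1L, round(K / 3))
  apex_ctr <- rings[[1]]$center_updated
  apex_k <- order_k[1]
  zdir <- if (apex_first) 1 else -1  # rays fan from the apex toward the base
  mask3 <- array(FALSE, d)
  for (i in seq_len(K)) mask3[, , order_k[i]] <- slice_masks[[order_k[i]]]
  cap <- matrix(NA_real_, 360, A)
  h <- olv$spacing[1]
  rmax_cap <- max(vapply(rings, function(r)
    max(r$samples$radius, na.rm = TRUE), 0)) + 2
  rr <- seq(0, rmax_cap, by = step_px)
  dirs <- angle_dir(0:359)
  # ray origin on the long axis one voxel inside the cavity, so that the
  # psi = 0 ray crosses the apical dome transmurally instead of grazing
  # the partial-volume-suppressed tip voxel
  z0 <- apex_k + zdir
  for (j in seq_len(A)) {
    psi <- (j - 0.5) / A * (pi / 2)  # 0 = toward the apex tip, pi/2 = in-plane
    dx <- dirs[, 1] * sin(psi); dy <- dirs[, 2] * sin(psi)
    dz <- rep(-zdir * cos(psi), 360)
    px <- outer(dx, rr) + apex_ctr[1]
    py <- outer(dy, rr) + apex_ctr[2]
    pz <- outer(dz, rr) + z0
    mw <- interp3(mask3 * 1, as.vector(px), as.vector(py), as.vector(pz),
                  fill = 0)
    vv <- if (is.null(smp)) {
      ifelse(mw >= 0.5,
             interp3(olv$values * (mask3 * 1), as.vector(px),
                     as.vector(py), as.vector(pz), fill = 0) /
               pmax(mw, 0.5),
             NA_real_)
    } else {
      ifelse(mw >= 0.5, smp(as.vector(px), as.vector(py), as.vector(pz)),
             NA_real_)
    }
    vm <- matrix(vv, 360, length(rr))
    any_sup <- rowSums(!is.na(vm)) > 0
    cap[any_sup, j] <- apply(vm[any_sup, , drop = FALSE], 1, max,
                             na.rm = TRUE)
  }
  ringvals <- vapply(rings, function(r) r$samples$value, numeric(360))
  values <- cbind(cap, ringvals)
  valid <- !is.na(values)
  values[!valid] <- 0
  R <- A + K
  ring_zone <- as.character(cut((seq_len(K) - 0.5) / K,
                                c(0, 1 / 3, 2 / 3, 1),
                                labels = c("apical", "mid", "basal")))
  zone <- c(rep("apex", A), ring_zone)
  segment <- matrix(0L, 360, R)
  for (m in seq_len(R))
    segment[, m] <- aha_segment_id(0:359, rep(zone[m], 360))
  structure(list(values = values, valid = valid, n_cap = A, n_rings = K,
                 ring_zone = ring_zone, segment = segment,
                 angles = 0:359,
                 provenance = list(
                   apex_first = apex_first,
                   slices_used = order_k[seq_len(K)],
                   truncated_slices = length(order_k) - K,
                   manual_masks = which(manual),
                   centers = lapply(rings, `[[`, "center"))),
            class = "polar_map")
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf("<polar_map> 360 angles x %d radial bins (%d apex-cap + %d rings)\n",
              ncol(x$values), x$n_cap, x$n_rings))
  cat(sprintf("  valid cells: %d / %d; basal slices truncated: %d\n",
              sum(x$valid), length(x$valid),
              x$provenance$truncated_slices))
  invisible(x)
}

#' Aggregate a polar map into the 17 AHA segments
#'
#' Partitions the map into the standard AHA segmentation — 6 basal and 6
#' mid segments of 60 degrees, 4 apical segments of 90 degrees, and the
#' apex (segment 17) as the central disc — and reports per-segment SUVmean,
#' SUVmax and the number of contributing cells. Every valid cell belongs to
#' exactly one segment; segments without valid cells are flagged with
#' `NA` metrics rather than zeros.
#'
#' @param pm a `polar_map`.
#' @return A data.frame of class `aha_segments` with columns `segment`,
#'   `name`, `suv_mean`, `suv_max`, `n_cells`.
#' @export
aggregate_segments <- function(pm) {
  stopifnot(inherits(pm, "polar_map"))
  seg <- pm$segment[pm$valid]
  val <- pm$values[pm$valid]
  out <- data.frame(segment = 1:17, name = AHA_SEGMENT_NAMES,
                    suv_mean = NA_real_, suv_max = NA_real_,
                    n_cells = 0L, stringsAsFactors = FALSE)
  for (s in 1:17) {
    v <- val[seg == s]
    out$n_cells[s] <- length(v)
    if (length(v)) {
      out$suv_mean[s] <- mean(v)
      out$suv_max[s] <- max(v)
    }
  }
  class(out) <- c("aha_segments", "data.frame")
  out
}

#' Render a polar map as a bullseye plot
#'
#' @param pm a `polar_map`.
#' @param main plot title.
#' @param segment_lines draw the AHA segment boundaries.
#' @param col color ramp.
#' @return Invisibly, `pm`.
#' @export
plot_polar_map <- function(pm, main = "LV polar map", segment_lines = TRUE,
                           col = grDevices::hcl.colors(64, "Inferno")) {
  stopifnot(inherits(pm, "polar_map"))
  R <- ncol(pm$values)
  vr <- range(pm$values[pm$valid])
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1),
                        asp = 1)
  graphics::title(main = main)
  for (m in R:1) {
    r0 <- (m - 1) / R; r1 <- m / R
    for (ang in 0:359) {
      if (!pm$valid[ang + 1, m]) next
      v <- pm$values[ang + 1, m]
      ci <- 1 + floor((v - vr[1]) / max(vr[2] - vr[1], 1e-12) *
                        (length(col) - 1))
      # bullseye: anterior (0 deg) up, septum (90 deg) to the left as in
      # the standard display (mirror of voxel x)
      th <- seq(ang - 0.5, ang + 0.5, length.out = 3) * pi / 180
      xs <- c(r0 * -sin(th), rev(r1 * -sin(th)))
      ys <- c(r0 * cos(th), rev(r1 * cos(th)))
      graphics::polygon(xs, ys, col = col[ci], border = NA)
    }
  }
  if (segment_lines) {
    rad <- c(0.25, 0.5, 0.75, 1)
    th <- seq(0, 2 * pi, length.out = 241)
    for (r in rad) graphics::lines(r * -sin(th), r * cos(th), col = "grey30")
    for (a in c(30, 90, 150, 210, 270, 330) * pi / 180)
      graphics::lines(c(0.5, 1) * -sin(a), c(0.5, 1) * cos(a), col = "grey30")
    for (a in c(45, 135, 225, 315) * pi / 180)
      graphics::lines(c(0.25, 0.5) * -sin(a), c(0.25, 0.5) * cos(a),
                      col = "grey30")
  }
  invisible(pm)
}

#' Export a polar map as a tidy CSV table
#'
#' @param pm a `polar_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_polar_map <- function(pm, path) {
  stopifnot(inherits(pm, "polar_map"))
  R <- ncol(pm$values)
  df <- data.frame(
    angle_bin = rep(0:359, times = R),
    radial_bin = rep(seq_len(R), each = 360),
    value = as.vector(pm$values),
    valid = as.vector(pm$valid),
    segment_id = as.vector(pm$segment))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
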