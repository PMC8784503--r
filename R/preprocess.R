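#' Variance-stabilized Poisson denoising
#'
#' Applies the Anscombe transform `f(x) = 2 * sqrt(x + 3/8)` voxelwise,
#' Gaussian smoothing at a physical scale in the stabilized domain, and the
#' algebraic inverse `(f/2)^2 - 3/8` clamped at zero. The transform makes
#' Poisson-distributed data approximately unit-variance Gaussian, so plain
#' Gaussian smoothing is the appropriate filter there; the smoothing kernel
#' is renormalized at the volume edges so that flat regions are preserved
#' and total counts are approximately conserved.
#'
#' @param vol a `scalar_volume` (activity or SUV) with non-negative values.
#' @param smoothing_mm Gaussian sigma in mm, applied isotropically in
#'   physical space (per-axis sigma in voxels is `smoothing_mm / spacing`).
#'   `0` returns the input unchanged (up to the transform roundtrip).
#' @return A volume of the same class and geometry.
#' @export
denoise_poisson <- function(vol, smoothing_mm = 2) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (min(vol$values) < 0)
    stop("negative values are incompatible with the Poisson noise model")
  if (smoothing_mm < 0) stop("smoothing scale must be >= 0")
  x <- 2 * sqrt(vol$values + 3 / 8)
  sigma_vox <- smoothing_mm / vol$spacing
  for (axis in 1:3) x <- smooth_axis(x, sigma_vox[axis], axis)
  out <- vol
  out$values <- pmax((x / 2)^2 - 3 / 8, 0)
  out
}

# Gaussian smoothing along one array axis via a dense row-renormalized
# band matrix; sigma in voxel units.
smooth_axis <- function(arr, sigma, axis) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  n <- d[axis]
  half <- max(1L, ceiling(3 * sigma))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    w <- exp(-((i - j)^2) / (2 * sigma^2))
    w * (abs(i - j) <= half)
  })
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  m <- K %*% m
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

#' Heuristic CT-based localization of the left ventricle
#'
#' Advisory localization of the heart from a thoracic CT: air-density
#' regions below `lung_hu_threshold` are labelled per axial slice,
#' components touching the image border (ambient air) are discarded, and on
#' slices showing two lung fields the soft-tissue voxels lying medially
#' between them are collected. Their centroid is returned with a padded
#' bounding box. The result is advisory and can always be replaced by a
#' user-supplied centre.
#'
#' @param ct a `scalar_volume` in HU.
#' @param lung_hu_threshold HU below which a voxel counts as lung/air.
#' @param pad_mm padding added to the candidate bounding box, mm.
#' @param center_override optional numeric(3) physical centre in mm; when
#'   given, heuristics are bypassed entirely.
#' @return A list of class `lv_localization` with `center_mm`,
#'   `bounding_box` (2x3 matrix, min/max per axis in mm) and
#'   `confidence_flag` (`"automatic"` or `"manual_override"`).
#' @export
localize_lv <- function(ct, lung_hu_threshold = -400, pad_mm = 20,
                        center_override = NULL) {
  stopifnot(inherits(ct, "scalar_volume"))
  axes <- voxel_axes(ct)
  lo <- sapply(axes, min) - ct$spacing / 2
  hi <- sapply(axes, max) + ct$spacing / 2
  if (!is.null(center_override)) {
    center <- as.numeric(center_override)
    if (length(center) != 3) stop("manual centre must be numeric(3) (mm)")
    bb <- rbind(pmax(center - pad_mm, lo), pmin(center + pad_mm, hi))
    return(structure(list(center_mm = center, bounding_box = bb,
                          confidence_flag = "manual_override"),
                     class = "lv_localization"))
  }
  d <- dim(ct$values)
  soft_lo <- -200  # soft tissue lower bound, HU
  cand <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    slice <- ct$values[, , k]
    air <- slice < lung_hu_threshold
    if (!any(air)) next
    lab <- EBImage::bwlabel(air * 1)
    if (max(lab) < 2) next
    border_ids <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
    ids <- setdiff(seq_len(max(lab)), c(0, border_ids))
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))[ids]
    ids <- ids[sizes >= 20]
    if (length(ids) < 2) next
    cx <- vapply(ids, function(i) mean(which(lab == i, arr.ind = TRUE)[, 1]),
                 0)
    left <- ids[which.min(cx)]
    right <- ids[which.max(cx)]
    if (left == right) next
    li <- which(lab == left, arr.ind = TRUE)
    ri <- which(lab == right, arr.ind = TRUE)
    x_lo <- max(li[, 1]); x_hi <- min(ri[, 1])
    if (x_hi <= x_lo) next
    y_rng <- range(c(li[, 2], ri[, 2]))
    sub <- slice[x_lo:x_hi, y_rng[1]:y_rng[2], drop = FALSE]
    hit <- which(sub > soft_lo, arr.ind = TRUE)
    if (!nrow(hit)) next
    cand[[k]] <- cbind(hit[, 1] + x_lo - 1, hit[, 2] + y_rng[1] - 1, k)
  }
  pts <- do.call(rbind, cand)
  if (is.null(pts) || !nrow(pts))
    stop("no lung-like regions found in the CT; ",
         "supply a manual centre via `center_override`")
  phys <- sweep(sweep(pts - 1, 2, ct$spacing, "*"), 2, ct$origin, "+")
  center <- colMeans(phys)
  bb <- rbind(pmax(apply(phys, 2, min) - pad_mm, lo),
              pmin(apply(phys, 2, max) + pad_mm, hi))
  structure(list(center_mm = center, bounding_box = bb,
                 confidence_flag = "automatic"),
            class = "lv_localization")
}
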