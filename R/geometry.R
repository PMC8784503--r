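#' Ellipsoidal volume of interest around the left ventricle
#'
#' An ellipsoid is used (rather than a box) because it follows the LV shape
#' and lets nearby hot structures such as tumour masses be excluded from the
#' analysed volume.
#'
#' @param center numeric(3) physical centre, mm.
#' @param semi_axes numeric(3) semi-axes (a, b, c), mm, all > 0.
#' @param euler_deg numeric(3) rotations in degrees about the x, y and z
#'   axes, applied in that order (positive = counterclockwise looking down
#'   the axis).
#' @return An object of class `ellipsoid_voi`.
#' @export
ellipsoid_voi <- function(center, semi_axes, euler_deg = c(0, 0, 0)) {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  if (length(center) != 3 || any(!is.finite(center)))
    stop("`center` must be numeric(3) (mm)")
  if (length(semi_axes) != 3 || any(semi_axes <= 0))
    stop("all semi-axes must be positive")
  structure(list(center = center, semi_axes = semi_axes,
                 euler_deg = as.numeric(euler_deg)),
            class = "ellipsoid_voi")
}

rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}
rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}
rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

euler_matrix <- function(euler_deg) {
  rot_z(euler_deg[3]) %*% rot_y(euler_deg[2]) %*% rot_x(euler_deg[1])
}

# Physical coordinates (n x 3) of every voxel centre of a volume.
grid_coords <- function(vol) {
  ax <- voxel_axes(vol)
  d <- dim(vol$values)
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

#' Restrict an SUV volume to an ellipsoidal VOI
#'
#' Voxels whose centre falls inside the ellipsoid are retained; all others
#' are marked *excluded* (carried as a logical mask, not zeroed, so that
#' exclusion is distinguishable from true zero uptake). The grid is cropped
#' to the ellipsoid extents plus a 1-voxel margin.
#'
#' @param suv a `scalar_volume` (typically SUV) or `masked_volume`.
#' @param voi an `ellipsoid_voi`.
#' @return A `masked_volume`: a `scalar_volume` with an additional logical
#'   array `mask` (TRUE = inside the VOI).
#' @export
apply_voi <- function(suv, voi) {
  stopifnot(inherits(suv, "scalar_volume"), inherits(voi, "ellipsoid_voi"))
  R <- euler_matrix(voi$euler_deg)
  pts <- grid_coords(suv)
  q <- sweep(pts, 2, voi$center) %*% R  # = t(R) applied to each row
  inside <- rowSums(sweep(q, 2, voi$semi_axes, "/")^2) <= 1
  d <- dim(suv$values)
  inside <- array(inside, dim = d)
  if (inherits(suv, "masked_volume")) inside <- inside & suv$mask
  if (!any(inside))
    stop("the ellipsoid VOI does not intersect the volume")
  idx <- which(inside, arr.ind = TRUE)
  rng <- lapply(1:3, function(a)
    max(1L, min(idx[, a]) - 1L):min(d[a], max(idx[, a]) + 1L))
  vals <- suv$values[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  msk <- inside[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  out <- scalar_volume(vals, suv$spacing,
                       origin = suv$origin +
                         (sapply(rng, min) - 1) * suv$spacing,
                       unit = suv$unit)
  out$mask <- msk
  class(out) <- c("masked_volume", class(out))
  out
}

# Vectorized trilinear interpolation of a 3-D array at fractional voxel
# indices (1-based). Out-of-range points return `fill`.
interp3 <- function(arr, xi, yi, zi, fill = 0) {
  d <- dim(arr)
  out <- rep(fill, length(xi))
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  if (!any(ok)) return(out)
  x <- xi[ok]; y <- yi[ok]; z <- zi[ok]
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}

#' Rotate the LV subvolume into the standard cardiac axes
#'
#' Rigid reorientation in two steps matching clinical practice: first a
#' rotation about the horizontal long axis (HLA, the volume x axis) by
#' `theta_hla`, then about the vertical long axis (VLA, the y axis) by
#' `theta_vla`; positive angles are counterclockwise looking down the axis.
#' After orientation the LV long axis runs along z, so the short-axis (SA)
#' slices are the axial planes of the output grid. Values are resampled by
#' mask-weighted trilinear interpolation onto an isotropic grid at the
#' finest input spacing; the exclusion mask travels by nearest-neighbour
#' (majority) resampling.
#'
#' @param mv a `masked_volume` (from [apply_voi()]).
#' @param theta_hla,theta_vla rotation angles in degrees, each in (-90, 90].
#' @return An `oriented_lv`: a `masked_volume` on an isotropic grid with
#'   attributes `theta_hla` and `theta_vla`.
#' @export
orient_lv <- function(mv, theta_hla, theta_vla) {
  stopifnot(inherits(mv, "masked_volume"))
  if (theta_hla <= -90 || theta_hla > 90 || theta_vla <= -90 || theta_vla > 90)
    stop("rotation angles must lie in (-90, 90] degrees")
  M <- rot_y(theta_vla) %*% rot_x(theta_hla)
  h <- min(mv$spacing)
  ax <- voxel_axes(mv)
  ctr <- sapply(ax, function(a) mean(range(a)))
  corners <- as.matrix(expand.grid(range(ax[[1]]), range(ax[[2]]),
                                   range(ax[[3]])))
  rc <- sweep(sweep(corners, 2, ctr) %*% t(M), 2, ctr, "+")
  newax <- lapply(1:3, function(a) {
    r <- range(rc[, a])
    seq(r[1], r[2] + h / 2, by = h)
  })
  nd <- sapply(newax, length)
  pts <- cbind(rep(newax[[1]], times = nd[2] * nd[3]),
               rep(rep(newax[[2]], each = nd[1]), times = nd[3]),
               rep(newax[[3]], each = nd[1] * nd[2]))
  src <- sweep(sweep(pts, 2, ctr) %*% M, 2, ctr, "+")  # rows: M^-1 (p - c) + c
  # fractional voxel indices in the source grid
  fi <- sweep(sweep(src, 2, mv$origin), 2, mv$spacing, "/") + 1
  m <- mv$mask * 1
  w <- interp3(m, fi[, 1], fi[, 2], fi[, 3], fill = 0)
  v <- interp3(mv$values * m, fi[, 1], fi[, 2], fi[, 3], fill = 0)
  vals <- ifelse(w > 1e-6, v / pmax(w, 1e-6), 0)
  msk <- w >= 0.5
  out <- scalar_volume(array(vals, nd), spacing = rep(h, 3),
                       origin = sapply(newax, min), unit = mv$unit)
  out$mask <- array(msk, nd)
  out$theta_hla <- theta_hla
  out$theta_vla <- theta_vla
  # the transform and source volume are kept so downstream sampling (ring
  # extraction) can interpolate the source directly through the composed
  # transform instead of resampling twice
  out$rotation <- M
  out$rot_center <- ctr
  out$source <- mv
  class(out) <- c("oriented_lv", "masked_volume", "scalar_volume")
  out
}

# Sampler over the oriented frame that interpolates the *source* volume
# through the composed rigid transform (single interpolation stage).
# Takes fractional voxel indices in the oriented grid; returns
# mask-weighted trilinearly interpolated values.
oriented_sampler <- function(olv) {
  src <- olv$source
  M <- olv$rotation
  ctr <- olv$rot_center
  h <- olv$spacing
  o <- olv$origin
  m <- src$mask * 1
  vm <- src$values * m
  function(xi, yi, zi) {
    p <- cbind(o[1] + (xi - 1) * h[1], o[2] + (yi - 1) * h[2],
               o[3] + (zi - 1) * h[3])
    q <- sweep(sweep(p, 2, ctr) %*% M, 2, ctr, "+")
    fi <- sweep(sweep(q, 2, src$origin), 2, src$spacing, "/") + 1
    w <- interp3(m, fi[, 1], fi[, 2], fi[, 3], fill = 0)
    v <- interp3(vm, fi[, 1], fi[, 2], fi[, 3], fill = 0)
    ifelse(w > 1e-6, v / pmax(w, 1e-6), 0)
  }
}

# 3-D mask of myocardium-like voxels inside the VOI: at least 40% of the
# volume's near-maximum uptake. An Otsu split would drop regionally
# reduced myocardium (e.g. an apical defect) and leave an open tube whose
# principal axis is transverse, so a fixed fraction is used instead.
shell_mask3d <- function(mv) {
  vals <- mv$values[mv$mask]
  thr <- 0.4 * stats::quantile(vals, 0.99)
  mv$mask & mv$values > thr
}

#' Estimate the reorientation angles from the uptake distribution
#'
#' Fits the principal axis of the myocardial-shell voxels (those reaching
#' 40% of the volume's near-maximum uptake) inside the VOI by PCA of their
#' physical coordinates and returns the
#' (`theta_hla`, `theta_vla`) pair that [orient_lv()] needs to align that
#' axis with the z (short-axis stack) direction. Intended as the automatic
#' initializer replacing interactive axis drawing; the angles can always be
#' overridden.
#'
#' @param mv a `masked_volume`.
#' @return numeric(2): `c(theta_hla, theta_vla)` in degrees.
#' @export
estimate_orientation <- function(mv) {
  stopifnot(inherits(mv, "masked_volume"))
  shell <- shell_mask3d(mv)
  if (sum(shell) < 10)
    stop("too few high-uptake voxels to estimate an axis")
  idx <- which(shell, arr.ind = TRUE)
  pts <- sweep(sweep(idx - 1, 2, mv$spacing, "*"), 2, mv$origin, "+")
  pc <- prcomp(pts)
  v <- pc$rotation[, 1]
  if (v[3] < 0) v <- -v
  a <- atan2(v[2], v[3]) * 180 / pi
  zp <- sqrt(v[2]^2 + v[3]^2)
  b <- atan2(-v[1], zp) * 180 / pi
  c(theta_hla = a, theta_vla = b)
}

#' Automatically orient an LV subvolume
#'
#' Convenience wrapper: [estimate_orientation()] followed by [orient_lv()].
#'
#' @param mv a `masked_volume`.
#' @return An `oriented_lv`.
#' @export
auto_orient <- function(mv) {
  th <- estimate_orientation(mv)
  orient_lv(mv, th[1], th[2])
}
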