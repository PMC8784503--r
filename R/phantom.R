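#' Specification of a synthetic LV PET/CT phantom
#'
#' Describes a half-ellipsoidal left-ventricular myocardial shell (outer
#' ellipsoid minus inner ellipsoid, cut by a basal plane, apex pointing
#' toward -z before rotation) embedded in a simple thorax: soft-tissue
#' body, two air-density lungs flanking the heart, blood pool filling the
#' cavity, and uniform background activity. Wall-sector uptake multipliers
#' follow the same angular conventions as the polar-map segmentation
#' (anterior 330-30 deg, septal 30-150, inferior 150-210, lateral 210-330,
#' with 0 deg at the anterior wall increasing toward the septum), so
#' segment-level ground truth is analytic; the true SLUR is
#' `100 * septal / lateral`. Grid defaults match a clinical cardiac FDG
#' acquisition: 168 x 168 matrix, 4.0728 mm in-plane voxels, 5 mm slices.
#'
#' @param matrix_size integer(2) in-plane matrix.
#' @param n_slices number of axial slices.
#' @param voxel_mm in-plane voxel size, mm.
#' @param slice_mm slice thickness, mm.
#' @param center_mm LV centre (mm); default = volume centre.
#' @param outer_semi_axes numeric(3) outer shell semi-axes (mm).
#' @param wall_mm myocardial wall thickness (mm), less than the smallest
#'   outer semi-axis.
#' @param base_cut_frac basal cut plane at `z' = base_cut_frac * c` (the
#'   shell is kept for `z'` below it; apex at `z' = -c`).
#' @param base_suv baseline myocardial SUV.
#' @param blood_pool_suv,background_suv SUV of cavity blood pool and of
#'   body background.
#' @param septal,lateral,anterior,inferior,apical wall-sector uptake
#'   multipliers (apical applies multiplicatively in the apical third).
#' @param segment_multipliers optional numeric(17) per-AHA-segment
#'   multipliers (overrides the wall multipliers).
#' @param sector_rotation_deg rotate the multiplier sectors in-plane
#'   (exercises rotational equivariance).
#' @param septal_base_extension_mm extend the septal wall basally by this
#'   much beyond the cut plane (exercises the equal-basal-limits
#'   truncation).
#' @param tumor optional `list(center_mm=, radius_mm=, suv=)` hot sphere;
#'   must not overlap the shell.
#' @param noise_scale Poisson noise scale in counts per SUV unit per voxel
#'   (`NULL` = noise-free).
#' @param rotation_deg numeric(2) initial LV rotation: about x by
#'   `rotation_deg[1]`, then about y by `rotation_deg[2]`.
#' @param seed RNG seed fixing all randomness.
#' @param patient_weight_kg,injected_dose_bq,uptake_time_s acquisition
#'   metadata for the activity-conversion roundtrip.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = c(168, 168), n_slices = 40,
                         voxel_mm = 4.0728, slice_mm = 5,
                         center_mm = NULL,
                         outer_semi_axes = c(30, 30, 55), wall_mm = 11,
                         base_cut_frac = 0.35,
                         base_suv = 5, blood_pool_suv = 1.5,
                         background_suv = 0.5,
                         septal = 1, lateral = 1, anterior = 1,
                         inferior = 1, apical = 1,
                         segment_multipliers = NULL,
                         sector_rotation_deg = 0,
                         septal_base_extension_mm = 0,
                         tumor = NULL, noise_scale = NULL,
                         rotation_deg = c(0, 0), seed = 1,
                         patient_weight_kg = 70,
                         injected_dose_bq = 4.89e6 * 70,
                         uptake_time_s = 3600) {
  if (wall_mm >= min(outer_semi_axes))
    stop("wall thickness must be smaller than the smallest outer semi-axis")
  mult <- c(septal = septal, lateral = lateral, anterior = anterior,
            inferior = inferior, apical = apical)
  if (any(mult < 0)) stop("uptake multipliers must be >= 0")
  if (!is.null(segment_multipliers)) {
    if (length(segment_multipliers) != 17 || any(segment_multipliers < 0))
      stop("`segment_multipliers` must be 17 non-negative values")
  }
  spec <- list(matrix_size = matrix_size, n_slices = n_slices,
               voxel_mm = voxel_mm, slice_mm = slice_mm,
               center_mm = center_mm,
               outer_semi_axes = outer_semi_axes, wall_mm = wall_mm,
               base_cut_frac = base_cut_frac, base_suv = base_suv,
               blood_pool_suv = blood_pool_suv,
               background_suv = background_suv,
               multipliers = mult,
               segment_multipliers = segment_multipliers,
               sector_rotation_deg = sector_rotation_deg,
               septal_base_extension_mm = septal_base_extension_mm,
               tumor = tumor, noise_scale = noise_scale,
               rotation_deg = rotation_deg, seed = seed,
               patient_weight_kg = patient_weight_kg,
               injected_dose_bq = injected_dose_bq,
               uptake_time_s = uptake_time_s)
  class(spec) <- "phantom_spec"
  spec
}

# true SLUR/territory ratios implied by a spec's multipliers
phantom_truth_ratios <- function(spec) {
  if (!is.null(spec$segment_multipliers)) {
    m <- spec$segment_multipliers
    slur <- 100 * mean(m[SEPTAL_SEGMENTS]) / mean(m[LATERAL_SEGMENTS])
    terr <- territory_segments(TRUE)
    tv <- vapply(terr, function(ids) mean(m[ids]), 0)
    return(list(slur_pct = slur,
                lad_lcx_pct = 100 * tv[["LAD"]] / tv[["LCX"]],
                rca_lcx_pct = 100 * tv[["RCA"]] / tv[["LCX"]],
                territory_exact = all(
                  vapply(terr, function(ids) length(unique(m[ids])) == 1,
                         TRUE))))
  }
  m <- spec$multipliers
  list(slur_pct = 100 * m[["septal"]] / m[["lateral"]],
       lad_lcx_pct = NA_real_, rca_lcx_pct = NA_real_,
       territory_exact = FALSE)
}

#' Generate a synthetic LV PET/CT phantom with ground truth
#'
#' Evaluates the [phantom_spec()] geometry analytically on the voxel grid
#' (voxels are classified in the rotated LV frame, so no resampling error
#' enters the ground truth), applies per-sector or per-segment uptake
#' multipliers, optionally adds a hot tumour sphere and Poisson count
#' noise, and builds a matching localization CT (soft-tissue body, two
#' air-density lungs flanking the heart).
#'
#' @param spec a `phantom_spec`.
#' @return A list of class `lv_phantom`: `pet` (a `scalar_volume` in SUV),
#'   `ct` (`scalar_volume` in HU), `meta` (an `acquisition_meta`),
#'   `truth` (centre, long-axis direction, multipliers, SLUR and territory
#'   ratios, shell mask), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- c(spec$matrix_size, spec$n_slices)
  sp <- c(spec$voxel_mm, spec$voxel_mm, spec$slice_mm)
  origin <- c(0, 0, 0)
  ctr <- if (is.null(spec$center_mm)) origin + (d - 1) * sp / 2
         else spec$center_mm
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(d[a]) - 1) * sp[a])
  X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  R <- rot_y(spec$rotation_deg[2]) %*% rot_x(spec$rotation_deg[1])
  # LV-frame coordinates: q = R^T (p - centre)
  qx <- (X - ctr[1]) * R[1, 1] + (Y - ctr[2]) * R[2, 1] + (Z - ctr[3]) * R[3, 1]
  qy <- (X - ctr[1]) * R[1, 2] + (Y - ctr[2]) * R[2, 2] + (Z - ctr[3]) * R[3, 2]
  qz <- (X - ctr[1]) * R[1, 3] + (Y - ctr[2]) * R[2, 3] + (Z - ctr[3]) * R[3, 3]
  oa <- spec$outer_semi_axes
  ia <- oa - spec$wall_mm
  r_out <- (qx / oa[1])^2 + (qy / oa[2])^2 + (qz / oa[3])^2
  r_in <- (qx / ia[1])^2 + (qy / ia[2])^2 + (qz / ia[3])^2
  zcut <- spec$base_cut_frac * oa[3]
  ang <- (atan2(qx, -qy) * 180 / pi - spec$sector_rotation_deg) %% 360
  basal_lim <- zcut + ifelse(in_sector(ang, 30, 150),
                             spec$septal_base_extension_mm, 0)
  shell <- r_out <= 1 & r_in > 1 & qz <= basal_lim
  cavity <- r_in <= 1 & qz <= zcut
  # uptake multipliers
  s_long <- (qz + oa[3]) / (zcut + oa[3])  # 0 at apex tip, 1 at base cut
  if (!is.null(spec$segment_multipliers)) {
    zone <- ifelse(s_long < 1 / 12, "apex",
                   ifelse(s_long < 1 / 3, "apical",
                          ifelse(s_long < 2 / 3, "mid", "basal")))
    segid <- aha_segment_id(as.vector(ang), as.vector(zone))
    mult <- array(spec$segment_multipliers[segid], d)
  } else {
    m <- spec$multipliers
    mult <- array(ifelse(in_sector(ang, 30, 150), m[["septal"]],
                    ifelse(in_sector(ang, 210, 330), m[["lateral"]],
                      ifelse(in_sector(ang, 330, 30), m[["anterior"]],
                             m[["inferior"]]))), d)
    mult <- mult * ifelse(s_long < 1 / 3, m[["apical"]], 1)
  }
  # body and lungs (axis-aligned; only the LV is tilted)
  fov <- d * sp
  body <- ((X - ctr[1]) / (0.46 * fov[1]))^2 +
    ((Y - ctr[2]) / (0.40 * fov[2]))^2 <= 1
  lung_off <- oa[1] + 45
  lung_semi <- c(40, min(70, 0.30 * fov[2]), min(90, 0.45 * fov[3]))
  lungL <- ((X - (ctr[1] - lung_off)) / lung_semi[1])^2 +
    ((Y - ctr[2]) / lung_semi[2])^2 +
    ((Z - ctr[3]) / lung_semi[3])^2 <= 1
  lungR <- ((X - (ctr[1] + lung_off)) / lung_semi[1])^2 +
    ((Y - ctr[2]) / lung_semi[2])^2 +
    ((Z - ctr[3]) / lung_semi[3])^2 <= 1
  pet <- array(0.05, d)
  pet[body] <- spec$background_suv
  pet[lungL | lungR] <- 0.2 * spec$background_suv
  pet[cavity] <- spec$blood_pool_suv
  pet[shell] <- spec$base_suv * mult[shell]
  if (!is.null(spec$tumor)) {
    tu <- spec$tumor
    tmask <- (X - tu$center_mm[1])^2 + (Y - tu$center_mm[2])^2 +
      (Z - tu$center_mm[3])^2 <= tu$radius_mm^2
    if (any(tmask & shell))
      stop("tumour sphere overlaps the myocardial shell; ",
           "ground truth would be corrupted")
    pet[tmask] <- tu$suv
  }
  if (!is.null(spec$noise_scale)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    pet <- array(rpois(length(pet), pet * spec$noise_scale) /
                   spec$noise_scale, d)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  ct <- array(-1000, d)
  ct[body] <- 40
  ct[lungL | lungR] <- -800
  ct[r_out <= 1.2 & qz <= zcut + 5] <- 30  # pericardial soft tissue
  meta <- acquisition_meta(spec$patient_weight_kg, spec$injected_dose_bq,
                           0, spec$uptake_time_s)
  ratios <- phantom_truth_ratios(spec)
  truth <- c(list(center_mm = ctr,
                  long_axis = as.numeric(R %*% c(0, 0, 1)),
                  multipliers = spec$multipliers,
                  shell = shell, cavity = cavity), ratios)
  structure(list(pet = scalar_volume(pet, sp, origin, unit = "SUV"),
                 ct = scalar_volume(ct, sp, origin, unit = "HU"),
                 meta = meta, truth = truth, spec = spec),
            class = "lv_phantom")
}

#' Write a phantom to disk as loadable PET/CT series
#'
#' The PET volume is converted from SUV back to activity concentration
#' (Bq/mL) using the phantom's acquisition metadata and written as NIfTI
#' with a JSON sidecar holding the metadata, so that reading it back with
#' [read_pet_scan()] and [compute_suv()] reproduces the SUV volume; the CT
#' is written alongside.
#'
#' @param phantom an `lv_phantom`.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_phantom_series <- function(phantom, dir) {
  stopifnot(inherits(phantom, "lv_phantom"))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  meta <- phantom$meta
  decayed <- meta$injected_dose_bq *
    2^(-meta$uptake_time_s / meta$half_life_s)
  act <- phantom$pet
  act$values <- act$values * (decayed / (meta$patient_weight_kg * 1000))
  act$unit <- "Bq/mL"
  pet_path <- file.path(dir, "pet.nii.gz")
  ct_path <- file.path(dir, "ct.nii.gz")
  write_volume(act, pet_path, sidecar_data = list(
    patient_weight_kg = meta$patient_weight_kg,
    injected_dose_bq = meta$injected_dose_bq,
    injection_time = meta$injection_time,
    acquisition_time = meta$acquisition_time,
    half_life_s = meta$half_life_s,
    unit = "Bq/mL"))
  write_volume(phantom$ct, ct_path, sidecar_data = list(unit = "HU"))
  invisible(c(pet = pet_path, ct = ct_path,
              pet_sidecar = sidecar_path(pet_path),
              ct_sidecar = sidecar_path(ct_path)))
}
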