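#' @importFrom stats sd var cor pchisq pt pnorm rnorm rpois runif prcomp
#'   median setNames
#' @importFrom utils write.csv combn
#' @importFrom dplyr .data
"_PACKAGE"

# F-18 physical half-life in seconds
F18_HALF_LIFE_S <- 6586.2

#' Construct a 3-D scalar volume with physical geometry
#'
#' The basic carrier for CT (Hounsfield units), PET activity (Bq/mL) and SUV
#' data: a 3-D array plus per-axis voxel size and the physical position of
#' the first voxel. Axis order is (x, y, z) with z the axial (slice)
#' direction; voxel `[i, j, k]` is centred at `origin + (c(i,j,k) - 1) * spacing`.
#'
#' @param values 3-D numeric array; all values must be finite.
#' @param spacing numeric(3), voxel size in mm per axis; all > 0.
#' @param origin numeric(3), physical position (mm) of voxel `[1,1,1]`.
#' @param unit character tag: `"Bq/mL"`, `"HU"`, `"SUV"` or `"arbitrary"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing, origin = c(0, 0, 0),
                          unit = "arbitrary") {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (any(dim(values) < 2L))
    stop("volume must have at least 2 voxels per axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  if (any(!is.finite(values)))
    stop("volume values must all be finite")
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = unit),
            class = "scalar_volume")
}

#' @export
dim.scalar_volume <- function(x) dim(x$values)

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm [%s]\n",
              paste(class(x), collapse = "/"), d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$unit))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# Per-axis physical coordinates of voxel centres.
voxel_axes <- function(vol) {
  d <- dim(vol$values)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

#' Acquisition metadata entering the SUV computation
#'
#' Injection and acquisition times may be given as `POSIXct` or as numeric
#' seconds on a common clock; only their difference is used.
#'
#' @param patient_weight_kg body weight in kg (> 0).
#' @param injected_dose_bq injected activity in Bq at injection time (> 0).
#' @param injection_time,acquisition_time timestamps; acquisition must not
#'   precede injection.
#' @param half_life_s radionuclide half-life in seconds (F-18 default).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(patient_weight_kg, injected_dose_bq,
                             injection_time = 0, acquisition_time = 0,
                             half_life_s = F18_HALF_LIFE_S) {
  if (!is.numeric(patient_weight_kg) || length(patient_weight_kg) != 1 ||
      !is.finite(patient_weight_kg) || patient_weight_kg <= 0)
    stop("patient weight must be a single positive number (kg)")
  if (!is.numeric(injected_dose_bq) || length(injected_dose_bq) != 1 ||
      !is.finite(injected_dose_bq) || injected_dose_bq <= 0)
    stop("injected dose must be a single positive number (Bq)")
  if (half_life_s <= 0) stop("half-life must be positive")
  dt <- as.numeric(difftime2(acquisition_time, injection_time))
  if (!is.finite(dt)) stop("injection/acquisition times are not interpretable")
  if (dt < 0) stop("acquisition time precedes injection time")
  structure(list(patient_weight_kg = patient_weight_kg,
                 injected_dose_bq = injected_dose_bq,
                 injection_time = injection_time,
                 acquisition_time = acquisition_time,
                 uptake_time_s = dt,
                 half_life_s = half_life_s),
            class = "acquisition_meta")
}

difftime2 <- function(t2, t1) {
  if (inherits(t2, "POSIXt") || inherits(t1, "POSIXt"))
    return(as.numeric(difftime(t2, t1, units = "secs")))
  as.numeric(t2) - as.numeric(t1)
}

#' Convert an activity volume to body-weight SUV
#'
#' Body-weight SUV with decay correction of the injected dose to acquisition
#' start: `SUV = activity / (dose * 2^(-dt / T_half) / (weight_kg * 1000))`,
#' assuming 1 g/mL tissue density so that weight in kg corresponds to
#' 1000 mL/kg. The result is dimensionless and the grid geometry is
#' preserved.
#'
#' @param activity a `scalar_volume` in Bq/mL with non-negative values.
#' @param meta an `acquisition_meta`.
#' @return A `scalar_volume` with `unit = "SUV"`.
#' @export
compute_suv <- function(activity, meta) {
  stopifnot(inherits(activity, "scalar_volume"),
            inherits(meta, "acquisition_meta"))
  if (min(activity$values) < 0)
    stop("activity values must be non-negative")
  decayed <- meta$injected_dose_bq *
    2^(-meta$uptake_time_s / meta$half_life_s)
  denom <- decayed / (meta$patient_weight_kg * 1000)  # Bq/mL per SUV unit
  out <- activity
  out$values <- activity$values / denom
  out$unit <- "SUV"
  out
}

required_sidecar_fields <- c("patient_weight_kg", "injected_dose_bq",
                             "injection_time", "acquisition_time")

read_sidecar <- function(path) {
  if (!file.exists(path))
    stop("sidecar metadata file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

meta_from_sidecar <- function(sc) {
  missing <- setdiff(required_sidecar_fields, names(sc))
  if (length(missing))
    stop("sidecar metadata is missing required field(s): ",
         paste(missing, collapse = ", "))
  acquisition_meta(sc$patient_weight_kg, sc$injected_dose_bq,
                   sc$injection_time, sc$acquisition_time,
                   if (!is.null(sc$half_life_s)) sc$half_life_s
                   else F18_HALF_LIFE_S)
}

read_volume_nifti <- function(path, unit, origin = NULL) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  arr <- array(as.numeric(arr), dim(arr))  # drop NIfTI header attributes
  pd <- RNifti::pixdim(img)[seq_len(3)]
  scalar_volume(arr, spacing = pd,
                origin = if (is.null(origin)) c(0, 0, 0) else origin,
                unit = unit)
}

#' Read a PET emission volume and its acquisition metadata
#'
#' Reads a NIfTI volume holding activity concentration (Bq/mL, any NIfTI
#' storage rescale is applied by the reader) together with a JSON sidecar
#' that carries the quantities entering the SUV computation (patient weight,
#' injected dose, injection/acquisition times) and, optionally, the physical
#' origin. A missing metadata field raises an error naming the field.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param sidecar path to the JSON sidecar; defaults to `path` with the
#'   NIfTI extension replaced by `.json`.
#' @return A list with elements `volume` (a `scalar_volume` in Bq/mL, or in
#'   SUV if the sidecar declares `unit = "SUV"`) and `meta`
#'   (an `acquisition_meta`, or `NULL` for precomputed SUV input).
#' @export
read_pet_scan <- function(path, sidecar = sidecar_path(path)) {
  sc <- read_sidecar(sidecar)
  origin <- if (!is.null(sc$origin_mm)) as.numeric(sc$origin_mm) else NULL
  if (identical(sc$unit, "SUV")) {
    vol <- read_volume_nifti(path, unit = "SUV", origin = origin)
    return(list(volume = vol, meta = NULL))
  }
  meta <- meta_from_sidecar(sc)
  vol <- read_volume_nifti(path, unit = "Bq/mL", origin = origin)
  if (min(vol$values) < 0)
    stop("PET activity volume contains negative values")
  list(volume = vol, meta = meta)
}

#' Read a CT volume in Hounsfield units
#'
#' @param path NIfTI file; stored rescale (e.g. to HU) is applied by the
#'   reader.
#' @param sidecar optional JSON sidecar; if present and carrying
#'   `origin_mm`, the origin is taken from it.
#' @return A `scalar_volume` with `unit = "HU"`.
#' @export
read_ct_scan <- function(path, sidecar = sidecar_path(path)) {
  origin <- NULL
  if (file.exists(sidecar)) {
    sc <- read_sidecar(sidecar)
    if (!is.null(sc$origin_mm)) origin <- as.numeric(sc$origin_mm)
  }
  read_volume_nifti(path, unit = "HU", origin = origin)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a scalar volume to NIfTI (+ JSON sidecar)
#'
#' @param vol a `scalar_volume`.
#' @param path output NIfTI path.
#' @param sidecar_data named list written as the JSON sidecar (geometry
#'   fields `origin_mm` and `unit` are added automatically); `NULL` to skip.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, sidecar_data = list()) {
  stopifnot(inherits(vol, "scalar_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar_data)) {
    sidecar_data$origin_mm <- vol$origin
    if (is.null(sidecar_data$unit)) sidecar_data$unit <- vol$unit
    jsonlite::write_json(sidecar_data, sidecar_path(path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
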