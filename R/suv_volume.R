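#' SUV volume container
#'
#' Bundles a 3D array of standardized uptake values (SUV, dimensionless) with
#' its voxel spacing in mm and optional study annotations. All spatial
#' computations in the package use the voxel-centre convention: the centre of
#' voxel `(i, j, k)` (1-based) sits at `(i - 0.5, j - 0.5, k - 0.5) *
#' voxel_size_mm` in the volume's own axis-aligned frame. World orientation is
#' not tracked; phantoms and analyses are axis-aligned.
#'
#' @param data 3D numeric array of SUV values; all finite and non-negative.
#' @param voxel_size_mm numeric length-3 (or scalar, recycled) voxel spacing
#'   in mm, all positive.
#' @param patient_id optional patient identifier.
#' @param timepoint optional, `"baseline"` or `"follow_up"`.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(data, voxel_size_mm, patient_id = NA_character_,
                       timepoint = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("SUV volume contains non-finite values")
  if (any(data < 0))
    stop("SUV values must be non-negative")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be positive")
  if (!is.na(timepoint))
    timepoint <- match.arg(timepoint, c("baseline", "follow_up"))
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm,
         patient_id = patient_id, timepoint = timepoint),
    class = "suv_volume"
  )
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("<suv_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(format(x$voxel_size_mm), collapse = " x "),
      " mm\n", sep = "")
  cat("  SUV range: [", format(min(x$data)), ", ", format(max(x$data)),
      "]\n", sep = "")
  if (!is.na(x$patient_id))
    cat("  patient: ", x$patient_id, " (", x$timepoint, ")\n", sep = "")
  invisible(x)
}

# voxel-centre coordinates (mm) along one axis
voxel_centres <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# physical extent of the volume along each axis, mm
volume_extent_mm <- function(vol) dim(vol$data) * vol$voxel_size_mm

# voxel volume in cm^3
voxel_volume_cm3 <- function(vol) prod(vol$voxel_size_mm) / 1000

#' Read an SUV volume from NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` file whose header carries voxel
#'   spacing (pixdim) in mm.
#' @param patient_id,timepoint annotations attached to the result.
#' @return An [suv_volume].
#' @export
read_volume <- function(path, patient_id = NA_character_,
                        timepoint = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (length(spacing) < 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI header carries no usable voxel spacing: ", path)
  arr <- array(as.numeric(img), dim = dim(img)[seq_len(3)])
  suv_volume(arr, spacing, patient_id = patient_id, timepoint = timepoint)
}

#' Write an SUV volume to NIfTI
#'
#' Voxel spacing is stored in the header pixdim; a write/read round trip
#' preserves data and spacing to float precision.
#'
#' @param vol an [suv_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "suv_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Injection metadata for SUV conversion
#'
#' @param injected_dose_MBq injected activity in MBq at injection time.
#' @param body_weight_kg patient body weight in kg.
#' @param injection_time,acquisition_time times in minutes (any common
#'   origin); acquisition must not precede injection.
#' @param half_life_min radionuclide half-life in minutes; default is
#'   68Ga (67.71 min).
#' @return An object of class `injection_meta`.
#' @export
injection_meta <- function(injected_dose_MBq, body_weight_kg,
                           injection_time = 0, acquisition_time = 0,
                           half_life_min = 67.71) {
  if (injected_dose_MBq <= 0) stop("injected dose must be positive")
  if (body_weight_kg <= 0) stop("body weight must be positive")
  if (acquisition_time < injection_time)
    stop("acquisition time precedes injection time")
  if (half_life_min <= 0) stop("half-life must be positive")
  structure(list(injected_dose_MBq = injected_dose_MBq,
                 body_weight_kg = body_weight_kg,
                 injection_time = injection_time,
                 acquisition_time = acquisition_time,
                 half_life_min = half_life_min),
            class = "injection_meta")
}

#' Convert an activity-concentration volume to SUV
#'
#' Body-weight SUV: `SUV = C / (D / w)` with `C` the activity concentration
#' (Bq/mL), `w` the body weight in grams and `D` the injected dose in Bq
#' decay-corrected to the acquisition start,
#' `D = D0 * 2^(-(t_acq - t_inj) / T_half)`. Tissue density is taken as
#' 1 g/mL, the usual convention.
#'
#' @param activity 3D array of activity concentration in Bq/mL.
#' @param meta an [injection_meta].
#' @param voxel_size_mm voxel spacing passed through to the result.
#' @param patient_id,timepoint annotations.
#' @return An [suv_volume].
#' @export
activity_to_suv <- function(activity, meta, voxel_size_mm,
                            patient_id = NA_character_,
                            timepoint = NA_character_) {
  stopifnot(inherits(meta, "injection_meta"))
  elapsed_min <- meta$acquisition_time - meta$injection_time
  dose_bq <- meta$injected_dose_MBq * 1e6 *
    2^(-elapsed_min / meta$half_life_min)
  if (dose_bq <= 0) stop("decay-corrected dose must be positive")
  weight_g <- meta$body_weight_kg * 1000
  suv <- activity * weight_g / dose_bq
  suv_volume(suv, voxel_size_mm, patient_id = patient_id,
             timepoint = timepoint)
}
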