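#' Lesion specification for the synthetic phantom
#'
#' @param center_mm lesion centre in mm (length 3).
#' @param shape `"sphere"`, `"ellipsoid"` or `"box"`. The box shape exists so
#'   that exact-volume checks reduce to integer arithmetic.
#' @param radii_mm radius (sphere: scalar) or per-axis semi-axes/half-widths
#'   in mm, all positive.
#' @param peak_suv uniform SUV of the lesion before blurring; must exceed the
#'   phantom background.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, shape = c("sphere", "ellipsoid", "box"),
                        radii_mm, peak_suv) {
  shape <- match.arg(shape)
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L) stop("`center_mm` must have length 3")
  radii_mm <- rep_len(as.numeric(radii_mm), 3L)
  if (any(radii_mm <= 0)) stop("`radii_mm` must be positive")
  if (peak_suv <= 0) stop("`peak_suv` must be positive")
  structure(list(center_mm = center_mm, shape = shape, radii_mm = radii_mm,
                 peak_suv = peak_suv),
            class = "lesion_spec")
}

#' Phantom specification
#'
#' Describes a synthetic whole-body-like SUV volume: a uniform background, a
#' spherical liver-like organ with Gaussian voxel noise of its own, and a set
#' of high-uptake lesions. The phantom emulates the substrate of a PSMA PET
#' study — lesions of known volume and uptake over a liver reference region —
#' without any scanner physics.
#'
#' @param grid_shape voxels per axis (length 3, positive integers).
#' @param voxel_size_mm voxel spacing in mm (scalar or length 3).
#' @param background_suv background SUV level.
#' @param liver_center_mm,liver_radius_mm geometry of the liver-like sphere.
#' @param liver_mean_suv,liver_sd_suv mean and per-voxel Gaussian SD of the
#'   liver SUV.
#' @param lesions list of [lesion_spec] objects.
#' @param psf_sigma_mm Gaussian point-spread blur width in mm (0 = none),
#'   applied before noise.
#' @param noise_sd additive i.i.d. Gaussian noise SD per voxel (0 = none).
#' @param seed RNG seed; identical spec + seed gives bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48), voxel_size_mm = 4,
                         background_suv = 0.5,
                         liver_center_mm = NULL, liver_radius_mm = 40,
                         liver_mean_suv = 5, liver_sd_suv = 0.5,
                         lesions = list(), psf_sigma_mm = 0, noise_sd = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be 3 positive integers")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("`voxel_size_mm` must be positive")
  extent <- grid_shape * voxel_size_mm
  if (is.null(liver_center_mm)) liver_center_mm <- extent / 2
  if (psf_sigma_mm < 0) stop("`psf_sigma_mm` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (background_suv < 0) stop("`background_suv` must be >= 0")
  for (les in lesions) {
    stopifnot(inherits(les, "lesion_spec"))
    if (any(les$center_mm < 0) || any(les$center_mm > extent))
      stop("lesion centre outside the grid")
    if (les$peak_suv <= background_suv)
      stop("lesion peak SUV must exceed the background")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 background_suv = background_suv,
                 liver_center_mm = as.numeric(liver_center_mm),
                 liver_radius_mm = liver_radius_mm,
                 liver_mean_suv = liver_mean_suv,
                 liver_sd_suv = liver_sd_suv,
                 lesions = lesions, psf_sigma_mm = psf_sigma_mm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# logical mask of voxels whose CENTRES lie inside the shape
shape_mask <- function(grid_shape, voxel_size_mm, center_mm, shape, radii_mm) {
  cx <- voxel_centres(grid_shape[1], voxel_size_mm[1])
  cy <- voxel_centres(grid_shape[2], voxel_size_mm[2])
  cz <- voxel_centres(grid_shape[3], voxel_size_mm[3])
  dx <- (cx - center_mm[1])
  dy <- (cy - center_mm[2])
  dz <- (cz - center_mm[3])
  if (shape == "box") {
    m <- outer(outer(abs(dx) <= radii_mm[1], abs(dy) <= radii_mm[2], "&"),
               abs(dz) <= radii_mm[3], "&")
  } else {
    # sphere is an ellipsoid with equal semi-axes
    m <- outer(outer((dx / radii_mm[1])^2, (dy / radii_mm[2])^2, "+"),
               (dz / radii_mm[3])^2, "+") <= 1
  }
  m
}

# separable Gaussian blur; sigma in mm, converted to voxels per axis.
# Truncated at 4 sigma; the kernel is renormalized per row so flat regions
# stay flat at the edges.
gaussian_blur_3d <- function(arr, sigma_mm, voxel_size_mm) {
  for (ax in 1:3) {
    sig <- sigma_mm / voxel_size_mm[ax]
    if (sig <= 0) next
    n <- dim(arr)[ax]
    r <- max(1L, ceiling(4 * sig))
    idx <- seq_len(n)
    K <- stats::dnorm(outer(idx, idx, "-"), sd = sig)
    K[abs(outer(idx, idx, "-")) > r] <- 0
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    d <- dim(a)
    a <- K %*% matrix(a, nrow = d[1])
    dim(a) <- d
    arr <- aperm(a, order(perm))
  }
  arr
}

# run `expr` under a private RNG stream so callers' RNG state is untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic SUV phantom with known ground truth
#'
#' Builds the analytic phantom (background, liver sphere with per-voxel
#' Gaussian variation, lesions at uniform peak SUV), then applies the optional
#' Gaussian point-spread blur and additive voxel noise. Ground truth reports,
#' per lesion, the analytic volume — the count of voxels whose centres fall
#' inside the shape times the voxel volume — and the peak SUV, both taken
#' before blur and noise.
#'
#' Lesions must not overlap one another or the liver sphere; overlap would
#' make the per-lesion ground truth ambiguous and is an error.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `volume` (an [suv_volume]) and `ground_truth`
#'   (data frame: `lesion_id`, `voxel_count`, `volume_cm3`, `peak_suv`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; vs <- spec$voxel_size_mm
  liver <- shape_mask(gs, vs, spec$liver_center_mm, "sphere",
                      rep(spec$liver_radius_mm, 3))
  lesion_masks <- lapply(spec$lesions, function(l)
    shape_mask(gs, vs, l$center_mm, l$shape, l$radii_mm))
  occupancy <- liver
  for (m in lesion_masks) {
    if (any(m & occupancy))
      stop("lesion overlaps the liver or another lesion; ground truth ",
           "would be ambiguous")
    occupancy <- occupancy | m
  }
  vox_cm3 <- prod(vs) / 1000
  gt <- data.frame(
    lesion_id = seq_along(lesion_masks),
    voxel_count = vapply(lesion_masks, sum, integer(1)),
    volume_cm3 = vapply(lesion_masks, sum, integer(1)) * vox_cm3,
    peak_suv = vapply(spec$lesions, function(l) l$peak_suv, numeric(1))
  )
  arr <- with_seed(spec$seed, {
    a <- array(spec$background_suv, dim = gs)
    nliv <- sum(liver)
    if (nliv > 0)
      a[liver] <- stats::rnorm(nliv, spec$liver_mean_suv, spec$liver_sd_suv)
    for (i in seq_along(lesion_masks))
      a[lesion_masks[[i]]] <- spec$lesions[[i]]$peak_suv
    if (spec$psf_sigma_mm > 0)
      a <- gaussian_blur_3d(a, spec$psf_sigma_mm, vs)
    if (spec$noise_sd > 0)
      a <- a + stats::rnorm(length(a), 0, spec$noise_sd)
    pmax(a, 0)
  })
  list(volume = suv_volume(arr, vs), ground_truth = gt)
}

#' Paired-measurement simulation specification
#'
#' Describes paired "method A / method B" biomarker measurements whose
#' relative differences (as percent of the pair mean, the same convention as
#' [bland_altman()]) follow a Gaussian, with an optional wider outlier
#' component. True values are log-normal, mimicking the heavy right tail of
#' whole-body tumour-volume distributions.
#'
#' @param n_patients number of pairs (>= 2).
#' @param log_mean,log_sd parameters of the log-normal true-value
#'   distribution (natural log scale).
#' @param bias_pct,sd_pct mean and SD of the relative difference, in percent.
#' @param outlier_fraction probability that a pair is drawn from the outlier
#'   component.
#' @param outlier_sd_pct SD of the outlier component, percent.
#' @param seed RNG seed.
#' @return An object of class `paired_measurement_spec`.
#' @export
paired_measurement_spec <- function(n_patients, log_mean = log(50),
                                    log_sd = 1, bias_pct = 0, sd_pct = 20,
                                    outlier_fraction = 0,
                                    outlier_sd_pct = 3 * sd_pct, seed = 1L) {
  if (n_patients < 2) stop("`n_patients` must be >= 2")
  if (sd_pct < 0) stop("`sd_pct` must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction > 1)
    stop("`outlier_fraction` must be in [0, 1]")
  structure(list(n_patients = as.integer(n_patients), log_mean = log_mean,
                 log_sd = log_sd, bias_pct = bias_pct, sd_pct = sd_pct,
                 outlier_fraction = outlier_fraction,
                 outlier_sd_pct = outlier_sd_pct, seed = as.integer(seed)),
            class = "paired_measurement_spec")
}

#' Simulate paired two-method measurements
#'
#' Draws the true value A from the log-normal, draws the pair's relative
#' difference d (percent) from the Gaussian (or the outlier component), and
#' sets `B = A * (1 - d/200) / (1 + d/200)` so that
#' `(A - B) / ((A + B) / 2) * 100 = d` holds exactly.
#'
#' @param spec a [paired_measurement_spec].
#' @return Data frame with columns `patient_id`, `value_A`, `value_B`,
#'   `true_rel_diff_pct`, `outlier`.
#' @export
generate_paired_measurements <- function(spec) {
  stopifnot(inherits(spec, "paired_measurement_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    a <- stats::rlnorm(n, spec$log_mean, spec$log_sd)
    is_out <- stats::runif(n) < spec$outlier_fraction
    sd_vec <- ifelse(is_out, spec$outlier_sd_pct, spec$sd_pct)
    d <- stats::rnorm(n, spec$bias_pct, sd_vec)
    b <- a * (1 - d / 200) / (1 + d / 200)
    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               value_A = a, value_B = b,
               true_rel_diff_pct = d, outlier = is_out)
  })
}
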