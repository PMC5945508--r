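#' Specification of a synthetic tumor phantom
#'
#' Describes one simulated subject: a spherical tumor with a smooth
#' heterogeneity texture embedded in a uniform soft-tissue background, plus a
#' box-shaped reference muscle region. The defaults emulate a pelvic
#' gynecological-cancer geometry on a 4 x 4 x 2 mm grid: a 15-mm-radius tumor
#' with mean uptake 9 SUV over a background of 1 SUV, and a gluteal-muscle
#' reference box of 0.7 SUV, giving a tumor-to-muscle ratio near 13.
#'
#' @param shape Integer triplet, grid size in voxels (x, y, z).
#' @param spacing Numeric triplet, mm per voxel.
#' @param tumor_center Voxel triplet (1-based) of the tumor sphere center.
#' @param tumor_radius Tumor radius in mm.
#' @param tumor_mean Mean tumor uptake (SUV).
#' @param heterogeneity Standard deviation (SUV) of the smooth spatial texture
#'   field modulating the tumor; 0 gives a perfectly uniform tumor.
#' @param het_length Correlation length (FWHM, mm) of the texture field.
#' @param background Background uptake (SUV).
#' @param muscle Muscle uptake (SUV).
#' @param muscle_box List with `lo` and `hi` voxel triplets bounding the
#'   muscle reference region (inclusive); must not intersect the tumor sphere.
#' @param seed Integer seed for the heterogeneity field.
#'
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec()
#' ph <- generate_phantom(spec)
#' mask_statistics(ph$volume, ph$tumor)
#' @export
phantom_spec <- function(shape = c(48L, 48L, 64L),
                         spacing = c(4, 4, 2),
                         tumor_center = c(24, 24, 32),
                         tumor_radius = 15,
                         tumor_mean = 9,
                         heterogeneity = 1.5,
                         het_length = 8,
                         background = 1,
                         muscle = 0.7,
                         muscle_box = list(lo = c(6, 6, 20), hi = c(12, 12, 44)),
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), length(spacing) == 3L,
            all(spacing > 0), length(tumor_center) == 3L)
  if (tumor_radius <= 0) stop("tumor_radius must be > 0", call. = FALSE)
  if (!(tumor_mean > background) || background < 0) {
    stop("require tumor_mean > background >= 0", call. = FALSE)
  }
  if (heterogeneity < 0 || muscle < 0) {
    stop("heterogeneity and muscle uptake must be >= 0", call. = FALSE)
  }
  spec <- structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                         tumor_center = as.numeric(tumor_center),
                         tumor_radius = tumor_radius, tumor_mean = tumor_mean,
                         heterogeneity = heterogeneity, het_length = het_length,
                         background = background, muscle = muscle,
                         muscle_box = muscle_box, seed = as.integer(seed)),
                    class = "phantom_spec")
  if (any(sphere_flags(spec) & box_flags(spec))) {
    stop("muscle_box must be disjoint from the tumor sphere", call. = FALSE)
  }
  spec
}

sphere_flags <- function(spec) {
  d <- spec$shape
  cx <- (seq_len(d[1]) - spec$tumor_center[1]) * spec$spacing[1]
  cy <- (seq_len(d[2]) - spec$tumor_center[2]) * spec$spacing[2]
  cz <- (seq_len(d[3]) - spec$tumor_center[3]) * spec$spacing[3]
  r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  array(r2 <= spec$tumor_radius^2, dim = d)
}

box_flags <- function(spec) {
  d <- spec$shape
  f <- array(FALSE, dim = d)
  b <- spec$muscle_box
  f[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- TRUE
  f
}

#' Generate one noiseless phantom subject
#'
#' Builds the ground-truth activity distribution: background everywhere, the
#' muscle box at its uptake, and the tumor sphere at
#' `tumor_mean + heterogeneity * field`, where `field` is a seeded white-noise
#' field smoothed to the requested correlation length and standardized to
#' zero mean / unit SD over the tumor voxels. Scanner effects (noise, bias,
#' smoothing, resampling) are applied separately by [apply_condition()].
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([suv_volume()]), `tumor` and
#'   `muscle` (ground-truth [region_mask()]s).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  r_vox <- spec$tumor_radius / spec$spacing
  lo <- spec$tumor_center - r_vox
  hi <- spec$tumor_center + r_vox
  if (any(lo < 0.5) || any(hi > d + 0.5)) {
    stop("geometry error: tumor sphere exceeds grid bounds", call. = FALSE)
  }
  tumor <- sphere_flags(spec)
  if (!any(tumor)) stop("geometry error: tumor sphere contains no voxel centers",
                        call. = FALSE)
  muscle <- box_flags(spec)

  vals <- array(spec$background, dim = d)
  vals[muscle] <- spec$muscle
  tumor_vals <- rep(spec$tumor_mean, sum(tumor))
  if (spec$heterogeneity > 0) {
    field <- with_seed(spec$seed, array(stats::rnorm(prod(d)), dim = d))
    field <- gaussian_smooth3d(field, spec$spacing, spec$het_length)
    f <- field[tumor]
    if (stats::sd(f) > 0) f <- (f - mean(f)) / stats::sd(f) else f <- f * 0
    tumor_vals <- spec$tumor_mean + spec$heterogeneity * f
  }
  vals[tumor] <- pmax(tumor_vals, 0)
  list(volume = suv_volume(vals, spacing = spec$spacing),
       tumor = region_mask(tumor), muscle = region_mask(muscle))
}

#' Specification of one acquisition condition
#'
#' Describes how one scan condition transforms the ground-truth activity:
#' delayed-uptake scaling of the tumor, a global attenuation-correction (AC)
#' bias multiplier (MR-based AC omits bone and underestimates uptake, so
#' `ac_bias <= 1`), additive Gaussian noise whose SD shrinks with the square
#' root of the acquisition duration, Gaussian post-smoothing, and resampling
#' to the scanner's native voxel grid.
#'
#' @param name Condition label, e.g. `"early"`, `"delayed_short"`.
#' @param uptake_scale Multiplier (> 0) applied to tumor voxels before any
#'   scanner effect; models continued tracer accumulation at delayed scans.
#' @param ac_bias Multiplier in (0, 1] applied to all uptake.
#' @param noise_sd SD (SUV) of additive Gaussian noise, before smoothing.
#' @param smoothing_fwhm Post-reconstruction Gaussian filter FWHM in mm.
#' @param spacing Output voxel spacing in mm, or `NULL` to keep the input grid.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(name, uptake_scale = 1, ac_bias = 1, noise_sd = 0,
                           smoothing_fwhm = 0, spacing = NULL) {
  if (uptake_scale <= 0) stop("uptake_scale must be > 0", call. = FALSE)
  if (ac_bias <= 0 || ac_bias > 1) stop("ac_bias must be in (0, 1]", call. = FALSE)
  if (noise_sd < 0 || smoothing_fwhm < 0) {
    stop("noise_sd and smoothing_fwhm must be >= 0", call. = FALSE)
  }
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    stopifnot(length(spacing) == 3L, all(spacing > 0))
  }
  structure(list(name = as.character(name), uptake_scale = uptake_scale,
                 ac_bias = ac_bias, noise_sd = noise_sd,
                 smoothing_fwhm = smoothing_fwhm, spacing = spacing),
            class = "condition_spec")
}

#' The three study conditions of a paired PET/CT + PET/MR protocol
#'
#' Returns the default condition set emulating an early whole-body PET/CT
#' scan (4 x 4 x 2 mm voxels, CT-based AC) followed by a delayed regional
#' PET/MR scan reconstructed from a short (0-2 min) and a long (0-10 min)
#' acquisition window (4 x 4 x 2.78 mm voxels, MR-based AC). All three use a
#' 4-mm Gaussian post-filter. Delayed tumor uptake is scaled by
#' `delayed_uptake`, delayed images carry the MR-AC bias `mr_ac_bias`, and the
#' noise SD of the delayed windows scales as 1/sqrt(duration): the 2-min
#' window has sqrt(5) times the SD of the 10-min window.
#'
#' @param delayed_uptake Tumor uptake multiplier at the delayed time point.
#' @param mr_ac_bias AC bias multiplier of the MR-based conditions.
#' @param noise_sd_early Noise SD (SUV) of the early whole-body scan.
#' @param noise_sd_10min Noise SD (SUV) of the delayed 10-min reconstruction.
#' @return A named list of three [condition_spec()]s:
#'   `early`, `delayed_short`, `delayed_long`.
#' @export
study_conditions <- function(delayed_uptake = 1.3, mr_ac_bias = 0.9,
                             noise_sd_early = 0.3, noise_sd_10min = 0.2) {
  list(
    early = condition_spec("early", uptake_scale = 1, ac_bias = 1,
                           noise_sd = noise_sd_early, smoothing_fwhm = 4,
                           spacing = c(4, 4, 2)),
    delayed_short = condition_spec("delayed_short", uptake_scale = delayed_uptake,
                                   ac_bias = mr_ac_bias,
                                   noise_sd = noise_sd_10min * sqrt(5),
                                   smoothing_fwhm = 4, spacing = c(4, 4, 2.78)),
    delayed_long = condition_spec("delayed_long", uptake_scale = delayed_uptake,
                                  ac_bias = mr_ac_bias,
                                  noise_sd = noise_sd_10min,
                                  smoothing_fwhm = 4, spacing = c(4, 4, 2.78))
  )
}

#' Apply an acquisition condition to a ground-truth volume
#'
#' The fixed order of operations is: tumor uptake scaling, AC bias, additive
#' Gaussian noise, Gaussian smoothing, trilinear resampling to the condition
#' grid, and clipping of negative values to zero. With `uptake_scale = 1`,
#' `ac_bias = 1`, `noise_sd = 0`, `smoothing_fwhm = 0` and unchanged spacing
#' the output equals the input exactly.
#'
#' @param volume Ground-truth [suv_volume()].
#' @param tumor_mask Ground-truth tumor [region_mask()] (receives the uptake
#'   scaling).
#' @param cond A [condition_spec()].
#' @param seed Integer seed for the noise realization.
#' @return An [suv_volume()] on the condition's grid. The number of
#'   negative voxels clipped to zero is attached as attribute `n_clipped`.
#' @export
apply_condition <- function(volume, tumor_mask, cond, seed = 1L) {
  check_alignment(volume, tumor_mask)
  stopifnot(inherits(cond, "condition_spec"))
  vals <- volume$values
  vals[tumor_mask$flags] <- vals[tumor_mask$flags] * cond$uptake_scale
  vals <- vals * cond$ac_bias
  if (cond$noise_sd > 0) {
    vals <- vals + with_seed(seed,
      array(stats::rnorm(length(vals), sd = cond$noise_sd), dim = dim(vals)))
  }
  vals <- gaussian_smooth3d(vals, volume$spacing, cond$smoothing_fwhm)
  sp_out <- if (is.null(cond$spacing)) volume$spacing else cond$spacing
  vals <- resample_trilinear(vals, volume$spacing, sp_out)
  n_clipped <- sum(vals < 0)
  vals[vals < 0] <- 0
  out <- suv_volume(vals, spacing = sp_out, origin = volume$origin)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Resample a ground-truth mask onto a condition's voxel grid
#'
#' Nearest-neighbor resampling preserving the physical field of view; used to
#' carry ground-truth tumor/muscle masks onto the native grid of each
#' simulated scanner.
#'
#' @param mask A [region_mask()].
#' @param spacing_in,spacing_out Input and output voxel spacing (mm).
#' @return A [region_mask()] on the output grid.
#' @export
resample_mask <- function(mask, spacing_in, spacing_out) {
  stopifnot(inherits(mask, "region_mask"))
  region_mask(resample_nearest(mask$flags, as.numeric(spacing_in),
                               as.numeric(spacing_out)))
}

#' Generate a paired multi-condition phantom cohort
#'
#' Simulates `n_subjects` tumors, each imaged under every condition, mirroring
#' a paired design in which the same lesion is scanned on two scanners at two
#' time points. Per-subject random effects on tumor size, uptake and
#' heterogeneity are shared across that subject's conditions, which induces
#' the cross-condition feature correlation a repeated-measures analysis
#' relies on. Multipliers are log-normal: `exp(rnorm(1, 0, sd))` with the
#' given coefficient-of-variation-like SDs; all-zero variability makes every
#' subject identical up to noise seeds.
#'
#' @param n_subjects Number of simulated subjects (>= 2).
#' @param base_spec A [phantom_spec()] serving as the cohort template.
#' @param conditions Named list of [condition_spec()]s (>= 2).
#' @param subject_sd Named numeric vector with elements `size`, `uptake`,
#'   `heterogeneity`: SDs of the per-subject log-normal multipliers.
#' @param seed Master integer seed; all per-subject and per-condition seeds
#'   are derived from it by a counter scheme.
#' @return A tibble with one row per (subject, condition): columns
#'   `subject` (factor), `condition` (factor), and list-columns `volume`
#'   (condition-grid [suv_volume()]), `tumor_truth` and `muscle`
#'   (condition-grid [region_mask()]s).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_subjects = 2, seed = 7)
#' nrow(cohort)
#' }
#' @export
generate_cohort <- function(n_subjects = 8,
                            base_spec = phantom_spec(),
                            conditions = study_conditions(),
                            subject_sd = c(size = 0.1, uptake = 0.15,
                                           heterogeneity = 0.15),
                            seed = 1L) {
  stopifnot(n_subjects >= 2, length(conditions) >= 2)
  cond_names <- vapply(conditions, `[[`, character(1), "name")
  rows <- list()
  for (i in seq_len(n_subjects)) {
    eff <- with_seed(derive_seed(seed, i, 0L, 1L),
                     stats::rnorm(3, 0, c(subject_sd[["size"]],
                                          subject_sd[["uptake"]],
                                          subject_sd[["heterogeneity"]])))
    spec_i <- base_spec
    spec_i$tumor_radius <- base_spec$tumor_radius * exp(eff[1])
    spec_i$tumor_mean <- base_spec$tumor_mean * exp(eff[2])
    spec_i$heterogeneity <- base_spec$heterogeneity * exp(eff[3])
    spec_i$seed <- derive_seed(seed, i, 0L, 2L)
    ph <- generate_phantom(spec_i)
    for (j in seq_along(conditions)) {
      cond <- conditions[[j]]
      vol <- apply_condition(ph$volume, ph$tumor, cond,
                             seed = derive_seed(seed, i, j, 3L))
      sp_out <- if (is.null(cond$spacing)) base_spec$spacing else cond$spacing
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = sprintf("S%02d", i),
        condition = cond_names[j],
        volume = list(vol),
        tumor_truth = list(resample_mask(ph$tumor, base_spec$spacing, sp_out)),
        muscle = list(resample_mask(ph$muscle, base_spec$spacing, sp_out))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$subject <- factor(out$subject)
  out$condition <- factor(out$condition, levels = cond_names)
  out
}
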