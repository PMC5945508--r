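#' Fixed-bound (absolute) discretization configuration
#'
#' Absolute resampling maps SUV onto a fixed number of integer gray levels
#' between bounds shared by every lesion, so the bin width in SUV units is
#' identical across tumors and scans. The defaults (bounds 0-25 SUV, 64
#' bins) give a bin width of about 0.4 SUV; 8 and 256 bins give about 3.1
#' and 0.1 SUV. Relative (per-lesion min-max) resampling is deliberately not
#' offered: it ties the bin width to lesion contrast and volume.
#'
#' @param lower,upper Intensity bounds in SUV; `upper > lower`.
#' @param bins Number of gray levels (>= 2).
#' @return An object of class `discretization_config`.
#' @examples
#' bin_width(discretization_config(bins = 64))
#' @export
discretization_config <- function(lower = 0, upper = 25, bins = 64L) {
  if (!(upper > lower)) stop("upper bound must exceed lower bound", call. = FALSE)
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  structure(list(lower = lower, upper = upper, bins = as.integer(bins)),
            class = "discretization_config")
}

#' Bin width of a discretization configuration
#'
#' @param config A [discretization_config()].
#' @return `(upper - lower) / bins`, in SUV units.
#' @export
bin_width <- function(config) {
  stopifnot(inherits(config, "discretization_config"))
  (config$upper - config$lower) / config$bins
}

# round half away from zero; inputs here are always >= 0, but keep the
# general rule so the behavior never depends on IEC half-to-even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Discretize VOI intensities onto integer gray levels
#'
#' Per voxel, `level = round(bins * (I - lower) / (upper - lower))` with
#' round-half-away-from-zero, after clipping `I` into `[lower, upper]`. Raw
#' levels span `0..bins` (bins + 1 values); level 0 is clamped into level 1
#' so levels index standard co-occurrence and run-length matrices 1..bins.
#' The clamp only affects voxels within half a bin of the lower bound, which
#' a tumor VOI essentially never contains.
#'
#' @param volume An [suv_volume()].
#' @param mask Non-empty [region_mask()] marking the VOI.
#' @param config A [discretization_config()].
#' @return An object of class `gray_level_volume`: list with `levels`
#'   (integer array, `NA` outside the mask), `config`, `mask`, and
#'   `n_clipped`, the number of voxels whose intensity was clipped into the
#'   bounds.
#' @examples
#' vol <- suv_volume(array(12.5, dim = c(2, 2, 2)))
#' m <- region_mask(array(TRUE, dim = c(2, 2, 2)))
#' g <- discretize(vol, m, discretization_config())
#' unique(g$levels[m$flags])  # round(64 * 12.5 / 25) = 32
#' @export
discretize <- function(volume, mask, config = discretization_config()) {
  check_alignment(volume, mask)
  if (mask_size(mask) == 0L) {
    stop("empty-region error: mask contains no voxels", call. = FALSE)
  }
  v <- volume$values[mask$flags]
  n_clipped <- sum(v < config$lower | v > config$upper)
  v <- pmin(pmax(v, config$lower), config$upper)
  lev <- round_half_away(config$bins * (v - config$lower) /
                           (config$upper - config$lower))
  lev <- pmin(pmax(lev, 1), config$bins)
  levels <- array(NA_integer_, dim = dim(volume$values))
  levels[mask$flags] <- as.integer(lev)
  structure(list(levels = levels, config = config, mask = mask,
                 n_clipped = n_clipped),
            class = "gray_level_volume")
}

#' @export
print.gray_level_volume <- function(x, ...) {
  cat(sprintf("<gray_level_volume> %d voxels, %d bins on [%g, %g] SUV (bin width %g)\n",
              mask_size(x$mask), x$config$bins, x$config$lower, x$config$upper,
              bin_width(x$config)))
  invisible(x)
}

#' Reconstruct bin-center SUVs from gray levels
#'
#' Maps each level back to the intensity at the center of its bin
#' (`lower + level * bin_width`); discretizing the reconstruction reproduces
#' the original levels.
#'
#' @param gray A [gray_level_volume()][discretize].
#' @return An [suv_volume()] with bin-center values (0 outside the mask).
#' @export
reconstruct_bin_centers <- function(gray) {
  stopifnot(inherits(gray, "gray_level_volume"))
  vals <- array(0, dim = dim(gray$levels))
  inm <- gray$mask$flags
  vals[inm] <- gray$config$lower + gray$levels[inm] * bin_width(gray$config)
  suv_volume(vals)
}
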