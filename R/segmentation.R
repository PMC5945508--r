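#' Parameters of the contrast-oriented adaptive threshold
#'
#' The delineation threshold is `T = beta * I70 + Ibgd`, where `I70` is the
#' mean uptake of the connected high-uptake core (all voxels above
#' `core_fraction` of the search-region maximum) and `Ibgd` is the mean
#' background uptake in a shell around that core. The shell starts
#' `shell_gap` Chebyshev dilation steps outside the core and is
#' `shell_thickness` steps thick; only shell voxels below `background_cap`
#' SUV enter the background mean, so spill-over from neighboring hot
#' structures is excluded.
#'
#' @param beta Dimensionless contrast weight in (0, 1); default 0.3, the
#'   value calibrated on a Jaszczak phantom for this algorithm family.
#' @param core_fraction Fraction of the maximum uptake defining the core
#'   contour; default 0.70.
#' @param shell_gap Distance from core to inner shell face, in voxel
#'   dilation steps; default 6.
#' @param shell_thickness Shell thickness in voxel dilation steps; default 2.
#' @param background_cap Upper SUV limit for shell voxels entering the
#'   background mean; default 2.5.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(beta = 0.3, core_fraction = 0.70,
                                shell_gap = 6L, shell_thickness = 2L,
                                background_cap = 2.5) {
  if (beta <= 0 || beta >= 1) stop("beta must be in (0, 1)", call. = FALSE)
  if (core_fraction <= 0 || core_fraction >= 1) {
    stop("core_fraction must be in (0, 1)", call. = FALSE)
  }
  if (shell_gap < 1 || shell_thickness < 1) {
    stop("shell_gap and shell_thickness must be >= 1", call. = FALSE)
  }
  if (background_cap <= 0) stop("background_cap must be > 0", call. = FALSE)
  structure(list(beta = beta, core_fraction = core_fraction,
                 shell_gap = as.integer(shell_gap),
                 shell_thickness = as.integer(shell_thickness),
                 background_cap = background_cap),
            class = "segmentation_params")
}

search_max_idx <- function(volume, search) {
  in_search <- which(search$flags)
  in_search[which.max(volume$values[in_search])]
}

#' High-uptake core of the tumor
#'
#' Returns the 26-connected component, among search-region voxels with value
#' strictly greater than `core_fraction` times the search-region maximum,
#' that contains the maximum voxel. Strict ">" follows the contour
#' definition "greater than 70 % of the maximum uptake"; a region whose
#' maximum is 0 therefore has an empty core.
#'
#' @param volume An [suv_volume()].
#' @param search Non-empty [region_mask()] bounding the tumor.
#' @param params A [segmentation_params()].
#' @return A [region_mask()] of the core.
#' @export
core_region <- function(volume, search, params = segmentation_params()) {
  check_alignment(volume, search)
  if (mask_size(search) == 0L) {
    stop("empty-region error: search region contains no voxels", call. = FALSE)
  }
  vmax <- max(volume$values[search$flags])
  cand <- search$flags & (volume$values > params$core_fraction * vmax)
  if (!any(cand)) {
    stop("degenerate-input error: no voxel exceeds ", params$core_fraction,
         " x max; core contour is empty", call. = FALSE)
  }
  region_mask(connected_component(cand, search_max_idx(volume, search)))
}

#' Mean uptake of the core contour (I70)
#'
#' @inheritParams core_region
#' @return Mean SUV over the core region.
#' @export
i70 <- function(volume, search, params = segmentation_params()) {
  core <- core_region(volume, search, params)
  mean(volume$values[core$flags])
}

#' Mean background uptake in a shell around the core (Ibgd)
#'
#' The shell is the set of voxels at Chebyshev dilation distance in
#' `(shell_gap, shell_gap + shell_thickness]` from the core; of these, only
#' voxels with uptake strictly below `background_cap` enter the mean. The
#' cap applies to shell voxels only, never to the tumor VOI itself.
#'
#' @param volume An [suv_volume()].
#' @param core Core [region_mask()] from [core_region()].
#' @param params A [segmentation_params()].
#' @return Mean SUV of the qualifying shell voxels.
#' @export
i_bgd <- function(volume, core, params = segmentation_params()) {
  check_alignment(volume, core)
  if (mask_size(core) == 0L) {
    stop("empty-region error: core contains no voxels", call. = FALSE)
  }
  # shell construction only needs the core neighborhood, so dilate on the
  # padded core bounding box rather than the whole grid
  margin <- params$shell_gap + params$shell_thickness
  bb <- mask_bbox(core$flags, pad = margin)
  core_c <- crop_bbox(core$flags, bb)
  inner <- dilate(core_c, params$shell_gap)
  outer_ <- dilate(inner, params$shell_thickness)
  shell_c <- outer_ & !inner
  shell <- array(FALSE, dim = dim(core$flags))
  shell[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- shell_c
  if (!any(shell)) {
    stop("background-undefined error: shell does not intersect the grid",
         call. = FALSE)
  }
  v <- volume$values[shell]
  v <- v[v < params$background_cap]
  if (length(v) == 0L) {
    stop("background-undefined error: no shell voxel below the ",
         params$background_cap, " SUV cap", call. = FALSE)
  }
  mean(v)
}

#' Contrast-oriented adaptive threshold tumor delineation
#'
#' Computes the threshold `T = beta * I70 + Ibgd` and returns the
#' 26-connected component, among search-region voxels with uptake strictly
#' greater than `T`, that contains the search-region maximum. The resulting
#' VOI is therefore always a single connected component containing the
#' hottest voxel.
#'
#' @inheritParams core_region
#' @return A [region_mask()] of the tumor VOI, with attributes `threshold`,
#'   `i70` and `i_bgd` recording the quantities that defined it.
#' @examples
#' ph <- generate_phantom(phantom_spec(heterogeneity = 0))
#' voi <- segment_tumor(ph$volume, search_box_around(ph$tumor, pad = 5))
#' attr(voi, "threshold")
#' @export
segment_tumor <- function(volume, search, params = segmentation_params()) {
  core <- core_region(volume, search, params)
  i70_val <- mean(volume$values[core$flags])
  ibgd_val <- i_bgd(volume, core, params)
  thr <- params$beta * i70_val + ibgd_val
  cand <- search$flags & (volume$values > thr)
  if (!any(cand)) {
    stop("segmentation-failed error: no search-region voxel above T = ",
         signif(thr, 4), call. = FALSE)
  }
  comp <- connected_component(cand, search_max_idx(volume, search))
  if (!any(comp)) {
    stop("segmentation-failed error: maximum voxel not above threshold",
         call. = FALSE)
  }
  out <- region_mask(comp)
  attr(out, "threshold") <- thr
  attr(out, "i70") <- i70_val
  attr(out, "i_bgd") <- ibgd_val
  out
}

#' Rectangular search region around a mask
#'
#' Convenience constructor of the user-supplied search region the adaptive
#' threshold requires (the operator's visually chosen box around the tumor):
#' the bounding box of a reference mask padded by `pad` voxels.
#'
#' @param mask A non-empty [region_mask()].
#' @param pad Padding in voxels on every side.
#' @return A [region_mask()] marking the padded bounding box.
#' @export
search_box_around <- function(mask, pad = 4L) {
  stopifnot(inherits(mask, "region_mask"))
  bb <- mask_bbox(mask$flags, pad = as.integer(pad))
  f <- array(FALSE, dim = dim(mask$flags))
  f[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- TRUE
  region_mask(f)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b [region_mask()]s of identical shape.
#' @return `2|A n B| / (|A| + |B|)`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "region_mask"), inherits(b, "region_mask"),
            identical(dim(a$flags), dim(b$flags)))
  denom <- sum(a$flags) + sum(b$flags)
  if (denom == 0L) return(NaN)
  2 * sum(a$flags & b$flags) / denom
}
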