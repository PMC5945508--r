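#' SUV volume container
#'
#' Wraps a 3-D array of standardized uptake values (SUV) together with its
#' physical voxel spacing and world-space origin. SUV is dimensionless
#' (tissue tracer concentration normalized by injected dose per body weight),
#' so the only physical metadata the measurement chain needs is the voxel
#' geometry. Axis order is fixed as (x, y, z) end-to-end: the array dimension
#' order, the spacing triplet and every voxel coordinate in this package use
#' the same 1-based (x, y, z) convention.
#'
#' @param values Numeric 3-D array of SUV values; all finite and >= 0.
#' @param spacing Numeric length-3 vector, mm per voxel along (x, y, z).
#' @param origin Numeric length-3 vector, world offset in mm.
#'
#' @return An object of class `suv_volume`: a list with elements `values`,
#'   `spacing` and `origin`.
#' @examples
#' vol <- suv_volume(array(1, dim = c(4, 4, 4)), spacing = c(4, 4, 2))
#' dim(vol$values)
#' @export
suv_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("dimensionality error: `values` must be a 3-D array, got ",
         length(dim(values)), " dimensions", call. = FALSE)
  }
  if (any(dim(values) < 1L)) {
    stop("`values` must have at least one voxel per axis", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("all SUV values must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("SUV values must be non-negative", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite numbers (mm)", call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<suv_volume> %d x %d x %d voxels, spacing %s mm, SUV range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A boolean 3-D grid aligned voxel-for-voxel with a companion [suv_volume()],
#' marking a volume of interest (VOI) such as the segmented tumor or the
#' reference muscle region.
#'
#' @param flags Logical 3-D array (or 0/1 numeric, coerced).
#' @return An object of class `region_mask` wrapping the logical array.
#' @examples
#' m <- region_mask(array(c(TRUE, FALSE), dim = c(2, 2, 2)))
#' mask_size(m)
#' @export
region_mask <- function(flags) {
  flags <- as.array(flags)
  if (length(dim(flags)) != 3L) {
    stop("dimensionality error: mask must be a 3-D array", call. = FALSE)
  }
  if (is.numeric(flags)) {
    if (!all(flags %in% c(0, 1))) {
      stop("numeric mask must contain only 0 and 1", call. = FALSE)
    }
    flags <- array(flags != 0, dim = dim(flags))
  }
  if (!is.logical(flags)) stop("mask must be logical or 0/1 numeric", call. = FALSE)
  if (anyNA(flags)) stop("mask must not contain NA", call. = FALSE)
  structure(list(flags = flags), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  d <- dim(x$flags)
  cat(sprintf("<region_mask> %d x %d x %d voxels, %d in mask\n",
              d[1], d[2], d[3], sum(x$flags)))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask A [region_mask()].
#' @return Integer count of `TRUE` voxels.
#' @export
mask_size <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  sum(mask$flags)
}

check_alignment <- function(volume, mask) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mask, "region_mask"))
  if (!identical(dim(volume$values), dim(mask$flags))) {
    stop("mask shape ", paste(dim(mask$flags), collapse = "x"),
         " does not match volume shape ",
         paste(dim(volume$values), collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a 3-D SUV volume from a NIfTI file
#'
#' Voxel spacing is taken from the file header; values are returned unchanged.
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3-D image.
#' @return An [suv_volume()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error reading '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("dimensionality error: '", path, "' has ", length(dim(arr)),
         " dimensions, expected 3", call. = FALSE)
  }
  attributes(arr) <- list(dim = dim(arr))
  hdr <- RNifti::niftiHeader(img)
  suv_volume(arr, spacing = abs(hdr$pixdim[2:4]),
             origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
}

#' Write a 3-D SUV volume to a NIfTI file
#'
#' Values are stored as 64-bit floats so that a read/write round trip is
#' bitwise exact.
#'
#' @param volume An [suv_volume()].
#' @param path Output path (`.nii` or `.nii.gz`); overwritten if it exists.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "suv_volume"))
  if (!dir.exists(dirname(path))) {
    stop("I/O error: parent directory does not exist: ", dirname(path),
         call. = FALSE)
  }
  img <- nifti_with_geometry(volume$values, volume$spacing, volume$origin)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

nifti_with_geometry <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::pixdim(img) <- spacing
  img
}

#' Read or write a region mask as a 0/1 NIfTI volume
#'
#' Masks are persisted as 8-bit 0/1 volumes in the same format as images, the
#' lowest-common-denominator encoding any PET analysis tool can open.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return `read_mask()` returns a [region_mask()]; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  region_mask(vol$values != 0)
}

#' @rdname read_mask
#' @param mask A [region_mask()].
#' @param spacing,origin Geometry to record in the file header.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(inherits(mask, "region_mask"))
  img <- nifti_with_geometry(array(as.integer(mask$flags),
                                   dim = dim(mask$flags)), spacing, origin)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Summary statistics of a volume inside a mask
#'
#' @param volume An [suv_volume()].
#' @param mask A non-empty [region_mask()] aligned with `volume`.
#' @return A one-row tibble with columns `n`, `min`, `max`, `mean`.
#' @examples
#' vol <- suv_volume(array(5, dim = c(3, 3, 3)))
#' m <- region_mask(array(TRUE, dim = c(3, 3, 3)))
#' mask_statistics(vol, m)
#' @export
mask_statistics <- function(volume, mask) {
  check_alignment(volume, mask)
  v <- volume$values[mask$flags]
  if (length(v) == 0L) stop("empty-region error: mask contains no voxels",
                            call. = FALSE)
  tibble::tibble(n = length(v), min = min(v), max = max(v), mean = mean(v))
}
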