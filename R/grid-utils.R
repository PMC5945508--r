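# Internal grid primitives shared by the phantom simulator and the
# segmentation stage: separable Gaussian smoothing, trilinear resampling,
# Chebyshev (3x3x3) binary dilation and 26-connected component extraction.
# All operate on plain 3-D arrays; the exported API wraps them in
# suv_volume/region_mask containers.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-(subject, condition, stage) seed derivation from a master
# seed: a counter scheme, so adding a subject never perturbs another
# subject's data. Kept below 2^31 - 1.
derive_seed <- function(master, subject = 0L, condition = 0L, stage = 0L) {
  m <- 2147483629
  s <- (as.numeric(master) %% m)
  s <- (s * 69069 + subject * 104729 + condition * 7919 + stage * 613) %% m
  as.integer(s + 1)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# 1-D convolution along the first margin of a 3-D array, replicate padding.
convolve_axis1 <- function(arr, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(arr)
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1])
  pad_top <- m[rep(1L, r), , drop = FALSE]
  pad_bot <- m[rep(d[1], r), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, nrow = d[1], ncol = ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * mp[(j - 1L) + seq_len(d[1]), , drop = FALSE]
  }
  array(out, dim = d)
}

# Separable 3-D Gaussian smoothing; fwhm in mm, spacing in mm/voxel.
gaussian_smooth3d <- function(arr, spacing, fwhm) {
  if (fwhm <= 0) return(arr)
  sigma_vox <- (fwhm * FWHM_TO_SIGMA) / spacing
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[ax])
    if (length(k) > 1L) {
      arr <- aperm(convolve_axis1(aperm(arr, c(ax, setdiff(1:3, ax))), k),
                   order(c(ax, setdiff(1:3, ax))))
    }
  }
  arr
}

# Linear interpolation along the first margin onto voxel centers of a new
# grid with `n_out` voxels of size `sp_out`, covering the same physical
# extent as the input axis (voxel center of index i at (i - 0.5) * spacing).
interp_axis1 <- function(arr, sp_in, sp_out, n_out) {
  d <- dim(arr)
  x_out <- (seq_len(n_out) - 0.5) * sp_out
  u <- x_out / sp_in + 0.5            # continuous 1-based input index
  u <- pmin(pmax(u, 1), d[1])
  i0 <- pmin(floor(u), d[1] - 1L)
  if (d[1] == 1L) i0 <- rep(1L, n_out)
  w <- u - i0
  m <- matrix(arr, nrow = d[1])
  out <- (1 - w) * m[i0, , drop = FALSE] +
    w * m[pmin(i0 + 1L, d[1]), , drop = FALSE]
  array(out, dim = c(n_out, d[2], d[3]))
}

# Trilinear resampling of a 3-D array from spacing_in to spacing_out,
# preserving the physical field of view.
resample_trilinear <- function(arr, spacing_in, spacing_out) {
  if (isTRUE(all.equal(spacing_in, spacing_out))) return(arr)
  d_in <- dim(arr)
  n_out <- pmax(1L, as.integer(round(d_in * spacing_in / spacing_out)))
  for (ax in 1:3) {
    if (spacing_in[ax] != spacing_out[ax] || dim(arr)[ax] != n_out[ax]) {
      perm <- c(ax, setdiff(1:3, ax))
      arr <- aperm(interp_axis1(aperm(arr, perm), spacing_in[ax],
                                spacing_out[ax], n_out[ax]),
                   order(perm))
    }
  }
  arr
}

# Nearest-neighbor resampling for boolean masks (same grid convention).
resample_nearest <- function(flags, spacing_in, spacing_out) {
  if (isTRUE(all.equal(spacing_in, spacing_out))) return(flags)
  d_in <- dim(flags)
  n_out <- pmax(1L, as.integer(round(d_in * spacing_in / spacing_out)))
  idx <- lapply(1:3, function(ax) {
    x_out <- (seq_len(n_out[ax]) - 0.5) * spacing_out[ax]
    i <- round(x_out / spacing_in[ax] + 0.5)
    pmin(pmax(i, 1L), d_in[ax])
  })
  flags[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# One Chebyshev dilation step: logical OR over the 3x3x3 neighborhood,
# implemented as 26 array shifts.
dilate_step <- function(flags) {
  d <- dim(flags)
  out <- flags
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
    tx <- sx + dx; ty <- sy + dy; tz <- sz + dz
    okx <- tx >= 1L & tx <= d[1]; oky <- ty >= 1L & ty <= d[2]
    okz <- tz >= 1L & tz <= d[3]
    out[tx[okx], ty[oky], tz[okz]] <-
      out[tx[okx], ty[oky], tz[okz]] | flags[sx[okx], sy[oky], sz[okz]]
  }
  out
}

dilate <- function(flags, steps) {
  for (i in seq_len(steps)) flags <- dilate_step(flags)
  flags
}

# 26-connected component of `candidates` containing voxel `seed_idx`
# (linear index). Grown by alternating dilation and intersection; the work
# happens on the candidate bounding box, not the full grid.
connected_component <- function(candidates, seed_idx) {
  out <- array(FALSE, dim = dim(candidates))
  if (!candidates[seed_idx]) return(out)
  bb <- mask_bbox(candidates, pad = 0L)
  cand <- crop_bbox(candidates, bb)
  seed_xyz <- arrayInd(seed_idx, dim(candidates))[1, ] - bb$lo + 1L
  comp <- array(FALSE, dim = dim(cand))
  comp[seed_xyz[1], seed_xyz[2], seed_xyz[3]] <- TRUE
  repeat {
    grown <- dilate_step(comp) & cand
    if (identical(grown, comp)) break
    comp <- grown
  }
  out[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- comp
  out
}

# Bounding box (1-based inclusive) of TRUE voxels, padded by `pad` voxels
# and clipped to the grid.
mask_bbox <- function(flags, pad = 0L) {
  idx <- which(flags, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty-region error: mask contains no voxels",
                            call. = FALSE)
  d <- dim(flags)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_bbox <- function(arr, bb) {
  arr[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}
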