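# Independent brute-force oracles. These deliberately share no code with the
# implementation: explicit voxel-by-voxel loops instead of vectorized shifts
# and sort-based line enumeration.

oracle_offsets <- function() petrad:::texture_offsets()

# Symmetrized GLCM counts by exhaustive enumeration of every ordered voxel
# pair at the given offset (both directions), restricted to in-mask voxels.
oracle_glcm_counts <- function(levels, offset, bins) {
  d <- dim(levels)
  cmat <- matrix(0L, bins, bins)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    for (s in c(1L, -1L)) {
      nx <- x + s * offset[1]; ny <- y + s * offset[2]; nz <- z + s * offset[3]
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3]) next
      b <- levels[nx, ny, nz]
      if (!is.na(b)) cmat[a, b] <- cmat[a, b] + 1L
    }
  }
  cmat
}

# GLRLM counts by explicit line walking: start at voxels whose predecessor
# along the offset lies outside the grid, then scan the run structure.
oracle_glrlm_counts <- function(levels, offset, bins, max_len) {
  d <- dim(levels)
  rmat <- matrix(0L, bins, max_len)
  inside <- function(p) all(p >= 1) && all(p <= d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    if (inside(p - offset)) next  # not a line start
    cur_val <- NA; cur_len <- 0L
    while (inside(p)) {
      v <- levels[p[1], p[2], p[3]]
      if (!is.na(v) && !is.na(cur_val) && v == cur_val) {
        cur_len <- cur_len + 1L
      } else {
        if (!is.na(cur_val)) rmat[cur_val, cur_len] <- rmat[cur_val, cur_len] + 1L
        cur_val <- v
        cur_len <- if (is.na(v)) 0L else 1L
      }
      p <- p + offset
    }
    if (!is.na(cur_val)) rmat[cur_val, cur_len] <- rmat[cur_val, cur_len] + 1L
  }
  rmat
}

# Chebyshev distance from each voxel to the nearest TRUE voxel of `core`.
oracle_chebyshev_distance <- function(core) {
  d <- dim(core)
  idx <- which(core, arr.ind = TRUE)
  out <- array(Inf, dim = d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    out[x, y, z] <- min(pmax(abs(idx[, 1] - x),
                             pmax(abs(idx[, 2] - y), abs(idx[, 3] - z))))
  }
  out
}

# 26-connected component containing `seed` (voxel triplet), by BFS.
oracle_component <- function(flags, seed) {
  d <- dim(flags)
  comp <- array(FALSE, dim = d)
  if (!flags[seed[1], seed[2], seed[3]]) return(comp)
  queue <- list(seed)
  comp[seed[1], seed[2], seed[3]] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (any(q < 1) || any(q > d)) next
      if (flags[q[1], q[2], q[3]] && !comp[q[1], q[2], q[3]]) {
        comp[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  comp
}

# One-way RM-ANOVA F via stats::aov with an Error(subject) stratum — an
# independent route through R's model-fitting machinery.
oracle_rm_anova_F <- function(Y) {
  df <- data.frame(
    value = as.vector(Y),
    subject = factor(rep(seq_len(nrow(Y)), ncol(Y))),
    condition = factor(rep(seq_len(ncol(Y)), each = nrow(Y))))
  fit <- stats::aov(value ~ condition + Error(subject), data = df)
  s <- summary(fit)[["Error: Within"]][[1]]
  list(F = s["condition", "F value"], p = s["condition", "Pr(>F)"])
}

# Random small gray-level VOI for property tests: intensities uniform on the
# discretization range, mask density ~0.6, guaranteed non-degenerate.
random_gray <- function(dim3, bins, seed) {
  set.seed(seed)
  repeat {
    vals <- array(stats::runif(prod(dim3), 0, 25), dim = dim3)
    mask <- array(stats::runif(prod(dim3)) < 0.6, dim = dim3)
    if (sum(mask) >= 3) break
  }
  vol <- suv_volume(vals)
  discretize(vol, region_mask(mask), discretization_config(bins = bins))
}

# Tiny fast phantom used across tests (24^3 grid, isotropic spacing).
small_phantom_spec <- function(...) {
  defaults <- list(shape = c(24L, 24L, 24L), spacing = c(4, 4, 4),
                   tumor_center = c(12, 12, 12), tumor_radius = 14,
                   tumor_mean = 10, heterogeneity = 1.5, het_length = 10,
                   background = 1, muscle = 0.7,
                   muscle_box = list(lo = c(2, 2, 2), hi = c(6, 6, 10)))
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Gray-level volume whose levels equal round(I), via bounds [0, bins]
# (bin width 1, so integer intensities are their own levels).
gray_from_levels <- function(levels, bins) {
  arr <- array(levels, dim = c(length(levels), 1, 1))
  mask <- region_mask(array(!is.na(levels), dim = dim(arr)))
  arr[is.na(arr)] <- 0
  discretize(suv_volume(arr), mask, discretization_config(0, bins, bins))
}
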