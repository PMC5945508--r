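# The 13 unique 3-D voxel offsets at Chebyshev distance 1 (one of each
# antipodal pair); texture matrices are symmetrized so the choice of
# representative does not matter.
texture_offsets <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- offs$dx > 0 | (offs$dx == 0 & offs$dy > 0) |
    (offs$dx == 0 & offs$dy == 0 & offs$dz > 0)
  as.matrix(offs[keep, c("dx", "dy", "dz")])
}

#' Names of the eight radiomic features
#'
#' Conventional (`suv_mean`, `tmr`), histogram (`skewness`, `kurtosis`),
#' GLCM (`entropy`, `homogeneity`) and GLRLM (`sre`, `lre`), in standard
#' reporting order.
#'
#' @return Character vector of length 8.
#' @export
radiomic_feature_names <- function() {
  c("suv_mean", "tmr", "skewness", "kurtosis",
    "entropy", "homogeneity", "sre", "lre")
}

#' Mean SUV inside a VOI
#'
#' Computed on raw (undiscretized) SUV values.
#'
#' @param volume An [suv_volume()].
#' @param voi Non-empty [region_mask()].
#' @return Mean SUV.
#' @export
suv_mean <- function(volume, voi) {
  mask_statistics(volume, voi)$mean
}

#' Tumor-to-muscle SUV ratio (TMR)
#'
#' Mean tumor SUV divided by the mean SUV of a reference muscle region
#' (e.g. gluteal muscles for pelvic tumors, posterior neck muscles for head
#' and neck tumors).
#'
#' @param volume An [suv_volume()].
#' @param voi Tumor [region_mask()].
#' @param muscle Reference muscle [region_mask()].
#' @return Dimensionless ratio.
#' @export
tmr <- function(volume, voi, muscle) {
  mm <- suv_mean(volume, muscle)
  if (mm <= 0) stop("undefined-ratio error: muscle mean SUV is ", mm,
                    call. = FALSE)
  suv_mean(volume, voi) / mm
}

gray_values <- function(gray) {
  stopifnot(inherits(gray, "gray_level_volume"))
  as.numeric(gray$levels[gray$mask$flags])
}

central_moment <- function(x, r) mean((x - mean(x))^r)

#' Histogram skewness of the gray-level distribution
#'
#' Population (divisor-N) third standardized moment of the in-mask levels.
#'
#' @param gray A gray-level volume from [discretize()], or a numeric vector
#'   of levels.
#' @return Dimensionless skewness.
#' @export
histogram_skewness <- function(gray) {
  x <- if (is.numeric(gray)) gray else gray_values(gray)
  m2 <- central_moment(x, 2)
  if (m2 == 0) stop("degenerate-distribution error: zero variance",
                    call. = FALSE)
  central_moment(x, 3) / m2^1.5
}

#' Histogram kurtosis of the gray-level distribution
#'
#' Non-excess population kurtosis `m4 / m2^2` (Gaussian value 3); no `-3`
#' subtraction.
#'
#' @inheritParams histogram_skewness
#' @return Dimensionless kurtosis.
#' @export
histogram_kurtosis <- function(gray) {
  x <- if (is.numeric(gray)) gray else gray_values(gray)
  m2 <- central_moment(x, 2)
  if (m2 == 0) stop("degenerate-distribution error: zero variance",
                    call. = FALSE)
  central_moment(x, 4) / m2^2
}

#' Gray-level co-occurrence matrix (GLCM)
#'
#' For each of the 13 unique 3-D directions at voxel distance 1, counts
#' ordered pairs of gray levels of in-mask voxel pairs, symmetrized (each
#' pair counted in both orders), and normalizes per direction to a joint
#' probability. Neighborhoods are defined in voxel units regardless of mm
#' anisotropy, the conventional texture-matrix definition.
#'
#' @param gray A gray-level volume from [discretize()].
#' @return An object of class `cooccurrence_matrix`: list with `p` (list of
#'   per-direction probability matrices, `bins x bins`), `counts`
#'   (symmetrized integer counts), `n_pairs` (symmetrized pair total per
#'   direction), `offsets` and `bins`.
#' @export
glcm <- function(gray) {
  stopifnot(inherits(gray, "gray_level_volume"))
  bb <- mask_bbox(gray$mask$flags, pad = 0L)
  lev <- crop_bbox(gray$levels, bb)
  d <- dim(lev)
  bins <- gray$config$bins
  offs <- texture_offsets()
  counts <- vector("list", nrow(offs))
  p <- vector("list", nrow(offs))
  n_pairs <- numeric(nrow(offs))
  axis_range <- function(n, o) {
    lo <- max(1L, 1L - o); hi <- min(n, n - o)
    if (lo > hi) integer(0) else lo:hi
  }
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    xr <- axis_range(d[1], o[1])
    yr <- axis_range(d[2], o[2])
    zr <- axis_range(d[3], o[3])
    cmat <- matrix(0L, bins, bins)
    if (length(xr) > 0 && length(yr) > 0 && length(zr) > 0) {
      a <- lev[xr, yr, zr, drop = FALSE]
      b <- lev[xr + o[1], yr + o[2], zr + o[3], drop = FALSE]
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        tab <- tabulate((a[ok] - 1L) * bins + b[ok], nbins = bins * bins)
        cmat <- matrix(tab, bins, bins, byrow = TRUE)
        cmat <- cmat + t(cmat)
      }
    }
    counts[[k]] <- cmat
    n_pairs[k] <- sum(cmat)
    p[[k]] <- if (n_pairs[k] > 0) cmat / n_pairs[k] else cmat
  }
  if (all(n_pairs == 0)) {
    stop("texture-undefined error: no in-mask voxel pair in any direction",
         call. = FALSE)
  }
  structure(list(p = p, counts = counts, n_pairs = n_pairs,
                 offsets = offs, bins = bins),
            class = "cooccurrence_matrix")
}

# Pool per-direction co-occurrence counts into one merged matrix (the
# alternative aggregation convention).
glcm_merge <- function(cm) {
  total <- Reduce(`+`, cm$counts)
  n <- sum(total)
  structure(list(p = list(if (n > 0) total / n else total),
                 counts = list(total), n_pairs = n,
                 offsets = matrix(NA_integer_, 1, 3), bins = cm$bins),
            class = "cooccurrence_matrix")
}

glcm_feature <- function(cm, fun) {
  contributing <- which(cm$n_pairs > 0)
  mean(vapply(contributing, function(k) fun(cm$p[[k]]), numeric(1)))
}

#' GLCM entropy
#'
#' Per direction, `-sum p(i,j) * log(p(i,j))` over nonzero entries, averaged
#' over directions with at least one pair. Base-2 logarithm (bits) by
#' default.
#'
#' @param cm A [glcm()] result.
#' @param base Logarithm base (2 for bits; e and 10 also in use).
#' @return Entropy, in units of `log base`.
#' @export
glcm_entropy <- function(cm, base = 2) {
  stopifnot(inherits(cm, "cooccurrence_matrix"))
  glcm_feature(cm, function(p) {
    q <- p[p > 0]
    -sum(q * log(q, base = base))
  })
}

#' GLCM homogeneity (inverse difference)
#'
#' Per direction, `sum p(i,j) / (1 + |i - j|)`, averaged over contributing
#' directions; lies in (0, 1], equal to 1 for a constant region.
#'
#' @param cm A [glcm()] result.
#' @return Dimensionless homogeneity.
#' @export
glcm_homogeneity <- function(cm) {
  stopifnot(inherits(cm, "cooccurrence_matrix"))
  w <- 1 / (1 + abs(outer(seq_len(cm$bins), seq_len(cm$bins), `-`)))
  glcm_feature(cm, function(p) sum(p * w))
}

#' Gray-level run-length matrix (GLRLM)
#'
#' For each of the 13 unique 3-D directions, counts maximal runs of equal
#' gray level among consecutive in-mask voxels along that direction;
#' out-of-mask voxels break runs. Every in-mask voxel belongs to exactly one
#' run per direction, so `sum_j j * r(i, j)` equals the VOI voxel count in
#' each direction.
#'
#' @param gray A gray-level volume from [discretize()].
#' @return An object of class `runlength_matrix`: list with `r` (list of
#'   per-direction count matrices, `bins x max_run_length`), `n_runs` (total
#'   runs per direction), `n_voxels`, `offsets` and `bins`.
#' @export
glrlm <- function(gray) {
  stopifnot(inherits(gray, "gray_level_volume"))
  if (mask_size(gray$mask) == 0L) {
    stop("empty-region error: mask contains no voxels", call. = FALSE)
  }
  bb <- mask_bbox(gray$mask$flags, pad = 0L)
  lev <- crop_bbox(gray$levels, bb)
  d <- dim(lev)
  bins <- gray$config$bins
  offs <- texture_offsets()
  n_vox <- sum(!is.na(lev))
  max_len <- max(d)
  coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                  z = seq_len(d[3])))
  vals_all <- as.vector(lev)  # expand.grid order matches array layout
  r_list <- vector("list", nrow(offs))
  n_runs <- numeric(nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    m <- sum(o^2)
    # Along a line p0 + j*o the anchor m*p - (p.o)*o is constant and integer,
    # so sorting by (anchor, p.o) enumerates every grid line voxel by voxel.
    t_pos <- coords %*% o
    anchor <- m * coords - t_pos %*% t(o)
    ord <- order(anchor[, 1], anchor[, 2], anchor[, 3], t_pos)
    v <- vals_all[ord]
    a_ord <- anchor[ord, , drop = FALSE]
    n <- length(v)
    newline <- c(TRUE, rowSums(abs(a_ord[-1, , drop = FALSE] -
                                     a_ord[-n, , drop = FALSE])) > 0)
    prev <- c(NA, v[-n])
    brk <- newline | is.na(v) != is.na(prev) |
      (!is.na(v) & !is.na(prev) & v != prev)
    brk[1] <- TRUE
    run_id <- cumsum(brk)
    runs_len <- tabulate(run_id)
    run_val <- v[brk]
    keep <- !is.na(run_val)
    rl <- runs_len[keep]
    rv <- run_val[keep]
    rmat <- matrix(0L, bins, max_len)
    if (length(rl) > 0) {
      tab <- tabulate((rv - 1L) * max_len + rl, nbins = bins * max_len)
      rmat <- matrix(tab, bins, max_len, byrow = TRUE)
    }
    r_list[[k]] <- rmat
    n_runs[k] <- sum(rmat)
  }
  structure(list(r = r_list, n_runs = n_runs, n_voxels = n_vox,
                 offsets = offs, bins = bins),
            class = "runlength_matrix")
}

glrlm_merge <- function(rm) {
  total <- Reduce(`+`, rm$r)
  structure(list(r = list(total), n_runs = sum(total),
                 n_voxels = rm$n_voxels,
                 offsets = matrix(NA_integer_, 1, 3), bins = rm$bins),
            class = "runlength_matrix")
}

glrlm_feature <- function(rm, weight_fun) {
  contributing <- which(rm$n_runs > 0)
  j2 <- weight_fun(seq_len(ncol(rm$r[[1]])))
  mean(vapply(contributing, function(k) {
    sum(sweep(rm$r[[k]], 2, j2, `*`)) / rm$n_runs[k]
  }, numeric(1)))
}

#' GLRLM short-run emphasis (SRE)
#'
#' Per direction, `(1/N_r) sum r(i,j) / j^2`, averaged over directions; lies
#' in (0, 1], equal to 1 when every run has length 1.
#'
#' @param rm A [glrlm()] result.
#' @return Dimensionless SRE.
#' @export
glrlm_sre <- function(rm) {
  stopifnot(inherits(rm, "runlength_matrix"))
  glrlm_feature(rm, function(j) 1 / j^2)
}

#' GLRLM long-run emphasis (LRE)
#'
#' Per direction, `(1/N_r) sum r(i,j) * j^2`, averaged over directions;
#' always >= 1.
#'
#' @param rm A [glrlm()] result.
#' @return Dimensionless LRE.
#' @export
glrlm_lre <- function(rm) {
  stopifnot(inherits(rm, "runlength_matrix"))
  glrlm_feature(rm, function(j) j^2)
}

#' Extract the eight radiomic features of one VOI
#'
#' Conventional features (`suv_mean`, `tmr`) are computed on raw SUV;
#' histogram features (`skewness`, `kurtosis`) and textural features
#' (`entropy`, `homogeneity` from the GLCM; `sre`, `lre` from the GLRLM) on
#' the discretized gray levels. A VOI with zero gray-level variance is
#' degenerate for skewness/kurtosis: those fields are returned as `NA` with
#' a warning (entropy 0 and homogeneity 1 remain well defined).
#'
#' @param volume An [suv_volume()].
#' @param voi Tumor [region_mask()].
#' @param muscle Reference muscle [region_mask()].
#' @param config A [discretization_config()].
#' @param aggregation `"average"` computes each textural index per direction
#'   and averages over the 13 directions; `"merged"` pools counts into one
#'   matrix first. Both conventions exist in texture software.
#' @param entropy_base Logarithm base for GLCM entropy.
#' @param histogram_on `"levels"` (default) computes skewness/kurtosis on
#'   discretized levels; `"suv"` on raw SUV values.
#' @return A one-row tibble: `bins`, `bin_width`, `n_voxels`, the eight
#'   feature columns of [radiomic_feature_names()], and `degenerate`
#'   (logical flag for zero-variance histogram moments).
#' @examples
#' ph <- generate_phantom(phantom_spec())
#' extract_features(ph$volume, ph$tumor, ph$muscle, discretization_config())
#' @export
extract_features <- function(volume, voi, muscle,
                             config = discretization_config(),
                             aggregation = c("average", "merged"),
                             entropy_base = 2,
                             histogram_on = c("levels", "suv")) {
  aggregation <- match.arg(aggregation)
  histogram_on <- match.arg(histogram_on)
  check_alignment(volume, voi)
  gray <- discretize(volume, voi, config)
  hvals <- if (histogram_on == "levels") gray_values(gray)
           else volume$values[voi$flags]
  degenerate <- central_moment(hvals, 2) == 0
  if (degenerate) {
    warning("degenerate gray-level distribution (zero variance): ",
            "skewness and kurtosis undefined, returned as NA", call. = FALSE)
    skew <- kurt <- NA_real_
  } else {
    skew <- histogram_skewness(hvals)
    kurt <- histogram_kurtosis(hvals)
  }
  cm <- glcm(gray)
  rm_ <- glrlm(gray)
  if (aggregation == "merged") {
    cm <- glcm_merge(cm)
    rm_ <- glrlm_merge(rm_)
  }
  tibble::tibble(
    bins = config$bins,
    bin_width = bin_width(config),
    n_voxels = mask_size(voi),
    suv_mean = suv_mean(volume, voi),
    tmr = tmr(volume, voi, muscle),
    skewness = skew,
    kurtosis = kurt,
    entropy = glcm_entropy(cm, base = entropy_base),
    homogeneity = glcm_homogeneity(cm),
    sre = glrlm_sre(rm_),
    lre = glrlm_lre(rm_),
    degenerate = degenerate
  )
}
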