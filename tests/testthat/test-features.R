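test_that("conventional features: SUVmean and TMR", {
  d <- c(4, 4, 4)
  vol <- suv_volume(array(5, dim = d))
  full <- region_mask(array(TRUE, dim = d))
  expect_equal(suv_mean(vol, full), 5)

  vals <- array(0.8, dim = d); vals[1:2, 1:2, 1:2] <- 10
  voi <- array(FALSE, dim = d); voi[1:2, 1:2, 1:2] <- TRUE
  mus <- array(FALSE, dim = d); mus[3:4, 3:4, 3:4] <- TRUE
  vol2 <- suv_volume(vals)
  expect_equal(tmr(vol2, region_mask(voi), region_mask(mus)), 12.5)
  expect_equal(tmr(vol2, region_mask(voi), region_mask(voi)), 1.0)
  vals0 <- vals; vals0[3:4, 3:4, 3:4] <- 0
  expect_error(tmr(suv_volume(vals0), region_mask(voi), region_mask(mus)),
               "undefined-ratio")
})

test_that("histogram moments use population (divisor-N) definitions", {
  expect_equal(histogram_skewness(c(1, 1, 3, 3)), 0)
  expect_equal(histogram_skewness(c(1, 1, 1, 5)), 2 / sqrt(3))  # m3/m2^1.5
  expect_equal(histogram_kurtosis(c(1, 1, 3, 3)), 1)            # two-point law
  expect_equal(histogram_kurtosis(1:5), 1.7)                    # 6.8 / 2^2
  # translation invariance; reflection flips the skewness sign
  x <- c(1, 2, 2, 3, 7, 9)
  expect_equal(histogram_skewness(x + 10), histogram_skewness(x))
  expect_equal(histogram_kurtosis(x + 10), histogram_kurtosis(x))
  expect_equal(histogram_skewness(-x), -histogram_skewness(x))
  expect_error(histogram_skewness(rep(2, 5)), "degenerate-distribution")
  expect_error(histogram_kurtosis(rep(2, 5)), "degenerate-distribution")
})

test_that("kurtosis of a large Gaussian sample approaches 3", {
  set.seed(4)
  x <- rnorm(2e5)
  # SE of sample kurtosis for a Gaussian is ~ sqrt(24/n)
  expect_lt(abs(histogram_kurtosis(x) - 3), 3 * sqrt(24 / length(x)))
})

test_that("GLCM of hand-checkable cases", {
  # constant VOI: one diagonal entry per direction
  g <- gray_from_levels(rep(3, 5), 8)
  cm <- glcm(g)
  xdir <- which(apply(cm$offsets, 1, function(o) all(o == c(1, 0, 0))))
  expect_equal(cm$p[[xdir]][3, 3], 1)
  expect_equal(glcm_entropy(cm), 0)
  expect_equal(glcm_homogeneity(cm), 1)

  # 1-D strip [1,2,1,2]: 3 adjacent pairs, symmetrized -> p(1,2)=p(2,1)=0.5
  g2 <- gray_from_levels(c(1, 2, 1, 2), 2)
  cm2 <- glcm(g2)
  expect_equal(cm2$p[[xdir]][1, 2], 0.5)
  expect_equal(cm2$p[[xdir]][2, 1], 0.5)
  expect_equal(sum(cm2$n_pairs > 0), 1)  # only x has neighbors
  expect_equal(glcm_entropy(cm2), 1)     # -2 * 0.5 log2 0.5
  expect_equal(glcm_homogeneity(cm2), 0.5)

  # uniform probability over k cells -> entropy log2 k (maximum entropy)
  g3 <- gray_from_levels(c(1, 2, 3, 4, 1), 4)
  cm3 <- glcm(g3)
  p <- cm3$p[[xdir]]
  k <- sum(p > 0)
  expect_equal(glcm_entropy(cm3), -sum(p[p > 0] * log2(p[p > 0])))
  expect_lte(glcm_entropy(cm3), log2(k))
})

test_that("GLCM matches exhaustive pair enumeration on random VOIs", {
  for (seed in 1:10) {
    g <- random_gray(c(5, 4, 4), bins = 8, seed = seed)
    cm <- glcm(g)
    bb <- petrad:::mask_bbox(g$mask$flags, 0L)
    lev <- petrad:::crop_bbox(g$levels, bb)
    for (k in seq_len(nrow(cm$offsets))) {
      expect_identical(unname(cm$counts[[k]]),
                       unname(oracle_glcm_counts(lev, cm$offsets[k, ], 8)))
    }
  }
})

test_that("GLRLM of hand-checkable cases", {
  # single voxel: one run of length 1 in every direction
  g1 <- gray_from_levels(5, 8)
  rm1 <- glrlm(g1)
  expect_true(all(rm1$n_runs == 1))
  expect_equal(glrlm_sre(rm1), 1)
  expect_equal(glrlm_lre(rm1), 1)

  # constant strip of length L along x: one x-run of length L
  L <- 6
  g2 <- gray_from_levels(rep(2, L), 8)
  rm2 <- glrlm(g2)
  xdir <- which(apply(rm2$offsets, 1, function(o) all(o == c(1, 0, 0))))
  expect_equal(rm2$r[[xdir]][2, L], 1)
  expect_equal(rm2$n_runs[[xdir]], 1)
  # per-direction closed forms: SRE = 1/L^2, LRE = L^2 for the x direction
  sre_x <- sum(rm2$r[[xdir]] %*% diag(1 / seq_len(ncol(rm2$r[[xdir]]))^2)) /
    rm2$n_runs[[xdir]]
  lre_x <- sum(rm2$r[[xdir]] %*% diag(seq_len(ncol(rm2$r[[xdir]]))^2)) /
    rm2$n_runs[[xdir]]
  expect_equal(sre_x, 1 / L^2)
  expect_equal(lre_x, L^2)
  # off-axis directions see L runs of length 1 each
  ydir <- which(apply(rm2$offsets, 1, function(o) all(o == c(0, 1, 0))))
  expect_equal(rm2$n_runs[[ydir]], L)
})

test_that("GLRLM matches brute-force line enumeration on random VOIs", {
  for (seed in 1:10) {
    g <- random_gray(c(4, 5, 4), bins = 8, seed = 100 + seed)
    rm_ <- glrlm(g)
    bb <- petrad:::mask_bbox(g$mask$flags, 0L)
    lev <- petrad:::crop_bbox(g$levels, bb)
    max_len <- ncol(rm_$r[[1]])
    for (k in seq_len(nrow(rm_$offsets))) {
      expect_identical(unname(rm_$r[[k]]),
                       unname(oracle_glrlm_counts(lev, rm_$offsets[k, ], 8,
                                                  max_len)))
    }
  }
})

test_that("GLRLM run lengths partition the VOI in every direction", {
  g <- random_gray(c(5, 5, 5), bins = 8, seed = 77)
  rm_ <- glrlm(g)
  n_vox <- sum(!is.na(g$levels))
  for (k in seq_along(rm_$r)) {
    expect_equal(sum(sweep(rm_$r[[k]], 2, seq_len(ncol(rm_$r[[k]])), `*`)),
                 n_vox)
  }
})

test_that("SRE and LRE bounds and Cauchy-Schwarz inequality hold", {
  for (seed in 1:20) {
    g <- random_gray(c(4, 4, 4), bins = 8, seed = 200 + seed)
    rm_ <- glrlm(g)
    for (k in seq_along(rm_$r)) {
      if (rm_$n_runs[k] == 0) next
      j2 <- seq_len(ncol(rm_$r[[k]]))^2
      sre_k <- sum(sweep(rm_$r[[k]], 2, 1 / j2, `*`)) / rm_$n_runs[k]
      lre_k <- sum(sweep(rm_$r[[k]], 2, j2, `*`)) / rm_$n_runs[k]
      expect_gt(sre_k, 0); expect_lte(sre_k, 1)
      expect_gte(lre_k, 1)
      expect_gte(sre_k * lre_k, 1 - 1e-12)
    }
  }
})

test_that("texture features on discretized levels are translation-sensitive only through binning", {
  # adding a constant SUV offset that shifts every voxel by exactly one bin
  # leaves GLCM/GLRLM structure unchanged
  set.seed(31)
  d <- c(5, 5, 5)
  vals <- array(runif(prod(d), 5, 10), dim = d)
  cfg <- discretization_config(0, 25, 64)
  mask <- region_mask(array(TRUE, dim = d))
  g1 <- discretize(suv_volume(vals), mask, cfg)
  g2 <- discretize(suv_volume(vals + 25 / 64), mask, cfg)
  expect_identical(g2$levels, g1$levels + 1L)
  cm1 <- glcm(g1); cm2 <- glcm(g2)
  expect_equal(glcm_entropy(cm1), glcm_entropy(cm2))
  expect_equal(glcm_homogeneity(cm1), glcm_homogeneity(cm2))
})

test_that("extract_features returns exactly the eight named features", {
  ph <- generate_phantom(small_phantom_spec())
  sm <- apply_condition(ph$volume, ph$tumor,
                        condition_spec("s", smoothing_fwhm = 4), seed = 6)
  voi <- segment_tumor(sm, search_box_around(ph$tumor, pad = 5))
  fv <- extract_features(sm, voi, ph$muscle, discretization_config(bins = 64))
  expect_equal(nrow(fv), 1L)
  expect_true(all(radiomic_feature_names() %in% names(fv)))
  expect_length(intersect(names(fv), radiomic_feature_names()), 8L)
  expect_true(all(is.finite(unlist(fv[radiomic_feature_names()]))))
  expect_false(fv$degenerate)
  # deterministic end to end
  fv2 <- extract_features(sm, voi, ph$muscle, discretization_config(bins = 64))
  expect_identical(fv, fv2)
})

test_that("a constant tumor yields degenerate histogram moments but exact others", {
  d <- c(8, 8, 8)
  vals <- array(0.8, dim = d); vals[3:6, 3:6, 3:6] <- 10
  voi <- array(FALSE, dim = d); voi[3:6, 3:6, 3:6] <- TRUE
  mus <- array(FALSE, dim = d); mus[1, 1, ] <- TRUE
  expect_warning(
    fv <- extract_features(suv_volume(vals), region_mask(voi),
                           region_mask(mus), discretization_config(bins = 64)),
    "degenerate")
  expect_equal(fv$suv_mean, 10)
  expect_equal(fv$entropy, 0)
  expect_equal(fv$homogeneity, 1)
  expect_true(is.na(fv$skewness) && is.na(fv$kurtosis))
  expect_true(fv$degenerate)
})

test_that("direction aggregation switch: merged pooling differs but stays in range", {
  g <- random_gray(c(5, 5, 5), bins = 8, seed = 55)
  cm <- glcm(g)
  merged <- petrad:::glcm_merge(cm)
  expect_equal(sum(merged$p[[1]]), 1)
  expect_lte(glcm_homogeneity(merged), 1)
  rm_ <- glrlm(g)
  rmm <- petrad:::glrlm_merge(rm_)
  expect_gte(glrlm_lre(rmm), 1)
})
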