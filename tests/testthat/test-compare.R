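# Small synthetic long-form cohort table builder.
make_table <- function(values, feature = "suv_mean", bins = 64) {
  # values: n x k matrix, rows = subjects, cols = conditions
  n <- nrow(values); k <- ncol(values)
  tibble::tibble(
    subject = rep(sprintf("S%02d", seq_len(n)), each = k),
    condition = rep(paste0("c", seq_len(k)), n),
    bins = bins, feature = feature,
    value = as.vector(t(values)))
}

test_that("Pearson correlation: affine series and direct formula", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  # 5-point table against the product-moment formula written out
  y <- c(2.3, 1.9, 4.4, 6.0, 9.1)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_r(x, y)
  expect_equal(res$r, r_direct)
  t_stat <- r_direct * sqrt(3 / (1 - r_direct^2))
  expect_equal(res$p, 2 * pt(abs(t_stat), df = 3, lower.tail = FALSE))
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10)
  r0 <- pearson_r(x, y)$r
  expect_equal(pearson_r(3 * x + 5, y)$r, r0)
  expect_equal(pearson_r(x, 0.2 * y - 4)$r, r0)
  expect_equal(pearson_r(-x, y)$r, -r0)
})

test_that("percent differences reproduce the reported case arithmetic", {
  expect_equal(round(percent_difference(11.6, 14.4)), 24)
  expect_equal(round(percent_difference(13.7, 14.0)), 2)
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(10, 8), -20)
  expect_equal(percent_difference(10, 8, absolute = TRUE), 20)
  expect_error(percent_difference(0, 1), "undefined-baseline")
})

test_that("RM-ANOVA: identical conditions give F = 0, p = 1", {
  base <- c(3, 5, 8, 2)
  tab <- make_table(cbind(base, base, base))
  fit <- rm_anova(tab, "suv_mean", 64)
  expect_equal(fit$statistic, 0)
  expect_equal(fit$p.value, 1)
})

test_that("RM-ANOVA matches the textbook partition on a hand table", {
  # 4 subjects x 3 conditions, worked by explicit sums of squares
  Y <- matrix(c(10, 12, 11,
                8,  9, 10,
                12, 14, 13,
                9, 10, 12), nrow = 4, byrow = TRUE)
  tab <- make_table(Y)
  fit <- rm_anova(tab, "suv_mean", 64)
  grand <- mean(Y)
  ss_cond <- 4 * sum((colMeans(Y) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(Y) - grand)^2)
  ss_err <- sum((Y - grand)^2) - ss_cond - ss_subj
  F_hand <- (ss_cond / 2) / (ss_err / 6)
  expect_equal(fit$statistic, F_hand)
  expect_equal(fit$df1, 2); expect_equal(fit$df2, 6)
  expect_equal(fit$p.value, pf(F_hand, 2, 6, lower.tail = FALSE))
  # and against R's own aov Error-stratum fit
  o <- oracle_rm_anova_F(Y)
  expect_equal(fit$statistic, o$F, tolerance = 1e-10)
  expect_equal(fit$p.value, o$p, tolerance = 1e-10)
})

test_that("RM-ANOVA F equals the aov oracle on random tables", {
  set.seed(99)
  for (rep in 1:20) {
    Y <- matrix(rnorm(15, mean = 5), nrow = 5, ncol = 3)
    fit <- rm_anova(make_table(Y), "suv_mean", 64)
    o <- oracle_rm_anova_F(Y)
    expect_lt(abs(fit$statistic - o$F) / o$F, 1e-10)
  }
})

test_that("RM-ANOVA rejects incomplete block designs", {
  tab <- make_table(matrix(rnorm(12), 4, 3))
  expect_error(rm_anova(tab[-1, ], "suv_mean", 64), "design error")
})

test_that("tidy and glance methods expose the decomposition", {
  Y <- matrix(rnorm(12, 5), 4, 3)
  fit <- rm_anova(make_table(Y), "suv_mean", 64)
  td <- tidy(fit)
  expect_equal(td$term, c("conditions", "subjects", "error"))
  expect_equal(sum(td$sumsq), sum((Y - mean(Y))^2))
  gl <- glance(fit)
  expect_equal(gl$statistic, fit$statistic)
  expect_equal(gl$n_subjects, 4L)
})

test_that("post-hoc paired t tests with Bonferroni adjustment", {
  base <- c(3, 5, 8, 2, 6)
  tab <- make_table(cbind(base, base, base))
  ph <- posthoc_pairwise(tab, "suv_mean", 64)
  expect_equal(nrow(ph), 3L)
  expect_true(all(ph$p.adjusted == 1))

  set.seed(17)
  Y <- matrix(rnorm(15, 5), 5, 3); Y[, 2] <- Y[, 2] + 1
  tab2 <- make_table(Y)
  ph2 <- posthoc_pairwise(tab2, "suv_mean", 64)
  expect_equal(ph2$p.adjusted, pmin(1, 3 * ph2$p.value))
  # paired t for pair (c1, c2) against the direct formula
  dvec <- Y[, 1] - Y[, 2]
  t_hand <- mean(dvec) / (sd(dvec) / sqrt(5))
  expect_equal(ph2$statistic[1], t_hand)
  expect_equal(ph2$p.value[1], 2 * pt(abs(t_hand), 4, lower.tail = FALSE))
  # holm and none are also available
  ph3 <- posthoc_pairwise(tab2, "suv_mean", 64, adjust = "none")
  expect_equal(ph3$p.adjusted, ph3$p.value)
})

test_that("type-I error of the RM-ANOVA is calibrated under the null", {
  set.seed(2026)
  n_rej <- 0L; reps <- 2000L
  for (r in seq_len(reps)) {
    Y <- matrix(rnorm(24), nrow = 8, ncol = 3)
    res <- petrad:::rm_anova_matrix(Y)
    if (res$p < 0.05) n_rej <- n_rej + 1L
  }
  expect_lt(abs(n_rej / reps - 0.05), 0.01)
})

test_that("stability report covers every feature x bins cell", {
  set.seed(23)
  tabs <- list()
  for (f in c("suv_mean", "entropy", "sre")) {
    for (b in c(8, 64)) {
      tabs[[paste(f, b)]] <- make_table(matrix(rnorm(12, 10), 4, 3),
                                        feature = f, bins = b)
    }
  }
  tab <- dplyr::bind_rows(tabs)
  rep_ <- stability_report(tab)
  expect_s3_class(rep_, "stability_report")
  expect_equal(nrow(rep_$anova), 6L)                  # features x bin configs
  expect_equal(nrow(rep_$correlations), 6L * 3L)      # x condition pairs
  expect_equal(nrow(rep_$percent_differences), 6L * 3L)
  expect_equal(nrow(rep_$summary), 6L * 3L)           # x conditions
  expect_equal(nrow(tidy(rep_)), 6L)
  expect_equal(glance(rep_)$n_cells, 6L)
})

test_that("noise-free cohort with zero condition effect: r = 1, F = 0", {
  base <- c(4, 7, 9, 5.5)
  tab <- make_table(cbind(base, base, base))
  rep_ <- stability_report(tab)
  expect_true(all(rep_$anova$statistic == 0))
  expect_true(all(rep_$anova$p.value == 1))
  expect_true(all(rep_$correlations$r == 1))
  expect_true(all(rep_$percent_differences$mean_abs_pct_diff == 0))
})

test_that("plot constructors return ggplot objects", {
  set.seed(41)
  tab <- dplyr::bind_rows(
    make_table(matrix(rnorm(12, 10), 4, 3), feature = "suv_mean"),
    make_table(matrix(rnorm(12, 3), 4, 3), feature = "entropy"))
  rep_ <- stability_report(tab)
  expect_s3_class(autoplot(rep_), "ggplot")
  expect_s3_class(plot_condition_agreement(tab, "c1", "c2"), "ggplot")
})
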