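#' Build a long-form cohort feature table
#'
#' Pivots a wide per-scan feature table (one row per subject x condition x
#' bin configuration, as produced by the extraction stage) into the long
#' form the comparison statistics consume: one record per
#' (subject, condition, bins, feature, value).
#'
#' @param features Wide tibble with columns `subject`, `condition`, `bins`
#'   and the eight feature columns of [radiomic_feature_names()].
#' @return Long tibble with columns `subject`, `condition`, `bins`,
#'   `feature`, `value`.
#' @export
cohort_table <- function(features) {
  stopifnot(all(c("subject", "condition", "bins") %in% names(features)))
  present <- intersect(radiomic_feature_names(), names(features))
  if (length(present) == 0L) stop("no feature columns found", call. = FALSE)
  out <- tidyr::pivot_longer(
    dplyr::select(features, dplyr::all_of(c("subject", "condition", "bins",
                                            present))),
    cols = dplyr::all_of(present),
    names_to = "feature", values_to = "value")
  out$feature <- factor(out$feature, levels = radiomic_feature_names())
  out
}

check_complete_blocks <- function(tab) {
  counts <- table(tab$subject, tab$condition)
  if (any(counts != 1)) {
    stop("design error: incomplete block design — every subject needs ",
         "exactly one value per condition", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pearson correlation between two paired series
#'
#' Standard product-moment correlation with a two-sided p-value from the
#' t transform on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, both nonconstant.
#' @return A one-row tibble with columns `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation error: constant series", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Percent difference between two measurements
#'
#' `100 * (b - a) / a`, with `a` the baseline. Values are stored at full
#' precision; rounding to integer percent happens only in reports.
#'
#' @param a Baseline value (nonzero).
#' @param b Comparison value.
#' @param absolute If `TRUE`, return `|100 * (b - a) / a|`.
#' @return Percent difference.
#' @examples
#' percent_difference(11.6, 14.4)  # ~ +24
#' @export
percent_difference <- function(a, b, absolute = FALSE) {
  if (any(a == 0)) stop("undefined-baseline error: baseline value is 0",
                        call. = FALSE)
  d <- 100 * (b - a) / a
  if (absolute) abs(d) else d
}

# F statistic of a one-way repeated-measures ANOVA on an n x k matrix
# (rows = subjects, columns = conditions): SS_total is partitioned into
# SS_subjects + SS_conditions + SS_error.
rm_anova_matrix <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  # a zero condition sum of squares is a clean null result (F = 0, p = 1)
  # even when the error stratum is also empty, e.g. identical conditions
  if (ss_cond == 0) {
    f <- 0; p <- 1
  } else if (ms_err <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_cond / ms_err
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, df1 = df1, df2 = df2, p = p,
       ss_cond = ss_cond, ss_subj = ss_subj, ss_err = ss_err)
}

#' One-way repeated-measures ANOVA
#'
#' Tests whether a feature differs across conditions measured on the same
#' subjects, removing between-subject variance from the error term.
#' Sphericity is assumed (no Greenhouse-Geisser correction).
#'
#' @param data Long cohort table from [cohort_table()].
#' @param feature Feature name to test.
#' @param bins Bin count selecting the discretization configuration.
#' @return An object of class `rm_anova` with elements `statistic` (F),
#'   `df1`, `df2`, `p.value`, sums of squares, `n_subjects`, `k_conditions`,
#'   `feature`, `bins`. Has [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @examples
#' tab <- tibble::tibble(
#'   subject = rep(paste0("S", 1:4), each = 3),
#'   condition = rep(c("a", "b", "c"), 4),
#'   bins = 64, feature = "suv_mean",
#'   value = rnorm(12))
#' tidy(rm_anova(tab, "suv_mean", 64))
#' @export
rm_anova <- function(data, feature, bins = NULL) {
  tab <- data[data$feature == feature, , drop = FALSE]
  if (!is.null(bins)) tab <- tab[tab$bins == bins, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no records for feature '", feature, "'",
                            call. = FALSE)
  tab$subject <- droplevels(factor(tab$subject))
  tab$condition <- droplevels(factor(tab$condition))
  check_complete_blocks(tab)
  Y <- matrix(NA_real_, nlevels(tab$subject), nlevels(tab$condition),
              dimnames = list(levels(tab$subject), levels(tab$condition)))
  Y[cbind(as.integer(tab$subject), as.integer(tab$condition))] <- tab$value
  if (nrow(Y) < 2L || ncol(Y) < 2L) {
    stop("design error: need >= 2 subjects and >= 2 conditions", call. = FALSE)
  }
  res <- rm_anova_matrix(Y)
  structure(c(list(statistic = res$F, df1 = res$df1, df2 = res$df2,
                   p.value = res$p, ss_conditions = res$ss_cond,
                   ss_subjects = res$ss_subj, ss_error = res$ss_err,
                   n_subjects = nrow(Y), k_conditions = ncol(Y),
                   feature = as.character(feature), bins = bins)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("One-way repeated-measures ANOVA: %s%s\n", x$feature,
              if (!is.null(x$bins)) sprintf(" (%d bins)", x$bins) else ""))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g  [n = %d subjects, k = %d conditions]\n",
              x$df1, x$df2, x$statistic, x$p.value, x$n_subjects,
              x$k_conditions))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname rm_anova
#' @param x An `rm_anova` object.
#' @param ... Unused.
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(
    term = c("conditions", "subjects", "error"),
    df = c(x$df1, x$n_subjects - 1, x$df2),
    sumsq = c(x$ss_conditions, x$ss_subjects, x$ss_error),
    meansq = c(x$ss_conditions / x$df1, x$ss_subjects / (x$n_subjects - 1),
               x$ss_error / x$df2),
    statistic = c(x$statistic, NA, NA),
    p.value = c(x$p.value, NA, NA))
}

#' @rdname rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p.value = x$p.value, n_subjects = x$n_subjects,
                 k_conditions = x$k_conditions)
}

#' Paired post-hoc tests between condition pairs
#'
#' Two-sided paired t-tests for every condition pair, with multiplicity
#' adjustment across the pairs (Bonferroni by default; the adjustment choice
#' is a documented convention, not a claim about any particular software).
#'
#' @inheritParams rm_anova
#' @param adjust Adjustment method: `"bonferroni"`, `"holm"` or `"none"`.
#' @return Tibble with one row per condition pair: `condition_a`,
#'   `condition_b`, `statistic`, `df`, `p.value`, `p.adjusted`.
#' @export
posthoc_pairwise <- function(data, feature, bins = NULL,
                             adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  tab <- data[data$feature == feature, , drop = FALSE]
  if (!is.null(bins)) tab <- tab[tab$bins == bins, , drop = FALSE]
  tab$subject <- droplevels(factor(tab$subject))
  tab$condition <- droplevels(factor(tab$condition))
  check_complete_blocks(tab)
  conds <- levels(tab$condition)
  pairs <- utils::combn(conds, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ta <- tab[tab$condition == a, ]
    tb <- tab[tab$condition == b, ]
    ord <- match(ta$subject, tb$subject)
    dvec <- ta$value - tb$value[ord]
    if (stats::sd(dvec) == 0) {
      # identical pairs: a clean null (p = 1); constant nonzero shift: p = 0
      stat <- if (mean(dvec) == 0) 0 else sign(mean(dvec)) * Inf
      tibble::tibble(condition_a = a, condition_b = b, statistic = stat,
                     df = length(dvec) - 1,
                     p.value = if (mean(dvec) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(ta$value, tb$value[ord], paired = TRUE)
      tibble::tibble(condition_a = a, condition_b = b,
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p.value = tt$p.value)
    }
  })
  res$p.adjusted <- stats::p.adjust(res$p.value, method = adjust)
  res
}

#' Cross-condition stability report
#'
#' The full comparison layer of a paired-scanner stability study. For every
#' (feature, bins) cell it computes: Pearson correlation for each condition
#' pair, a one-way repeated-measures ANOVA across conditions, paired
#' post-hoc tests, and the mean absolute percent difference per condition
#' pair (baseline = first condition of the pair in factor order). Cells
#' whose statistics are undefined (e.g. constant features) are recorded
#' with `NA` and the remaining cells are still computed.
#'
#' @param data Long cohort table from [cohort_table()].
#' @param alpha Significance level used for the `significant` flag.
#' @param posthoc Post-hoc adjustment passed to [posthoc_pairwise()].
#' @return An object of class `stability_report`: list of tibbles
#'   `anova` (per feature x bins: F, df, p, significant), `correlations`
#'   (per feature x bins x condition pair: r, p), `posthoc` (adjusted
#'   pairwise p), `percent_differences` (mean |% difference| per pair),
#'   `summary` (mean and SD per feature x bins x condition), and `ranking`
#'   (features ordered by mean |% difference| within each bins). Has
#'   `tidy()`, `glance()` and `autoplot()` methods.
#' @export
stability_report <- function(data, alpha = 0.05,
                             posthoc = c("bonferroni", "holm", "none")) {
  posthoc <- match.arg(posthoc)
  data$feature <- droplevels(factor(data$feature))
  data$condition <- factor(data$condition,
                           levels = unique(as.character(data$condition)))
  cells <- dplyr::distinct(data, .data$feature, .data$bins)

  safe <- function(expr) tryCatch(expr, error = function(e) NULL)

  anova_tbl <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    ft <- cells$feature[i]; bn <- cells$bins[i]
    fit <- safe(rm_anova(data, ft, bn))
    if (is.null(fit)) {
      tibble::tibble(feature = ft, bins = bn, statistic = NA_real_,
                     df1 = NA_real_, df2 = NA_real_, p.value = NA_real_,
                     significant = NA)
    } else {
      tibble::tibble(feature = ft, bins = bn, statistic = fit$statistic,
                     df1 = fit$df1, df2 = fit$df2, p.value = fit$p.value,
                     significant = fit$p.value < alpha)
    }
  })

  wide_cell <- function(ft, bn) {
    tab <- data[data$feature == ft & data$bins == bn, ]
    tidyr::pivot_wider(tab[, c("subject", "condition", "value")],
                       names_from = "condition", values_from = "value")
  }

  conds <- levels(data$condition)
  pairs <- if (length(conds) >= 2) utils::combn(conds, 2) else NULL

  cor_tbl <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    ft <- cells$feature[i]; bn <- cells$bins[i]
    w <- wide_cell(ft, bn)
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      pr <- safe(pearson_r(w[[a]], w[[b]]))
      tibble::tibble(feature = ft, bins = bn, condition_a = a, condition_b = b,
                     r = if (is.null(pr)) NA_real_ else pr$r,
                     p = if (is.null(pr)) NA_real_ else pr$p)
    })
  })

  posthoc_tbl <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    ft <- cells$feature[i]; bn <- cells$bins[i]
    ph <- safe(posthoc_pairwise(data, ft, bn, adjust = posthoc))
    if (is.null(ph)) return(tibble::tibble())
    dplyr::mutate(ph, feature = ft, bins = bn, .before = 1)
  })

  pdiff_tbl <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    ft <- cells$feature[i]; bn <- cells$bins[i]
    w <- wide_cell(ft, bn)
    purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      pd <- safe(mean(percent_difference(w[[a]], w[[b]], absolute = TRUE)))
      tibble::tibble(feature = ft, bins = bn, condition_a = a, condition_b = b,
                     mean_abs_pct_diff = if (is.null(pd)) NA_real_ else pd)
    })
  })

  summary_tbl <- dplyr::summarise(
    dplyr::group_by(data, .data$feature, .data$bins, .data$condition),
    mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop")

  ranking_tbl <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(pdiff_tbl, .data$feature, .data$bins),
                     mean_abs_pct_diff = mean(.data$mean_abs_pct_diff),
                     .groups = "drop"),
    .data$bins, .data$mean_abs_pct_diff)

  structure(list(anova = anova_tbl, correlations = cor_tbl,
                 posthoc = posthoc_tbl, percent_differences = pdiff_tbl,
                 summary = summary_tbl, ranking = ranking_tbl,
                 alpha = alpha, posthoc_method = posthoc,
                 sphericity_assumed = TRUE),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Cross-condition stability report\n")
  cat(sprintf("  alpha = %g, post-hoc adjustment: %s (sphericity assumed)\n\n",
              x$alpha, x$posthoc_method))
  cat("ANOVA across conditions (per feature x bins):\n")
  df <- as.data.frame(x$anova)
  df$p.value <- signif(df$p.value, 3)
  df$statistic <- signif(df$statistic, 4)
  print(df, row.names = FALSE)
  cat("\nStability ranking (mean |% difference| across condition pairs):\n")
  rk <- as.data.frame(x$ranking)
  rk$mean_abs_pct_diff <- round(rk$mean_abs_pct_diff)
  print(rk, row.names = FALSE)
  invisible(x)
}

#' @rdname stability_report
#' @param x A `stability_report`.
#' @param ... Unused.
#' @export
tidy.stability_report <- function(x, ...) x$anova

#' @rdname stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$anova),
    n_significant = sum(x$anova$significant, na.rm = TRUE),
    alpha = x$alpha,
    posthoc = x$posthoc_method)
}
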