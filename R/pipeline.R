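#' Configuration of a full simulated stability study
#'
#' Bundles everything [run_study()] needs: the phantom template, the
#' acquisition conditions, the segmentation parameters, the discretization
#' bin counts and the master seed. A configuration round-trips through YAML
#' via [write_run_config()] / [read_run_config()].
#'
#' @param phantom A [phantom_spec()] template for the cohort.
#' @param conditions Named list of [condition_spec()]s.
#' @param segmentation A [segmentation_params()].
#' @param bins Integer vector of distinct bin counts; default `c(8, 64, 256)`.
#' @param n_subjects Number of simulated subjects.
#' @param subject_sd Per-subject variability SDs, see [generate_cohort()].
#' @param search_pad Padding (voxels) of the search box derived from the
#'   ground-truth tumor mask.
#' @param seed Master integer seed.
#' @param output_dir Directory for persisted volumes/CSV/report, or `NULL`
#'   to keep everything in memory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       conditions = study_conditions(),
                       segmentation = segmentation_params(),
                       bins = c(8L, 64L, 256L),
                       n_subjects = 8L,
                       subject_sd = c(size = 0.1, uptake = 0.15,
                                      heterogeneity = 0.15),
                       search_pad = 4L,
                       seed = 1L,
                       output_dir = NULL) {
  bins <- as.integer(bins)
  if (anyDuplicated(bins)) stop("bin counts must be distinct", call. = FALSE)
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(segmentation, "segmentation_params"),
            all(vapply(conditions, inherits, logical(1), "condition_spec")))
  structure(list(phantom = phantom, conditions = conditions,
                 segmentation = segmentation, bins = bins,
                 n_subjects = as.integer(n_subjects), subject_sd = subject_sd,
                 search_pad = as.integer(search_pad), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full simulated stability study
#'
#' Orchestrates the whole measurement chain: phantom cohort generation,
#' per-scan adaptive threshold segmentation (each image delineated
#' independently on its native grid, as in a paired-scanner protocol),
#' discretization at every configured bin count, feature extraction, and
#' the cross-condition comparison statistics. Deterministic given the
#' master seed.
#'
#' @param config A [run_config()].
#' @param verbose Print per-stage progress messages.
#' @return A list of class `study_result`:
#'   \describe{
#'     \item{features}{wide tibble, one row per (subject, condition, bins)
#'       with the eight feature columns plus segmentation metadata}
#'     \item{cohort_table}{the long-form table fed to the statistics}
#'     \item{report}{the [stability_report()]}
#'     \item{segmentation}{per-scan tibble of threshold, I70, Ibgd, VOI size
#'       and Dice overlap with the ground-truth sphere}
#'     \item{config}{the configuration used}
#'   }
#'   If `config$output_dir` is set, volumes and masks are written as NIfTI,
#'   features as `features.csv`, and the report tables as CSV files.
#' @examples
#' \donttest{
#' cfg <- run_config(n_subjects = 3, bins = c(8L, 64L), seed = 11)
#' res <- run_study(cfg)
#' dplyr::count(res$features, condition, bins)
#' }
#' @export
run_study <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating cohort: %d subjects x %d conditions",
      config$n_subjects, length(config$conditions))
  cohort <- generate_cohort(n_subjects = config$n_subjects,
                            base_spec = config$phantom,
                            conditions = config$conditions,
                            subject_sd = config$subject_sd,
                            seed = config$seed)

  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  feat_rows <- list()
  seg_rows <- list()
  for (i in seq_len(nrow(cohort))) {
    subj <- as.character(cohort$subject[i])
    cond <- as.character(cohort$condition[i])
    vol <- cohort$volume[[i]]
    truth <- cohort$tumor_truth[[i]]
    muscle <- cohort$muscle[[i]]
    search <- search_box_around(truth, pad = config$search_pad)
    voi <- segment_tumor(vol, search, config$segmentation)
    seg_rows[[i]] <- tibble::tibble(
      subject = subj, condition = cond,
      threshold = attr(voi, "threshold"), i70 = attr(voi, "i70"),
      i_bgd = attr(voi, "i_bgd"), voi_voxels = mask_size(voi),
      dice_vs_truth = dice_coefficient(voi, truth))
    for (b in config$bins) {
      fv <- extract_features(vol, voi, muscle,
                             discretization_config(bins = b))
      feat_rows[[length(feat_rows) + 1L]] <-
        dplyr::mutate(fv, subject = subj, condition = cond, .before = 1)
    }
    if (!is.null(out_dir)) {
      base <- file.path(out_dir, sprintf("%s_%s", subj, cond))
      write_volume(vol, paste0(base, ".nii.gz"))
      write_mask(voi, paste0(base, "_voi.nii.gz"), spacing = vol$spacing)
      write_mask(truth, paste0(base, "_truth.nii.gz"), spacing = vol$spacing)
    }
    say("segmented %s / %s: %d voxels (Dice %.3f)", subj, cond,
        mask_size(voi), seg_rows[[i]]$dice_vs_truth)
  }

  features <- dplyr::bind_rows(feat_rows)
  features$condition <- factor(features$condition,
                               levels = levels(cohort$condition))
  seg_tbl <- dplyr::bind_rows(seg_rows)
  tab <- cohort_table(features)
  report <- stability_report(tab)

  if (!is.null(out_dir)) {
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(seg_tbl, file.path(out_dir, "segmentation.csv"),
                     row.names = FALSE)
    utils::write.csv(report$anova, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    utils::write.csv(report$percent_differences,
                     file.path(out_dir, "percent_differences.csv"),
                     row.names = FALSE)
    utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }

  structure(list(features = features, cohort_table = tab, report = report,
                 segmentation = seg_tbl, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d subjects x %d conditions x %d bin configs = %d feature rows\n",
              x$config$n_subjects, length(x$config$conditions),
              length(x$config$bins), nrow(x$features)))
  cat(sprintf("  mean Dice vs ground truth: %.3f\n",
              mean(x$segmentation$dice_vs_truth)))
  print(x$report)
  invisible(x)
}

spec_to_list <- function(x) {
  out <- unclass(x)
  lapply(out, function(e) if (inherits(e, "condition_spec") ||
                              inherits(e, "phantom_spec")) spec_to_list(e)
         else e)
}

#' Serialize / restore a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- list(
    phantom = spec_to_list(config$phantom),
    conditions = lapply(config$conditions, spec_to_list),
    segmentation = unclass(config$segmentation),
    bins = config$bins,
    n_subjects = config$n_subjects,
    subject_sd = as.list(config$subject_sd),
    search_pad = config$search_pad,
    seed = config$seed,
    output_dir = config$output_dir)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ph <- lst$phantom
  phantom <- phantom_spec(shape = unlist(ph$shape), spacing = unlist(ph$spacing),
                          tumor_center = unlist(ph$tumor_center),
                          tumor_radius = ph$tumor_radius,
                          tumor_mean = ph$tumor_mean,
                          heterogeneity = ph$heterogeneity,
                          het_length = ph$het_length,
                          background = ph$background, muscle = ph$muscle,
                          muscle_box = list(lo = unlist(ph$muscle_box$lo),
                                            hi = unlist(ph$muscle_box$hi)),
                          seed = ph$seed)
  conds <- lapply(lst$conditions, function(cd) {
    condition_spec(cd$name, uptake_scale = cd$uptake_scale,
                   ac_bias = cd$ac_bias, noise_sd = cd$noise_sd,
                   smoothing_fwhm = cd$smoothing_fwhm,
                   spacing = if (is.null(cd$spacing)) NULL
                             else unlist(cd$spacing))
  })
  sg <- lst$segmentation
  run_config(phantom = phantom, conditions = conds,
             segmentation = segmentation_params(
               beta = sg$beta, core_fraction = sg$core_fraction,
               shell_gap = sg$shell_gap, shell_thickness = sg$shell_thickness,
               background_cap = sg$background_cap),
             bins = unlist(lst$bins), n_subjects = lst$n_subjects,
             subject_sd = unlist(lst$subject_sd),
             search_pad = lst$search_pad, seed = lst$seed,
             output_dir = lst$output_dir)
}
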