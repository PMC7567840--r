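#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti keeping the package's array-plus-voxel-size
#' convention: `read_volume()` returns the data array with its voxel size,
#' `write_volume()` stores an array (3-D scalar map or 4-D DWI series)
#' with anisotropic voxel sizes preserved.
#'
#' @param path NIfTI-1 file path (`.nii` or `.nii.gz`).
#' @param data numeric array.
#' @param voxel_size per-axis size in mm (spatial axes).
#' @return `read_volume()`: list with `data` and `voxel_size`;
#'   `write_volume()`: the path, invisibly.
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI volume: ", path,
                                           call. = FALSE))
  list(data = as.array(img),
       voxel_size = RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))])
}

#' @rdname read_volume
#' @export
write_volume <- function(data, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(data)
  pd <- c(voxel_size, rep(1, length(dim(data)) - length(voxel_size)))
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export one simulated subject to standard on-disk formats
#'
#' Writes the subject's noisy 4-D DWI and label volume as NIfTI, the
#' gradient table as FSL bval/bvec, and the covariate row as CSV, under
#' `dir` with the subject-session id as prefix.
#'
#' @param subject a `subject_record`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_subject_data <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, sprintf("%s_ses%d", subject$subject_id, subject$session))
  vs <- subject$masks$voxel_size
  paths <- c(dwi = paste0(stem, "_dwi.nii.gz"),
             labels = paste0(stem, "_labels.nii.gz"),
             bval = paste0(stem, ".bval"), bvec = paste0(stem, ".bvec"),
             covariates = paste0(stem, "_covariates.csv"))
  write_volume(subject_dwi(subject), paths[["dwi"]], vs)
  write_volume(subject$masks$labels, paths[["labels"]], vs)
  write_gradient_table(subject$scheme, paths[["bval"]], paths[["bvec"]])
  utils::write.csv(tibble::tibble(
    subject_id = subject$subject_id, group = subject$group, age = subject$age,
    sex = subject$sex, radiculopathy = subject$radiculopathy,
    session = subject$session), paths[["covariates"]], row.names = FALSE)
  invisible(paths)
}

#' Pipeline configuration
#'
#' All knobs of the end-to-end run in one list: the cohort generator
#' configuration, how per-subject metric maps are obtained (`"truth"` =
#' phantom observed maps, `"fit"` = voxel-wise tensor and
#' ball-and-stick-and-stick fits on regenerated DWI), fit options,
#' feature options (heuristic intervals, MI bins), statistics options
#' (FWE divisor, stepwise entry/removal p, k-means restarts) and the
#' output directory. `read_pipeline_config()` loads the same structure
#' from YAML; a fully populated template ships in
#' `system.file("extdata", "pipeline-default.yaml", package = "cordiff")`.
#'
#' @param cohort a [cohort_config()].
#' @param map_source `"truth"` or `"fit"`.
#' @param fit_restarts restarts of the ball-stick fit when
#'   `map_source = "fit"`.
#' @param mi_bins histogram bins of the mutual-information estimate.
#' @param intervals heuristic intervals.
#' @param entry_p,removal_p stepwise thresholds.
#' @param kmeans_restarts k-means restarts.
#' @param output_dir where result tables are written; `NULL` keeps
#'   everything in memory.
#' @param seed master seed (also seeds the cohort unless it sets its own).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(seed = seed),
                            map_source = c("truth", "fit"),
                            fit_restarts = 5, mi_bins = 64,
                            intervals = heuristic_intervals(),
                            entry_p = 0.05, removal_p = 0.10,
                            kmeans_restarts = 100,
                            output_dir = NULL, seed = 1) {
  map_source <- match.arg(map_source)
  structure(list(cohort = cohort, map_source = map_source,
                 fit_restarts = fit_restarts, mi_bins = mi_bins,
                 intervals = intervals, entry_p = entry_p,
                 removal_p = removal_p, kmeans_restarts = kmeans_restarts,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scalar_lists <- setdiff(names(y$cohort),
                          c("baseline", "voxel_jitter", "geometry"))
  cohort_args <- lapply(y$cohort[scalar_lists], function(v) {
    if (is.list(v)) unlist(v) else v
  })
  cc <- do.call(cohort_config, c(
    cohort_args,
    list(baseline = as.list(y$cohort$baseline %||% cohort_config()$baseline),
         voxel_jitter = as.list(y$cohort$voxel_jitter %||% cohort_config()$voxel_jitter))))
  args <- y[setdiff(names(y), "cohort")]
  if (!is.null(args$intervals)) args$intervals <- lapply(args$intervals, unlist)
  do.call(pipeline_config, c(list(cohort = cc), args))
}

fit_metric_maps <- function(subject, n_restarts = 5) {
  dwi <- subject_dwi(subject)
  cord <- subject$masks$labels > 0L
  dti <- fit_dti_wls(dwi, subject$scheme, cord)
  bss <- fit_ball_stick_stick(dwi, subject$scheme, cord,
                              n_restarts = n_restarts,
                              seed = subject$noise_seed %% 1e6 + 13L)
  zero <- function(a) { a[is.na(a)] <- 0; a }
  list(FA = metric_map("FA", zero(dti$fa), subject$masks),
       f1 = metric_map("f1", zero(bss$f1), subject$masks),
       MD = metric_map("MD", zero(dti$md), subject$masks),
       d = metric_map("d", zero(bss$d), subject$masks))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> maps -> features -> group statistics ->
#' classification -> reproducibility on a synthetic cohort and returns a
#' manifest of results: the significant-parameter list at the family-wise
#' threshold, ANCOVA confirmations, the stepwise model, the k-means
#' sensitivity/specificity, test-retest CVs, and (when an output
#' directory is configured) the paths of the written tables. Re-running
#' with the same configuration reproduces every number.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list with elements `features`, `tests`,
#'   `significant`, `ancova`, `radiculopathy`, `model`, `classification`,
#'   `repro`, `summary`, `files`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cohort <- simulate_cohort(config$cohort)
  map_fun <- if (config$map_source == "truth") {
    observed_metric_maps
  } else {
    function(s) fit_metric_maps(s, config$fit_restarts)
  }
  features <- cohort_features(cohort, map_fun = map_fun)

  base <- dplyr::filter(features, .data$session == 1)
  tests <- ranksum_all(base)
  params <- default_params(features)

  # candidate set: parameters separating age-comparable controls from a
  # patient group at the family-wise threshold
  cvp <- dplyr::filter(tests, .data$group1 == "age_control" &
                         .data$group2 %in% c("mild_patient", "severe_patient"))
  significant <- unique(cvp$parameter[cvp$significant])

  study <- dplyr::filter(base, .data$group != "young_control")
  is_control <- study$group == "age_control"
  ancova <- purrr::map_dfr(significant, function(par) {
    dplyr::bind_cols(tibble::tibble(parameter = par),
                     ancova_test(study[[par]], !is_control, study$age))
  })
  radic <- radiculopathy_posthoc(
    dplyr::filter(study, !is_control),
    params = if (length(significant)) significant else params)

  model <- if (length(significant)) {
    stepwise_regression(study, candidates = c(significant, "age"), is_control,
                        entry_p = config$entry_p, removal_p = config$removal_p)
  } else NULL
  classification <- if (!is.null(model) && length(model$selected)) {
    kmeans_classify(study[, model$selected, drop = FALSE], !is_control,
                    n_restarts = config$kmeans_restarts, seed = config$seed)
  } else NULL

  # CV is meaningful for location parameters only (means/medians of the
  # WM and GM ROIs); dispersion/shape statistics can have near-zero means
  repro <- session_cv(dplyr::filter(features, .data$group == "young_control"),
                      params = grep("^(FA|f1|MD|d)[wg][Mm]$", params, value = TRUE))

  summary <- list(
    n_records = nrow(features),
    n_significant = length(significant),
    significant = significant,
    selected = if (!is.null(model)) model$selected else character(0),
    model = if (!is.null(model)) as.list(glance(model)) else NULL,
    classification = if (!is.null(classification)) as.list(glance(classification)) else NULL,
    mean_cv = if (nrow(repro)) mean(repro$cv) else NA_real_,
    seed = config$seed)

  files <- character(0)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$output_dir, name)
    write_feature_table(features, out("features.csv"))
    utils::write.csv(tests, out("tests.csv"), row.names = FALSE)
    utils::write.csv(repro, out("repro_cv.csv"), row.names = FALSE)
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(features = out("features.csv"), tests = out("tests.csv"),
               repro = out("repro_cv.csv"), summary = out("summary.json"))
    if (!is.null(classification)) {
      utils::write.csv(glance(classification), out("confusion.csv"),
                       row.names = FALSE)
      files <- c(files, confusion = out("confusion.csv"))
    }
  }

  structure(list(features = features, tests = tests, significant = significant,
                 ancova = ancova, radiculopathy = radic, model = model,
                 classification = classification, repro = repro,
                 summary = summary, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d records, %d significant parameter(s)\n",
              nrow(x$features), length(x$significant)))
  if (!is.null(x$model)) {
    cat("  selected:", if (length(x$model$selected))
      paste(x$model$selected, collapse = ", ") else "(none)", "\n")
  }
  if (!is.null(x$classification)) {
    cat(sprintf("  SE = %.2f%%, SP = %.2f%%\n",
                x$classification$se, x$classification$sp))
  }
  invisible(x)
}

#' Boxplots of selected features by group
#'
#' @param features feature tibble with `group`.
#' @param params feature columns to show.
#' @return a ggplot.
#' @export
plot_group_features <- function(features, params) {
  df <- tidyr::pivot_longer(features[, c("group", params)],
                            dplyr::all_of(params),
                            names_to = "parameter", values_to = "value")
  df$group <- factor(df$group, levels = group_levels())
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}
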