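#' Rank-sum group comparisons over all feature parameters
#'
#' Runs the two-sided Wilcoxon rank-sum test for every parameter and every
#' pairwise combination of the subject groups (four groups give six
#' pairs), flagging significance at the Bonferroni family-wise threshold
#' 0.05/6. Exact enumeration p-values are used when both groups have at
#' most 10 subjects (and no ties); the normal approximation with tie
#' correction otherwise. The percent difference of group medians is
#' reported in the second-vs-first group direction.
#'
#' @param features tibble with a `group` column and feature columns; use
#'   one row per subject (pass session 1 only for test-retest subjects).
#' @param params feature columns to test; default: all numeric columns
#'   except covariates.
#' @param groups group levels to compare; pairs with a missing or
#'   single-subject group are skipped with a warning.
#' @param alpha per-comparison significance threshold, default
#'   [fwe_alpha()].
#' @return tibble: `parameter`, `group1`, `group2`, `median1`, `median2`,
#'   `diff_pct`, `p`, `significant`.
#' @export
ranksum_all <- function(features, params = NULL, groups = group_levels(),
                        alpha = fwe_alpha()) {
  if (is.null(params)) params <- default_params(features)
  present <- intersect(groups, unique(features$group))
  skipped <- setdiff(groups, present)
  ok <- present[vapply(present, function(g) sum(features$group == g) >= 2,
                       logical(1))]
  skipped <- c(skipped, setdiff(present, ok))
  if (length(skipped)) {
    warning("skipping group(s) with < 2 subjects: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (length(ok) < 2L) return(tibble::tibble())
  pairs <- utils::combn(ok, 2, simplify = FALSE)
  purrr::map_dfr(params, function(par) {
    purrr::map_dfr(pairs, function(pr) {
      x <- features[[par]][features$group == pr[1]]
      y <- features[[par]][features$group == pr[2]]
      p <- ranksum_p(x, y)
      m1 <- stats::median(x); m2 <- stats::median(y)
      tibble::tibble(parameter = par, group1 = pr[1], group2 = pr[2],
                     median1 = m1, median2 = m2,
                     diff_pct = if (m1 != 0) round(100 * (m2 / m1 - 1), 2) else NA_real_,
                     p = p, significant = p < alpha)
    })
  })
}

ranksum_p <- function(x, y) {
  exact <- length(x) <= 10 && length(y) <= 10 && !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
}

default_params <- function(features) {
  setdiff(names(features)[vapply(features, is.numeric, logical(1))],
          c("age", "session"))
}

#' Percent difference of a patient statistic against a control statistic
#'
#' The patient-versus-control percent change `100 * (patient/control - 1)`
#' rounded to two decimals, the arithmetic behind the group-median "diff
#' %" report.
#'
#' @param control_stat,patient_stat scalar group statistics.
#' @return signed percent, rounded to 2 decimals.
#' @examples
#' percent_difference(1.0509, 0.9951)
#' @export
percent_difference <- function(control_stat, patient_stat) {
  if (any(control_stat == 0)) {
    stop("percent difference undefined for a zero control value", call. = FALSE)
  }
  round(100 * (patient_stat / control_stat - 1), 2)
}

#' Age-adjusted group difference (ANCOVA)
#'
#' Linear model `feature ~ group + age` comparing controls against the
#' pooled patient groups with age as confounding covariate; the group
#' effect is judged by its partial F-test.
#'
#' @param feature numeric response vector.
#' @param is_patient logical (or two-level factor) group indicator.
#' @param age numeric covariate, no missing values.
#' @return one-row tibble: `statistic` (partial F of the group term),
#'   `p.value`, `df`, `df.residual`.
#' @export
ancova_test <- function(feature, is_patient, age) {
  if (anyNA(age) || anyNA(feature)) stop("missing values in ANCOVA inputs", call. = FALSE)
  g <- as.factor(is_patient)
  if (nlevels(droplevels(g)) < 2L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  full <- stats::lm(feature ~ g + age)
  if (any(is.na(stats::coef(full)))) {
    stop("rank-deficient ANCOVA design", call. = FALSE)
  }
  reduced <- stats::lm(feature ~ age)
  ssef <- sum(stats::residuals(full)^2)
  sser <- sum(stats::residuals(reduced)^2)
  df1 <- reduced$df.residual - full$df.residual
  # explicit partial F; a zero (or numerically negative) increment is F = 0
  fstat <- max(sser - ssef, 0) / df1 / (ssef / full$df.residual)
  tibble::tibble(statistic = fstat,
                 p.value = stats::pf(fstat, df1, full$df.residual,
                                     lower.tail = FALSE),
                 df = df1, df.residual = full$df.residual)
}

#' Radiculopathy post-hoc comparisons within patients
#'
#' Two-sided rank-sum test per parameter between patients with and
#' without radiculopathy, at uncorrected alpha = 0.05 (a post-hoc screen,
#' no family-wise correction).
#'
#' @param features tibble of patient rows with a logical `radiculopathy`
#'   column and feature columns.
#' @param params feature columns; default all numeric non-covariates.
#' @param alpha significance level.
#' @return tibble `parameter`, `p`, `significant`; empty (with a warning)
#'   if either subgroup is empty.
#' @export
radiculopathy_posthoc <- function(features, params = NULL, alpha = 0.05) {
  if (is.null(params)) params <- default_params(features)
  with_r <- features$radiculopathy
  if (all(with_r) || !any(with_r)) {
    warning("one radiculopathy subgroup is empty; tests skipped", call. = FALSE)
    return(tibble::tibble(parameter = character(0), p = numeric(0),
                          significant = logical(0)))
  }
  purrr::map_dfr(params, function(par) {
    p <- ranksum_p(features[[par]][with_r], features[[par]][!with_r])
    tibble::tibble(parameter = par, p = p, significant = p < alpha)
  })
}

#' Forward stepwise linear regression on the class signal
#'
#' Builds the minimal linear mixture model separating controls from
#' patients: the response is +0.5 for controls and -0.5 for patients, and
#' candidate columns enter while their coefficient p-value is below
#' `entry_p` (0.05) and leave when it rises above `removal_p` (0.10).
#' Selection is deterministic given column order; entry ties go to the
#' smaller p, then earlier column. Reported diagnostics: Pearson r
#' between the class signal and the fitted signal, root-mean-square error,
#' overall model F and p, and R^2.
#'
#' @param features tibble holding the candidate columns.
#' @param candidates character vector of candidate column names (include
#'   `"age"` to offer the age covariate to the model).
#' @param is_control logical vector defining the class signal.
#' @param entry_p,removal_p selection thresholds.
#' @return A `stepwise_model` with [tidy()] and [glance()] methods.
#' @export
stepwise_regression <- function(features, candidates, is_control,
                                entry_p = 0.05, removal_p = 0.10) {
  if (length(candidates) < 1L) stop("no candidate columns", call. = FALSE)
  y <- ifelse(is_control, 0.5, -0.5)
  X <- as.data.frame(features[, candidates, drop = FALSE])
  n <- length(y)
  selected <- character(0)

  coef_p <- function(cols) {
    fit <- stats::lm(y ~ ., data = X[, cols, drop = FALSE])
    s <- summary(fit)$coefficients
    # coefficient rows in column order; intercept dropped
    stats::setNames(s[-1, 4], cols)
  }

  for (step in seq_len(length(candidates) + 1L)) {
    remaining <- setdiff(candidates, selected)
    if (length(selected) + 3L >= n) break
    entry <- vapply(remaining, function(cand) {
      p <- tryCatch(coef_p(c(selected, cand))[[cand]], error = function(e) NA_real_)
      if (is.finite(p)) p else NA_real_
    }, numeric(1))
    entry <- entry[!is.na(entry)]
    if (!length(entry) || min(entry) >= entry_p) break
    selected <- c(selected, names(entry)[which.min(entry)])
    repeat {
      if (length(selected) < 2L) break
      ps <- coef_p(selected)
      if (max(ps) <= removal_p) break
      selected <- setdiff(selected, names(ps)[which.max(ps)])
    }
  }

  if (length(selected)) {
    fit <- stats::lm(y ~ ., data = X[, selected, drop = FALSE])
    sm <- summary(fit)
    fstat <- unname(sm$fstatistic[1])
    model_p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                         lower.tail = FALSE)
    r <- stats::cor(y, stats::fitted(fit))
    r2 <- sm$r.squared
  } else {
    fit <- stats::lm(y ~ 1)
    fstat <- NA_real_; model_p <- NA_real_; r <- NA_real_; r2 <- 0
  }
  rmse <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
  structure(list(selected = selected, fit = fit,
                 coefficients = stats::coef(fit), r = r, rmse = rmse,
                 fstatistic = fstat, p.value = model_p, r.squared = r2,
                 n = n, y = y), class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("<stepwise_model>\n  selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  cat(sprintf("  r = %.3f, RMSE = %.3f, F = %.2f, p = %.3g, R^2 = %.1f%%\n",
              x$r, x$rmse, x$fstatistic, x$p.value, 100 * x$r.squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname stepwise_regression
#' @param x,... a `stepwise_model` and unused arguments.
#' @method tidy stepwise_model
#' @export
tidy.stepwise_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname stepwise_regression
#' @method glance stepwise_model
#' @export
glance.stepwise_model <- function(x, ...) {
  tibble::tibble(r = x$r, rmse = x$rmse, statistic = x$fstatistic,
                 p.value = x$p.value, r.squared = x$r.squared,
                 n = x$n, n.selected = length(x$selected))
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) <= 0) {
      centers[j, ] <- x[sample.int(n, 1), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' K-means control-patient classification
#'
#' Clusters the selected feature columns (z-scored) into two classes with
#' seeded k-means++ initialization and multiple restarts, maps each
#' cluster to control or patient by the majority of the expert labels, and
#' scores sensitivity and specificity with patients as the positive class.
#'
#' @param features tibble or matrix of the selected feature columns.
#' @param is_patient logical expert labels.
#' @param n_restarts restarts (best total within-cluster SS wins).
#' @param seed integer seed.
#' @param standardize z-score the columns first (recorded in the result).
#' @return A `kmeans_classification`: confusion counts `tp`, `fn`, `tn`,
#'   `fp`, percentages `se`, `sp`, the cluster vector and predicted
#'   labels; has a [glance()] method.
#' @export
kmeans_classify <- function(features, is_patient, n_restarts = 100, seed = 1,
                            standardize = TRUE) {
  x <- as.matrix(features)
  if (nrow(x) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (ncol(x) < 1L) stop("need at least 1 feature", call. = FALSE)
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    keep <- sds > 0
    if (!any(keep)) stop("all features are constant; clustering is degenerate",
                         call. = FALSE)
    x <- scale(x[, keep, drop = FALSE])
  }
  if (all(stats::dist(x) < 1e-12)) {
    stop("all subjects identical; clustering is degenerate", call. = FALSE)
  }
  set.seed(as.integer(seed))
  best <- NULL
  if (nrow(x) == 2L) {
    # two subjects: each is its own cluster center
    best <- list(cluster = 1:2, tot.withinss = 0)
  } else for (r in seq_len(n_restarts)) {
    init <- kmeanspp_centers(x, 2L)
    if (any(duplicated(init))) next
    km <- tryCatch(suppressWarnings(stats::kmeans(x, centers = init, iter.max = 50)),
                   error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on every restart", call. = FALSE)
  cl <- best$cluster
  # majority mapping cluster -> class; the two clusters take distinct
  # classes (of the two permutations, the one agreeing best with the
  # expert labels -- identical to per-cluster majority except when both
  # clusters lean the same way)
  acc1 <- mean((cl == 1) == is_patient)
  predicted <- if (acc1 >= 0.5) cl == 1 else cl == 2
  tp <- sum(predicted & is_patient)
  fn <- sum(!predicted & is_patient)
  tn <- sum(!predicted & !is_patient)
  fp <- sum(predicted & !is_patient)
  ss <- sensitivity_specificity(tp, fn, tn, fp)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 se = ss$se, sp = ss$sp, cluster = cl, predicted = predicted,
                 standardized = standardize, tot.withinss = best$tot.withinss),
            class = "kmeans_classification")
}

#' Sensitivity and specificity from confusion counts
#'
#' `SE = 100 * TP / (TP + FN)` and `SP = 100 * TN / (TN + FP)`, patients
#' positive, rounded to 2 decimals.
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return one-row tibble `se`, `sp` (percent).
#' @examples
#' sensitivity_specificity(29, 4, 12, 1)
#' @export
sensitivity_specificity <- function(tp, fn, tn, fp) {
  tibble::tibble(se = round(100 * tp / (tp + fn), 2),
                 sp = round(100 * tn / (tn + fp), 2))
}

#' @export
print.kmeans_classification <- function(x, ...) {
  cat(sprintf("<kmeans_classification> SE = %.2f%%, SP = %.2f%% (TP %d, FN %d, TN %d, FP %d)\n",
              x$se, x$sp, x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' @rdname kmeans_classify
#' @param x,... a `kmeans_classification` and unused arguments.
#' @method glance kmeans_classification
#' @export
glance.kmeans_classification <- function(x, ...) {
  tibble::tibble(se = x$se, sp = x$sp, tp = x$tp, fn = x$fn, tn = x$tn,
                 fp = x$fp)
}

#' Cross-subject Pearson correlation matrix
#'
#' Pairwise Pearson correlations between feature columns (plus any extra
#' nuisance columns bound in by the caller). Zero-variance columns yield
#' missing correlations.
#'
#' @param features tibble/matrix of numeric columns, >= 3 rows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 3L) stop("need at least 3 rows", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  r
}
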