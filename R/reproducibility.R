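#' Test-retest coefficient of variation
#'
#' CV of a repeated measurement pair: the sample (n-1) standard deviation
#' of the two values divided by their mean. For a pair this reduces to
#' `|x1 - x2| / (sqrt(2) * mean)`.
#'
#' @param session1,session2 paired scalar measurements (vectorized).
#' @return CV, unitless.
#' @examples
#' coefficient_of_variation(9, 11)
#' @export
coefficient_of_variation <- function(session1, session2) {
  m <- (session1 + session2) / 2
  if (any(m == 0)) stop("CV undefined for a zero-mean pair", call. = FALSE)
  abs(session1 - session2) / sqrt(2) / abs(m)
}

#' Per-subject session CVs of a feature table
#'
#' Pairs sessions 1 and 2 by subject and computes the CV of every
#' parameter per subject, the per-subject reproducibility summary of the
#' test-retest cohort.
#'
#' @param features feature tibble with `subject_id`, `session` and
#'   feature columns; only subjects with both sessions are used.
#' @param params feature columns; default all numeric non-covariates.
#' @return long tibble `subject_id`, `parameter`, `cv`.
#' @export
session_cv <- function(features, params = NULL) {
  if (is.null(params)) params <- default_params(features)
  s1 <- dplyr::filter(features, .data$session == 1)
  s2 <- dplyr::filter(features, .data$session == 2)
  both <- intersect(s1$subject_id, s2$subject_id)
  purrr::map_dfr(both, function(id) {
    a <- s1[s1$subject_id == id, params]
    b <- s2[s2$subject_id == id, params]
    tibble::tibble(subject_id = id, parameter = params,
                   cv = unname(coefficient_of_variation(unlist(a), unlist(b))))
  })
}

#' Min-max normalized session differences per protocol
#'
#' For each parameter, pools the per-subject absolute session differences
#' across all protocols, min-max normalizes them to [0, 1], and reports
#' each protocol's mean normalized difference. A parameter whose pooled
#' minimum equals its maximum contributes 0 (degenerate-range
#' convention).
#'
#' @param differences named list, one element per protocol, each a matrix
#'   or tibble of absolute differences (rows = subjects, columns =
#'   parameters, identical across protocols).
#' @return list with `normalized` (list of matrices) and `protocol_means`
#'   (tibble `protocol`, `mean_normalized`).
#' @export
normalized_session_differences <- function(differences) {
  if (length(differences) < 2L) stop("need at least 2 protocols", call. = FALSE)
  mats <- lapply(differences, as.matrix)
  cols <- ncol(mats[[1]])
  if (any(vapply(mats, ncol, integer(1)) != cols)) {
    stop("protocols must share the same parameters", call. = FALSE)
  }
  pooled <- do.call(rbind, mats)
  lo <- apply(pooled, 2, min)
  hi <- apply(pooled, 2, max)
  span <- hi - lo
  norm <- lapply(mats, function(m) {
    out <- sweep(sweep(m, 2, lo), 2, ifelse(span > 0, span, 1), "/")
    out[, span == 0] <- 0
    out
  })
  means <- tibble::tibble(
    protocol = names(differences),
    mean_normalized = unname(vapply(norm, mean, numeric(1))))
  list(normalized = norm, protocol_means = means)
}

#' Pairwise protocol comparisons by signed-rank test
#'
#' Two-sided Wilcoxon signed-rank test between every pair of protocols on
#' paired per-subject (or per-parameter) reproducibility summaries, with
#' Bonferroni adjustment over the number of pairs (capped at 1). Zero
#' differences are dropped before ranking.
#'
#' @param values named list, one equal-length numeric vector per
#'   protocol, paired across protocols.
#' @return tibble `protocol1`, `protocol2`, `p_raw`, `p_adj`.
#' @export
protocol_comparison_tests <- function(values) {
  lens <- lengths(values)
  if (length(unique(lens)) != 1L) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  pairs <- utils::combn(names(values), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    d <- values[[pr[1]]] - values[[pr[2]]]
    p <- if (all(d == 0)) 1 else {
      suppressWarnings(stats::wilcox.test(values[[pr[1]]], values[[pr[2]]],
                                          paired = TRUE)$p.value)
    }
    tibble::tibble(protocol1 = pr[1], protocol2 = pr[2], p_raw = p,
                   p_adj = min(1, p * length(pairs)))
  })
}
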