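#' Scalar metric map on the phantom grid
#'
#' Wraps one scalar microstructure map (FA, f1, MD or d) together with its
#' tissue masks. FA and f1 are unitless; MD and d are in 1e-3 mm^2/s.
#'
#' @param metric one of `"FA"`, `"f1"`, `"MD"`, `"d"`.
#' @param values numeric 3-D array on the mask grid.
#' @param masks a `tissue_masks` object.
#' @return A `metric_map` object.
#' @export
metric_map <- function(metric, values, masks) {
  metric <- match.arg(metric, c("FA", "f1", "MD", "d"))
  if (!all(dim(values) == dim(masks$labels))) {
    stop("metric map and masks are on different grids", call. = FALSE)
  }
  structure(list(metric = metric, values = values, masks = masks,
                 units = if (metric %in% c("MD", "d")) "1e-3 mm^2/s" else "unitless"),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("<metric_map> %s (%s), grid %s\n", x$metric, x$units,
              paste(dim(x$values), collapse = " x ")))
  invisible(x)
}

roi_values <- function(map, roi_label) {
  v <- map$values[map$masks$labels == roi_label]
  v[is.finite(v)]
}

#' ROI descriptive statistics
#'
#' The five per-ROI summaries used throughout the analysis: mean, median,
#' standard deviation, skewness and kurtosis, all moment-based with
#' divide-by-n (population) moments; kurtosis is non-excess, so a Gaussian
#' sample gives 3. A zero-variance ROI reports skewness and kurtosis as
#' missing.
#'
#' @param map a [metric_map()].
#' @param roi_label 1 (GM) or 2 (WM).
#' @return one-row tibble: `mean`, `median`, `STD`, `skewness`, `kurtosis`.
#' @export
descriptive_stats <- function(map, roi_label) {
  x <- roi_values(map, roi_label)
  if (length(x) == 0L) stop("ROI is empty", call. = FALSE)
  if (length(x) < 2L) stop("ROI needs at least 2 voxels", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 > 0) {
    sk <- mean((x - m)^3) / m2^1.5
    ku <- mean((x - m)^4) / m2^2
  } else {
    sk <- NA_real_
    ku <- NA_real_
  }
  tibble::tibble(mean = m, median = stats::median(x), STD = sqrt(m2),
                 skewness = sk, kurtosis = ku)
}

#' White-gray matter difference of an ROI statistic
#'
#' The diffusivity-gradient style marker: `stat(WM) - stat(GM)` for the
#' chosen statistic of a metric map.
#'
#' @param map a [metric_map()].
#' @param stat `"mean"` or `"median"`.
#' @return scalar difference.
#' @export
wm_gm_difference <- function(map, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  wm <- roi_values(map, 2L)
  gm <- roi_values(map, 1L)
  if (length(wm) == 0L || length(gm) == 0L) {
    stop("both WM and GM ROIs must be non-empty", call. = FALSE)
  }
  f <- if (stat == "mean") mean else stats::median
  f(wm) - f(gm)
}

#' Gaussian kernel density estimate of ROI values
#'
#' Smooth probability density fitted to an ROI histogram with a Gaussian
#' ("normal") kernel and the normal-reference (Silverman) bandwidth. The
#' mixture form is kept explicitly so interval masses integrate in closed
#' form through the normal CDF.
#'
#' @param values numeric sample (at least 2 finite values).
#' @param bw kernel bandwidth; default `stats::bw.nrd0(values)`.
#' @return A `pdf_estimate`: list with `values`, `bw`.
#' @export
kde_pdf <- function(values, bw = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("density estimate needs at least 2 values", call. = FALSE)
  }
  if (is.null(bw)) bw <- stats::bw.nrd0(values)
  if (bw <= 0) bw <- 1e-8
  structure(list(values = values, bw = bw), class = "pdf_estimate")
}

#' Evaluate a kernel density estimate
#'
#' @param pdf a [kde_pdf()].
#' @param x evaluation points.
#' @return density values.
#' @export
pdf_density <- function(pdf, x) {
  vapply(x, function(xi) mean(stats::dnorm(xi, pdf$values, pdf$bw)), numeric(1))
}

#' Heuristic interval-mass parameter
#'
#' The heuristic marker H: the probability mass of the kernel-density
#' fitted metric distribution inside a fixed interval,
#' `H = integral of g(x) dx over [x1, x2]`, evaluated exactly as the
#' Gaussian-mixture CDF difference. H always lies in `[0, 1]` and never
#' decreases when the interval is enlarged.
#'
#' @param pdf a [kde_pdf()].
#' @param interval numeric `c(x1, x2)` with `x1 < x2`; the canonical
#'   per-metric intervals are in [heuristic_intervals()].
#' @return scalar H in `[0, 1]`.
#' @examples
#' h <- heuristic_parameter(kde_pdf(rnorm(500, 1.05, 0.21)),
#'                          heuristic_intervals()$MD_WM)
#' @export
heuristic_parameter <- function(pdf, interval) {
  if (length(interval) != 2L || interval[1] >= interval[2]) {
    stop("interval must be c(x1, x2) with x1 < x2", call. = FALSE)
  }
  mean(stats::pnorm(interval[2], pdf$values, pdf$bw) -
         stats::pnorm(interval[1], pdf$values, pdf$bw))
}

#' Shell-wise SNR estimate with Rayleigh background correction
#'
#' Estimates the signal-to-noise ratio of each diffusion-weighted shell
#' from raw (unpreprocessed) volumes: the shell's mean DWI intensity
#' inside the cord (excluding the first and last `exclude_slices` slices)
#' divided by the air-noise estimate `sqrt(2/(4-pi)) * sigma_air`, where
#' `sigma_air` is the standard deviation of magnitude values in the
#' segmented air region. Because pure-noise magnitude data are
#' Rayleigh-distributed, the correction converts the air SD to the
#' Gaussian channel SD. Air is located by low-intensity thresholding of
#' the mean b0 image within the superior half of the field of view.
#'
#' @param dwi 4-D array of raw volumes.
#' @param scheme matching [gradient_scheme()] with at least one b0 volume.
#' @param masks a `tissue_masks` object (cord = labels > 0).
#' @param exclude_slices slices dropped at each end of the slice axis.
#' @param air_threshold air cut as a fraction of the in-cord mean b0.
#' @return tibble, one row per shell: `shell`, `bval`, `i_sc`,
#'   `sigma_air`, `correction`, `snr`.
#' @export
estimate_snr <- function(dwi, scheme, masks, exclude_slices = 4,
                         air_threshold = 0.10) {
  dm <- dim(dwi)
  if (dm[4] != nrow(scheme)) {
    stop("dwi volume count does not match the gradient scheme", call. = FALSE)
  }
  nz <- dm[3]
  keep <- setdiff(seq_len(nz), c(seq_len(exclude_slices),
                                 nz - seq_len(exclude_slices) + 1L))
  if (length(keep) == 0L) stop("all slices excluded", call. = FALSE)
  b0 <- which(scheme$bval == 0)
  if (length(b0) == 0L) stop("SNR estimation needs b0 volumes", call. = FALSE)
  mean_over <- function(ks) {
    acc <- array(0, dm[1:3])
    for (k in ks) acc <- acc + dwi[, , , k]
    acc / length(ks)
  }
  b0_mean <- mean_over(b0)
  cord <- masks$labels > 0L

  superior <- array(FALSE, dm[1:3])
  superior[, seq.int(floor(dm[2] / 2) + 1L, dm[2]), ] <- TRUE
  air <- superior & b0_mean < air_threshold * mean(b0_mean[cord])
  if (!any(air)) stop("no air voxels found for noise estimation", call. = FALSE)

  cord_keep <- cord
  cord_keep[, , setdiff(seq_len(nz), keep)] <- FALSE

  shells <- sort(unique(scheme$shell[scheme$bval > 0]))
  purrr::map_dfr(shells, function(s) {
    ks <- which(scheme$shell == s)
    i_sc <- mean(mean_over(ks)[cord_keep])
    vals <- unlist(lapply(ks, function(k) dwi[, , , k][air]), use.names = FALSE)
    sigma_air <- stats::sd(vals)
    if (!is.finite(sigma_air) || sigma_air < .Machine$double.eps * 100) {
      stop("air noise estimate is zero; cannot form SNR", call. = FALSE)
    }
    tibble::tibble(shell = s, bval = scheme$bval[ks[1]], i_sc = i_sc,
                   sigma_air = sigma_air, correction = rayleigh_correction(),
                   snr = i_sc / (rayleigh_correction() * sigma_air))
  })
}

#' Mutual information between a metric map and the tissue labels
#'
#' Non-normalized mutual information `I = E_a + E_b - E_ab` (nats) between
#' a metric map a and the 3-level label image b (background 0, GM 1,
#' WM 2): the map is discretized to `q` equal-width bins over its range in
#' the evaluated region, marginal and joint histograms are normalized to
#' probabilities, and entropies use the natural log with `0 log 0 = 0`.
#' The default region is the bounding box of the cord dilated by 2 voxels,
#' so all three labels (including a background rim) occur; `region =
#' "cord"` restricts to cord voxels only.
#'
#' @param map a [metric_map()] (or plain numeric array with `labels` given).
#' @param masks a `tissue_masks`; defaults to the map's own.
#' @param region `"box"`, `"cord"`, or a logical array.
#' @param q number of map intensity bins.
#' @return A `mi_report`: list with `I`, `E_a`, `E_b`, `E_ab`, `q`, `r`.
#' @export
mutual_information <- function(map, masks = map$masks, region = "box", q = 64) {
  vals <- if (inherits(map, "metric_map")) map$values else map
  lab <- masks$labels
  if (is.character(region)) {
    region <- switch(match.arg(region, c("box", "cord")),
                     cord = lab > 0L,
                     box = dilated_bounding_box(lab > 0L, 2L))
  }
  if (!any(region)) stop("evaluation region is empty", call. = FALSE)
  a <- vals[region]
  b <- lab[region]
  rng <- range(a)
  ai <- if (rng[1] == rng[2]) rep(1L, length(a)) else {
    pmin(pmax(findInterval(a, seq(rng[1], rng[2], length.out = q + 1),
                           rightmost.closed = TRUE), 1L), q)
  }
  bi <- match(b, 0:2)
  joint <- table(factor(ai, levels = seq_len(q)), factor(bi, levels = 1:3))
  v <- joint / sum(joint)
  s <- rowSums(v)
  u <- colSums(v)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  e_a <- ent(s); e_b <- ent(u); e_ab <- ent(as.numeric(v))
  structure(list(I = e_a + e_b - e_ab, E_a = e_a, E_b = e_b, E_ab = e_ab,
                 q = q, r = 3L), class = "mi_report")
}

#' @export
print.mi_report <- function(x, ...) {
  cat(sprintf("<mi_report> I = %.4f nats (E_a %.4f, E_b %.4f, E_ab %.4f; q = %d, r = %d)\n",
              x$I, x$E_a, x$E_b, x$E_ab, x$q, x$r))
  invisible(x)
}

dilated_bounding_box <- function(mask, pad) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  rng <- lapply(1:3, function(j) {
    seq.int(max(1L, min(idx[, j]) - pad), min(d[j], max(idx[, j]) + pad))
  })
  out[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  out
}

feature_stats <- c(M = "median", m = "mean", S = "STD", SK = "skewness",
                   K = "kurtosis")

#' Extract the per-subject feature vector
#'
#' Builds the full 54-parameter feature vector of one subject-session from
#' its four metric maps: 5 descriptive statistics (median, mean, STD,
#' skewness, kurtosis) per metric per tissue (40), WM-GM differences of
#' medians and means per metric (8), and the 6 kernel-density heuristic
#' parameters (FAwH, f1wH, MDwH, MDgH, dwH, dgH). Columns follow the
#' three-part shortcut convention: metric (FA/f1/MD/d), region (w = WM,
#' g = GM, wg = WM-GM difference), then statistic (M median, m mean,
#' S STD, SK skewness, K kurtosis, H heuristic) -- e.g. `MDwgm` is the
#' WM-GM difference of MD means and `f1wSK` the WM skewness of f1.
#'
#' @param maps named list with metric maps `FA`, `f1`, `MD`, `d`.
#' @param intervals heuristic intervals, default [heuristic_intervals()].
#' @return one-row tibble with 54 named feature columns.
#' @export
extract_features <- function(maps, intervals = heuristic_intervals()) {
  missing <- setdiff(c("FA", "f1", "MD", "d"), names(maps))
  if (length(missing)) {
    stop("missing metric map(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (metric in c("FA", "f1", "MD", "d")) {
    for (roi_code in c("w", "g")) {
      st <- descriptive_stats(maps[[metric]], if (roi_code == "w") 2L else 1L)
      for (code in names(feature_stats)) {
        out[[paste0(metric, roi_code, code)]] <- st[[feature_stats[[code]]]]
      }
    }
    out[[paste0(metric, "wgM")]] <- wm_gm_difference(maps[[metric]], "median")
    out[[paste0(metric, "wgm")]] <- wm_gm_difference(maps[[metric]], "mean")
  }
  heur <- list(FAwH = c("FA", 2L, "FA_WM"), f1wH = c("f1", 2L, "f1_WM"),
               MDwH = c("MD", 2L, "MD_WM"), MDgH = c("MD", 1L, "MD_GM"),
               dwH = c("d", 2L, "d_WM"), dgH = c("d", 1L, "d_GM"))
  for (nm in names(heur)) {
    spec <- heur[[nm]]
    vals <- roi_values(maps[[spec[1]]], as.integer(spec[2]))
    out[[nm]] <- heuristic_parameter(kde_pdf(vals), intervals[[spec[3]]])
  }
  tibble::as_tibble(out)
}

#' Decompose a feature shortcut name
#'
#' Splits a shortcut such as `"f1wSK"` into its three parts: metric,
#' region and statistic.
#'
#' @param name character vector of shortcuts.
#' @return tibble with `shortcut`, `metric`, `region`, `stat`.
#' @export
parse_feature_name <- function(name) {
  purrr::map_dfr(name, function(nm) {
    metric <- c("FA", "f1", "MD", "d")[startsWith(nm, c("FA", "f1", "MD", "d"))][1]
    rest <- substring(nm, nchar(metric) + 1)
    region <- if (startsWith(rest, "wg")) "wg" else substring(rest, 1, 1)
    code <- substring(rest, nchar(region) + 1)
    stat <- if (code == "H") "heuristic" else unname(feature_stats[code])
    tibble::tibble(
      shortcut = nm, metric = metric,
      region = c(w = "WM", g = "GM", wg = "WM-GM")[[region]],
      stat = stat)
  })
}

long_feature_name <- function(shortcut) {
  p <- parse_feature_name(shortcut)
  reg <- c(WM = "WM", GM = "GM", `WM-GM` = "WM-GM")[p$region]
  paste(p$metric, reg, p$stat, sep = "_")
}

#' Feature table of a whole cohort
#'
#' Maps [extract_features()] over every subject-session of a simulated
#' cohort, prepending the covariates. By default per-session maps are the
#' phantom's observed (noise-perturbed) metric maps; pass `map_fun =
#' function(subject) ...` to supply maps from a model fit instead.
#'
#' @param cohort a `dwi_cohort`.
#' @param map_fun function of a subject record returning the named list of
#'   metric maps.
#' @return tibble: covariates + 54 feature columns per record.
#' @export
cohort_features <- function(cohort, map_fun = observed_metric_maps) {
  purrr::map_dfr(cohort, function(subj) {
    dplyr::bind_cols(
      tibble::tibble(subject_id = subj$subject_id, group = subj$group,
                     age = subj$age, sex = subj$sex,
                     radiculopathy = subj$radiculopathy, session = subj$session),
      extract_features(map_fun(subj)))
  })
}

#' Write a feature table as CSV
#'
#' Writes long parameter names as the header row, the shortcut names as a
#' second metadata row, then the data.
#'
#' @param features feature tibble from [cohort_features()].
#' @param path output path.
#' @export
write_feature_table <- function(features, path) {
  meta <- intersect(c("subject_id", "group", "age", "sex", "radiculopathy",
                      "session"), names(features))
  feat <- setdiff(names(features), meta)
  header <- c(meta, long_feature_name(feat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(paste(c(meta, feat), collapse = ","), con)
  utils::write.table(features, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Plot an axial slice of a metric map
#'
#' @param object a [metric_map()].
#' @param slice slice index along the slice axis (default: middle).
#' @param ... unused.
#' @return a ggplot raster with the GM outline overlaid.
#' @method autoplot metric_map
#' @export
autoplot.metric_map <- function(object, slice = NULL, ...) {
  d <- dim(object$values)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(object$values[, , slice])
  df$label <- as.vector(object$masks$labels[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$label == 1L),
                        size = 0.2, colour = "white", alpha = 0.5) +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s map, slice %d", object$metric, slice),
                  fill = object$units) +
    ggplot2::theme_minimal()
}
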