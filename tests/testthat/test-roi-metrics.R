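toy_map <- function(wm_vals, gm_vals, metric = "MD") {
  n <- length(wm_vals) + length(gm_vals)
  side <- ceiling(sqrt(n))
  lab <- array(0L, c(side, side, 1))
  lab[seq_along(wm_vals)] <- 2L
  lab[length(wm_vals) + seq_along(gm_vals)] <- 1L
  masks <- structure(list(labels = lab, voxel_size = c(1, 1, 1),
                          slice_axis = 3L,
                          geometry = list(center = c(side / 2, side / 2),
                                          band_halfwidth = 1)),
                     class = "tissue_masks")
  vals <- array(0, dim(lab))
  vals[lab == 2L] <- wm_vals
  vals[lab == 1L] <- gm_vals
  metric_map(metric, vals, masks)
}

test_that("descriptive statistics use population moments and non-excess kurtosis", {
  m <- toy_map(c(1, 2, 3), c(1, 1))
  st <- descriptive_stats(m, 2L)
  expect_equal(st$mean, 2)
  expect_equal(st$median, 2)
  expect_equal(st$skewness, 0)
  expect_equal(st$STD, sqrt(2 / 3))        # divide-by-n, not n-1

  # direct-moment oracle on {0,0,0,1}
  x <- c(0, 0, 0, 1)
  st2 <- descriptive_stats(toy_map(x, c(1, 1)), 2L)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  expect_equal(st2$skewness, m3 / m2^1.5)
  expect_equal(st2$kurtosis, mean((x - mean(x))^4) / m2^2)

  # large Gaussian sample: kurtosis near 3
  set.seed(1)
  g <- rnorm(1e6)
  st3 <- descriptive_stats(toy_map(g, c(1, 1)), 2L)
  expect_equal(st3$kurtosis, 3, tolerance = 0.05 / 3)

  # degenerate ROIs
  zv <- descriptive_stats(toy_map(c(5, 5, 5), c(1, 1)), 2L)
  expect_true(is.na(zv$skewness) && is.na(zv$kurtosis))
  expect_equal(zv$STD, 0)
  expect_error(descriptive_stats(toy_map(c(1), c(1, 1)), 2L), "at least 2")
  empty <- toy_map(c(1, 2), c(1, 1))
  empty$masks$labels[empty$masks$labels == 1L] <- 0L
  expect_error(descriptive_stats(empty, 1L), "empty")
})

test_that("WM-GM differences behave like a signed gradient", {
  m <- toy_map(c(1.2, 1.0), c(0.8, 0.6))
  expect_equal(wm_gm_difference(m, "mean"), 0.4)
  expect_equal(wm_gm_difference(m, "median"), 0.4)
  same <- toy_map(c(1, 2, 3), c(1, 2, 3))
  expect_equal(wm_gm_difference(same, "mean"), 0)
  swapped <- toy_map(c(0.8, 0.6), c(1.2, 1.0))
  expect_equal(wm_gm_difference(swapped, "mean"), -wm_gm_difference(m, "mean"))
})

test_that("heuristic H is an interval probability mass with the fixed bounds", {
  iv <- heuristic_intervals()
  expect_equal(iv$FA_WM, c(0.47, 0.67))
  expect_equal(iv$f1_WM, c(0.30, 0.55))
  expect_equal(iv$MD_WM, c(0.84, 1.26))
  expect_equal(iv$d_WM, c(1.70, 2.20))
  expect_equal(iv$d_GM, c(1.00, 1.48))

  # all mass at the interval center with a tiny bandwidth
  pdf <- kde_pdf(rep(1.05, 50) + rnorm(50, 0, 1e-6))
  expect_gte(heuristic_parameter(pdf, c(0.84, 1.26)), 0.999)

  # Gaussian-oracle: N(1.05, 0.21^2) over (0.84, 1.26) is Phi(1) - Phi(-1)
  set.seed(2)
  pdf2 <- kde_pdf(rnorm(1e4, 1.05, 0.21))
  expect_equal(heuristic_parameter(pdf2, c(0.84, 1.26)),
               pnorm(1) - pnorm(-1), tolerance = 0.02 / 0.68)

  # bounds and monotonicity in the interval
  set.seed(3)
  for (i in 1:10) {
    pdf3 <- kde_pdf(rnorm(40, runif(1), runif(1, 0.05, 0.4)))
    a <- sort(runif(2)); b <- c(a[1] - 0.2, a[2] + 0.2)
    h1 <- heuristic_parameter(pdf3, a)
    h2 <- heuristic_parameter(pdf3, b)
    expect_gte(h1, 0); expect_lte(h1, 1)
    expect_gte(h2, h1)
  }
  expect_error(heuristic_parameter(pdf2, c(1.2, 0.8)), "x1 < x2")
  expect_error(kde_pdf(c(1)), "at least 2")
  # the KDE integrates to one
  grid <- seq(-2, 4, length.out = 4000)
  expect_equal(sum(pdf_density(pdf2, grid)) * diff(grid)[1], 1, tolerance = 1e-3)
})

test_that("SNR estimation recovers truth through the Rayleigh correction", {
  # noise-free cord at 10, Rayleigh air with Gaussian channel SD 2
  dims <- c(40, 40, 10)
  lab <- array(0L, dims)
  lab[16:25, 5:14, ] <- 2L                 # cord in the inferior half
  masks <- structure(list(labels = lab, voxel_size = c(1, 1, 1), slice_axis = 3L,
                          geometry = list(center = c(20, 10), band_halfwidth = 1)),
                     class = "tissue_masks")
  n_vol <- 10
  sch <- gradient_scheme(c(0, rep(650, n_vol - 1)),
                         rbind(c(0, 0, 0),
                               matrix(rnorm(3 * (n_vol - 1)), n_vol - 1, 3) |>
                                 (\(x) x / sqrt(rowSums(x^2)))()),
                         c(0L, rep(1L, n_vol - 1)))
  set.seed(4)
  dwi <- array(0, c(dims, n_vol))
  for (k in seq_len(n_vol)) {
    clean <- array(0, dims)
    clean[lab == 2L] <- 10
    dwi[, , , k] <- add_rician_noise(clean, 0, 1)
    air <- lab == 0L
    nz <- sum(air)
    dwi[, , , k][air] <- sqrt(rnorm(nz, 0, 2)^2 + rnorm(nz, 0, 2)^2)
  }
  rep <- estimate_snr(dwi, sch, masks)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$snr, 5, tolerance = 0.02)
  expect_equal(rep$correction, sqrt(2 / (4 - pi)))

  # two shells with identical signal and noise agree
  sch2 <- gradient_scheme(c(0, rep(550, 4), rep(1000, 5)),
                          rbind(c(0, 0, 0),
                                matrix(rnorm(27), 9, 3) |>
                                  (\(x) x / sqrt(rowSums(x^2)))()),
                          c(0L, rep(1L, 4), rep(2L, 5)))
  rep2 <- estimate_snr(dwi, sch2, masks)
  expect_equal(nrow(rep2), 2L)
  expect_equal(rep2$snr[1], rep2$snr[2], tolerance = 0.05)

  # zero air noise is an estimation error, not a division by zero
  flat <- dwi; for (k in seq_len(n_vol)) flat[, , , k][lab == 0L] <- 0
  expect_error(estimate_snr(flat, sch, masks), "zero")
  # all slices excluded
  thin <- dwi[, , 1:6, , drop = FALSE]
  masks_thin <- masks; masks_thin$labels <- lab[, , 1:6, drop = FALSE]
  expect_error(estimate_snr(thin, sch, masks_thin, exclude_slices = 4), "excluded")
})

test_that("mutual information matches hand-computed entropies", {
  # self-comparison: a 3-level map against its own labels gives I = E_b
  m <- build_cord_masks(c(24, 24, 4))
  self_map <- metric_map("FA", array(as.numeric(m$labels) / 2, dim(m$labels)), m)
  rep <- mutual_information(self_map)
  expect_equal(rep$I, rep$E_b, tolerance = 1e-12)
  expect_lte(rep$I, min(rep$E_a, rep$E_b) + 1e-9)

  # independence: shuffled map carries (almost) no label information
  set.seed(5)
  shuf <- metric_map("FA", array(runif(length(m$labels)), dim(m$labels)), m)
  rep2 <- mutual_information(shuf, q = 8)
  expect_lt(rep2$I, 0.01)
  expect_gte(rep2$I, -1e-9)

  # hand-computed joint [[0.5, 0], [0, 0.5]]: I = ln 2
  lab <- array(0L, c(10, 10, 2)); lab[, 6:10, ] <- 2L
  mm <- structure(list(labels = lab, voxel_size = c(1, 1, 1), slice_axis = 3L,
                       geometry = list(center = c(5, 5), band_halfwidth = 1)),
                  class = "tissue_masks")
  vals <- array(0, dim(lab)); vals[lab == 2L] <- 1
  rep3 <- mutual_information(metric_map("FA", vals, mm), masks = mm,
                             region = array(TRUE, dim(lab)), q = 2)
  expect_equal(rep3$I, log(2), tolerance = 1e-12)
  expect_equal(rep3$E_ab, log(2), tolerance = 1e-12)

  # constant map: zero information, zero map entropy
  rep4 <- mutual_information(metric_map("FA", array(1, dim(m$labels)), m))
  expect_equal(rep4$I, 0)
  expect_equal(rep4$E_a, 0)

  # invariance to monotone transforms that preserve bin occupancy
  mono <- mutual_information(self_map)
  mono2 <- mutual_information(metric_map("FA", exp(self_map$values), m))
  expect_equal(mono$I, mono2$I, tolerance = 1e-12)
  # relabeling symmetry: swapping label codes leaves I unchanged
  m_swap <- m
  m_swap$labels[m$labels == 1L] <- 2L
  m_swap$labels[m$labels == 2L] <- 1L
  rep5 <- mutual_information(self_map, masks = m_swap)
  expect_equal(rep5$I, rep$I, tolerance = 1e-12)
})

test_that("feature extraction produces the full 54-parameter vector", {
  m <- build_cord_masks(c(32, 32, 6))
  micro <- assign_microstructure(m, "age_control", quick_config(), seed = 7)
  maps <- truth_metric_maps(micro)
  f <- extract_features(maps)
  expect_equal(ncol(f), 54L)
  expect_false(any(duplicated(names(f))))
  # 40 descriptive + 8 gradients + 6 heuristics
  expect_equal(sum(grepl("^(FA|f1|MD|d)[wg](M|m|S|SK|K)$", names(f))), 40L)
  expect_equal(sum(grepl("^(FA|f1|MD|d)wg(M|m)$", names(f))), 8L)
  expect_equal(sum(grepl("H$", names(f))), 6L)
  expect_true(all(c("FAwH", "f1wH", "MDwH", "MDgH", "dwH", "dgH") %in% names(f)))

  # definitional consistency with the underlying operations
  expect_equal(f$MDwgm, wm_gm_difference(maps$MD, "mean"))
  expect_equal(f$dwgM, wm_gm_difference(maps$d, "median"))
  expect_equal(f$f1wm, descriptive_stats(maps$f1, 2L)$mean)
  expect_equal(f$MDgSK, descriptive_stats(maps$MD, 1L)$skewness)
  wm_fa <- maps$FA$values[m$labels == 2L]
  expect_equal(f$FAwH, heuristic_parameter(kde_pdf(wm_fa),
                                           heuristic_intervals()$FA_WM))

  # determinism and error on a missing map
  expect_identical(f, extract_features(maps))
  expect_error(extract_features(maps[c("FA", "MD", "d")]), "f1")
})

test_that("shortcut names decompose into metric, region and statistic", {
  p <- parse_feature_name(c("f1wSK", "MDwgm", "dgH", "FAwK"))
  expect_equal(p$metric, c("f1", "MD", "d", "FA"))
  expect_equal(p$region, c("WM", "WM-GM", "GM", "WM"))
  expect_equal(p$stat, c("skewness", "mean", "heuristic", "kurtosis"))
})

test_that("feature tables round-trip to CSV with long names and shortcuts", {
  m <- build_cord_masks(c(24, 24, 4))
  micro <- assign_microstructure(m, "age_control", quick_config(), seed = 1)
  f <- dplyr::bind_cols(tibble::tibble(subject_id = "S01", group = "age_control",
                                       age = 50, sex = "F",
                                       radiculopathy = FALSE, session = 1L),
                        extract_features(truth_metric_maps(micro)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(f, path)
  lines <- readLines(path)
  expect_match(lines[1], "MD_WM-GM_mean")
  expect_match(lines[2], "MDwgm")
  dat <- utils::read.csv(path, skip = 1)
  expect_equal(dat$MDwgm, f$MDwgm, tolerance = 1e-12)
})
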