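# independent enumeration oracle for the two-sample rank-sum p-value:
# every C(n1+n2, n1) group assignment, two-sided tail of the rank sum
ranksum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  stats <- apply(combs, 2, function(i) sum(r[i]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

test_that("rank-sum p-values match full enumeration at small n", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(cordiff:::ranksum_p(x, y), ranksum_enum_p(x, y), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:10) {
    x <- round(rnorm(sample(4:7, 1)), 3)
    y <- round(rnorm(sample(4:7, 1), mean = runif(1, 0, 2)), 3)
    expect_equal(cordiff:::ranksum_p(x, y), ranksum_enum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("pairwise testing flags at the 0.05/6 family-wise threshold", {
  expect_equal(fwe_alpha(), 0.05 / 6)
  feats <- tibble::tibble(
    group = rep(group_levels(), each = 6),
    a = c(rnorm(18), rnorm(6, 50)),        # severe clearly shifted
    b = rep(c(1, 2, 3, 4, 5, 6), 4))       # identical in every group
  res <- ranksum_all(feats, params = c("a", "b"))
  expect_equal(nrow(res), 12L)             # 2 parameters x 6 pairs
  bres <- res[res$parameter == "b", ]
  expect_true(all(!bres$significant))
  expect_true(all(bres$p > fwe_alpha()))
  sev <- res[res$parameter == "a" & res$group2 == "severe_patient", ]
  expect_true(all(sev$significant))
  expect_true(all(res$significant == (res$p < 0.05 / 6)))
})

test_that("missing or tiny groups are skipped with a warning", {
  feats <- tibble::tibble(group = c(rep("age_control", 5), "mild_patient"),
                          a = rnorm(6))
  expect_warning(res <- ranksum_all(feats, params = "a"), "skipping")
  expect_equal(nrow(res), 0L)
})

test_that("percent differences reproduce the published arithmetic", {
  expect_equal(percent_difference(1.0509, 0.9951), -5.31)
  expect_equal(percent_difference(2.4934, 2.8241), 13.26)
  expect_equal(percent_difference(3.7, 3.7), 0)
  expect_error(percent_difference(0, 1), "zero control")
  # not antisymmetric under swapping the roles
  expect_false(isTRUE(all.equal(percent_difference(2, 3),
                                -percent_difference(3, 2))))
})

test_that("ANCOVA matches an explicit normal-equations oracle", {
  feature <- c(1.2, 0.9, 1.1, 0.6, 0.5, 0.7)
  grp <- c(0, 0, 0, 1, 1, 1)
  age <- c(50, 55, 60, 52, 57, 62)
  res <- ancova_test(feature, grp == 1, age)
  # oracle: explicit least squares for full and reduced models
  Xf <- cbind(1, grp, age)
  Xr <- cbind(1, age)
  bf <- solve(crossprod(Xf), crossprod(Xf, feature))
  br <- solve(crossprod(Xr), crossprod(Xr, feature))
  ssef <- sum((feature - Xf %*% bf)^2)
  sser <- sum((feature - Xr %*% br)^2)
  f_oracle <- (sser - ssef) / (ssef / 3)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-8)
  expect_equal(res$p.value, pf(f_oracle, 1, 3, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("ANCOVA is null-calibrated and rejects degenerate designs", {
  # identical (feature, age) pairs in both groups: group coefficient 0
  feature <- rep(c(1.1, 2.4, 2.9, 4.2), 2)
  age <- rep(c(50, 55, 60, 65), 2)
  grp <- rep(c(0, 1), each = 4)
  expect_gt(ancova_test(feature, grp == 1, age)$p.value, 0.99)

  # pure age trend, balanced groups: type-I error near nominal
  set.seed(12)
  rejections <- replicate(1000, {
    age <- rnorm(20, 55, 6)
    feature <- 0.05 * age + rnorm(20, 0, 0.1)
    grp <- rep(c(TRUE, FALSE), 10)
    ancova_test(feature, grp, age)$p.value < 0.05
  })
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)

  expect_error(ancova_test(c(1, 2, 3), c(TRUE, TRUE, TRUE), c(1, 2, 3)),
               "non-empty")
  expect_error(ancova_test(c(1, NA, 3), c(TRUE, FALSE, TRUE), c(1, 2, 3)),
               "missing")
})

test_that("radiculopathy screen is null-calibrated and catches real shifts", {
  mk <- function(shift) {
    tibble::tibble(group = rep("mild_patient", 20),
                   radiculopathy = rep(c(TRUE, FALSE), 10),
                   a = rnorm(20) + shift * rep(c(1, 0), 10))
  }
  set.seed(13)
  null_frac <- mean(replicate(400, radiculopathy_posthoc(mk(0), "a")$significant))
  expect_gt(null_frac, 0.02)
  expect_lt(null_frac, 0.09)
  expect_true(radiculopathy_posthoc(mk(10), "a")$significant)
  all_flagged <- mk(0); all_flagged$radiculopathy <- TRUE
  expect_warning(res <- radiculopathy_posthoc(all_flagged, "a"), "skipped")
  expect_equal(nrow(res), 0L)
})

test_that("stepwise selection is conservative under the null", {
  set.seed(14)
  n_sel <- replicate(200, {
    feats <- tibble::as_tibble(as.data.frame(matrix(rnorm(40 * 10), 40, 10)))
    names(feats) <- paste0("x", 1:10)
    m <- stepwise_regression(feats, names(feats), rep(c(TRUE, FALSE), 20))
    length(m$selected)
  })
  # each entry test is at p < 0.05; selections stay rare and small
  expect_lt(mean(n_sel), 1)
  expect_gte(mean(n_sel == 0), 0.5)
})

test_that("stepwise selection finds a strong informative candidate", {
  set.seed(15)
  hits <- replicate(200, {
    y_class <- rep(c(TRUE, FALSE), each = 20)
    feats <- tibble::as_tibble(as.data.frame(matrix(rnorm(40 * 11), 40, 11)))
    names(feats) <- c("signal", paste0("noise", 1:10))
    feats$signal <- feats$signal + ifelse(y_class, 3, 0)  # 3 SD separation
    m <- stepwise_regression(feats, names(feats), y_class)
    "signal" %in% m$selected
  })
  expect_gte(mean(hits), 0.95)
})

test_that("stepwise diagnostics equal a direct least-squares solve", {
  set.seed(16)
  y_class <- rep(c(TRUE, FALSE), each = 15)
  feats <- tibble::tibble(a = rnorm(30) + ifelse(y_class, 2, 0),
                          b = rnorm(30) + ifelse(y_class, 1.5, 0),
                          c = rnorm(30))
  m <- stepwise_regression(feats, c("a", "b", "c"), y_class)
  expect_gt(length(m$selected), 0)
  y <- ifelse(y_class, 0.5, -0.5)
  X <- cbind(1, as.matrix(feats[, m$selected]))
  beta <- solve(crossprod(X), crossprod(X, y))
  yp <- drop(X %*% beta)
  r2_oracle <- 1 - sum((y - yp)^2) / sum((y - mean(y))^2)
  expect_equal(m$r.squared, r2_oracle, tolerance = 1e-10)
  expect_equal(m$r, cor(y, yp), tolerance = 1e-10)
  expect_equal(unname(m$coefficients), as.vector(beta), tolerance = 1e-10)
  g <- glance(m)
  expect_equal(g$r.squared, r2_oracle)
  td <- tidy(m)
  expect_equal(nrow(td), length(m$selected) + 1L)
})

test_that("a null response yields the intercept-only stepwise model", {
  set.seed(17)
  feats <- tibble::tibble(a = rnorm(12) * 1e-9 + 5)
  m <- stepwise_regression(feats, "a", rep(c(TRUE, FALSE), 6))
  expect_equal(m$selected, character(0))
  expect_equal(m$r.squared, 0)
})

test_that("k-means classification separates well-separated groups perfectly", {
  set.seed(18)
  is_patient <- rep(c(TRUE, FALSE), c(20, 10))
  feats <- tibble::tibble(
    a = rnorm(30, ifelse(is_patient, 10, 0), 1),
    b = rnorm(30, ifelse(is_patient, -10, 0), 1))
  cl <- kmeans_classify(feats, is_patient, seed = 1)
  expect_equal(cl$se, 100)
  expect_equal(cl$sp, 100)
  # one subject per class
  tiny <- kmeans_classify(tibble::tibble(a = c(0, 5)), c(TRUE, FALSE), seed = 1)
  expect_equal(tiny$se, 100)
  expect_equal(tiny$sp, 100)
  # degenerate input
  expect_error(kmeans_classify(tibble::tibble(a = rep(1, 6)),
                               rep(c(TRUE, FALSE), 3)), "degenerate")
})

test_that("sensitivity/specificity arithmetic matches direct division", {
  ss <- sensitivity_specificity(29, 4, 12, 1)
  expect_equal(ss$se, round(100 * 29 / 33, 2))
  expect_equal(ss$sp, round(100 * 12 / 13, 2))
  expect_equal(ss$se, 87.88)
  expect_equal(ss$sp, 92.31)
})

test_that("k-means classification is reproducible for a fixed seed", {
  set.seed(19)
  is_patient <- rep(c(TRUE, FALSE), c(18, 12))
  feats <- tibble::tibble(a = rnorm(30, ifelse(is_patient, 1.5, 0)),
                          b = rnorm(30))
  a <- kmeans_classify(feats, is_patient, seed = 7)
  b <- kmeans_classify(feats, is_patient, seed = 7)
  expect_identical(glance(a), glance(b))
})

test_that("correlation matrices are symmetric with unit diagonal", {
  feats <- tibble::tibble(x = c(1, 2, 3), y = c(2, 4, 6), z = c(3, 1, 2),
                          flat = c(1, 1, 1))
  r <- correlation_matrix(feats)
  expect_equal(r["x", "x"], 1)
  expect_equal(r["x", "y"], 1)             # exact collinearity
  expect_equal(r, t(r))
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(is.na(r["flat", ])))
  neg <- correlation_matrix(tibble::tibble(x = c(1, 2, 3), y = -c(1, 2, 3)))
  expect_equal(neg["x", "y"], -1)
  expect_error(correlation_matrix(tibble::tibble(x = c(1, 2))), "3 rows")
})
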