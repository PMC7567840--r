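# Shared fixtures, built in code at test time.

# the study's two-shell scheme, computed once per test run
study_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_multishell_scheme(c(21, 42), c(550, 1000),
                                           n_b0 = 7, seed = 42)
    }
    cache
  }
})

# three-compartment signal of a single voxel, written independently of
# forward_signal() so the two routes cross-check each other
bss_signal <- function(scheme, S0 = 100, d = 1.0, f1 = 0, f2 = 0,
                       v1 = c(0, 0, 1), v2 = c(1, 0, 0)) {
  dirs <- as.matrix(scheme[, c("gx", "gy", "gz")])
  bd <- scheme$bval * d * 1e-3
  S0 * ((1 - f1 - f2) * exp(-bd) +
          f1 * exp(-bd * drop(dirs %*% v1)^2) +
          f2 * exp(-bd * drop(dirs %*% v2)^2))
}

# pack per-voxel signal rows into a V x 1 x 1 x n array plus its mask
voxel_grid <- function(signal_rows) {
  if (is.null(dim(signal_rows))) signal_rows <- matrix(signal_rows, nrow = 1)
  v <- nrow(signal_rows)
  n <- ncol(signal_rows)
  dwi <- array(0, c(v, 1, 1, n))
  for (k in seq_len(n)) dwi[, 1, 1, k] <- signal_rows[, k]
  list(dwi = dwi, mask = array(TRUE, c(v, 1, 1)))
}

angle_between_deg <- function(a, b) {
  acos(min(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1)) * 180 / pi
}

small_masks <- function(grid = c(32, 32, 8)) build_cord_masks(grid)

# a quick cohort at reduced grid for pipeline-level tests
quick_config <- function(seed = 1, ...) {
  cohort_config(grid_shape = c(32, 32, 8), seed = seed, ...)
}
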