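#' Voxel-wise diffusion tensor fit (weighted linear least squares)
#'
#' Fits the 7-parameter diffusion tensor model to the log signal by
#' ordinary least squares followed by iteratively reweighted linear least
#' squares with weights equal to the squared predicted signal (two
#' reweighting passes by default). Negative tensor eigenvalues are clamped
#' to zero before deriving fractional anisotropy (FA) and mean diffusivity
#' (MD = trace/3). Signals are floored at `1e-6 * S0` before the log.
#'
#' @param dwi 4-D array, grid x volumes.
#' @param scheme a [gradient_scheme()] matching the 4th dimension.
#' @param mask logical 3-D array of voxels to fit.
#' @param n_iter number of reweighting passes after the OLS start.
#' @return A `dti_fit`: list with arrays `fa`, `md` (1e-3 mm^2/s), `s0`,
#'   `tensor` (grid x 6: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, 1e-3 mm^2/s),
#'   `evecs` (grid x 3, principal eigenvector) and the `mask`. Values
#'   outside the mask are NA.
#' @export
fit_dti_wls <- function(dwi, scheme, mask, n_iter = 2) {
  dm <- dim(dwi)
  if (length(dm) != 4L || dm[4] != nrow(scheme)) {
    stop("dwi volume count does not match the gradient scheme", call. = FALSE)
  }
  b0 <- scheme$bval == 0
  if (nrow(scheme) < 7L) stop("tensor fit needs at least 7 volumes", call. = FALSE)
  if (!any(b0)) stop("tensor fit needs at least one b0 volume", call. = FALSE)
  if (all(b0)) stop("tensor fit needs diffusion-weighted volumes", call. = FALSE)

  dirs <- scheme_directions(scheme)
  bp <- scheme$bval * 1e-3                 # tensor in 1e-3 mm^2/s units
  X <- cbind(1, -bp * dirs[, 1]^2, -bp * dirs[, 2]^2, -bp * dirs[, 3]^2,
             -2 * bp * dirs[, 1] * dirs[, 2], -2 * bp * dirs[, 1] * dirs[, 3],
             -2 * bp * dirs[, 2] * dirs[, 3])

  idx <- which(mask)
  vol <- matrix(dwi, prod(dm[1:3]), dm[4])
  Y <- vol[idx, , drop = FALSE]
  s0_est <- rowMeans(Y[, b0, drop = FALSE])
  Yf <- pmax(Y, pmax(1e-6 * s0_est, .Machine$double.xmin))
  L <- t(log(Yf))                          # volumes x voxels
  beta <- solve(crossprod(X), crossprod(X, L))
  for (it in seq_len(n_iter)) {
    for (v in seq_len(ncol(beta))) {
      w <- exp(2 * drop(X %*% beta[, v]))
      beta[, v] <- solve(crossprod(X, w * X), crossprod(X, w * L[, v]))
    }
  }

  V <- ncol(beta)
  fa <- md <- numeric(V)
  ev1 <- matrix(0, V, 3)
  for (v in seq_len(V)) {
    b <- beta[, v]
    D <- matrix(c(b[2], b[5], b[6],
                  b[5], b[3], b[7],
                  b[6], b[7], b[4]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    md[v] <- mean(lam)
    denom <- sum(lam^2)
    fa[v] <- if (denom > 0) sqrt(1.5 * sum((lam - mean(lam))^2) / denom) else 0
    ev1[v, ] <- e$vectors[, 1]
  }

  blank <- array(NA_real_, dm[1:3])
  fill <- function(vals) { a <- blank; a[idx] <- vals; a }
  tensor <- array(NA_real_, c(dm[1:3], 6))
  for (j in 1:6) tensor[, , , j][idx] <- beta[j + 1, ]
  evecs <- array(NA_real_, c(dm[1:3], 3))
  for (j in 1:3) evecs[, , , j][idx] <- ev1[, j]
  structure(list(fa = fill(fa), md = fill(md), s0 = fill(exp(beta[1, ])),
                 tensor = tensor, evecs = evecs, mask = mask),
            class = "dti_fit")
}

softmax3 <- function(a1, a2) {
  e <- exp(c(0, a1, a2) - max(0, a1, a2))
  e / sum(e)
}

sph_to_vec <- function(th, ph) c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
vec_to_sph <- function(v) c(acos(min(max(v[3], -1), 1)), atan2(v[2], v[1]))

#' Voxel-wise ball-and-stick-and-stick fit
#'
#' Fits the three-compartment crossing-fiber model (isotropic ball plus
#' two fully anisotropic sticks sharing one diffusivity, 8 parameters per
#' voxel) by bound-respecting nonlinear least squares: sticks are
#' parameterized as spherical angles, the partial volumes through a
#' softmax simplex transform (so f1, f2 >= 0 and f1 + f2 <= 1 by
#' construction), diffusivity through its log, and S0 is profiled out in
#' closed form. Each voxel starts from a tensor-informed initialization
#' plus seeded random restarts; the best residual wins, ties broken toward
#' lower f2, and sticks are returned sorted so f1 >= f2. The fit is
#' deterministic for a fixed seed. Voxels whose optimizer fails are
#' flagged rather than raising an error.
#'
#' @param dwi 4-D array, grid x volumes.
#' @param scheme a [gradient_scheme()]; a two-shell scheme is recommended.
#' @param mask logical 3-D array.
#' @param n_restarts random restarts per voxel after the informed start.
#' @param seed integer seed for the restart stream.
#' @return A `ball_stick_fit`: list of arrays `s0`, `d` (1e-3 mm^2/s),
#'   `f1`, `f2`, `v1`, `v2` (grid x 3), logical `flag`, and the `mask`.
#' @export
fit_ball_stick_stick <- function(dwi, scheme, mask, n_restarts = 5, seed = 1) {
  dm <- dim(dwi)
  if (length(dm) != 4L || dm[4] != nrow(scheme)) {
    stop("dwi volume count does not match the gradient scheme", call. = FALSE)
  }
  dti <- fit_dti_wls(dwi, scheme, mask)
  dirs <- scheme_directions(scheme)
  bp <- scheme$bval * 1e-3
  idx <- which(mask)
  vol <- matrix(dwi, prod(dm[1:3]), dm[4])

  # log-diffusivity is clamped so line-search excursions cannot overflow
  # exp() and poison the b0 rows (where bp = 0) with 0 * Inf
  objective <- function(p, y) {
    d <- exp(min(max(p[1], -20), 10))
    fr <- softmax3(p[2], p[3])
    a1 <- drop(dirs %*% sph_to_vec(p[4], p[5]))^2
    a2 <- drop(dirs %*% sph_to_vec(p[6], p[7]))^2
    m <- fr[1] * exp(-bp * d) + fr[2] * exp(-bp * d * a1) +
      fr[3] * exp(-bp * d * a2)
    mm <- sum(m * m)
    if (!is.finite(mm) || mm <= 0) return(sum(y^2))
    sum(y^2) - sum(m * y)^2 / mm
  }

  set.seed(as.integer(seed))
  V <- length(idx)
  out <- matrix(NA_real_, V, 4)            # s0, d, f1, f2
  vv1 <- vv2 <- matrix(NA_real_, V, 3)
  flag <- logical(V)

  for (v in seq_len(V)) {
    y <- vol[idx[v], ]
    ss <- sum(y^2)
    if (ss == 0) { flag[v] <- TRUE; next }
    # tensor-informed start
    e1 <- c(dti$evecs[, , , 1][idx[v]], dti$evecs[, , , 2][idx[v]],
            dti$evecs[, , , 3][idx[v]])
    if (anyNA(e1) || sum(e1^2) == 0) e1 <- c(0, 0, 1)
    fa0 <- dti$fa[idx[v]]; md0 <- dti$md[idx[v]]
    if (!is.finite(fa0)) fa0 <- 0.5
    if (!is.finite(md0) || md0 <= 0) md0 <- 1
    f1_0 <- min(max(fa0, 0.1), 0.8)
    sph1 <- vec_to_sph(e1)
    perp <- c(-e1[2], e1[1], 0)
    if (sum(perp^2) < 1e-8) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    p0 <- c(log(md0 * 1.5),
            log(f1_0 / (1 - f1_0 - 0.02)), log(0.02 / (1 - f1_0 - 0.02)),
            sph1, vec_to_sph(perp))

    best <- NULL
    best_val <- Inf
    best_f2 <- Inf
    for (r in seq_len(n_restarts + 1L)) {
      p <- if (r == 1L) p0 else p0 + stats::rnorm(7, 0, c(0.4, 1, 1, 0.5, 1, 0.5, 1))
      res <- tryCatch(
        stats::optim(p, objective, y = y, method = "BFGS",
                     control = list(maxit = 400, reltol = 1e-14)),
        error = function(e) NULL)
      if (is.null(res)) next
      f2_here <- softmax3(res$par[2], res$par[3])[3]
      if (res$value < best_val - 1e-12 * ss ||
          (abs(res$value - best_val) <= 1e-12 * ss && f2_here < best_f2)) {
        best <- res$par; best_val <- res$value; best_f2 <- f2_here
      }
      if (best_val < 1e-14 * ss) break     # exact fit; skip remaining restarts
    }
    if (is.null(best)) { flag[v] <- TRUE; next }
    d <- exp(min(max(best[1], -20), 10))
    fr <- softmax3(best[2], best[3])
    u1 <- sph_to_vec(best[4], best[5])
    u2 <- sph_to_vec(best[6], best[7])
    a1 <- drop(dirs %*% u1)^2
    a2 <- drop(dirs %*% u2)^2
    m <- fr[1] * exp(-bp * d) + fr[2] * exp(-bp * d * a1) +
      fr[3] * exp(-bp * d * a2)
    s0 <- sum(m * y) / sum(m * m)
    f1 <- fr[2]; f2 <- fr[3]
    if (f2 > f1) { tmp <- f1; f1 <- f2; f2 <- tmp; tmpv <- u1; u1 <- u2; u2 <- tmpv }
    # collinear sticks are a single fiber population split by an exact-fit
    # degeneracy; merge them so f2 measures genuine crossings only
    if (abs(sum(u1 * u2)) > 0.985) { f1 <- f1 + f2; f2 <- 0 }
    out[v, ] <- c(s0, d, f1, f2)
    vv1[v, ] <- u1
    vv2[v, ] <- u2
  }

  blank <- array(NA_real_, dm[1:3])
  fill <- function(col) { a <- blank; a[idx] <- col; a }
  v1 <- v2 <- array(NA_real_, c(dm[1:3], 3))
  for (j in 1:3) {
    v1[, , , j][idx] <- vv1[, j]
    v2[, , , j][idx] <- vv2[, j]
  }
  fl <- array(FALSE, dm[1:3]); fl[idx] <- flag
  structure(list(s0 = fill(out[, 1]), d = fill(out[, 2]), f1 = fill(out[, 3]),
                 f2 = fill(out[, 4]), v1 = v1, v2 = v2, flag = fl, mask = mask),
            class = "ball_stick_fit")
}

#' Detect crossing-fiber voxels
#'
#' Flags voxels whose second stick carries a significant partial volume,
#' `f2 > threshold` (default 0.05), and reports the flagged fraction of
#' the mask.
#'
#' @param fit a `ball_stick_fit`.
#' @param mask logical 3-D array; must contain at least one voxel.
#' @param threshold partial-volume cut, default [crossing_threshold()].
#' @return list with `mask` (logical array) and `fraction`.
#' @export
detect_crossings <- function(fit, mask, threshold = crossing_threshold()) {
  if (!any(mask)) stop("crossing detection needs a non-empty mask", call. = FALSE)
  cross <- mask & !is.na(fit$f2) & fit$f2 > threshold
  list(mask = cross, fraction = sum(cross) / sum(mask))
}
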