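#' Gradient sampling schemes
#'
#' A gradient scheme describes one diffusion acquisition: one row per
#' volume with its b-value (s/mm^2), unit gradient direction (zero vector
#' for b = 0 volumes) and shell index (0 for b0 volumes). Schemes are
#' tibbles with columns `bval`, `gx`, `gy`, `gz`, `shell`, so they chain
#' with the usual dplyr verbs.
#'
#' @param bvalues numeric vector of b-values, s/mm^2.
#' @param directions numeric matrix, one row per volume, three columns.
#' @param shell_ids integer shell index per volume; 0 marks b0 volumes.
#' @return A `gradient_scheme` tibble.
#' @export
gradient_scheme <- function(bvalues, directions, shell_ids) {
  directions <- as.matrix(directions)
  if (length(bvalues) != nrow(directions) ||
      length(bvalues) != length(shell_ids)) {
    stop("bvalues, directions and shell_ids must describe the same number of volumes",
         call. = FALSE)
  }
  if (any(bvalues < 0)) stop("b-values must be non-negative", call. = FALSE)
  nrm <- sqrt(rowSums(directions^2))
  weighted <- bvalues > 0
  if (any(weighted) && any(abs(nrm[weighted] - 1) > 1e-6)) {
    stop("directions of diffusion-weighted volumes must have unit norm", call. = FALSE)
  }
  directions[!weighted, ] <- 0
  for (s in unique(shell_ids[weighted])) {
    if (length(unique(bvalues[shell_ids == s])) != 1L) {
      stop("all volumes in a shell must share one b-value", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    bval = as.numeric(bvalues),
    gx = directions[, 1], gy = directions[, 2], gz = directions[, 3],
    shell = as.integer(shell_ids)
  )
  class(out) <- c("gradient_scheme", class(out))
  out
}

#' @export
print.gradient_scheme <- function(x, ...) {
  nb0 <- sum(x$bval == 0)
  shells <- dplyr::filter(x, .data$bval > 0)
  cat(sprintf("<gradient_scheme> %d volumes: %d b0 + %d weighted\n",
              nrow(x), nb0, nrow(shells)))
  if (nrow(shells)) {
    tab <- dplyr::count(shells, .data$shell, .data$bval)
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  shell %d: %d directions at b = %g s/mm^2\n",
                  tab$shell[i], tab$n[i], tab$bval[i]))
    }
  }
  invisible(x)
}

scheme_directions <- function(scheme) {
  unname(as.matrix(scheme[, c("gx", "gy", "gz")]))
}

#' Electrostatic energy of antipodally symmetric point sets
#'
#' Repulsion energy used by the scheme optimizer: for every point pair the
#' antipodal Coulomb term `1/|xi - xj| + 1/|xi + xj|`, summed within each
#' shell, plus the same sum over the union of all shells weighted by
#' `coupling` so the combined set is also close to uniform.
#'
#' @param shells list of n x 3 unit-row matrices, one per shell.
#' @param coupling weight of the all-shell union term.
#' @return scalar energy.
#' @export
scheme_energy <- function(shells, coupling = 0.5) {
  e <- sum(vapply(shells, pair_energy, numeric(1)))
  if (length(shells) > 1L && coupling > 0) {
    e <- e + coupling * pair_energy(do.call(rbind, shells))
  }
  e
}

pair_energy <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(0)
  g <- tcrossprod(x)                      # cosines between points
  iu <- upper.tri(g)
  dm <- sqrt(pmax(2 - 2 * g[iu], 0))      # |xi - xj|
  dp <- sqrt(pmax(2 + 2 * g[iu], 0))      # |xi + xj|
  sum(1 / pmax(dm, 1e-12)) + sum(1 / pmax(dp, 1e-12))
}

# Euclidean gradient of the antipodal pair energy wrt all points, rows of x.
pair_energy_grad <- function(x) {
  n <- nrow(x)
  g <- matrix(0, n, 3)
  if (n < 2L) return(g)
  for (i in seq_len(n)) {
    d <- sweep(x[-i, , drop = FALSE], 2, x[i, ], "-")   # xj - xi
    s <- sweep(x[-i, , drop = FALSE], 2, x[i, ], "+")   # xj + xi
    dn <- pmax(sqrt(rowSums(d^2)), 1e-12)
    sn <- pmax(sqrt(rowSums(s^2)), 1e-12)
    # d/dxi 1/|xi-xj| = (xj - xi)/|xi-xj|^3 ; d/dxi 1/|xi+xj| = -(xi+xj)/|.|^3
    g[i, ] <- colSums(d / dn^3) - colSums(s / sn^3)
  }
  g
}

#' Design a multi-shell uniformly distributed gradient scheme
#'
#' Places antipodally symmetric point sets on each b-value shell by
#' minimizing an electrostatic repulsion energy with a cross-shell coupling
#' term, so that every shell and the union of shells are near-uniform over
#' the sphere. Optimization is projected gradient descent on the product of
#' unit spheres with step halving, started from a seeded random
#' configuration; it is deterministic for a fixed seed.
#'
#' @param shell_counts integer vector, directions per shell.
#' @param shell_bvalues numeric vector of shell b-values, s/mm^2.
#' @param n_b0 number of b = 0 volumes, placed first in the scheme.
#' @param seed integer seed for the random start.
#' @param coupling weight of the all-shell union energy term.
#' @param max_iter,tol optimizer iteration cap and relative-energy tolerance.
#' @return A [gradient_scheme()] tibble with `n_b0 + sum(shell_counts)` rows.
#' @examples
#' sch <- generate_multishell_scheme(c(21, 42), c(550, 1000), n_b0 = 7, seed = 1)
#' sum(sch$bval > 0)
#' @export
generate_multishell_scheme <- function(shell_counts, shell_bvalues, n_b0 = 0,
                                       seed = 1, coupling = 0.5,
                                       max_iter = 2000, tol = 1e-10) {
  if (length(shell_counts) != length(shell_bvalues)) {
    stop("shell_counts and shell_bvalues must have the same length", call. = FALSE)
  }
  if (any(shell_counts < 1L)) stop("each shell needs at least one direction", call. = FALSE)
  if (sum(shell_counts) == 0L) stop("scheme must contain at least one direction", call. = FALSE)
  if (n_b0 < 0) stop("n_b0 must be non-negative", call. = FALSE)

  set.seed(as.integer(seed))
  shells <- lapply(shell_counts, function(n) {
    x <- matrix(stats::rnorm(3 * n), n, 3)
    x / sqrt(rowSums(x^2))
  })

  energy <- scheme_energy(shells, coupling)
  step <- 0.05
  for (iter in seq_len(max_iter)) {
    grads <- lapply(shells, pair_energy_grad)
    if (length(shells) > 1L && coupling > 0) {
      allg <- pair_energy_grad(do.call(rbind, shells))
      off <- 0L
      for (k in seq_along(shells)) {
        n <- nrow(shells[[k]])
        grads[[k]] <- grads[[k]] + coupling * allg[off + seq_len(n), , drop = FALSE]
        off <- off + n
      }
    }
    # project onto the tangent plane of each unit sphere
    grads <- Map(function(x, g) g - x * rowSums(g * x), shells, grads)
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gnorm == 0) break
    repeat {
      cand <- Map(function(x, g) {
        y <- x - step * g / gnorm
        y / sqrt(rowSums(y^2))
      }, shells, grads)
      cand_energy <- scheme_energy(cand, coupling)
      if (cand_energy < energy || step < 1e-14) break
      step <- step / 2
    }
    if (cand_energy < energy) {
      improved <- (energy - cand_energy) / energy
      shells <- cand
      energy <- cand_energy
      step <- step * 1.2
      if (improved < tol) break
    } else {
      break
    }
  }

  bvals <- c(rep(0, n_b0), rep(shell_bvalues, shell_counts))
  dirs <- rbind(matrix(0, n_b0, 3), do.call(rbind, shells))
  ids <- c(rep(0L, n_b0), rep(seq_along(shell_counts), shell_counts))
  gradient_scheme(bvals, dirs, ids)
}

#' Minimum antipodally folded angular distance of a direction set
#'
#' Smallest pairwise angle (degrees) between directions after folding
#' antipodes together; a uniformity summary of one shell.
#'
#' @param directions n x 3 matrix of unit rows.
#' @return scalar angle in degrees.
#' @export
min_angular_distance <- function(directions) {
  g <- abs(tcrossprod(directions))
  g <- pmin(g[upper.tri(g)], 1)
  min(acos(g)) * 180 / pi
}

#' Read and write FSL-dialect gradient tables
#'
#' `read_gradient_table()` parses a bval file (one whitespace-separated row
#' of N b-values) and a bvec file (three rows of N components) into a
#' [gradient_scheme()]; b0 directions are normalized to the zero vector and
#' weighted directions to unit length, and shells are inferred from the
#' distinct nonzero b-values. `write_gradient_table()` writes the inverse
#' format; b-values and components round-trip to six significant digits.
#'
#' @param bval_path,bvec_path paths of the two text files.
#' @param scheme a [gradient_scheme()].
#' @return `read_gradient_table()` returns a `gradient_scheme`;
#'   `write_gradient_table()` returns the scheme invisibly.
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_lines <- readLines(bvec_path)
  if (length(bvals) == 0L && !any(nzchar(trimws(bvec_lines)))) {
    return(gradient_scheme(numeric(0), matrix(0, 0, 3), integer(0)))
  }
  bvec_lines <- bvec_lines[nzchar(trimws(bvec_lines))]
  if (length(bvec_lines) != 3L) {
    stop("bvec file must contain exactly 3 rows (x, y, z components)", call. = FALSE)
  }
  rows <- lapply(bvec_lines, function(l) scan(text = l, quiet = TRUE))
  if (any(lengths(rows) != length(bvals))) {
    stop("bval and bvec files disagree on the number of volumes", call. = FALSE)
  }
  dirs <- t(do.call(rbind, rows))
  if (length(bvals) == 0L) {
    return(gradient_scheme(numeric(0), matrix(0, 0, 3), integer(0)))
  }
  nrm <- sqrt(rowSums(dirs^2))
  weighted <- bvals > 0
  if (any(weighted & nrm == 0)) {
    stop("diffusion-weighted volume has a zero gradient vector", call. = FALSE)
  }
  dirs[weighted, ] <- dirs[weighted, , drop = FALSE] / nrm[weighted]
  dirs[!weighted, ] <- 0
  ub <- sort(unique(bvals[weighted]))
  ids <- ifelse(weighted, match(bvals, ub), 0L)
  ids[is.na(ids)] <- 0L
  gradient_scheme(bvals, dirs, ids)
}

#' @rdname read_gradient_table
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  dirs <- scheme_directions(scheme)
  fmt <- function(x) paste(formatC(x, digits = 6, format = "g"), collapse = " ")
  writeLines(fmt(scheme$bval), bval_path)
  writeLines(c(fmt(dirs[, 1]), fmt(dirs[, 2]), fmt(dirs[, 3])), bvec_path)
  invisible(scheme)
}

#' Plot a gradient scheme
#'
#' Azimuthal projection of the weighted directions (upper hemisphere after
#' antipodal folding), colored by shell.
#'
#' @param object a [gradient_scheme()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gradient_scheme
#' @export
autoplot.gradient_scheme <- function(object, ...) {
  df <- dplyr::filter(object, .data$bval > 0)
  flip <- df$gz < 0
  df[flip, c("gx", "gy", "gz")] <- -df[flip, c("gx", "gy", "gz")]
  ggplot2::ggplot(df, ggplot2::aes(.data$gx, .data$gy,
                                   colour = factor(.data$bval))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "gx", y = "gy", colour = "b (s/mm²)",
                  title = "Gradient directions (upper hemisphere)") +
    ggplot2::theme_minimal()
}
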