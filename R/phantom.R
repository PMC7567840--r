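#' Parametric cervical-cord tissue masks
#'
#' Builds an aligned, segmented axial label volume emulating a C3-C6
#' spinal-cord slab: per slice an elliptical cord cross-section whose gray
#' matter forms the characteristic butterfly (two dorsal and two ventral
#' horn lobes joined by a central commissure band), surrounded by
#' signal-free air. Labels are 0 = background, 1 = GM, 2 = WM. The cord is
#' placed in the low-index half of in-plane axis 2 so the opposite
#' ("superior") half of the field of view is pure air for noise
#' estimation.
#'
#' @param grid_shape integer triple, voxels per axis; axis 3 is
#'   superior-inferior (the slice axis).
#' @param voxel_size numeric triple, mm.
#' @param geometry shape parameters as produced by [cord_geometry()].
#' @param seed unused at present (geometry is deterministic); kept so mask
#'   construction shares the calling convention of the other generators.
#' @return A `tissue_masks` object: list with `labels` (integer 3-D
#'   array), `voxel_size`, `slice_axis` and the `geometry` used.
#' @examples
#' m <- build_cord_masks(c(48, 48, 8))
#' table(m$labels)
#' @export
build_cord_masks <- function(grid_shape = c(48, 48, 12),
                             voxel_size = c(0.65, 0.65, 3),
                             geometry = cord_geometry(),
                             seed = 1) {
  grid_shape <- as.integer(grid_shape)
  cx <- grid_shape[1] / 2 + 0.5
  cy <- grid_shape[2] * geometry$center_frac_y + 0.5
  if (cx + geometry$cord_rx > grid_shape[1] || cy + geometry$cord_ry > grid_shape[2] ||
      geometry$cord_rx >= cx || geometry$cord_ry >= cy) {
    stop("cord geometry does not fit inside the grid", call. = FALSE)
  }
  u <- outer(seq_len(grid_shape[1]) - cx, rep(1, grid_shape[2]))  # lateral
  v <- outer(rep(1, grid_shape[1]), seq_len(grid_shape[2]) - cy)  # antero-posterior
  in_ellipse <- function(u0, v0, ru, rv) {
    if (ru <= 0 || rv <= 0) return(matrix(FALSE, nrow(u), ncol(u)))
    ((u - u0) / ru)^2 + ((v - v0) / rv)^2 <= 1
  }
  cord <- in_ellipse(0, 0, geometry$cord_rx, geometry$cord_ry)
  g <- geometry
  gm <- in_ellipse(-g$horn_dx, g$dorsal_dy, g$dorsal_ru, g$dorsal_rv) |
    in_ellipse(g$horn_dx, g$dorsal_dy, g$dorsal_ru, g$dorsal_rv) |
    in_ellipse(-g$horn_dx, -g$ventral_dy, g$ventral_ru, g$ventral_rv) |
    in_ellipse(g$horn_dx, -g$ventral_dy, g$ventral_ru, g$ventral_rv)
  if (g$band_halfwidth > 0 && g$band_halflength > 0) {
    gm <- gm | (abs(v) <= g$band_halfwidth & abs(u) <= g$band_halflength)
  }
  gm <- gm & cord
  slice <- matrix(0L, grid_shape[1], grid_shape[2])
  slice[cord] <- 2L
  slice[gm] <- 1L
  labels <- array(slice, dim = grid_shape)
  structure(
    list(labels = labels, voxel_size = voxel_size, slice_axis = 3L,
         geometry = c(geometry, list(center = c(cx, cy)))),
    class = "tissue_masks"
  )
}

#' @rdname build_cord_masks
#' @param cord_rx,cord_ry cord ellipse semi-axes, voxels (lateral, AP).
#' @param horn_dx lateral offset of all four horn lobes, voxels.
#' @param dorsal_dy,dorsal_ru,dorsal_rv dorsal-horn offset and semi-axes.
#' @param ventral_dy,ventral_ru,ventral_rv ventral-horn offset and semi-axes.
#' @param band_halfwidth,band_halflength central commissure band half-sizes.
#' @param center_frac_y cord center position along in-plane axis 2
#'   (fraction of the field of view; < 0.5 keeps the superior half air).
#' @export
cord_geometry <- function(cord_rx = 10, cord_ry = 8, horn_dx = 3.8,
                          dorsal_dy = 3.0, dorsal_ru = 1.8, dorsal_rv = 2.8,
                          ventral_dy = 2.8, ventral_ru = 2.0, ventral_rv = 2.2,
                          band_halfwidth = 1.0, band_halflength = 3.5,
                          center_frac_y = 0.32) {
  as.list(environment())
}

#' @export
print.tissue_masks <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<tissue_masks> %d x %d x %d grid, voxel %s mm\n",
              d[1], d[2], d[3], paste(x$voxel_size, collapse = " x ")))
  cat(sprintf("  cord voxels: %d (GM %d, WM %d)\n",
              sum(x$labels > 0), sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' Cohort simulation configuration
#'
#' Bundles every knob of the synthetic cohort: group sizes and
#' demographics, baseline tissue microstructure, per-group effect-size
#' multipliers, noise level and grid geometry. Defaults reproduce the
#' study conditions: 7 young controls scanned twice, 13 age-comparable
#' controls, 18 mild and 15 severe compression patients; 13 of the 33
#' patients carry a radiculopathy flag; two-shell 21 + 42 direction
#' acquisition with 7 b0 volumes at b = 550/1000 s/mm^2.
#'
#' Baselines (control tissue): WM diffusivity 1.5 and GM 1.0 (1e-3
#' mm^2/s), WM f1 0.65, GM f1 0.35, S0 = 100 signal units; the Rician
#' channel noise `sigma` = 12 puts the b = 550 shell SNR near 5.5 (and the b = 1000
#' shell near 4). Patient
#' groups shrink the WM-GM diffusivity gap via `gap_multiplier` (mild
#' 0.75, severe 0.55, applied with GM held fixed), scale WM f1 via
#' `f1_multiplier`, inflate WM voxel-wise dispersion via
#' `dispersion_multiplier`, and scale crossing prevalence via
#' `crossing_multiplier`.
#'
#' @param group_sizes named integer vector over the four groups.
#' @param age_mean,age_sd per-group age distributions, years.
#' @param n_female per-group female counts.
#' @param baseline list: `wm_d`, `gm_d` (1e-3 mm^2/s), `wm_f1`, `gm_f1`, `S0`.
#' @param gap_multiplier,f1_multiplier,dispersion_multiplier,crossing_multiplier
#'   per-group effect multipliers (order of `group_sizes`).
#' @param crossing_prevalence target fraction of cord voxels with a
#'   significant second stick (f2 > 0.05) in controls.
#' @param voxel_jitter list of voxel-wise ground-truth SDs: `d`, `f1`.
#' @param subject_sd between-subject fractional SD of the shared
#'   (cord-level) diffusivity scale; shared variation cancels in WM-GM
#'   difference markers, which is what makes the gradient robust.
#' @param tissue_sd additional tissue-specific (WM vs GM independent)
#'   fractional scale SD; this is what survives in the gradient markers.
#' @param sigma Rician channel noise SD, signal units.
#' @param n_radiculopathy number of patients flagged with radiculopathy.
#' @param grid_shape,voxel_size,geometry phantom grid, see [build_cord_masks()].
#' @param shell_counts,shell_bvalues,n_b0 acquisition scheme specification.
#' @param seed master seed; all per-subject streams derive from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    group_sizes = c(young_control = 7, age_control = 13,
                    mild_patient = 18, severe_patient = 15),
    age_mean = c(young_control = 27.4, age_control = 51.9,
                 mild_patient = 55.6, severe_patient = 58.1),
    age_sd = c(young_control = 1.7, age_control = 9.4,
               mild_patient = 6.1, severe_patient = 6.8),
    n_female = c(young_control = 3, age_control = 9,
                 mild_patient = 7, severe_patient = 7),
    baseline = list(wm_d = 1.5, gm_d = 1.0, wm_f1 = 0.65, gm_f1 = 0.35, S0 = 100),
    gap_multiplier = c(1, 1, 0.75, 0.55),
    f1_multiplier = c(1, 1, 0.95, 0.90),
    dispersion_multiplier = c(1, 1, 1.2, 1.4),
    crossing_multiplier = c(1, 1, 1, 1),
    crossing_prevalence = 0.10,
    voxel_jitter = list(d = 0.08, f1 = 0.05),
    subject_sd = 0.05,
    tissue_sd = 0.02,
    sigma = 12,
    n_radiculopathy = 13,
    grid_shape = c(48, 48, 12),
    voxel_size = c(0.65, 0.65, 3),
    geometry = cord_geometry(),
    shell_counts = c(21, 42),
    shell_bvalues = c(550, 1000),
    n_b0 = 7,
    seed = 1) {
  if (any(group_sizes < 0)) stop("group sizes must be non-negative", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  groups <- names(group_sizes)
  for (nm in c("gap_multiplier", "f1_multiplier", "dispersion_multiplier",
               "crossing_multiplier")) {
    v <- get(nm)
    if (is.null(names(v))) names(v) <- groups
    assign(nm, v)
  }
  structure(as.list(environment()), class = "cohort_config")
}

group_levels <- function() {
  c("young_control", "age_control", "mild_patient", "severe_patient")
}

#' Assign ground-truth microstructure to a masked grid
#'
#' Fills a tissue-labelled grid with three-compartment ground truth: an
#' isotropic ball of diffusivity `d`, a primary stick `v1` along the
#' superior-inferior axis with partial volume `f1`, and, in
#' dorsal-horn-adjacent and anterior-commissure voxels, a transverse
#' secondary stick `v2` with `f2 > 0.05` (crossing fibers). Control WM has
#' higher `f1` and higher `d` than GM; patient groups apply the configured
#' effect multipliers, shrinking the WM-GM diffusivity gap with severity.
#' Voxel values are jittered with a seeded stream, so the field is
#' reproducible and, with all multipliers at 1, identical across groups
#' for the same seed.
#'
#' @param masks a `tissue_masks` object.
#' @param group one of `"young_control"`, `"age_control"`,
#'   `"mild_patient"`, `"severe_patient"`.
#' @param config a [cohort_config()].
#' @param seed integer seed of the voxel jitter stream.
#' @param subject_scale optional named multipliers (`wm_d`, `gm_d`, `f1`)
#'   expressing between-subject variation; default all 1.
#' @return A `microstructure_field`: list of arrays `S0`, `d`, `f1`, `f2`
#'   (grid-shaped) and `v1`, `v2` (grid x 3).
#' @export
assign_microstructure <- function(masks, group, config = cohort_config(),
                                  seed = 1,
                                  subject_scale = c(wm_d = 1, gm_d = 1, f1 = 1)) {
  if (!group %in% names(config$group_sizes)) {
    stop("unknown group label: ", group, call. = FALSE)
  }
  lab <- masks$labels
  dims <- dim(lab)
  wm <- lab == 2L
  gm <- lab == 1L
  cord <- wm | gm
  n_cord <- sum(cord)

  set.seed(as.integer(seed))
  jit_d <- array(stats::rnorm(length(lab), 0, config$voxel_jitter$d), dims)
  jit_f <- array(stats::rnorm(length(lab), 0, config$voxel_jitter$f1), dims)
  # crossing placement and in-plane stick angles drawn before effects are
  # applied, so multiplier-one groups are bit-identical to controls
  cross_order <- sample.int(max(n_cord, 1L))
  phi <- stats::runif(length(lab), 0, pi)

  b <- config$baseline
  gap <- config$gap_multiplier[[group]]
  f1m <- config$f1_multiplier[[group]]
  disp <- config$dispersion_multiplier[[group]]
  crossm <- config$crossing_multiplier[[group]]

  wm_d <- (b$gm_d + gap * (b$wm_d - b$gm_d)) * subject_scale[["wm_d"]]
  gm_d <- b$gm_d * subject_scale[["gm_d"]]
  wm_f1 <- b$wm_f1 * f1m * subject_scale[["f1"]]
  gm_f1 <- b$gm_f1 * subject_scale[["f1"]]

  d <- array(0, dims)
  d[wm] <- wm_d + disp * jit_d[wm]
  d[gm] <- gm_d + jit_d[gm]
  d[cord] <- pmax(d[cord], 0.05)

  f1 <- array(0, dims)
  f1[wm] <- wm_f1 + disp * jit_f[wm]
  f1[gm] <- gm_f1 + jit_f[gm]
  f1[cord] <- pmin(pmax(f1[cord], 0.02), 0.95)

  # crossing zone: WM voxels adjacent to dorsal-horn or commissure GM
  f2 <- array(0, dims)
  zone <- crossing_zone(masks)
  n_target <- round(config$crossing_prevalence * crossm * n_cord)
  zone_idx <- which(zone)
  if (n_target > 0 && length(zone_idx) > 0) {
    ord <- cross_order[cross_order <= n_cord]
    cord_idx <- which(cord)
    ranked <- cord_idx[ord]                 # seeded permutation of cord voxels
    chosen <- ranked[ranked %in% zone_idx][seq_len(min(n_target, length(zone_idx)))]
    f2[chosen] <- stats::runif(length(chosen), 0.12, 0.28)
  }
  # keep f1 + f2 <= 1 and f1 >= f2
  over <- f1 + f2 > 0.95
  f1[over] <- 0.95 - f2[over]

  v1 <- array(0, c(dims, 3))
  v1_z <- array(0, dims); v1_z[cord] <- 1
  v1[, , , 3] <- v1_z
  v2 <- array(0, c(dims, 3))
  has2 <- f2 > 0
  cx <- array(0, dims); cy <- array(0, dims)
  cx[has2] <- cos(phi[has2]); cy[has2] <- sin(phi[has2])
  v2[, , , 1] <- cx
  v2[, , , 2] <- cy

  S0 <- array(0, dims)
  S0[cord] <- b$S0
  structure(list(S0 = S0, d = d, f1 = f1, f2 = f2, v1 = v1, v2 = v2,
                 masks = masks, group = group),
            class = "microstructure_field")
}

# WM voxels within one voxel (in-plane 8-neighborhood) of dorsal-horn GM
# (posterior to cord center) or of the central commissure band.
crossing_zone <- function(masks) {
  lab <- masks$labels
  dims <- dim(lab)
  cy <- masks$geometry$center[2]
  v <- array(rep(rep(seq_len(dims[2]) - cy, each = dims[1]), dims[3]), dims)
  seedgm <- (lab == 1L) & (v > 1 | abs(v) <= masks$geometry$band_halfwidth)
  grown <- seedgm
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    grown <- grown | shift_xy(seedgm, dx, dy)
  }
  grown & lab == 2L
}

shift_xy <- function(a, dx, dy) {
  d <- dim(a)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy
  ok_x <- xs >= 1 & xs <= d[1]; ok_y <- ys >= 1 & ys <= d[2]
  out[which(ok_x), which(ok_y), ] <- a[xs[ok_x], ys[ok_y], , drop = FALSE]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noiseless three-compartment forward signal
#'
#' Evaluates the ball-and-stick-and-stick signal model for every voxel and
#' scheme volume:
#' `S = S0 * ((1 - f1 - f2) exp(-b d) + f1 exp(-b d (g.v1)^2) + f2 exp(-b d (g.v2)^2))`
#' with b in s/mm^2 and d stored in 1e-3 mm^2/s. At b = 0 the signal
#' equals S0 exactly.
#'
#' @param micro a `microstructure_field`.
#' @param scheme a [gradient_scheme()].
#' @return 4-D array, grid x volumes.
#' @export
forward_signal <- function(micro, scheme) {
  dims <- dim(micro$S0)
  n <- nrow(scheme)
  dirs <- scheme_directions(scheme)
  out <- array(0, c(dims, n))
  bd <- micro$d * 1e-3
  f0 <- 1 - micro$f1 - micro$f2
  g1x <- micro$v1[, , , 1]; g1y <- micro$v1[, , , 2]; g1z <- micro$v1[, , , 3]
  g2x <- micro$v2[, , , 1]; g2y <- micro$v2[, , , 2]; g2z <- micro$v2[, , , 3]
  for (k in seq_len(n)) {
    b <- scheme$bval[k]
    if (b == 0) {
      out[, , , k] <- micro$S0
      next
    }
    g <- dirs[k, ]
    c1 <- (g[1] * g1x + g[2] * g1y + g[3] * g1z)^2
    c2 <- (g[1] * g2x + g[2] * g2y + g[3] * g2z)^2
    out[, , , k] <- micro$S0 *
      (f0 * exp(-b * bd) + micro$f1 * exp(-b * bd * c1) +
         micro$f2 * exp(-b * bd * c2))
  }
  out
}

#' Add Rician noise to a magnitude volume
#'
#' Replaces every value S by `|(S + n1) + i n2|` with independent
#' zero-mean Gaussian `n1`, `n2` of standard deviation `sigma`: the
#' magnitude-MRI noise model under which pure-noise background follows a
#' Rayleigh distribution.
#'
#' @param volume numeric array of any shape.
#' @param sigma channel noise SD, signal units.
#' @param seed integer seed.
#' @return noisy array, same shape, non-negative.
#' @export
add_rician_noise <- function(volume, sigma, seed = 1) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(volume)
  set.seed(as.integer(seed))
  n <- length(volume)
  re <- volume + stats::rnorm(n, 0, sigma)
  im <- stats::rnorm(n, 0, sigma)
  array(sqrt(re^2 + im^2), dim = dim(volume) %||% n)
}

#' Simulate a synthetic spinal-cord DWI cohort
#'
#' Generates the full study cohort from a [cohort_config()]: per subject a
#' tissue-labelled grid, a ground-truth microstructure field with the
#' group's effect sizes and a subject-specific scale jitter, the shared
#' two-shell gradient scheme, demographics (age, sex, radiculopathy flag)
#' and seeds for the noise streams. Young controls receive two sessions
#' that share their ground truth and differ only in the noise stream. DWI
#' volumes are not stored: [subject_dwi()] regenerates them on demand,
#' bit-reproducibly, from the recorded seeds.
#'
#' @param config a [cohort_config()].
#' @return A `dwi_cohort`: list of subject records with a `covariates`
#'   attribute (tibble: subject_id, group, age, sex, radiculopathy,
#'   session).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  set.seed(as.integer(config$seed))
  masks <- build_cord_masks(config$grid_shape, config$voxel_size, config$geometry)
  scheme <- generate_multishell_scheme(config$shell_counts, config$shell_bvalues,
                                       config$n_b0, seed = config$seed)
  groups <- rep(names(config$group_sizes), config$group_sizes)
  n_sub <- length(groups)
  ages <- stats::rnorm(n_sub, config$age_mean[groups], config$age_sd[groups])
  sexes <- character(n_sub)
  for (g in names(config$group_sizes)) {
    idx <- which(groups == g)
    s <- rep("M", length(idx))
    s[seq_len(min(config$n_female[[g]], length(idx)))] <- "F"
    sexes[idx] <- sample(s)
  }
  patients <- which(groups %in% c("mild_patient", "severe_patient"))
  radic <- logical(n_sub)
  radic[sample(patients, min(config$n_radiculopathy, length(patients)))] <- TRUE
  micro_seeds <- sample.int(2^31 - 2, n_sub)
  noise_seeds <- matrix(sample.int(2^31 - 2, 2 * n_sub), n_sub, 2)
  shared <- stats::rnorm(n_sub, 1, config$subject_sd)
  tissue <- matrix(stats::rnorm(2 * n_sub, 1, config$tissue_sd %||% 0.02), n_sub, 2)
  f1_jit <- stats::rnorm(n_sub, 1, config$subject_sd)

  records <- list()
  for (i in seq_len(n_sub)) {
    scale <- c(wm_d = shared[i] * tissue[i, 1], gm_d = shared[i] * tissue[i, 2],
               f1 = f1_jit[i])
    truth <- assign_microstructure(masks, groups[i], config,
                                   seed = micro_seeds[i], subject_scale = scale)
    n_sessions <- if (groups[i] == "young_control") 2L else 1L
    for (s in seq_len(n_sessions)) {
      records[[length(records) + 1L]] <- structure(
        list(subject_id = sprintf("S%02d", i), group = groups[i],
             age = ages[i], sex = sexes[i], radiculopathy = radic[i],
             session = s, masks = masks, scheme = scheme,
             ground_truth = truth, sigma = config$sigma,
             noise_seed = noise_seeds[i, s], map_seed = noise_seeds[i, s] %% 1e6 + 7L),
        class = "subject_record")
    }
  }
  cov <- purrr::map_dfr(records, function(r) {
    tibble::tibble(subject_id = r$subject_id, group = r$group, age = r$age,
                   sex = r$sex, radiculopathy = r$radiculopathy,
                   session = r$session)
  })
  structure(records, covariates = cov, config = config, class = "dwi_cohort")
}

#' @export
print.dwi_cohort <- function(x, ...) {
  cov <- attr(x, "covariates")
  cat(sprintf("<dwi_cohort> %d records, %d subjects\n",
              nrow(cov), length(unique(cov$subject_id))))
  print(dplyr::count(dplyr::distinct(cov, .data$subject_id, .data$group),
                     .data$group))
  invisible(x)
}

#' Cohort covariate table
#'
#' @param cohort a `dwi_cohort`.
#' @return tibble of per-record covariates.
#' @export
cohort_covariates <- function(cohort) attr(cohort, "covariates")

#' Regenerate a subject's noisy DWI volume
#'
#' Evaluates the forward model on the subject's ground truth and applies
#' Rician noise from the subject-session seed recorded at cohort
#' simulation; repeated calls return bit-identical volumes.
#'
#' @param subject a `subject_record`.
#' @return 4-D array, grid x volumes.
#' @export
subject_dwi <- function(subject) {
  add_rician_noise(forward_signal(subject$ground_truth, subject$scheme),
                   subject$sigma, seed = subject$noise_seed)
}

#' Ground-truth metric maps of a microstructure field
#'
#' Converts the three-compartment ground truth into the four analysis
#' metrics. `f1` and `d` are taken directly from the field. `MD` and `FA`
#' are those of the equivalent diffusion tensor
#' `D = d ((1 - f1 - f2) I + f1 v1 v1' + f2 v2 v2')`, computed in closed
#' form from tensor invariants (no per-voxel eigendecomposition).
#'
#' @param micro a `microstructure_field`.
#' @param masks tissue masks (defaults to those carried by the field).
#' @return named list of four [metric_map()] objects: FA, f1, MD, d.
#' @export
truth_metric_maps <- function(micro, masks = micro$masks) {
  f <- micro$f1 + micro$f2
  d <- micro$d
  md <- d * (1 - 2 * f / 3)
  c12 <- (micro$v1[, , , 1] * micro$v2[, , , 1] +
            micro$v1[, , , 2] * micro$v2[, , , 2] +
            micro$v1[, , , 3] * micro$v2[, , , 3])^2
  fro2 <- d^2 * (3 * (1 - f)^2 + 2 * (1 - f) * f +
                   micro$f1^2 + micro$f2^2 + 2 * micro$f1 * micro$f2 * c12)
  fa <- array(0, dim(d))
  pos <- fro2 > 0
  fa[pos] <- sqrt(pmax(1.5 * (fro2[pos] - 3 * md[pos]^2) / fro2[pos], 0))
  list(
    FA = metric_map("FA", fa, masks),
    f1 = metric_map("f1", micro$f1, masks),
    MD = metric_map("MD", md, masks),
    d  = metric_map("d", d, masks)
  )
}

#' Observed (noise-perturbed) metric maps
#'
#' Emulates voxel-wise estimation error on top of the ground-truth metric
#' maps: seeded iid Gaussian perturbations inside the cord, with per-metric
#' standard deviations chosen to reflect fit uncertainty at the phantom's
#' SNR. This gives the statistical cascade realistic per-subject maps
#' without re-fitting every voxel; model-fit accuracy itself is validated
#' separately against the forward model.
#'
#' @param subject a `subject_record`.
#' @param map_noise named per-metric SDs (FA/f1 unitless, MD/d 1e-3 mm^2/s).
#' @param seed seed; defaults to the subject-session map seed.
#' @return named list of four [metric_map()] objects.
#' @export
observed_metric_maps <- function(subject,
                                 map_noise = c(FA = 0.05, f1 = 0.05,
                                               MD = 0.08, d = 0.10),
                                 seed = subject$map_seed) {
  maps <- truth_metric_maps(subject$ground_truth, subject$masks)
  cord <- subject$masks$labels > 0L
  set.seed(as.integer(seed))
  for (m in names(maps)) {
    v <- maps[[m]]$values
    v[cord] <- v[cord] + stats::rnorm(sum(cord), 0, map_noise[[m]])
    if (m %in% c("FA", "f1")) v[cord] <- pmin(pmax(v[cord], 0), 1)
    else v[cord] <- pmax(v[cord], 1e-4)
    maps[[m]]$values <- v
  }
  maps
}
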