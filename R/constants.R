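#' Analysis constants
#'
#' Fixed constants of the analysis: the family-wise error threshold for the
#' six pairwise group comparisons, the crossing-fiber detection threshold on
#' the second stick's partial volume, the Rayleigh-to-Gaussian noise
#' correction used in the SNR estimator, and the metric intervals of the
#' heuristic density-mass parameters.
#'
#' @details
#' * `fwe_alpha()` is the Bonferroni-corrected per-comparison significance
#'   level 0.05/6 used for all pairwise group tests (four groups give six
#'   pairs).
#' * `crossing_threshold()` is the partial-volume cut `f2 > 0.05` above
#'   which a voxel is declared to hold crossing fibers.
#' * `rayleigh_correction()` is `sqrt(2 / (4 - pi))`: multiplying the
#'   standard deviation of background (pure-noise) magnitude values by this
#'   factor recovers the Gaussian noise standard deviation of the complex
#'   signal channels.
#' * `heuristic_intervals()` returns the fixed integration intervals of the
#'   heuristic parameters, one per metric/tissue combination. Diffusivity
#'   bounds are in 1e-3 mm^2/s.
#'
#' @return Scalars, or for `heuristic_intervals()` a named list of
#'   length-two numeric vectors (`FA_WM`, `f1_WM`, `MD_WM`, `MD_GM`,
#'   `d_WM`, `d_GM`).
#' @examples
#' fwe_alpha()
#' heuristic_intervals()$d_WM
#' @name constants
NULL

#' @rdname constants
#' @export
fwe_alpha <- function() 0.05 / 6

#' @rdname constants
#' @export
crossing_threshold <- function() 0.05

#' @rdname constants
#' @export
rayleigh_correction <- function() sqrt(2 / (4 - pi))

#' @rdname constants
#' @export
heuristic_intervals <- function() {
  list(
    FA_WM = c(0.47, 0.67),
    f1_WM = c(0.30, 0.55),
    MD_WM = c(0.84, 1.26),
    MD_GM = c(0.84, 1.26),
    d_WM  = c(1.70, 2.20),
    d_GM  = c(1.00, 1.48)
  )
}
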