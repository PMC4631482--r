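# Tabulated average-protein Wilson intensity curve, relative units, max = 1.
# Knots in h = 1/d (1/Angstrom). The shape carries the canonical features of
# mean protein diffraction: a strong low-resolution maximum, the dip near
# d ~ 5.5 A where solvent and macromolecular terms cancel, the secondary
# maximum near d ~ 4.5 A from backbone/side-chain repeat distances, then a
# smooth monotone fall-off. Interpolation is piecewise linear in h^2.
.wilson_knots_h <- c(
  0.00, 0.04, 0.08, 0.12, 0.155, 0.180, 0.205, 0.230, 0.260,
  0.30, 0.35, 0.40, 0.45, 0.50, 0.60, 0.70, 0.80, 0.90,
  1.00, 1.20, 1.50
)
.wilson_knots_i <- c(
  1.000, 0.700, 0.380, 0.190, 0.125, 0.118, 0.160, 0.210, 0.200,
  0.165, 0.130, 0.105, 0.088, 0.074, 0.052, 0.037, 0.026, 0.018,
  0.0125, 0.0062, 0.0022
)

#' Standard protein Wilson curve
#'
#' The package's tabulation of the resolution dependence of mean diffracted
#' intensity for an "average" protein crystal, `Sigma_p(h)`, in relative units
#' with maximum 1 at `h = 0`. The curve is interpolated piecewise-linearly in
#' `h^2` between fixed knots; inputs outside the tabulated range
#' `[0, 1.5] / Angstrom` are clamped to the end values. Used both by the frame
#' simulator (spot intensities follow `Sigma_p(h) * exp(-2 B s^2)`) and by the
#' Wilson-model fit in the scoring stage.
#'
#' @param h Diffraction-vector length `1/d` in 1/Angstrom; vectorized.
#' @return Relative intensity, strictly positive.
#' @examples
#' standard_wilson_curve(c(0, 0.25, 0.5))
#' @export
standard_wilson_curve <- function(h) {
  h <- pmin(pmax(h, 0), max(.wilson_knots_h))
  stats::approx(.wilson_knots_h^2, .wilson_knots_i, xout = h^2,
                method = "linear", rule = 2)$y
}

# expose knots for tests / documentation
wilson_curve_knots <- function() {
  tibble::tibble(h = .wilson_knots_h, intensity = .wilson_knots_i)
}
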