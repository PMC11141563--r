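#' Interpolation coefficients of one subslab
#'
#' Within a subslab of length `Ln`, the shape ratios and the identity segment
#' are taken to vary linearly between its two bases. This packs the slopes
#' `alpha` (phi per length), `beta` (d, dimensionless) and `gamma` (psi per
#' length) together with the base values at the anterior face, from which the
#' section area and circumference at any interior offset follow in closed form.
#'
#' @param phi_prev,phi_k Area shape ratio at the anterior / posterior base.
#' @param psi_prev,psi_k Perimeter shape ratio at the anterior / posterior base.
#' @param d_prev,d_k Identity segment at the anterior / posterior base.
#' @param Ln Subslab length (> 0).
#' @return An object of class `subslab_coefficients` with fields
#'   `alpha`, `beta`, `gamma`, `base_d`, `base_phi`, `base_psi`, `Ln`.
#' @export
subslab_coefficients <- function(phi_prev, phi_k, psi_prev, psi_k,
                                 d_prev, d_k, Ln) {
  stopifnot(Ln > 0)
  x <- list(alpha = (phi_k - phi_prev) / Ln,
            beta  = (d_k - d_prev) / Ln,
            gamma = (psi_k - psi_prev) / Ln,
            base_d = d_prev, base_phi = phi_prev, base_psi = psi_prev,
            Ln = Ln)
  class(x) <- "subslab_coefficients"
  x
}

#' Section area at an offset inside a subslab
#'
#' Evaluates `S(l) = (alpha l + phi0) (beta l + d0)^2`, the cubic in `l`
#' obtained from linear interpolation of the shape ratio and the identity
#' segment.
#'
#' @param l Offset from the subslab's anterior base, `0 <= l <= Ln`.
#'   Vectorised.
#' @param coeff A [subslab_coefficients()] object.
#' @return Section area at `l`.
#' @export
section_area_at <- function(l, coeff) {
  if (any(l < 0) || any(l > coeff$Ln * (1 + 1e-12)))
    stop("offset l outside subslab [0, Ln]")
  (coeff$alpha * l + coeff$base_phi) * (coeff$beta * l + coeff$base_d)^2
}

#' Section circumference at an offset inside a subslab
#'
#' Evaluates `C(l) = (gamma l + psi0) (beta l + d0)`, the quadratic in `l`
#' from linear interpolation of the perimeter ratio and the identity segment.
#'
#' @inheritParams section_area_at
#' @return Section circumference at `l`.
#' @export
section_circumference_at <- function(l, coeff) {
  if (any(l < 0) || any(l > coeff$Ln * (1 + 1e-12)))
    stop("offset l outside subslab [0, Ln]")
  (coeff$gamma * l + coeff$base_psi) * (coeff$beta * l + coeff$base_d)
}

#' Subslab volume in closed form
#'
#' The exact antiderivative of the cubic section-area function over the
#' subslab: with `a = alpha`, `b = beta`, `d = d0`, `p = phi0`,
#' `V = a b^2 Ln^4 / 4 + (2 a b d + p b^2) Ln^3 / 3 +
#'  (a d^2 + 2 b d p) Ln^2 / 2 + p d^2 Ln`.
#' Evaluated in Horner form to limit cancellation.
#'
#' @param coeff A [subslab_coefficients()] object.
#' @return Subslab volume.
#' @export
subslab_volume <- function(coeff) {
  a <- coeff$alpha; b <- coeff$beta; d <- coeff$base_d; p <- coeff$base_phi
  Ln <- coeff$Ln
  ((((a * b^2 / 4) * Ln + (2 * a * b * d + p * b^2) / 3) * Ln +
      (a * d^2 + 2 * b * d * p) / 2) * Ln + p * d^2) * Ln
}

#' Subslab volume with a constant area shape ratio
#'
#' Cone-mode shortcut: when `phi` is held constant at the measured base's
#' value `Phi` (so `alpha = 0`), the volume reduces to
#' `Phi b^2 Ln^3 / 3 + b d Phi Ln^2 + Phi d^2 Ln`. Identical to
#' [subslab_volume()] with `alpha = 0`; kept as the explicit constant-ratio
#' path used for terminal cone slabs.
#'
#' @param Phi Constant area shape ratio.
#' @param coeff A [subslab_coefficients()] object (its `alpha` is ignored).
#' @return Subslab volume.
#' @export
subslab_volume_constant_phi <- function(Phi, coeff) {
  b <- coeff$beta; d <- coeff$base_d; Ln <- coeff$Ln
  (((Phi * b^2 / 3) * Ln + b * d * Phi) * Ln + Phi * d^2) * Ln
}

#' Subslab lateral surface area in closed form
#'
#' The exact antiderivative of the quadratic circumference function:
#' `A = g b Ln^3 / 3 + (g d + b s) Ln^2 / 2 + s d Ln` with `g = gamma`,
#' `b = beta`, `d = d0`, `s = psi0`. Note this is the method's definition of
#' lateral area — circumference integrated along the axis — which understates
#' true slant area on tapering solids.
#'
#' @param coeff A [subslab_coefficients()] object.
#' @return Subslab lateral area (axial circumference integral).
#' @export
subslab_lateral_area <- function(coeff) {
  g <- coeff$gamma; b <- coeff$beta; d <- coeff$base_d; s <- coeff$base_psi
  Ln <- coeff$Ln
  (((g * b / 3) * Ln + (g * d + b * s) / 2) * Ln + s * d) * Ln
}

#' Subslab lateral area with a constant perimeter shape ratio
#'
#' Cone-mode shortcut with `psi` fixed at `Psi` (`gamma = 0`):
#' `A = b Psi Ln^2 / 2 + Psi d Ln`.
#'
#' @param Psi Constant perimeter shape ratio.
#' @param coeff A [subslab_coefficients()] object (its `gamma` is ignored).
#' @return Subslab lateral area.
#' @export
subslab_lateral_area_constant_psi <- function(Psi, coeff) {
  b <- coeff$beta; d <- coeff$base_d; Ln <- coeff$Ln
  ((b * Psi / 2) * Ln + Psi * d) * Ln
}

#' Axial centroid of a subslab
#'
#' Position of the centroid plane measured from the subslab's anterior base:
#' `lbar = integral(S(l) l dl) / integral(S(l) dl)` over `[0, Ln]`. The
#' numerator is the exact quintic antiderivative of `l S(l)`:
#' `a b^2 Ln^5 / 5 + (2 a b d + p b^2) Ln^4 / 4 +
#'  (a d^2 + 2 b d p) Ln^3 / 3 + p d^2 Ln^2 / 2`.
#'
#' @param coeff A [subslab_coefficients()] object.
#' @return Centroid offset in `[0, Ln]`.
#' @export
subslab_centroid <- function(coeff) {
  V <- subslab_volume(coeff)
  if (V <= 0) stop("undefined centroid: subslab volume is not positive")
  subslab_first_moment(coeff) / V
}

# First moment of area about the anterior base, integral of l * S(l) over
# [0, Ln]; shared by subslab_centroid and the centre-of-mass machinery.
subslab_first_moment <- function(coeff) {
  a <- coeff$alpha; b <- coeff$beta; d <- coeff$base_d; p <- coeff$base_phi
  Ln <- coeff$Ln
  ((((a * b^2 / 5) * Ln + (2 * a * b * d + p * b^2) / 4) * Ln +
      (a * d^2 + 2 * b * d * p) / 3) * Ln + p * d^2 / 2) * Ln^2
}
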