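#' Yeoh hyperelastic material for a vessel wall
#'
#' Isotropic incompressible Yeoh strain-energy density
#' `W = C10 (I1-3) + C20 (I1-3)^2 + C30 (I1-3)^3`, with `I1` the first
#' invariant of the right Cauchy-Green tensor. The graft wall is represented
#' by the same form with all coefficients multiplied by `stiffness_multiplier`
#' (2.5 reproduces a graft two and a half times less compliant than the native
#' wall, reading the compliance ratio as a coefficient scaling).
#'
#' The default coefficients are configurable stand-ins of the order measured
#' for porcine thoracic aorta; they are not taken from any specific published
#' fit and should be overridden when a calibrated set is available.
#'
#' @param C10,C20,C30 Yeoh coefficients (kPa); `C10 > 0`.
#' @param thickness wall thickness (mm).
#' @param stiffness_multiplier unitless multiplier on all coefficients.
#' @return Object of class `yeoh_material`.
#' @export
yeoh_material <- function(C10 = 30, C20 = 150, C30 = 1000, thickness = 1.5,
                          stiffness_multiplier = 1) {
  if (C10 <= 0) stop("C10 must be positive")
  if (thickness <= 0) stop("thickness must be positive")
  if (stiffness_multiplier <= 0) stop("stiffness_multiplier must be positive")
  structure(list(C10 = C10, C20 = C20, C30 = C30, thickness = thickness,
                 stiffness_multiplier = stiffness_multiplier),
            class = "yeoh_material")
}

#' Yeoh strain-energy density
#'
#' @param I1 first invariant of the right Cauchy-Green tensor (>= 3 for
#'   incompressible membrane kinematics).
#' @param mat a [yeoh_material()].
#' @return energy density (kPa), scaled by the material's stiffness multiplier.
#' @export
yeoh_energy_density <- function(I1, mat) {
  if (any(I1 < 3 - 1e-9))
    stop("I1 < 3 is not attainable for incompressible deformations")
  x <- pmax(I1 - 3, 0)
  mat$stiffness_multiplier * (mat$C10 * x + mat$C20 * x^2 + mat$C30 * x^3)
}

# dW/dI1, including the stiffness multiplier.
yeoh_dW <- function(I1, mat) {
  x <- I1 - 3
  mat$stiffness_multiplier * (mat$C10 + 2 * mat$C20 * x + 3 * mat$C30 * x^2)
}

#' Principal Cauchy stresses of an incompressible Yeoh membrane
#'
#' Plane-stress specialization: the thickness stretch is
#' `lambda3 = 1/(lambda1*lambda2)` and the in-plane principal Cauchy stresses
#' are `sigma_i = 2 (lambda_i^2 - lambda3^2) dW/dI1` at
#' `I1 = lambda1^2 + lambda2^2 + lambda3^2`.
#'
#' @param lambda1,lambda2 in-plane principal stretches (> 0).
#' @param mat a [yeoh_material()].
#' @return numeric length 2, principal Cauchy stresses (kPa).
#' @export
membrane_stress <- function(lambda1, lambda2, mat) {
  stopifnot(lambda1 > 0, lambda2 > 0)
  l3sq <- 1 / (lambda1 * lambda2)^2
  I1 <- lambda1^2 + lambda2^2 + l3sq
  dW <- yeoh_dW(I1, mat)
  c(2 * (lambda1^2 - l3sq) * dW, 2 * (lambda2^2 - l3sq) * dW)
}
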