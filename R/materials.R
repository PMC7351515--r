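# Constitutive laws: ECM anisotropic exponential energy, volume-constancy
# penalty, myofiber active + titin fiber stress, aponeurosis Mooney-Rivlin.
# All stresses are dimensionless (normalized by maximal active fiber stress);
# strains are Green-Lagrange components in the local frame
# (1 = cross-fiber, 2 = fiber, 3 = thickness).

.check_sym3 <- function(E, tol = 1e-10) {
  if (!is.matrix(E) || !all(dim(E) == c(3L, 3L)))
    stop("strain tensor must be a 3x3 matrix", call. = FALSE)
  if (max(abs(E - t(E))) > tol * max(1, max(abs(E))))
    stop("strain tensor must be symmetric", call. = FALSE)
  invisible(E)
}

# scalar (vectorized) component energy: normal branch uses the exponential
# form for all strains (non-symmetric response); shear uses the even energy
# k*(exp(a|eps|) - a|eps|) so the shear stress is an odd function.
.wij_normal <- function(eps, k, a) k * (exp(a * eps) - a * eps)
.wij_shear  <- function(eps, k, a) k * (exp(a * abs(eps)) - a * abs(eps))
.sij_normal <- function(eps, k, a) k * a * (exp(a * eps) - 1)
.sij_shear  <- function(eps, k, a) sign(eps) * k * a * (exp(a * abs(eps)) - 1)

#' Anisotropic ECM strain-energy density
#'
#' Sum over the six independent local Green-Lagrange components of the
#' exponential component energies `k (exp(a_ij eps_ij) - a_ij eps_ij)`.
#' Normal components keep this non-symmetric form for strains of either
#' sign; shear components use the even form in `|eps_ij|` so that the
#' corresponding shear stress is odd (sign-symmetric), as for physical
#' shearing of the matrix.
#'
#' Note the energy does not vanish in the reference state: each component
#' contributes the constant offset `k` at zero strain, which carries no
#' stress.
#'
#' @param E_local symmetric 3x3 local Green-Lagrange strain tensor.
#' @param p [ecm_params()].
#' @return Scalar energy density (per unit reference volume).
#' @export
#' @examples
#' ecm_energy(matrix(0, 3, 3))          # 6 k = 0.30
ecm_energy <- function(E_local, p = ecm_params()) {
  .check_sym3(E_local)
  .wij_normal(E_local[1, 1], p$k, p$a11) +
    .wij_normal(E_local[2, 2], p$k, p$a22) +
    .wij_normal(E_local[3, 3], p$k, p$a33) +
    .wij_shear(E_local[1, 2], p$k, p$a12) +
    .wij_shear(E_local[2, 3], p$k, p$a23) +
    .wij_shear(E_local[3, 1], p$k, p$a31)
}

#' Anisotropic ECM local second Piola-Kirchhoff stress
#'
#' Component `(i, j)` is the derivative of [ecm_energy()] with respect to
#' the independent strain component `eps_ij` (off-diagonal components are
#' each counted once, and the returned tensor is symmetric).  Normal
#' components are `k a_ij (exp(a_ij eps_ij) - 1)`; shear components are odd
#' in `eps_ij`.
#'
#' @inheritParams ecm_energy
#' @return Symmetric 3x3 local stress tensor.
#' @export
ecm_stress <- function(E_local, p = ecm_params()) {
  .check_sym3(E_local)
  S <- matrix(0, 3, 3)
  S[1, 1] <- .sij_normal(E_local[1, 1], p$k, p$a11)
  S[2, 2] <- .sij_normal(E_local[2, 2], p$k, p$a22)
  S[3, 3] <- .sij_normal(E_local[3, 3], p$k, p$a33)
  S[1, 2] <- S[2, 1] <- .sij_shear(E_local[1, 2], p$k, p$a12)
  S[2, 3] <- S[3, 2] <- .sij_shear(E_local[2, 3], p$k, p$a23)
  S[3, 1] <- S[1, 3] <- .sij_shear(E_local[3, 1], p$k, p$a31)
  S
}

#' Two-part volume-constancy penalty energy
#'
#' Per Gauss point, `Ss (I3 - 1)^2 + Sf (I3avg - 1)^2`, where `I3` is the
#' third invariant (determinant) of the right Cauchy-Green tensor -- the
#' squared local volume ratio -- and `I3avg` is the quadrature-weighted
#' element mean of `I3`.  The first term treats the solid elastic
#' structures (conserved point-wise); the second treats the intracellular
#' fluid, free to migrate within the element but conserved in element
#' total.
#'
#' @param I3_points numeric vector of `I3` values at the element's Gauss
#'   points (all > 0).
#' @param weights quadrature weights, summing to 1.
#' @param p [ecm_params()].
#' @return Vector of penalty energy densities, one per Gauss point.
#' @export
#' @examples
#' volume_penalty_energy(c(1.1, rep(1, 7)), rep(1/8, 8))
volume_penalty_energy <- function(I3_points, weights = NULL,
                                  p = ecm_params()) {
  n <- length(I3_points)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n)
    stop("weights must match I3_points in length", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  if (any(!is.finite(I3_points)) || any(I3_points <= 0))
    stop("invalid state: nonpositive volume ratio (element inversion)",
         call. = FALSE)
  I3avg <- sum(weights * I3_points)
  p$Ss * (I3_points - 1)^2 + p$Sf * (I3avg - 1)^2
}

#' Active contractile fiber stress
#'
#' Piecewise-exponential active length-force relation in the local fiber
#' direction, scaled so the stress at optimum length (zero fiber strain)
#' equals the activation level `b3`: `b3 exp(b2 eps^2)` for lengthening and
#' `b3 exp(b1 eps^3)` for shortening.
#'
#' @param eps22 fiber-direction Green-Lagrange strain (vectorized).
#' @param b3 activation level in `[0, 1]`.
#' @param p [fiber_params()] supplying `b1`, `b2`.
#' @return Cauchy stress along the current fiber direction.
#' @export
#' @examples
#' active_stress(0, 1)       # maximal stress, unity at optimum length
active_stress <- function(eps22, b3 = 1, p = fiber_params()) {
  if (any(b3 < 0) || any(b3 > 1))
    stop("activation 'b3' must lie in [0, 1]", call. = FALSE)
  b3 * ifelse(eps22 >= 0, exp(p$b2 * eps22^2), exp(p$b1 * eps22^3))
}

#' Intracellular passive (titin) fiber stress
#'
#' Parabolic tension `t1 eps^2 + t2 eps + t3` for non-negative fiber
#' strain, and exactly zero for shortening.  With `clamp = TRUE` (the
#' default taken from `p$clamp_titin`) the parabola is additionally clamped
#' at zero from below, removing the small negative offset `t3` near zero
#' strain so the passive reference state is stress-free.
#'
#' @inheritParams active_stress
#' @param clamp clamp the parabola to non-negative values.
#' @return Cauchy stress along the current fiber direction.
#' @export
titin_stress <- function(eps22, p = fiber_params(), clamp = p$clamp_titin) {
  s <- ifelse(eps22 >= 0, p$t1 * eps22^2 + p$t2 * eps22 + p$t3, 0)
  if (clamp) s <- pmax(s, 0)
  s
}

#' Total myofiber fiber-direction stress
#'
#' Sum of the active contractile stress and the intracellular passive
#' (titin) tension.  This Cauchy stress acts in the local fiber direction
#' exclusively; all other local stress components of the myofiber element
#' are zero.
#'
#' @inheritParams titin_stress
#' @inheritParams active_stress
#' @return Cauchy stress along the current fiber direction.
#' @export
fiber_total_stress <- function(eps22, b3 = 1, p = fiber_params(),
                               clamp = p$clamp_titin) {
  active_stress(eps22, b3, p) + titin_stress(eps22, p, clamp)
}

# invariants of C = t(F) %*% F and reduced (volume-normalized) invariants
.mr_invariants <- function(C) {
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * C))
  I3 <- det(C)
  list(I1 = I1, I2 = I2, I3 = I3, J = sqrt(I3))
}

#' Aponeurosis Mooney-Rivlin strain-energy density
#'
#' Two-parameter Mooney-Rivlin law in the reduced invariants of the right
#' Cauchy-Green tensor, `a10 (Ibar1 - 3) + a01 (Ibar2 - 3) +
#' kappa/2 (Ibar3 - 1)^2`, with `Ibar1 = I1 J^(-2/3)`,
#' `Ibar2 = I2 J^(-4/3)` and `Ibar3 = J = sqrt(I3)` the volume ratio.
#' Isochoric deformations leave the bulk term exactly zero.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param p [apon_params()].
#' @return Scalar energy density (per unit reference volume).
#' @export
aponeurosis_energy <- function(F, p = apon_params()) {
  if (!is.matrix(F) || !all(dim(F) == c(3L, 3L)))
    stop("'F' must be a 3x3 matrix", call. = FALSE)
  if (det(F) <= 0)
    stop("invalid state: non-positive det(F)", call. = FALSE)
  iv <- .mr_invariants(crossprod(F))
  p$a10 * (iv$I1 / iv$J^(2 / 3) - 3) + p$a01 * (iv$I2 / iv$J^(4 / 3) - 3) +
    p$bulk / 2 * (iv$J - 1)^2
}

#' Aponeurosis second Piola-Kirchhoff stress
#'
#' Analytic derivative of [aponeurosis_energy()] with respect to the
#' Green-Lagrange strain (`S = 2 dW/dC`).
#'
#' @inheritParams aponeurosis_energy
#' @return Symmetric 3x3 PK2 stress tensor (global frame of `F`).
#' @export
aponeurosis_pk2 <- function(F, p = apon_params()) {
  if (det(F) <= 0)
    stop("invalid state: non-positive det(F)", call. = FALSE)
  C <- crossprod(F)
  iv <- .mr_invariants(C)
  Cinv <- solve(C)
  I <- diag(3)
  J <- iv$J
  # d(Ibar1)/dC, d(Ibar2)/dC, dJ/dC = J/2 Cinv
  dI1b <- J^(-2 / 3) * (I - iv$I1 / 3 * Cinv)
  dI2b <- J^(-4 / 3) * (iv$I1 * I - C - 2 * iv$I2 / 3 * Cinv)
  dJ <- J / 2 * Cinv
  S <- 2 * (p$a10 * dI1b + p$a01 * dI2b + p$bulk * (J - 1) * dJ)
  (S + t(S)) / 2
}
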