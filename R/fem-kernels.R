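# Total-Lagrangian kernels for 8-node trilinear hexahedra with 2x2x2 Gauss
# quadrature.  All kernels are vectorized across the elements of a family:
# arrays are indexed (element, node, axis) and per-Gauss-point quantities
# are held as lists of (element, 3, 3) arrays.  Internal forces are the
# gradients of the element strain energy with respect to the current nodal
# coordinates, integrated over the reference configuration.

# shape function derivatives dN/dxi at the 2x2x2 Gauss points (8 x 3 each)
.hex_quadrature <- function() {
  a <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-a, a), eta = c(-a, a),
                              zeta = c(-a, a)))
  # node local coordinates, counter-clockwise bottom face then top
  nl <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
              c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  dN <- lapply(seq_len(8), function(g) {
    x <- gp[g, ]
    d <- matrix(0, 8, 3)
    for (n in 1:8) {
      d[n, 1] <- nl[n, 1] * (1 + nl[n, 2] * x[2]) * (1 + nl[n, 3] * x[3]) / 8
      d[n, 2] <- nl[n, 2] * (1 + nl[n, 1] * x[1]) * (1 + nl[n, 3] * x[3]) / 8
      d[n, 3] <- nl[n, 3] * (1 + nl[n, 1] * x[1]) * (1 + nl[n, 2] * x[2]) / 8
    }
    d
  })
  list(points = gp, dN = dN, weights = rep(1, 8), nodes_local = nl)
}
.HEXQ <- .hex_quadrature()

# Precompute reference-configuration data for one element family:
# connectivity, reference coordinates, dN/dX and w*detJ per Gauss point,
# and the local frame rotation split into per-element component vectors.
family_precompute <- function(mesh, family) {
  conn <- mesh$families[[family]]
  nel <- nrow(conn)
  if (nel == 0L) return(NULL)
  X <- array(0, dim = c(nel, 8, 3))
  for (n in 1:8) X[, n, ] <- mesh$nodes[conn[, n], , drop = FALSE]
  G <- array(0, dim = c(nel, 8, 3, 8))     # dN/dX: (el, node, axis, gp)
  wdet <- matrix(0, nel, 8)
  for (g in 1:8) {
    dN <- .HEXQ$dN[[g]]
    for (e in seq_len(nel)) {
      J <- t(X[e, , ]) %*% dN              # 3x3 dX/dxi
      dj <- det(J)
      if (dj <= 0) stop("degenerate element geometry in family '", family,
                        "'", call. = FALSE)
      G[e, , , g] <- dN %*% solve(J)
      wdet[e, g] <- dj
    }
  }
  fr <- mesh$frames[[family]]
  R <- array(0, dim = c(nel, 3, 3))
  for (a in 1:3) for (b in 1:3) R[, a, b] <- fr[a, b, ]
  list(family = family, conn = conn, nel = nel, X = X, G = G, wdet = wdet,
       R = R,
       act_scale = if (family == "myofiber") mesh$act_scale else NULL)
}

# deformation gradient, right Cauchy-Green tensor and derived quantities at
# one Gauss point for all elements: returns list of (nel,3,3) arrays
.kinematics_gp <- function(fam, xcur, g) {
  nel <- fam$nel
  F <- array(0, dim = c(nel, 3, 3))
  for (a in 1:3) for (b in 1:3)
    F[, a, b] <- rowSums(matrix(xcur[, , a], nel, 8) *
                           matrix(fam$G[, , b, g], nel, 8))
  C <- array(0, dim = c(nel, 3, 3))
  for (a in 1:3) for (b in a:3) {
    v <- F[, 1, a] * F[, 1, b] + F[, 2, a] * F[, 2, b] +
      F[, 3, a] * F[, 3, b]
    C[, a, b] <- v; C[, b, a] <- v
  }
  I3 <- C[, 1, 1] * (C[, 2, 2] * C[, 3, 3] - C[, 2, 3]^2) -
    C[, 1, 2] * (C[, 1, 2] * C[, 3, 3] - C[, 2, 3] * C[, 1, 3]) +
    C[, 1, 3] * (C[, 1, 2] * C[, 2, 3] - C[, 2, 2] * C[, 1, 3])
  if (any(!is.finite(I3)) || any(I3 <= 0))
    stop("invalid state: element inversion (non-positive volume ratio)",
         call. = FALSE)
  # inverse of C via adjugate
  Ci <- array(0, dim = c(nel, 3, 3))
  Ci[, 1, 1] <- (C[, 2, 2] * C[, 3, 3] - C[, 2, 3]^2) / I3
  Ci[, 2, 2] <- (C[, 1, 1] * C[, 3, 3] - C[, 1, 3]^2) / I3
  Ci[, 3, 3] <- (C[, 1, 1] * C[, 2, 2] - C[, 1, 2]^2) / I3
  v <- (C[, 1, 3] * C[, 2, 3] - C[, 1, 2] * C[, 3, 3]) / I3
  Ci[, 1, 2] <- v; Ci[, 2, 1] <- v
  v <- (C[, 1, 2] * C[, 2, 3] - C[, 1, 3] * C[, 2, 2]) / I3
  Ci[, 1, 3] <- v; Ci[, 3, 1] <- v
  v <- (C[, 1, 2] * C[, 1, 3] - C[, 1, 1] * C[, 2, 3]) / I3
  Ci[, 2, 3] <- v; Ci[, 3, 2] <- v
  list(F = F, C = C, Cinv = Ci, I3 = I3)
}

# rotate a global symmetric tensor array (nel,3,3) into the local frame
.to_local <- function(R, T) {
  nel <- dim(T)[1]
  out <- array(0, dim = c(nel, 3, 3))
  for (i in 1:3) for (j in i:3) {
    acc <- 0
    for (a in 1:3) for (b in 1:3)
      acc <- acc + R[, a, i] * T[, a, b] * R[, b, j]
    out[, i, j] <- acc; out[, j, i] <- acc
  }
  out
}

.to_global <- function(R, T) {
  nel <- dim(T)[1]
  out <- array(0, dim = c(nel, 3, 3))
  for (a in 1:3) for (b in a:3) {
    acc <- 0
    for (i in 1:3) for (j in 1:3)
      acc <- acc + R[, a, i] * T[, i, j] * R[, b, j]
    out[, a, b] <- acc; out[, b, a] <- acc
  }
  out
}

# local PK2 stress of the ECM anisotropic part as the tensor gradient of
# the energy density (off-diagonal derivative split over the two slots)
.ecm_stress_tensor_vec <- function(Eloc, p) {
  nel <- dim(Eloc)[1]
  S <- array(0, dim = c(nel, 3, 3))
  S[, 1, 1] <- .sij_normal(Eloc[, 1, 1], p$k, p$a11)
  S[, 2, 2] <- .sij_normal(Eloc[, 2, 2], p$k, p$a22)
  S[, 3, 3] <- .sij_normal(Eloc[, 3, 3], p$k, p$a33)
  v <- 0.5 * .sij_shear(Eloc[, 1, 2], p$k, p$a12)
  S[, 1, 2] <- v; S[, 2, 1] <- v
  v <- 0.5 * .sij_shear(Eloc[, 2, 3], p$k, p$a23)
  S[, 2, 3] <- v; S[, 3, 2] <- v
  v <- 0.5 * .sij_shear(Eloc[, 3, 1], p$k, p$a31)
  S[, 3, 1] <- v; S[, 1, 3] <- v
  S
}

.ecm_energy_vec <- function(Eloc, p) {
  .wij_normal(Eloc[, 1, 1], p$k, p$a11) +
    .wij_normal(Eloc[, 2, 2], p$k, p$a22) +
    .wij_normal(Eloc[, 3, 3], p$k, p$a33) +
    .wij_shear(Eloc[, 1, 2], p$k, p$a12) +
    .wij_shear(Eloc[, 2, 3], p$k, p$a23) +
    .wij_shear(Eloc[, 3, 1], p$k, p$a31)
}

# Mooney-Rivlin PK2 stress, vectorized over elements
.mr_stress_vec <- function(kin, p) {
  nel <- dim(kin$C)[1]
  C <- kin$C; Ci <- kin$Cinv
  I1 <- C[, 1, 1] + C[, 2, 2] + C[, 3, 3]
  CC <- 0
  for (a in 1:3) for (b in 1:3) CC <- CC + C[, a, b]^2
  I2 <- 0.5 * (I1^2 - CC)
  J <- sqrt(kin$I3)
  f1 <- 2 * p$a10 * J^(-2 / 3); f2 <- 2 * p$a01 * J^(-4 / 3)
  fb <- p$bulk * (J - 1) * J
  S <- array(0, dim = c(nel, 3, 3))
  for (a in 1:3) for (b in a:3) {
    eye <- as.numeric(a == b)
    v <- f1 * (eye - I1 / 3 * Ci[, a, b]) +
      f2 * (I1 * eye - C[, a, b] - 2 * I2 / 3 * Ci[, a, b]) +
      fb * Ci[, a, b]
    S[, a, b] <- v; S[, b, a] <- v
  }
  S
}

.mr_energy_vec <- function(kin, p) {
  C <- kin$C
  I1 <- C[, 1, 1] + C[, 2, 2] + C[, 3, 3]
  CC <- 0
  for (a in 1:3) for (b in 1:3) CC <- CC + C[, a, b]^2
  I2 <- 0.5 * (I1^2 - CC)
  J <- sqrt(kin$I3)
  p$a10 * (I1 * J^(-2 / 3) - 3) + p$a01 * (I2 * J^(-4 / 3) - 3) +
    p$bulk / 2 * (J - 1)^2
}

# Internal nodal forces of one element family at current coordinates xcur
# (nel x 8 x 3).  b3 is the global activation level; per-element activation
# is b3 * act_scale.  Returns an (nel x 8 x 3) force array.
family_force <- function(fam, xcur, materials, b3 = 0) {
  nel <- fam$nel
  kin <- lapply(1:8, function(g) .kinematics_gp(fam, xcur, g))
  f <- array(0, dim = c(nel, 8, 3))
  ecm <- fam$family == "ecm"
  if (ecm) {
    vol <- rowSums(fam$wdet)
    I3avg <- Reduce(`+`, lapply(1:8, function(g)
      fam$wdet[, g] * kin[[g]]$I3)) / vol
  }
  for (g in 1:8) {
    kg <- kin[[g]]
    Sg <- switch(fam$family,
      ecm = {
        E <- (kg$C - outer(rep(1, nel), diag(3))) / 2
        Eloc <- .to_local(fam$R, E)
        S <- .to_global(fam$R, .ecm_stress_tensor_vec(Eloc, materials$ecm))
        pen <- 4 * (materials$ecm$Ss * (kg$I3 - 1) +
                      materials$ecm$Sf * (I3avg - 1)) * kg$I3
        for (a in 1:3) for (b in 1:3)
          S[, a, b] <- S[, a, b] + pen * kg$Cinv[, a, b]
        S
      },
      myofiber = {
        E <- (kg$C - outer(rep(1, nel), diag(3))) / 2
        Eloc <- .to_local(fam$R, E)
        eps22 <- Eloc[, 2, 2]
        act <- b3 * fam$act_scale
        sig <- act * ifelse(eps22 >= 0, exp(materials$fiber$b2 * eps22^2),
                            exp(materials$fiber$b1 * eps22^3)) +
          titin_stress(eps22, materials$fiber)
        s22 <- if (identical(materials$fiber_stress_mode, "pk2_direct"))
          sig
        else
          sqrt(kg$I3) * sig / (2 * eps22 + 1)
        Sl <- array(0, dim = c(nel, 3, 3))
        Sl[, 2, 2] <- s22
        .to_global(fam$R, Sl)
      },
      aponeurosis = .mr_stress_vec(kg, materials$apon))
    # P = F S, then f[n, a] += wdet * sum_b G[n, b] P[a, b]
    P <- array(0, dim = c(nel, 3, 3))
    for (a in 1:3) for (b in 1:3)
      P[, a, b] <- kg$F[, a, 1] * Sg[, 1, b] + kg$F[, a, 2] * Sg[, 2, b] +
        kg$F[, a, 3] * Sg[, 3, b]
    w <- fam$wdet[, g]
    for (n in 1:8) for (a in 1:3)
      f[, n, a] <- f[, n, a] +
        w * (fam$G[, n, 1, g] * P[, a, 1] + fam$G[, n, 2, g] * P[, a, 2] +
               fam$G[, n, 3, g] * P[, a, 3])
  }
  f
}

# Total strain energy per element (nel vector).  For the myofiber family
# the fiber stress is integrated to a 1D potential; this is the exact
# element energy in "pk2_direct" mode.
family_energy <- function(fam, xcur, materials, b3 = 0) {
  nel <- fam$nel
  kin <- lapply(1:8, function(g) .kinematics_gp(fam, xcur, g))
  ecm <- fam$family == "ecm"
  if (ecm) {
    vol <- rowSums(fam$wdet)
    I3avg <- Reduce(`+`, lapply(1:8, function(g)
      fam$wdet[, g] * kin[[g]]$I3)) / vol
  }
  en <- numeric(nel)
  for (g in 1:8) {
    kg <- kin[[g]]
    dens <- switch(fam$family,
      ecm = {
        E <- (kg$C - outer(rep(1, nel), diag(3))) / 2
        Eloc <- .to_local(fam$R, E)
        .ecm_energy_vec(Eloc, materials$ecm) +
          materials$ecm$Ss * (kg$I3 - 1)^2 +
          materials$ecm$Sf * (I3avg - 1)^2
      },
      myofiber = {
        E <- (kg$C - outer(rep(1, nel), diag(3))) / 2
        Eloc <- .to_local(fam$R, E)
        fiber_stress_potential(Eloc[, 2, 2], b3 * fam$act_scale,
                               materials$fiber)
      },
      aponeurosis = .mr_energy_vec(kg, materials$apon))
    en <- en + fam$wdet[, g] * dens
  }
  en
}

#' Fiber stress potential
#'
#' One-dimensional potential of the total myofiber fiber-direction stress:
#' the integral of [fiber_total_stress()] over fiber strain from 0.  The
#' titin part is integrated in closed form (respecting the non-negativity
#' clamp); the smooth active part uses fixed-order Gauss-Legendre
#' quadrature.
#'
#' @inheritParams fiber_total_stress
#' @return Energy density per unit reference volume (vectorized).
#' @export
fiber_stress_potential <- function(eps22, b3 = 1, p = fiber_params(),
                                   clamp = p$clamp_titin) {
  gl <- .gauss_legendre_24
  active_int <- vapply(seq_along(eps22), function(i) {
    e <- eps22[i]
    if (e == 0) return(0)
    x <- e / 2 * (gl$x + 1)                       # map [-1,1] -> [0, e]
    sum(gl$w * ifelse(x >= 0, exp(p$b2 * x^2), exp(p$b1 * x^3))) * e / 2
  }, numeric(1))
  b3v <- rep_len(b3, length(eps22))
  titin_int <- function(e) {
    Pfun <- function(x) p$t1 * x^3 / 3 + p$t2 * x^2 / 2 + p$t3 * x
    if (!clamp) return(ifelse(e > 0, Pfun(e), 0))
    disc <- p$t2^2 - 4 * p$t1 * p$t3
    root <- if (p$t3 < 0 && disc > 0)
      (-p$t2 + sqrt(disc)) / (2 * p$t1) else 0
    ifelse(e > root, Pfun(e) - Pfun(root), 0)
  }
  b3v * active_int + titin_int(eps22)
}

.gauss_legendre <- function(n) {
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  m <- matrix(0, n, n)
  m[cbind(i, i + 1)] <- b
  m[cbind(i + 1, i)] <- b
  ev <- eigen(m, symmetric = TRUE)
  ord <- order(ev$values)
  list(x = ev$values[ord], w = 2 * ev$vectors[1, ord]^2)
}
.gauss_legendre_24 <- .gauss_legendre(24)

# Central finite-difference tangent of a family's internal force with
# respect to the 24 element coordinates; returns (nel x 24 x 24), ordered
# node-major (node 1 xyz, node 2 xyz, ...).
family_tangent <- function(fam, xcur, materials, b3 = 0, h = 1e-6) {
  nel <- fam$nel
  K <- array(0, dim = c(nel, 24, 24))
  for (n in 1:8) for (a in 1:3) {
    d <- 3 * (n - 1) + a
    xp <- xcur; xp[, n, a] <- xp[, n, a] + h
    xm <- xcur; xm[, n, a] <- xm[, n, a] - h
    df <- (family_force(fam, xp, materials, b3) -
             family_force(fam, xm, materials, b3)) / (2 * h)
    K[, , d] <- matrix(aperm(df, c(1, 3, 2)), nel, 24)
  }
  K
}

#' Green-Lagrange strain tensor
#'
#' `E = (t(F) F - I) / 2` for a deformation gradient `F`.
#'
#' @param F 3x3 deformation gradient.
#' @return Symmetric 3x3 strain tensor.
#' @export
#' @examples
#' green_lagrange(diag(c(1.2, 1, 1)))[1, 1]   # (1.2^2 - 1)/2 = 0.22
green_lagrange <- function(F) {
  if (!is.matrix(F) || !all(dim(F) == c(3L, 3L)))
    stop("'F' must be a 3x3 matrix", call. = FALSE)
  (crossprod(F) - diag(3)) / 2
}

#' Internal force vector of a single hexahedral element
#'
#' Total-Lagrangian internal nodal forces of one 8-node element at the
#' given displacement state: the gradient of the element strain energy
#' with respect to the nodal coordinates.  ECM elements carry the
#' anisotropic exponential stress plus the volume-constancy penalty;
#' myofiber elements carry fiber-direction stress exclusively; aponeurosis
#' elements the Mooney-Rivlin stress.
#'
#' @param X 8x3 reference nodal coordinates.
#' @param u 8x3 nodal displacements.
#' @param family `"ecm"`, `"myofiber"` or `"aponeurosis"`.
#' @param materials [material_set()].
#' @param frame 3x3 local fiber triad (columns: cross-fiber, fiber,
#'   thickness).
#' @param b3 activation level (myofiber family only).
#' @return 8x3 matrix of nodal forces.
#' @export
element_internal_force <- function(X, u, family = "ecm",
                                   materials = material_set(),
                                   frame = diag(3), b3 = 0) {
  fam <- .single_element_family(X, family, frame)
  drop_3d(family_force(fam, .as_xcur(X, u), materials, b3))
}

#' Strain energy of a single hexahedral element
#'
#' @inheritParams element_internal_force
#' @return Scalar total element energy.
#' @export
element_energy <- function(X, u, family = "ecm",
                           materials = material_set(), frame = diag(3),
                           b3 = 0) {
  fam <- .single_element_family(X, family, frame)
  family_energy(fam, .as_xcur(X, u), materials, b3)[1]
}

.single_element_family <- function(X, family, frame) {
  mesh <- list(nodes = X,
               families = setNames(list(matrix(1:8, 1, 8)), family),
               frames = setNames(list(array(frame, dim = c(3, 3, 1))),
                                 family),
               act_scale = 1)
  family_precompute(mesh, family)
}

.as_xcur <- function(X, u) {
  x <- array(0, dim = c(1, 8, 3))
  x[1, , ] <- X + u
  x
}

drop_3d <- function(a) matrix(a[1, , ], dim(a)[2], dim(a)[3])
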