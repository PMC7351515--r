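# Constitutive laws: frozen scalar oracles, derivative consistency, and
# shape properties of the stress-strain relations.

test_that("ECM energy and stress match scalar arithmetic oracles", {
  p <- ecm_params()
  expect_equal(ecm_energy(matrix(0, 3, 3), p), 6 * p$k)

  E <- matrix(0, 3, 3); E[2, 2] <- 0.1
  expect_equal(ecm_energy(E, p),
               5 * p$k + p$k * (exp(0.6) - 0.6), tolerance = 1e-12)
  expect_equal(ecm_stress(E, p)[2, 2], 0.05 * 6 * (exp(0.6) - 1),
               tolerance = 1e-12)
  expect_equal(ecm_stress(matrix(0, 3, 3), p), matrix(0, 3, 3))

  # finite and real across the working strain range in every component
  for (val in c(-0.5, -0.1, 0.2, 0.5)) for (i in 1:3) for (j in 1:3) {
    E <- matrix(0, 3, 3); E[i, j] <- E[j, i] <- val
    expect_true(is.finite(ecm_energy(E, p)))
  }
})

test_that("ECM stress is the strain gradient of the energy", {
  set.seed(11)
  p <- ecm_params()
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(2, 3), c(3, 1))
  for (rep in 1:100) {
    E <- random_strain(0.3)
    S <- ecm_stress(E, p)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      fd <- fd_grad_sym(function(M) ecm_energy(M, p), E, i, j)
      expect_equal(S[i, j], fd, tolerance = 1e-6)
    }
  }
})

test_that("ECM normal response is asymmetric and shear response is odd", {
  p <- ecm_params()
  for (eps in c(0.05, 0.15, 0.3)) {
    En <- matrix(0, 3, 3)
    En[2, 2] <- eps
    Em <- matrix(0, 3, 3)
    Em[2, 2] <- -eps
    expect_false(isTRUE(all.equal(abs(ecm_stress(En, p)[2, 2]),
                                  abs(ecm_stress(Em, p)[2, 2]))))
    Es <- matrix(0, 3, 3); Es[1, 2] <- Es[2, 1] <- eps
    Es2 <- -Es
    expect_equal(ecm_stress(Es, p)[1, 2], -ecm_stress(Es2, p)[1, 2])
    # even energy under shear sign flip
    expect_equal(ecm_energy(Es, p), ecm_energy(Es2, p))
  }
})

test_that("volume penalty matches the two-part oracle and rejects inversion", {
  p <- ecm_params()
  expect_equal(volume_penalty_energy(rep(1, 8), rep(1 / 8, 8), p),
               rep(0, 8))
  w <- volume_penalty_energy(c(1.1, rep(1, 7)), rep(1 / 8, 8), p)
  expect_equal(w[1], 5 * 0.01 + 20 * 0.0125^2, tolerance = 1e-12)
  # uniform I3 = c: every point sees (Ss + Sf) (c - 1)^2
  for (cc in c(0.9, 1.05, 1.2))
    expect_equal(volume_penalty_energy(rep(cc, 8), rep(1 / 8, 8), p),
                 rep((p$Ss + p$Sf) * (cc - 1)^2, 8))
  expect_error(volume_penalty_energy(c(-0.1, rep(1, 7)), rep(1 / 8, 8), p),
               "inversion")
  expect_error(volume_penalty_energy(rep(1, 4), rep(1, 4)), "sum to 1")
})

test_that("active stress follows the piecewise exponential law", {
  expect_identical(active_stress(0, 1), 1)
  expect_equal(active_stress(0.2, 1), exp(-6 * 0.04), tolerance = 1e-12)
  expect_equal(active_stress(-0.2, 1), exp(30 * (-0.008)),
               tolerance = 1e-12)
  expect_equal(active_stress(seq(-0.4, 0.4, by = 0.05), 0),
               rep(0, 17))
  # hill shape: bounded by b3 with the optimum only at zero strain
  eps <- seq(-0.45, 0.45, by = 0.01)
  s <- active_stress(eps, 0.7)
  expect_true(all(s <= 0.7 + 1e-15))
  expect_identical(which(s == max(s)), which(eps == 0))
  expect_error(active_stress(0, 1.2), "b3")
})

test_that("titin stress is a clamped parabola, zero for shortening", {
  p <- fiber_params()
  expect_identical(titin_stress(-0.1, p), 0)
  expect_equal(titin_stress(1.0, p), 0.522 + 0.019 - 0.002)
  expect_equal(titin_stress(0.5, p), 0.522 * 0.25 + 0.019 * 0.5 - 0.002)
  # clamped by default near zero strain; formula as printed when unclamped
  expect_identical(titin_stress(0, p), 0)
  expect_equal(titin_stress(0, p, clamp = FALSE), p$t3)
  expect_true(all(titin_stress(seq(-0.5, 1.5, by = 0.01), p) >= 0))
})

test_that("total fiber stress sums active and titin parts", {
  p <- fiber_params()
  expect_equal(fiber_total_stress(0, 1, p), 1.0)
  expect_equal(fiber_total_stress(0, 1, p, clamp = FALSE), 1 + p$t3)
  expect_equal(fiber_total_stress(-0.2, 1, p), exp(30 * (-0.008)))
  expect_equal(fiber_total_stress(0.3, 0, p),
               0.522 * 0.09 + 0.019 * 0.3 - 0.002, tolerance = 1e-12)
  # passive shortening carries no fiber stress at all
  expect_equal(fiber_total_stress(seq(-0.4, -0.01, by = 0.01), 0, p),
               rep(0, 40))
})

test_that("fiber stress potential differentiates back to the stress", {
  p <- fiber_params()
  for (b3 in c(0, 0.5, 1)) for (e in c(-0.3, -0.1, 0.02, 0.2, 0.4)) {
    h <- 1e-6
    fd <- (fiber_stress_potential(e + h, b3, p) -
             fiber_stress_potential(e - h, b3, p)) / (2 * h)
    expect_equal(fd, fiber_total_stress(e, b3, p), tolerance = 1e-6)
  }
})

test_that("aponeurosis energy and stress are mutually consistent", {
  p <- apon_params()
  expect_equal(aponeurosis_energy(diag(3), p), 0)
  expect_equal(aponeurosis_pk2(diag(3), p), matrix(0, 3, 3),
               tolerance = 1e-12)
  # isochoric deformations never engage the bulk term
  Fiso <- diag(c(1.3, 1 / 1.3, 1))
  p2 <- apon_params(p$a10, p$a01, poisson = 0.45)   # different bulk
  expect_equal(aponeurosis_energy(Fiso, p), aponeurosis_energy(Fiso, p2))
  expect_error(aponeurosis_energy(-diag(3), p), "det")

  set.seed(21)
  for (rep in 1:40) {
    F <- random_defgrad()
    C <- crossprod(F)
    S <- aponeurosis_pk2(F, p)
    # S = dW/dE: perturb E (= C/2) symmetrically
    for (i in 1:3) for (j in i:3) {
      fd <- fd_grad_sym(function(Cm) {
        # energy as a function of C through a compatible F
        ev <- eigen(Cm, symmetric = TRUE)
        Fm <- ev$vectors %*% diag(sqrt(pmax(ev$values, 1e-12))) %*%
          t(ev$vectors)
        aponeurosis_energy(Fm, p)
      }, C, i, j, h = 1e-6)
      # dW/dE_ij = 2 dW/dC_ij for off-diagonal (two slots), 2 dW/dC ii on
      # the diagonal; fd above is dW/dC_ij counting both slots
      target <- if (i == j) S[i, j] / 2 else S[i, j]
      expect_equal(fd, target, tolerance = 2e-5)
    }
  }
})

test_that("parameter constructors enforce their invariants", {
  expect_error(ecm_params(k = -1), "'k'")
  expect_error(fiber_params(b3 = 2), "b3")
  expect_error(apon_params(poisson = 0.5), "poisson")
  expect_error(link_params(k_extra_stiff = 0.01), "exceed")
  expect_error(geometry_params(fascicle_span = 30), "self-intersect")
  # bulk modulus is always derived, never free
  ap <- apon_params(10, 5, 0.25)
  expect_equal(ap$bulk, 2 * 15 / 0.5)
})
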