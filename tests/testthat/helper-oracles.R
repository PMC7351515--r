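# Shared oracles and fixtures, built in code.

# central finite-difference gradient of a scalar function of a matrix,
# perturbing entry (i, j) (and (j, i) for symmetric arguments)
fd_grad_sym <- function(fun, M, i, j, h = 1e-6) {
  Mp <- M; Mp[i, j] <- Mp[i, j] + h; Mp[j, i] <- Mp[i, j]
  Mm <- M; Mm[i, j] <- Mm[i, j] - h; Mm[j, i] <- Mm[i, j]
  (fun(Mp) - fun(Mm)) / (2 * h)
}

# random symmetric local strain state with components in [-range, range]
random_strain <- function(range = 0.3) {
  E <- matrix(runif(9, -range, range), 3, 3)
  (E + t(E)) / 2
}

# random deformation gradient near identity with positive determinant
random_defgrad <- function(spread = 0.15) {
  repeat {
    F <- diag(3) + matrix(runif(9, -spread, spread), 3, 3)
    if (det(F) > 0.3) return(F)
  }
}

small_geometry <- function(n_series = 2L, n_parallel = 2L)
  geometry_params(n_series = n_series, n_parallel = n_parallel)

# interior faces of a hexahedral connectivity must be shared by exactly
# two elements; boundary faces by exactly one
face_share_counts <- function(conn) {
  faces <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                 c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  keys <- character(0)
  for (e in seq_len(nrow(conn))) for (f in 1:6)
    keys <- c(keys, paste(sort(conn[e, faces[f, ]]), collapse = "-"))
  table(keys)
}
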