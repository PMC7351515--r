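# Dual-mesh muscle geometry: coincident ECM and myofiber hexahedral meshes
# sharing nodes at the myotendinous attachment planes, single aponeurosis
# element layers proximally and distally, and elastic links (fiber-matrix,
# extramuscular, intermuscular).
#
# Global frame: X = proximo-distal axis (distal positive), Y = in-plane
# across the belly, Z = slice thickness.  Hexahedra are numbered with the
# standard trilinear convention: four nodes counter-clockwise on the z-low
# face, then the same four on the z-high face.

# contour of the upper (proximal aponeurosis) attachment line; xi in [0, 1]
.contour_top <- function(g, xi) {
  cbind(x = xi * (g$initial_length - g$fascicle_span),
        y = g$belly_height + g$belly_bulge * sin(pi * xi) +
          g$belly_tilt * (xi - 0.5))
}

.contour_bottom <- function(g, xi) {
  cbind(x = xi * (g$initial_length - g$fascicle_span) + g$fascicle_span,
        y = rep(0, length(xi)))
}

# aponeurosis thickness profiles: linear growth toward the tendon end
.apon_th_top <- function(g, xi)       # proximal tendon end at xi = 0
  g$apon_thickness * (g$apon_thickness_factor -
                        (g$apon_thickness_factor - 1) * xi)
.apon_th_bottom <- function(g, xi)    # distal tendon end at xi = 1
  g$apon_thickness * (1 + (g$apon_thickness_factor - 1) * xi)

#' Build the dual-mesh muscle geometry
#'
#' Constructs the reference-state muscle mesh: `n_series x n_parallel`
#' coincident pairs of ECM and myofiber hexahedra (one element through the
#' thickness), sharing nodes exactly at the proximal and distal myotendinous
#' attachment planes and nowhere else, plus single layers of aponeurosis
#' elements whose thickness grows toward the tendon ends.  The proximal
#' tendon end face sits at X = 0 and the distal end face at
#' X = `initial_length`.
#'
#' @param g [geometry_params()].
#' @return An object of class `muscle_mesh` with fields `nodes` (N x 3
#'   reference coordinates, mm), `families` (connectivity per element
#'   family), `frames` (local fiber triads per element), `links` (initially
#'   empty), `node_sets`, and the fascicle sampling grid
#'   (face x section x interface node ids of the fiber mesh).
#' @export
#' @examples
#' m <- build_muscle_mesh(geometry_params(n_series = 1, n_parallel = 1))
#' nrow(m$families$ecm)
build_muscle_mesh <- function(g = geometry_params()) {
  stopifnot(inherits(g, "geometry_params"))
  ns <- g$n_series; np <- g$n_parallel
  xi <- (seq_len(np + 1L) - 1) / np
  top <- .contour_top(g, xi)
  bot <- .contour_bottom(g, xi)
  if (any(top[, "y"] <= 0))
    stop("degenerate contour: upper attachment line touches the lower one",
         call. = FALSE)
  zs <- c(0, g$slice_thickness)

  nodes <- matrix(numeric(0), ncol = 3)
  new_node <- function(x, y, z) {
    nodes <<- rbind(nodes, c(x, y, z))
    nrow(nodes)
  }

  # matrix-mesh grid: interfaces i, section rows r (1 = proximal attachment
  # plane at the upper contour, ns+1 = distal plane at the lower contour),
  # z layers l
  mat_id <- array(0L, dim = c(np + 1L, ns + 1L, 2L))
  for (l in 1:2) for (r in seq_len(ns + 1L)) {
    frac <- (r - 1) / ns
    for (i in seq_len(np + 1L)) {
      p <- top[i, ] + frac * (bot[i, ] - top[i, ])
      mat_id[i, r, l] <- new_node(p[1], p[2], zs[l])
    }
  }

  # fiber mesh: attachment rows shared, interior rows duplicated
  fib_id <- mat_id
  if (ns >= 2L) for (l in 1:2) for (r in 2:ns) for (i in seq_len(np + 1L)) {
    p <- nodes[mat_id[i, r, l], ]
    fib_id[i, r, l] <- new_node(p[1], p[2], p[3])
  }

  # aponeurosis outer nodes
  th_top <- .apon_th_top(g, xi); th_bot <- .apon_th_bottom(g, xi)
  topo_id <- boto_id <- matrix(0L, np + 1L, 2L)
  for (l in 1:2) for (i in seq_len(np + 1L)) {
    topo_id[i, l] <- new_node(top[i, "x"], top[i, "y"] + th_top[i], zs[l])
    boto_id[i, l] <- new_node(bot[i, "x"], bot[i, "y"] - th_bot[i], zs[l])
  }

  hex <- function(i1, i2, i3, i4) c(i1, i2, i3, i4)
  ecm_conn <- myo_conn <- matrix(0L, 0, 8)
  for (j in seq_len(np)) for (rr in seq_len(ns)) {
    low <- c(mat_id[j, rr + 1L, 1], mat_id[j + 1L, rr + 1L, 1],
             mat_id[j + 1L, rr, 1], mat_id[j, rr, 1])
    ecm_conn <- rbind(ecm_conn, c(low, mat_id[j, rr + 1L, 2],
                                  mat_id[j + 1L, rr + 1L, 2],
                                  mat_id[j + 1L, rr, 2], mat_id[j, rr, 2]))
    lowf <- c(fib_id[j, rr + 1L, 1], fib_id[j + 1L, rr + 1L, 1],
              fib_id[j + 1L, rr, 1], fib_id[j, rr, 1])
    myo_conn <- rbind(myo_conn, c(lowf, fib_id[j, rr + 1L, 2],
                                  fib_id[j + 1L, rr + 1L, 2],
                                  fib_id[j + 1L, rr, 2], fib_id[j, rr, 2]))
  }
  apon_conn <- matrix(0L, 0, 8)
  for (j in seq_len(np)) {         # proximal (upper) aponeurosis layer
    apon_conn <- rbind(apon_conn, c(mat_id[j, 1, 1], mat_id[j + 1L, 1, 1],
                                    topo_id[j + 1L, 1], topo_id[j, 1],
                                    mat_id[j, 1, 2], mat_id[j + 1L, 1, 2],
                                    topo_id[j + 1L, 2], topo_id[j, 2]))
  }
  for (j in seq_len(np)) {         # distal (lower) aponeurosis layer
    apon_conn <- rbind(apon_conn,
                       c(boto_id[j, 1], boto_id[j + 1L, 1],
                         mat_id[j + 1L, ns + 1L, 1], mat_id[j, ns + 1L, 1],
                         boto_id[j, 2], boto_id[j + 1L, 2],
                         mat_id[j + 1L, ns + 1L, 2], mat_id[j, ns + 1L, 2]))
  }

  # local fiber triads per muscle element: direction 2 along the
  # aponeurosis-to-aponeurosis fascicle edge (pointing proximally),
  # direction 3 the thickness normal, direction 1 completing the triad
  n_musc <- np * ns
  frames_musc <- array(0, dim = c(3, 3, n_musc))
  e <- 0L
  for (j in seq_len(np)) for (rr in seq_len(ns)) {
    e <- e + 1L
    tmid <- (top[j, ] + top[j + 1L, ]) / 2
    bmid <- (bot[j, ] + bot[j + 1L, ]) / 2
    d2 <- c(tmid - bmid, 0); d2 <- d2 / sqrt(sum(d2^2))
    d3 <- c(0, 0, 1)
    d1 <- c(d2[2] * d3[3] - d2[3] * d3[2],
            d2[3] * d3[1] - d2[1] * d3[3],
            d2[1] * d3[2] - d2[2] * d3[1])
    frames_musc[, , e] <- cbind(d1, d2, d3)
  }
  frames_apon <- array(diag(3), dim = c(3, 3, nrow(apon_conn)))

  grid_ids <- list(
    lateral = t(fib_id[, , 1]),   # sections x interfaces, z = 0 face
    medial  = t(fib_id[, , 2]))   # z = slice_thickness face

  interior_l <- interior_m <- integer(0)
  if (ns >= 2L) {
    interior_fib <- as.integer(fib_id[, 2:ns, , drop = FALSE])
    interior_mat <- as.integer(mat_id[, 2:ns, , drop = FALSE])
    keep <- interior_fib != interior_mat
    interior_l <- interior_fib[keep]; interior_m <- interior_mat[keep]
  }

  node_sets <- list(
    proximal_end = c(mat_id[1, 1, ], topo_id[1, ]),
    distal_end = c(mat_id[np + 1L, ns + 1L, ], boto_id[np + 1L, ]),
    lateral_face = as.integer(mat_id[, , 1]),
    medial_face = as.integer(mat_id[, , 2]),
    interior_fiber = interior_l,
    interior_matrix = interior_m)

  structure(list(
    nodes = nodes,
    families = list(ecm = ecm_conn, myofiber = myo_conn,
                    aponeurosis = apon_conn),
    frames = list(ecm = frames_musc, myofiber = frames_musc,
                  aponeurosis = frames_apon),
    act_scale = rep(1, nrow(myo_conn)),
    links = empty_links(),
    node_sets = node_sets,
    fascicle_grid = grid_ids,
    maps = list(mat_id = mat_id, fib_id = fib_id,
                topo_id = topo_id, boto_id = boto_id),
    muscles = list(target = list(node_sets = node_sets,
                                 fascicle_grid = grid_ids,
                                 lateral_layer = 1L, medial_layer = 2L)),
    geometry = g, n_series = ns, n_parallel = np),
    class = "muscle_mesh")
}

empty_links <- function() {
  data.frame(kind = character(0), node_a = integer(0), node_b = integer(0),
             ax = numeric(0), ay = numeric(0), az = numeric(0),
             stiffness = numeric(0), ref_length = numeric(0),
             interface = integer(0), muscle = character(0),
             stringsAsFactors = FALSE)
}

add_links <- function(mesh, kind, node_a, node_b, stiffness,
                      anchors = NULL, interface = NA_integer_,
                      muscle = "target") {
  n <- length(node_a)
  if (is.null(anchors)) anchors <- matrix(NA_real_, n, 3)
  df <- data.frame(kind = rep(kind, n), node_a = as.integer(node_a),
                   node_b = if (is.null(node_b)) rep(NA_integer_, n)
                            else as.integer(node_b),
                   ax = anchors[, 1], ay = anchors[, 2], az = anchors[, 3],
                   stiffness = rep_len(stiffness, n),
                   ref_length = rep(0, n),
                   interface = rep_len(interface, n),
                   muscle = rep_len(muscle, n), stringsAsFactors = FALSE)
  mesh$links <- rbind(mesh$links, df)
  mesh
}

#' Add trans-sarcolemmal fiber-matrix links
#'
#' Ties every interior (non-attachment) node of the fiber mesh to its
#' coincident matrix-mesh node by a uniaxial spring of zero initial length
#' and high stiffness.  With the default topology this places 34 links on
#' each of the two model surfaces (z faces).
#'
#' @param mesh a [build_muscle_mesh()] result.
#' @param lp [link_params()].
#' @return The mesh with `fiber_matrix` links appended.
#' @export
add_fiber_matrix_links <- function(mesh, lp = link_params()) {
  stopifnot(inherits(mesh, "muscle_mesh"))
  fi <- mesh$node_sets$interior_fiber
  mi <- mesh$node_sets$interior_matrix
  if (length(fi) != length(mi))
    stop("topology error: unpaired interior fiber node", call. = FALSE)
  if (length(fi) == 0L) return(mesh)
  if (max(abs(mesh$nodes[fi, ] - mesh$nodes[mi, ])) > 1e-12)
    stop("topology error: interior fiber/matrix nodes are not coincident",
         call. = FALSE)
  add_links(mesh, "fiber_matrix", fi, mi, lp$k_fiber_matrix)
}

# row index of the extramuscular attachment plane: one third of the
# fascicle length from the proximal side
.extra_row <- function(ns) 1L + as.integer(round(ns / 3))

#' Attach extramuscular connections to mechanical ground
#'
#' Grounds one matrix-mesh node per fascicle interface, at one third of the
#' fascicle length from the proximal side, on the requested z face.  Ground
#' anchors coincide with the linked nodes in the reference state, so the
#' links carry zero force before any displacement is imposed.  The
#' `n_stiff_proximal` most proximal links (the neurovascular-tract side)
#' use `k_extra_stiff`; the rest use `k_extra_compliant`.
#'
#' @param mesh a [build_muscle_mesh()] result.
#' @param lp [link_params()].
#' @param face `"lateral"` (z = 0) or `"medial"` (z = slice thickness).
#' @param muscle label recorded on the links (used by the epimuscular pair).
#' @return The mesh with `extramuscular` links appended.
#' @export
attach_extramuscular <- function(mesh, lp = link_params(),
                                 face = c("lateral", "medial"),
                                 muscle = "target") {
  stopifnot(inherits(mesh, "muscle_mesh"))
  face <- match.arg(face)
  ms <- mesh$muscles[[muscle]]
  if (is.null(ms)) stop("unknown muscle '", muscle, "'", call. = FALSE)
  layer <- if (face == "lateral") ms$lateral_layer else ms$medial_layer
  mat_id <- if (muscle == "target" || is.null(ms$mat_id)) mesh$maps$mat_id
            else ms$mat_id
  r <- .extra_row(mesh$n_series)
  ids <- mat_id[, r, layer]
  if (length(ids) == 0L)
    stop("topology error: face has no matching node column", call. = FALSE)
  k <- ifelse(seq_along(ids) <= lp$n_stiff_proximal,
              lp$k_extra_stiff, lp$k_extra_compliant)
  add_links(mesh, "extramuscular", ids, NULL, k,
            anchors = mesh$nodes[ids, , drop = FALSE],
            interface = seq_along(ids), muscle = muscle)
}

#' Build the epimuscularly connected muscle pair
#'
#' Duplicates the muscle, offsets the copy (the synergist) by one slice
#' thickness so its medial face coincides with the target's, links the
#' corresponding matrix-mesh nodes of the two medial faces with
#' intermuscular springs, adds fiber-matrix links within each muscle, and
#' attaches extramuscular connections on the lateral face of each muscle.
#'
#' @param g [geometry_params()].
#' @param lp [link_params()].
#' @return A combined `muscle_mesh` holding both muscles; per-muscle node
#'   sets and fascicle grids live under `$muscles$target` and
#'   `$muscles$synergist`.
#' @export
build_epimuscular_pair <- function(g = geometry_params(),
                                   lp = link_params()) {
  a <- build_muscle_mesh(g)
  b <- build_muscle_mesh(g)
  off <- nrow(a$nodes)
  bn <- b$nodes; bn[, 3] <- bn[, 3] + g$slice_thickness
  mesh <- a
  mesh$nodes <- rbind(a$nodes, bn)
  for (f in names(mesh$families)) {
    mesh$families[[f]] <- rbind(a$families[[f]], b$families[[f]] + off)
    mesh$frames[[f]] <- array(c(a$frames[[f]], b$frames[[f]]),
                              dim = c(3, 3, dim(a$frames[[f]])[3] +
                                        dim(b$frames[[f]])[3]))
  }
  mesh$act_scale <- c(a$act_scale, b$act_scale)
  # which myofiber elements belong to which muscle
  mesh$myofiber_muscle <- rep(c("target", "synergist"),
                              each = nrow(a$families$myofiber))

  shift_sets <- lapply(b$node_sets, function(s) s + off)
  syn_grid <- list(lateral = t(b$maps$fib_id[, , 2]) + off,  # outer z face
                   medial  = t(b$maps$fib_id[, , 1]) + off)  # facing target
  mesh$muscles <- list(
    target = list(node_sets = a$node_sets, fascicle_grid = a$fascicle_grid,
                  lateral_layer = 1L, medial_layer = 2L,
                  mat_id = a$maps$mat_id),
    synergist = list(node_sets = shift_sets, fascicle_grid = syn_grid,
                     lateral_layer = 2L, medial_layer = 1L,
                     mat_id = a$maps$mat_id + off))
  mesh$node_sets$synergist_proximal_end <- shift_sets$proximal_end
  mesh$node_sets$synergist_distal_end <- shift_sets$distal_end

  # intermuscular links between corresponding medial-face matrix nodes
  ta <- as.integer(a$maps$mat_id[, , 2])
  tb <- as.integer(b$maps$mat_id[, , 1]) + off
  if (max(abs(mesh$nodes[ta, ] - mesh$nodes[tb, ])) > 1e-12)
    stop("topology error: intermuscular node correspondence mismatch",
         call. = FALSE)
  mesh <- add_links(mesh, "intermuscular", ta, tb, lp$k_inter,
                    interface = rep(seq_len(g$n_parallel + 1L),
                                    times = g$n_series + 1L),
                    muscle = "pair")

  mesh <- add_fiber_matrix_links(mesh, lp)  # target interior pairs
  fi <- shift_sets$interior_fiber; mi <- shift_sets$interior_matrix
  if (length(fi))
    mesh <- add_links(mesh, "fiber_matrix", fi, mi, lp$k_fiber_matrix,
                      muscle = "synergist")
  mesh <- attach_extramuscular(mesh, lp, "lateral", muscle = "target")
  mesh <- attach_extramuscular(mesh, lp, "lateral", muscle = "synergist")
  mesh
}

#' Local fiber triad of an element
#'
#' Returns the orthonormal local coordinate frame of an element as a 3x3
#' matrix whose columns are the cross-fiber, fiber, and thickness
#' directions.  Muscle (ECM and myofiber) elements align direction 2 with
#' the aponeurosis-to-aponeurosis fascicle edge; aponeurosis elements are
#' isotropic and use the identity triad.
#'
#' @param mesh a `muscle_mesh`.
#' @param family `"ecm"`, `"myofiber"` or `"aponeurosis"`.
#' @param element element index within the family.
#' @return 3x3 rotation matrix (columns: local 1, 2, 3 in global frame).
#' @export
local_fiber_frame <- function(mesh, family = "myofiber", element = 1L) {
  fr <- mesh$frames[[family]]
  if (is.null(fr) || element < 1L || element > dim(fr)[3])
    stop("no such element", call. = FALSE)
  fr[, , element]
}

#' Muscle length along the proximo-distal axis
#'
#' Distance between the proximal and distal tendon end faces, measured
#' along the global X axis, in the given displacement state.
#'
#' @param mesh a `muscle_mesh`.
#' @param u displacement vector (3N, node-major) or NULL for the reference
#'   state.
#' @param muscle `"target"` or `"synergist"`.
#' @return Length in mm.
#' @export
muscle_length <- function(mesh, u = NULL, muscle = "target") {
  ns <- mesh$muscles[[muscle]]$node_sets
  x <- mesh$nodes[, 1]
  if (!is.null(u)) x <- x + u[3 * (seq_len(nrow(mesh$nodes)) - 1L) + 1L]
  mean(x[ns$distal_end]) - mean(x[ns$proximal_end])
}

#' @export
print.muscle_mesh <- function(x, ...) {
  cat("muscle_mesh:", nrow(x$nodes), "nodes;",
      paste(sprintf("%s=%d", names(x$families),
                    vapply(x$families, nrow, 1L)), collapse = ", "),
      "\n  links:", nrow(x$links),
      if (nrow(x$links)) paste0("(", paste(sprintf(
        "%s=%d", names(table(x$links$kind)), table(x$links$kind)),
        collapse = ", "), ")") else "", "\n")
  invisible(x)
}
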