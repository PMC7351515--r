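#' Extracellular-matrix material parameters
#'
#' Constants of the anisotropic exponential strain-energy function of the ECM
#' element and of its two-part volume-constancy penalty.  Defaults are the
#' model constants fitted to rat/dog experimental data: initial passive
#' stiffness `k`, exponential stiffness coefficients `a11`, `a22`, `a33` for
#' the local normal directions (1 = cross-fiber, 2 = fiber, 3 = thickness)
#' and `a12`, `a23`, `a31` for shear, and the solid/fluid volume penalty
#' weights `Ss` and `Sf`.
#'
#' Stress here is dimensionless: all stresses are normalized by the maximal
#' active fiber stress, so `k` and the penalty weights carry no units.
#'
#' @param k initial passive stiffness (> 0).
#' @param a11,a22,a33 normal-direction stiffness exponents; cross-fiber and
#'   thickness (`a11`, `a33`) are stiffer than the fiber direction (`a22`).
#' @param a12,a23,a31 shear stiffness exponents.
#' @param Ss penalty weight on the per-Gauss-point volume ratio (solid part).
#' @param Sf penalty weight on the element-mean volume ratio (fluid part).
#' @return An object of class `ecm_params`.
#' @export
#' @examples
#' p <- ecm_params()
#' p$k
ecm_params <- function(k = 0.05, a11 = 8.0, a22 = 6.0, a33 = 8.0,
                       a12 = 6.0, a23 = 6.0, a31 = 6.0,
                       Ss = 5.0, Sf = 20.0) {
  p <- list(k = k, a11 = a11, a22 = a22, a33 = a33,
            a12 = a12, a23 = a23, a31 = a31, Ss = Ss, Sf = Sf)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("ecm_params: field '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  structure(p, class = "ecm_params")
}

#' Myofiber material parameters
#'
#' Coefficients of the fiber-direction stress of the intracellular domain:
#' `b1`, `b2` shape the piecewise-exponential active length-force relation
#' (scaled so the maximal stress at optimum length is unity) and `b3` is the
#' activation level (0 passive, 1 maximal); `t1`, `t2`, `t3` are the
#' parabola coefficients of the intracellular passive (titin) tension.
#'
#' `clamp_titin` controls whether the titin parabola is clamped to
#' non-negative values.  As printed, the parabola evaluates to `t3 = -0.002`
#' at zero strain; clamping (the default) keeps the passive reference state
#' exactly stress-free so that an isometric passive muscle shows identically
#' zero strain.
#'
#' @param b1,b2 active stress shape coefficients (shortening / lengthening
#'   branch).
#' @param b3 activation level in `[0, 1]`.
#' @param t1,t2,t3 titin parabola coefficients.
#' @param clamp_titin clamp intracellular passive tension at zero from below.
#' @return An object of class `fiber_params`.
#' @export
fiber_params <- function(b1 = 30.0, b2 = -6.0, b3 = 1.0,
                         t1 = 0.522, t2 = 0.019, t3 = -0.002,
                         clamp_titin = TRUE) {
  num <- list(b1 = b1, b2 = b2, b3 = b3, t1 = t1, t2 = t2, t3 = t3)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("fiber_params: field '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  if (b3 < 0 || b3 > 1)
    stop("fiber_params: activation 'b3' must lie in [0, 1]", call. = FALSE)
  structure(c(num, list(clamp_titin = isTRUE(clamp_titin))),
            class = "fiber_params")
}

#' Aponeurosis material parameters
#'
#' Two-parameter Mooney-Rivlin law for the aponeurosis layers, with bulk
#' modulus derived as `kappa = 2 (a10 + a01) / (1 - 2 nu)`.  The bulk
#' modulus is always recomputed from `a10`, `a01` and `poisson` and cannot
#' be set independently.
#'
#' Defaults give a small-strain Young's modulus of about 130 in the
#' normalized stress units, roughly 70 times the passive fiber-direction
#' tangent stiffness of the muscle tissue at zero strain.  This keeps the
#' thin aponeurosis layers stiff enough for a representative
#' force-transmission role while retaining the myotendinous series
#' compliance through which a fixed-end, fully activated muscle shortens
#' its fascicles by the physiological ~10%.
#'
#' @param a10,a01 Mooney-Rivlin constants (normalized stress units, > 0).
#' @param poisson Poisson's ratio, in `[0, 0.5)`.
#' @return An object of class `apon_params` with derived field `bulk`.
#' @export
apon_params <- function(a10 = 20.0, a01 = 5.0, poisson = 0.3) {
  if (!is.numeric(a10) || a10 <= 0 || !is.numeric(a01) || a01 <= 0)
    stop("apon_params: 'a10' and 'a01' must be positive", call. = FALSE)
  if (!is.numeric(poisson) || poisson < 0 || poisson >= 0.5)
    stop("apon_params: 'poisson' must lie in [0, 0.5)", call. = FALSE)
  structure(list(a10 = a10, a01 = a01, poisson = poisson,
                 bulk = 2 * (a10 + a01) / (1 - 2 * poisson)),
            class = "apon_params")
}

#' Spring-link stiffness parameters
#'
#' Stiffnesses (unit force / mm) of the three kinds of elastic links:
#' trans-sarcolemmal fiber-matrix ties, extramuscular connections to
#' mechanical ground (with the `n_stiff_proximal` most proximal links --
#' representing the neurovascular tract -- stiffer than the rest), and
#' intermuscular connections between two adjacent muscles.
#'
#' @param k_extra_stiff stiffness of the proximal extramuscular links.
#' @param k_extra_compliant stiffness of the remaining extramuscular links.
#' @param k_inter intermuscular link stiffness.
#' @param n_stiff_proximal how many most-proximal extramuscular links use
#'   `k_extra_stiff`.
#' @param k_fiber_matrix stiffness of the fiber-matrix ties; high by default
#'   (100 x `k_extra_stiff`) so non-pathological links act as near-rigid.
#' @return An object of class `link_params`.
#' @export
link_params <- function(k_extra_stiff = 0.25, k_extra_compliant = 0.033,
                        k_inter = 0.2, n_stiff_proximal = 7L,
                        k_fiber_matrix = 25.0) {
  num <- list(k_extra_stiff = k_extra_stiff,
              k_extra_compliant = k_extra_compliant,
              k_inter = k_inter, k_fiber_matrix = k_fiber_matrix)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("link_params: field '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (k_extra_stiff <= k_extra_compliant)
    stop("link_params: 'k_extra_stiff' must exceed 'k_extra_compliant'",
         call. = FALSE)
  if (n_stiff_proximal < 0)
    stop("link_params: 'n_stiff_proximal' must be >= 0", call. = FALSE)
  structure(c(num, list(n_stiff_proximal = as.integer(n_stiff_proximal))),
            class = "link_params")
}

#' Bundle of all material parameter blocks
#'
#' @param ecm [ecm_params()] block.
#' @param fiber [fiber_params()] block.
#' @param apon [apon_params()] block.
#' @param fiber_stress_mode `"cauchy_pullback"` (default) converts the
#'   fiber-direction Cauchy stress to a local second Piola-Kirchhoff uniaxial
#'   stress through the fiber stretch and volume ratio before integration;
#'   `"pk2_direct"` uses it directly as local PK2 (the conservative variant).
#' @return An object of class `material_set`.
#' @export
material_set <- function(ecm = ecm_params(), fiber = fiber_params(),
                         apon = apon_params(),
                         fiber_stress_mode = c("cauchy_pullback",
                                               "pk2_direct")) {
  stopifnot(inherits(ecm, "ecm_params"), inherits(fiber, "fiber_params"),
            inherits(apon, "apon_params"))
  structure(list(ecm = ecm, fiber = fiber, apon = apon,
                 fiber_stress_mode = match.arg(fiber_stress_mode)),
            class = "material_set")
}

#' Muscle geometry parameters
#'
#' Parameterization of the unipennate, extruded longitudinal-slice geometry.
#' The global frame is X = proximo-distal axis (distal positive), Y = the
#' in-plane axis across the muscle belly, Z = slice thickness.  Fascicles
#' run from the proximal aponeurosis (upper contour line) to the distal
#' aponeurosis (lower line) at a small pennation angle set by the axial
#' fascicle span against the belly height.
#'
#' Defaults approximate a rat extensor digitorum longus muscle belly:
#' 28.7 mm long, fascicle length about one third of muscle length, a
#' pennation angle of roughly 13 degrees, and a gently curved, slightly
#' asymmetric belly contour.
#'
#' @param initial_length muscle length, mm (proximal to distal end).
#' @param n_series muscle elements in series per fascicle.
#' @param n_parallel fascicles in parallel.
#' @param belly_height in-plane distance between the aponeurosis contour
#'   lines, mm.
#' @param fascicle_span axial (X) span of each fascicle, mm; sets pennation.
#' @param belly_bulge mid-belly outward bow of the upper contour line, mm.
#' @param belly_tilt proximo-distal asymmetry of the upper line, mm (the
#'   proximal side is taller for negative values).
#' @param slice_thickness extruded thickness, mm.
#' @param apon_thickness aponeurosis layer thickness at the muscle-belly
#'   end, mm.
#' @param apon_thickness_factor thickness growth factor toward the tendon
#'   end.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(initial_length = 28.7, n_series = 3L,
                            n_parallel = 16L, belly_height = 2.2,
                            fascicle_span = 9.4, belly_bulge = 0.3,
                            belly_tilt = -0.4, slice_thickness = 3.0,
                            apon_thickness = 0.15,
                            apon_thickness_factor = 3.0) {
  if (!is.numeric(initial_length) || initial_length <= 0)
    stop("geometry_params: 'initial_length' must be positive", call. = FALSE)
  n_series <- as.integer(n_series); n_parallel <- as.integer(n_parallel)
  if (n_series < 1L || n_parallel < 1L)
    stop("geometry_params: 'n_series' and 'n_parallel' must be >= 1",
         call. = FALSE)
  for (nm in c("belly_height", "fascicle_span", "slice_thickness",
               "apon_thickness")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0)
      stop("geometry_params: '", nm, "' must be positive", call. = FALSE)
  }
  if (fascicle_span >= initial_length)
    stop("geometry_params: 'fascicle_span' must be smaller than ",
         "'initial_length' (the contour would self-intersect)",
         call. = FALSE)
  if (apon_thickness_factor < 1)
    stop("geometry_params: 'apon_thickness_factor' must be >= 1",
         call. = FALSE)
  structure(list(initial_length = initial_length, n_series = n_series,
                 n_parallel = n_parallel, belly_height = belly_height,
                 fascicle_span = fascicle_span, belly_bulge = belly_bulge,
                 belly_tilt = belly_tilt, slice_thickness = slice_thickness,
                 apon_thickness = apon_thickness,
                 apon_thickness_factor = apon_thickness_factor),
            class = "geometry_params")
}
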