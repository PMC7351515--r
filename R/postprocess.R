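# Post-processing: fiber-direction strain grids over the fascicle sampling
# planes, epimuscular myofascial load reports, and proximo-distal force
# balance summaries.

# Gauss-to-node extrapolation matrix for the 2x2x2 rule (8 nodes x 8 gp)
.gauss_extrapolation <- function() {
  gp_sign <- sign(.HEXQ$points)
  nl <- .HEXQ$nodes_local
  M <- matrix(0, 8, 8)
  for (n in 1:8) for (g in 1:8)
    M[n, g] <- prod((1 + nl[n, ] * gp_sign[g, ] * sqrt(3)) / 2)
  M
}
.GEXT <- .gauss_extrapolation()

.check_converged <- function(solution) {
  if (!inherits(solution, "lfmm_solution"))
    stop("expected an 'lfmm_solution'", call. = FALSE)
  if (!isTRUE(solution$converged) ||
      !is.finite(solution$residual_ratio) ||
      solution$residual_ratio > solution$control$tol)
    stop("solution is not converged (residual ratio ",
         signif(solution$residual_ratio, 3), "); refusing to report",
         call. = FALSE)
  invisible(solution)
}

# nodal fiber-direction strain of the fiber mesh: Gauss values extrapolated
# to element corners, then averaged over the elements sharing each node
.nodal_fiber_strain <- function(mesh, u) {
  fam <- family_precompute(mesh, "myofiber")
  eg <- family_fiber_strain(fam, u)          # nel x 8 Gauss values
  en <- eg %*% t(.GEXT)                      # nel x 8 corner values
  n_nodes <- nrow(mesh$nodes)
  acc <- cnt <- numeric(n_nodes)
  for (n in 1:8) {
    tab <- rowsum(en[, n], fam$conn[, n])
    ids <- as.integer(rownames(tab))
    acc[ids] <- acc[ids] + tab[, 1]
    tabc <- rowsum(rep(1, fam$nel), fam$conn[, n])
    cnt[ids] <- cnt[ids] + tabc[, 1]
  }
  ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
}

.roman_sections <- function(n) as.character(utils::as.roman(seq_len(n)))

#' Fiber-direction strain report
#'
#' Green-Lagrange fiber-direction strain of the fiber mesh at every
#' fascicle sampling node: per face (lateral / medial), per serial fascicle
#' section plane (I = proximal ... ordered toward the distal attachment),
#' per fascicle interface.  Gauss-point strains of the myofiber elements
#' are extrapolated to the nodal planes and averaged over adjacent
#' elements.  Zero strain corresponds to the undeformed sarcomere state of
#' the passive muscle at initial length.
#'
#' @param solution a converged [newton_solve()] result.
#' @param muscle `"target"` or `"synergist"` (epimuscular pair).
#' @return Object of class `strain_report`: a data frame with columns
#'   `face`, `section`, `interface`, `strain` (dimensionless) and
#'   `strain_pct`, with a per-section summary in
#'   `attr(, "section_summary")`.
#' @export
fiber_strain_report <- function(solution, muscle = "target") {
  .check_converged(solution)
  mesh <- solution$mesh
  ms <- mesh$muscles[[muscle]]
  if (is.null(ms)) stop("unknown muscle '", muscle, "'", call. = FALSE)
  nodal <- .nodal_fiber_strain(mesh, solution$u)
  ns <- mesh$n_series; np <- mesh$n_parallel
  secs <- .roman_sections(ns + 1L)
  out <- do.call(rbind, lapply(c("lateral", "medial"), function(fc) {
    ids <- ms$fascicle_grid[[fc]]        # sections x interfaces
    data.frame(face = fc,
               section = rep(secs, times = np + 1L),
               interface = rep(seq_len(np + 1L), each = ns + 1L),
               strain = as.numeric(nodal[ids]))
  }))
  if (anyNA(out$strain))
    stop("incomplete strain grid: sampling node without adjacent myofiber ",
         "element", call. = FALSE)
  out$strain_pct <- 100 * out$strain
  summ <- do.call(rbind, lapply(split(out, out$section), function(d)
    data.frame(section = d$section[1], min = min(d$strain),
               max = max(d$strain), mean = mean(d$strain))))
  summ <- summ[order(match(summ$section, secs)), ]
  rownames(summ) <- NULL
  structure(out, class = c("strain_report", "data.frame"),
            section_summary = summ, muscle = muscle)
}

# proximally-pointing unit fiber direction per fascicle interface
.interface_fiber_dirs <- function(mesh, muscle = "target") {
  ms <- mesh$muscles[[muscle]]
  mat_id <- if (!is.null(ms$mat_id)) ms$mat_id else mesh$maps$mat_id
  ns <- mesh$n_series
  topn <- mesh$nodes[mat_id[, 1L, 1L], , drop = FALSE]
  botn <- mesh$nodes[mat_id[, ns + 1L, 1L], , drop = FALSE]
  d <- topn - botn
  d[, 3] <- 0
  d / sqrt(rowSums(d^2))
}

#' Epimuscular myofascial load report
#'
#' Projects the force exerted on the muscle by each extramuscular and
#' intermuscular link onto the local fiber direction at its attachment
#' interface, for the three cases of one model variant, and normalizes all
#' values by the single largest magnitude observed across the three cases.
#' Positive fiber-direction components are proximally directed.
#'
#' @param solutions named list of converged solutions for cases
#'   `I`, `II`, `III` of the same model variant.
#' @param muscle muscle whose loads are reported.
#' @return Object of class `load_report`: data frame with one row per
#'   link and case (`case`, `kind`, `interface`, `node`,
#'   `fiber_component`, `normalized`, `direction`); the normalization
#'   constant is in `attr(, "normalization")`.  Empty for the isolated
#'   variant.
#' @export
myofascial_load_report <- function(solutions, muscle = "target") {
  stopifnot(is.list(solutions), length(solutions) >= 1)
  for (s in solutions) .check_converged(s)
  variants <- vapply(solutions, function(s) s$scenario$model_variant, "")
  if (length(unique(variants)) != 1L)
    stop("all solutions must share one model variant", call. = FALSE)
  mesh <- solutions[[1]]$mesh
  rows <- lapply(names(solutions), function(nm) {
    sol <- solutions[[nm]]
    lf <- link_forces(sol$mesh, sol$u)
    epi <- lf$kind %in% c("extramuscular", "intermuscular") &
      (lf$muscle %in% c(muscle, "pair"))
    lf <- lf[epi, , drop = FALSE]
    if (nrow(lf) == 0L) return(NULL)
    dirs <- .interface_fiber_dirs(sol$mesh, muscle)
    d <- dirs[lf$interface, , drop = FALSE]
    comp <- lf$fx * d[, 1] + lf$fy * d[, 2] + lf$fz * d[, 3]
    data.frame(case = nm, kind = lf$kind, interface = lf$interface,
               node = lf$node_a, fiber_component = comp)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(case = character(0), kind = character(0),
                      interface = integer(0), node = integer(0),
                      fiber_component = numeric(0))
  norm_const <- if (nrow(out)) max(abs(out$fiber_component)) else NA_real_
  out$normalized <- if (nrow(out) && norm_const > 0)
    out$fiber_component / norm_const else numeric(nrow(out))
  out$direction <- ifelse(out$fiber_component >= 0, "proximal", "distal")
  structure(out, class = c("load_report", "data.frame"),
            normalization = norm_const, muscle = muscle)
}

#' Proximo-distal force balance
#'
#' Axial (X) reaction force sums at the proximal and distal tendon ends,
#' their net out-of-balance, and the summed axial component of the
#' myofascial (extramuscular + intermuscular) link forces acting on the
#' muscle.  At equilibrium the proximo-distal force difference equals the
#' net axial myofascial load; for the isolated muscle both vanish and the
#' two tendon forces are equal and opposite.
#'
#' @param solution a converged solution.
#' @param muscle muscle to balance.
#' @return List: `proximal_reaction`, `distal_reaction`,
#'   `difference` (`-(proximal + distal)`), `net_link_axial`, and
#'   `closure` (their mismatch, which should be within solver tolerance).
#' @export
proximo_distal_balance <- function(solution, muscle = "target") {
  .check_converged(solution)
  mesh <- solution$mesh
  ns <- mesh$muscles[[muscle]]$node_sets
  rx <- function(nodes) sum(solution$reactions[3 * (nodes - 1L) + 1L])
  pr <- rx(ns$proximal_end); di <- rx(ns$distal_end)
  lf <- link_forces(mesh, solution$u)
  epi <- lf$kind %in% c("extramuscular", "intermuscular") &
    lf$muscle %in% c(muscle, "pair")
  net_link <- if (any(epi)) sum(lf$fx[epi]) else 0
  list(proximal_reaction = pr, distal_reaction = di,
       difference = -(pr + di), net_link_axial = net_link,
       closure = -(pr + di) - net_link)
}

#' @export
print.strain_report <- function(x, ...) {
  cat("fiber-direction strain grid (", attr(x, "muscle"), " muscle): ",
      nrow(x), " cells\n", sep = "")
  print(attr(x, "section_summary"))
  invisible(x)
}

#' @export
print.load_report <- function(x, ...) {
  cat("myofascial load report:", nrow(x), "link forces; normalization",
      signif(attr(x, "normalization"), 4), "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 8))
  invisible(x)
}
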