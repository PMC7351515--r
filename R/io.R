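# Plain-text exports: legacy-ASCII VTK unstructured grids for visual
# inspection of deformed states, and CSV dumps of nodes/elements.

#' Write the mesh as a legacy ASCII VTK unstructured grid
#'
#' All element families are written as hexahedral cells with cell data
#' identifying the family and, for muscle elements, the local fiber
#' direction; optional extra per-cell scalars (e.g. fiber strain) can be
#' supplied per family.
#'
#' @param mesh a `muscle_mesh`.
#' @param file output path.
#' @param u optional displacement vector; when given, deformed coordinates
#'   are written.
#' @param cell_scalars optional named list (by family) of per-element
#'   scalar vectors, written as cell data `scalar`.
#' @return Invisibly, the file path.
#' @export
write_vtk <- function(mesh, file, u = NULL, cell_scalars = NULL) {
  pts <- mesh$nodes
  if (!is.null(u)) pts <- pts + matrix(u, ncol = 3, byrow = TRUE)
  fams <- names(mesh$families)
  conns <- do.call(rbind, mesh$families[fams])
  nel <- nrow(conns)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "linked fiber-matrix mesh muscle model", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(pts))), con)
  utils::write.table(format(pts, digits = 10, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nel, 9 * nel), con)
  utils::write.table(cbind(8L, conns - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  writeLines(as.character(rep(12L, nel)), con)
  writeLines(sprintf("CELL_DATA %d", nel), con)
  writeLines(c("SCALARS family int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(rep(seq_along(fams),
                              vapply(mesh$families[fams], nrow, 1L))), con)
  writeLines("VECTORS fiber_direction double", con)
  dirs <- do.call(rbind, lapply(fams, function(f) {
    fr <- mesh$frames[[f]]
    t(vapply(seq_len(dim(fr)[3]), function(e) fr[, 2, e], numeric(3)))
  }))
  utils::write.table(format(dirs, digits = 8), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(cell_scalars)) {
    vals <- unlist(lapply(fams, function(f) {
      v <- cell_scalars[[f]]
      if (is.null(v)) rep(NA_real_, nrow(mesh$families[[f]])) else v
    }))
    writeLines(c("SCALARS scalar double 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(ifelse(is.na(vals), 0, vals)), con)
  }
  invisible(file)
}

#' Dump nodes and elements as CSV
#'
#' @param mesh a `muscle_mesh`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_mesh_csv <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  np <- file.path(dir, "nodes.csv")
  utils::write.csv(data.frame(node = seq_len(nrow(mesh$nodes)),
                              x = mesh$nodes[, 1], y = mesh$nodes[, 2],
                              z = mesh$nodes[, 3]), np, row.names = FALSE)
  ep <- file.path(dir, "elements.csv")
  el <- do.call(rbind, lapply(names(mesh$families), function(f) {
    conn <- mesh$families[[f]]
    if (nrow(conn) == 0L) return(NULL)
    data.frame(family = f, element = seq_len(nrow(conn)),
               setNames(as.data.frame(conn), paste0("n", 1:8)))
  }))
  utils::write.csv(el, ep, row.names = FALSE)
  lp <- file.path(dir, "links.csv")
  utils::write.csv(mesh$links, lp, row.names = FALSE)
  invisible(c(np, ep, lp))
}
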