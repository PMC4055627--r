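## Minimal base-graphics rendering of meshes and inferred forces.

#' Plot a CellMesh, optionally colored by inferred forces
#'
#' Edges are drawn as their node chains, colored by Standard Tension when a
#' solution is supplied; cell centroids are colored by Standard Pressure.
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param solution optional \code{\linkS4class{ForceSolution}}.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotMesh <- function(mesh, solution = NULL, ...) {
  plot(mesh@nodes$x, mesh@nodes$y, type = "n", asp = 1,
       xlab = "x", ylab = "y", ...)
  cols <- "grey30"
  if (!is.null(solution)) {
    g <- standardTensions(solution)
    pal <- hcl.colors(64, "Viridis")
    idx <- pmin(64L, pmax(1L, as.integer(
      1 + 63 * (g - min(g)) / max(diff(range(g)), 1e-12))))
    cols <- setNames(pal[idx], names(g))
  }
  for (i in seq_len(nrow(mesh@edges))) {
    id <- as.character(mesh@edges$id[i])
    xy <- nodeXY(mesh, mesh@chains[[id]])
    col <- if (length(cols) > 1L && id %in% names(cols)) cols[[id]] else cols[[1L]]
    graphics::lines(xy[, 1L], xy[, 2L], col = col,
                    lwd = if (mesh@edges$stub[i]) 1 else 2)
  }
  if (!is.null(solution) && length(standardPressures(solution))) {
    p <- standardPressures(solution)
    cc <- intersect(names(p),
                    as.character(mesh@cells$id[!mesh@cells$partial &
                                                 !mesh@cells$medium]))
    if (length(cc)) {
      cent <- t(vapply(as.integer(cc), function(c)
        .polyCentroid(cellPolygon(mesh, c)), numeric(2)))
      pal <- hcl.colors(64, "Blue-Red 3")
      idx <- pmin(64L, pmax(1L, as.integer(
        1 + 63 * (p[cc] - min(p[cc])) / max(diff(range(p[cc])), 1e-12))))
      points(cent[, 1L], cent[, 2L], pch = 16, cex = 1.2, col = pal[idx])
    }
  }
  invisible(NULL)
}
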