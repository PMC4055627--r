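## Generics. Accessor and analysis verbs used across the package.

#' Number of cells, edges, junctions
#'
#' @param x a \code{\linkS4class{CellMesh}}.
#' @return integer(1).
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname nCells
#' @export
setGeneric("nJunctions", function(x) standardGeneric("nJunctions"))

#' Mesh component tables
#'
#' Accessors for the node, edge, cell and junction tables of a
#' \code{\linkS4class{CellMesh}}, the per-edge node chains and per-cell edge
#' lists.
#'
#' @param x a \code{\linkS4class{CellMesh}}.
#' @return A data.frame (\code{meshNodes}, \code{meshEdges}, \code{meshCells},
#'   \code{meshJunctions}) or a named list (\code{meshChains},
#'   \code{meshCellEdges}).
#' @export
setGeneric("meshNodes", function(x) standardGeneric("meshNodes"))

#' @rdname meshNodes
#' @export
setGeneric("meshEdges", function(x) standardGeneric("meshEdges"))

#' @rdname meshNodes
#' @export
setGeneric("meshCells", function(x) standardGeneric("meshCells"))

#' @rdname meshNodes
#' @export
setGeneric("meshJunctions", function(x) standardGeneric("meshJunctions"))

#' @rdname meshNodes
#' @export
setGeneric("meshChains", function(x) standardGeneric("meshChains"))

#' @rdname meshNodes
#' @export
setGeneric("meshCellEdges", function(x) standardGeneric("meshCellEdges"))

#' Tally equation and unknown counts
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param excludedEdges integer vector of edge ids to exclude from analysis.
#' @return a \code{\linkS4class{MeshCounts}}.
#' @export
setGeneric("tallyCounts", function(mesh, excludedEdges = integer())
  standardGeneric("tallyCounts"))

#' Standard Tensions and Standard Pressures of a solution
#'
#' @param x a \code{\linkS4class{ForceSolution}}.
#' @return named numeric vector (per edge id / per cell id).
#' @export
setGeneric("standardTensions", function(x) standardGeneric("standardTensions"))

#' @rdname standardTensions
#' @export
setGeneric("standardPressures", function(x) standardGeneric("standardPressures"))
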