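## Mesh JSON serialization.
## Schema: {"length_scale": float,
##          "nodes":  [{"id", "x", "y"}],
##          "edges":  [{"id", "junctions": [a, b], "chain": [node ids],
##                      "cells": [left, right], "stub": bool}],
##          "cells":  [{"id", "edges": [...], "partial": bool,
##                      "medium": bool}]}
## The medium is encoded as cell id 0.

#' Write a CellMesh to JSON
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @seealso \code{\link{readMeshJSON}}
#' @export
writeMeshJSON <- function(mesh, path) {
  ed <- mesh@edges
  obj <- list(
    length_scale = mesh@lengthScale,
    nodes = lapply(seq_len(nrow(mesh@nodes)), function(i)
      list(id = mesh@nodes$id[i], x = mesh@nodes$x[i], y = mesh@nodes$y[i])),
    edges = lapply(seq_len(nrow(ed)), function(i)
      list(id = ed$id[i],
           junctions = c(ed$j1[i], ed$j2[i]),
           chain = mesh@chains[[as.character(ed$id[i])]],
           cells = c(ed$cellLeft[i], ed$cellRight[i]),
           stub = ed$stub[i])),
    cells = lapply(seq_len(nrow(mesh@cells)), function(i)
      list(id = mesh@cells$id[i],
           edges = mesh@cellEdges[[as.character(mesh@cells$id[i])]],
           partial = mesh@cells$partial[i],
           medium = mesh@cells$medium[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

.require <- function(x, key, where) {
  if (is.null(x[[key]])) stop(sprintf("mesh JSON schema error: missing '%s' in %s",
                                      key, where))
  x[[key]]
}

#' Read a CellMesh from JSON
#'
#' Performs schema validation (missing keys are reported with their path)
#' and rebuilds the mesh, re-deriving junctions and stub flags from the
#' topology.  A write/read round trip is lossless.
#'
#' @param path JSON file path.
#' @return a \code{\linkS4class{CellMesh}}.
#' @export
readMeshJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("nodes", "edges", "cells"))
    if (is.null(obj[[key]]))
      stop(sprintf("mesh JSON schema error: missing '%s'", key))
  ls <- if (is.null(obj$length_scale)) 1 else obj$length_scale
  nodes <- data.frame(
    id = vapply(obj$nodes, function(n) as.integer(.require(n, "id", "nodes")),
                integer(1)),
    x = vapply(obj$nodes, function(n) as.numeric(.require(n, "x", "nodes")),
               numeric(1)),
    y = vapply(obj$nodes, function(n) as.numeric(.require(n, "y", "nodes")),
               numeric(1)))
  edges <- data.frame(
    id = vapply(obj$edges, function(e) as.integer(.require(e, "id", "edges")),
                integer(1)),
    cellLeft = vapply(obj$edges, function(e)
      as.integer(.require(e, "cells", "edges")[[1L]]), integer(1)),
    cellRight = vapply(obj$edges, function(e)
      as.integer(.require(e, "cells", "edges")[[2L]]), integer(1)))
  chains <- setNames(lapply(obj$edges, function(e)
    as.integer(unlist(.require(e, "chain", "edges")))),
    as.character(edges$id))
  cells <- data.frame(
    id = vapply(obj$cells, function(c) as.integer(.require(c, "id", "cells")),
                integer(1)),
    partial = vapply(obj$cells, function(c)
      isTRUE(.require(c, "partial", "cells")), logical(1)),
    medium = vapply(obj$cells, function(c)
      isTRUE(.require(c, "medium", "cells")), logical(1)))
  cellEdges <- setNames(lapply(obj$cells, function(c)
    as.integer(unlist(c$edges))), as.character(cells$id))
  buildMesh(nodes, edges, cells, chains, cellEdges, ls)
}
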