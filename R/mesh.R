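## CellMesh construction, validation, accessors and topology analysis.

## ---- internal helpers -------------------------------------------------------

.nodeIndex <- function(mesh, ids) {
  idx <- match(ids, mesh@nodes$id)
  if (anyNA(idx)) stop("unknown node id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

## n x 2 matrix of node coordinates for a vector of node ids
nodeXY <- function(mesh, ids) {
  idx <- .nodeIndex(mesh, ids)
  cbind(x = mesh@nodes$x[idx], y = mesh@nodes$y[idx])
}

.chainOf <- function(mesh, edgeId) mesh@chains[[as.character(edgeId)]]

## ordered node cycle of a cell, walking its (ordered) edge loop.
## Each chain is traversed forward when the cell is its left cell, reversed
## otherwise; shared junction nodes are not duplicated.
cellLoopNodes <- function(mesh, cellId) {
  eids <- mesh@cellEdges[[as.character(cellId)]]
  out <- integer(0)
  for (e in eids) {
    er <- mesh@edges[match(e, mesh@edges$id), ]
    ch <- .chainOf(mesh, e)
    if (!identical(er$cellLeft, as.integer(cellId)) &&
        isTRUE(er$cellRight == cellId)) ch <- rev(ch)
    if (length(out) && out[length(out)] == ch[1L]) ch <- ch[-1L]
    out <- c(out, ch)
  }
  if (length(out) > 1L && out[1L] == out[length(out)]) out <- out[-length(out)]
  out
}

cellPolygon <- function(mesh, cellId) nodeXY(mesh, cellLoopNodes(mesh, cellId))

shoelaceArea <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  i2 <- c(2:n, 1L)
  0.5 * sum(xy[, 1L] * xy[i2, 2L] - xy[i2, 1L] * xy[, 2L])
}

cellArea <- function(mesh, cellId) abs(shoelaceArea(cellPolygon(mesh, cellId)))

## mean over complete cells of sqrt(area / pi)
meanCellRadius <- function(mesh) {
  cc <- mesh@cells$id[!mesh@cells$partial & !mesh@cells$medium]
  if (!length(cc)) return(NA_real_)
  mean(vapply(cc, function(c) sqrt(cellArea(mesh, c) / pi), numeric(1)))
}

## ---- validity ---------------------------------------------------------------

.validCellMesh <- function(object) {
  msg <- character(0)
  nd <- object@nodes; ed <- object@edges; cl <- object@cells
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicated node ids")
  if (!all(is.finite(nd$x)) || !all(is.finite(nd$y)))
    msg <- c(msg, "non-finite node coordinates")
  if (anyDuplicated(ed$id)) msg <- c(msg, "duplicated edge ids")
  if (anyDuplicated(cl$id)) msg <- c(msg, "duplicated cell ids")
  if (sum(cl$medium) > 1L) msg <- c(msg, "more than one medium cell")
  if (any(cl$medium & cl$id != MEDIUM))
    msg <- c(msg, "medium cell must have id 0")
  if (any(cl$medium & !cl$partial))
    msg <- c(msg, "medium cell must be partial")
  allNodes <- nd$id
  for (i in seq_len(nrow(ed))) {
    ch <- object@chains[[as.character(ed$id[i])]]
    if (length(ch) < 2L) msg <- c(msg, sprintf("edge %d chain too short", ed$id[i]))
    if (!all(ch %in% allNodes))
      msg <- c(msg, sprintf("edge %d references undeclared node(s)", ed$id[i]))
    if (identical(ed$cellLeft[i], ed$cellRight[i]))
      msg <- c(msg, sprintf("edge %d has identical side cells", ed$id[i]))
    for (s in c(ed$cellLeft[i], ed$cellRight[i]))
      if (!is.na(s) && !(s %in% cl$id))
        msg <- c(msg, sprintf("edge %d references undeclared cell %d", ed$id[i], s))
  }
  ## each cell must claim only edges that list it as a side
  for (k in seq_len(nrow(cl))) {
    cid <- cl$id[k]
    eids <- object@cellEdges[[as.character(cid)]]
    if (!all(eids %in% ed$id)) {
      msg <- c(msg, sprintf("cell %d references undeclared edge(s)", cid)); next
    }
    ei <- match(eids, ed$id)
    owned <- ed$cellLeft[ei] == cid | ed$cellRight[ei] == cid
    if (!all(owned, na.rm = TRUE) || anyNA(owned))
      msg <- c(msg, sprintf("cell %d claims an edge that does not border it", cid))
    ## complete cells: ordered edges must form one closed loop with
    ## consistent sidedness (cell on the left going forward)
    if (!cl$partial[k] && !cl$medium[k] && length(msg) == 0L) {
      path <- tryCatch(cellLoopNodes(object, cid), error = function(e) NULL)
      first <- integer(length(eids)); last <- integer(length(eids))
      ok <- TRUE
      prevEnd <- NA_integer_
      for (j in seq_along(eids)) {
        ch <- object@chains[[as.character(eids[j])]]
        if (ed$cellLeft[ei[j]] != cid) ch <- rev(ch)
        if (j > 1L && ch[1L] != prevEnd) ok <- FALSE
        prevEnd <- ch[length(ch)]
      }
      ch1 <- object@chains[[as.character(eids[1L])]]
      if (ed$cellLeft[ei[1L]] != cid) ch1 <- rev(ch1)
      if (!identical(prevEnd, ch1[1L])) ok <- FALSE
      if (!ok || is.null(path))
        msg <- c(msg, sprintf("cell %d boundary is not a single closed loop", cid))
    }
  }
  ## junction bookkeeping
  for (j in seq_len(nrow(object@junctions))) {
    jid <- object@junctions$id[j]
    inc <- object@junctionEdges[[as.character(jid)]]
    if (length(inc) < 2L) msg <- c(msg, sprintf("junction %d has order < 2", jid))
    ei <- match(inc, ed$id)
    if (!all(ed$j1[ei] == jid | ed$j2[ei] == jid, na.rm = TRUE))
      msg <- c(msg, sprintf("junction %d incidence inconsistent", jid))
  }
  if (length(msg)) msg else TRUE
}

setValidity("CellMesh", .validCellMesh)

## ---- construction -----------------------------------------------------------

#' Build a CellMesh from node, edge and cell tables
#'
#' Junctions are derived, not declared: a node is a junction when at least two
#' edge endpoints meet there.  An edge whose chain terminates at a node with a
#' single incident edge end is a stub (truncated by the region of interest);
#' an edge with no junction endpoint at all is rejected.
#'
#' @param nodes data.frame with columns \code{id}, \code{x}, \code{y}.
#' @param edges data.frame with columns \code{id}, \code{cellLeft},
#'   \code{cellRight} (cell ids; 0 denotes the medium) and a list-column or
#'   companion list \code{chains} of node-id vectors.  The chain is ordered so
#'   \code{cellLeft} lies to the left of the direction of travel.
#' @param cells data.frame with columns \code{id}, \code{partial},
#'   \code{medium}.
#' @param chains named list of integer node-id vectors, one per edge id
#'   (names must be the edge ids).
#' @param cellEdges named list of edge-id vectors, one per cell id; ordered
#'   boundary loops for complete cells.
#' @param lengthScale physical length units per coordinate unit.
#' @return a validated \code{\linkS4class{CellMesh}}.
#' @examples
#' ## three stub edges radiating from one junction (a single triple junction)
#' m <- starMesh(3)
#' nJunctions(m)  # 1
#' @export
buildMesh <- function(nodes, edges, cells, chains, cellEdges, lengthScale = 1) {
  nodes <- data.frame(id = as.integer(nodes$id),
                      x = as.numeric(nodes$x), y = as.numeric(nodes$y))
  edges <- data.frame(id = as.integer(edges$id),
                      cellLeft = as.integer(edges$cellLeft),
                      cellRight = as.integer(edges$cellRight))
  cells <- data.frame(id = as.integer(cells$id),
                      partial = as.logical(cells$partial),
                      medium = as.logical(cells$medium))
  chains <- lapply(chains, as.integer)
  if (is.null(names(chains)) || !setequal(names(chains), as.character(edges$id)))
    stop("'chains' must be named by edge id, one entry per edge")
  chains <- chains[as.character(edges$id)]
  if (is.null(names(cellEdges)) || !setequal(names(cellEdges), as.character(cells$id)))
    stop("'cellEdges' must be named by cell id, one entry per cell")
  cellEdges <- lapply(cellEdges[as.character(cells$id)], as.integer)

  ## derive junctions from endpoint incidence
  ends1 <- vapply(chains, function(ch) ch[1L], integer(1))
  ends2 <- vapply(chains, function(ch) ch[length(ch)], integer(1))
  if (!all(c(ends1, ends2) %in% nodes$id))
    stop("edge chain endpoint references a missing node id")
  cnt <- table(c(ends1, ends2))
  jnodes <- as.integer(names(cnt)[cnt >= 2L])
  j1 <- ifelse(ends1 %in% jnodes, ends1, NA_integer_)
  j2 <- ifelse(ends2 %in% jnodes, ends2, NA_integer_)
  if (any(is.na(j1) & is.na(j2)))
    stop("edge with no junction endpoint (dangling edge): id ",
         paste(edges$id[is.na(j1) & is.na(j2)], collapse = ", "))
  edges$j1 <- as.integer(j1); edges$j2 <- as.integer(j2)
  edges$stub <- is.na(j1) | is.na(j2)

  junctionEdges <- lapply(jnodes, function(j)
    edges$id[!is.na(edges$j1) & edges$j1 == j | !is.na(edges$j2) & edges$j2 == j])
  ## count with multiplicity (an edge may loop back to the same junction)
  ord <- vapply(jnodes, function(j)
    sum(edges$j1 == j, na.rm = TRUE) + sum(edges$j2 == j, na.rm = TRUE), integer(1))
  junctions <- data.frame(id = jnodes, order = ord)
  names(junctionEdges) <- as.character(jnodes)

  new("CellMesh", nodes = nodes, edges = edges, chains = chains,
      cells = cells, cellEdges = cellEdges, junctions = junctions,
      junctionEdges = junctionEdges, lengthScale = as.numeric(lengthScale))
}

## ---- accessors and show -----------------------------------------------------

#' @rdname nCells
setMethod("nCells", "CellMesh", function(x) sum(!x@cells$medium))
#' @rdname nCells
setMethod("nEdges", "CellMesh", function(x) nrow(x@edges))
#' @rdname nCells
setMethod("nJunctions", "CellMesh", function(x) nrow(x@junctions))

#' @rdname meshNodes
setMethod("meshNodes", "CellMesh", function(x) x@nodes)
#' @rdname meshNodes
setMethod("meshEdges", "CellMesh", function(x) x@edges)
#' @rdname meshNodes
setMethod("meshCells", "CellMesh", function(x) x@cells)
#' @rdname meshNodes
setMethod("meshJunctions", "CellMesh", function(x) x@junctions)
#' @rdname meshNodes
setMethod("meshChains", "CellMesh", function(x) x@chains)
#' @rdname meshNodes
setMethod("meshCellEdges", "CellMesh", function(x) x@cellEdges)

setMethod("show", "CellMesh", function(object) {
  cl <- object@cells
  cat("CellMesh:", nrow(object@nodes), "nodes,", nrow(object@edges), "edges",
      sprintf("(%d stubs),", sum(object@edges$stub)),
      sum(!cl$partial & !cl$medium), "complete +",
      sum(cl$partial & !cl$medium), "partial cells",
      if (any(cl$medium)) "+ medium" else "", "\n")
  ord <- table(object@junctions$order)
  cat("  junctions:", nrow(object@junctions),
      paste(sprintf("[order %s: %d]", names(ord), as.integer(ord)), collapse = " "),
      "\n")
  cat("  length scale:", object@lengthScale, "per unit\n")
})

setMethod("show", "MeshCounts", function(object) {
  s <- function(n) methods::slot(object, n)
  cat("MeshCounts\n")
  cat(sprintf("  tensions: %d unknowns, %d equations (junctions %d, removed %d)\n",
              s("nTensions"), s("nTensionEqns"), s("nJunctions"), s("nJunctionsRemoved")))
  cat(sprintf("  pressures: %d unknowns, %d equations\n",
              s("nPressures"), s("nPressureEqns")))
  cat(sprintf("  cells: %d complete, %d partial; stubs %d; DJs %d; excess edges %d; removed edges %d\n",
              s("nCompleteCells"), s("nPartialCells"), s("nStubs"),
              s("nDoubleJunctions"), s("nExcessEdges"), s("nRemovedEdges")))
})

## ---- tallies ----------------------------------------------------------------

#' @rdname tallyCounts
#' @details All counts are obtained by direct enumeration of the pre-removal
#'   topology.  Excluding an edge removes the x/y force balances of both its
#'   endpoint junctions (as if those junctions did not exist), so
#'   \code{nTensionEqns = 2 *} (junctions not incident to an excluded edge).
#'   Stub edges keep their tension unknowns but contribute no pressure
#'   equations; edges without intermediate chain nodes carry no usable
#'   curvature and are likewise not counted in \code{nPressureEqns}.
#' @examples
#' m <- starMesh(3)
#' tallyCounts(m)   # 2 tension equations over 3 unknowns
#' @export
setMethod("tallyCounts", "CellMesh", function(mesh, excludedEdges = integer()) {
  excludedEdges <- as.integer(excludedEdges)
  if (!all(excludedEdges %in% mesh@edges$id))
    stop("excluded edge id(s) not present in mesh")
  ed <- mesh@edges; jn <- mesh@junctions; cl <- mesh@cells
  exc <- ed$id %in% excludedEdges
  remJ <- unique(c(ed$j1[exc], ed$j2[exc]))
  remJ <- remJ[!is.na(remJ)]
  retainedJ <- setdiff(jn$id, remJ)
  keep <- !exc
  ## a retained edge must still touch at least one retained junction
  touches <- (ed$j1 %in% retainedJ) | (ed$j2 %in% retainedJ)
  nTens <- sum(keep & touches)
  nInter <- vapply(mesh@chains[as.character(ed$id)],
                   function(ch) length(ch) - 2L, integer(1))
  usable <- keep & !ed$stub & nInter >= 1L
  new("MeshCounts",
      nJunctions = nrow(jn),
      nJunctionsRemoved = length(remJ),
      nTensions = as.integer(nTens),
      nTensionEqns = 2L * length(retainedJ),
      nCompleteCells = sum(!cl$partial & !cl$medium),
      nPartialCells = sum(cl$partial),
      nExcessEdges = as.integer(sum(pmax(jn$order - 3L, 0L))),
      nRemovedEdges = length(excludedEdges),
      nDoubleJunctions = sum(jn$order == 2L),
      nStubs = sum(ed$stub),
      nPressureEqns = as.integer(sum(usable)),
      nPressures = as.integer(sum(!cl$partial & !cl$medium) + sum(cl$partial)))
})

## ---- connectivity -----------------------------------------------------------

#' Connected components of the tension problem
#'
#' Junctions belong to the same tension component when connected by a chain of
#' retained (non-excluded) edges; a separate tension system must be solved for
#' each component.
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param excludedEdges edge ids excluded from the analysis.
#' @return list of integer junction-id vectors (a partition of the retained
#'   junctions).
#' @export
tensionComponents <- function(mesh, excludedEdges = integer()) {
  ed <- mesh@edges
  exc <- ed$id %in% as.integer(excludedEdges)
  remJ <- unique(c(ed$j1[exc], ed$j2[exc])); remJ <- remJ[!is.na(remJ)]
  retained <- setdiff(mesh@junctions$id, remJ)
  if (!length(retained)) return(list())
  link <- !exc & !is.na(ed$j1) & !is.na(ed$j2) &
    ed$j1 %in% retained & ed$j2 %in% retained
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$j1[link]), to = as.character(ed$j2[link])),
    directed = FALSE, vertices = data.frame(name = as.character(retained)))
  comp <- igraph::components(g)
  unname(lapply(split(as.integer(igraph::V(g)$name), comp$membership), sort))
}

#' Connected components of the pressure problem
#'
#' Cells (including the medium) belong to the same pressure component when
#' connected by at least one chain of usable edges (edges with known tension
#' and finite curvature).
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param usableEdges edge ids usable for pressure equations.
#' @return list of integer cell-id vectors.
#' @export
pressureComponents <- function(mesh, usableEdges) {
  ed <- mesh@edges
  use <- ed$id %in% as.integer(usableEdges)
  cells <- mesh@cells$id
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$cellLeft[use]),
               to = as.character(ed$cellRight[use])),
    directed = FALSE, vertices = data.frame(name = as.character(cells)))
  comp <- igraph::components(g)
  unname(lapply(split(as.integer(igraph::V(g)$name), comp$membership), sort))
}

## ---- simple fixture constructors -------------------------------------------

#' Star mesh: n stub edges radiating from one junction
#'
#' A minimal topology useful for tests and worked examples: \code{n} straight
#' stub edges radiate from a shared central node at the given angles, with
#' \code{n} partial sector cells between consecutive edges.
#'
#' @param n number of edges (>= 2).
#' @param angles radiation angles in radians (default equally spaced).
#' @param center center position.
#' @param r edge length.
#' @param idOffset added to all node/edge/cell ids (to compose several stars
#'   into one mesh).
#' @param nIntermediate intermediate nodes per edge.
#' @return a \code{\linkS4class{CellMesh}}.
#' @export
starMesh <- function(n, angles = 2 * pi * (seq_len(n) - 1) / n,
                     center = c(0, 0), r = 1, idOffset = 0L,
                     nIntermediate = 0L) {
  stopifnot(n >= 2L, length(angles) == n)
  npts <- nIntermediate + 2L
  t <- seq(0, 1, length.out = npts)
  nodes <- data.frame(id = idOffset + 1L, x = center[1], y = center[2])
  chains <- list(); nid <- idOffset + 1L
  for (k in seq_len(n)) {
    xs <- center[1] + r * t * cos(angles[k])
    ys <- center[2] + r * t * sin(angles[k])
    ids <- c(idOffset + 1L, nid + seq_len(npts - 1L))
    nodes <- rbind(nodes, data.frame(id = ids[-1L], x = xs[-1L], y = ys[-1L]))
    chains[[as.character(idOffset + k)]] <- ids
    nid <- nid + npts - 1L
  }
  ## sector cell k lies between edges k and k+1; edge k has sector k on its
  ## left (edges ordered counter-clockwise)
  cellIds <- idOffset + seq_len(n)
  edges <- data.frame(id = idOffset + seq_len(n),
                      cellLeft = cellIds,
                      cellRight = cellIds[c(n, seq_len(n - 1L))])
  cells <- data.frame(id = cellIds, partial = TRUE, medium = FALSE)
  cellEdges <- setNames(lapply(seq_len(n), function(k)
    edges$id[c(k, if (k == n) 1L else k + 1L)]), as.character(cellIds))
  buildMesh(nodes, edges, cells, chains, cellEdges)
}
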