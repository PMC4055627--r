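## Forward model: annealed synthetic epithelia with known ground truth.

#' Default interface-tension table
#'
#' Unordered cell-type pairs map to interface tensions in the ratio
#' 5:6:7:10:11:12 for classes 1-1, 1-2, 1-3, 2-2, 2-3, 3-3 (sorted-pair
#' ordering).  Medium-facing interfaces default to the homotypic value of the
#' adjacent cell.
#'
#' @export
defaultTensionTable <- c(`11` = 5, `12` = 6, `13` = 7,
                         `22` = 10, `23` = 11, `33` = 12)

#' Generate a Voronoi patch mesh
#'
#' Seeds \code{nCells} points uniformly in a square of side
#' \code{sqrt(nCells)} (unit mean cell area), applies a small number of Lloyd
#' relaxation steps to avoid sliver cells, tessellates, and converts the
#' tessellation into a \code{\linkS4class{CellMesh}} whose edges carry
#' \code{nIntermediate} equally spaced intermediate nodes.  The surrounding
#' region outside the bounding box is the medium (cell id 0).
#'
#' @param nCells number of cells (>= 3).
#' @param seed integer random seed (mesh is a deterministic function of it).
#' @param nIntermediate intermediate nodes per edge (default 4).
#' @param lloyd number of Lloyd centroid-relaxation steps.
#' @param points optional explicit seed points (overrides random seeding).
#' @return a \code{\linkS4class{CellMesh}} with attribute \code{"bbox"}.
#' @export
generatePatch <- function(nCells, seed = 1L, nIntermediate = 4L, lloyd = 2L,
                          points = NULL) {
  stopifnot(nCells >= 3L)
  L <- sqrt(nCells)
  bbox <- c(0, L, 0, L)
  for (attempt in 0:9) {
    if (is.null(points)) {
      set.seed(seed + 1000L * attempt)
      pts <- cbind(runif(nCells, 0, L), runif(nCells, 0, L))
    } else pts <- as.matrix(points)
    for (it in seq_len(lloyd)) {
      polys <- voronoiPolygons(pts, bbox)
      pts <- t(vapply(polys, .polyCentroid, numeric(2)))
    }
    polys <- voronoiPolygons(pts, bbox)
    mesh <- tryCatch(.voronoiToMesh(polys, bbox, nIntermediate),
                     error = function(e) NULL)
    if (!is.null(mesh)) { attr(mesh, "bbox") <- bbox; return(mesh) }
    if (!is.null(points)) stop("degenerate tessellation for supplied points")
  }
  stop("degenerate tessellation: could not build a valid mesh after reseeding")
}

## Convert Voronoi cell polygons into a CellMesh with subdivided edges.
.voronoiToMesh <- function(polys, bbox, nIntermediate) {
  n <- length(polys)
  vkey <- function(xy) sprintf("%.6f_%.6f", xy[, 1L], xy[, 2L])
  ## collect unique vertices
  allV <- do.call(rbind, polys)
  keys <- vkey(allV)
  uk <- !duplicated(keys)
  vxy <- allV[uk, , drop = FALSE]
  vids <- setNames(seq_len(sum(uk)), keys[uk])
  cycles <- lapply(polys, function(p) {
    ids <- unname(vids[vkey(p)])
    ids[c(TRUE, diff(ids) != 0L)]  # drop consecutive duplicates
  })
  cycles <- lapply(cycles, function(cy) {
    if (length(cy) > 1L && cy[1L] == cy[length(cy)]) cy[-length(cy)] else cy
  })
  if (any(vapply(cycles, length, integer(1)) < 3L))
    stop("degenerate cell polygon")

  ## edges: unordered vertex pairs; first traversal (CCW cell) defines the
  ## chain direction, that cell lies on the left
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edgeEnv <- new.env(hash = TRUE)
  edges <- list()
  cellEdges <- vector("list", n)
  for (ci in seq_len(n)) {
    cy <- cycles[[ci]]
    m <- length(cy)
    eids <- integer(m)
    for (k in seq_len(m)) {
      a <- cy[k]; b <- cy[if (k == m) 1L else k + 1L]
      key <- ekey(a, b)
      if (is.null(edgeEnv[[key]])) {
        id <- length(edges) + 1L
        edges[[id]] <- list(id = id, a = a, b = b, left = ci, right = NA_integer_)
        edgeEnv[[key]] <- id
      } else {
        id <- edgeEnv[[key]]
        if (!is.na(edges[[id]]$right)) stop("edge claimed three times")
        edges[[id]]$right <- ci
      }
      eids[k] <- id
    }
    cellEdges[[ci]] <- eids
  }
  ## unclaimed sides are the medium
  for (id in seq_along(edges))
    if (is.na(edges[[id]]$right)) edges[[id]]$right <- MEDIUM

  ## subdivide chains with intermediate nodes
  nV <- nrow(vxy)
  nodes <- data.frame(id = seq_len(nV), x = vxy[, 1L], y = vxy[, 2L])
  chains <- list()
  nextId <- nV
  for (e in edges) {
    pa <- vxy[e$a, ]; pb <- vxy[e$b, ]
    if (nIntermediate > 0L) {
      t <- seq_len(nIntermediate) / (nIntermediate + 1L)
      mid <- cbind(pa[1L] + t * (pb[1L] - pa[1L]),
                   pa[2L] + t * (pb[2L] - pa[2L]))
      ids <- nextId + seq_len(nIntermediate)
      nodes <- rbind(nodes, data.frame(id = ids, x = mid[, 1L], y = mid[, 2L]))
      nextId <- nextId + nIntermediate
      chains[[as.character(e$id)]] <- c(e$a, ids, e$b)
    } else chains[[as.character(e$id)]] <- c(e$a, e$b)
  }
  edgeDf <- data.frame(id = vapply(edges, `[[`, integer(1), "id"),
                       cellLeft = vapply(edges, `[[`, integer(1), "left"),
                       cellRight = vapply(edges, `[[`, integer(1), "right"))
  hasMedium <- any(edgeDf$cellLeft == MEDIUM | edgeDf$cellRight == MEDIUM)
  cells <- data.frame(id = seq_len(n), partial = FALSE, medium = FALSE)
  ce <- setNames(cellEdges, as.character(seq_len(n)))
  if (hasMedium) {
    cells <- rbind(cells, data.frame(id = MEDIUM, partial = TRUE, medium = TRUE))
    ce <- c(ce, setNames(list(
      edgeDf$id[edgeDf$cellLeft == MEDIUM | edgeDf$cellRight == MEDIUM]),
      as.character(MEDIUM)))
  }
  buildMesh(nodes, edgeDf, cells, chains, ce)
}

#' Assign cell types and interface tensions
#'
#' Cell types are drawn i.i.d. uniform over \{1, 2, 3\}; each interface class
#' is the unordered type pair of its side cells and maps to a tension through
#' \code{tensionTable}.  Medium-facing edges take the homotypic value of the
#' adjacent cell.
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param seed integer random seed.
#' @param tensionTable named tension table (see
#'   \code{\link{defaultTensionTable}}).
#' @param types optional named integer vector forcing the cell types.
#' @return a \code{\linkS4class{TissueTruth}} (pressures empty until
#'   annealing).
#' @export
assignTypesAndTensions <- function(mesh, seed = 1L,
                                   tensionTable = defaultTensionTable,
                                   types = NULL) {
  realCells <- mesh@cells$id[!mesh@cells$medium]
  if (is.null(types)) {
    set.seed(seed)
    types <- setNames(sample.int(3L, length(realCells), replace = TRUE),
                      as.character(realCells))
  } else types <- setNames(as.integer(types[as.character(realCells)]),
                           as.character(realCells))
  ed <- mesh@edges
  tens <- vapply(seq_len(nrow(ed)), function(i) {
    a <- ed$cellLeft[i]; b <- ed$cellRight[i]
    ta <- if (a == MEDIUM) NA_integer_ else types[[as.character(a)]]
    tb <- if (b == MEDIUM) NA_integer_ else types[[as.character(b)]]
    if (is.na(ta)) ta <- tb
    if (is.na(tb)) tb <- ta
    tensionTable[[paste0(min(ta, tb), max(ta, tb))]]
  }, numeric(1))
  new("TissueTruth",
      tensions = setNames(tens, as.character(ed$id)),
      pressures = numeric(0), cellTypes = types)
}

## ---- annealing --------------------------------------------------------------

## Precompute vectorized index structures for the energy and gradient.
.annealStructure <- function(mesh, truth) {
  ed <- mesh@edges
  segA <- integer(0); segB <- integer(0); segG <- numeric(0)
  for (i in seq_len(nrow(ed))) {
    ch <- .nodeIndex(mesh, .chainOf(mesh, ed$id[i]))
    m <- length(ch)
    segA <- c(segA, ch[-m]); segB <- c(segB, ch[-1L])
    segG <- c(segG, rep(truth@tensions[[as.character(ed$id[i])]], m - 1L))
  }
  realCells <- mesh@cells$id[!mesh@cells$medium & !mesh@cells$partial]
  loopIdx <- integer(0); loopCell <- integer(0)
  loopPrev <- integer(0); loopNext <- integer(0)
  for (k in seq_along(realCells)) {
    cy <- .nodeIndex(mesh, cellLoopNodes(mesh, realCells[k]))
    m <- length(cy)
    loopIdx <- c(loopIdx, cy)
    loopCell <- c(loopCell, rep(k, m))
    loopPrev <- c(loopPrev, cy[c(m, seq_len(m - 1L))])
    loopNext <- c(loopNext, cy[c(seq_len(m - 1L) + 1L, 1L)])
  }
  list(segA = segA, segB = segB, segG = segG,
       loopIdx = loopIdx, loopCell = loopCell,
       loopPrev = loopPrev, loopNext = loopNext,
       cells = realCells, nCellsReal = length(realCells))
}

.cellAreasFromLoops <- function(xy, st) {
  cr <- xy[st$loopIdx, 1L] * xy[st$loopNext, 2L] -
    xy[st$loopNext, 1L] * xy[st$loopIdx, 2L]
  0.5 * drop(rowsum(cr, st$loopCell, reorder = TRUE))
}

#' Anneal a synthetic mesh to static force equilibrium
#'
#' Relaxes node positions so that every free node is in mechanical
#' equilibrium under the assigned edge tensions and a per-cell area penalty.
#' The total energy is \eqn{E = \sum_e \gamma_e \ell_e + \sum_c (k/2)
#' (A_c - A_{0,c})^2 / A_{0,c}}; its stationary points are configurations in
#' which each cell exerts the emergent pressure \eqn{p_c = k (A_{0,c} -
#' A_c)/A_{0,c}} on its boundary and all junction and edge force balances
#' hold.  Minimization uses L-BFGS-B with interleaved uniform re-sampling of
#' the chain nodes (tangential node spacing along an edge is energetically
#' indifferent, so re-sampling removes that degeneracy); edges that shrink
#' below the target spacing end up with fewer or no intermediate nodes,
#' reproducing the short-edge phenomenology of segmented tissues.
#'
#' @param mesh a \code{\linkS4class{CellMesh}} from
#'   \code{\link{generatePatch}}.
#' @param truth a \code{\linkS4class{TissueTruth}} with assigned tensions.
#' @param areaStiffness area penalty stiffness \code{k} (tension units /
#'   length; default 100).
#' @param rounds minimize/re-sample rounds.
#' @param maxit L-BFGS-B iteration cap per round.
#' @param forceTol convergence tolerance: maximum residual nodal force as a
#'   fraction of the mean tension.
#' @param pinBoundary pin nodes on the patch bounding box (interior equilibria
#'   then exist irrespective of what lies outside).
#' @param bbox bounding box for pinning (default: the mesh's generation box).
#' @param targetSpacing chain re-sampling spacing (default: mean initial
#'   segment length).
#' @param contractTol chord length below which an interior edge is
#'   contracted into a higher-order junction.  Interface tensions that favor
#'   neighbour exchange drive some edges toward zero length; at fixed
#'   topology no equilibrium exists there, so such edges are merged into
#'   quad junctions or rosettes, which are genuine equilibria and are fully
#'   supported by the inference equations.
#' @return list with \code{mesh} (equilibrated), \code{truth} (tensions
#'   restricted to surviving edges, pressures filled in), \code{converged},
#'   \code{maxForce}, \code{A0}.
#' @export
annealMesh <- function(mesh, truth, areaStiffness = 100, rounds = 4L,
                       maxit = 4000L, forceTol = 1e-3, pinBoundary = TRUE,
                       bbox = NULL, targetSpacing = NULL, contractTol = 0.02,
                       tensionTable = defaultTensionTable) {
  if (is.null(bbox)) bbox <- attr(mesh, "bbox")
  t1Counts <- new.env(parent = emptyenv())
  meanG <- mean(truth@tensions)
  st0 <- .annealStructure(mesh, truth)
  xy0 <- cbind(mesh@nodes$x, mesh@nodes$y)
  A0 <- setNames(.cellAreasFromLoops(xy0, st0), as.character(st0$cells))
  if (is.null(targetSpacing)) {
    ## edges shorten as the tissue relaxes; the 0.72 shrinkage allowance
    ## keeps the post-anneal average at about 4 intermediate nodes per edge
    segLen <- sqrt(rowSums((xy0[st0$segB, , drop = FALSE] -
                            xy0[st0$segA, , drop = FALSE])^2))
    targetSpacing <- 0.72 * mean(segLen)
  }
  k <- areaStiffness
  cur <- mesh
  maxForce <- Inf
  for (round in seq_len(rounds)) {
    st <- .annealStructure(cur, truth)
    A0r <- unname(A0[as.character(st$cells)])
    xy <- cbind(cur@nodes$x, cur@nodes$y)
    pinned <- if (pinBoundary && !is.null(bbox)) {
      tol <- 1e-6
      abs(xy[, 1L] - bbox[1L]) < tol | abs(xy[, 1L] - bbox[2L]) < tol |
        abs(xy[, 2L] - bbox[3L]) < tol | abs(xy[, 2L] - bbox[4L]) < tol
    } else rep(FALSE, nrow(xy))
    free <- which(!pinned)
    nf <- length(free)
    par0 <- c(xy[free, 1L], xy[free, 2L])
    fill <- function(par) {
      xy[free, 1L] <- par[seq_len(nf)]
      xy[free, 2L] <- par[nf + seq_len(nf)]
      xy
    }
    energy <- function(par) {
      p <- fill(par)
      d <- p[st$segB, , drop = FALSE] - p[st$segA, , drop = FALSE]
      len <- sqrt(d[, 1L]^2 + d[, 2L]^2)
      A <- .cellAreasFromLoops(p, st)
      sum(st$segG * len) + sum(0.5 * k * (A - A0r)^2 / A0r)
    }
    gradient <- function(par) {
      p <- fill(par)
      d <- p[st$segB, , drop = FALSE] - p[st$segA, , drop = FALSE]
      len <- pmax(sqrt(d[, 1L]^2 + d[, 2L]^2), 1e-12)
      ux <- st$segG * d[, 1L] / len; uy <- st$segG * d[, 2L] / len
      nN <- nrow(p)
      gx <- numeric(nN); gy <- numeric(nN)
      agg <- rowsum(cbind(c(-ux, ux), c(-uy, uy)), c(st$segA, st$segB))
      ii <- as.integer(rownames(agg))
      gx[ii] <- agg[, 1L]; gy[ii] <- agg[, 2L]
      A <- .cellAreasFromLoops(p, st)
      dEdA <- (k * (A - A0r) / A0r)[st$loopCell]
      dAx <- 0.5 * (p[st$loopNext, 2L] - p[st$loopPrev, 2L])
      dAy <- 0.5 * (p[st$loopPrev, 1L] - p[st$loopNext, 1L])
      agg2 <- rowsum(cbind(dEdA * dAx, dEdA * dAy), st$loopIdx)
      jj <- as.integer(rownames(agg2))
      gx[jj] <- gx[jj] + agg2[, 1L]; gy[jj] <- gy[jj] + agg2[, 2L]
      c(gx[free], gy[free])
    }
    opt <- optim(par0, energy, gradient, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 1e2, pgtol = 0))
    xy <- fill(opt$par)
    cur@nodes$x <- xy[, 1L]; cur@nodes$y <- xy[, 2L]
    g <- gradient(opt$par)
    maxForce <- if (nf) max(sqrt(g[seq_len(nf)]^2 + g[nf + seq_len(nf)]^2)) else 0
    if (round < rounds) {
      rm <- .remodelShortEdges(cur, truth, contractTol, bbox, tensionTable,
                               t1Counts)
      cur <- rm$mesh; truth <- rm$truth
      cur <- .resampleChains(cur, targetSpacing)
    }
  }
  if (maxForce > 10 * forceTol * meanG)
    stop(sprintf("annealing did not converge: max nodal force %.3g (tol %.3g)",
                 maxForce, forceTol * meanG))
  if (maxForce > forceTol * meanG)
    warning(sprintf("annealing marginally converged: max nodal force %.3g",
                    maxForce))
  st <- .annealStructure(cur, truth)
  A0r <- unname(A0[as.character(st$cells)])
  A <- .cellAreasFromLoops(cbind(cur@nodes$x, cur@nodes$y), st)
  pressures <- setNames(k * (A0r - A) / A0r, as.character(st$cells))
  truth@pressures <- pressures
  truth@tensions <- truth@tensions[as.character(cur@edges$id)]
  attr(cur, "bbox") <- bbox
  list(mesh = cur, truth = truth,
       converged = maxForce <= forceTol * meanG,
       maxForce = maxForce, A0 = A0)
}

## Re-order a cell's edge ids into a single closed boundary loop by walking
## oriented chains (forward when the cell is the left cell).
.orderLoop <- function(cid, eids, chains, edgeDf) {
  endsOf <- function(e) {
    ch <- chains[[as.character(e)]]
    if (edgeDf$cellLeft[match(e, edgeDf$id)] == cid) c(ch[1L], ch[length(ch)])
    else c(ch[length(ch)], ch[1L])
  }
  remaining <- eids
  out <- remaining[1L]; remaining <- remaining[-1L]
  cur <- endsOf(out)[2L]
  while (length(remaining)) {
    nxt <- remaining[vapply(remaining, function(e) endsOf(e)[1L] == cur,
                            logical(1))]
    if (length(nxt) < 1L) stop("cell ", cid, " loop cannot be ordered")
    out <- c(out, nxt[1L]); cur <- endsOf(nxt[1L])[2L]
    remaining <- setdiff(remaining, nxt[1L])
  }
  if (cur != endsOf(out[1L])[1L]) stop("cell ", cid, " loop does not close")
  out
}

## T1 neighbour exchange: a collapsing edge between two triple junctions is
## contracted and re-opened perpendicular to its old direction, swapping the
## adjacencies (the two former side cells separate, the two end cells come
## into contact).  The re-opened interface takes the tension of its new cell
## type pair.  Returns NULL when the local topology does not admit a clean
## swap (then the caller falls back to contraction into a rosette).
.applyT1 <- function(mesh, truth, edgeId, delta, tensionTable) {
  ed <- mesh@edges
  i <- match(edgeId, ed$id)
  ch <- mesh@chains[[as.character(edgeId)]]
  n1 <- ch[1L]; n2 <- ch[length(ch)]
  if (n1 == n2) return(NULL)
  jord <- mesh@junctions$order[match(c(n1, n2), mesh@junctions$id)]
  if (anyNA(jord) || any(jord != 3L)) return(NULL)
  A <- ed$cellLeft[i]; B <- ed$cellRight[i]
  sidesOf <- function(e) {
    j <- match(e, ed$id); c(ed$cellLeft[j], ed$cellRight[j])
  }
  o1 <- setdiff(mesh@junctionEdges[[as.character(n1)]], edgeId)
  o2 <- setdiff(mesh@junctionEdges[[as.character(n2)]], edgeId)
  if (length(o1) != 2L || length(o2) != 2L) return(NULL)
  third <- function(o) {
    s <- setdiff(intersect(sidesOf(o[1L]), sidesOf(o[2L])), c(A, B))
    if (length(s) == 1L) s else NA_integer_
  }
  C <- third(o1); D <- third(o2)
  if (is.na(C) || is.na(D) || C == D || C == MEDIUM || D == MEDIUM)
    return(NULL)
  pick <- function(o, s1, s2)
    o[vapply(o, function(e) setequal(sidesOf(e), c(s1, s2)), logical(1))]
  a1 <- pick(o1, A, C); b1 <- pick(o1, B, C)
  a2 <- pick(o2, A, D); b2 <- pick(o2, B, D)
  if (length(a1) != 1L || length(b1) != 1L ||
      length(a2) != 1L || length(b2) != 1L) return(NULL)

  p1 <- drop(nodeXY(mesh, n1)); p2 <- drop(nodeXY(mesh, n2))
  d <- p2 - p1; d <- d / sqrt(sum(d^2))
  nrm <- c(-d[2L], d[1L])           # left normal: toward cell A
  mid <- (p1 + p2) / 2
  newp1 <- mid + (delta / 2) * nrm  # junction where A meets C and D
  newp2 <- mid - (delta / 2) * nrm  # junction where B meets C and D

  chains <- mesh@chains
  swapEnd <- function(e, from, to) {
    c2 <- chains[[as.character(e)]]
    if (c2[1L] == from) c2[1L] <- to
    else if (c2[length(c2)] == from) c2[length(c2)] <- to
    else stop("edge ", e, " does not end at node ", from)
    chains[[as.character(e)]] <<- c2
  }
  swapEnd(b1, n1, n2)
  swapEnd(a2, n2, n1)
  inner <- setdiff(ch, c(n1, n2))
  chains[[as.character(edgeId)]] <- c(n1, n2)

  nodes <- mesh@nodes[!(mesh@nodes$id %in% inner), ]
  i1 <- match(n1, nodes$id); i2 <- match(n2, nodes$id)
  nodes$x[i1] <- newp1[1L]; nodes$y[i1] <- newp1[2L]
  nodes$x[i2] <- newp2[1L]; nodes$y[i2] <- newp2[2L]

  edgeDf <- ed[, c("id", "cellLeft", "cellRight")]
  ## new chain runs from the A-side junction to the B-side junction; D lies
  ## on its left, C on its right
  edgeDf$cellLeft[i] <- D; edgeDf$cellRight[i] <- C

  ce <- mesh@cellEdges
  ce[[as.character(A)]] <- setdiff(ce[[as.character(A)]], edgeId)
  ce[[as.character(B)]] <- setdiff(ce[[as.character(B)]], edgeId)
  ce[[as.character(C)]] <- c(ce[[as.character(C)]], edgeId)
  ce[[as.character(D)]] <- c(ce[[as.character(D)]], edgeId)
  cl <- mesh@cells
  for (cid in c(A, B, C, D)) {
    k <- match(cid, cl$id)
    if (!cl$partial[k] && !cl$medium[k])
      ce[[as.character(cid)]] <- .orderLoop(cid, ce[[as.character(cid)]],
                                            chains, edgeDf)
  }
  out <- tryCatch(
    buildMesh(nodes, edgeDf, cl, chains[as.character(edgeDf$id)], ce,
              mesh@lengthScale),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  tC <- truth@cellTypes[[as.character(C)]]
  tD <- truth@cellTypes[[as.character(D)]]
  truth@tensions[[as.character(edgeId)]] <-
    tensionTable[[paste0(min(tC, tD), max(tC, tD))]]
  list(mesh = out, truth = truth)
}

## Remodel collapsing edges between annealing rounds: T1 neighbour exchange
## where the local topology admits it (at most twice per edge, to stop
## flip-flopping), contraction into a quad junction / rosette otherwise.
.remodelShortEdges <- function(mesh, truth, tol, bbox, tensionTable,
                               t1Counts) {
  delta <- 2.5 * tol
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 50L) break
    ed <- mesh@edges
    e1 <- vapply(mesh@chains[as.character(ed$id)], `[`, integer(1), 1L)
    e2 <- vapply(mesh@chains[as.character(ed$id)],
                 function(c2) c2[length(c2)], integer(1))
    xy1 <- nodeXY(mesh, e1); xy2 <- nodeXY(mesh, e2)
    onBox <- function(xy) {
      if (is.null(bbox)) return(rep(FALSE, nrow(xy)))
      btol <- 1e-6
      abs(xy[, 1L] - bbox[1L]) < btol | abs(xy[, 1L] - bbox[2L]) < btol |
        abs(xy[, 2L] - bbox[3L]) < btol | abs(xy[, 2L] - bbox[4L]) < btol
    }
    len <- sqrt(rowSums((xy2 - xy1)^2))
    cand <- which(len < tol & !ed$stub &
                    ed$cellLeft != MEDIUM & ed$cellRight != MEDIUM &
                    !onBox(xy1) & !onBox(xy2))
    if (!length(cand)) break
    i <- cand[which.min(len[cand])]
    id <- as.character(ed$id[i])
    nT1 <- if (is.null(t1Counts[[id]])) 0L else t1Counts[[id]]
    res <- if (nT1 < 2L)
      .applyT1(mesh, truth, ed$id[i], delta, tensionTable) else NULL
    if (!is.null(res)) {
      t1Counts[[id]] <- nT1 + 1L
      mesh <- res$mesh; truth <- res$truth
    } else {
      mesh <- .contractOneEdge(mesh, ed$id[i])
      truth@tensions <- truth@tensions[as.character(mesh@edges$id)]
    }
  }
  list(mesh = mesh, truth = truth)
}

## Contract one edge: its two endpoint junctions merge into one
## higher-order junction (quad junction or rosette) at the midpoint, and the
## edge and its tension unknown disappear.
.contractOneEdge <- function(mesh, id) {
  ed <- mesh@edges
  i <- match(id, ed$id)
  ch <- mesh@chains[[as.character(id)]]
  n1 <- ch[1L]; n2 <- ch[length(ch)]
  if (n1 == n2) return(.dropEdge(mesh, id))
  mid <- (nodeXY(mesh, n1) + nodeXY(mesh, n2)) / 2
  ni <- match(n1, mesh@nodes$id)
  mesh@nodes$x[ni] <- mid[1L]; mesh@nodes$y[ni] <- mid[2L]
  ## re-point every other chain ending at n2 to n1
  inner <- setdiff(ch, c(n1, n2))
  chains <- mesh@chains
  for (nm in names(chains)) {
    if (nm == as.character(id)) next
    c2 <- chains[[nm]]
    if (c2[1L] == n2) c2[1L] <- n1
    if (c2[length(c2)] == n2) c2[length(c2)] <- n1
    chains[[nm]] <- c2
  }
  keep <- ed$id != id
  nodes <- mesh@nodes[!(mesh@nodes$id %in% c(inner, n2)), ]
  ce <- lapply(mesh@cellEdges, function(v) v[v != id])
  buildMesh(nodes, ed[keep, c("id", "cellLeft", "cellRight")],
            mesh@cells, chains[as.character(ed$id[keep])], ce,
            mesh@lengthScale)
}

.dropEdge <- function(mesh, id) {
  ed <- mesh@edges
  keep <- ed$id != id
  inner <- setdiff(mesh@chains[[as.character(id)]],
                   unlist(lapply(mesh@chains[as.character(ed$id[keep])],
                                 function(ch) ch)))
  nodes <- mesh@nodes[!(mesh@nodes$id %in% inner), ]
  ce <- lapply(mesh@cellEdges, function(v) v[v != id])
  buildMesh(nodes, ed[keep, c("id", "cellLeft", "cellRight")],
            mesh@cells, mesh@chains[as.character(ed$id[keep])], ce,
            mesh@lengthScale)
}

## Re-sample every chain to uniform spacing along its polyline.  Node
## counts never shrink (edges keep their allocated intermediate nodes as
## they shorten, like a finite element mesh would), but re-opened or grown
## edges gain nodes to keep the target spacing.
.resampleChains <- function(mesh, spacing) {
  newChains <- list()
  for (i in seq_len(nrow(mesh@edges))) {
    id <- mesh@edges$id[i]
    xy <- nodeXY(mesh, .chainOf(mesh, id))
    seg <- sqrt(rowSums(diff(xy)^2))
    len <- sum(seg)
    nSeg <- max(nrow(xy) - 1L, 1L, round(len / spacing))
    if (nSeg == 1L) { newChains[[as.character(id)]] <- xy[c(1L, nrow(xy)), ]; next }
    cum <- c(0, cumsum(seg))
    tq <- seq(0, len, length.out = nSeg + 1L)
    nx <- stats::approx(cum, xy[, 1L], xout = tq)$y
    ny <- stats::approx(cum, xy[, 2L], xout = tq)$y
    newChains[[as.character(id)]] <- cbind(nx, ny)
  }
  rebuildChains(mesh, newChains)
}

## Rebuild a mesh with new chain point coordinates (same topology).
## Junction endpoints keep their node ids; intermediate nodes are renumbered.
rebuildChains <- function(mesh, newChains) {
  ends <- unique(unlist(lapply(mesh@chains, function(ch) ch[c(1L, length(ch))])))
  endXY <- nodeXY(mesh, ends)
  nodes <- data.frame(id = ends, x = endXY[, 1L], y = endXY[, 2L])
  nextId <- max(ends)
  chains <- list()
  for (i in seq_len(nrow(mesh@edges))) {
    id <- as.character(mesh@edges$id[i])
    old <- mesh@chains[[id]]
    xy <- newChains[[id]]
    m <- nrow(xy)
    if (m < 2L) stop("resampled chain too short")
    inner <- if (m > 2L) nextId + seq_len(m - 2L) else integer(0)
    if (m > 2L) {
      nodes <- rbind(nodes, data.frame(id = inner, x = xy[2:(m - 1L), 1L],
                                       y = xy[2:(m - 1L), 2L]))
      nextId <- nextId + m - 2L
    }
    chains[[id]] <- c(old[1L], inner, old[length(old)])
  }
  out <- buildMesh(nodes, mesh@edges[, c("id", "cellLeft", "cellRight")],
                   mesh@cells, chains, mesh@cellEdges, mesh@lengthScale)
  attr(out, "bbox") <- attr(mesh, "bbox")
  out
}

## ---- region extraction ------------------------------------------------------

#' Extract a frayed sub-region of an annealed patch
#'
#' Keeps the cells whose centroids fall inside the window; these remain
#' complete.  Their neighbours become partial perimeter cells, edges between
#' two discarded cells are dropped, and kept edges whose far junction loses
#' all other incident edges become stubs -- producing the "frayed" boundary
#' characteristic of regions cut from a larger sheet.  The ground truth is
#' restricted to the kept edges and cells.
#'
#' @param mesh annealed patch mesh.
#' @param truth its \code{\linkS4class{TissueTruth}}.
#' @param window c(xmin, xmax, ymin, ymax), strictly inside the patch; or
#'   NULL to size a centered square via \code{targetComplete}.
#' @param targetComplete approximate number of complete cells to retain.
#' @return list with \code{mesh} (sub-mesh), \code{truth} (restricted),
#'   \code{window}, \code{completeCells}.
#' @export
extractRegion <- function(mesh, truth, window = NULL, targetComplete = 50L) {
  realC <- mesh@cells$id[!mesh@cells$partial & !mesh@cells$medium]
  cent <- t(vapply(realC, function(c) .polyCentroid(cellPolygon(mesh, c)),
                   numeric(2)))
  if (is.null(window)) {
    bbox <- attr(mesh, "bbox")
    if (is.null(bbox)) bbox <- c(range(mesh@nodes$x), range(mesh@nodes$y))[c(1, 2, 3, 4)]
    cx <- mean(bbox[1:2]); cy <- mean(bbox[3:4])
    lo <- 0; hi <- min(bbox[2L] - bbox[1L], bbox[4L] - bbox[3L])
    for (it in 1:40) {
      s <- (lo + hi) / 2
      inW <- abs(cent[, 1L] - cx) <= s / 2 & abs(cent[, 2L] - cy) <= s / 2
      if (sum(inW) < targetComplete) lo <- s else hi <- s
    }
    s <- hi
    window <- c(cx - s / 2, cx + s / 2, cy - s / 2, cy + s / 2)
  }
  inW <- cent[, 1L] >= window[1L] & cent[, 1L] <= window[2L] &
    cent[, 2L] >= window[3L] & cent[, 2L] <= window[4L]
  K <- realC[inW]
  if (!length(K)) stop("empty window")
  ed <- mesh@edges
  keep <- ed$cellLeft %in% K | ed$cellRight %in% K
  ## also keep the truncated continuations: edges between two discarded
  ## cells that hang off a retained junction; they become the frayed stubs
  end1 <- vapply(mesh@chains[as.character(ed$id)], `[`, integer(1), 1L)
  end2 <- vapply(mesh@chains[as.character(ed$id)],
                 function(ch) ch[length(ch)], integer(1))
  jset <- unique(c(end1[keep], end2[keep]))
  frayed <- !keep & (end1 %in% jset | end2 %in% jset) &
    ed$cellLeft != MEDIUM & ed$cellRight != MEDIUM
  keep <- keep | frayed
  ## truncate one-sided frayed edges shortly after they leave the window so
  ## their far ends are free termini (stubs), never spurious junctions
  chains <- mesh@chains
  for (i in which(frayed)) {
    a1 <- end1[i] %in% jset; a2 <- end2[i] %in% jset
    if (a1 && a2) next  # bridging edge between two retained junctions
    ch <- chains[[as.character(ed$id[i])]]
    if (!a1) ch <- rev(ch)  # orient with the retained junction first
    xy <- nodeXY(mesh, ch)
    outw <- xy[, 1L] < window[1L] | xy[, 1L] > window[2L] |
      xy[, 2L] < window[3L] | xy[, 2L] > window[4L]
    cut <- which(outw)
    keepN <- if (length(cut)) max(2L, min(cut[1L] + 1L, length(ch) - 1L))
             else length(ch) - 1L
    ch <- ch[seq_len(max(2L, keepN))]
    if (!a1) ch <- rev(ch)
    chains[[as.character(ed$id[i])]] <- ch
  }
  ## iteratively drop kept edges left with no junction endpoint
  repeat {
    ends <- c(vapply(mesh@chains[as.character(ed$id[keep])], `[`, integer(1), 1L),
              vapply(mesh@chains[as.character(ed$id[keep])],
                     function(ch) ch[length(ch)], integer(1)))
    cnt <- table(ends)
    jn <- as.integer(names(cnt)[cnt >= 2L])
    bad <- keep & !(vapply(mesh@chains[as.character(ed$id)], `[`, integer(1), 1L)
                    %in% jn) &
      !(vapply(mesh@chains[as.character(ed$id)],
               function(ch) ch[length(ch)], integer(1)) %in% jn)
    if (!any(bad & keep)) break
    keep <- keep & !bad
  }
  ## a node retained as a junction must keep its full complement of parent
  ## edges, otherwise its force balance would be silently violated; drop
  ## frayed edges that would create such incomplete junctions
  parentInc <- table(c(end1, end2))
  repeat {
    ke <- which(keep)
    se1 <- vapply(chains[as.character(ed$id[ke])], `[`, integer(1), 1L)
    se2 <- vapply(chains[as.character(ed$id[ke])],
                  function(ch) ch[length(ch)], integer(1))
    subInc <- table(c(se1, se2))
    badN <- as.integer(names(subInc)[subInc >= 2L &
      subInc < parentInc[names(subInc)]])
    badN <- setdiff(badN, jset)
    if (!length(badN)) break
    victim <- frayed & keep & (end1 %in% badN | end2 %in% badN)
    if (!any(victim)) break
    keep <- keep & !victim
  }
  keptE <- ed$id[keep]
  P <- setdiff(unique(c(ed$cellLeft[keep], ed$cellRight[keep])), K)
  nodesKeep <- unique(unlist(chains[as.character(keptE)]))
  ni <- match(nodesKeep, mesh@nodes$id)
  nodes <- data.frame(id = nodesKeep, x = mesh@nodes$x[ni], y = mesh@nodes$y[ni])
  edgeDf <- ed[keep, c("id", "cellLeft", "cellRight")]
  cells <- data.frame(id = c(K, P),
                      partial = c(rep(FALSE, length(K)), rep(TRUE, length(P))),
                      medium = c(rep(FALSE, length(K)), P == MEDIUM))
  ce <- c(setNames(mesh@cellEdges[as.character(K)], as.character(K)),
          setNames(lapply(P, function(p)
            keptE[edgeDf$cellLeft == p | edgeDf$cellRight == p]),
            as.character(P)))
  sub <- buildMesh(nodes, edgeDf, cells, chains[as.character(keptE)], ce,
                   mesh@lengthScale)
  attr(sub, "window") <- window
  subTruth <- new("TissueTruth",
                  tensions = truth@tensions[as.character(keptE)],
                  pressures = truth@pressures[
                    intersect(as.character(c(K, P)), names(truth@pressures))],
                  cellTypes = truth@cellTypes[
                    intersect(as.character(c(K, P)), names(truth@cellTypes))])
  list(mesh = sub, truth = subTruth, window = window, completeCells = K)
}

## ---- noise and metrics ------------------------------------------------------

#' Inject measurement noise into an edge-geometry table
#'
#' Noise level \code{x} adds independent Gaussian errors of RMS \code{x}
#' degrees to every limiting tangent angle (each edge end independently) and
#' multiplies every signed curvature by \code{1 + N(0, (x/100)^2)} (an RMS
#' relative error of \code{x} percent).  Noise perturbs the measurements, not
#' the node coordinates.
#'
#' @param geom edge-geometry table from \code{\link{edgeGeometry}}.
#' @param level noise level \code{x >= 0}.
#' @param seed integer seed for reproducibility.
#' @return perturbed copy of \code{geom}.
#' @export
injectNoise <- function(geom, level, seed = 1L) {
  stopifnot(level >= 0)
  if (level == 0) return(geom)
  set.seed(seed)
  n <- nrow(geom)
  sdAng <- level * pi / 180
  geom$theta1 <- geom$theta1 + rnorm(n, 0, sdAng)
  geom$theta2 <- geom$theta2 + rnorm(n, 0, sdAng)
  geom$curvature <- geom$curvature * (1 + rnorm(n, 0, level / 100))
  geom
}

#' Normalized tension and pressure error metrics
#'
#' Both the inferred and the ground-truth force sets are standardized over
#' the compared sets (tensions scaled to mean one over the common edges;
#' pressures demeaned over the common cells and divided by the corresponding
#' mean tension), then compared as RMS differences: the tension error is
#' normalized to the mean ground-truth tension and the pressure error to the
#' RMS ground-truth pressure, both reported as percentages.
#'
#' @param gammaHat inferred tensions (named by edge id).
#' @param pHat inferred pressures (named by cell id; may be NULL/empty).
#' @param truth a \code{\linkS4class{TissueTruth}}.
#' @param solution optional \code{\linkS4class{ForceSolution}}; when
#'   supplied, the comparison is restricted to the largest connected tension
#'   and pressure components.  Relative scales between disconnected
#'   components are not determined by the image (each component carries its
#'   own normalization), so mixing components would conflate gauge freedom
#'   with inference error.
#' @return list with \code{tensionErrorPct}, \code{pressureErrorPct},
#'   \code{nEdges}, \code{nCells}.
#' @export
errorMetrics <- function(gammaHat, pHat, truth, solution = NULL) {
  if (!is.null(solution)) {
    ts <- solution@systems$tension
    if (length(ts) > 1L) {
      big <- ts[[which.max(vapply(ts, function(s) length(s@cols), integer(1)))]]
      gammaHat <- gammaHat[as.character(big@cols)]
    }
    ps <- solution@systems$pressure
    if (length(ps) > 1L && length(pHat)) {
      bigP <- ps[[which.max(vapply(ps, function(s) length(s@cols), integer(1)))]]
      pHat <- pHat[as.character(bigP@cols)]
    }
  }
  ce <- intersect(names(gammaHat), names(truth@tensions))
  if (!length(ce)) stop("no edges in common between solution and truth")
  gh <- gammaHat[ce] / mean(gammaHat[ce])
  gt <- truth@tensions[ce] / mean(truth@tensions[ce])
  tErr <- 100 * sqrt(mean((gh - gt)^2))
  pErr <- NA_real_; nc <- 0L
  if (length(pHat) && length(truth@pressures)) {
    cc <- intersect(names(pHat), names(truth@pressures))
    if (length(cc) >= 2L) {
      ph <- (pHat[cc] - mean(pHat[cc])) / mean(gammaHat[ce])
      pt <- (truth@pressures[cc] - mean(truth@pressures[cc])) /
        mean(truth@tensions[ce])
      pErr <- 100 * sqrt(mean((ph - pt)^2)) / sqrt(mean(pt^2))
      nc <- length(cc)
    }
  }
  list(tensionErrorPct = tErr, pressureErrorPct = pErr,
       nEdges = length(ce), nCells = nc)
}

## ---- high-level convenience -------------------------------------------------

#' Generate, anneal and extract a synthetic tissue with ground truth
#'
#' The full forward pipeline: Voronoi patch, random cell types with the
#' 5:6:7:10:11:12 interface-tension table, annealing to equilibrium with the
#' patch boundary pinned, and extraction of a frayed interior region.
#'
#' @param nCells cells in the full patch (default 120).
#' @param seed master seed; stage seeds are derived from it.
#' @param targetComplete complete cells to retain in the extracted region
#'   (default 50).
#' @param nIntermediate intermediate nodes per edge (default 4).
#' @param areaStiffness area penalty stiffness (default 100).
#' @param ... further arguments to \code{\link{annealMesh}}.
#' @return list with \code{mesh}, \code{truth} (the extracted region and its
#'   ground truth), \code{patch}, \code{patchTruth} (the annealed full
#'   patch), \code{window}.
#' @export
syntheticTissue <- function(nCells = 120L, seed = 1L, targetComplete = 50L,
                            nIntermediate = 4L, areaStiffness = 100, ...) {
  patch <- generatePatch(nCells, seed = seed, nIntermediate = nIntermediate)
  truth <- assignTypesAndTensions(patch, seed = seed + 1L)
  ann <- annealMesh(patch, truth, areaStiffness = areaStiffness, ...)
  reg <- extractRegion(ann$mesh, ann$truth, targetComplete = targetComplete)
  list(mesh = reg$mesh, truth = reg$truth, patch = ann$mesh,
       patchTruth = ann$truth, window = reg$window,
       completeCells = reg$completeCells, maxForce = ann$maxForce)
}

#' Run the validation protocol
#'
#' For each angle method and noise level, infers forces on a synthetic
#' tissue and reports the mean and standard deviation of the normalized
#' tension and pressure errors over \code{nRuns} noise realizations
#' (noise level 0 is deterministic and run once).  The
#' \code{"polyarc_short"} method is polyarc inference with edges lacking
#' intermediate nodes excluded.
#'
#' @param tissue result of \code{\link{syntheticTissue}} (generated from
#'   \code{seed} if NULL).
#' @param methods subset of \code{c("polyarc", "polyarc_short",
#'   "closest_segment", "minimal_polygon")}.
#' @param noiseLevels numeric noise levels (default \code{c(0, 1, 2, 5)}).
#' @param nRuns noise realizations per level (default 100).
#' @param seed master seed (tissue generation and noise fan-out).
#' @param csv optional path for a CSV report.
#' @param ... passed to \code{\link{syntheticTissue}} when generating.
#' @return data.frame with columns \code{method}, \code{noise},
#'   \code{tensionMean}, \code{tensionSD}, \code{pressureMean},
#'   \code{pressureSD}, \code{nRuns}.
#' @export
runValidation <- function(tissue = NULL,
                          methods = c("polyarc", "polyarc_short",
                                      "closest_segment", "minimal_polygon"),
                          noiseLevels = c(0, 1, 2, 5), nRuns = 100L,
                          seed = 1L, csv = NULL, ...) {
  if (is.null(tissue)) tissue <- syntheticTissue(seed = seed, ...)
  mesh <- tissue$mesh; truth <- tissue$truth
  out <- list()
  for (method in methods) {
    base <- if (method == "polyarc_short") "polyarc" else method
    geom0 <- edgeGeometry(mesh, base)
    excl <- if (method == "polyarc_short")
      geom0$edge[geom0$nIntermediate == 0L] else integer(0)
    for (lev in noiseLevels) {
      runs <- if (lev == 0) 1L else nRuns
      tE <- numeric(runs); pE <- numeric(runs)
      for (r in seq_len(runs)) {
        g <- injectNoise(geom0, lev, seed = seed + 7919L * r + round(100 * lev))
        sol <- suppressWarnings(
          inferForces(mesh, excludedEdges = excl, geom = g))
        m <- errorMetrics(standardTensions(sol), standardPressures(sol),
                          truth, solution = sol)
        tE[r] <- m$tensionErrorPct; pE[r] <- m$pressureErrorPct
      }
      out[[length(out) + 1L]] <- data.frame(
        method = method, noise = lev,
        tensionMean = mean(tE), tensionSD = if (runs > 1L) sd(tE) else NA_real_,
        pressureMean = mean(pE, na.rm = TRUE),
        pressureSD = if (runs > 1L) sd(pE, na.rm = TRUE) else NA_real_,
        nRuns = runs)
    }
  }
  rep <- do.call(rbind, out)
  attr(rep, "seed") <- seed
  if (!is.null(csv)) write.csv(rep, csv, row.names = FALSE)
  rep
}
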