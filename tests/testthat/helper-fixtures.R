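## Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- build()
  .fixtureCache[[key]]
}

## A small annealed tissue with a frayed extracted region (~15 complete
## cells): cheap enough for many unit tests.
smallTissue <- function() {
  .cached("smallTissue", function()
    suppressWarnings(syntheticTissue(nCells = 48, seed = 11,
                                     targetComplete = 15)))
}

## Study-scale tissue (~50 complete cells) for the acceptance checks.
studyTissue <- function(seed = 1) {
  .cached(paste0("studyTissue", seed), function()
    suppressWarnings(syntheticTissue(nCells = 120, seed = seed,
                                     targetComplete = 50)))
}

## Ensemble of study-scale tissues (generated lazily; used by acceptance
## tests only).
studyEnsemble <- function(n = 10) {
  lapply(seq_len(n), studyTissue)
}

## A two-cell "lens" mesh: two cells separated by a circular interface, with
## known geometry.  The shared edge bulges into cell 2 with radius `rho`.
lensMesh <- function(rho = 2, half = 0.8) {
  ## junctions at (0, +-half); shared edge = arc of radius rho through them,
  ## center on the cell-1 side (x < 0), bulging into cell 2 (x > 0)
  cx <- -sqrt(rho^2 - half^2)
  thTop <- atan2(half, -cx); thBot <- -thTop
  th <- seq(thTop, thBot, length.out = 9)
  arcShared <- cbind(cx + rho * cos(th), rho * sin(th))
  ## outer boundaries: big arcs through the same junctions
  Rout <- 1.6; cxr <- sqrt(Rout^2 - half^2)
  phTop <- atan2(half, -cxr)
  ph <- seq(phTop, 2 * pi - phTop, length.out = 15)
  arcLeft <- cbind(-cxr + Rout * cos(rev(ph)), Rout * sin(rev(ph)))
  arcRight <- cbind(cxr - Rout * cos(ph), Rout * sin(ph))
  pts <- rbind(arcShared, arcLeft[-c(1, nrow(arcLeft)), ],
               arcRight[-c(1, nrow(arcRight)), ])
  nodes <- data.frame(id = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2])
  nShared <- nrow(arcShared)
  nL <- nrow(arcLeft) - 2
  idsShared <- seq_len(nShared)
  idsLeft <- c(1L, nShared + seq_len(nL), nShared)          # top -> bottom
  idsRight <- c(1L, nShared + nL + seq_len(nrow(arcRight) - 2), nShared)
  ## chain orientations: going from (0,half) to (0,-half) along the bulge
  ## (x>0), the left side is x>0 = cell 2.  The outer arcs border the
  ## medium (cell 0).
  edges <- data.frame(id = 1:3,
                      cellLeft = c(2L, 1L, 2L),
                      cellRight = c(1L, 0L, 0L))
  chains <- list(`1` = idsShared, `2` = idsLeft, `3` = rev(idsRight))
  cells <- data.frame(id = c(1L, 2L, 0L), partial = c(FALSE, FALSE, TRUE),
                      medium = c(FALSE, FALSE, TRUE))
  cellEdges <- list(`1` = c(2L, 1L), `2` = c(3L, 1L), `0` = c(2L, 3L))
  buildMesh(nodes, edges, cells, chains, cellEdges)
}

## Random small Voronoi mesh for property-style tests.
randomSmallMesh <- function(seed, nCells = 9) {
  generatePatch(nCells, seed = seed, nIntermediate = 2L, lloyd = 1L)
}

## Independent breadth-first search over a junction graph (oracle for
## tensionComponents).
bfsComponents <- function(vertices, edgePairs) {
  adj <- setNames(vector("list", length(vertices)), as.character(vertices))
  if (nrow(edgePairs)) for (k in seq_len(nrow(edgePairs))) {
    a <- as.character(edgePairs[k, 1]); b <- as.character(edgePairs[k, 2])
    adj[[a]] <- c(adj[[a]], edgePairs[k, 2])
    adj[[b]] <- c(adj[[b]], edgePairs[k, 1])
  }
  seen <- setNames(rep(FALSE, length(vertices)), as.character(vertices))
  comps <- list()
  for (v in vertices) {
    if (seen[[as.character(v)]]) next
    queue <- v; comp <- integer(0)
    seen[[as.character(v)]] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      for (nb in adj[[as.character(cur)]]) {
        if (!seen[[as.character(nb)]]) {
          seen[[as.character(nb)]] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

## Canonical form of a component partition, for set comparison.
canonComponents <- function(comps) {
  s <- lapply(comps, function(x) unname(sort(as.integer(x))))
  unname(s[order(vapply(s, `[`, integer(1), 1))])
}
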