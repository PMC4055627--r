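## Rasterization and re-digitization: mesh -> pixel image -> mesh.
## Emulates the pixelation and segmentation noise of real image analysis in
## four steps: (1) draw each cell-cell boundary as a spline curve onto an
## image; (2) label the enclosed regions and grow them over the drawn lines
## (watershed-style); (3) relabel regions to match the original cells by
## interior overlap; (4) trace the relabeled image back into a mesh.

## point-in-polygon (even-odd rule), vectorized over points
.pip <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & is.finite(cross))
    j <- i
  }
  inside
}

#' Rasterize a mesh to a label image
#'
#' Draws every edge chain as a dense interpolating spline onto a pixel grid
#' of the requested width, labels the interior regions (4-connected), grows
#' region labels over the one-pixel boundary lines, and matches regions to
#' the original cells by sampling interior points of each cell polygon.
#' Regions that match no cell (typically rim fragments between frayed stub
#' edges) receive fresh labels and later become partial cells.
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param widthPx image width in pixels (>= 100).
#' @param window optional c(xmin, xmax, ymin, ymax) giving the imaged
#'   extent; default is the mesh's node bounding box.
#' @return list with \code{labels} (integer matrix, original cell ids where
#'   matched), \code{boundary} (logical matrix), \code{scale} (pixels per
#'   length unit), \code{origin} (xmin, ymin), \code{matched} (named map
#'   region -> cell id), \code{lost} (cell ids that vanished at this
#'   resolution).
#' @export
rasterizeMesh <- function(mesh, widthPx = 675L, window = NULL) {
  if (widthPx < 100L) stop("image must be at least 100 px wide")
  if (is.null(window)) window <- attr(mesh, "window")
  if (is.null(window))
    window <- c(range(mesh@nodes$x), range(mesh@nodes$y))
  xmin <- window[1L]; xmax <- window[2L]; ymin <- window[3L]; ymax <- window[4L]
  s <- (widthPx - 1L) / (xmax - xmin)
  heightPx <- as.integer(round((ymax - ymin) * s)) + 1L
  toCol <- function(x) pmin(pmax(1L, as.integer(round((x - xmin) * s)) + 1L), widthPx)
  toRow <- function(y) pmin(pmax(1L, as.integer(round((ymax - y) * s)) + 1L), heightPx)
  boundary <- matrix(FALSE, heightPx, widthPx)
  for (id in mesh@edges$id) {
    xy <- nodeXY(mesh, .chainOf(mesh, id))
    seg <- sqrt(rowSums(diff(xy)^2))
    len <- sum(seg)
    nDense <- max(8L, as.integer(ceiling(len * s / 0.3)))
    t0 <- c(0, cumsum(seg))
    tq <- seq(0, len, length.out = nDense)
    ## spline interpolation through the chain points (falls back to linear
    ## interpolation for two-point chains)
    xs <- if (nrow(xy) > 2L) spline(t0, xy[, 1L], xout = tq)$y
          else stats::approx(t0, xy[, 1L], xout = tq)$y
    ys <- if (nrow(xy) > 2L) spline(t0, xy[, 2L], xout = tq)$y
          else stats::approx(t0, xy[, 2L], xout = tq)$y
    ## points beyond the imaged frame are simply not drawn (the frame
    ## truncates the frayed continuations, as in a real micrograph)
    inW <- xs >= xmin & xs <= xmax & ys >= ymin & ys <= ymax
    if (!any(inW)) next
    boundary[cbind(toRow(ys[inW]), toCol(xs[inW]))] <- TRUE
  }
  ## label interior regions (4-connected), then grow them over the drawn
  ## one-pixel lines by Voronoi-style propagation (watershed relabeling)
  regions <- EBImage::bwlabel(!boundary)
  regions <- EBImage::imageData(
    EBImage::propagate(EBImage::Image(matrix(0, nrow(boundary), ncol(boundary))),
                       seeds = EBImage::Image(regions)))
  storage.mode(regions) <- "integer"
  ## match regions to cells by interior sampling: grid points inside the
  ## polygon for complete cells, points offset just inside each kept edge
  ## for partial cells (whose boundaries are open)
  realC <- mesh@cells$id[!mesh@cells$medium]
  matched <- integer(0); lost <- integer(0)
  partialFlag <- mesh@cells$partial[match(realC, mesh@cells$id)]
  for (cid in realC) {
    isPartial <- partialFlag[match(cid, realC)]
    px <- py <- numeric(0)
    if (!isPartial) {
      poly <- tryCatch(cellPolygon(mesh, cid), error = function(e) NULL)
      if (!is.null(poly) && nrow(poly) >= 3L) {
        bb <- c(range(poly[, 1L]), range(poly[, 2L]))
        g <- expand.grid(x = seq(bb[1L], bb[2L], length.out = 9L)[2:8],
                         y = seq(bb[3L], bb[4L], length.out = 9L)[2:8])
        ins <- .pip(g$x, g$y, poly)
        px <- g$x[ins]; py <- g$y[ins]
      }
    } else {
      off <- 2.5 / s
      for (e in mesh@cellEdges[[as.character(cid)]]) {
        i <- match(e, mesh@edges$id)
        ch <- nodeXY(mesh, .chainOf(mesh, e))
        k <- max(1L, nrow(ch) %/% 2L)
        d <- ch[min(k + 1L, nrow(ch)), ] - ch[k, ]
        d <- d / max(sqrt(sum(d^2)), 1e-12)
        nrm <- c(-d[2L], d[1L])
        if (mesh@edges$cellRight[i] == cid) nrm <- -nrm
        q <- (ch[k, ] + ch[min(k + 1L, nrow(ch)), ]) / 2 + off * nrm
        px <- c(px, q[1L]); py <- c(py, q[2L])
      }
    }
    inW <- px >= xmin & px <= xmax & py >= ymin & py <= ymax
    px <- px[inW]; py <- py[inW]
    if (!length(px)) { if (!isPartial) lost <- c(lost, cid); next }
    labsAt <- regions[cbind(toRow(py), toCol(px))]
    labsAt <- labsAt[labsAt > 0L]
    if (!length(labsAt)) { if (!isPartial) lost <- c(lost, cid); next }
    best <- as.integer(names(sort(table(labsAt), decreasing = TRUE))[1L])
    matched[as.character(cid)] <- best
  }
  if (length(lost))
    warning("cell(s) vanished at this resolution: ", paste(lost, collapse = ", "))
  ## relabel: region -> original cell id; unmatched regions get fresh ids
  out <- matrix(0L, heightPx, widthPx)
  maxId <- max(c(mesh@cells$id, 0L))
  regionToCell <- integer(max(regions))
  ## complete cells claim regions first; a partial cell never steals a
  ## region already claimed
  ord <- names(matched)[order(partialFlag[match(as.integer(names(matched)),
                                                realC)])]
  for (cid in ord) {
    r <- matched[[cid]]
    if (regionToCell[r] == 0L) regionToCell[r] <- as.integer(cid)
  }
  fresh <- maxId
  for (r in seq_len(max(regions)))
    if (regionToCell[r] == 0L) { fresh <- fresh + 1L; regionToCell[r] <- fresh }
  out[regions > 0L] <- regionToCell[regions[regions > 0L]]
  list(labels = out, boundary = boundary, scale = s,
       origin = c(xmin, ymin), matched = matched, lost = lost)
}

#' Rasterize a mesh and re-digitize it back into a mesh
#'
#' Runs the full pixelation round trip: draw, label, relabel to the
#' original cell ids, and re-extract a mesh from the label image with
#' \code{\link{meshFromLabels}}.  Because matched regions keep their
#' original cell ids, edges of the new mesh correspond to original edges
#' through their unordered side-cell pair.
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param widthPx image width in pixels.
#' @param window optional imaged extent.
#' @return list with \code{mesh} (re-extracted, in pixel coordinates),
#'   \code{raster} (the \code{\link{rasterizeMesh}} result),
#'   \code{edgeMap} (data.frame mapping original edge id to new edge id via
#'   side-cell pairs).
#' @export
rasterizeRedigitize <- function(mesh, widthPx = 675L, window = NULL) {
  ras <- rasterizeMesh(mesh, widthPx, window)
  unmatched <- setdiff(unique(as.vector(ras$labels)),
                       c(0L, as.integer(names(ras$matched))))
  newMesh <- suppressWarnings(meshFromLabels(ras$labels,
                                             lengthScale = 1 / ras$scale,
                                             outsideLabels = unmatched))
  pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  oldKey <- pairKey(mesh@edges$cellLeft, mesh@edges$cellRight)
  newKey <- pairKey(newMesh@edges$cellLeft, newMesh@edges$cellRight)
  ## only unambiguous pairs (appearing once on each side) are mapped
  tabOld <- table(oldKey); tabNew <- table(newKey)
  uniq <- names(tabOld)[tabOld == 1L]
  uniq <- intersect(uniq, names(tabNew)[tabNew == 1L])
  em <- data.frame(
    oldEdge = mesh@edges$id[match(uniq, oldKey)],
    newEdge = newMesh@edges$id[match(uniq, newKey)])
  list(mesh = newMesh, raster = ras, edgeMap = em)
}

#' Tension/pressure accuracy through the re-digitization round trip
#'
#' Rasterizes an annealed synthetic region at the given width, re-extracts
#' the mesh, runs polyarc inference on it, and compares the inferred forces
#' with the ground truth through the edge and cell correspondences.
#'
#' @param mesh annealed region mesh.
#' @param truth its \code{\linkS4class{TissueTruth}}.
#' @param widthPx image width in pixels.
#' @param method angle method for inference on the re-extracted mesh.
#' @param minChordPx edges whose endpoint junctions are closer than this (in
#'   pixels) are excluded from the analysis: their approach angles cannot be
#'   determined from a couple of pixels, and the overdetermined equations
#'   tolerate the loss of their junctions.
#' @param maxFitRMSPx edges whose arc-fit RMS exceeds this (in pixels) are
#'   excluded as crenulated / poorly defined.
#' @param curvatureMinChordPx edges shorter than this contribute no pressure
#'   equation: like stub edges, they are too short to carry reliable
#'   curvature information at pixel resolution.
#' @param trimEnds chain points at each end excluded from the arc fits (see
#'   \code{\link{edgeGeometry}}).
#' @return list with the \code{\link{errorMetrics}} fields plus
#'   \code{redigitized} (the round-trip result) and \code{solution}.
#' @export
redigitizeErrors <- function(mesh, truth, widthPx = 675L,
                             method = "polyarc", minChordPx = 10,
                             maxFitRMSPx = 0.7, curvatureMinChordPx = 30,
                             trimEnds = 3L) {
  rd <- rasterizeRedigitize(mesh, widthPx)
  geom <- edgeGeometry(rd$mesh, method, trimEnds = trimEnds)
  excl <- geom$edge[geom$chord < minChordPx | geom$fitRMS > maxFitRMSPx]
  geom$curvatureUsable <- geom$curvatureUsable &
    geom$chord >= curvatureMinChordPx
  sol <- suppressWarnings(inferForces(rd$mesh, geom = geom,
                                      excludedEdges = excl))
  gam <- standardTensions(sol)
  ## express inferred tensions under original edge ids
  em <- rd$edgeMap
  gamOld <- setNames(gam[as.character(em$newEdge)], as.character(em$oldEdge))
  gamOld <- gamOld[!is.na(gamOld)]
  ## image-mesh pressures are per pixel; convert to the mesh length units
  p <- standardPressures(sol) / rd$mesh@lengthScale
  m <- errorMetrics(gamOld, p, truth)
  c(m, list(redigitized = rd, solution = sol))
}
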