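## Bounded Voronoi tessellation by iterative half-plane clipping.
## Each cell is the intersection of the bounding box with the half-planes
## closer to its seed than to any other seed; neighbors are processed in
## order of distance with an early exit once no further seed can cut.

## Sutherland-Hodgman clip of a convex polygon against the half-plane
## {x : (x - m) . d <= 0}
.clipHalfPlane <- function(poly, m, d) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  s <- (poly[, 1L] - m[1L]) * d[1L] + (poly[, 2L] - m[2L]) * d[2L]
  inside <- s <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(NA_real_, n + 2L, 2L); k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) { k <- k + 1L; out[k, ] <- poly[i, ] }
    if (inside[i] != inside[j]) {
      t <- s[i] / (s[i] - s[j])
      k <- k + 1L
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

#' Bounded Voronoi tessellation
#'
#' Computes the Voronoi cell polygon of every seed point, clipped to a
#' rectangular bounding box.  Intended for modest point counts (hundreds);
#' cells are convex and returned counter-clockwise.
#'
#' @param pts numeric n x 2 matrix of seed points.
#' @param bbox c(xmin, xmax, ymin, ymax).
#' @return list of counter-clockwise polygon matrices, one per seed.
#' @export
voronoiPolygons <- function(pts, bbox) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  base <- rbind(c(bbox[1L], bbox[3L]), c(bbox[2L], bbox[3L]),
                c(bbox[2L], bbox[4L]), c(bbox[1L], bbox[4L]))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    d2 <- (pts[, 1L] - p[1L])^2 + (pts[, 2L] - p[2L])^2
    ord <- order(d2)[-1L]
    poly <- base
    for (j in ord) {
      ## no seed farther than twice the max vertex distance can cut
      maxR2 <- max((poly[, 1L] - p[1L])^2 + (poly[, 2L] - p[2L])^2)
      if (d2[j] > 4 * maxR2) break
      poly <- .clipHalfPlane(poly, (p + pts[j, ]) / 2, pts[j, ] - p)
      if (nrow(poly) < 3L) break
    }
    if (shoelaceArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    out[[i]] <- poly
  }
  out
}

## polygon centroid (for Lloyd relaxation)
.polyCentroid <- function(poly) {
  n <- nrow(poly)
  i2 <- c(2:n, 1L)
  cr <- poly[, 1L] * poly[i2, 2L] - poly[i2, 1L] * poly[, 2L]
  a <- sum(cr) / 2
  c(sum((poly[, 1L] + poly[i2, 1L]) * cr) / (6 * a),
    sum((poly[, 2L] + poly[i2, 2L]) * cr) / (6 * a))
}
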