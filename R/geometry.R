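## Edge geometry: circular-arc fits, limiting tangents, signed curvature.

#' Fit a circular arc to an ordered point chain
#'
#' Algebraic (Kasa) circle fit refined by one Gauss-Newton pass on the
#' geometric distances.  The edge is declared straight when it has only two
#' points, when the points are collinear within tolerance (maximum
#' perpendicular deviation from the chord relative to chord length), or when
#' the fitted sagitta-to-chord ratio falls below \code{straightnessTol}.
#'
#' @param points numeric n x 2 matrix of ordered chain points.
#' @param straightnessTol dimensionless sagitta/chord threshold below which
#'   the edge is treated as straight (default 1e-3).
#' @return list with elements \code{center} (length-2, NA if straight),
#'   \code{radius} (NA if straight), \code{isStraight}, \code{fitRMS}
#'   (point-to-arc RMS deviation; 0 for straight edges it is the RMS
#'   perpendicular deviation from the chord).
#' @examples
#' th <- seq(0, pi / 2, length.out = 12)
#' fitCircularArc(cbind(10 * cos(th), 10 * sin(th)))$radius  # 10
#' @export
fitCircularArc <- function(points, straightnessTol = 1e-3) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points to fit an arc")
  p1 <- points[1L, ]; p2 <- points[n, ]
  chordVec <- p2 - p1
  chord <- sqrt(sum(chordVec^2))
  if (chord == 0) stop("zero-length chord")
  straight <- function(rms) list(center = c(NA_real_, NA_real_),
                                 radius = NA_real_, isStraight = TRUE,
                                 fitRMS = rms)
  ## perpendicular deviations from the chord
  nhat <- c(-chordVec[2L], chordVec[1L]) / chord
  dev <- (sweep(points, 2L, p1) %*% nhat)[, 1L]
  if (n == 2L || max(abs(dev)) / chord < straightnessTol)
    return(straight(sqrt(mean(dev^2))))

  ## Kasa: minimize sum((|p - c|^2 - r^2)^2), linear in (a, b, c0)
  x <- points[, 1L]; y <- points[, 2L]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(straight(sqrt(mean(dev^2))))
  cen <- sol[1:2]
  r <- sqrt(max(sol[3L] + sum(cen^2), 0))
  ## one Gauss-Newton refinement on geometric residuals |p - c| - r
  for (pass in 1L) {
    dx <- x - cen[1L]; dy <- y - cen[2L]
    d <- sqrt(dx^2 + dy^2)
    if (any(d < .Machine$double.eps)) break
    res <- d - r
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cen <- cen + step[1:2]; r <- r + step[3L]
  }
  if (!is.finite(r) || r <= 0) return(straight(sqrt(mean(dev^2))))
  sagitta <- r - sqrt(max(r^2 - (chord / 2)^2, 0))
  if (sagitta / chord < straightnessTol) return(straight(sqrt(mean(dev^2))))
  d <- sqrt((x - cen[1L])^2 + (y - cen[2L])^2)
  list(center = unname(cen), radius = unname(r), isStraight = FALSE,
       fitRMS = sqrt(mean((d - r)^2)))
}

#' Limiting tangent of an edge at a junction
#'
#' For arcs, the tangent of the fitted circle at the point of its closest
#' approach to the junction, oriented away from the junction (toward the edge
#' interior).  For straight edges, the unit chord direction away from the
#' junction.
#'
#' @param arc result of \code{\link{fitCircularArc}} for this chain.
#' @param chain numeric n x 2 matrix of chain points.
#' @param atEnd 1 (first chain endpoint) or 2 (second).
#' @return unit 2-vector pointing away from the junction.
#' @export
limitingTangent <- function(arc, chain, atEnd = 1L) {
  chain <- as.matrix(chain)
  n <- nrow(chain)
  J <- if (atEnd == 1L) chain[1L, ] else chain[n, ]
  ## interior reference ~30% along the chain: robust to direction noise of
  ## the first segment (e.g. pixel staircases) while staying well within a
  ## half-turn for any sub-semicircular arc
  k <- max(2L, min(n, ceiling(0.3 * n)))
  inward <- if (atEnd == 1L) chain[k, ] - chain[1L, ]
            else chain[n + 1L - k, ] - chain[n, ]
  if (sum(inward^2) == 0)
    inward <- if (atEnd == 1L) chain[2L, ] - chain[1L, ]
              else chain[n - 1L, ] - chain[n, ]
  if (sum(inward^2) == 0) stop("zero-length chord at junction")
  if (isTRUE(arc$isStraight)) {
    d <- if (atEnd == 1L) chain[n, ] - chain[1L, ] else chain[1L, ] - chain[n, ]
    return(d / sqrt(sum(d^2)))
  }
  rad <- J - arc$center
  rl <- sqrt(sum(rad^2))
  if (rl < .Machine$double.eps) stop("junction coincides with arc center")
  t <- c(-rad[2L], rad[1L]) / rl
  ## pick the tangent pointing into the edge interior
  if (sum(t * inward) < 0) t <- -t
  t
}

#' Junction tangent under a chosen angle-determination method
#'
#' Three variants of determining the angle at which an edge approaches a
#' junction: \code{"polyarc"} uses the fitted-arc limiting tangent;
#' \code{"closest_segment"} uses the direction of the chain segment adjacent
#' to the junction; \code{"minimal_polygon"} treats the edge as a single
#' straight chord between its endpoints.
#'
#' @param chain numeric n x 2 matrix of chain points.
#' @param arc arc fit for the chain (only used by \code{"polyarc"}).
#' @param method one of \code{"polyarc"}, \code{"closest_segment"},
#'   \code{"minimal_polygon"}.
#' @param atEnd 1 or 2.
#' @return unit 2-vector pointing away from the junction.
#' @export
angleVariantTangent <- function(chain, arc, method = c("polyarc",
                                "closest_segment", "minimal_polygon"),
                                atEnd = 1L) {
  method <- match.arg(method)
  chain <- as.matrix(chain)
  n <- nrow(chain)
  d <- switch(method,
    polyarc = return(limitingTangent(arc, chain, atEnd)),
    closest_segment = if (atEnd == 1L) chain[2L, ] - chain[1L, ]
                      else chain[n - 1L, ] - chain[n, ],
    minimal_polygon = if (atEnd == 1L) chain[n, ] - chain[1L, ]
                      else chain[1L, ] - chain[n, ])
  d / sqrt(sum(d^2))
}

#' Signed curvature of an edge
#'
#' Zero for straight edges; otherwise \code{+/- 1/radius}, positive when the
#' edge bulges (is convex) into the right-hand cell, i.e. when the arc center
#' lies on the left (cellLeft) side of the chain.  With the pressure-jump
#' convention \eqn{\Delta p = p_{left} - p_{right} = \gamma \kappa}, a
#' positive curvature means the left cell has the higher pressure.
#'
#' @param arc arc fit for the chain.
#' @param chain numeric n x 2 matrix of chain points (ordered with cellLeft on
#'   the left).
#' @return signed curvature (1/length units).
#' @export
signedCurvature <- function(arc, chain) {
  if (isTRUE(arc$isStraight)) return(0)
  chain <- as.matrix(chain)
  n <- nrow(chain)
  ## side test against the chord: robust to local (e.g. pixel-staircase)
  ## direction noise; cell edges never exceed a semicircle, for which the
  ## chord direction gives the correct side
  d <- chain[n, ] - chain[1L, ]
  if (sum(d^2) < .Machine$double.eps) {
    k <- max(1L, floor(n / 2))
    d <- chain[min(k + 1L, n), ] - chain[k, ]
  }
  v <- arc$center - chain[1L, ]
  s <- d[1L] * v[2L] - d[2L] * v[1L]   # > 0: center on the left
  sign(s) / arc$radius
}

#' Per-edge geometry table of a mesh
#'
#' Fits a circular arc to every edge chain and tabulates, per edge, the arc
#' parameters, limiting tangent angles at both junction ends (under the
#' requested angle method), signed curvature, chord length and fit quality.
#' These are the measurements from which the tension and pressure systems are
#' assembled; noise-injection experiments perturb this table, not the mesh.
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param method angle-determination method (see
#'   \code{\link{angleVariantTangent}}).
#' @param straightnessTol sagitta/chord threshold for straightness.
#' @param trimEnds number of chain points at each end excluded from the arc
#'   fit (tangents are still evaluated at the junction endpoints).  Useful
#'   for pixel meshes, where the points next to a junction are the least
#'   reliable; applied only to chains long enough to spare them.
#' @return data.frame with one row per edge: \code{edge}, \code{j1},
#'   \code{j2}, \code{stub}, \code{cellLeft}, \code{cellRight},
#'   \code{isStraight}, \code{radius}, \code{curvature} (signed),
#'   \code{theta1}, \code{theta2} (tangent angles, radians, pointing away
#'   from the respective junction), \code{chord}, \code{fitRMS},
#'   \code{nIntermediate}, \code{curvatureUsable} (chains of only 2 nodes
#'   are straight by construction and unusable for pressure equations).
#' @export
edgeGeometry <- function(mesh, method = c("polyarc", "closest_segment",
                                          "minimal_polygon"),
                         straightnessTol = 1e-3, trimEnds = 0L) {
  method <- match.arg(method)
  ed <- mesh@edges
  nE <- nrow(ed)
  out <- data.frame(edge = ed$id, j1 = ed$j1, j2 = ed$j2, stub = ed$stub,
                    cellLeft = ed$cellLeft, cellRight = ed$cellRight,
                    isStraight = NA, radius = NA_real_, curvature = NA_real_,
                    theta1 = NA_real_, theta2 = NA_real_, chord = NA_real_,
                    fitRMS = NA_real_, nIntermediate = NA_integer_,
                    curvatureUsable = NA)
  for (i in seq_len(nE)) {
    ch <- nodeXY(mesh, .chainOf(mesh, ed$id[i]))
    fitPts <- if (trimEnds > 0L && nrow(ch) >= 2L * trimEnds + 8L)
      ch[(1L + trimEnds):(nrow(ch) - trimEnds), , drop = FALSE] else ch
    arc <- fitCircularArc(fitPts, straightnessTol)
    t1 <- angleVariantTangent(ch, arc, method, atEnd = 1L)
    t2 <- angleVariantTangent(ch, arc, method, atEnd = 2L)
    out$isStraight[i] <- arc$isStraight
    out$radius[i] <- arc$radius
    out$curvature[i] <- signedCurvature(arc, ch)
    out$theta1[i] <- atan2(t1[2L], t1[1L])
    out$theta2[i] <- atan2(t2[2L], t2[1L])
    out$chord[i] <- sqrt(sum((ch[nrow(ch), ] - ch[1L, ])^2))
    out$fitRMS[i] <- arc$fitRMS
    out$nIntermediate[i] <- nrow(ch) - 2L
    out$curvatureUsable[i] <- nrow(ch) >= 3L
  }
  attr(out, "method") <- method
  out
}

#' Export per-edge geometry to CSV
#'
#' @param geom result of \code{\link{edgeGeometry}}.
#' @param path output file path.
#' @return invisibly, the data.frame written.
#' @export
writeGeometryCSV <- function(geom, path) {
  df <- data.frame(edge = geom$edge, radius = geom$radius,
                   signed_curvature = geom$curvature,
                   theta1_deg = geom$theta1 * 180 / pi,
                   theta2_deg = geom$theta2 * 180 / pi,
                   chord = geom$chord, fit_rms = geom$fitRMS)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
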