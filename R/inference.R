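## Assembly and solution of the constrained tension and pressure systems.

## Solve the equality-constrained least squares problem
##   min ||G x - q||^2  s.t.  c' x = d
## through the KKT block system [[2 G'G, c], [c', 0]] [x; lambda] = [2 G'q; d].
## A singular-value-decomposition fallback handles ill-conditioned KKT
## matrices; a truly rank-deficient system raises an error that carries the
## condition number.
.solveConstrainedLS <- function(G, q, cvec, d, condLimit = 1e12) {
  n <- ncol(G)
  K <- rbind(cbind(2 * crossprod(G), cvec), c(cvec, 0))
  rhs <- c(2 * crossprod(G, q), d)
  sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
  kcond <- NA_real_
  if (!is.null(sol)) kcond <- kappa(K, exact = FALSE)
  if (is.null(sol) || !all(is.finite(sol)) || kcond > condLimit) {
    sv <- svd(K)
    tol <- max(dim(K)) * .Machine$double.eps * sv$d[1L]
    pos <- sv$d > tol
    if (sum(pos) < n + 1L)
      stop(sprintf(paste0("degenerate geometry: constrained system is rank ",
                          "deficient (condition number %.3g)"),
                   sv$d[1L] / sv$d[length(sv$d)]))
    sol <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
    sol <- drop(sol)
  }
  list(x = sol[seq_len(n)], lambda = sol[n + 1L], kktCondition = kcond)
}

#' Assemble the junction force-balance (tension) system
#'
#' Two rows per retained junction (one x, one y).  The entry in the column of
#' an incident edge is the cosine (x row) or sine (y row) of that edge's
#' limiting tangent angle at the junction.  Excluding an edge removes the
#' force balances of both its endpoint junctions and the edge's column;
#' junctions left with fewer than two retained incident edges are dropped
#' with a warning.
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param geom per-edge geometry from \code{\link{edgeGeometry}} (possibly
#'   noise-perturbed).
#' @param excludedEdges edge ids excluded from the analysis.
#' @param junctionSubset optional junction ids restricting assembly to one
#'   connected tension component.
#' @return a \code{\linkS4class{TensionSystem}}.
#' @export
assembleTensionSystem <- function(mesh, geom, excludedEdges = integer(),
                                  junctionSubset = NULL) {
  ed <- mesh@edges
  excludedEdges <- as.integer(excludedEdges)
  exc <- ed$id %in% excludedEdges
  remJ <- unique(c(ed$j1[exc], ed$j2[exc])); remJ <- remJ[!is.na(remJ)]
  retainedJ <- setdiff(mesh@junctions$id, remJ)
  if (!is.null(junctionSubset)) retainedJ <- intersect(retainedJ, junctionSubset)
  gi <- match(ed$id, geom$edge)

  rowsJ <- integer(0); entries <- list()
  colEdges <- integer(0)
  dropJ <- integer(0)
  for (j in retainedJ) {
    inc <- setdiff(mesh@junctionEdges[[as.character(j)]], excludedEdges)
    if (length(inc) < 2L) { dropJ <- c(dropJ, j); next }
    th <- vapply(inc, function(e) {
      i <- match(e, ed$id)
      if (!is.na(ed$j1[i]) && ed$j1[i] == j) geom$theta1[gi[i]]
      else geom$theta2[gi[i]]
    }, numeric(1))
    entries[[length(entries) + 1L]] <- list(j = j, edges = inc, theta = th)
    colEdges <- union(colEdges, inc)
  }
  if (length(dropJ))
    warning("junction(s) with < 2 retained incident edges dropped: ",
            paste(dropJ, collapse = ", "))
  colEdges <- sort(colEdges)
  nR <- 2L * length(entries); nC <- length(colEdges)
  G <- matrix(0, nR, nC)
  rows <- data.frame(junction = integer(nR), axis = character(nR))
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    ci <- match(e$edges, colEdges)
    G[2L * k - 1L, ci] <- cos(e$theta)
    G[2L * k, ci] <- sin(e$theta)
    rows$junction[2L * k - 1L] <- rows$junction[2L * k] <- e$j
    rows$axis[2L * k - 1L] <- "x"; rows$axis[2L * k] <- "y"
  }
  new("TensionSystem", G = G,
      constraint = rep(1 / max(nC, 1L), nC),
      rows = rows, cols = as.integer(colEdges))
}

#' Solve the tension system for Standard Tensions
#'
#' Minimizes \eqn{\|G_\gamma \gamma\|^2} subject to the mean-one constraint
#' \eqn{\bar\gamma = 1}.  Negative inferred tensions are reported (with a
#' warning), not clipped.
#'
#' @param system a \code{\linkS4class{TensionSystem}} (one connected
#'   component).
#' @return list with \code{gamma} (named by edge id, mean 1) and
#'   \code{lambda} (the constraint's Lagrange multiplier).
#' @examples
#' m <- starMesh(3)  # symmetric triple junction
#' solveTensions(assembleTensionSystem(m, edgeGeometry(m)))$gamma  # 1 1 1
#' @export
solveTensions <- function(system) {
  if (nrow(system@G) < 1L) stop("tension system has no equations")
  sol <- .solveConstrainedLS(system@G, rep(0, nrow(system@G)),
                             system@constraint, 1)
  gamma <- setNames(sol$x, as.character(system@cols))
  if (any(gamma < 0))
    warning(sum(gamma < 0), " negative inferred tension(s); reported unclipped")
  list(gamma = gamma, lambda = sol$lambda, kktCondition = sol$kktCondition)
}

#' Assemble the Laplace (pressure) system
#'
#' One row per usable edge: non-stub, non-excluded, curvature-usable (at
#' least one intermediate chain node) and with a known tension.  The row has
#' +1 at the left cell and -1 at the right cell; the right-hand side is
#' \eqn{\gamma_{ij} \kappa_{ij}} (straight edges enter with 0).
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param gamma named numeric of edge tensions (names are edge ids).
#' @param geom per-edge geometry (supplies curvatures and chord lengths).
#' @param excludedEdges edge ids excluded from the analysis.
#' @param cellSubset optional cell ids restricting assembly to one pressure
#'   component.
#' @return a \code{\linkS4class{PressureSystem}}.
#' @export
assemblePressureSystem <- function(mesh, gamma, geom,
                                   excludedEdges = integer(),
                                   cellSubset = NULL) {
  ed <- mesh@edges
  excludedEdges <- as.integer(excludedEdges)
  gi <- match(ed$id, geom$edge)
  hasGamma <- as.character(ed$id) %in% names(gamma)
  usable <- !ed$stub & !(ed$id %in% excludedEdges) &
    geom$curvatureUsable[gi] & hasGamma
  cells <- mesh@cells$id
  if (!is.null(cellSubset)) {
    cells <- intersect(cells, cellSubset)
    usable <- usable & ed$cellLeft %in% cells & ed$cellRight %in% cells
  }
  bad <- usable & (!(ed$cellLeft %in% mesh@cells$id) |
                   !(ed$cellRight %in% mesh@cells$id))
  if (any(bad)) stop("edge bordering an undeclared cell: ",
                     paste(ed$id[bad], collapse = ", "))
  ids <- ed$id[usable]
  nR <- length(ids); nC <- length(cells)
  G <- matrix(0, nR, nC)
  q <- numeric(nR); chord <- numeric(nR)
  for (k in seq_len(nR)) {
    i <- match(ids[k], ed$id)
    G[k, match(ed$cellLeft[i], cells)] <- 1
    G[k, match(ed$cellRight[i], cells)] <- -1
    q[k] <- gamma[[as.character(ids[k])]] * geom$curvature[gi[i]]
    chord[k] <- geom$chord[gi[i]]
  }
  if (!all(is.finite(q))) stop("non-finite pressure right-hand side")
  new("PressureSystem", G = G, q = q,
      constraint = rep(1 / max(nC, 1L), nC),
      rows = as.integer(ids), cols = as.integer(cells), chord = chord)
}

#' Solve the pressure system for Standard Pressures
#'
#' Minimizes \eqn{\|G_p p - q\|^2} subject to the mean-zero constraint
#' \eqn{\bar p = 0}.
#'
#' @param system a \code{\linkS4class{PressureSystem}} (one connected
#'   component).
#' @return list with \code{p} (named by cell id, mean 0) and \code{lambda}.
#' @export
solvePressures <- function(system) {
  if (nrow(system@G) < 1L) stop("pressure system has no equations")
  sol <- .solveConstrainedLS(system@G, system@q, system@constraint, 0)
  list(p = setNames(sol$x, as.character(system@cols)),
       lambda = sol$lambda, kktCondition = sol$kktCondition)
}

#' General Solution from Standard Tensions and Pressures
#'
#' All force sets consistent with an image are \eqn{\gamma = \alpha\gamma^*},
#' \eqn{p = \alpha p^* + \beta}; \eqn{\alpha} is the mean edge tension and
#' \eqn{\beta} the mean intracellular pressure, both determined only from
#' information external to the image.
#'
#' @param gammaStar Standard Tensions (mean 1).
#' @param pStar Standard Pressures (mean 0).
#' @param alpha tension scale (> 0).
#' @param beta pressure offset.
#' @return list with \code{gamma} and \code{p}.
#' @export
generalSolution <- function(gammaStar, pStar, alpha, beta) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  list(gamma = alpha * gammaStar, p = alpha * pStar + beta)
}

#' Standardize a consistent tension/pressure pair
#'
#' The inverse of \code{\link{generalSolution}}: recovers the Standard
#' Tensions, Standard Pressures, scale \eqn{\alpha = \bar\gamma} and offset
#' \eqn{\beta = \bar p} from any mutually consistent pair.
#'
#' @param gamma edge tensions (mean must be positive).
#' @param p cell pressures (may be NULL).
#' @return list with \code{gammaStar}, \code{pStar}, \code{alpha},
#'   \code{beta}.
#' @export
standardizeSolution <- function(gamma, p = NULL) {
  alpha <- mean(gamma)
  if (!is.finite(alpha) || alpha <= 0) stop("mean tension must be positive")
  beta <- if (is.null(p)) NA_real_ else mean(p)
  list(gammaStar = gamma / alpha,
       pStar = if (is.null(p)) numeric(0) else (p - beta) / alpha,
       alpha = alpha, beta = beta)
}

#' Infer Standard Tensions and Pressures for a mesh
#'
#' The full inverse pipeline: per-edge geometry (unless supplied), connected
#' tension components, one constrained least-squares tension solve per
#' component, then -- unless \code{tensionsOnly} -- pressure components over
#' the usable edges and one constrained pressure solve per component.
#' Tensions and pressures are solved sequentially, never jointly.
#'
#' @param mesh a \code{\linkS4class{CellMesh}}.
#' @param method angle-determination method.
#' @param excludedEdges edge ids to exclude (e.g. short or poorly imaged
#'   edges).
#' @param geom optional precomputed (possibly noise-perturbed) geometry
#'   table; when supplied, \code{method} is ignored for assembly.
#' @param tensionsOnly skip the pressure stage (curvatures then need never be
#'   trusted).
#' @param straightnessTol passed to \code{\link{edgeGeometry}}.
#' @return a \code{\linkS4class{ForceSolution}}.
#' @examples
#' m <- starMesh(3, angles = c(0, pi / 2, 5 * pi / 4))
#' round(standardTensions(inferForces(m, tensionsOnly = TRUE)), 4)
#' @export
inferForces <- function(mesh, method = c("polyarc", "closest_segment",
                                         "minimal_polygon"),
                        excludedEdges = integer(), geom = NULL,
                        tensionsOnly = FALSE, straightnessTol = 1e-3) {
  method <- match.arg(method)
  if (is.null(geom)) geom <- edgeGeometry(mesh, method, straightnessTol)
  comps <- tensionComponents(mesh, excludedEdges)
  gamma <- numeric(0); lambda1 <- numeric(0)
  tsys <- list()
  for (k in seq_along(comps)) {
    sys <- assembleTensionSystem(mesh, geom, excludedEdges, comps[[k]])
    if (ncol(sys@G) == 0L) next
    sol <- solveTensions(sys)
    gamma <- c(gamma, sol$gamma)
    lambda1 <- c(lambda1, sol$lambda)
    tsys[[length(tsys) + 1L]] <- sys
  }
  pStar <- numeric(0); lambda2 <- numeric(0)
  psys <- list(); pcomps <- list()
  if (!tensionsOnly && nrow(mesh@cells) > 0L) {
    ed <- mesh@edges
    gi <- match(ed$id, geom$edge)
    ## pressure equations only combine edges whose tensions share one
    ## normalization, i.e. come from the same tension component; larger
    ## components take precedence for cells reachable from several
    ord <- order(-vapply(tsys, function(s) length(s@cols), integer(1)))
    for (s in tsys[ord]) {
      usable <- ed$id[!ed$stub & !(ed$id %in% excludedEdges) &
                      geom$curvatureUsable[gi] &
                      ed$id %in% s@cols]
      if (!length(usable)) next
      notUsable <- setdiff(ed$id, usable)
      for (pc in pressureComponents(mesh, usable)) {
        if (any(as.character(pc) %in% names(pStar))) next
        sys <- assemblePressureSystem(mesh, gamma, geom, notUsable, pc)
        if (nrow(sys@G) == 0L) next
        sol <- solvePressures(sys)
        pStar <- c(pStar, sol$p)
        lambda2 <- c(lambda2, sol$lambda)
        psys[[length(psys) + 1L]] <- sys
        pcomps[[length(pcomps) + 1L]] <- pc
      }
    }
  }
  new("ForceSolution", gammaStar = gamma, pStar = pStar,
      alpha = NA_real_, beta = NA_real_,
      lambdaTension = lambda1, lambdaPressure = lambda2,
      tensionComponents = comps, pressureComponents = pcomps,
      systems = list(tension = tsys, pressure = psys),
      method = method)
}

#' @rdname standardTensions
setMethod("standardTensions", "ForceSolution", function(x) x@gammaStar)
#' @rdname standardTensions
setMethod("standardPressures", "ForceSolution", function(x) x@pStar)

setMethod("show", "ForceSolution", function(object) {
  cat("ForceSolution (", object@method, " angles)\n", sep = "")
  cat(sprintf("  Standard Tensions: %d edges in %d component(s), mean %.6f\n",
              length(object@gammaStar), length(object@tensionComponents),
              if (length(object@gammaStar)) mean(object@gammaStar) else NA))
  if (length(object@pStar))
    cat(sprintf("  Standard Pressures: %d cells in %d component(s), mean %.2e\n",
                length(object@pStar), length(object@pressureComponents),
                mean(object@pStar)))
  if (is.finite(object@alpha))
    cat(sprintf("  calibrated: alpha = %.4g, beta = %.4g\n",
                object@alpha, object@beta))
})
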