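## S4 classes for the polyarc force-inference pipeline.

#' CellMesh: topological model of a polyarc cell sheet
#'
#' A \code{CellMesh} is the single source of topology for all downstream
#' computations.  It stores nodes (junctions and the intermediate points along
#' each edge), edges as ordered node chains with declared side cells, cells
#' with their (ordered, for complete cells) boundary edge lists, and the
#' derived junction table.
#'
#' Conventions:
#' \itemize{
#'   \item Coordinates are mathematical (x right, y up); image readers flip
#'     the row axis.  All angles are radians internally.
#'   \item An edge's chain is ordered so that \code{cellLeft} lies to the left
#'     when traversing the chain in stored order.
#'   \item The surrounding medium, when present, is a single cell with id 0,
#'     \code{medium = TRUE} and \code{partial = TRUE}.
#'   \item A stub edge has exactly one endpoint junction inside the region of
#'     interest; its other end is a free chain terminus.
#'   \item Junctions of order 3 are triple junctions (TJs), order 2 double
#'     junctions (DJs), order >= 4 quad junctions / rosettes.
#' }
#'
#' @slot nodes data.frame with columns \code{id}, \code{x}, \code{y}.
#' @slot edges data.frame with columns \code{id}, \code{j1}, \code{j2}
#'   (endpoint junction node ids, \code{NA} for a free stub end),
#'   \code{cellLeft}, \code{cellRight} (cell ids, 0 = medium), \code{stub}.
#' @slot chains named list (by edge id) of integer node-id vectors, ordered
#'   from the \code{j1} end to the \code{j2} end.
#' @slot cells data.frame with columns \code{id}, \code{partial},
#'   \code{medium}.
#' @slot cellEdges named list (by cell id) of edge ids; a single closed
#'   ordered loop for complete cells.
#' @slot junctions data.frame with columns \code{id} (= node id) and
#'   \code{order} (number of incident edge ends).
#' @slot junctionEdges named list (by junction id) of incident edge ids.
#' @slot lengthScale numeric(1), physical length units per coordinate unit.
#'
#' @seealso \code{\link{buildMesh}}, \code{\link{tallyCounts}},
#'   \code{\link{edgeGeometry}}
#' @export
setClass("CellMesh", slots = c(
  nodes = "data.frame",
  edges = "data.frame",
  chains = "list",
  cells = "data.frame",
  cellEdges = "list",
  junctions = "data.frame",
  junctionEdges = "list",
  lengthScale = "numeric"
))

#' MeshCounts: tally of equations and unknowns for a mesh
#'
#' Counts computed by direct enumeration on the pre-removal topology; they
#' describe how many force-balance equations and unknowns the tension and
#' pressure systems will have, and are the primary tool for judging whether a
#' region of interest yields overdetermined systems.
#'
#' @slot nJunctions junctions present before any edge exclusions.
#' @slot nJunctionsRemoved junctions incident to at least one excluded edge.
#' @slot nTensions unknown edge tensions (non-excluded edges, stubs included).
#' @slot nTensionEqns \code{2 *} retained junctions (an x and a y balance each).
#' @slot nCompleteCells fully surrounded cells.
#' @slot nPartialCells perimeter cells, medium counted as one partial cell.
#' @slot nExcessEdges sum over junctions of \code{max(order - 3, 0)}.
#' @slot nRemovedEdges excluded edges.
#' @slot nDoubleJunctions junctions of order 2.
#' @slot nStubs stub (truncated) edges.
#' @slot nPressureEqns usable pressure rows (non-stub, non-excluded,
#'   curvature-usable edges).
#' @slot nPressures unknown pressures (complete + partial cells).
#' @export
setClass("MeshCounts", slots = c(
  nJunctions = "integer", nJunctionsRemoved = "integer",
  nTensions = "integer", nTensionEqns = "integer",
  nCompleteCells = "integer", nPartialCells = "integer",
  nExcessEdges = "integer", nRemovedEdges = "integer",
  nDoubleJunctions = "integer", nStubs = "integer",
  nPressureEqns = "integer", nPressures = "integer"
))

#' TensionSystem: assembled junction force-balance system
#'
#' The homogeneous system \eqn{G_\gamma \gamma = 0} with two rows (x and y)
#' per retained junction.  Every nonzero entry is the cosine (x rows) or sine
#' (y rows) of a limiting tangent angle, hence lies in [-1, 1].  The
#' natural solution \eqn{\gamma = 0} is excluded by the mean-one constraint
#' \eqn{c^T\gamma = 1} with \eqn{c = (1/N)\mathbf{1}}.
#'
#' @slot G numeric matrix, \code{nTensionEqns x nTensions}.
#' @slot constraint numeric vector \code{c}, each entry \code{1/nTensions}.
#' @slot rows data.frame mapping row to \code{junction} id and \code{axis}
#'   ("x" or "y").
#' @slot cols integer vector mapping column to edge id.
#' @export
setClass("TensionSystem", slots = c(
  G = "matrix", constraint = "numeric", rows = "data.frame", cols = "integer"
))

#' PressureSystem: assembled Laplace pressure-difference system
#'
#' One row per usable edge: \code{+1} at the left cell, \code{-1} at the
#' right cell, right-hand side \eqn{q = \gamma_{ij}\kappa_{ij}} (the Laplace
#' pressure jump \eqn{\Delta p = \gamma/\rho}).  Solved under the mean-zero
#' constraint \eqn{c^T p = 0}, \eqn{c = (1/N)\mathbf{1}}.
#'
#' @slot G numeric matrix with one +1 and one -1 per row.
#' @slot q numeric right-hand side, \eqn{\gamma \times} signed curvature.
#' @slot constraint numeric constraint vector.
#' @slot rows integer vector mapping row to edge id.
#' @slot cols integer vector mapping column to cell id.
#' @slot chord numeric per-row chord lengths (for residual force scaling).
#' @export
setClass("PressureSystem", slots = c(
  G = "matrix", q = "numeric", constraint = "numeric",
  rows = "integer", cols = "integer", chord = "numeric"
))

#' ForceSolution: Standard Tensions and Standard Pressures
#'
#' The mean-one tension solution \eqn{\gamma^*} and mean-zero pressure
#' solution \eqn{p^*} (per connected component), together with the Lagrange
#' multipliers of the normalization constraints and optional calibration
#' scale \eqn{\alpha} (mean edge tension) and offset \eqn{\beta} (mean
#' intracellular pressure).  The General Solution for an image is
#' \eqn{\gamma = \alpha\gamma^*,\; p = \alpha p^* + \beta}.
#'
#' @slot gammaStar named numeric, Standard Tension per edge id.
#' @slot pStar named numeric, Standard Pressure per cell id (may be empty if
#'   tensions only were requested).
#' @slot alpha numeric(1) tension scale (NA until calibrated).
#' @slot beta numeric(1) pressure offset (NA until calibrated).
#' @slot lambdaTension numeric, constraint multiplier per tension component.
#' @slot lambdaPressure numeric, multiplier per pressure component.
#' @slot tensionComponents list of junction-id vectors.
#' @slot pressureComponents list of cell-id vectors.
#' @slot systems list with elements \code{tension} and \code{pressure}, each a
#'   list of assembled systems (one per component).
#' @slot method character(1), angle-determination method used.
#' @export
setClass("ForceSolution", slots = c(
  gammaStar = "numeric", pStar = "numeric",
  alpha = "numeric", beta = "numeric",
  lambdaTension = "numeric", lambdaPressure = "numeric",
  tensionComponents = "list", pressureComponents = "list",
  systems = "list", method = "character"
))

#' ForceDiagnostics: solution-quality report
#'
#' @slot condTension condition number(s) of the constraint-augmented tension
#'   matrix \code{rbind(G, t(c))}, one per component.
#' @slot condPressure condition number(s) of the augmented pressure matrix.
#' @slot tensionResiduals data.frame: per-junction residual vectors
#'   (\code{rx}, \code{ry}) and normalized magnitudes \code{|r|/mean(gamma)}.
#' @slot pressureResiduals data.frame: per-edge raw residuals and
#'   chord-weighted normalized force residuals \code{|r| L / mean(gamma)}.
#' @slot seTension named numeric, standard error per edge tension.
#' @slot sePressure named numeric, standard error per cell pressure.
#' @slot meanCellRadius numeric(1), mean over complete cells of
#'   \code{sqrt(area/pi)}; display scale for residual rendering.
#' @slot meanTension numeric(1), mean tension used for normalization.
#' @export
setClass("ForceDiagnostics", slots = c(
  condTension = "numeric", condPressure = "numeric",
  tensionResiduals = "data.frame", pressureResiduals = "data.frame",
  seTension = "numeric", sePressure = "numeric",
  meanCellRadius = "numeric", meanTension = "numeric"
))

#' TissueTruth: ground-truth forces of a synthetic tissue
#'
#' Interface tensions are assigned from the cell-type interface table; the
#' pressures are emergent properties of the annealed (force-equilibrated)
#' configuration, \eqn{p_c = k (A_{0,c} - A_c)/A_{0,c}} for area stiffness
#' \eqn{k}.
#'
#' @slot tensions named numeric, assigned tension per edge id.
#' @slot pressures named numeric, emergent pressure per cell id (filled by
#'   \code{\link{annealMesh}}).
#' @slot cellTypes named integer in \{1, 2, 3\} per (non-medium) cell id.
#' @export
setClass("TissueTruth", slots = c(
  tensions = "numeric", pressures = "numeric", cellTypes = "integer"
))
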