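## Solution-quality tooling: condition numbers, residuals, standard errors.

#' Condition number of a constraint-augmented system
#'
#' Both inverse systems have a rank deficiency of one (tension scale,
#' pressure offset) that is removed by the mean constraint; the condition
#' number is therefore computed on the augmented matrix \code{rbind(G, t(c))}
#' -- the constraint row appended to the geometric matrix -- as the ratio of
#' its largest to smallest singular values.  A zero smallest singular value
#' yields \code{Inf} with attribute \code{illPosed = TRUE}.
#'
#' @param system a \code{\linkS4class{TensionSystem}} or
#'   \code{\linkS4class{PressureSystem}} (or a bare matrix, taken as already
#'   augmented).
#' @return numeric(1) >= 1.
#' @examples
#' conditionNumber(diag(c(4, 2)))  # 2
#' @export
conditionNumber <- function(system) {
  A <- if (is.matrix(system)) system else rbind(system@G, system@constraint)
  d <- svd(A, nu = 0, nv = 0)$d
  smin <- min(d)
  if (smin <= max(dim(A)) * .Machine$double.eps * max(d)) {
    out <- Inf
    attr(out, "illPosed") <- TRUE
    ## export the near-null singular vector raw, for inspection
    sv <- svd(A)
    attr(out, "nullVector") <- sv$v[, which.min(sv$d)]
    return(out)
  }
  max(d) / smin
}

#' Per-junction tension residuals
#'
#' The residual \eqn{r = G_\gamma \gamma} regrouped per junction as an (x, y)
#' force vector; it measures how far the inferred tensions are from
#' equilibrium at each junction.  Magnitudes are normalized by the mean
#' tension; for display, a residual of one is conventionally drawn with a
#' length equal to the mean cell radius (reported by
#' \code{\link{diagnoseSolution}} as the display scale).
#'
#' @param system a \code{\linkS4class{TensionSystem}}.
#' @param gamma named tension vector (must cover \code{system@cols}).
#' @return data.frame with \code{junction}, \code{rx}, \code{ry},
#'   \code{magnitude}, \code{normalized}.
#' @export
tensionResiduals <- function(system, gamma) {
  g <- gamma[as.character(system@cols)]
  r <- drop(system@G %*% g)
  jx <- system@rows$axis == "x"
  df <- data.frame(junction = system@rows$junction[jx],
                   rx = r[jx], ry = r[!jx])
  df$magnitude <- sqrt(df$rx^2 + df$ry^2)
  df$normalized <- df$magnitude / mean(g)
  df
}

#' Per-edge pressure residuals
#'
#' Raw residuals \eqn{r = G_p p - q} per edge, plus normalized force
#' residuals: each residual is converted to a force by multiplying by the
#' chordal length of its edge, then normalized by the mean tension.
#'
#' @param system a \code{\linkS4class{PressureSystem}}.
#' @param p named pressure vector (must cover \code{system@cols}).
#' @param meanGamma mean tension used for normalization (1 for Standard
#'   Tensions).
#' @return data.frame with \code{edge}, \code{residual}, \code{chord},
#'   \code{normalized}.
#' @export
pressureResiduals <- function(system, p, meanGamma = 1) {
  r <- drop(system@G %*% p[as.character(system@cols)]) - system@q
  data.frame(edge = system@rows, residual = r, chord = system@chord,
             normalized = abs(r) * system@chord / meanGamma)
}

#' Standard errors of constrained least-squares unknowns
#'
#' The mean constraint is eliminated by a reduced parametrization
#' \eqn{x = x_0 + Z\theta} with \eqn{Z} an orthonormal basis of the
#' constraint's null space, so the problem has \eqn{n - 1} effective
#' parameters.  The residual variance is
#' \eqn{\hat\sigma^2 = \|r\|^2 / (m - (n - 1))} and the covariance of the
#' full parameter set is \eqn{\hat\sigma^2 Z (A^T A)^{-1} Z^T} with
#' \eqn{A = GZ}; standard errors are the square roots of its diagonal.
#'
#' @param system a \code{\linkS4class{TensionSystem}} or
#'   \code{\linkS4class{PressureSystem}}.
#' @param solution the solved unknowns (named numeric covering
#'   \code{system@cols}).
#' @return named numeric of standard errors; all \code{NA} (with attribute
#'   \code{underdetermined = TRUE}) when \code{m <= n - 1}.
#' @export
standardErrors <- function(system, solution) {
  G <- system@G
  q <- if (is(system, "PressureSystem")) system@q else rep(0, nrow(G))
  n <- ncol(G); m <- nrow(G)
  x <- solution[as.character(system@cols)]
  out <- setNames(rep(NA_real_, n), as.character(system@cols))
  if (m <= n - 1L) {
    attr(out, "underdetermined") <- TRUE
    return(out)
  }
  Z <- qr.Q(qr(matrix(system@constraint, ncol = 1)), complete = TRUE)[, -1L,
                                                                      drop = FALSE]
  A <- G %*% Z
  r <- drop(G %*% x) - q
  sigma2 <- sum(r^2) / (m - (n - 1L))
  AtAinv <- tryCatch(solve(crossprod(A)), error = function(e) NULL)
  if (is.null(AtAinv)) {
    attr(out, "underdetermined") <- TRUE
    return(out)
  }
  covx <- Z %*% AtAinv %*% t(Z) * sigma2
  out[] <- sqrt(pmax(diag(covx), 0))
  out
}

#' Diagnose a force-inference solution
#'
#' Collects the quality tooling into one report: condition numbers of the
#' augmented tension and pressure matrices, per-junction tension residuals,
#' per-edge chord-weighted pressure residuals, and covariance-based standard
#' errors for every unknown.
#'
#' @param mesh the analyzed \code{\linkS4class{CellMesh}}.
#' @param solution a \code{\linkS4class{ForceSolution}} from
#'   \code{\link{inferForces}}.
#' @return a \code{\linkS4class{ForceDiagnostics}}.
#' @export
diagnoseSolution <- function(mesh, solution) {
  ts <- solution@systems$tension
  ps <- solution@systems$pressure
  condT <- vapply(ts, conditionNumber, numeric(1))
  condP <- if (length(ps)) vapply(ps, conditionNumber, numeric(1)) else numeric(0)
  tres <- do.call(rbind, lapply(ts, tensionResiduals,
                                gamma = solution@gammaStar))
  if (is.null(tres)) tres <- data.frame()
  pres <- if (length(ps))
    do.call(rbind, lapply(ps, pressureResiduals, p = solution@pStar,
                          meanGamma = mean(solution@gammaStar)))
  else data.frame()
  seT <- unlist(lapply(ts, function(s) standardErrors(s, solution@gammaStar)))
  seP <- if (length(ps))
    unlist(lapply(ps, function(s) standardErrors(s, solution@pStar)))
  else numeric(0)
  new("ForceDiagnostics",
      condTension = condT, condPressure = condP,
      tensionResiduals = tres, pressureResiduals = pres,
      seTension = if (is.null(seT)) numeric(0) else seT,
      sePressure = if (is.null(seP)) numeric(0) else seP,
      meanCellRadius = meanCellRadius(mesh),
      meanTension = if (length(solution@gammaStar))
        mean(solution@gammaStar) else NA_real_)
}

setMethod("show", "ForceDiagnostics", function(object) {
  cat("ForceDiagnostics\n")
  cat("  condition numbers: tension",
      paste(sprintf("%.3g", object@condTension), collapse = ", "),
      "| pressure",
      if (length(object@condPressure))
        paste(sprintf("%.3g", object@condPressure), collapse = ", ")
      else "-", "\n")
  if (nrow(object@tensionResiduals))
    cat(sprintf("  tension residuals (normalized): median %.3g, max %.3g\n",
                stats::median(object@tensionResiduals$normalized),
                max(object@tensionResiduals$normalized)))
  if (nrow(object@pressureResiduals))
    cat(sprintf("  pressure residuals (normalized force): median %.3g, max %.3g\n",
                stats::median(object@pressureResiduals$normalized),
                max(object@pressureResiduals$normalized)))
  if (length(object@seTension))
    cat(sprintf("  SE(tension): median %.3g | SE(pressure): median %.3g\n",
                stats::median(object@seTension, na.rm = TRUE),
                if (length(object@sePressure))
                  stats::median(object@sePressure, na.rm = TRUE) else NA))
  cat(sprintf("  mean cell radius: %.4g; mean tension: %.4g\n",
              object@meanCellRadius, object@meanTension))
})
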