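## Result serialization: tensions/pressures CSV, diagnostics JSON.
## Column names and JSON keys are a frozen interface contract.

#' Write inference results and diagnostics to files
#'
#' \code{writeTensionsCSV} writes per-edge rows (edge, gamma_star, se,
#' junction residual context); \code{writePressuresCSV} per-cell rows (cell,
#' p_star, se); \code{writeDiagnosticsJSON} the condition numbers, residual
#' summaries and scales.
#'
#' @param solution a \code{\linkS4class{ForceSolution}}.
#' @param diagnostics a \code{\linkS4class{ForceDiagnostics}} (optional for
#'   the CSV writers).
#' @param path output file path.
#' @return invisibly, the object written.
#' @export
writeTensionsCSV <- function(solution, path, diagnostics = NULL) {
  g <- standardTensions(solution)
  df <- data.frame(edge = as.integer(names(g)), gamma_star = unname(g))
  if (!is.null(diagnostics) && length(diagnostics@seTension))
    df$se <- unname(diagnostics@seTension[names(g)])
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname writeTensionsCSV
#' @export
writePressuresCSV <- function(solution, path, diagnostics = NULL) {
  p <- standardPressures(solution)
  df <- data.frame(cell = as.integer(names(p)), p_star = unname(p))
  if (!is.null(diagnostics) && length(diagnostics@sePressure))
    df$se <- unname(diagnostics@sePressure[names(p)])
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname writeTensionsCSV
#' @param alpha,beta optional calibration (tension scale / pressure offset);
#'   serialized as null when unknown.
#' @export
writeDiagnosticsJSON <- function(solution, diagnostics, path,
                                 alpha = NULL, beta = NULL) {
  obj <- list(
    method = solution@method,
    alpha = alpha, beta = beta,
    lambda_tension = solution@lambdaTension,
    lambda_pressure = solution@lambdaPressure,
    condition_tension = diagnostics@condTension,
    condition_pressure = diagnostics@condPressure,
    mean_cell_radius = diagnostics@meanCellRadius,
    tension_residuals = diagnostics@tensionResiduals,
    pressure_residuals = diagnostics@pressureResiduals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}
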