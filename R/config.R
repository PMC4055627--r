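## Run configuration: a validated, JSON-serializable record of every knob a
## run depends on, so analyses can be reproduced from the file alone.

.runConfigFields <- c("angleMethod", "straightnessTol", "noiseLevel",
                      "noiseSeed", "nCells", "targetComplete",
                      "nIntermediate", "tensionTable", "areaStiffness",
                      "forceTol", "contractTol", "seed", "alpha", "beta",
                      "calibrateEdge", "outputDir")

#' Create a run configuration
#'
#' Collects the tunable parameters of a full inference or validation run:
#' the angle method, geometry tolerances, noise specification, generator
#' parameters, seeds, optional calibration (tension scale \code{alpha},
#' pressure offset \code{beta}, or an edge anchored to a known tension) and
#' output paths.  Unknown keys are rejected, and a write/read round trip
#' reproduces the configuration exactly.
#'
#' @param ... named configuration entries (see
#'   \code{arcforce:::.runConfigFields} for the accepted names).
#' @return a named list of class \code{"runConfig"}.
#' @examples
#' cfg <- runConfig(angleMethod = "polyarc", seed = 7)
#' @export
runConfig <- function(...) {
  entries <- list(...)
  if (length(entries) && (is.null(names(entries)) || any(names(entries) == "")))
    stop("all configuration entries must be named")
  unknown <- setdiff(names(entries), .runConfigFields)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(angleMethod = "polyarc", straightnessTol = 1e-3,
                   noiseLevel = 0, noiseSeed = 1L, nCells = 120L,
                   targetComplete = 50L, nIntermediate = 4L,
                   tensionTable = as.list(defaultTensionTable),
                   areaStiffness = 100, forceTol = 1e-3, contractTol = 0.02,
                   seed = 1L, alpha = NULL, beta = NULL,
                   calibrateEdge = NULL, outputDir = NULL)
  cfg <- utils::modifyList(defaults, entries, keep.null = TRUE)
  structure(cfg, class = "runConfig")
}

#' Write / read a run configuration
#'
#' @param config a \code{runConfig}.
#' @param path JSON file path.
#' @return \code{readRunConfig} returns the \code{runConfig};
#'   \code{writeRunConfig} returns \code{path} invisibly.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "runConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, obj)
}

#' @export
print.runConfig <- function(x, ...) {
  cat("runConfig\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-16s %s\n", k,
                if (is.null(v)) "NULL" else paste(unlist(v), collapse = " ")))
  }
  invisible(x)
}
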