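# Human-readable configuration files (YAML key-value, SI units). Unknown
# keys are rejected so every under-specified geometry choice stays visible.

#' Read a brushing configuration from a YAML file
#'
#' The file holds any subset of the arguments of [brushing_config()] in SI
#' units; missing keys take the documented defaults, unknown keys are an
#' error.
#'
#' @param path Path to a YAML file.
#' @return A `brushing_config`.
#' @export
read_brushing_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(brushing_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(brushing_config, vals)
}

#' Write the resolved configuration (run manifest) to a YAML file
#'
#' Echoes back every resolved parameter of a configuration or run manifest,
#' so a result file can be reproduced exactly.
#'
#' @param x A `brushing_config` or a `brush_run` (whose manifest is
#'   written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(x, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("writing manifests requires the 'yaml' package")
  obj <- if (inherits(x, "brush_run")) x$manifest
  else if (inherits(x, "brushing_config")) {
    o <- unclass(x); o$materials <- lapply(o$materials, unclass); o
  } else stop("x must be a brushing_config or brush_run")
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Export a wear map as a plain-text grid
#'
#' One CSV with a commented header naming the cell size and, per row, the
#' facet, cell coordinates and accumulated wear volume.
#'
#' @param map A `wear_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wear_csv <- function(map, path) {
  stopifnot(inherits(map, "wear_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wear map: cell = %g m; Q in m^3 per unit K", map$cell),
             con)
  utils::write.table(as.data.frame(map), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export particle positions as a legacy VTK polydata snapshot
#'
#' Minimal ASCII legacy VTK file of the particle centres (with radius and
#' chain id as point data) for external 3-D viewers.
#'
#' @param pos n x 3 matrix of positions (m).
#' @param path Output path.
#' @param radius,chain Optional per-particle scalars.
#' @return `path`, invisibly.
#' @export
write_vtk_particles <- function(pos, path, radius = NULL, chain = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "brushwear particles", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  utils::write.table(format(pos, scientific = TRUE, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(radius) || !is.null(chain)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    if (!is.null(radius)) {
      writeLines(c("SCALARS radius double 1", "LOOKUP_TABLE default"), con)
      writeLines(format(rep_len(radius, n)), con)
    }
    if (!is.null(chain)) {
      writeLines(c("SCALARS chain int 1", "LOOKUP_TABLE default"), con)
      writeLines(format(rep_len(as.integer(chain), n)), con)
    }
  }
  invisible(path)
}
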