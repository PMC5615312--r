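# Configuration files, result serialization and VTK export.
#
# A run configuration is a flat YAML key-value file; exactly two of
# {pore_side_um, fiber_width_um, porosity} may be given and the third is
# derived. Result files embed the package version and a content hash of
# the configuration so every table is traceable to the design that
# produced it.

.config_schema <- c("pore_side_um", "fiber_width_um", "porosity",
                    "cells_per_side", "layers", "material", "dialect",
                    "axis", "mode", "bc_dialect", "strain", "pressure_pa",
                    "resolution")

#' Load and validate a run configuration
#'
#' Reads a YAML key-value file describing one scaffold simulation and
#' validates it in full, reporting every violation in a single aggregated
#' error. Missing optional keys get documented defaults; which values were
#' defaulted is recorded in the `provenance` attribute.
#'
#' @param path Path to the YAML file.
#' @return A list of class `"run_config"` with elements `spec`
#'   ([scaffold_spec()]), `bc` ([boundary_condition()]), `resolution`, and
#'   attribute `provenance`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  problems <- character()
  unknown <- setdiff(names(raw), .config_schema)
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  geom_given <- c(pore_side_um = !is.null(raw$pore_side_um),
                  fiber_width_um = !is.null(raw$fiber_width_um),
                  porosity = !is.null(raw$porosity))
  if (sum(geom_given) != 2L)
    problems <- c(problems, sprintf(
      "exactly two of pore_side_um, fiber_width_um, porosity must be given (got %d); the third is derived from the closed-form porosity",
      sum(geom_given)))
  if (is.null(raw$material))
    problems <- c(problems, "material is required")
  defaults <- list(cells_per_side = 1L, layers = 1L, dialect = "channel_cell",
                   axis = "x", mode = "displacement_control",
                   bc_dialect = "homogenization_rollers", strain = 0.01,
                   resolution = 4L)
  used_default <- setdiff(names(defaults), names(raw))
  for (k in used_default) raw[[k]] <- defaults[[k]]
  cfg <- NULL
  if (length(problems) == 0L) {
    cfg <- tryCatch({
      spec <- scaffold_spec(pore_um = raw$pore_side_um,
                            fiber_um = raw$fiber_width_um,
                            porosity = raw$porosity,
                            cells_per_side = raw$cells_per_side,
                            layers = raw$layers,
                            material = raw$material,
                            dialect = raw$dialect)
      bc <- if (raw$mode == "pressure_control")
        boundary_condition(axis = raw$axis, mode = "pressure_control",
                           dialect = raw$bc_dialect,
                           magnitude = raw$pressure_pa)
      else
        boundary_condition(axis = raw$axis, mode = "displacement_control",
                           dialect = raw$bc_dialect, magnitude = raw$strain)
      list(spec = spec, bc = bc, resolution = as.integer(raw$resolution))
    }, error = function(e) {
      problems <<- c(problems, conditionMessage(e))
      NULL
    })
  }
  if (length(problems) > 0L)
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  attr(cfg, "provenance") <- list(path = path, defaults_used = used_default,
                                  hash = config_hash(raw))
  class(cfg) <- "run_config"
  cfg
}

# Polynomial rolling hash (mod 2^31 - 1, exact in double arithmetic) of the
# canonicalized key=value content; dependency-free and used only to
# fingerprint configurations in outputs.
config_hash <- function(x) {
  if (is.list(x)) {
    x <- x[order(names(x))]
    x <- paste(names(x), vapply(x, function(v) paste(format(v), collapse = ","), ""),
               sep = "=", collapse = ";")
  }
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  m <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% m
  sprintf("%08x", as.integer(h))
}

#' Write sweep or fit results to CSV or JSON
#'
#' CSV output has a stable column order with units in the headers and a
#' leading comment line carrying the package version and configuration
#' hash; identical inputs produce byte-identical files. JSON round-trips
#' losslessly.
#'
#' @param results A `"scaffold_sweep"`, `"scaffold_fit"` or data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- results_table(results)
  meta <- sprintf("scaffoldFE %s config %s",
                  as.character(utils::packageVersion("scaffoldFE")),
                  config_hash(paste(utils::capture.output(utils::str(df)), collapse = "")))
  if (format == "csv") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("# ", meta), con)
    utils::write.csv(df, con, row.names = FALSE)
  } else {
    jsonlite::write_json(list(meta = meta, rows = df), path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Canonical result table
#'
#' @param results A `"scaffold_sweep"`, `"scaffold_fit"` or data.frame.
#' @return Data.frame with the documented column schema.
#' @export
results_table <- function(results) {
  if (inherits(results, "scaffold_sweep")) return(results$rows)
  if (inherits(results, "scaffold_fit")) {
    f <- results
    sp <- f$spec
    return(data.frame(
      pore_um = if (!is.null(sp)) sp$cell$p_um else NA_real_,
      fiber_um = if (!is.null(sp)) sp$cell$d_um else NA_real_,
      porosity_measured = f$porosity,
      cells_per_layer = if (!is.null(sp)) sp$n^2 else NA_integer_,
      layers = if (!is.null(sp)) sp$m else NA_integer_,
      material = f$material$name,
      axis = names(f$E_eff_kPa),
      E_eff_kPa = unname(f$E_eff_kPa),
      lineage = classify_lineage(unname(f$E_eff_kPa)),
      resolution = f$resolution
    ))
  }
  if (is.data.frame(results)) return(results)
  stop("unsupported results object", call. = FALSE)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return Data.frame (the meta comment line is skipped).
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

# --- VTK legacy exports ---------------------------------------------------

#' Export a voxel grid as a VTK legacy structured-points file
#'
#' ASCII, one scalar (`solid`, 0/1) per cell; loads directly into ParaView.
#'
#' @param grid A `"voxel_grid"`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- grid$dims
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "scaffoldFE voxel occupancy", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1] + 1L, d[2] + 1L, d[3] + 1L),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", grid$h_um, grid$h_um, grid$h_um),
               sprintf("CELL_DATA %d", prod(d)),
               "SCALARS solid int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(grid$occ)), con)
  invisible(path)
}

#' Export a field solution as a VTK legacy polydata point cloud
#'
#' Writes node positions with displacement vectors and displacement
#' magnitude, mirroring the deformation-field visualizations produced by
#' commercial FE post-processors.
#'
#' @param sol A `"field_solution"`.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(sol, path) {
  stopifnot(inherits(sol, "field_solution"))
  n <- nrow(sol$coords_um)
  u_um <- sol$displacements * 1e6
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "scaffoldFE displacement field", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(sol$coords_um, 1, paste, collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "VECTORS displacement_um float"), con)
  writeLines(apply(u_um, 1, function(v) paste(format(v, digits = 9), collapse = " ")), con)
  writeLines(c("SCALARS magnitude_um float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(sqrt(rowSums(u_um^2)), digits = 9), con)
  invisible(path)
}
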