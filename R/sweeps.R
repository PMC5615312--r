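# The five parametric design studies (fiber width, porosity, cells per
# layer, layer count, material) and the guideline report mapping design
# points to lineage stiffness bands.
#
# Because the model is linear, the effective modulus for material M equals
# the effective modulus of a reference solve with the same geometry and
# Poisson ratio, rescaled by E_M / E_ref. run_sweep() therefore solves each
# distinct (geometry, Poisson ratio) once and rescales across materials,
# which is exact, not an approximation.

.sweep_studies <- c("fiber_width", "porosity", "cells_per_layer", "layers",
                    "material")

#' Preset design sweeps
#'
#' Returns the standard design of one of the five parametric studies:
#' \describe{
#'   \item{fiber_width}{single layer, 16 cells (4 x 4), p = 200 um,
#'     d = 50..100 um in steps of 10; gelatins G5/G7/G14.}
#'   \item{porosity}{single layer, 16 cells, d = 100 um, porosity 30..90%
#'     in steps of 10% (pore side inverted); gelatins.}
#'   \item{cells_per_layer}{single layer, p = 200 um, d = 80 um, 1, 4, 16,
#'     36, 64 and 100 cells per layer; gelatins.}
#'   \item{layers}{16 cells/layer, p = 200 um, porosities 70/90/95%
#'     (fiber width inverted), 1, 5, 10, 20, 30 layers; gelatins.}
#'   \item{material}{as `layers` but porosities 70/80/90% and materials
#'     chitosan and PCL.}
#' }
#'
#' @param study Study name.
#' @param layers Optional override of the layer counts (for desk-scale
#'   runs of the `layers`/`material` studies).
#' @param resolution Voxels per fiber width.
#' @param axis Loading axis; the default `"x"` loads multi-layer scaffolds
#'   in-plane.
#' @param dialect Geometry dialect.
#' @return An object of class `"sweep_spec"`.
#' @examples
#' sweep_preset("fiber_width")$design$fiber_um  # 50 60 70 80 90 100
#' @export
sweep_preset <- function(study, layers = NULL, resolution = 4L, axis = "x",
                         dialect = "channel_cell") {
  study <- match.arg(study, .sweep_studies)
  design <- switch(study,
    fiber_width = data.frame(pore_um = 200, fiber_um = seq(50, 100, by = 10),
                             porosity = NA_real_, n = 4L, m = 1L),
    porosity = data.frame(pore_um = NA_real_, fiber_um = 100,
                          porosity = seq(0.3, 0.9, by = 0.1), n = 4L, m = 1L),
    cells_per_layer = data.frame(pore_um = 200, fiber_um = 80,
                                 porosity = NA_real_,
                                 n = c(1L, 2L, 4L, 6L, 8L, 10L), m = 1L),
    layers = expand.grid(pore_um = 200, fiber_um = NA_real_,
                         porosity = c(0.7, 0.9, 0.95),
                         n = 4L, m = c(1L, 5L, 10L, 20L, 30L)),
    material = expand.grid(pore_um = 200, fiber_um = NA_real_,
                           porosity = c(0.7, 0.8, 0.9),
                           n = 4L, m = c(1L, 5L, 10L, 20L, 30L))
  )
  if (!is.null(layers)) {
    if (!study %in% c("layers", "material"))
      stop("layer override applies only to the layers/material studies",
           call. = FALSE)
    design <- design[design$m %in% as.integer(layers), , drop = FALSE]
  }
  design <- design[order(design$m, design$porosity, design$fiber_um,
                         design$n, na.last = FALSE), , drop = FALSE]
  rownames(design) <- NULL
  varied <- switch(study, fiber_width = "fiber_um", porosity = "porosity",
                   cells_per_layer = "n", layers = "m", material = "m")
  materials <- if (study == "material") c("chitosan", "PCL")
               else c("G5", "G7", "G14")
  structure(list(study = study, design = design, varied = varied,
                 materials = materials,
                 resolution = as.integer(resolution), axis = axis,
                 dialect = dialect),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("<sweep_spec %s> %d design point(s) x %d material(s), resolution %d, axis %s\n",
              x$study, nrow(x$design), length(x$materials), x$resolution,
              x$axis))
  invisible(x)
}

# Build the scaffold_spec for one design row; a prescribed porosity inverts
# the free parameter (fiber width when the pore side is fixed and vice
# versa).
.design_spec <- function(row, material, dialect) {
  args <- list(cells_per_side = row$n, layers = row$m, material = material,
               dialect = dialect)
  if (!is.na(row$porosity)) {
    args$porosity <- row$porosity
    if (!is.na(row$pore_um)) args$pore_um <- row$pore_um
    else args$fiber_um <- row$fiber_um
  } else {
    args$pore_um <- row$pore_um
    args$fiber_um <- row$fiber_um
  }
  do.call(scaffold_spec, args)
}

#' Run a design sweep
#'
#' Executes every (design point, material) combination and collects the
#' effective moduli. Rows that fail (infeasible geometry, no load path,
#' solver failure) are kept with their error message, never silently
#' dropped. Row order is deterministic.
#'
#' @param spec A `"sweep_spec"` from [sweep_preset()] or built by hand with
#'   the same fields.
#' @param use_symmetry,tol,solver Passed to [scaffold_stiffness()].
#' @param progress Print one line per design point.
#' @return An object of class `"scaffold_sweep"`: `rows` (data.frame),
#'   `spec` echo, `version`, `timestamp`.
#' @export
run_sweep <- function(spec, use_symmetry = TRUE, tol = 1e-8, solver = "auto",
                      progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  bc <- boundary_condition(axis = spec$axis)
  mats <- lapply(spec$materials, get_material)
  names(mats) <- spec$materials
  rows <- list()
  for (i in seq_len(nrow(spec$design))) {
    row <- spec$design[i, , drop = FALSE]
    # one reference solve per Poisson ratio present among the materials
    ratio_by_nu <- list()
    for (mname in spec$materials) {
      mat <- mats[[mname]]
      nu_key <- sprintf("%.10g", mat$nu)
      rec <- ratio_by_nu[[nu_key]]
      if (is.null(rec)) {
        rec <- tryCatch({
          sspec <- .design_spec(row, mat, spec$dialect)
          fit <- suppressWarnings(scaffold_stiffness(
            sspec, bc, resolution = spec$resolution,
            use_symmetry = use_symmetry, tol = tol, solver = solver))
          d <- fit$diagnostics[[1]]
          list(ratio = fit$E_eff_Pa[[1]] / mat$E, porosity = fit$porosity,
               spec = sspec, diag = d, error = NA_character_)
        }, error = function(e) list(ratio = NA_real_, porosity = NA_real_,
                                    spec = NULL, diag = NULL,
                                    error = conditionMessage(e)))
        ratio_by_nu[[nu_key]] <- rec
      }
      E_kPa <- rec$ratio * mat$E / 1e3
      geom <- rec$spec
      rows[[length(rows) + 1L]] <- data.frame(
        study = spec$study,
        pore_um = if (!is.null(geom)) geom$cell$p_um else row$pore_um,
        fiber_um = if (!is.null(geom)) geom$cell$d_um else row$fiber_um,
        porosity_target = row$porosity,
        porosity_measured = rec$porosity,
        cells_per_layer = row$n^2,
        layers = row$m,
        thickness_um = if (!is.null(geom)) row$m * geom$cell$L_um else NA_real_,
        material = mats[[mname]]$name,
        E_eff_kPa = E_kPa,
        lineage = if (is.na(E_kPa)) NA_character_ else classify_lineage(E_kPa),
        resolution = spec$resolution,
        solver = if (!is.null(rec$diag)) rec$diag$solver else NA_character_,
        iterations = if (!is.null(rec$diag)) rec$diag$iterations else NA_integer_,
        error = rec$error
      )
      if (progress)
        message(sprintf("  %s | %s = %s | %s -> %s",
                        spec$study, spec$varied, format(row[[spec$varied]]),
                        mname,
                        if (is.na(E_kPa)) rec$error else sprintf("%.4g kPa", E_kPa)))
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  if (all(!is.na(rows$error)))
    stop("sweep failed: every design point errored; first error: ",
         rows$error[1], call. = FALSE)
  structure(list(rows = rows, spec = spec,
                 version = as.character(utils::packageVersion("scaffoldFE")),
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "scaffold_sweep")
}

#' @export
print.scaffold_sweep <- function(x, ...) {
  cat(sprintf("<scaffold_sweep %s> %d rows (%d failed)\n",
              x$spec$study, nrow(x$rows), sum(!is.na(x$rows$error))))
  print(utils::head(x$rows[, c("pore_um", "fiber_um", "porosity_measured",
                               "cells_per_layer", "layers", "material",
                               "E_eff_kPa", "lineage")], 10))
  if (nrow(x$rows) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
summary.scaffold_sweep <- function(object, ...) {
  r <- object$rows[is.na(object$rows$error), , drop = FALSE]
  agg <- stats::aggregate(E_eff_kPa ~ material, data = r,
                          FUN = function(v) c(min = min(v), max = max(v)))
  cat(sprintf("Sweep '%s': %d design points, materials %s\n",
              object$spec$study, nrow(r),
              paste(unique(r$material), collapse = ", ")))
  print(agg)
  invisible(object)
}

#' @export
plot.scaffold_sweep <- function(x, log_y = TRUE, ...) {
  r <- x$rows[is.na(x$rows$error), , drop = FALSE]
  varied <- x$spec$varied
  vmap <- c(fiber_um = "fiber_um", porosity = "porosity_measured",
            n = "cells_per_layer", m = "layers")
  vcol <- vmap[[varied]]
  mats <- unique(r$material)
  cols <- grDevices::hcl.colors(max(3, length(mats)), "Dark 3")
  graphics::plot(NA, xlim = range(r[[vcol]]), ylim = range(r$E_eff_kPa),
                 log = if (log_y) "y" else "",
                 xlab = vcol, ylab = "E_eff (kPa)",
                 main = sprintf("Sweep: %s", x$spec$study), ...)
  for (j in seq_along(mats)) {
    sub <- r[r$material == mats[j], , drop = FALSE]
    sub <- sub[order(sub[[vcol]]), , drop = FALSE]
    graphics::lines(sub[[vcol]], sub$E_eff_kPa, col = cols[j], type = "b",
                    pch = 19)
  }
  graphics::legend("topleft", legend = mats, col = cols[seq_along(mats)],
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Design-guideline report
#'
#' Summarizes a sweep into the design guidance used to pick scaffolds for a
#' target lineage: which design points land in each stiffness band per
#' material, which exceed the 500-um thickness above which hypoxic
#' gradients become a concern, and (when layer count was varied) the
#' minimum number of layers reaching each band per material and porosity.
#'
#' @param sweep A `"scaffold_sweep"`.
#' @param hypoxia_limit_um Thickness flag threshold (default 500 um).
#' @param asymptote_tol Relative successive change below which the
#'   stiffness-versus-layers trend counts as flat (default 5%).
#' @return A list of class `"guideline_report"`: `by_lineage` (data.frame of
#'   design points with lineage and hypoxia flag), `min_layers` (data.frame
#'   or NULL), `layer_asymptote` (data.frame or NULL: smallest layer count
#'   at which successive change in E drops below `asymptote_tol`, per
#'   material and porosity), `spread` (relative spread of E across design
#'   points, per material).
#' @export
guideline_report <- function(sweep, hypoxia_limit_um = 500,
                             asymptote_tol = 0.05) {
  stopifnot(inherits(sweep, "scaffold_sweep"))
  r <- sweep$rows[is.na(sweep$rows$error), , drop = FALSE]
  r$hypoxia_flag <- !is.na(r$thickness_um) & r$thickness_um > hypoxia_limit_um
  spread <- vapply(split(r$E_eff_kPa, r$material), relative_spread, 0)
  min_layers <- NULL
  layer_asymptote <- NULL
  if (length(unique(r$layers)) > 1L) {
    combos <- unique(r[, c("material", "porosity_target")])
    recs <- list()
    asy <- list()
    for (i in seq_len(nrow(combos))) {
      sub <- r[r$material == combos$material[i] &
               (is.na(combos$porosity_target[i]) |
                r$porosity_target == combos$porosity_target[i]), , drop = FALSE]
      sub <- sub[order(sub$layers), , drop = FALSE]
      if (nrow(sub) > 1L) {
        rel <- abs(diff(sub$E_eff_kPa)) / abs(sub$E_eff_kPa[-nrow(sub)])
        flat <- which(rel < asymptote_tol)
        asy[[length(asy) + 1L]] <- data.frame(
          material = combos$material[i],
          porosity = combos$porosity_target[i],
          layers_at_asymptote = if (length(flat))
            sub$layers[flat[1] + 1L] else NA_integer_)
      }
      for (band in c("neurogenic", "myogenic", "osteogenic")) {
        hit <- sub[sub$lineage == band, , drop = FALSE]
        recs[[length(recs) + 1L]] <- data.frame(
          material = combos$material[i],
          porosity = combos$porosity_target[i],
          lineage = band,
          min_layers = if (nrow(hit)) min(hit$layers) else NA_integer_,
          thickness_um = if (nrow(hit))
            min(hit$thickness_um[hit$layers == min(hit$layers)]) else NA_real_)
      }
    }
    min_layers <- do.call(rbind, recs)
    layer_asymptote <- do.call(rbind, asy)
  }
  structure(list(
    by_lineage = r[, c("material", "pore_um", "fiber_um", "porosity_measured",
                       "cells_per_layer", "layers", "thickness_um",
                       "E_eff_kPa", "lineage", "hypoxia_flag")],
    min_layers = min_layers,
    layer_asymptote = layer_asymptote,
    spread = spread,
    study = sweep$spec$study
  ), class = "guideline_report")
}

#' Relative spread of a set of moduli
#'
#' `(max - min) / mean`, the sensitivity measure used to quantify how much
#' a design parameter moves the effective stiffness.
#'
#' @param v Numeric vector of moduli.
#' @return Scalar relative spread.
#' @export
relative_spread <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(NA_real_)
  (max(v) - min(v)) / mean(v)
}

#' @export
print.guideline_report <- function(x, ...) {
  cat(sprintf("<guideline_report %s>\n", x$study))
  tab <- table(x$by_lineage$material, x$by_lineage$lineage)
  print(tab)
  cat("relative spread of E per material:\n")
  print(round(x$spread, 4))
  if (!is.null(x$min_layers)) {
    cat("minimum layers reaching each band:\n")
    print(x$min_layers[!is.na(x$min_layers$min_layers), , drop = FALSE])
  }
  if (!is.null(x$layer_asymptote)) {
    cat("layer count at which E flattens (successive change < 5%):\n")
    print(x$layer_asymptote)
  }
  n_flag <- sum(x$by_lineage$hypoxia_flag)
  if (n_flag > 0)
    cat(sprintf("%d design point(s) exceed the 500 um hypoxia thickness flag\n",
                n_flag))
  invisible(x)
}
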