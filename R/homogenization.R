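# Effective Young's modulus of a scaffold from a field solution, and the
# stiffness-band classification used to match scaffold designs to stem-cell
# lineages.
#
# E = (F / A) / (dL / L): F is the axial reaction sum under displacement
# control (or the applied load under pressure control), A the GROSS
# bounding-face area (voids included), L the total span along the loading
# axis and dL the length change. Gross area is the convention under which a
# fully dense block recovers exactly its bulk modulus.

#' Effective Young's modulus from a field solution
#'
#' @param sol A `"field_solution"` from [solve_elasticity()].
#' @param area_m2 Gross cross-section area normal to the loading axis (m^2);
#'   defaults to the solved grid's bounding face.
#' @return Effective modulus in Pa.
#' @export
effective_modulus <- function(sol, area_m2 = NULL) {
  stopifnot(inherits(sol, "field_solution"))
  ai <- .axis_index(sol$bc$axis)
  h_m <- sol$h_um * 1e-6
  if (is.null(area_m2)) {
    od <- setdiff(1:3, ai)
    area_m2 <- prod(sol$dims[od]) * h_m^2
  }
  L <- sol$span_m
  if (sol$bc$mode == "displacement_control") {
    FA <- abs(sum(sol$reactions[sol$on_A, ai]))
    dL <- sol$delta_m
    if (dL == 0) stop("degenerate solution: zero imposed displacement", call. = FALSE)
    (FA / area_m2) * (L / dL)
  } else {
    uB <- sol$displacements[sol$on_B, ai]
    dL <- switch(sol$bc$delta_rule, max = max(abs(uB)), mean = mean(abs(uB)))
    if (dL == 0) stop("degenerate solution: loaded face did not move", call. = FALSE)
    # total applied force over gross area; the traction acts on the solid
    # part of the face only
    Ftot <- sum(sol$reactions[sol$on_A, ai])
    (abs(Ftot) / area_m2) * (L / dL)
  }
}

#' Map a stiffness to a stem-cell lineage band
#'
#' Stiffness bands for lineage specification by matrix stiffness:
#' neurogenic 0.1-1 kPa, myogenic 8-17 kPa, osteogenic 25 kPa and above.
#' Band edges are inclusive; moduli in the gaps (below 0.1, 1-8, 17-25 kPa)
#' are `"indeterminate"` rather than snapped to a nearest band.
#'
#' @param E_kPa Effective modulus in kPa (vectorized).
#' @return Character vector of `"neurogenic"`, `"myogenic"`, `"osteogenic"`
#'   or `"indeterminate"`.
#' @examples
#' classify_lineage(c(0.5, 12, 30, 5))
#' @export
classify_lineage <- function(E_kPa) {
  if (any(!is.finite(E_kPa)) || any(E_kPa <= 0))
    stop("modulus must be positive", call. = FALSE)
  out <- rep("indeterminate", length(E_kPa))
  out[E_kPa >= 0.1 & E_kPa <= 1] <- "neurogenic"
  out[E_kPa >= 8 & E_kPa <= 17] <- "myogenic"
  out[E_kPa >= 25] <- "osteogenic"
  out
}

# Decide which mirror-symmetry reductions a scaffold solve admits and build
# the reduced grid. Loading axis and both transverse axes are halved when
# the occupancy is mirror-symmetric about the mid-plane and the voxel count
# is even. The halved problem with the symmetry-plane conditions
# (u_axis = strain * span/2 on the cut loading plane; zero normal
# displacement on cut transverse planes) has exactly the full problem's
# solution restricted to the half domain, so the effective modulus is
# unchanged while cost drops up to 8-fold.
.reduce_symmetric <- function(grid, bc) {
  if (bc$mode != "displacement_control" || bc$dialect != "homogenization_rollers")
    return(list(grid = grid, symmetry = character(), reduced = FALSE))
  occ <- grid$occ
  dims <- dim(occ)
  ai <- .axis_index(bc$axis)
  axes <- c("x", "y", "z")
  symmetry <- character()
  reduced <- FALSE
  for (s in 1:3) {
    if (dims[s] %% 2L != 0L) next
    flipped <- switch(s,
      occ[rev(seq_len(dims[1])), , , drop = FALSE],
      occ[, rev(seq_len(dims[2])), , drop = FALSE],
      occ[, , rev(seq_len(dims[3])), drop = FALSE])
    if (!identical(as.logical(flipped), as.logical(occ))) next
    half <- seq_len(dims[s] %/% 2L)
    occ <- switch(s,
      occ[half, , , drop = FALSE],
      occ[, half, , drop = FALSE],
      occ[, , half, drop = FALSE])
    dims <- dim(occ)
    reduced <- TRUE
    if (s != ai) symmetry <- c(symmetry, axes[s])
    # the loading-axis cut needs no marker: the cut plane simply becomes the
    # loaded face of the half problem at the same imposed strain
  }
  list(grid = if (reduced) new_voxel_grid(occ, grid$h_um) else grid,
       symmetry = symmetry, reduced = reduced)
}

#' Homogenize one scaffold design
#'
#' The package's central computation: voxelizes a scaffold design, solves
#' the elasticity problem along the requested axes, and reports the
#' effective Young's modulus per axis together with the measured porosity,
#' the lineage band of the (first-axis) modulus and solver diagnostics.
#'
#' @param spec A [scaffold_spec()] (or a `"voxel_grid"` plus `material`).
#' @param bc A [boundary_condition()]; its `axis` is ignored when `axes`
#'   names several.
#' @param resolution Voxels per fiber width passed to [voxelize()].
#' @param axes Axes to load, subset of `c("x","y","z")`.
#' @param use_symmetry Exploit mirror symmetry of the voxel pattern to solve
#'   on a reduced domain (exact, roller displacement control only).
#' @param tol,solver Passed to [solve_elasticity()].
#' @param quiet Suppress messages.
#' @return An object of class `"scaffold_fit"` with elements `E_eff_Pa`
#'   (named per axis), `E_eff_kPa`, `porosity`, `lineage`, `spec`, `bc`,
#'   `resolution`, `diagnostics`.
#' @examples
#' \donttest{
#' fit <- scaffold_stiffness(
#'   scaffold_spec(pore_um = 200, fiber_um = 100, material = "G5"),
#'   resolution = 2)
#' coef(fit)
#' }
#' @export
scaffold_stiffness <- function(spec, bc = boundary_condition(),
                               resolution = 4L, axes = bc$axis,
                               use_symmetry = TRUE,
                               tol = 1e-8, solver = "auto",
                               material = NULL, quiet = TRUE) {
  if (inherits(spec, "voxel_grid")) {
    grid <- spec
    mat <- get_material(material)
    spec <- NULL
  } else {
    stopifnot(inherits(spec, "scaffold_spec"))
    grid <- voxelize(spec, resolution)
    mat <- spec$material
  }
  phi <- measured_porosity(grid)
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  E <- numeric(0)
  diag_list <- list()
  for (ax in axes) {
    bca <- bc; bca$axis <- ax
    red <- if (use_symmetry) .reduce_symmetric(grid, bca)
           else list(grid = grid, symmetry = character(), reduced = FALSE)
    sol <- solve_elasticity(red$grid, mat, bca, tol = tol, solver = solver,
                            symmetry = red$symmetry, quiet = quiet)
    E[ax] <- effective_modulus(sol)
    diag_list[[ax]] <- list(iterations = sol$iterations, relres = sol$relres,
                            solver = sol$solver, n_nodes = sol$n_nodes,
                            n_elements = sol$n_elements,
                            n_dropped_voxels = sol$n_dropped_voxels,
                            reduced = red$reduced)
  }
  structure(list(
    E_eff_Pa = E,
    E_eff_kPa = E / 1e3,
    porosity = phi,
    lineage = classify_lineage(E[[1]] / 1e3),
    material = mat,
    spec = spec,
    bc = bc,
    resolution = if (is.null(spec)) NA_integer_ else as.integer(resolution),
    grid_dims = grid$dims,
    h_um = grid$h_um,
    diagnostics = diag_list
  ), class = "scaffold_fit")
}

#' @export
print.scaffold_fit <- function(x, ...) {
  cat("<scaffold_fit>\n")
  if (!is.null(x$spec)) print(x$spec)
  cat(sprintf("  material %s | measured porosity %.4f | grid %s @ %.3g um\n",
              x$material$name, x$porosity,
              paste(x$grid_dims, collapse = "x"), x$h_um))
  for (ax in names(x$E_eff_Pa))
    cat(sprintf("  E_%s = %s\n", ax, format_pressure(x$E_eff_Pa[[ax]])))
  cat(sprintf("  lineage band: %s\n", x$lineage))
  invisible(x)
}

#' @export
summary.scaffold_fit <- function(object, ...) {
  d <- object$diagnostics[[1]]
  cat(sprintf(
    "Scaffold stiffness fit: E = %s (%s), porosity %.3f, %s solver, %d iterations, relres %.2g%s\n",
    format_pressure(object$E_eff_Pa[[1]]), object$lineage, object$porosity,
    d$solver, d$iterations, d$relres,
    if (isTRUE(d$reduced)) ", symmetry-reduced domain" else ""))
  invisible(object)
}

#' @export
coef.scaffold_fit <- function(object, ...) object$E_eff_kPa

#' @export
plot.scaffold_fit <- function(x, ...) {
  # mid-thickness slice of the voxel pattern the fit was computed on
  if (is.null(x$spec)) {
    stop("plot requires a fit built from a scaffold_spec", call. = FALSE)
  }
  grid <- voxelize(x$spec, x$resolution)
  k <- max(1L, grid$dims[3] %/% 2L)
  graphics::image(grid$occ[, , k], col = c("white", "grey30"), axes = FALSE,
                  main = sprintf("%s mid-slice, E = %s (%s)",
                                 x$material$name,
                                 format_pressure(x$E_eff_Pa[[1]]), x$lineage),
                  ...)
  invisible(x)
}

#' Effective modulus along all three axes
#'
#' Three independent solves, one per axis. For an n x n x n tiling of the
#' symmetric cubic unit cell the three modul agree to solver precision; a
#' single layer (m < n) is stiffer in-plane than through-thickness.
#'
#' @param grid A `"voxel_grid"` or [scaffold_spec()].
#' @param material Material (ignored when `grid` is a spec).
#' @param bc Boundary-condition template (axis overridden).
#' @param ... Passed to [scaffold_stiffness()].
#' @return Named numeric vector (Pa) with elements `x`, `y`, `z`.
#' @export
directional_moduli <- function(grid, material = NULL, bc = boundary_condition(),
                               ...) {
  fit <- scaffold_stiffness(grid, bc = bc, axes = c("x", "y", "z"),
                            material = material, ...)
  fit$E_eff_Pa
}

#' Mesh-refinement convergence study
#'
#' Recomputes the effective modulus at each resolution and reports the first
#' resolution at which the successive relative change drops below
#' `threshold`.
#'
#' @param spec A [scaffold_spec()].
#' @param bc A [boundary_condition()].
#' @param resolutions Increasing integer vector, length >= 3.
#' @param threshold Relative-change convergence threshold (default 0.02).
#' @param ... Passed to [scaffold_stiffness()].
#' @return A data.frame with columns `resolution`, `E_eff_kPa`,
#'   `rel_change`, `converged`; attribute `converged_resolution` (NA if the
#'   sequence never settles).
#' @export
convergence_study <- function(spec, bc = boundary_condition(),
                              resolutions = c(2L, 4L, 8L), threshold = 0.02,
                              ...) {
  stopifnot(length(resolutions) >= 3L, !is.unsorted(resolutions))
  E <- vapply(resolutions, function(r)
    scaffold_stiffness(spec, bc, resolution = r, ...)$E_eff_Pa[[1]], 0)
  rel <- c(NA, abs(diff(E)) / abs(E[-length(E)]))
  conv <- !is.na(rel) & rel < threshold
  out <- data.frame(resolution = as.integer(resolutions),
                    E_eff_kPa = E / 1e3,
                    rel_change = rel,
                    converged = conv)
  attr(out, "converged_resolution") <-
    if (any(conv)) as.integer(resolutions[which(conv)[1]]) else NA_integer_
  out
}
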