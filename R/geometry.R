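# Parametric cubic unit-cell scaffold geometry: closed-form porosity, its
# inversion, and voxelization.
#
# A unit cell is a cube of side L = p + 2 d, where p is the pore side and d
# the fiber width (both um). Two solid-geometry dialects are supported:
#   channel_cell - cube of side L with three orthogonal square through-
#                  channels of side p (interconnected pores on all axes);
#                  porosity (3 p^2 L - 2 p^3) / L^3.
#   strut_frame  - square beams of cross-section d x d along the 12 cube
#                  edges; porosity 1 - (12 d^2 L - 16 d^3) / L^3.
# Scaffolds tile n x n unit cells per layer and m layers face-to-face at
# pitch L, so interior walls have width 2 d.

.scaffold_dialects <- c("channel_cell", "strut_frame")

#' Cubic unit-cell specification
#'
#' @param pore_um Pore side length p (um), > 0.
#' @param fiber_um Fiber width d (um), > 0.
#' @param dialect Solid geometry dialect, `"channel_cell"` (default) or
#'   `"strut_frame"`.
#' @return An object of class `"unit_cell"` with fields `p_um`, `d_um`,
#'   `dialect` and the derived cell side `L_um = p + 2 d`.
#' @examples
#' uc <- unit_cell(200, 100)
#' uc$L_um  # 400
#' @export
unit_cell <- function(pore_um, fiber_um, dialect = "channel_cell") {
  dialect <- match.arg(dialect, .scaffold_dialects)
  if (!is.finite(pore_um) || pore_um <= 0)
    stop("pore side 'p' must be positive", call. = FALSE)
  if (!is.finite(fiber_um) || fiber_um <= 0)
    stop("fiber width 'd' must be positive", call. = FALSE)
  structure(list(p_um = as.numeric(pore_um), d_um = as.numeric(fiber_um),
                 L_um = as.numeric(pore_um) + 2 * as.numeric(fiber_um),
                 dialect = dialect),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell %s> p = %g um, d = %g um, L = %g um, porosity %.4f\n",
              x$dialect, x$p_um, x$d_um, x$L_um, closed_form_porosity(x)))
  invisible(x)
}

#' Exact porosity of a unit cell
#'
#' Void volume fraction of the cell from the closed form of its dialect; no
#' discretization is involved.
#'
#' @param cell A [unit_cell()], or the pore side p (um) if `fiber_um` given.
#' @param fiber_um,dialect Used only when `cell` is numeric.
#' @return Porosity in `[0, 1]`.
#' @examples
#' closed_form_porosity(unit_cell(200, 100))  # 0.5
#' @export
closed_form_porosity <- function(cell, fiber_um = NULL, dialect = "channel_cell") {
  if (!inherits(cell, "unit_cell"))
    cell <- unit_cell(cell, fiber_um, dialect)
  p <- cell$p_um; L <- cell$L_um; d <- cell$d_um
  switch(cell$dialect,
    channel_cell = (3 * p^2 * L - 2 * p^3) / L^3,
    strut_frame  = 1 - (12 * d^2 * L - 16 * d^3) / L^3)
}

# Porosity as a function of t = p / L; strictly increasing in t on (0, 1)
# for both dialects, which is what makes the inversions below monotone.
.porosity_of_ratio <- function(t, dialect) {
  switch(dialect,
    channel_cell = 3 * t^2 - 2 * t^3,
    strut_frame  = 1 - (3 * (1 - t)^2 - 2 * (1 - t)^3))
}

.invert_porosity_ratio <- function(target, dialect, rel_tol = 1e-10) {
  # monotone bisection for t = p/L in (0, 1)
  lo <- 0; hi <- 1
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (.porosity_of_ratio(mid, dialect) < target) lo <- mid else hi <- mid
    if ((hi - lo) < rel_tol * max(mid, 1e-12)) break
  }
  (lo + hi) / 2
}

#' Fiber width achieving a target porosity at fixed pore side
#'
#' Inverts the closed-form porosity by monotone bisection (porosity is
#' strictly decreasing in d at fixed p).
#'
#' @param pore_um Pore side p (um).
#' @param porosity Target porosity in (0, 1).
#' @param dialect Geometry dialect.
#' @return Fiber width d (um) with
#'   `closed_form_porosity(unit_cell(pore_um, d))` within 1e-10 relative of
#'   the target.
#' @examples
#' solve_fiber_width(200, 0.5)  # 100
#' @export
solve_fiber_width <- function(pore_um, porosity, dialect = "channel_cell") {
  dialect <- match.arg(dialect, .scaffold_dialects)
  if (!is.finite(pore_um) || pore_um <= 0)
    stop("pore side 'p' must be positive", call. = FALSE)
  .check_porosity_target(porosity, dialect)
  t <- .invert_porosity_ratio(porosity, dialect)
  # L = p / t, d = (L - p) / 2
  pore_um * (1 / t - 1) / 2
}

#' Pore side achieving a target porosity at fixed fiber width
#'
#' Mirror of [solve_fiber_width()]: porosity is strictly increasing in p at
#' fixed d.
#'
#' @param fiber_um Fiber width d (um).
#' @inheritParams solve_fiber_width
#' @return Pore side p (um).
#' @examples
#' solve_pore_side(100, 0.5)  # 200
#' @export
solve_pore_side <- function(fiber_um, porosity, dialect = "channel_cell") {
  dialect <- match.arg(dialect, .scaffold_dialects)
  if (!is.finite(fiber_um) || fiber_um <= 0)
    stop("fiber width 'd' must be positive", call. = FALSE)
  .check_porosity_target(porosity, dialect)
  t <- .invert_porosity_ratio(porosity, dialect)
  # L = 2 d / (1 - t), p = t L
  2 * fiber_um * t / (1 - t)
}

.check_porosity_target <- function(porosity, dialect) {
  if (!is.finite(porosity) || porosity <= 0 || porosity >= 1)
    stop(sprintf(
      "target porosity %s is infeasible: attainable porosities for %s lie strictly inside (0, 1)",
      format(porosity), dialect), call. = FALSE)
  invisible(TRUE)
}

#' Full scaffold design point
#'
#' Describes one scaffold: the unit cell, the layout (an `n x n` layer of
#' unit cells, `m` layers stacked along z at pitch L), and the material.
#' Exactly two of `pore_um`, `fiber_um`, `porosity` must be given; the third
#' is derived from the closed form.
#'
#' @param pore_um,fiber_um,porosity Any two of pore side (um), fiber width
#'   (um) and porosity; the missing one is solved for.
#' @param cells_per_side Unit cells per side of a layer (n; the layer holds
#'   n^2 cells).
#' @param layers Number of stacked layers m.
#' @param material Material name or [material()] object.
#' @param dialect Geometry dialect.
#' @return An object of class `"scaffold_spec"`.
#' @examples
#' scaffold_spec(pore_um = 200, porosity = 0.8, cells_per_side = 4,
#'               layers = 1, material = "G5")
#' @export
scaffold_spec <- function(pore_um = NULL, fiber_um = NULL, porosity = NULL,
                          cells_per_side = 1, layers = 1,
                          material = "G5", dialect = "channel_cell") {
  dialect <- match.arg(dialect, .scaffold_dialects)
  given <- c(pore = !is.null(pore_um), fiber = !is.null(fiber_um),
             phi = !is.null(porosity))
  if (sum(given) != 2L)
    stop("exactly two of pore_um, fiber_um, porosity must be given",
         call. = FALSE)
  if (!given[["pore"]])
    pore_um <- solve_pore_side(fiber_um, porosity, dialect)
  else if (!given[["fiber"]])
    fiber_um <- solve_fiber_width(pore_um, porosity, dialect)
  cell <- unit_cell(pore_um, fiber_um, dialect)
  n <- as.integer(cells_per_side); m <- as.integer(layers)
  if (is.na(n) || n < 1L) stop("cells_per_side must be a positive integer", call. = FALSE)
  if (is.na(m) || m < 1L) stop("layers must be a positive integer", call. = FALSE)
  structure(list(cell = cell, n = n, m = m,
                 material = get_material(material)),
            class = "scaffold_spec")
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat(sprintf(
    "<scaffold_spec> %s | %d x %d cells/layer, %d layer(s) | %s\n",
    sub("\n$", "", format(x$cell)), x$n, x$n, x$m, x$material$name))
  cat(sprintf("  span %g x %g um, thickness %g um, porosity %.4f\n",
              x$n * x$cell$L_um, x$n * x$cell$L_um, x$m * x$cell$L_um,
              closed_form_porosity(x$cell)))
  invisible(x)
}

#' @export
format.unit_cell <- function(x, ...) {
  sprintf("%s p=%g d=%g um", x$dialect, x$p_um, x$d_um)
}

# --- voxelization ---------------------------------------------------------

new_voxel_grid <- function(occ, h_um) {
  stopifnot(is.logical(occ), length(dim(occ)) == 3L)
  if (!any(occ)) stop("voxel grid has no solid voxels", call. = FALSE)
  structure(list(occ = occ, h_um = h_um, dims = dim(occ)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels @ %.4g um, porosity %.4f\n",
              x$dims[1], x$dims[2], x$dims[3], x$h_um, measured_porosity(x)))
  invisible(x)
}

# Occupancy of one unit cell as a logical c x c x c array, where
# c = p_vox + 2 d_vox.
.unit_cell_occupancy <- function(p_vox, d_vox, dialect) {
  c_vox <- p_vox + 2L * d_vox
  idx <- seq_len(c_vox)
  in_window <- idx > d_vox & idx <= d_vox + p_vox   # pore window, centered
  wx <- array(in_window, dim = c(c_vox, c_vox, c_vox))
  wy <- aperm(wx, c(2, 1, 3))
  wz <- aperm(wx, c(3, 2, 1))
  # number of coordinates inside the pore window
  k <- wx + wy + wz
  if (dialect == "channel_cell") {
    # void where a voxel lies in at least one through-channel, i.e. at least
    # two coordinates fall in the pore window
    k < 2L
  } else {
    # solid where at least two coordinates fall in the edge bands, i.e. at
    # most one coordinate in the pore window
    k <= 1L
  }
}

#' Voxelize a scaffold design
#'
#' Discretizes the scaffold solid on a regular voxel grid. The voxel size is
#' `d / resolution` so the fiber width is exactly resolved; the pore side is
#' snapped to the nearest voxel multiple (a snap beyond 1e-9 relative raises
#' a warning giving the realized pore side). Unit cells are tiled at pitch L
#' along all three axes: n x n cells in-plane, m layers along z.
#'
#' @param spec A [scaffold_spec()].
#' @param resolution Voxels per fiber width (integer >= 2).
#' @return A `"voxel_grid"`: logical occupancy array, voxel size `h_um`,
#'   dims.
#' @examples
#' g <- voxelize(scaffold_spec(pore_um = 200, fiber_um = 100), resolution = 4)
#' g$dims  # 16 16 16
#' @export
voxelize <- function(spec, resolution = 4L) {
  stopifnot(inherits(spec, "scaffold_spec"))
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 2L)
    stop("resolution must be an integer >= 2 voxels per fiber width",
         call. = FALSE)
  cell <- spec$cell
  h <- cell$d_um / resolution
  d_vox <- resolution
  p_vox <- as.integer(round(cell$p_um / h))
  if (p_vox < 1L)
    stop("pore side is below one voxel at this resolution; increase resolution",
         call. = FALSE)
  snapped <- p_vox * h
  if (abs(snapped - cell$p_um) > 1e-9 * cell$p_um)
    warning(sprintf(
      "pore side snapped from %g to %g um (voxel size %g um)",
      cell$p_um, snapped, h), call. = FALSE)
  cell_occ <- .unit_cell_occupancy(p_vox, d_vox, cell$dialect)
  c_vox <- p_vox + 2L * d_vox
  tile <- rep(seq_len(c_vox), times = spec$n)
  tile_z <- rep(seq_len(c_vox), times = spec$m)
  occ <- cell_occ[tile, tile, tile_z]
  dim(occ) <- c(c_vox * spec$n, c_vox * spec$n, c_vox * spec$m)
  new_voxel_grid(occ, h)
}

#' Fully dense voxel block
#'
#' All-solid control geometry (porosity 0), mainly for solver verification.
#'
#' @param nx,ny,nz Voxel counts per axis (`ny`, `nz` default to `nx`).
#' @param h_um Voxel size (um).
#' @return A `"voxel_grid"`.
#' @export
dense_block_grid <- function(nx, ny = nx, nz = nx, h_um = 1) {
  new_voxel_grid(array(TRUE, dim = c(nx, ny, nz)), h_um)
}

#' Measured porosity of a voxel grid
#'
#' One minus the solid voxel fraction; converges to
#' [closed_form_porosity()] as the voxel size shrinks.
#'
#' @param grid A `"voxel_grid"`.
#' @return Porosity in `[0, 1]`.
#' @export
measured_porosity <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  1 - sum(grid$occ) / prod(grid$dims)
}
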