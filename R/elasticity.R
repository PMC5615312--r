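# Small-strain isotropic linear elasticity on the voxel grid.
#
# Every solid voxel becomes one 8-node trilinear hexahedral element; shared
# nodes are merged; solid material not face-connected to both loading faces
# carries no load and is removed before assembly. Systems below a size
# threshold are solved by sparse Cholesky (Matrix); larger ones by a
# matrix-free Jacobi-preconditioned conjugate gradient (C++ kernel). Node
# ordering is lexicographic and fixed, so results are run-to-run
# deterministic on one platform.

#' Element stiffness matrix of a cubic trilinear hexahedron
#'
#' Standard 8-node hexahedron stiffness, exact 2x2x2 Gauss quadrature of
#' `B' C B` with the isotropic elasticity tensor `C(E, nu)`. For a cube the
#' matrix scales linearly in both `E` and the element edge length.
#'
#' @param E Young's modulus (Pa).
#' @param nu Poisson's ratio.
#' @param h Element edge length (m).
#' @param n_gauss Gauss points per direction (2 is exact; higher orders are
#'   available as an independent quadrature cross-check).
#' @return A 24x24 symmetric matrix; dof order is node-major
#'   (node1 x,y,z, node2 x,y,z, ...), with local nodes at offsets
#'   (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),(1,1,1),(0,1,1).
#' @export
hex8_stiffness <- function(E, nu, h = 1, n_gauss = 2L) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, h > 0)
  # isotropic elasticity, Voigt order (xx, yy, zz, yz, xz, xy), engineering shear
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lam
  # local node corners in natural coords xi, eta, zeta in [-1, 1]
  sgn <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                  -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                ncol = 3, byrow = TRUE)
  gp <- .gauss_points(n_gauss)
  K <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  for (a in seq_len(n_gauss)) for (b in seq_len(n_gauss)) for (cc in seq_len(n_gauss)) {
    xi <- gp$x[a]; eta <- gp$x[b]; zeta <- gp$x[cc]
    w <- gp$w[a] * gp$w[b] * gp$w[cc]
    # dN/dxi etc. for N_i = (1 + s1 xi)(1 + s2 eta)(1 + s3 zeta)/8
    dN <- cbind(
      sgn[, 1] * (1 + sgn[, 2] * eta) * (1 + sgn[, 3] * zeta),
      (1 + sgn[, 1] * xi) * sgn[, 2] * (1 + sgn[, 3] * zeta),
      (1 + sgn[, 1] * xi) * (1 + sgn[, 2] * eta) * sgn[, 3]) / 8
    dNdx <- dN * (2 / h)
    B <- matrix(0, 6, 24)
    ix <- 3 * (0:7) + 1
    B[1, ix]     <- dNdx[, 1]
    B[2, ix + 1] <- dNdx[, 2]
    B[3, ix + 2] <- dNdx[, 3]
    B[4, ix + 1] <- dNdx[, 3]; B[4, ix + 2] <- dNdx[, 2]
    B[5, ix]     <- dNdx[, 3]; B[5, ix + 2] <- dNdx[, 1]
    B[6, ix]     <- dNdx[, 2]; B[6, ix + 1] <- dNdx[, 1]
    K <- K + w * detJ * (t(B) %*% C %*% B)
  }
  (K + t(K)) / 2
}

# Gauss-Legendre points and weights on [-1, 1] for n = 1..6 without
# external dependencies (hard-coded abscissae for the small orders used).
.gauss_points <- function(n) {
  switch(as.character(n),
    "1" = list(x = 0, w = 2),
    "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
    "3" = list(x = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9),
    "4" = {
      a <- sqrt(3 / 7 - 2 / 7 * sqrt(6 / 5)); b <- sqrt(3 / 7 + 2 / 7 * sqrt(6 / 5))
      wa <- (18 + sqrt(30)) / 36; wb <- (18 - sqrt(30)) / 36
      list(x = c(-b, -a, a, b), w = c(wb, wa, wa, wb))
    },
    stop("unsupported Gauss order", call. = FALSE))
}

#' Loading configuration for a homogenization solve
#'
#' @param axis Loading axis, `"x"`, `"y"` or `"z"`.
#' @param mode `"displacement_control"` (imposed axial strain on the loaded
#'   face; the default) or `"pressure_control"` (uniform axial traction on
#'   the loaded face's solid surface).
#' @param dialect Support dialect for the opposite (constrained) face:
#'   `"homogenization_rollers"` fixes only the axial component there (plus
#'   minimal pins against rigid-body modes), so a homogeneous block returns
#'   exactly its bulk modulus; `"fixed_face"` fixes all three
#'   components, the fully-clamped support typical of commercial-FEA
#'   scaffold studies.
#' @param magnitude Imposed axial strain (dimensionless, default 0.01,
#'   capped at 0.05 to stay in the linear regime) for displacement control,
#'   or traction in Pa for pressure control.
#' @param delta_rule How `pressure_control` extracts the length change:
#'   `"max"` (maximum axial displacement of the loaded face) or `"mean"`.
#' @return An object of class `"boundary_condition"`.
#' @export
boundary_condition <- function(axis = "x",
                               mode = "displacement_control",
                               dialect = "homogenization_rollers",
                               magnitude = 0.01,
                               delta_rule = "max") {
  axis <- match.arg(axis, c("x", "y", "z"))
  mode <- match.arg(mode, c("displacement_control", "pressure_control"))
  dialect <- match.arg(dialect, c("homogenization_rollers", "fixed_face"))
  delta_rule <- match.arg(delta_rule, c("max", "mean"))
  if (!is.finite(magnitude) || magnitude <= 0)
    stop("load magnitude must be positive", call. = FALSE)
  if (mode == "displacement_control" && magnitude > 0.05)
    stop("imposed strain above 0.05 leaves the small-strain linear regime",
         call. = FALSE)
  structure(list(axis = axis, mode = mode, dialect = dialect,
                 magnitude = magnitude, delta_rule = delta_rule),
            class = "boundary_condition")
}

#' @export
print.boundary_condition <- function(x, ...) {
  unit <- if (x$mode == "displacement_control") "strain" else "Pa"
  cat(sprintf("<boundary_condition> axis %s, %s (%g %s), %s\n",
              x$axis, x$mode, x$magnitude, unit, x$dialect))
  invisible(x)
}

.axis_index <- function(axis) match(axis, c("x", "y", "z"))

# Remove solid material that cannot carry load between the two faces normal
# to `axis`. Errors if nothing connects them.
filter_load_path <- function(grid, axis, quiet = FALSE) {
  ai <- .axis_index(axis)
  res <- vf_load_path(as.logical(grid$occ), as.integer(grid$dims), ai - 1L)
  if (res$n_kept == 0)
    stop("no load path: no solid component connects the two loading faces along ",
         axis, call. = FALSE)
  if (res$n_dropped > 0 && !quiet)
    message(sprintf("dropped %g solid voxel(s) not connected to both loading faces",
                    res$n_dropped))
  occ <- array(res$occ, dim = grid$dims)
  list(grid = new_voxel_grid(occ, grid$h_um), n_dropped = res$n_dropped)
}

# Build the constrained-dof description for a boundary condition on a
# meshed grid. coords are integer lattice coordinates (0..n per axis).
# symmetry: optional character vector naming axes whose MAX face is a
# mirror symmetry plane (normal displacement fixed to zero there).
.build_constraints <- function(coords, dims_vox, bc, h_m, symmetry = character(),
                               node_comp = NULL) {
  n_nodes <- nrow(coords)
  ndof <- 3L * n_nodes
  fixed <- logical(ndof)
  uval <- numeric(ndof)
  ai <- .axis_index(bc$axis)
  axmax <- dims_vox[ai]
  on_A <- coords[, ai] == 0L
  on_B <- coords[, ai] == axmax
  dof_of <- function(nodes, comp) 3L * (nodes - 1L) + comp
  span_m <- axmax * h_m
  delta <- if (bc$mode == "displacement_control") bc$magnitude * span_m else NA_real_

  if (bc$dialect == "fixed_face") {
    for (comp in 1:3) {
      ix <- dof_of(which(on_A), comp)
      fixed[ix] <- TRUE; uval[ix] <- 0
    }
  } else {
    ix <- dof_of(which(on_A), ai)
    fixed[ix] <- TRUE; uval[ix] <- 0
  }
  if (bc$mode == "displacement_control") {
    ix <- dof_of(which(on_B), ai)
    fixed[ix] <- TRUE; uval[ix] <- delta
  }
  # mirror symmetry planes: zero normal displacement on the max face
  sym_fixed <- integer(0)
  for (s in symmetry) {
    si <- .axis_index(s)
    if (si == ai) next
    ix <- dof_of(which(coords[, si] == dims_vox[si]), si)
    fixed[ix] <- TRUE; uval[ix] <- 0
    sym_fixed <- c(sym_fixed, si)
  }
  # minimal pins against the remaining rigid-body modes (rollers only).
  # Rollers leave the transverse translations and the rotation about the
  # loading axis unconstrained, independently for every node-connected
  # solid component, so pins are chosen per component. Pins sit on Face A
  # at extreme corners so the exact affine patch field satisfies them on a
  # homogeneous block (patch test stays exact).
  if (bc$dialect == "homogenization_rollers" && !is.null(node_comp)) {
    off_axes <- setdiff(1:3, ai)
    for (cid in unique(node_comp)) {
      in_comp <- node_comp == cid
      comp_fixed_dir <- vapply(1:3, function(comp)
        any(fixed[dof_of(which(in_comp), comp)]), TRUE)
      free_tr <- off_axes[!comp_fixed_dir[off_axes]]
      anchors <- which(on_A & in_comp)
      if (length(anchors) == 0L) next
      ord <- anchors[order(coords[anchors, off_axes[1]],
                           coords[anchors, off_axes[2]])]
      n1 <- ord[1]
      for (comp in free_tr) {
        ix <- dof_of(n1, comp)
        fixed[ix] <- TRUE; uval[ix] <- 0
      }
      if (length(free_tr) == 2L) {
        # second pin kills rotation about the loading axis: same position
        # along off_axes[2] as n1, far along off_axes[1]
        cand <- anchors[coords[anchors, off_axes[2]] == coords[n1, off_axes[2]] &
                        coords[anchors, off_axes[1]] != coords[n1, off_axes[1]]]
        if (length(cand) == 0L)
          cand <- anchors[anchors != n1]
        if (length(cand) > 0L) {
          n2 <- cand[which.max(abs(coords[cand, off_axes[1]] - coords[n1, off_axes[1]]))]
          ix <- dof_of(n2, off_axes[2])
          fixed[ix] <- TRUE; uval[ix] <- 0
        }
      }
    }
  }
  list(fixed = fixed, uval = uval, on_A = on_A, on_B = on_B, delta = delta,
       span_m = span_m)
}

# External nodal forces for pressure control: uniform traction on the solid
# portion of Face B, lumped per exposed voxel face (h^2 / 4 per node).
.pressure_loads <- function(grid, mesh, bc, h_m) {
  ai <- .axis_index(bc$axis)
  dims <- grid$dims
  occ <- grid$occ
  # solid voxels on the max layer along the axis
  idx <- switch(ai,
    `1` = which(occ[dims[1], , , drop = FALSE]),
    `2` = which(occ[, dims[2], , drop = FALSE]),
    `3` = which(occ[, , dims[3], drop = FALSE]))
  ndof <- 3L * mesh$n_nodes
  f <- numeric(ndof)
  coords <- mesh$coords
  on_B_node <- coords[, ai] == dims[ai]
  # for each solid boundary voxel, add traction to its 4 face nodes
  per_node <- bc$magnitude * h_m^2 / 4
  # reconstruct (j,k) transverse indices of boundary voxels
  od <- setdiff(1:3, ai)
  tdims <- dims[od]
  jj <- ((idx - 1L) %% tdims[1]) + 1L
  kk <- ((idx - 1L) %/% tdims[1]) + 1L
  # node lattice coords of the 4 corner nodes of each loaded face
  key <- function(cd) (cd[, 1] + 1) + (dims[1] + 1) * (cd[, 2] + (dims[2] + 1) * cd[, 3])
  node_key <- key(coords)
  lookup <- integer(max(node_key))
  lookup[node_key] <- seq_len(nrow(coords))
  for (da in 0:1) for (db in 0:1) {
    cd <- matrix(0L, length(jj), 3)
    cd[, ai] <- dims[ai]
    cd[, od[1]] <- jj - 1L + da
    cd[, od[2]] <- kk - 1L + db
    nid <- lookup[key(cd)]
    f[3L * (nid - 1L) + ai] <- f[3L * (nid - 1L) + ai] + per_node
  }
  f
}

#' Solve the elasticity problem on a voxel grid
#'
#' Filters off-load-path material, meshes the solid voxels, applies the
#' boundary condition and solves. Systems under `direct_max_dof` use a
#' sparse Cholesky factorization; larger systems the matrix-free
#' Jacobi-preconditioned conjugate gradient.
#'
#' @param grid A `"voxel_grid"`.
#' @param material Material name or [material()] object.
#' @param bc A [boundary_condition()].
#' @param tol Relative residual tolerance for the iterative solver.
#' @param solver `"auto"`, `"direct"` or `"cg"`.
#' @param direct_max_dof Size threshold for the direct path under `"auto"`.
#' @param symmetry Character vector of axes whose max face is treated as a
#'   mirror-symmetry plane (zero normal displacement); used by the reduced-
#'   domain fast path for geometries with mirror symmetry.
#' @param quiet Suppress informational messages.
#' @return An object of class `"field_solution"`: node coordinates (um),
#'   `displacements` (n x 3, m), `reactions` (n x 3, N, nonzero only on
#'   constrained dofs), iteration count, relative residual, and bookkeeping
#'   (`span_m`, `delta_m`, `bc`, `h_um`, `dims`).
#' @export
solve_elasticity <- function(grid, material, bc = boundary_condition(),
                             tol = 1e-8, solver = c("auto", "direct", "cg"),
                             direct_max_dof = 15000L,
                             symmetry = character(), quiet = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(bc, "boundary_condition"))
  solver <- match.arg(solver)
  mat <- get_material(material)
  fp <- filter_load_path(grid, bc$axis, quiet = quiet)
  grid <- fp$grid
  h_m <- grid$h_um * 1e-6
  mesh <- vf_mesh(as.logical(grid$occ), as.integer(grid$dims))
  Ke <- hex8_stiffness(mat$E, mat$nu, h_m)
  node_comp <- if (bc$dialect == "homogenization_rollers")
    vf_node_components(mesh$elem, mesh$n_nodes) else NULL
  con <- .build_constraints(mesh$coords, grid$dims, bc, h_m, symmetry,
                            node_comp)
  ndof <- 3L * mesh$n_nodes
  fext <- if (bc$mode == "pressure_control")
    .pressure_loads(grid, mesh, bc, h_m) else numeric(ndof)

  use_direct <- switch(solver, direct = TRUE, cg = FALSE,
                       auto = ndof <= direct_max_dof)
  if (use_direct) {
    sol <- .solve_direct(mesh, Ke, con, fext)
  } else {
    maxit <- max(1000L, as.integer(ceiling(50 * sqrt(ndof))))
    u0 <- NULL
    if (bc$mode == "displacement_control") {
      # affine field of the homogeneous problem as initial guess; the
      # residual then reflects only the heterogeneity
      ai <- .axis_index(bc$axis)
      eps <- bc$magnitude
      guess <- matrix(0, mesh$n_nodes, 3)
      guess[, ai] <- eps * mesh$coords[, ai] * h_m
      for (s in setdiff(1:3, ai)) {
        ref <- if (c("x", "y", "z")[s] %in% symmetry) grid$dims[s] else 0
        guess[, s] <- -mat$nu * eps * (mesh$coords[, s] - ref) * h_m
      }
      u0 <- as.numeric(t(guess))
    }
    sol <- vf_pcg(mesh$elem, Ke, mesh$n_nodes, con$fixed, con$uval, fext,
                  tol, maxit, u0)
  }
  u <- matrix(sol$u, ncol = 3, byrow = TRUE)
  resid_force <- sol$Ku - fext
  reactions <- matrix(ifelse(con$fixed, resid_force, 0), ncol = 3, byrow = TRUE)
  structure(list(
    coords_um = mesh$coords * grid$h_um,
    displacements = u,
    reactions = reactions,
    iterations = sol$iterations,
    relres = sol$relres,
    energy = 0.5 * sum(sol$u * sol$Ku),
    on_A = con$on_A, on_B = con$on_B,
    span_m = con$span_m, delta_m = con$delta,
    bc = bc, material = mat,
    h_um = grid$h_um, dims = grid$dims,
    n_nodes = mesh$n_nodes,
    n_elements = nrow(mesh$elem),
    n_dropped_voxels = fp$n_dropped,
    solver = if (use_direct) "direct" else "cg"
  ), class = "field_solution")
}

.solve_direct <- function(mesh, Ke, con, fext) {
  tp <- vf_triplets(mesh$elem, Ke)
  ndof <- 3L * mesh$n_nodes
  K <- Matrix::sparseMatrix(i = tp$i, j = tp$j, x = tp$x, dims = c(ndof, ndof))
  free <- !con$fixed
  u <- con$uval
  rhs <- fext[free] - as.numeric(K[free, !free, drop = FALSE] %*% con$uval[!free])
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  u[free] <- as.numeric(Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE), rhs))
  Ku <- as.numeric(K %*% u)
  list(u = u, Ku = Ku, iterations = 0L, relres = 0)
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf(
    "<field_solution> %d nodes, %d elements | %s on %s axis | %s solve, %d iter, relres %.2g\n",
    x$n_nodes, x$n_elements, x$bc$mode, x$bc$axis, x$solver,
    x$iterations, x$relres))
  invisible(x)
}

# Global equilibrium check helper: axial reaction sums on the two faces.
face_reaction_sums <- function(sol) {
  ai <- .axis_index(sol$bc$axis)
  c(A = sum(sol$reactions[sol$on_A, ai]),
    B = sum(sol$reactions[sol$on_B, ai]))
}
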