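test_that("element stiffness is symmetric, PSD, with 6 rigid-body modes", {
  K <- hex8_stiffness(40e3, 0.4, 25e-6)
  expect_equal(dim(K), c(24L, 24L))
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-9 * max(ev)
  expect_equal(sum(ev < tol), 6L)
  expect_true(all(ev > -tol))
  # any rigid translation lies in the nullspace
  for (comp in 1:3) {
    tr <- rep(0, 24); tr[seq(comp, 24, by = 3)] <- 1
    expect_lt(max(abs(K %*% tr)), 1e-9 * max(abs(K)))
  }
})

test_that("element stiffness scales linearly in E and element size", {
  K1 <- hex8_stiffness(40e3, 0.4, 25e-6)
  expect_equal(hex8_stiffness(80e3, 0.4, 25e-6), 2 * K1, tolerance = 1e-12)
  expect_equal(hex8_stiffness(40e3, 0.4, 50e-6), 2 * K1, tolerance = 1e-12)
})

test_that("2-point quadrature matches an independent 4-point quadrature", {
  K2 <- hex8_stiffness(63e3, 0.3, 10e-6, n_gauss = 2L)
  K4 <- hex8_stiffness(63e3, 0.3, 10e-6, n_gauss = 4L)
  expect_lt(max(abs(K2 - K4)) / max(abs(K2)), 1e-10)
})

test_that("meshing merges shared nodes and counts dofs correctly", {
  # one voxel: 8 nodes, 24 dofs
  m1 <- scaffoldFE:::vf_mesh(array(TRUE, c(1, 1, 1)), c(1L, 1L, 1L))
  expect_equal(m1$n_nodes, 8L)
  # two voxels sharing a face: 12 nodes, 36 dofs
  m2 <- scaffoldFE:::vf_mesh(array(TRUE, c(2, 1, 1)), c(2L, 1L, 1L))
  expect_equal(m2$n_nodes, 12L)
  expect_equal(nrow(m2$elem), 2L)
})

test_that("patch test: dense blocks of any aspect ratio reproduce the affine field", {
  for (dims in list(c(4, 4, 4), c(6, 3, 2), c(2, 5, 3))) {
    g <- dense_block_grid(dims[1], dims[2], dims[3], h_um = 25)
    sol <- solve_elasticity(g, "G5", boundary_condition(), solver = "direct")
    eps <- 0.01; nu <- 0.4; h <- 25e-6
    x <- sol$coords_um * 1e-6
    u_exact <- cbind(eps * x[, 1],
                     -nu * eps * (x[, 2] - min(x[, 2])),
                     -nu * eps * (x[, 3] - min(x[, 3])))
    scale <- max(abs(u_exact))
    expect_lt(max(abs(sol$displacements - u_exact)) / scale, 1e-8)
  }
})

test_that("global equilibrium: face reactions balance in every solve", {
  g <- voxelize(scaffold_spec(pore_um = 200, fiber_um = 100,
                              cells_per_side = 2), resolution = 2)
  for (solver in c("direct", "cg")) {
    sol <- solve_elasticity(g, "G7", boundary_condition(), solver = solver,
                            tol = 1e-10)
    rs <- scaffoldFE:::face_reaction_sums(sol)
    expect_lt(abs(rs[["A"]] + rs[["B"]]) / abs(rs[["B"]]), 1e-6)
  }
})

test_that("energy consistency: strain energy equals external work", {
  g <- voxelize(scaffold_spec(pore_um = 200, fiber_um = 100), resolution = 3)
  sol <- solve_elasticity(g, "G5", boundary_condition(), solver = "direct")
  rs <- scaffoldFE:::face_reaction_sums(sol)
  work <- 0.5 * sol$delta_m * rs[["B"]]
  expect_equal(sol$energy, work, tolerance = 1e-8)
})

test_that("solution is linear in the imposed strain", {
  g <- voxelize(scaffold_spec(pore_um = 200, fiber_um = 100), resolution = 2)
  s1 <- solve_elasticity(g, "G5", boundary_condition(magnitude = 0.01),
                         solver = "direct")
  s2 <- solve_elasticity(g, "G5", boundary_condition(magnitude = 0.02),
                         solver = "direct")
  expect_equal(s2$displacements, 2 * s1$displacements, tolerance = 1e-9)
  expect_equal(s2$reactions, 2 * s1$reactions, tolerance = 1e-9)
})

test_that("iterative solve matches the direct factorization", {
  g <- voxelize(scaffold_spec(pore_um = 200, fiber_um = 100), resolution = 3)
  sd <- solve_elasticity(g, "G14", boundary_condition(), solver = "direct")
  sc <- solve_elasticity(g, "G14", boundary_condition(), solver = "cg",
                         tol = 1e-12)
  expect_lt(3 * sd$n_nodes, 15000) # genuinely a small instance
  scale <- max(abs(sd$displacements))
  expect_lt(max(abs(sd$displacements - sc$displacements)) / scale, 1e-8)
  Ed <- effective_modulus(sd); Ec <- effective_modulus(sc)
  expect_equal(Ec, Ed, tolerance = 1e-8)
})

test_that("floating solid is dropped and does not change the solution", {
  occ <- array(FALSE, c(6, 5, 5))
  occ[, 2:3, 2:3] <- TRUE        # a beam spanning x
  occ_f <- occ
  occ_f[3, 5, 5] <- TRUE         # plus an isolated voxel
  g <- scaffoldFE:::new_voxel_grid(occ, 10)
  gf <- scaffoldFE:::new_voxel_grid(occ_f, 10)
  s <- solve_elasticity(g, "G5", boundary_condition(), solver = "direct")
  sf <- suppressMessages(
    solve_elasticity(gf, "G5", boundary_condition(), solver = "direct"))
  expect_equal(sf$n_dropped_voxels, 1)
  expect_equal(sf$n_elements, s$n_elements)
  expect_equal(effective_modulus(sf), effective_modulus(s), tolerance = 1e-12)
})

test_that("a grid with no path between the loading faces is an error", {
  occ <- array(TRUE, c(6, 4, 4))
  occ[3, , ] <- FALSE            # transverse void slab severs the path
  g <- scaffoldFE:::new_voxel_grid(occ, 10)
  expect_error(solve_elasticity(g, "G5", boundary_condition()),
               "no load path")
  # the same slab parallel to the load is fine
  occ2 <- array(TRUE, c(6, 4, 4))
  occ2[, 3, ] <- FALSE
  g2 <- scaffoldFE:::new_voxel_grid(occ2, 10)
  expect_s3_class(solve_elasticity(g2, "G5", boundary_condition(),
                                   solver = "direct"),
                  "field_solution")
})

test_that("boundary condition validation guards the linear regime", {
  expect_error(boundary_condition(magnitude = 0.1), "linear regime")
  expect_error(boundary_condition(magnitude = -0.01), "positive")
  expect_s3_class(boundary_condition(mode = "pressure_control",
                                     magnitude = 1e3), "boundary_condition")
})

test_that("symmetry-reduced solve reproduces the full-domain modulus", {
  sp <- scaffold_spec(pore_um = 200, fiber_um = 100, cells_per_side = 2,
                      layers = 2, material = "G5")
  f_full <- scaffold_stiffness(sp, resolution = 2, use_symmetry = FALSE,
                               solver = "direct")
  f_red <- scaffold_stiffness(sp, resolution = 2, use_symmetry = TRUE,
                              solver = "direct")
  expect_true(f_red$diagnostics[[1]]$reduced)
  expect_lt(f_red$diagnostics[[1]]$n_elements,
            f_full$diagnostics[[1]]$n_elements)
  expect_equal(f_red$E_eff_Pa[[1]], f_full$E_eff_Pa[[1]], tolerance = 1e-9)
})

test_that("fully-clamped support stiffens a short dense block beyond E_o", {
  g <- dense_block_grid(6, h_um = 25)
  bc <- boundary_condition(dialect = "fixed_face")
  f <- scaffold_stiffness(g, material = "G5", bc = bc)
  expect_gt(f$E_eff_kPa[[1]], 40)   # Poisson confinement, nu = 0.4
  expect_lt(f$E_eff_kPa[[1]], 60)
})

test_that("pressure control on a dense block recovers E_o under rollers", {
  bc <- boundary_condition(mode = "pressure_control", magnitude = 400)
  f <- scaffold_stiffness(dense_block_grid(4, h_um = 25), material = "G5",
                          bc = bc)
  expect_equal(f$E_eff_kPa[[1]], 40, tolerance = 1e-9)
})
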