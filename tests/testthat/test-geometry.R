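# Independent voxel-counting porosity oracle for the channel cell:
# classifies sample-point coordinates directly from the geometric
# definition (a point is void iff it lies inside one of the three
# orthogonal square channels, i.e. at least two of its coordinates fall in
# the pore window), without touching the package's geometry code. The
# count over the full 3-D lattice is aggregated combinatorially from the
# per-axis membership count a: void points = a^2 (3 nvox - 2 a).
porosity_by_counting <- function(p, d, nvox = 20001) {
  L <- p + 2 * d
  xc <- (seq_len(nvox) - 0.5) / nvox * L
  a <- sum(xc > d & xc < d + p)
  a^2 * (3 * nvox - 2 * a) / nvox^3
}

test_that("closed-form porosity matches a voxel-counting oracle", {
  # channel cell: oracle counts void voxel centers
  expect_equal(porosity_by_counting(200, 100), 0.5, tolerance = 1e-3)
  expect_equal(closed_form_porosity(unit_cell(200, 100)), 0.5)
  for (pd in list(c(150, 60), c(300, 40), c(100, 100))) {
    expect_equal(closed_form_porosity(unit_cell(pd[1], pd[2])),
                 porosity_by_counting(pd[1], pd[2]),
                 tolerance = 1e-3)
  }
})

test_that("porosity limits behave as the geometry dictates", {
  # d -> 0: the cell becomes all channel
  expect_gt(closed_form_porosity(unit_cell(200, 1e-6)), 1 - 1e-6)
  # p -> 0: no void remains
  expect_lt(closed_form_porosity(unit_cell(1e-6, 100)), 1e-6)
  # strut frame mirrors: d -> 0 leaves nothing solid
  expect_gt(closed_form_porosity(unit_cell(200, 1e-6, "strut_frame")),
            1 - 1e-4)
})

test_that("cell side length is pore plus twice the fiber width", {
  uc <- unit_cell(200, 80)
  expect_equal(uc$L_um, 360)
  expect_error(unit_cell(-1, 80), "positive")
  expect_error(unit_cell(200, 0), "positive")
})

test_that("porosity is strictly monotone in d (down) and p (up)", {
  ps <- seq(50, 500, length.out = 20)
  ds <- seq(10, 200, length.out = 20)
  for (dialect in c("channel_cell", "strut_frame")) {
    for (p in ps) {
      phi <- vapply(ds, function(d)
        closed_form_porosity(unit_cell(p, d, dialect)), 0)
      expect_true(all(diff(phi) < 0), info = sprintf("%s p=%g", dialect, p))
    }
    for (d in ds) {
      phi <- vapply(ps, function(p)
        closed_form_porosity(unit_cell(p, d, dialect)), 0)
      expect_true(all(diff(phi) > 0), info = sprintf("%s d=%g", dialect, d))
    }
  }
})

test_that("porosity inversions recover the closed form and round-trip", {
  expect_equal(solve_fiber_width(200, 0.5), 100, tolerance = 1e-9)
  expect_equal(solve_pore_side(100, 0.5), 200, tolerance = 1e-9)
  for (dialect in c("channel_cell", "strut_frame")) {
    for (phi in c(0.11, 0.3, 0.5, 0.7, 0.9, 0.97)) {
      d <- solve_fiber_width(200, phi, dialect)
      expect_equal(closed_form_porosity(unit_cell(200, d, dialect)), phi,
                   tolerance = 1e-9)
      p <- solve_pore_side(80, phi, dialect)
      expect_equal(closed_form_porosity(unit_cell(p, 80, dialect)), phi,
                   tolerance = 1e-9)
    }
  }
  expect_error(solve_fiber_width(200, 1.2), "infeasible")
  expect_error(solve_pore_side(100, 0), "infeasible")
  expect_error(solve_fiber_width(-5, 0.5), "positive")
})

test_that("scaffold_spec requires exactly two of p, d, porosity", {
  s <- scaffold_spec(pore_um = 200, porosity = 0.5, material = "G5")
  expect_equal(s$cell$d_um, 100, tolerance = 1e-8)
  s2 <- scaffold_spec(fiber_um = 100, porosity = 0.5, material = "G5")
  expect_equal(s2$cell$p_um, 200, tolerance = 1e-8)
  expect_error(scaffold_spec(pore_um = 200, material = "G5"), "exactly two")
  expect_error(scaffold_spec(pore_um = 200, fiber_um = 100, porosity = 0.5),
               "exactly two")
})

test_that("voxelization tiles cells at pitch L and measures porosity exactly", {
  g <- voxelize(scaffold_spec(pore_um = 200, fiber_um = 100), resolution = 4)
  expect_equal(g$dims, c(16L, 16L, 16L))
  expect_equal(measured_porosity(g), 0.5, tolerance = 1e-12)
  # multi-cell tiling multiplies dims
  g2 <- voxelize(scaffold_spec(pore_um = 200, fiber_um = 100,
                               cells_per_side = 3, layers = 2),
                 resolution = 2)
  expect_equal(g2$dims, c(24L, 24L, 16L))
  expect_equal(measured_porosity(g2), 0.5, tolerance = 1e-12)
})

test_that("measured porosity approaches the closed form as voxels shrink", {
  # a geometry whose pore does not fall on voxel boundaries at low res
  sp <- scaffold_spec(pore_um = 190, fiber_um = 60, material = "G5")
  phi_exact <- closed_form_porosity(sp$cell)
  errs <- vapply(c(4L, 8L, 16L), function(r) {
    g <- suppressWarnings(voxelize(sp, r))
    abs(measured_porosity(g) - phi_exact)
  }, 0)
  expect_lt(errs[1], 0.02)
  expect_lt(errs[2], 0.005)
  expect_true(all(diff(errs) <= 1e-12))
  # the grid porosity equals the closed form of the snapped geometry exactly
  g4 <- suppressWarnings(voxelize(sp, 4L))
  p_snap <- round(190 / (60 / 4)) * (60 / 4)
  expect_equal(measured_porosity(g4),
               closed_form_porosity(unit_cell(p_snap, 60)), tolerance = 1e-12)
})

test_that("voxel pattern is invariant under uniform length rescaling", {
  g1 <- voxelize(scaffold_spec(pore_um = 200, fiber_um = 80), resolution = 4)
  g2 <- voxelize(scaffold_spec(pore_um = 2000, fiber_um = 800), resolution = 4)
  expect_identical(g1$occ, g2$occ)
  expect_equal(measured_porosity(g1), measured_porosity(g2))
})

test_that("strut-frame dialect voxelizes to its closed-form porosity", {
  sp <- scaffold_spec(pore_um = 200, fiber_um = 100, material = "G5",
                      dialect = "strut_frame")
  g <- voxelize(sp, 4)
  expect_equal(measured_porosity(g), closed_form_porosity(sp$cell),
               tolerance = 1e-12)
})

test_that("degenerate grids are rejected", {
  expect_error(voxelize(scaffold_spec(pore_um = 200, fiber_um = 100),
                        resolution = 1), "resolution")
  expect_error(scaffoldFE:::new_voxel_grid(array(FALSE, c(2, 2, 2)), 1),
               "no solid")
})
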