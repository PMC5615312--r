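# Analytic fixtures: geometries whose effective modulus has a closed form
# (dense block, aligned struts / rule of mixtures, Voigt slabs), used to
# verify the finite-element pipeline without any external reference data.
# Every expected value is computed here from its closed form; the solver
# under test never feeds back its own output as an expectation.

new_fixture <- function(name, grid, material, expected_Pa, tolerance) {
  structure(list(name = name, grid = grid, material = get_material(material),
                 expected_Pa = expected_Pa, tolerance = tolerance),
            class = "analytic_fixture")
}

#' @export
print.analytic_fixture <- function(x, ...) {
  cat(sprintf("<analytic_fixture %s> expected %s (tol %.2g rel)\n",
              x$name, format_pressure(x$expected_Pa), x$tolerance))
  invisible(x)
}

#' Dense-block fixture
#'
#' A fully solid cube. Under roller-supported uniaxial displacement control
#' the homogenized modulus equals the bulk modulus exactly (uniform-strain
#' patch solution), at any resolution.
#'
#' @param material Material name or object.
#' @param n Voxels per side (>= 2).
#' @param h_um Voxel size (um).
#' @return An `"analytic_fixture"`.
#' @export
dense_block <- function(material, n = 4L, h_um = 25) {
  stopifnot(n >= 2L)
  mat <- get_material(material)
  new_fixture(sprintf("dense_block_%s_n%d", mat$name, n),
              dense_block_grid(n, h_um = h_um), mat,
              expected_Pa = mat$E, tolerance = 1e-9)
}

#' Aligned-strut fixture (rule of mixtures)
#'
#' `k` square prismatic struts spanning the loading axis (x) with no
#' transverse members: parallel springs, so the expected modulus is the
#' bulk modulus times the load-aligned solid area fraction.
#'
#' @param material Material.
#' @param k Number of struts (1..4).
#' @param strut_vox Strut cross-section side, in voxels.
#' @param section_vox Gross cross-section side, in voxels.
#' @param length_vox Strut length in voxels.
#' @param h_um Voxel size (um).
#' @return An `"analytic_fixture"`; expected modulus
#'   `E_o * k * strut_vox^2 / section_vox^2`, tolerance 2%.
#' @export
aligned_struts <- function(material, k = 4L, strut_vox = 2L,
                           section_vox = 8L, length_vox = 8L, h_um = 25) {
  stopifnot(k >= 1L, k <= 4L, strut_vox >= 1L,
            2L * strut_vox <= section_vox)
  mat <- get_material(material)
  occ <- array(FALSE, dim = c(length_vox, section_vox, section_vox))
  # strut anchor corners in the y-z section: the four section corners
  anchors <- list(c(1L, 1L), c(section_vox - strut_vox + 1L, 1L),
                  c(1L, section_vox - strut_vox + 1L),
                  c(section_vox - strut_vox + 1L, section_vox - strut_vox + 1L))
  for (s in seq_len(k)) {
    a <- anchors[[s]]
    occ[, a[1]:(a[1] + strut_vox - 1L), a[2]:(a[2] + strut_vox - 1L)] <- TRUE
  }
  frac <- k * strut_vox^2 / section_vox^2
  new_fixture(sprintf("aligned_struts_%s_k%d", mat$name, k),
              new_voxel_grid(occ, h_um), mat,
              expected_Pa = mat$E * frac, tolerance = 0.02)
}

#' Voigt slab fixture
#'
#' Alternating solid/void slabs. Slabs parallel to the load act as parallel
#' springs (expected modulus `E_o * solid_fraction`, the Voigt closed
#' form); slabs transverse to the load leave no solid path between the
#' loading faces, which must raise the no-load-path error rather than
#' return a modulus.
#'
#' @param material Material.
#' @param solid_vox,void_vox Slab thicknesses in voxels per period.
#' @param periods Number of solid/void periods.
#' @param n_vox Extent of the other two axes, voxels.
#' @param orientation `"parallel"` (slabs normal to y, load along x) or
#'   `"transverse"` (slabs normal to x, load along x).
#' @param h_um Voxel size (um).
#' @return An `"analytic_fixture"`; for `"transverse"` the `expected_Pa` is
#'   `NA` and the fixture's expectation is the connectivity error.
#' @export
voigt_reuss_slabs <- function(material, solid_vox = 2L, void_vox = 2L,
                              periods = 2L, n_vox = 8L,
                              orientation = c("parallel", "transverse"),
                              h_um = 25) {
  orientation <- match.arg(orientation)
  mat <- get_material(material)
  period <- solid_vox + void_vox
  extent <- period * periods
  pattern <- rep(rep(c(TRUE, FALSE), times = c(solid_vox, void_vox)), periods)
  s <- solid_vox / period
  if (orientation == "parallel") {
    # slabs normal to y, each spanning the full x (loading) axis
    occ <- array(FALSE, dim = c(n_vox, extent, n_vox))
    occ[, pattern, ] <- TRUE
    expected <- mat$E * s
  } else {
    # slabs normal to x: any void slab severs the load path
    occ <- array(FALSE, dim = c(extent, n_vox, n_vox))
    occ[pattern, , ] <- TRUE
    expected <- NA_real_
  }
  new_fixture(sprintf("voigt_slabs_%s_%s", mat$name, orientation),
              new_voxel_grid(occ, h_um), mat,
              expected_Pa = expected, tolerance = 0.02)
}

#' Evaluate a fixture against the solver
#'
#' Runs the roller-supported displacement-control homogenization on the
#' fixture's grid and compares with its closed-form expectation.
#'
#' @param fx An `"analytic_fixture"`.
#' @param ... Passed to [scaffold_stiffness()].
#' @return A one-row data.frame: `name`, `expected_kPa`, `measured_kPa`,
#'   `rel_error`, `pass`.
#' @export
check_fixture <- function(fx, ...) {
  stopifnot(inherits(fx, "analytic_fixture"))
  if (is.na(fx$expected_Pa)) {
    err <- tryCatch({
      scaffold_stiffness(fx$grid, material = fx$material, ...)
      NA_character_
    }, error = function(e) conditionMessage(e))
    pass <- !is.na(err) && grepl("no load path", err)
    return(data.frame(name = fx$name, expected_kPa = NA_real_,
                      measured_kPa = NA_real_, rel_error = NA_real_,
                      pass = pass))
  }
  fit <- scaffold_stiffness(fx$grid, material = fx$material, ...)
  E <- fit$E_eff_Pa[[1]]
  rel <- abs(E - fx$expected_Pa) / fx$expected_Pa
  data.frame(name = fx$name, expected_kPa = fx$expected_Pa / 1e3,
             measured_kPa = E / 1e3, rel_error = rel,
             pass = rel <= fx$tolerance)
}

#' Built-in verification suite
#'
#' Runs the full analytic-fixture suite (dense blocks for all built-in
#' materials, aligned struts, Voigt slabs both orientations) and returns a
#' pass/fail table. Designed to complete in well under two minutes on one
#' CPU.
#'
#' @param ... Passed to [check_fixture()].
#' @return Data.frame of fixture results.
#' @export
run_selftest <- function(...) {
  fixtures <- c(
    lapply(names(builtin_materials()), dense_block),
    list(aligned_struts("G5", k = 4L),
         aligned_struts("G5", k = 1L, strut_vox = 3L, section_vox = 6L),
         voigt_reuss_slabs("G7", orientation = "parallel"),
         voigt_reuss_slabs("G7", orientation = "transverse"))
  )
  out <- do.call(rbind, lapply(fixtures, check_fixture, ...))
  rownames(out) <- NULL
  out
}
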