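test_that("presets reproduce the published study designs", {
  fw <- sweep_preset("fiber_width")
  expect_equal(sort(unique(fw$design$fiber_um)), seq(50, 100, by = 10))
  expect_true(all(fw$design$pore_um == 200))
  expect_true(all(fw$design$n == 4L & fw$design$m == 1L))
  expect_equal(fw$materials, c("G5", "G7", "G14"))

  po <- sweep_preset("porosity")
  expect_equal(sort(unique(po$design$porosity)), seq(0.3, 0.9, by = 0.1))
  expect_true(all(po$design$fiber_um == 100))

  cl <- sweep_preset("cells_per_layer")
  expect_equal(sort(cl$design$n^2), c(1, 4, 16, 36, 64, 100))
  expect_true(all(cl$design$pore_um == 200 & cl$design$fiber_um == 80))

  ly <- sweep_preset("layers")
  expect_equal(sort(unique(ly$design$porosity)), c(0.7, 0.9, 0.95))
  expect_equal(sort(unique(ly$design$m)), c(1, 5, 10, 20, 30))

  mt <- sweep_preset("material")
  expect_equal(sort(unique(mt$design$porosity)), c(0.7, 0.8, 0.9))
  expect_equal(mt$materials, c("chitosan", "PCL"))

  expect_error(sweep_preset("unknown"), "should be one of")
})

test_that("layer override restricts the layers/material designs only", {
  mt <- sweep_preset("material", layers = c(1, 5))
  expect_equal(sort(unique(mt$design$m)), c(1, 5))
  expect_error(sweep_preset("fiber_width", layers = 1), "override")
})

test_that("run_sweep is deterministic and flags failed rows", {
  sp <- sweep_preset("fiber_width", resolution = 2)
  sp$design <- sp$design[sp$design$fiber_um %in% c(50, 100), , drop = FALSE]
  sw1 <- run_sweep(sp)
  sw2 <- run_sweep(sp)
  expect_identical(sw1$rows, sw2$rows)
  expect_true(all(is.na(sw1$rows$error)))
  # an infeasible design point is flagged, not dropped, and the rest survive
  bad <- sp
  bad$design <- rbind(bad$design,
                      data.frame(pore_um = 1, fiber_um = 100,
                                 porosity = NA_real_, n = 4L, m = 1L))
  swb <- run_sweep(bad)
  expect_equal(nrow(swb$rows), nrow(sw1$rows) + length(sp$materials))
  failed <- swb$rows[!is.na(swb$rows$error), ]
  expect_equal(unique(failed$pore_um), 1)
  expect_true(all(is.na(failed$E_eff_kPa)))
})

test_that("rescaled materials in a sweep match independent direct solves", {
  sp <- sweep_preset("fiber_width", resolution = 2)
  sp$design <- sp$design[sp$design$fiber_um == 100, , drop = FALSE]
  sw <- run_sweep(sp)
  # G7 and G14 rows come from rescaling the shared-nu reference solve;
  # check them against their own full solves
  for (m in c("G7", "G14")) {
    direct <- scaffold_stiffness(
      scaffold_spec(pore_um = 200, fiber_um = 100, cells_per_side = 4,
                    material = m),
      resolution = 2)$E_eff_kPa[[1]]
    expect_equal(sw$rows$E_eff_kPa[sw$rows$material == m], direct,
                 tolerance = 1e-6, info = m)
  }
})

test_that("stiffness rises with fiber width and falls with porosity", {
  sp <- sweep_preset("fiber_width", resolution = 2)
  sw <- run_sweep(sp)
  for (m in c("G5", "G7", "G14")) {
    E <- sw$rows$E_eff_kPa[sw$rows$material == m]
    expect_true(all(diff(E) > 0), info = m)
  }
  po <- sweep_preset("porosity", resolution = 2)
  swp <- suppressWarnings(run_sweep(po))
  for (m in c("G5", "G7", "G14")) {
    E <- swp$rows$E_eff_kPa[swp$rows$material == m]
    expect_true(all(diff(E) < 0), info = m)
  }
})

test_that("guideline report maps bands, spread and the thickness flag", {
  sp <- sweep_preset("material", layers = c(1, 5), resolution = 2)
  sw <- run_sweep(sp)
  rep <- guideline_report(sw)
  chit <- rep$by_lineage[rep$by_lineage$material == "chitosan", ]
  expect_true(all(chit$lineage %in% c("neurogenic", "indeterminate")))
  expect_true(all(chit$E_eff_kPa < 1))
  pcl <- rep$by_lineage[rep$by_lineage$material == "PCL", ]
  expect_true(all(pcl$lineage == "osteogenic"))
  # thickness flag: 1 layer of L ~ 250-314 um is unflagged, 5 layers exceed
  # the 500 um hypoxia threshold
  expect_true(all(!rep$by_lineage$hypoxia_flag[rep$by_lineage$layers == 1]))
  expect_true(all(rep$by_lineage$hypoxia_flag[rep$by_lineage$layers == 5]))
  # minimum-layer table exists and is consistent
  expect_false(is.null(rep$min_layers))
  osteo <- rep$min_layers[rep$min_layers$material == "PCL" &
                          rep$min_layers$lineage == "osteogenic", ]
  expect_true(all(osteo$min_layers == 1))
  # the stiffness-vs-layers trend is already flat (< 5% change) by 5 layers
  expect_false(is.null(rep$layer_asymptote))
  expect_true(all(rep$layer_asymptote$layers_at_asymptote == 5))
})

test_that("relative spread summarizes design-parameter sensitivity", {
  expect_equal(relative_spread(c(1, 1, 1)), 0)
  expect_equal(relative_spread(c(9, 10, 11)), 0.2)
  expect_true(is.na(relative_spread(numeric(0))))
})
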