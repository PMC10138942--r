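test_that("simulation is deterministic under a fixed seed", {
  cfg <- pmc_preset("cepa_like", seed = 11)
  a <- simulate_chiasmata(cfg)
  b <- simulate_chiasmata(cfg)
  expect_identical(a, b)
  expect_identical(simulate_foci(cfg), simulate_foci(cfg))

  # different seeds diverge
  other <- simulate_chiasmata(pmc_preset("cepa_like", seed = 12))
  expect_false(identical(a$chiasmata$rel_pos, other$chiasmata$rel_pos))
})

test_that("obligate crossover: no chiasma-free bivalents when univalent rate is 0", {
  cfg <- simulation_config("S", n_cells = 50, chiasma_mean = 1.2,
                           univalent_rate = 0, seed = 4)
  sim <- simulate_chiasmata(cfg)
  expect_equal(min(sim$bivalents$chiasma_count), 1)
  expect_false(any(sim$bivalents$is_univalent_pair))

  # with a univalent rate, achiasmate pairs appear and are flagged
  cfg_u <- simulation_config("S", n_cells = 100, chiasma_mean = 1.2,
                             univalent_rate = 0.3, seed = 4)
  sim_u <- simulate_chiasmata(cfg_u)
  expect_true(any(sim_u$bivalents$is_univalent_pair))
  expect_true(all(sim_u$bivalents$chiasma_count[
    sim_u$bivalents$is_univalent_pair] == 0))
})

test_that("uniform Beta positions give region proportions of one third each", {
  cfg <- simulation_config("S", n_cells = 500, n_bivalents_per_cell = 8,
                           chiasma_mean = 25, position_alpha = 1,
                           position_beta = 1, seed = 6)
  sim <- simulate_chiasmata(cfg)
  expect_gt(nrow(sim$chiasmata), 1e5)
  prop <- table(classify_position(sim$chiasmata$rel_pos)) /
    nrow(sim$chiasmata)
  expect_true(all(abs(prop - 1 / 3) < 0.01))
})

test_that("focus counts hit the configured Poisson means on separate slides", {
  cfg <- simulation_config("S", n_cells = 10, chiasma_mean = 2,
                           foci_lambda_mlh1 = 11.05,
                           foci_lambda_mus81 = 4.05,
                           n_cells_foci_per_marker = 10000, seed = 21)
  foci <- simulate_foci(cfg)
  mlh1 <- foci$count[foci$marker == "MLH1"]
  mus81 <- foci$count[foci$marker == "MUS81"]
  # 3 sigma Monte Carlo band: sd/sqrt(n) ~ 0.033
  expect_lt(abs(mean(mlh1) - 11.05), 0.1)
  expect_lt(abs(mean(mus81) - 4.05), 0.1)
  expect_equal(unique(foci$slide_id[foci$marker == "MLH1"]), "slide_MLH1")
  expect_equal(unique(foci$slide_id[foci$marker == "MUS81"]), "slide_MUS81")

  zero <- simulation_config("S", n_cells = 10, chiasma_mean = 2,
                            foci_lambda_mlh1 = 0, foci_lambda_mus81 = 0,
                            n_cells_foci_per_marker = 50, seed = 1)
  expect_true(all(simulate_foci(zero)$count == 0))
})

test_that("interference constraint separates same-arm chiasmata or flags", {
  cfg <- simulation_config("S", n_cells = 150, chiasma_mean = 2.5,
                           interference_min_distance = 0.1, seed = 13)
  sim <- simulate_chiasmata(cfg)
  flagged_key <- with(sim$bivalents[grepl("interference-flagged",
                                          sim$bivalents$subtype), ],
                      paste(cell_id, bivalent_id))
  chi <- sim$chiasmata
  key <- paste(chi$cell_id, chi$bivalent_id, chi$arm_id)
  min_sep <- tapply(chi$rel_pos, key, function(p)
    if (length(p) < 2) Inf else min(diff(sort(p))))
  biv_key <- sub(" [12]$", "", names(min_sep))
  unflagged <- !(biv_key %in% flagged_key)
  expect_true(all(min_sep[unflagged] >= 0.1))

  # impossible constraint is a configuration error
  impossible <- simulation_config("S", n_cells = 5, chiasma_mean = 12,
                                  interference_min_distance = 0.45,
                                  seed = 1)
  expect_error(simulate_chiasmata(impossible),
               class = "chiasmetry_config_error")
})

test_that("Beta calibration recovers targets and respects reflection symmetry", {
  # uniform solution
  shp <- calibrate_beta(c(1, 1, 1) / 3)
  expect_equal(unname(shp), c(1, 1), tolerance = 0.02)

  # distal-heavy target triple reproduces analytic proportions to 0.01
  target <- c(18, 207, 808) / 1033
  shp <- calibrate_beta(target)
  p <- region_proportions(list(position_alpha = shp[["alpha"]],
                               position_beta = shp[["beta"]]))
  expect_true(all(abs(p - target) < 0.01))

  # reversed targets swap the shape parameters
  rev_shp <- calibrate_beta(rev(target))
  expect_equal(rev_shp[["alpha"]], shp[["beta"]], tolerance = 1e-3)
  expect_equal(rev_shp[["beta"]], shp[["alpha"]], tolerance = 1e-3)

  expect_error(calibrate_beta(c(0, 0.5, 0.5)),
               class = "chiasmetry_config_error")
})

test_that("preset analytic proportions match the reference percentage triples", {
  cc <- allium_chiasma_counts()
  presets <- c(cepa_like = "cepa", fistulosum_like = "fistulosum",
               diploid_hybrid_like = "f1_diploid",
               triploid_hybrid_like = "f1_triploid")
  for (nm in names(presets)) {
    cfg <- pmc_preset(nm)
    row <- cc[cc$sample_id == presets[[nm]], ]
    total <- row$n_proximal + row$n_interstitial + row$n_distal
    target <- c(row$n_proximal, row$n_interstitial, row$n_distal) / total
    expect_true(all(abs(region_proportions(cfg) - target) < 0.05),
                info = nm)
  }
})

test_that("end-to-end parameter recovery at 200 cells", {
  fist <- pmc_preset("fistulosum_like", seed = 17)
  fist$n_cells <- 200L
  sim <- simulate_chiasmata(fist)
  s <- summarize_chiasmata(sim$chiasmata, sim$bivalents)
  analytic <- region_proportions(fist)[["proximal"]] * 100
  expect_lt(abs(s$pct_proximal - analytic), 3)

  cepa <- pmc_preset("cepa_like", seed = 18)
  cepa$n_cells <- 200L
  sim2 <- simulate_chiasmata(cepa)
  both <- summarize_chiasmata(rbind(sim$chiasmata, sim2$chiasmata),
                              rbind(sim$bivalents, sim2$bivalents))
  v <- chi_square(region_contingency(both))$cramers_v
  expect_gt(v, 0.8)
})
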