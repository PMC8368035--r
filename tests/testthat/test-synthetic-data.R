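test_that("noiseless vehicle decay follows the first-order law", {
  p <- one_well_plate(seed = 1, noise_cv = 0)
  r <- well_series(p, "A01", "red")
  # half-life 7.5 h forces normalized red 0.5 at t = 7.5
  expect_equal(normalized_red(r, 7.5), 0.5, tolerance = 1e-10)
  expect_equal(normalized_red(r, 0), 1.0, tolerance = 1e-12)
  # tripling k cubes the normalized survival fraction at any fixed time
  p3 <- one_well_plate(seed = 1, noise_cv = 0, flux_multiplier = 3)
  r3 <- well_series(p3, "A01", "red")
  for (t in c(1.5, 6, 12))
    expect_equal(normalized_red(r3, t), normalized_red(r, t)^3,
                 tolerance = 1e-9)
})

test_that("no photoconversion means the red channel stays at background", {
  p <- one_well_plate(seed = 2, noise_cv = 0, phi = 0)
  r <- well_series(p, "A01", "red")
  expect_true(all(abs(r$intensity - r$intensity[1]) < 1e-9))
  expect_error(normalized_red(r, 9), "failed conversion")
})

test_that("conversion is conserved: red jump equals yield times green drop", {
  for (phi in c(0.2, 0.4, 0.8)) {
    for (mult in c(0.5, 1, 3)) {
      p <- one_well_plate(seed = 3, noise_cv = 0, phi = phi,
                          flux_multiplier = mult, yield = 2.5)
      r <- well_series(p, "A01", "red")
      g <- well_series(p, "A01", "green")
      red_jump <- r$intensity[r$time_h == 0] - r$intensity[r$time_h < 0]
      green_drop <- g$intensity[g$time_h < 0] - g$intensity[g$time_h == 0]
      expect_equal(red_jump, 2.5 * green_drop, tolerance = 1e-9)
    }
  }
})

test_that("green signal dips 40% and returns to within 5% by 13.5 h", {
  p <- one_well_plate(seed = 4, noise_cv = 0)
  g <- well_series(p, "A01", "green")
  pre <- g$intensity[g$time_h < 0]
  expect_equal(g$intensity[g$time_h == 0] / pre, 0.6, tolerance = 1e-9)
  # the vehicle k_green is calibrated to land exactly on the 95% point
  expect_gte(g$intensity[g$time_h == 13.5] / pre, 0.95 - 1e-9)
})

test_that("normalized red decreases in k; green ratio increases as k falls", {
  mults <- c(0.25, 0.5, 1, 2, 4)
  red9 <- vapply(mults, function(m) {
    p <- one_well_plate(seed = 5, noise_cv = 0, flux_multiplier = m)
    normalized_red(well_series(p, "A01", "red"), 9)
  }, numeric(1))
  expect_true(all(diff(red9) < 0))
  gfp15 <- vapply(mults, function(m) {
    p <- one_well_plate(seed = 5, noise_cv = 0, flux_multiplier = m,
                        schedule = opl_schedule(-0.5, c(0, 7.5, 15)))
    gfp_flux_ratio(well_series(p, "A01", "green"), 0, 15)
  }, numeric(1))
  expect_true(all(diff(gfp15) < 0))  # smaller k (first) -> larger ratio
})

test_that("plate generation is bit-reproducible for a fixed seed", {
  lay <- layout_90_10()
  a <- generate_plate(lay, seed = 11)
  b <- generate_plate(lay, seed = 11)
  expect_identical(a$timeseries, b$timeseries)
  c <- generate_plate(lay, seed = 12)
  expect_false(identical(a$timeseries$intensity, c$timeseries$intensity))
})

test_that("invalid schedules and parameters are rejected", {
  expect_error(opl_schedule(0.5), "preconversion")
  expect_error(opl_schedule(-0.5, c(1.5, 3)), "t = 0")
  expect_error(opl_schedule(-0.5, c(0, 1.5)), "two post-conversion")
  expect_error(one_well_plate(seed = 1, half_life_h = -2), "positive")
  expect_error(one_well_plate(seed = 1, phi = 1.5), "phi")
  expect_error(one_well_plate(seed = 1, noise_cv = -0.1), "noise_cv")
  expect_error(generate_plate(layout_90_10()), "seed")
})

test_that("toxic wells lose cell area and intensity after onset", {
  p <- one_well_plate(seed = 6, noise_cv = 0, toxic = TRUE,
                      toxicity_onset_h = 5, toxicity_ramp_h = 5,
                      toxicity_floor = 0.4)
  g <- well_series(p, "A01", "green")
  pre_area <- g$cell_area_fraction[g$time_h == 0]
  late_area <- g$cell_area_fraction[g$time_h == 13.5]
  expect_equal(late_area / pre_area, 0.4, tolerance = 1e-9)
})

test_that("dilution series follows the 4PL in dose and resolves 2 nM steps", {
  doses <- 10^seq(-9, -7, length.out = 8)
  hp <- list(ec50 = 1e-8, slope = 1, bottom = 1, top = 3)
  ds <- generate_dilution_series("vehicle", doses, hp, seed = 21,
                                 n_replicates = 2)
  tr <- unique(ds$truth[c("compound_id", "flux_multiplier", "concentration_M")])
  tr <- tr[order(tr$concentration_M), ]
  expect_true(all(diff(tr$flux_multiplier) > 0))       # monotone in dose
  # midpoint: multiplier halfway between plateaus at dose = ec50
  mid <- hill_response(1e-8, 1, 3, 1e-8, 1)
  expect_equal(mid, 2)
  expect_equal(tr$flux_multiplier[which.min(abs(tr$concentration_M - 1e-8))],
               2, tolerance = 0.1)
  # low-dose plateau
  expect_equal(hill_response(1e-12, 1, 3, 1e-8, 1), 1, tolerance = 1e-3)
  expect_error(generate_dilution_series("vehicle", c(-1, 1e-8, 1e-7, 1e-6),
                                        hp, seed = 1), "positive")
  expect_error(generate_dilution_series("vehicle", c(1e-8, 2e-8, 3e-8, 4e-8),
                                        hp, seed = 1), "2 log units")

  # a bafilomycin-like series distinguishes doses 2 nM apart near the IC50
  hp_baf <- list(ec50 = 1e-8, slope = -2, bottom = 0.02, top = 1)
  ds2 <- generate_dilution_series("vehicle", c(9e-9, 1.1e-8, 1e-10, 1e-6),
                                  hp_baf, seed = 22, n_replicates = 8)
  fm <- flux_metrics(ds2, fit_half_lives = FALSE)
  fm$dose <- ds2$truth$concentration_M[match(fm$well, ds2$truth$well)]
  lo <- fm$red_ratio_9h[abs(fm$dose - 9e-9) < 1e-12]
  hi <- fm$red_ratio_9h[abs(fm$dose - 1.1e-8) < 1e-12]
  expect_lt(t.test(lo, hi)$p.value, 0.05)
})

test_that("synthetic fields plant the requested colocalization exactly", {
  cfg <- field_config(n_cells = 6L, n_red_puncta = 10L, n_green_extra = 5L)
  f1 <- generate_images(cfg, planted_colocalization = 1, seed = 31)
  red <- f1$puncta[f1$puncta$channel == "red", ]
  expect_true(all(red$colocalized))
  f0 <- generate_images(cfg, planted_colocalization = 0, seed = 31)
  expect_false(any(f0$puncta$colocalized[f0$puncta$channel == "red"]))
  f7 <- generate_images(cfg, planted_colocalization = 0.7, seed = 31)
  expect_identical(sum(f7$puncta$colocalized[f7$puncta$channel == "red"]), 7L)
  expect_error(generate_images(cfg, planted_colocalization = 1.2, seed = 1),
               "planted_colocalization")
  expect_identical(generate_images(cfg, 0.5, seed = 5)$red,
                   generate_images(cfg, 0.5, seed = 5)$red)
})

test_that("neuron generator reproduces its configured population moments", {
  nt <- generate_neuron_tracks(500, "cortical", seed = 41)
  ns <- generate_neuron_tracks(500, "spinal", seed = 42)
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(nt$truth$true_half_life_h) - 33.2),
            2 * se(nt$truth$true_half_life_h))
  expect_lt(abs(mean(ns$truth$true_half_life_h) - 37.1),
            2 * se(ns$truth$true_half_life_h))
})

test_that("the hazard link ties death time to half-life with the right sign", {
  null <- generate_neuron_tracks(800, "cortical", seed = 43,
                                 overrides = list(hazard_beta = 0,
                                                  baseline_hazard = 5e-3))
  obs <- !null$truth$censored
  expect_lt(abs(cor(null$truth$true_half_life_h[obs],
                    null$truth$true_death_h[obs])), 0.1)
  pos <- generate_neuron_tracks(800, "cortical", seed = 44,
                                overrides = list(hazard_beta = 0.1,
                                                 baseline_hazard = 5e-3))
  obs <- !pos$truth$censored
  # slower flux (longer half-life) -> earlier death
  expect_lt(cor(pos$truth$true_half_life_h[obs],
                pos$truth$true_death_h[obs]), -0.1)
  expect_error(generate_neuron_tracks(10, "cortical", seed = 1,
                                      overrides = list(baseline_hazard = -1)),
               "hazard")
})
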