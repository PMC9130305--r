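zero_noise_profiles <- function() {
  pf <- elevrich:::default_climate_profiles()
  for (v in names(pf)) pf[[v]]$sd <- 0
  pf
}

test_that("noise-free climate follows the configured elevation responses", {
  cfg <- synthetic_config(seed = 1, climate_profiles = zero_noise_profiles())
  cl <- generate_climate_table(cfg)
  # direct evaluation of 25 - 5.5 * elev_km at the band midpoints
  expect_equal(cl$bio1[cl$mid == 50], 24.725)
  expect_equal(cl$bio1[cl$mid == 4950], -2.225)
  # monotone-in-expectation variables
  expect_true(all(diff(cl$bio1) < 0))
  expect_true(all(diff(cl$bio4) < 0))
  expect_true(all(diff(cl$bio6) < 0))
  expect_true(all(diff(cl$bio14) < 0))
  # symmetric hump forces the annual-precipitation peak into 2000-2100 m
  expect_equal(cl$band[which.max(cl$bio12)], "2000-2100")
  # seasonality of precipitation rises then levels off near 3350 m
  expect_gt(which.max(cl$bio15), 30)
  # area decreases with elevation
  expect_true(all(diff(cl$area) < 0))
  # physical invariants
  expect_true(all(cl$bio6 <= cl$bio1))
  expect_true(all(cl$bio12 >= cl$bio14 & cl$bio14 >= 0))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 99)
  expect_identical(generate_climate_table(cfg), generate_climate_table(cfg))
  expect_identical(generate_species_ranges(cfg), generate_species_ranges(cfg))
  d1 <- generate_recovery_dataset(cfg, default_recovery_law())
  d2 <- generate_recovery_dataset(cfg, default_recovery_law())
  expect_identical(d1$truth$realized, d2$truth$realized)
  expect_identical(d1$ranges, d2$ranges)
  # a different seed changes the draw
  cfg2 <- synthetic_config(seed = 100)
  expect_false(identical(generate_species_ranges(cfg),
                         generate_species_ranges(cfg2)))
})

test_that("species ranges honour degenerate and boundary configurations", {
  empty <- generate_species_ranges(synthetic_config(n_species = 0, peak_richness = 1))
  expect_equal(nrow(empty), 0L)
  # zero-width ranges occupy exactly one band each
  cfg <- synthetic_config(n_species = 200, seed = 5, peak_richness = 150,
                          range_width_meanlog = -Inf, range_width_sdlog = 0)
  rg <- generate_species_ranges(cfg)
  expect_true(all(rg$elev_min_m == rg$elev_max_m))
  pm <- assign_species_to_bands(rg, make_bands(0, 5000, 100))
  expect_true(all(colSums(pm$occupancy) == 1L))
  # no lycophytes when the fraction is zero
  rg0 <- generate_species_ranges(synthetic_config(n_species = 100, seed = 5,
                                                  peak_richness = 80,
                                                  lycophyte_fraction = 0))
  expect_equal(sum(rg0$group == "lycophyte"), 0L)
  # ranges stay inside the gradient
  rg1 <- generate_species_ranges(synthetic_config(seed = 6))
  expect_true(all(rg1$elev_min_m >= 0 & rg1$elev_max_m <= 5000))
  expect_error(synthetic_config(n_species = 10, peak_richness = 50), "peak_richness")
  expect_error(synthetic_config(band_width = 300), "divide")
})

test_that("band richness from sampled ranges is unimodal with the configured peak", {
  sch <- make_bands(0, 5000, 100)
  for (s in 1:20) {
    cfg <- synthetic_config(n_species = 1000, seed = s, peak_richness = 310,
                            range_width_meanlog = log(800), range_width_sdlog = 0.5)
    pm <- assign_species_to_bands(generate_species_ranges(cfg), sch)
    S <- rowSums(pm$occupancy)
    peak_mid <- sch$bands$mid[which.max(S)]
    expect_lt(abs(peak_mid - 2000), 500)
  }
})

test_that("recovery datasets realize the law's band counts exactly", {
  law0 <- richness_law(250, c(bio1_sq = -60), noise_sd = 0)
  cfg <- synthetic_config(seed = 13, climate_profiles = zero_noise_profiles())
  d <- generate_recovery_dataset(cfg, law0)
  pm <- assign_species_to_bands(d$ranges, make_bands(0, 5000, 100))
  expect_equal(unname(rowSums(pm$occupancy)), as.numeric(d$truth$realized))
  expect_equal(d$truth$realized, as.integer(round(d$truth$expected)))
  # noiseless quadratic law: second-order fit on that variable is exact up
  # to integer rounding of the counts, with a negative quadratic slope
  y <- standardize(as.numeric(d$truth$realized))
  fit <- ols_fit(build_design(d$climate, c("bio1", "bio1_sq")), y)
  expect_gt(fit$R2_adj, 0.999)
  expect_lt(fit$coefficients["bio1_sq"], 0)
})

test_that("a law with no climate signal leaves nothing for adjusted R2 to find", {
  law <- richness_law(100, numeric(0), noise_sd = 8)
  d <- generate_recovery_dataset(synthetic_config(seed = 17), law)
  y <- standardize(as.numeric(d$truth$realized))
  r2a <- vapply(bioclim_vars(), function(v)
    ols_fit(build_design(d$climate, v), y)$R2_adj, numeric(1))
  expect_true(all(r2a < 0.1))
  expect_lt(mean(r2a), 0.02)
})

test_that("laws predicting substantially negative richness are rejected", {
  law <- richness_law(10, c(bio12 = 200), noise_sd = 0)
  expect_error(generate_recovery_dataset(synthetic_config(seed = 1), law),
               "negative expected richness")
  expect_error(richness_law(100, c(foo = 1)), "unknown term")
  expect_error(richness_law(100, c(bio1 = 1), noise_sd = -1), "noise_sd")
})

test_that("YAML round-trips a configuration", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c("n_species: 50",
               "seed: 7",
               "richness_peak_elev: 1500",
               "peak_richness: 40",
               "climate_profiles:",
               "  bio1: {coef: [20, -5, 0], sd: 0}"), path)
  cfg <- synthetic_config_from_yaml(path)
  expect_equal(cfg$n_species, 50L)
  expect_equal(cfg$richness_peak_elev, 1500)
  expect_equal(cfg$climate_profiles$bio1$coef, c(20, -5, 0))
  # untouched variables keep their defaults
  expect_equal(cfg$climate_profiles$bio12$coef[3], -250)
  writeLines("bogus_key: 1", path)
  expect_error(synthetic_config_from_yaml(path), "bogus_key")
})

test_that("the replicated recovery study scores inclusion and curvature", {
  st <- run_recovery_study(n_reps = 3, seed = 4)
  expect_equal(st$n_reps, 3L)
  expect_true(st$inclusion_rate >= 0 && st$inclusion_rate <= 1)
  expect_true(st$negative_quadratic_rate >= 0 && st$negative_quadratic_rate <= 1)
  expect_length(st$selected, 3L)
})
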