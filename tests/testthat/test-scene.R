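test_that("zero-noise pure-grass cells invert the planted biomass relation exactly", {
  scene <- small_scene(seed = 11, noise_sd = 0)
  cfg <- scene$config
  pure <- scene$fractions[, , "grass"] >= 1 - 1e-12
  expect_gt(mean(pure), 0.3)
  i <- cfg$biomass_band_pair[1]; j <- cfg$biomass_band_pair[2]
  sri <- scene$reflectance[, , i][pure] / scene$reflectance[, , j][pure]
  recon <- cfg$biomass_relation$coef[1] * exp(cfg$biomass_relation$coef[2] * sri)
  expect_lt(max(abs(recon - scene$biomass[pure])), 1e-6)
  # nitrogen relation, inverted on the increasing branch
  i <- cfg$n_band_pair[1]; j <- cfg$n_band_pair[2]
  sri <- scene$reflectance[, , i][pure] / scene$reflectance[, , j][pure]
  cf <- cfg$n_relation$coef
  recon <- cf[1] + cf[2] * sri + cf[3] * sri^2
  expect_lt(max(abs(recon - scene$nitrogen[pure])), 1e-6)
})

test_that("fraction maps lie on the unit simplex and the cube is non-negative", {
  scene <- small_scene(seed = 4, noise_sd = 0.01)
  sums <- apply(scene$fractions, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(scene$fractions >= 0))
  expect_true(all(scene$reflectance >= 0))
})

test_that("noise-free reflectance is the exact endmember mixture", {
  scene <- small_scene(seed = 8, noise_sd = 0)
  nb <- dim(scene$reflectance)[3]
  lib <- scene$endmembers
  recon <- array(0, dim = dim(scene$reflectance))
  for (b in seq_len(nb)) {
    rb <- scene$fractions[, , "grass"] * scene$grass_reflectance[, , b]
    for (k in c("forest", "rock", "snow", "water")) {
      rb <- rb + scene$fractions[, , k] * lib[k, b]
    }
    recon[, , b] <- rb
  }
  expect_lt(max(abs(recon - scene$reflectance)), 1e-12)
  # mixed (non-pure) cells exist, so the identity covers real mixtures
  expect_gt(sum(scene$fractions[, , "grass"] < 0.7), 0)
})

test_that("planted truth fields reproduce the configured mean and sd within 5%", {
  cfg <- scene_config(n_rows = 100, n_cols = 100, n_bands = 8, seed = 21)
  scene <- generate_scene(cfg)
  expect_lt(abs(mean(scene$biomass) - 295.26) / 295.26, 0.05)
  expect_lt(abs(sd(scene$biomass) - 230.10) / 230.10, 0.05)
  expect_lt(abs(mean(scene$nitrogen) - 2.11) / 2.11, 0.05)
  expect_lt(abs(sd(scene$nitrogen) - 0.53) / 0.53, 0.05)
})

test_that("an invalid relation is rejected with its coefficients named", {
  cfg <- scene_config(n_rows = 16, n_cols = 16, n_bands = 8,
                      biomass_relation = list(form = "exponential", coef = c(-3, 1)),
                      seed = 1)
  expect_error(generate_scene(cfg), "-3")
})

test_that("plot records average the 3 x 3 window exactly and 51 plots fit", {
  scene <- small_scene(seed = 11, noise_sd = 0.01)
  plots <- sample_plots(scene, 51, seed = 3)
  expect_equal(nrow(plots), 51)
  S <- plot_spectra(plots)
  for (p in c(1, 25, 51)) {
    r <- plots$row[p]; cl <- plots$col[p]
    win <- scene$reflectance[(r - 1):(r + 1), (cl - 1):(cl + 1), , drop = FALSE]
    expect_equal(unname(S[p, ]), apply(win, 3, mean), tolerance = 1e-12)
    expect_equal(plots$biomass[p], mean(scene$biomass[(r - 1):(r + 1), (cl - 1):(cl + 1)]))
  }
  # single-cell records supported
  p1 <- sample_plots(scene, 10, seed = 3, window = 1)
  r <- p1$row[1]; cl <- p1$col[1]
  expect_equal(unname(plot_spectra(p1)[1, ]), scene$reflectance[r, cl, ])
})

test_that("species usage responds to planted preferences and is deterministic", {
  scene <- small_scene(seed = 6, noise_sd = 0)
  null_prefs <- list(species_preference("chamois"), species_preference("ibex"),
                     species_preference("red_deer"))
  u0 <- simulate_species_usage(scene, null_prefs, 1000, seed = 5)
  m <- tapply(u0$nitrogen, u0$species, mean)
  s <- tapply(u0$nitrogen, u0$species, sd) / sqrt(1000)
  expect_lt(max(m) - min(m), 6 * max(s))  # equal within sampling error
  prefs <- list(species_preference("chamois"),
                species_preference("ibex", b_n = 8),
                species_preference("red_deer"))
  u1 <- simulate_species_usage(scene, prefs, 1000, seed = 5)
  m1 <- tapply(u1$nitrogen, u1$species, mean)
  expect_gt(m1["ibex"], m1["chamois"])
  expect_gt(m1["ibex"], m1["red_deer"])
  u2 <- simulate_species_usage(scene, prefs, 1000, seed = 5)
  expect_identical(u1$x, u2$x)
  expect_identical(attr(u1, "implied_coefficients"), attr(u2, "implied_coefficients"))
})

test_that("usage tables keep the biomass rescaling contract", {
  scene <- small_scene(seed = 6, noise_sd = 0)
  u <- simulate_species_usage(scene, default_species_preferences(), 200, seed = 1)
  expect_identical(u$biom_rs, u$biomass / 100)
})
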