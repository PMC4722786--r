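test_that("plot aggregation averages the 3 x 3 window and validates the grid", {
  cube <- array(rep(1:4, each = 25), dim = c(5, 5, 4))
  expect_equal(aggregate_plot_reflectance(cube, c(5, 5)), as.numeric(1:4))
  # checkerboard: window mean equals occupancy-weighted mean
  cb <- array(0, dim = c(5, 5, 1))
  cb[, , 1] <- outer(1:5, 1:5, function(i, j) (i + j) %% 2)
  got <- aggregate_plot_reflectance(cb, c(5, 5), res = 2)
  expect_equal(got, mean(cb[2:4, 2:4, 1]))
  expect_error(aggregate_plot_reflectance(cube, c(0.5, 0.5)), "beyond")
})

test_that("SRI ranking finds exact relations, counts candidates, and matches brute force", {
  set.seed(7)
  n <- 20; nb <- 10
  S <- matrix(runif(n * nb, 0.1, 1), n, nb, dimnames = list(NULL, sprintf("b%02d", 1:nb)))
  plots <- data.frame(plot_id = 1:n, biomass = 3 + 2 * S[, 5] / S[, 2])
  plots <- cbind(plots, as.data.frame(S))
  rk <- rank_sri(plots, "biomass")
  expect_equal(nrow(rk), 90)  # 10 * 9 ordered pairs
  expect_equal(c(rk$i[1], rk$j[1]), c(5, 2))  # the exact linear relation wins
  expect_equal(rk$r2[rk$i == 5 & rk$j == 2], 1, tolerance = 1e-12)
  # independent-noise response: top R2 equals the exhaustive-search oracle
  plots$noise <- rnorm(n)
  rk2 <- rank_sri(plots, "noise")
  ora <- max(apply(expand.grid(i = 1:nb, j = 1:nb), 1, function(p) {
    if (p[1] == p[2]) return(-Inf)
    cor(S[, p[1]] / S[, p[2]], plots$noise)^2
  }))
  expect_equal(rk2$r2[1], ora)
})

test_that("candidate fits reproduce exact data and rank forms sensibly", {
  set.seed(3)
  n <- 15
  S <- matrix(runif(n * 4, 0.2, 1), n, 4, dimnames = list(NULL, sprintf("b%02d", 1:4)))
  x <- S[, 1] / S[, 2]
  mk <- function(y) cbind(data.frame(plot_id = 1:n, resp = y), as.data.frame(S))
  lin <- fit_candidate(mk(2 + 3 * x), c(1, 2), "resp", "linear")
  expect_lt(max(abs(lin$loocv_pred - (2 + 3 * x))), 1e-8)
  expect_equal(lin$stats$rmse, 0, tolerance = 1e-8)
  quad <- mk(1 + x - 2 * x^2)
  f_lin <- fit_candidate(quad, c(1, 2), "resp", "linear")
  f_pol <- fit_candidate(quad, c(1, 2), "resp", "polynomial2")
  expect_lt(f_pol$aic, f_lin$aic)
  ex <- mk(0.5 * exp(1.7 * x))
  f_exp <- fit_candidate(ex, c(1, 2), "resp", "exponential")
  expect_equal(unname(f_exp$coef), c(0.5, 1.7), tolerance = 1e-6)
  # too few points for the quadratic
  expect_error(fit_candidate(mk(x)[1:3, ], c(1, 2), "resp", "polynomial2"), "at least")
  # non-positive responses skip the exponential with a warning
  expect_warning(out <- fit_candidate(mk(x - mean(x)), c(1, 2), "resp", "exponential"),
                 "non-positive")
  expect_null(out)
})

test_that("Theil's U matches its definition, bounds and scale invariance", {
  expect_equal(theils_u(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(theils_u(c(1, -2, 3), -c(1, -2, 3)), 1)
  expect_equal(theils_u(c(1, 2, 3), c(2, 3, 4)),
               1 / (sqrt(14 / 3) + sqrt(29 / 3)), tolerance = 1e-12)
  set.seed(8)
  for (k in 1:25) {
    o <- rnorm(10); p <- rnorm(10)
    u <- theils_u(o, p)
    expect_gte(u, 0); expect_lte(u, 1)
    expect_equal(u, theils_u(3.7 * o, 3.7 * p))
  }
  expect_error(theils_u(c(0, 0), c(0, 0)), "undefined")
})

test_that("prediction statistics follow their definitions", {
  ev <- evaluate_fit(1:10, 1:10)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$adj_r2, 1)
  obs <- c(1, 2, 3, 4, 50)
  pred <- c(1.1, 2.1, 2.9, 4.2, 10)
  ev2 <- evaluate_fit(obs, pred)
  expect_equal(ev2$pct_within_20pct_rmse,
               100 * mean(abs(pred - obs) < 0.2 * sqrt(mean((pred - obs)^2))))
  ev3 <- evaluate_fit(1:5, rep(2, 5))
  expect_true(ev3$degenerate)
  expect_equal(ev3$adj_r2, 0)
  expect_error(evaluate_fit(1:3, 1:4), "mismatch")
})

test_that("model selection honours AIC with Theil's U and size as tie-breaks", {
  m1 <- structure(list(aic = 5, n_coef = 2L, observed = 1:4, fitted = 1:4,
                       stats = list(theils_u = 0.3)), class = "sri_model")
  expect_identical(select_best(list(m1)), m1)
  m2 <- structure(list(aic = 5, n_coef = 3L, observed = 1:4, fitted = 1:4,
                       stats = list(theils_u = 0.1)), class = "sri_model")
  expect_identical(select_best(list(m1, m2)), m2)   # tie: lower U wins
  m3 <- structure(list(aic = 5, n_coef = 2L, observed = 1:4, fitted = 1:4,
                       stats = list(theils_u = 0.1)), class = "sri_model")
  expect_identical(select_best(list(m2, m3)), m3)   # tie on U: fewer coefficients
  expect_error(select_best(list(NULL)), "empty")
})

test_that("constrained unmixing recovers known mixtures and masks by dominance", {
  lib <- endmember_library(seq(400, 2400, length.out = 12))
  as_cube <- function(spec) array(spec, dim = c(1, 1, length(spec)))
  pure <- unmix_lsu(as_cube(lib["grass", ]), lib)
  expect_equal(unname(pure$fractions[1, 1, "grass"]), 1, tolerance = 1e-9)
  expect_true(pure$mask[1, 1])
  mix <- unmix_lsu(as_cube(0.3 * lib["grass", ] + 0.7 * lib["rock", ]), lib)
  expect_equal(unname(mix$fractions[1, 1, "grass"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(mix$fractions[1, 1, "rock"]), 0.7, tolerance = 1e-6)
  expect_false(mix$mask[1, 1])
  half <- unmix_lsu(as_cube(0.5 * lib["grass", ] + 0.5 * lib["forest", ]), lib)
  expect_true(half$mask[1, 1])  # boundary rule: >= threshold
  # noisy pixels stay on the simplex and beat every pure-endmember residual
  set.seed(21)
  for (k in 1:10) {
    spec <- pmax(0.5 * lib["grass", ] + 0.5 * lib["water", ] + rnorm(12, sd = 0.05), 0)
    u <- unmix_lsu(as_cube(spec), lib)
    f <- u$fractions[1, 1, ]
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_true(all(f >= -1e-12))
    vertex_res <- min(colSums((t(lib) - spec)^2))
    expect_lte(u$residual[1, 1], vertex_res + 1e-12)
  }
  bad <- lib
  bad["water", ] <- bad["rock", ] * 2
  expect_error(unmix_lsu(as_cube(lib["grass", ]), bad), "rock and water|collinear")
})

test_that("zero-noise scenes are predicted back to truth through the fitted model", {
  scene <- small_scene(seed = 11, noise_sd = 0)
  cells <- sample_plots(scene, 60, seed = 2, window = 1)
  mb <- fit_sri_models(cells, "biomass", top_n = 50)
  mn <- fit_sri_models(cells, "nitrogen", top_n = 50)
  pure <- scene$fractions[, , "grass"] >= 1 - 1e-12
  pred_b <- predict_raster(mb, scene, mask = pure)
  pred_n <- predict_raster(mn, scene, mask = pure)
  expect_lt(max(abs(pred_b$values[pure] - scene$biomass[pure])), 1e-6)
  expect_lt(max(abs(pred_n$values[pure] - scene$nitrogen[pure])), 1e-6)
  expect_equal(sum(is.na(pred_b$values)), sum(!pure))
  # uniform cube gives a constant layer
  lib <- scene$endmembers
  ucube <- array(rep(lib["grass", ], each = 16), dim = c(4, 4, ncol(lib)))
  pl <- predict_raster(mb, ucube)
  expect_equal(length(unique(as.numeric(pl$values))), 1)
  expect_error(predict_raster(structure(list(pair = c(99, 1), form = "linear",
                                             coef = c(0, 1), response = "biomass"),
                                        class = "sri_model"), ucube), "outside")
})
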