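make_raster <- function(vals_b, vals_n, res = 2) {
  structure(list(biomass = vals_b, nitrogen = vals_n, mask = NULL,
                 origin = c(0, 0), res = res), class = "resource_raster")
}

square_cfa <- function(x0, y0, x1, y1, species, individual = paste0(species, "_1")) {
  structure(list(rings = list(list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))),
                 level = 0.3, species = species, individual = individual),
            class = "cfa")
}

test_that("cell extraction counts centres inside polygons, boundary included", {
  ras <- make_raster(matrix(100, 4, 4), matrix(2, 4, 4))
  # a square covering exactly the four lower-left cell centres (1,1)..(3,3)
  cfas <- list(square_cfa(0.5, 0.5, 3.5, 3.5, "chamois"),
               square_cfa(0.5, 0.5, 3.5, 3.5, "ibex"),
               square_cfa(1, 1, 3, 3, "red_deer"))  # boundary through centres
  tab <- extract_cells(ras, cfas)
  expect_equal(sum(tab$species == "chamois"), 4)
  expect_equal(sum(tab$species == "red_deer"), 4)  # centres on the boundary count
  expect_identical(tab$biom_rs, tab$biomass / 100)
  # within-species duplicates from two individuals counted once
  cfas2 <- list(square_cfa(0.5, 0.5, 3.5, 3.5, "chamois", "c1"),
                square_cfa(0.5, 0.5, 3.5, 3.5, "chamois", "c2"),
                square_cfa(0.5, 0.5, 3.5, 3.5, "ibex"),
                square_cfa(0.5, 0.5, 3.5, 3.5, "red_deer"))
  expect_equal(sum(extract_cells(ras, cfas2)$species == "chamois"), 4)
})

test_that("random polygons extract exactly the oracle centre-in-polygon count", {
  set.seed(14)
  ras <- make_raster(matrix(runif(400, 50, 500), 20, 20), matrix(runif(400, 1, 4), 20, 20))
  for (k in 1:5) {
    ring <- circle_ring(runif(1, 8, 32), runif(1, 8, 32), runif(1, 5, 15), n = 17)
    cfas <- list(structure(list(rings = list(ring), species = "chamois",
                                individual = "c"), class = "cfa"),
                 square_cfa(0, 0, 40, 40, "ibex"),
                 square_cfa(0, 0, 40, 40, "red_deer"))
    tab <- extract_cells(ras, cfas)
    grid <- expand.grid(row = 1:20, col = 1:20)
    cx <- (grid$col - 0.5) * 2; cy <- (grid$row - 0.5) * 2
    expect_equal(sum(tab$species == "chamois"), sum(oracle_in_ring(cx, cy, ring)))
  }
})

test_that("intercept-only fits recover the closed-form class log-ratios", {
  tab <- data.frame(species = factor(rep(c("chamois", "ibex", "red_deer"),
                                         times = c(100, 60, 30)),
                                     levels = c("chamois", "ibex", "red_deer")),
                    biom_rs = 1, nitrogen = 2)
  fit <- fit_mnl(tab, "intercept")
  expect_equal(fit$coef_table$estimate, c(log(60 / 100), log(30 / 100)),
               tolerance = 1e-5)
  expect_equal(fit$df, 2L)
})

test_that("simulated coefficients are recovered within three standard errors", {
  cov <- valley_covariates(5000, seed = 77)
  cfb <- balanced_intercepts(cov$biom_rs, cov$nitrogen, planted_slopes())
  lab <- simulate_mnl_labels(cov$biom_rs, cov$nitrogen, cfb, seed = 78)
  tab <- data.frame(species = lab, biom_rs = cov$biom_rs, nitrogen = cov$nitrogen)
  fit <- fit_mnl(tab, "interaction")
  dev <- abs(fit$coef_table$estimate - c(t(cfb))) / fit$coef_table$se
  expect_lt(max(dev), 3)
  expect_equal(fit$df, 8L)
})

test_that("missing species and the rescaling contract are enforced", {
  tab <- data.frame(species = factor(rep(c("chamois", "ibex"), 20),
                                     levels = c("chamois", "ibex", "red_deer")),
                    biom_rs = rnorm(40, 3), nitrogen = rnorm(40, 2))
  expect_error(fit_mnl(tab, "interaction"), "three species")
  tab2 <- data.frame(species = factor(rep(c("chamois", "ibex", "red_deer"), 20)),
                     biomass = rep(100, 60), biom_rs = 2, nitrogen = rnorm(60, 2))
  expect_error(fit_mnl(tab2, "main_effects"), "biom_rs")
})

test_that("model comparison reports the published df structure and exact LRT identities", {
  cov <- valley_covariates(1500, seed = 5)
  cfb <- balanced_intercepts(cov$biom_rs, cov$nitrogen, planted_slopes())
  lab <- simulate_mnl_labels(cov$biom_rs, cov$nitrogen, cfb, seed = 6)
  tab <- data.frame(species = lab, biom_rs = cov$biom_rs, nitrogen = cov$nitrogen)
  cmp <- compare_models(tab)
  expect_equal(cmp$table$df[match(c("intercept", "biomass_only", "nitrogen_only",
                                    "main_effects", "interaction"), cmp$table$form)],
               c(2L, 4L, 4L, 6L, 8L))
  self <- cmp$table[cmp$table$form == "interaction", ]
  expect_equal(self$lrt_stat, 0, tolerance = 1e-6)
  expect_equal(self$delta_aic, 0)
  expect_true(all(cmp$table$lrt_stat > -1e-6))
})

test_that("the Hosmer-Lemeshow statistic vanishes for exactly calibrated grouped data", {
  # two distinct predicted probabilities whose groups match observed frequencies
  n <- 200
  tab <- data.frame(
    species = factor(c(rep("chamois", 80), rep("ibex", 20),
                       rep("chamois", 40), rep("ibex", 60),
                       rep("red_deer", 10)),
                     levels = c("chamois", "ibex", "red_deer")),
    biom_rs = c(rep(1, 100), rep(2, 100), rep(1.5, 10)),
    nitrogen = 2)
  fit <- fit_mnl(tab, "biomass_only")
  hl <- suppressWarnings(hosmer_lemeshow_logit(fit, tab, 1, groups = 2))
  # recompute the statistic from the model's own conditional probabilities
  cp <- foragemap:::conditional_probs(fit, tab, 1)
  g <- cp$cond > median(cp$cond)
  chi2 <- 0
  for (gr in c(FALSE, TRUE)) {
    O <- sum(cp$is_pos[g == gr]); E <- sum(cp$cond[g == gr]); ng <- sum(g == gr)
    chi2 <- chi2 + (O - E)^2 / (E * (1 - E / ng))
  }
  expect_equal(hl$statistic, chi2, tolerance = 1e-6)
  expect_lt(hl$statistic, 1)  # near-calibrated by construction
})

test_that("rank-based AUC matches pair counting, pROC, and is monotone-invariant", {
  expect_equal(foragemap:::rank_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(foragemap:::rank_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(44)
  scores <- sample(seq(0, 1, by = 0.05), 20, replace = TRUE)  # forces ties
  lab <- runif(20) < 0.4
  lab[1:2] <- c(TRUE, FALSE)
  got <- foragemap:::rank_auc(scores, lab)
  expect_equal(got, oracle_auc(scores, lab))
  expect_equal(got, as.numeric(pROC::auc(pROC::roc(lab, scores, quiet = TRUE))))
  expect_equal(foragemap:::rank_auc(exp(5 * scores), lab), got)
})

test_that("a zero buffer changes nothing and degenerate shrinks fail loudly", {
  set.seed(3)
  ras <- make_raster(matrix(runif(900, 50, 600), 30, 30),
                     matrix(runif(900, 1, 4), 30, 30))
  cfas <- list(square_cfa(2, 2, 28, 28, "chamois"),
               square_cfa(6, 6, 40, 40, "ibex"),
               square_cfa(10, 10, 50, 50, "red_deer"))
  bs <- buffer_sensitivity(ras, cfas, buffer = 0)
  expect_true(all(bs$table$p == 1))
  expect_true(all(bs$table$estimate_base == bs$table$estimate_buffered))
  tiny <- c(cfas[1:2], list(square_cfa(10, 10, 18, 18, "red_deer")))
  expect_error(buffer_sensitivity(ras, tiny, buffer = 5), "vanishes")
})
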