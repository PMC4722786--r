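test_that("time-scaled distance has its closed form and metric properties", {
  expect_equal(tsd(3, 4, 1e6, 0, 2), 5)                    # s = 0
  expect_equal(tsd(3, 4, 0, 5, 2), 5)                      # dt = 0
  expect_equal(tsd(3, 4, 3600, 0.01, 0.5), sqrt(349))      # hand-computed
  set.seed(2)
  for (k in 1:50) {
    dx <- rnorm(1); dy <- rnorm(1); dt <- runif(1, 0, 1e5)
    s <- runif(1, 0, 2); v <- runif(1, 0.1, 2)
    d <- tsd(dx, dy, dt, s, v)
    expect_equal(d, tsd(-dx, -dy, -dt, s, v))              # symmetry
    expect_gte(d, sqrt(dx^2 + dy^2) - 1e-12)               # >= Euclidean
  }
})

test_that("maximum observed speed equals the brute-force consecutive maximum", {
  tr <- toy_traj(x = rep(1, 5), y = rep(2, 5))
  expect_equal(max_observed_speed(tr), 0)
  tr2 <- toy_traj(x = c(0, 100), y = c(0, 0), dt = 3600)
  expect_equal(max_observed_speed(tr2), 100 / 3600)
  traj <- simulate_trajectory(trajectory_config(seed = 3))
  ora <- max(sapply(2:nrow(traj), function(i) {
    sqrt((traj$x[i] - traj$x[i - 1])^2 + (traj$y[i] - traj$y[i - 1])^2) /
      (traj$t[i] - traj$t[i - 1])
  }))
  expect_equal(max_observed_speed(traj), ora)
})

test_that("the time-selected-hull proportion is 0 at s = 0 and trends upward in s", {
  traj <- simulate_trajectory(trajectory_config(
    n_days = 10, patches = data.frame(x = c(0, 1200), y = 0, radius = 150), seed = 8))
  v <- max_observed_speed(traj)
  sel <- select_s(traj, s_grid = c(1e-6, 10^seq(-4, 1, length.out = 20)))
  curve <- sel$curve
  # near-zero s leaves every neighbour set unchanged
  expect_equal(curve$ptsh[1], 0)
  # broad trend: the upper third of the grid changes more sets than the lower third
  k <- nrow(curve)
  expect_gt(mean(curve$ptsh[(2 * k %/% 3):k]), mean(curve$ptsh[1:(k %/% 3)]))
})

test_that("neighbour selection handles the degenerate extremes of a", {
  traj <- simulate_trajectory(trajectory_config(
    n_days = 5, patches = data.frame(x = 0, y = 0, radius = 150), seed = 2))
  tiny <- select_neighbors(traj, 0, hull_config(method = "a", a = 1e-9))
  expect_true(all(lengths(tiny) == 0))
  all_in <- select_neighbors(traj, 0, hull_config(method = "a", a = Inf))
  expect_true(all(lengths(all_in) == nrow(traj) - 1))
})

test_that("a/k/r neighbour selection matches the exhaustive oracle", {
  set.seed(17)
  traj <- data.frame(id = "z", t = (0:49) * 14400,
                     x = cumsum(rnorm(50, sd = 120)), y = cumsum(rnorm(50, sd = 120)))
  v <- max_observed_speed(traj)
  s <- 0.005
  for (spec in list(list("a", 2500), list("k", 7), list("r", 700))) {
    cfg <- switch(spec[[1]],
                  a = hull_config(method = "a", a = spec[[2]]),
                  k = hull_config(method = "k", k = spec[[2]]),
                  r = hull_config(method = "r", r = spec[[2]]))
    got <- select_neighbors(traj, s, cfg, v_max = v)
    want <- oracle_neighbors(traj, s, v, spec[[1]], spec[[2]])
    expect_identical(got, want)
  }
})

test_that("hull geometry matches hand computations and the enclosure oracle", {
  # unit right triangle: shoelace area 1/2
  tr <- toy_traj(x = c(0, 1, 0, 0.25), y = c(0, 0, 1, 0.25))
  nn <- list(c(2L, 3L), integer(0), integer(0), integer(0))
  hs <- build_hulls(tr[1:3, ], list(c(2L, 3L), integer(0), integer(0)))
  expect_equal(hs$hulls[[1]]$area, 0.5)
  expect_equal(hs$hulls[[1]]$perimeter, 2 + sqrt(2))
  # collinear: zero area, perimeter twice the segment
  col <- toy_traj(x = c(0, 1, 2), y = c(0, 0, 0))
  hsc <- build_hulls(col, list(c(2L, 3L), integer(0), integer(0)))
  expect_equal(hsc$hulls[[1]]$area, 0)
  expect_equal(hsc$hulls[[1]]$perimeter, 4)
  expect_setequal(hsc$hulls[[1]]$enclosed, 1:3)
  # enclosure against the sp oracle on a random fixture
  set.seed(5)
  traj <- data.frame(id = "q", t = (0:39) * 14400,
                     x = runif(40, 0, 100), y = runif(40, 0, 100))
  nn <- select_neighbors(traj, 0, hull_config(method = "k", k = 6))
  hs2 <- build_hulls(traj, nn)
  for (i in c(1, 10, 25, 40)) {
    h <- hs2$hulls[[i]]
    ora <- which(oracle_in_ring(traj$x, traj$y, h$ring))
    expect_setequal(h$enclosed, ora)
  }
})

test_that("revisitation counts come from inter-visit gap grouping", {
  tr <- toy_traj(x = c(0, 0.5, 0, 5, 0.2), y = rep(0, 5), dt = 3600)
  tr$t <- c(0, 4, 20, 30, 44) * 3600
  hs <- build_hulls(tr, list(2L, integer(0), integer(0), integer(0), integer(0)))
  # hull 1 encloses fixes 1, 2, 3, 5 (all near origin)
  hs <- hull_metrics(hs, ivg = 43200)
  expect_equal(hs$metrics$nsv[1], 3)  # visits {0,4}, {20}, {44}
  # all-in-one-window case
  tr2 <- toy_traj(x = c(0, 0.1, 0.2), y = rep(0, 3), dt = 3600)
  hs2 <- hull_metrics(build_hulls(tr2, list(c(2L, 3L), integer(0), integer(0))), ivg = 43200)
  expect_equal(hs2$metrics$nsv[1], 1)
  # the busiest hull gets nnsv 1
  traj <- simulate_trajectory(trajectory_config(seed = 4))
  nn <- select_neighbors(traj, 0, hull_config(method = "k", k = 8))
  hs3 <- hull_metrics(build_hulls(traj, nn))
  expect_equal(max(hs3$metrics$nnsv), 1)
  expect_equal(hs3$metrics$nnsv, hs3$metrics$nsv / max(hs3$metrics$nsv))
})

test_that("isopleths enclose their level and nest across levels", {
  traj <- simulate_trajectory(trajectory_config(seed = 6))
  nn <- select_neighbors(traj, 0, hull_config(method = "k", k = 10))
  hs <- hull_metrics(build_hulls(traj, nn))
  iso <- build_isopleths(hs, levels = c(0.3, 0.6, 1.0))
  expect_true(all(iso$summary$enclosed_fraction >= iso$summary$level))
  expect_equal(iso$summary$enclosed_fraction[3], 1.0)
  expect_true(all(diff(iso$summary$area) >= -1e-9))
  # nesting: every vertex of the smaller polygon lies inside the larger
  r1 <- iso$rings[[1]]; r3 <- iso$rings[[3]]
  pts <- do.call(rbind, lapply(r1, function(r) cbind(r$x, r$y)))
  # 1 cm tolerance absorbs clipper quantisation over chained unions
  expect_true(all(foragemap:::points_in_rings(pts[, 1], pts[, 2], r3, tol = 0.01)))
})

test_that("step-wise enclosed counts agree with a brute-force point-in-union oracle", {
  set.seed(9)
  traj <- data.frame(id = "w", t = (0:9) * 14400,
                     x = runif(10, 0, 50), y = runif(10, 0, 50))
  nn <- select_neighbors(traj, 0, hull_config(method = "k", k = 3))
  hs <- hull_metrics(build_hulls(traj, nn))
  iso <- build_isopleths(hs, levels = 1.0)
  ord <- iso$order
  for (step in seq_along(iso$step_fraction)) {
    rings <- Filter(Negate(is.null),
                    lapply(hs$hulls[ord[seq_len(step)]], `[[`, "ring"))
    ora <- oracle_in_rings_union(traj$x, traj$y, rings)
    # degenerate hulls enclose their segment points too
    for (h in hs$hulls[ord[seq_len(step)]]) ora[h$enclosed] <- TRUE
    expect_equal(iso$step_fraction[step], mean(ora))
  }
})

test_that("a-selection validates its inputs and areas grow with a", {
  traj <- simulate_trajectory(trajectory_config(
    n_days = 15, patches = data.frame(x = c(0, 1200), y = 0, radius = 150), seed = 3))
  expect_error(select_a(traj, 0, candidates = 500), "ascending")
  cand <- default_a_candidates(traj, 0)
  sel <- suppressWarnings(select_a(traj, 0, cand))
  expect_true(sel$a %in% cand)
  # containment theorem: the union of all hulls can only grow with a
  union_area <- vapply(cand[c(1, 4, 7)], function(a) {
    nn <- select_neighbors(traj, 0, hull_config(method = "a", a = a))
    hs <- build_hulls(traj, nn)
    rings <- Filter(Negate(is.null), lapply(hs$hulls, `[[`, "ring"))
    foragemap:::rings_area(foragemap:::rings_union(lapply(rings, list)))
  }, numeric(1))
  expect_true(all(diff(union_area) >= -1e-6))
})

test_that("core-foraging-area export round-trips through GeoJSON", {
  traj <- simulate_trajectory(trajectory_config(seed = 10))
  iso <- tlocoh_isopleths(traj, 0, hull_config(method = "k", k = 10, levels = 0.3))
  cfa <- export_cfa(iso, level = 0.3, species = "ibex", individual = "ibex_1")
  expect_equal(cfa$area, iso$summary$area[1])
  expect_error(export_cfa(iso, level = 0.5), "not present")
  path <- tempfile(fileext = ".geojson")
  write_cfa_geojson(cfa, path)
  back <- read_cfa_geojson(path)[[1]]
  expect_equal(back$species, "ibex")
  expect_equal(back$area, cfa$area, tolerance = 1e-9)
  expect_equal(length(back$rings), length(cfa$rings))
})
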