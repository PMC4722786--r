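# Shared fixtures and independent oracles used across the suite.

circle_ring <- function(cx, cy, r, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

# a tiny hand-made trajectory: regular 4 h fixes along a path
toy_traj <- function(x, y, dt = 14400, id = "toy") {
  data.frame(id = id, t = seq_along(x) * dt - dt, x = x, y = y,
             stringsAsFactors = FALSE)
}

# small scene shared by several spectral tests
small_scene <- function(seed = 11, noise_sd = 0, n = 48) {
  generate_scene(scene_config(n_rows = n, n_cols = n, n_bands = 12,
                              noise_sd = noise_sd, seed = seed))
}

# independent point-in-polygon oracle (sp, C implementation unrelated to
# the package's ray-casting code)
oracle_in_ring <- function(px, py, ring) {
  sp::point.in.polygon(px, py, ring$x, ring$y) > 0
}

oracle_in_rings_union <- function(px, py, rings_list) {
  hit <- rep(FALSE, length(px))
  for (r in rings_list) hit <- hit | oracle_in_ring(px, py, r)
  hit
}

# O(n^2) pair-counting AUC oracle
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive TSD neighbour oracle (sorts the full row, no shortcuts)
oracle_neighbors <- function(traj, s, v_max, method, par) {
  n <- nrow(traj)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt((traj$x[i] - traj$x[j])^2 + (traj$y[i] - traj$y[j])^2 +
                    (s * v_max * (traj$t[i] - traj$t[j]))^2)
  }
  lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i]
    d <- D[i, ord]
    if (method == "a") ord[cumsum(d) <= par]
    else if (method == "k") ord[seq_len(min(par, n - 1))]
    else ord[d <= par]
  })
}

# Table 3 slope structure (chamois reference)
planted_slopes <- function() {
  rbind(ibex = c(0, 1.0043, 3.6048, -0.1314),
        red_deer = c(0, -0.1548, -2.4917, 0.5535))
}

# covariates resembling the valley's resource distribution
valley_covariates <- function(n, seed) {
  set.seed(seed)
  list(biom_rs = pmax(stats::rlnorm(n, log(2.5), 0.7), 0.1),
       nitrogen = pmin(pmax(stats::rnorm(n, 2.11, 0.53), 0.3), 4.3))
}
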