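# Time-local convex hull engine: time-scaled distance, parameter selection,
# hull construction, revisitation metrics and isopleth assembly.

#' Time-scaled distance between two fixes
#'
#' TSD combines spatial separation and time lag:
#' sqrt(dx^2 + dy^2 + (s * v_max * dt)^2). It is symmetric, never smaller
#' than the Euclidean distance, and reduces to it when `s = 0` or `dt = 0`.
#'
#' @param dx,dy Spatial separation in metres.
#' @param dt Time lag in seconds.
#' @param s Dimensionless time-weighting parameter (>= 0).
#' @param v_max Maximum observed speed of the trajectory, m/s.
#' @return Distance in metres.
#' @export
tsd <- function(dx, dy, dt, s, v_max) {
  if (any(s < 0)) stop_fm("s must be >= 0")
  sqrt(dx^2 + dy^2 + (s * v_max * dt)^2)
}

# full pairwise TSD matrix for one trajectory
tsd_matrix <- function(traj, s, v_max) {
  dx <- outer(traj$x, traj$x, "-")
  dy <- outer(traj$y, traj$y, "-")
  dt <- outer(traj$t, traj$t, "-")
  sqrt(dx^2 + dy^2 + (s * v_max * dt)^2)
}

#' Maximum observed speed of a trajectory
#'
#' Maximum displacement/time over consecutive fixes; used to put the TSD
#' time term on a distance scale.
#' @param traj Trajectory data frame (>= 2 fixes).
#' @return Speed in m/s.
#' @export
max_observed_speed <- function(traj) {
  check_trajectory(traj, min_fixes = 2L)
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  max(d / diff(traj$t))
}

# k-nearest-neighbour index sets (excluding self) under a distance matrix;
# ties broken by index order for determinism
knn_sets <- function(D, k) {
  n <- nrow(D)
  k <- min(k, n - 1)
  lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))
    setdiff(ord, i)[seq_len(k)]
  })
}

#' Select the TSD time weighting s for a target proportion of time-selected hulls
#'
#' A point is "time selected" at a given `s` when its `k_probe` nearest
#' neighbours under TSD(s) differ from its nearest neighbours under pure
#' spatial distance (s = 0). The returned `s` is the log-spaced candidate
#' whose proportion of time-selected points is closest to `target_ptsh`
#' (default 0.60, the conventional diagnostic target).
#'
#' @param traj Screened trajectory data frame.
#' @param target_ptsh Target proportion in (0, 1).
#' @param k_probe Neighbour count for the diagnostic (default 10).
#' @param s_grid Candidate values; default 120 log-spaced values in
#'   [1e-4, 10] (dense enough that the step in achieved ptsh near the
#'   transition stays well under 0.05).
#' @return List with `s`, achieved `ptsh`, and the full `curve` data frame.
#' @export
select_s <- function(traj, target_ptsh = 0.60, k_probe = 10,
                     s_grid = 10^seq(-4, 1, length.out = 120)) {
  check_trajectory(traj, min_fixes = max(3L, k_probe + 1L))
  v_max <- max_observed_speed(traj)
  if (v_max <= 0) stop_fm("trajectory is entirely stationary; s cannot be selected")
  n <- nrow(traj)
  D2xy <- outer(traj$x, traj$x, "-")^2 + outer(traj$y, traj$y, "-")^2
  Dt2 <- outer(traj$t, traj$t, "-")^2
  base <- knn_sets(sqrt(D2xy), k_probe)
  ptsh <- vapply(s_grid, function(s) {
    nn <- knn_sets(sqrt(D2xy + (s * v_max)^2 * Dt2), k_probe)
    mean(vapply(seq_len(n), function(i) !setequal(nn[[i]], base[[i]]), logical(1)))
  }, numeric(1))
  if (all(ptsh == 0)) stop_fm("no candidate s changes any neighbour set")
  best <- which.min(abs(ptsh - target_ptsh))
  list(s = s_grid[best], ptsh = ptsh[best],
       curve = data.frame(s = s_grid, ptsh = ptsh))
}

#' Hull construction configuration
#'
#' @param method One of `"a"` (cumulative TSD), `"k"` (neighbour count),
#'   `"r"` (TSD radius). Exactly the matching parameter must be supplied.
#' @param a,k,r Method parameter (cumulative TSD metres / count / metres).
#' @param ivg Inter-visit gap in seconds (default 43200 = 12 h).
#' @param levels Isopleth fractions in (0, 1], ascending (default 0.3, the
#'   core-foraging-area threshold).
#' @param sort_metric Hull sort metric; `"nnsv"` (normalised number of
#'   separate visits, default) or `"nsv"`.
#' @return Object of class `hull_config`.
#' @export
hull_config <- function(method = c("a", "k", "r"), a = NULL, k = NULL, r = NULL,
                        ivg = 43200, levels = 0.3, sort_metric = "nnsv") {
  method <- match.arg(method)
  given <- c(a = !is.null(a), k = !is.null(k), r = !is.null(r))
  if (!given[method] || sum(given) != 1) {
    stop_fm("exactly the parameter of the chosen method ('", method, "') must be set")
  }
  if (method == "a" && !(length(a) == 1 && is.numeric(a) && !is.na(a) && a > 0)) {
    stop_fm("a must be positive")  # Inf allowed: every point becomes a neighbour
  }
  if (method == "k" && (!is_count(k) || k < 1)) stop_fm("k must be a positive integer")
  if (method == "r" && (!is_number(r) || r <= 0)) stop_fm("r must be positive")
  if (!is_number(ivg) || ivg <= 0) stop_fm("ivg must be positive")
  if (length(levels) < 1 || any(levels <= 0 | levels > 1) || is.unsorted(levels)) {
    stop_fm("levels must be ascending fractions in (0, 1]")
  }
  if (!sort_metric %in% c("nnsv", "nsv")) stop_fm("sort_metric must be 'nnsv' or 'nsv'")
  structure(list(method = method, a = a, k = k, r = r, ivg = ivg,
                 levels = levels, sort_metric = sort_metric),
            class = "hull_config")
}

#' Select TSD neighbours for every fix
#'
#' a-method: neighbours are added in ascending TSD while the running sum of
#' their TSDs stays within `a` (the parent, at TSD 0, is always included).
#' k-method: the `k` nearest by TSD. r-method: all fixes within TSD `r`.
#'
#' @param traj Trajectory data frame.
#' @param s TSD time weighting.
#' @param config A [hull_config()].
#' @param v_max Maximum speed; computed from `traj` when NULL.
#' @return List of integer neighbour index vectors (parent excluded, sorted
#'   by ascending TSD).
#' @export
select_neighbors <- function(traj, s, config, v_max = NULL) {
  check_trajectory(traj, min_fixes = 2L)
  if (is.null(v_max)) v_max <- if (s > 0) max_observed_speed(traj) else 1
  D <- tsd_matrix(traj, s, v_max)
  n <- nrow(D)
  lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))
    ord <- setdiff(ord, i)
    di <- D[i, ord]
    switch(config$method,
      a = ord[cumsum(di) <= config$a],
      k = ord[seq_len(min(config$k, n - 1))],
      r = ord[di <= config$r]
    )
  })
}

#' Build local convex hulls around each fix
#'
#' Each hull is the convex hull of the parent plus its neighbours. Enclosed
#' points are all trajectory fixes inside or on the hull; degenerate hulls
#' (fewer than 3 distinct non-collinear positions) get zero area, perimeter
#' twice the segment length, and enclosed points on the segment.
#'
#' @param traj Trajectory data frame.
#' @param neighbors Output of [select_neighbors()].
#' @return Object of class `hullset`: list with `hulls` (per-fix list of
#'   ring, area, perimeter, enclosed indices) and the trajectory.
#' @export
build_hulls <- function(traj, neighbors) {
  n <- nrow(traj)
  if (length(neighbors) != n) stop_fm("neighbour list length must match trajectory")
  hulls <- vector("list", n)
  for (i in seq_len(n)) {
    members <- c(i, neighbors[[i]])
    px <- traj$x[members]; py <- traj$y[members]
    ring <- convex_ring(px, py)
    if (is.null(ring)) {
      # degenerate: point or segment
      u <- unique(cbind(px, py))
      if (nrow(u) == 1) {
        enc <- which(abs(traj$x - u[1, 1]) < 1e-9 & abs(traj$y - u[1, 2]) < 1e-9)
        hulls[[i]] <- list(parent = i, neighbors = neighbors[[i]], ring = NULL,
                           area = 0, perimeter = 0, enclosed = enc)
      } else {
        # collinear: find the extreme pair as the segment
        dproj <- (u[, 1] - u[1, 1]) * (u[nrow(u), 1] - u[1, 1]) +
                 (u[, 2] - u[1, 2]) * (u[nrow(u), 2] - u[1, 2])
        a_ <- u[which.min(dproj), ]; b_ <- u[which.max(dproj), ]
        seg_len <- sqrt(sum((b_ - a_)^2))
        ex <- b_[1] - a_[1]; ey <- b_[2] - a_[2]
        len2 <- max(ex^2 + ey^2, 1e-300)
        tt <- ((traj$x - a_[1]) * ex + (traj$y - a_[2]) * ey) / len2
        d2 <- (traj$x - (a_[1] + pmin(pmax(tt, 0), 1) * ex))^2 +
              (traj$y - (a_[2] + pmin(pmax(tt, 0), 1) * ey))^2
        enc <- which(d2 < 1e-12)
        hulls[[i]] <- list(parent = i, neighbors = neighbors[[i]], ring = NULL,
                           area = 0, perimeter = 2 * seg_len, enclosed = enc)
      }
    } else {
      enc <- which(points_in_convex(traj$x, traj$y, ring))
      hulls[[i]] <- list(parent = i, neighbors = neighbors[[i]], ring = ring,
                         area = abs(ring_area_signed(ring)),
                         perimeter = ring_perimeter(ring), enclosed = enc)
    }
  }
  structure(list(hulls = hulls, traj = traj), class = "hullset")
}

#' Revisitation metrics for a hull set
#'
#' For each hull, the number of separate visits (NSV) is the number of
#' maximal runs of enclosed fix timestamps in which consecutive gaps do not
#' exceed the inter-visit gap `ivg`. NNSV rescales NSV to [0, 1] by the
#' maximum NSV in the set, preserving the sort order of NSV.
#'
#' @param hullset A [build_hulls()] result.
#' @param ivg Inter-visit gap in seconds (default 43200 = 12 h).
#' @return The hull set with a `metrics` data frame (parent, area,
#'   perimeter, n_enclosed, nsv, nnsv).
#' @export
hull_metrics <- function(hullset, ivg = 43200) {
  if (!inherits(hullset, "hullset") || length(hullset$hulls) == 0) {
    stop_fm("empty hull set")
  }
  t <- hullset$traj$t
  nsv <- vapply(hullset$hulls, function(h) {
    ts <- sort(t[h$enclosed])
    if (length(ts) == 0) return(0L)
    1L + sum(diff(ts) > ivg)
  }, integer(1))
  max_nsv <- max(nsv)
  nnsv <- if (max_nsv > 0) nsv / max_nsv else rep(0, length(nsv))
  hullset$metrics <- data.frame(
    parent = vapply(hullset$hulls, `[[`, integer(1), "parent"),
    area = vapply(hullset$hulls, `[[`, numeric(1), "area"),
    perimeter = vapply(hullset$hulls, `[[`, numeric(1), "perimeter"),
    n_enclosed = vapply(hullset$hulls, function(h) length(h$enclosed), integer(1)),
    nsv = nsv, nnsv = nnsv
  )
  hullset$ivg <- ivg
  hullset
}

#' Build isopleths by sorted progressive hull union
#'
#' Hulls are sorted by the chosen metric (descending; ties broken by smaller
#' area, then lower parent index) and unioned in order. After each union the
#' fraction of all fixes enclosed by the union is evaluated; the level-L
#' isopleth is the first union whose enclosed fraction reaches L.
#'
#' @param hullset A [hull_metrics()] result.
#' @param levels Ascending fractions in (0, 1].
#' @param sort_metric `"nnsv"` or `"nsv"`.
#' @return Object of class `isopleth_set`: `summary` data frame (level,
#'   n_hulls, enclosed_fraction, area, perimeter, edge_area), `rings` per
#'   level, `order` (hull ordering used), `step_fraction` (enclosed fraction
#'   after each union step).
#' @export
build_isopleths <- function(hullset, levels = 0.3, sort_metric = c("nnsv", "nsv")) {
  sort_metric <- match.arg(sort_metric)
  if (is.null(hullset$metrics)) stop_fm("hull metrics not computed; call hull_metrics()")
  if (any(levels <= 0 | levels > 1) || is.unsorted(levels)) {
    stop_fm("levels must be ascending fractions in (0, 1]")
  }
  m <- hullset$metrics
  ord <- order(-m[[sort_metric]], m$area, m$parent)
  n_fix <- nrow(hullset$traj)
  enclosed <- logical(n_fix)
  step_fraction <- numeric(length(ord))
  union_rings <- list()
  out_rings <- vector("list", length(levels))
  out <- data.frame(level = levels, n_hulls = NA_integer_,
                    enclosed_fraction = NA_real_, area = NA_real_,
                    perimeter = NA_real_, edge_area = NA_real_)
  li <- 1L
  for (step in seq_along(ord)) {
    h <- hullset$hulls[[ord[step]]]
    enclosed[h$enclosed] <- TRUE
    if (!is.null(h$ring)) {
      union_rings <- if (length(union_rings) == 0) list(h$ring) else {
        polyclip::polyclip(union_rings, list(h$ring), op = "union")
      }
    }
    step_fraction[step] <- mean(enclosed)
    while (li <= length(levels) && step_fraction[step] >= levels[li]) {
      area <- rings_area(union_rings)
      per <- rings_perimeter(union_rings)
      out$n_hulls[li] <- step
      out$enclosed_fraction[li] <- step_fraction[step]
      out$area[li] <- area
      out$perimeter[li] <- per
      out$edge_area[li] <- if (area > 0) per / area else NA_real_
      out_rings[[li]] <- union_rings
      li <- li + 1L
    }
    if (li > length(levels)) break
  }
  if (li <= length(levels)) {
    stop_fm("level ", levels[li], " unreachable: hull set encloses only ",
            signif(max(step_fraction), 3), " of fixes")
  }
  structure(list(summary = out, rings = out_rings, order = ord,
                 step_fraction = step_fraction[seq_len(max(out$n_hulls))]),
            class = "isopleth_set")
}

#' Select the cumulative-distance parameter a from isopleth stability
#'
#' For each candidate `a` the core-level isopleth is built and its area and
#' edge-to-area ratio recorded. The selected `a` is the smallest candidate
#' at which the relative change of edge:area versus the previous candidate
#' falls below `tol_ratio` while the relative area increase at the next
#' candidate does not exceed `jump_tol` (stabilised before an area jump).
#' If no candidate satisfies both rules the candidate minimising the
#' edge:area change is returned with a warning.
#'
#' @param traj Trajectory data frame.
#' @param s TSD time weighting.
#' @param candidates Ascending candidate values of `a` (>= 3).
#' @param level Core isopleth level (default 0.3).
#' @param ivg Inter-visit gap seconds.
#' @param sort_metric Hull sort metric.
#' @param tol_ratio Relative edge:area stabilisation tolerance.
#' @param jump_tol Relative area-jump tolerance at the next candidate.
#' @return List with `a`, `diagnostics` data frame (a, area, edge_area) and
#'   `stabilised` flag.
#' @export
select_a <- function(traj, s, candidates, level = 0.3, ivg = 43200,
                     sort_metric = "nnsv", tol_ratio = 0.05, jump_tol = 0.50) {
  if (length(candidates) < 3 || is.unsorted(candidates, strictly = TRUE)) {
    stop_fm("need >= 3 strictly ascending candidates for a")
  }
  v_max <- max_observed_speed(traj)
  diag_df <- data.frame(a = candidates, area = NA_real_, edge_area = NA_real_)
  for (ci in seq_along(candidates)) {
    cfg <- hull_config(method = "a", a = candidates[ci], ivg = ivg, levels = level,
                       sort_metric = sort_metric)
    nn <- select_neighbors(traj, s, cfg, v_max = v_max)
    hs <- hull_metrics(build_hulls(traj, nn), ivg = ivg)
    iso <- build_isopleths(hs, levels = level, sort_metric = sort_metric)
    diag_df$area[ci] <- iso$summary$area[1]
    diag_df$edge_area[ci] <- iso$summary$edge_area[1]
  }
  ea <- diag_df$edge_area; ar <- diag_df$area
  rel_ea <- abs(diff(ea)) / pmax(abs(ea[-length(ea)]), 1e-12)
  sel <- NA_integer_
  for (ci in 2:length(candidates)) {
    stab <- rel_ea[ci - 1] < tol_ratio
    no_jump <- if (ci < length(candidates)) {
      (ar[ci + 1] - ar[ci]) / pmax(ar[ci], 1e-12) <= jump_tol
    } else TRUE
    if (stab && no_jump) { sel <- ci; break }
  }
  stabilised <- !is.na(sel)
  if (!stabilised) {
    sel <- which.min(rel_ea) + 1L
    warning("no candidate stabilised edge:area before an area jump; ",
            "returning the candidate with the smallest edge:area change")
  }
  list(a = candidates[sel], diagnostics = diag_df, stabilised = stabilised)
}

#' Run the full hull pipeline for one individual
#'
#' Convenience wrapper: neighbour selection, hulls, revisitation metrics and
#' isopleths under one configuration.
#' @param traj Trajectory data frame.
#' @param s TSD time weighting.
#' @param config A [hull_config()].
#' @return An `isopleth_set` with the hull set attached as attribute
#'   `hullset`.
#' @export
tlocoh_isopleths <- function(traj, s, config) {
  v_max <- if (s > 0) max_observed_speed(traj) else 1
  nn <- select_neighbors(traj, s, config, v_max = v_max)
  hs <- hull_metrics(build_hulls(traj, nn), ivg = config$ivg)
  iso <- build_isopleths(hs, levels = config$levels, sort_metric = config$sort_metric)
  attr(iso, "hullset") <- hs
  iso
}

#' Extract a core-foraging-area polygon from an isopleth set
#'
#' @param isopleths An `isopleth_set`.
#' @param level Isopleth level to extract (default 0.3).
#' @param species,individual Metadata labels attached to the polygon.
#' @return Object of class `cfa`: list with `rings`, `level`, `species`,
#'   `individual`, `area`.
#' @export
export_cfa <- function(isopleths, level = 0.3, species = NA_character_,
                       individual = NA_character_) {
  i <- match(level, isopleths$summary$level)
  if (is.na(i)) stop_fm("level ", level, " not present in isopleth set")
  structure(list(rings = isopleths$rings[[i]], level = level, species = species,
                 individual = individual, area = isopleths$summary$area[i]),
            class = "cfa")
}
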