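#' Configuration for a synthetic foraging trajectory
#'
#' Describes a biased correlated random walk that follows a fixed patch
#' itinerary, emulating an ungulate that alternates directed travel between
#' foraging patches with within-patch wandering. The itinerary cycles through
#' the patches, so every patch is revisited at regular intervals; revisitation
#' ground truth is therefore exact by construction rather than emergent.
#'
#' @param n_days Number of days of data (default 43, i.e. a six-week
#'   collaring window around an image acquisition).
#' @param fix_interval Fix interval in seconds (default 14400 = 4 h).
#' @param patches Data frame with columns `x`, `y` (patch centres, metres),
#'   `radius` (metres) and `weight` (relative attraction, currently used to
#'   order the itinerary). Defaults to four patches on a 1.2 km square.
#' @param step_scale Maximum displacement per fix interval in metres
#'   (default 250 m per 4 h; well below the 1.5 km/h screening threshold).
#' @param turn_concentration Concentration of turning angles (>= 0);
#'   larger values give straighter within-patch movement.
#' @param revisit_period Minimum separation in seconds between two visits to
#'   the same patch (default 86400 = 24 h).
#' @param seed Integer seed; the walk is deterministic given the seed.
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(n_days = 43,
                              fix_interval = 14400,
                              patches = NULL,
                              step_scale = 250,
                              turn_concentration = 2,
                              revisit_period = 86400,
                              seed = 1L) {
  if (!is_number(n_days) || n_days <= 0) stop_fm("n_days must be a positive number")
  if (!is_number(fix_interval) || fix_interval <= 0) stop_fm("fix_interval must be positive")
  if (is.null(patches)) {
    patches <- data.frame(
      x = c(0, 1200, 1200, 0),
      y = c(0, 0, 1200, 1200),
      radius = 150,
      weight = 1
    )
  }
  if (!is.data.frame(patches) || nrow(patches) < 1 ||
      !all(c("x", "y", "radius") %in% names(patches))) {
    stop_fm("patches must be a data frame with columns x, y, radius (>= 1 row)")
  }
  if (is.null(patches$weight)) patches$weight <- 1
  if (any(patches$radius <= 0)) stop_fm("patch radius must be positive")
  if (!is_number(step_scale) || step_scale < 0) stop_fm("step_scale must be >= 0")
  if (!is_number(turn_concentration) || turn_concentration < 0) {
    stop_fm("turn_concentration must be >= 0")
  }
  if (!is_number(revisit_period) || revisit_period <= 0) stop_fm("revisit_period must be positive")
  structure(list(n_days = n_days, fix_interval = fix_interval, patches = patches,
                 step_scale = step_scale, turn_concentration = turn_concentration,
                 revisit_period = revisit_period, seed = as.integer(seed)),
            class = "trajectory_config")
}

# Itinerary: one visit block per patch, cycled. The block length is chosen so
# that (i) travel between the two farthest patches fits inside a block with
# several dwell fixes to spare and (ii) consecutive visits to the same patch
# are separated by more than revisit_period.
patch_schedule <- function(config) {
  p <- config$patches
  np <- nrow(p)
  travel_steps <- if (np > 1 && config$step_scale > 0) {
    dmax <- max(stats::dist(cbind(p$x, p$y)))
    ceiling(dmax / config$step_scale)
  } else 0
  block <- max((travel_steps + 6) * config$fix_interval,
               if (np > 1) config$revisit_period / (np - 1) * 1.25 else config$fix_interval)
  block <- ceiling(block / config$fix_interval) * config$fix_interval
  total <- config$n_days * 86400
  if (np > 1 && total < 2 * np * block) {
    stop_fm("trajectory too short for two visits per patch: need >= ",
            2 * np * block / 86400, " days")
  }
  list(block = block, order = order(-p$weight, seq_len(np)))
}

#' Simulate a foraging trajectory with guaranteed patch revisitation
#'
#' Fixes fall on exact multiples of `fix_interval`. The animal heads towards
#' the scheduled patch when outside its radius (displacement capped at
#' `step_scale`) and wanders inside it otherwise, so the per-step speed never
#' exceeds `step_scale / fix_interval`.
#'
#' @param config A [trajectory_config()].
#' @param id Individual identifier stored in the `id` column.
#' @return A trajectory data frame with columns `id`, `t` (seconds, UTC),
#'   `x`, `y`, plus attributes `patches` and `schedule`.
#' @export
simulate_trajectory <- function(config, id = "ind1") {
  if (!inherits(config, "trajectory_config")) stop_fm("config must be a trajectory_config")
  sched <- patch_schedule(config)
  p <- config$patches
  np <- nrow(p)
  times <- seq(0, config$n_days * 86400, by = config$fix_interval)
  n <- length(times)
  with_seed(config$seed, {
    x <- numeric(n); y <- numeric(n)
    x[1] <- p$x[sched$order[1]]; y[1] <- p$y[sched$order[1]]
    heading <- stats::runif(1, 0, 2 * pi)
    turn_sd <- 1 / sqrt(config$turn_concentration + 0.25)
    for (i in seq_len(n - 1)) {
      blk <- floor(times[i] / sched$block)
      target <- sched$order[(blk %% np) + 1]
      cx <- p$x[target]; cy <- p$y[target]; rad <- p$radius[target]
      dxc <- cx - x[i]; dyc <- cy - y[i]
      dc <- sqrt(dxc^2 + dyc^2)
      if (dc > rad) {
        # directed travel with angular noise
        heading <- atan2(dyc, dxc) + stats::rnorm(1, 0, turn_sd * 0.3)
        step <- min(config$step_scale, dc)
      } else {
        # within-patch wander, correlated heading
        heading <- heading + stats::rnorm(1, 0, turn_sd)
        step <- config$step_scale * 0.4 * stats::runif(1)
      }
      nx <- x[i] + step * cos(heading)
      ny <- y[i] + step * sin(heading)
      if (dc <= rad) {
        # keep the wander inside the patch: retarget towards centre if leaving
        if (sqrt((nx - cx)^2 + (ny - cy)^2) > rad) {
          pull <- atan2(cy - y[i], cx - x[i]) + stats::rnorm(1, 0, 0.4)
          nx <- x[i] + step * cos(pull)
          ny <- y[i] + step * sin(pull)
          heading <- pull
        }
      }
      x[i + 1] <- nx; y[i + 1] <- ny
    }
    traj <- data.frame(id = id, t = times, x = x, y = y, stringsAsFactors = FALSE)
    attr(traj, "patches") <- p
    attr(traj, "schedule") <- sched
    check_trajectory(traj)
  })
}

#' Inject GPS spikes and outliers with known truth flags
#'
#' Spikes are out-and-back displacements of interior fixes large enough that
#' both implied speeds exceed 1.5 km/h and the turn cosine falls below -0.97;
#' outliers are single fixes moved more than 50 km from the trajectory median.
#' Injected records are marked in the returned truth table.
#'
#' @param traj Trajectory data frame (single individual, >= 5 fixes).
#' @param n_spikes,n_outliers Numbers of spikes / outliers to inject.
#' @param seed Integer seed.
#' @param spike_km Range (km) of spike displacements; the default (10, 30)
#'   exceeds the speed threshold at a 4 h interval but stays below the 50 km
#'   distance rule, so spikes are only detectable as turnarounds.
#' @param outlier_km Range (km) of outlier displacements from the median.
#' @return A list with elements `trajectory` (corrupted copy) and
#'   `truth` (data frame `index`, `type`).
#' @export
inject_gps_errors <- function(traj, n_spikes = 0, n_outliers = 0, seed = 1L,
                              spike_km = c(10, 30), outlier_km = c(80, 150)) {
  check_trajectory(traj, min_fixes = 5L)
  if (!is_count(n_spikes) || !is_count(n_outliers)) stop_fm("counts must be non-negative integers")
  n <- nrow(traj)
  # avoid the first/last 3 fixes: the truncated screening windows there hold
  # too few clean fixes for a robust median
  interior <- if (n >= 9) 4:(n - 3) else 2:(n - 1)
  need <- n_spikes + n_outliers
  if (need == 0) {
    return(list(trajectory = traj, truth = data.frame(index = integer(0), type = character(0))))
  }
  with_seed(seed, {
    # keep injected fixes at least 5 apart: each spike's neighbours stay clean
    # and no 20 h screening window ever contains two injected fixes
    chosen <- integer(0)
    pool <- interior
    for (k in seq_len(need)) {
      pool_ok <- pool[vapply(pool, function(i) all(abs(i - chosen) >= 5), logical(1))]
      if (length(pool_ok) == 0) stop_fm("requested errors exceed available interior fixes")
      pick <- if (length(pool_ok) == 1) pool_ok else sample(pool_ok, 1)
      chosen <- c(chosen, pick)
      pool <- setdiff(pool, pick)
    }
    types <- c(rep("spike", n_spikes), rep("outlier", n_outliers))
    out <- traj
    for (k in seq_len(need)) {
      i <- chosen[k]
      ang <- stats::runif(1, 0, 2 * pi)
      if (types[k] == "spike") {
        d <- stats::runif(1, spike_km[1], spike_km[2]) * 1000
        out$x[i] <- traj$x[i] + d * cos(ang)
        out$y[i] <- traj$y[i] + d * sin(ang)
      } else {
        d <- stats::runif(1, outlier_km[1], outlier_km[2]) * 1000
        medx <- stats::median(traj$x); medy <- stats::median(traj$y)
        out$x[i] <- medx + d * cos(ang)
        out$y[i] <- medy + d * sin(ang)
      }
    }
    truth <- data.frame(index = chosen, type = types, stringsAsFactors = FALSE)
    truth <- truth[order(truth$index), , drop = FALSE]
    rownames(truth) <- NULL
    list(trajectory = out, truth = truth)
  })
}
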