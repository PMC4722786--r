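# Fix preparation and two-stage location-error screening.

#' Screening parameters
#'
#' Defaults follow the published collar-screening settings: speed threshold
#' alpha = 1.5 km/h with turn cosine -0.97 for spikes, and distance limits
#' mu = 50 km (distance coverable within the 20 h window) and delta = 200 km
#' (distance impossible to cover) for the median rule.
#'
#' @param alpha Speed threshold in km/h.
#' @param cos_theta Turn-cosine threshold in [-1, 1].
#' @param mu Distance from the windowed median, km.
#' @param delta Distance from the overall median, km.
#' @param window Median window length in hours (centred).
#' @return Object of class `screening_params`.
#' @export
screening_params <- function(alpha = 1.5, cos_theta = -0.97, mu = 50,
                             delta = 200, window = 20) {
  if (!is_number(alpha) || alpha <= 0) stop_fm("alpha must be positive")
  if (!is_number(cos_theta) || cos_theta < -1 || cos_theta > 1) {
    stop_fm("cos_theta must lie in [-1, 1]")
  }
  if (!is_number(mu) || !is_number(delta) || !(delta > mu && mu > 0)) {
    stop_fm("need delta > mu > 0")
  }
  if (!is_number(window) || window <= 0) stop_fm("window must be positive")
  structure(list(alpha = alpha, cos_theta = cos_theta, mu = mu, delta = delta,
                 window = window), class = "screening_params")
}

#' Resample a trajectory to a common fix interval
#'
#' Keeps, for each grid time (multiples of `interval` from the first fix),
#' the fix nearest in time within half an interval. Already-regular data are
#' returned unchanged and the operation is idempotent.
#'
#' @param traj Trajectory data frame (single individual).
#' @param interval Target interval in seconds (default 14400 = 4 h).
#' @return The thinned trajectory.
#' @export
resample_fixes <- function(traj, interval = 14400) {
  check_trajectory(traj, min_fixes = 1L)
  if (!is_number(interval) || interval <= 0) stop_fm("interval must be positive")
  t0 <- traj$t[1]
  grid <- seq(t0, traj$t[nrow(traj)], by = interval)
  keep <- integer(0)
  for (g in grid) {
    j <- which.min(abs(traj$t - g))
    if (abs(traj$t[j] - g) <= interval / 2) keep <- c(keep, j)
  }
  keep <- sort(unique(keep))
  out <- traj[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove capture days and the first/last day of a record
#'
#' Drops all fixes on the UTC calendar day of each capture event, plus the
#' first and last calendar day of the record.
#'
#' @param traj Trajectory data frame.
#' @param capture_events Numeric timestamps (seconds) of capture events.
#' @return The trimmed trajectory; error if nothing remains.
#' @export
trim_capture_days <- function(traj, capture_events = numeric(0)) {
  check_trajectory(traj, min_fixes = 1L)
  day <- floor(traj$t / 86400)
  drop_days <- unique(c(day[1], day[length(day)], floor(capture_events / 86400)))
  out <- traj[!day %in% drop_days, , drop = FALSE]
  if (nrow(out) == 0) stop_fm("all fixes removed by day trimming")
  rownames(out) <- NULL
  out
}

#' Two-stage screening for unrealistic movement
#'
#' Stage 1 flags a fix when it lies farther than `mu` km from the median
#' location of the surrounding (centred, leave-one-out) time window, or
#' farther than `delta` km from the overall leave-one-out median. Stage 2
#' flags turnaround spikes: fixes whose incoming and outgoing speeds both
#' exceed `alpha` km/h while the cosine of the turning angle between the
#' incoming and outgoing displacement vectors falls below `cos_theta`.
#' Flagged fixes are retained (flags only); callers drop them.
#'
#' @param traj Trajectory data frame (single individual), ideally resampled.
#' @param params A [screening_params()].
#' @return Data frame of `nrow(traj)` rows: `flag_stage1`, `flag_stage2`,
#'   `flag` (either stage). With fewer than 3 fixes stage 2 is skipped with
#'   a warning.
#' @export
screen_errors <- function(traj, params = screening_params()) {
  check_trajectory(traj, min_fixes = 1L)
  n <- nrow(traj)
  half_w <- params$window * 3600 / 2
  flag1 <- logical(n)
  for (i in seq_len(n)) {
    others <- setdiff(which(abs(traj$t - traj$t[i]) <= half_w), i)
    med <- if (length(others) > 0) {
      c(stats::median(traj$x[others]), stats::median(traj$y[others]))
    } else {
      c(stats::median(traj$x[-i]), stats::median(traj$y[-i]))
    }
    d_win <- sqrt((traj$x[i] - med[1])^2 + (traj$y[i] - med[2])^2)
    gmed <- c(stats::median(traj$x[-i]), stats::median(traj$y[-i]))
    d_glob <- sqrt((traj$x[i] - gmed[1])^2 + (traj$y[i] - gmed[2])^2)
    flag1[i] <- d_win > params$mu * 1000 || d_glob > params$delta * 1000
  }
  flag2 <- logical(n)
  if (n < 3) {
    warning("fewer than 3 fixes: spike screening skipped")
  } else {
    alpha_ms <- params$alpha / 3.6
    for (i in 2:(n - 1)) {
      ax <- traj$x[i] - traj$x[i - 1]; ay <- traj$y[i] - traj$y[i - 1]
      bx <- traj$x[i + 1] - traj$x[i]; by <- traj$y[i + 1] - traj$y[i]
      v_in <- sqrt(ax^2 + ay^2) / (traj$t[i] - traj$t[i - 1])
      v_out <- sqrt(bx^2 + by^2) / (traj$t[i + 1] - traj$t[i])
      na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
      cth <- if (na > 0 && nb > 0) (ax * bx + ay * by) / (na * nb) else 1
      flag2[i] <- v_in > alpha_ms && v_out > alpha_ms && cth < params$cos_theta
    }
  }
  data.frame(flag_stage1 = flag1, flag_stage2 = flag2, flag = flag1 | flag2)
}

#' Collar location error from a stationary test
#'
#' For repeated fixes of a collar at a fixed site, returns
#' sqrt(sd(x)^2 + sd(y)^2) with sample (n-1) standard deviations, the
#' statistic reported for stationary collar accuracy tests.
#'
#' @param x,y Coordinate vectors (metres), or a data frame with `x`, `y`
#'   passed as `x`.
#' @return Location error in metres.
#' @export
location_error <- function(x, y = NULL) {
  if (is.data.frame(x)) { y <- x$y; x <- x$x }
  if (length(x) < 2 || length(y) != length(x)) {
    stop_fm("need >= 2 paired fixes from a stationary collar")
  }
  sqrt(stats::sd(x)^2 + stats::sd(y)^2)
}
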