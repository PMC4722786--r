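# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are
#' deterministic without clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# abort with a consistent error class so pipeline stages can be identified
stop_fm <- function(..., class = "foragemap_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

#' Validate a trajectory data frame
#'
#' A trajectory is a data frame with columns `id` (character), `t`
#' (numeric seconds, UTC, strictly increasing within an individual),
#' `x` and `y` (planar metres).
#' @noRd
check_trajectory <- function(traj, min_fixes = 1L) {
  if (!is.data.frame(traj) || !all(c("id", "t", "x", "y") %in% names(traj))) {
    stop_fm("trajectory must be a data frame with columns id, t, x, y")
  }
  if (nrow(traj) < min_fixes) {
    stop_fm("trajectory has ", nrow(traj), " fixes; at least ", min_fixes, " required")
  }
  if (!all(is.finite(traj$t)) || !all(is.finite(traj$x)) || !all(is.finite(traj$y))) {
    stop_fm("trajectory contains non-finite timestamps or coordinates")
  }
  for (ind in unique(traj$id)) {
    ti <- traj$t[traj$id == ind]
    if (any(diff(ti) <= 0)) stop_fm("timestamps not strictly increasing for individual ", ind)
  }
  invisible(traj)
}

# format numeric UTC seconds as ISO-8601
iso8601 <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
}

parse_iso8601 <- function(s) {
  as.numeric(as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}
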