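# Simple-ratio-index regression of forage quantity/quality, leave-one-out
# validation, linear spectral unmixing and resource-raster prediction.

#' Mean reflectance over a 3 x 3 pixel window around a plot centre
#'
#' @param cube Reflectance array (rows x cols x bands) or a `scene`.
#' @param centre Numeric `c(x, y)` plot centre in map units.
#' @param origin,res Grid origin (lower-left corner) and cell size; taken
#'   from the scene when a `scene` is supplied.
#' @param window Odd window edge length (default 3).
#' @return Mean spectrum (numeric vector, one value per band).
#' @export
aggregate_plot_reflectance <- function(cube, centre, origin = c(0, 0), res = 2,
                                       window = 3) {
  if (inherits(cube, "scene")) {
    origin <- cube$origin; res <- cube$res; cube <- cube$reflectance
  }
  half <- (window - 1) / 2
  col <- floor((centre[1] - origin[1]) / res) + 1
  row <- floor((centre[2] - origin[2]) / res) + 1
  nr <- dim(cube)[1]; nc <- dim(cube)[2]
  if (row - half < 1 || row + half > nr || col - half < 1 || col + half > nc) {
    stop_fm("plot window extends beyond the cube grid")
  }
  apply(cube[(row - half):(row + half), (col - half):(col + half), , drop = FALSE],
        3, mean)
}

#' Rank all simple ratio indices by squared correlation with a response
#'
#' Every ordered band pair (i, j), i != j, with strictly positive
#' denominator reflectance across all plots is a candidate; candidates are
#' ranked by the squared Pearson correlation between band_i/band_j and the
#' response. Ties are broken by ascending (i, j).
#'
#' @param plots A [sample_plots()]-style data frame.
#' @param response `"biomass"` or `"nitrogen"` (any numeric plot column).
#' @param top_n Number of top pairs to return (default 100, the published
#'   shortlist size).
#' @return Data frame `i`, `j`, `r2`, best first; attribute `n_excluded`
#'   counts pairs dropped for non-positive denominators.
#' @export
rank_sri <- function(plots, response, top_n = 100) {
  S <- plot_spectra(plots)
  y <- plots[[response]]
  if (is.null(y)) stop_fm("response column '", response, "' not found")
  if (nrow(S) < 4) stop_fm("need at least 4 plots")
  if (stats::sd(y) == 0) stop_fm("response has zero variance")
  nb <- ncol(S)
  pos <- apply(S > 0, 2, all)
  res <- expand.grid(i = seq_len(nb), j = seq_len(nb))
  res <- res[res$i != res$j, ]
  keep <- pos[res$j]
  n_excluded <- sum(!keep)
  res <- res[keep, ]
  res$r2 <- vapply(seq_len(nrow(res)), function(k) {
    sri <- S[, res$i[k]] / S[, res$j[k]]
    if (stats::sd(sri) == 0) return(0)
    stats::cor(sri, y)^2
  }, numeric(1))
  res <- res[order(-res$r2, res$i, res$j), ]
  res <- utils::head(res, top_n)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  res
}

# damped Gauss-Newton for y = b0 * exp(b1 * x), started from the log-linear fit
fit_exponential <- function(x, y, start = NULL, max_iter = 50, tol = 1e-12) {
  if (is.null(start)) {
    lf <- stats::lm.fit(cbind(1, x), log(y))
    start <- c(exp(lf$coefficients[1]), lf$coefficients[2])
  }
  b <- unname(start)
  f <- b[1] * exp(b[2] * x)
  rss <- sum((y - f)^2)
  for (it in seq_len(max_iter)) {
    e <- exp(b[2] * x)
    J <- cbind(e, b[1] * x * e)
    r <- y - b[1] * e
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)), error = function(cnd) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      bn <- b + lambda * as.numeric(step)
      rss_n <- sum((y - bn[1] * exp(bn[2] * x))^2)
      if (rss_n <= rss || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (!is.finite(rss_n) || rss - rss_n < tol * (rss + 1e-300)) {
      if (is.finite(rss_n) && rss_n < rss) { b <- bn; rss <- rss_n }
      break
    }
    b <- bn; rss <- rss_n
  }
  list(coef = c(b0 = b[1], b1 = b[2]), fitted = b[1] * exp(b[2] * x), rss = rss)
}

fit_form <- function(x, y, form) {
  n <- length(y)
  switch(form,
    linear = {
      X <- cbind(1, x)
      qrX <- qr(X)
      if (qrX$rank < 2) stop_fm("singular design for linear fit")
      cf <- qr.coef(qrX, y)
      list(coef = c(b0 = cf[1], b1 = cf[2]), fitted = as.numeric(X %*% cf), n_coef = 2L)
    },
    exponential = {
      if (any(y <= 0)) return(NULL)
      fit <- fit_exponential(x, y)
      c(fit, list(n_coef = 2L))
    },
    polynomial2 = {
      X <- cbind(1, x, x^2)
      qrX <- qr(X)
      if (qrX$rank < 3) stop_fm("singular design for polynomial fit")
      cf <- qr.coef(qrX, y)
      list(coef = c(b0 = cf[1], b1 = cf[2], b2 = cf[3]),
           fitted = as.numeric(X %*% cf), n_coef = 3L)
    },
    stop_fm("unknown form: ", form)
  )
}

predict_form <- function(form, coef, x) {
  relation_apply(list(form = form, coef = unname(coef)), x)
}

#' Fit one SRI candidate model, optionally with leave-one-out validation
#'
#' Functional forms: linear `y = b0 + b1 x`, exponential `y = b0 exp(b1 x)`
#' (nonlinear least squares started from the log-linear fit), and second
#' order polynomial. AIC is the Gaussian criterion
#' `n log(RSS/n) + 2 (p + 1)` on the full fit; leave-one-out predictions
#' are obtained by actually refitting on each n-1 subset.
#'
#' @param plots Plot table.
#' @param pair Integer `c(i, j)` band pair (SRI = band i / band j).
#' @param response Response column name.
#' @param form `"linear"`, `"exponential"` or `"polynomial2"`.
#' @param loocv Compute leave-one-out predictions (default TRUE).
#' @return Object of class `sri_model` (or NULL with a warning when the
#'   exponential form is requested for non-positive responses).
#' @export
fit_candidate <- function(plots, pair, response, form, loocv = TRUE) {
  S <- plot_spectra(plots)
  y <- plots[[response]]
  n <- length(y)
  x <- S[, pair[1]] / S[, pair[2]]
  if (any(!is.finite(x))) stop_fm("non-finite SRI values for pair (", pair[1], ",", pair[2], ")")
  fit <- fit_form(x, y, form)
  if (is.null(fit)) {
    warning("exponential form skipped: response contains non-positive values")
    return(NULL)
  }
  if (n < fit$n_coef + 2) stop_fm("need at least ", fit$n_coef + 2, " plots for form ", form)
  rss <- sum((y - fit$fitted)^2)
  aic <- n * log(rss / n) + 2 * (fit$n_coef + 1)
  loocv_pred <- NULL
  if (loocv) {
    loocv_pred <- vapply(seq_len(n), function(i) {
      f <- fit_form(x[-i], y[-i], form)
      if (is.null(f)) return(NA_real_)
      predict_form(form, f$coef, x[i])
    }, numeric(1))
  }
  structure(list(response = response, pair = pair, form = form,
                 coef = fit$coef, n_coef = fit$n_coef, n = n,
                 observed = y, fitted = fit$fitted, rss = rss, aic = aic,
                 loocv_pred = loocv_pred,
                 stats = if (loocv) evaluate_fit(y, loocv_pred, n_coef = fit$n_coef) else NULL),
            class = "sri_model")
}

#' Theil's uncertainty coefficient
#'
#' U = RMSE(p, o) / (RMS(o) + RMS(p)), in [0, 1]; 0 iff the series are
#' identical, 1 for maximal disagreement (e.g. p = -o). Invariant to a
#' common positive rescaling of both series.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 values).
#' @return Scalar U.
#' @export
theils_u <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop_fm("need equal-length vectors of at least 2 values")
  }
  den <- sqrt(mean(observed^2)) + sqrt(mean(predicted^2))
  if (den == 0) stop_fm("Theil's U undefined for all-zero observed and predicted")
  sqrt(mean((predicted - observed)^2)) / den
}

#' Predictive fit statistics from leave-one-out predictions
#'
#' RMSE of prediction, the percentage of samples predicted within less than
#' 20% of that RMSE (absolute leave-one-out error < 0.2 RMSE; set
#' `pct_mode = "observed"` for the alternative error < 20% of the observed
#' value), Theil's U, and the adjusted squared correlation between observed
#' and predicted.
#'
#' @param observed Observed responses.
#' @param predicted Leave-one-out predictions.
#' @param n_coef Number of model coefficients (for the adjustment).
#' @param pct_mode `"rmse"` (default) or `"observed"`.
#' @return List: `rmse`, `pct_within_20pct_rmse`, `theils_u`, `adj_r2`,
#'   `degenerate` flag (TRUE when predictions are constant).
#' @export
evaluate_fit <- function(observed, predicted, n_coef = 2L, pct_mode = c("rmse", "observed")) {
  pct_mode <- match.arg(pct_mode)
  if (length(observed) != length(predicted)) stop_fm("length mismatch")
  err <- predicted - observed
  rmse <- sqrt(mean(err^2))
  pct <- if (pct_mode == "rmse") {
    100 * mean(abs(err) < 0.2 * rmse)
  } else {
    100 * mean(abs(err) < 0.2 * abs(observed))
  }
  n <- length(observed)
  degenerate <- stats::sd(predicted) == 0 || stats::sd(observed) == 0
  adj_r2 <- if (degenerate) 0 else {
    r2 <- stats::cor(observed, predicted)^2
    1 - (1 - r2) * (n - 1) / (n - n_coef)
  }
  list(rmse = rmse, pct_within_20pct_rmse = pct, theils_u = theils_u(observed, predicted),
       adj_r2 = adj_r2, degenerate = degenerate)
}

#' Select the best SRI model by AIC
#'
#' Minimum AIC wins; AIC ties are broken by lower Theil's U, then fewer
#' coefficients.
#' @param models List of `sri_model` objects (NULLs are dropped).
#' @return The winning `sri_model`.
#' @export
select_best <- function(models) {
  models <- Filter(Negate(is.null), models)
  if (length(models) == 0) stop_fm("empty candidate set")
  aic <- vapply(models, `[[`, numeric(1), "aic")
  best_aic <- min(aic)
  tied <- which(aic <= best_aic + 1e-8)
  if (length(tied) > 1) {
    u <- vapply(models[tied], function(m) {
      if (!is.null(m$stats)) m$stats$theils_u else theils_u(m$observed, m$fitted)
    }, numeric(1))
    nc <- vapply(models[tied], `[[`, integer(1), "n_coef")
    tied <- tied[order(u, nc)]
  }
  models[[tied[1]]]
}

#' Full SRI model search for one response
#'
#' Ranks all band pairs by squared correlation, keeps the `top_n` best,
#' fits every candidate form to each, and selects the minimum-AIC model.
#' Leave-one-out statistics are computed for the selected model (and for
#' AIC-tied candidates, whose tie is broken by Theil's U); set
#' `loocv = "all"` to validate every candidate.
#'
#' @param plots Plot table.
#' @param response `"biomass"` or `"nitrogen"`.
#' @param top_n Shortlist size (default 100).
#' @param forms Candidate functional forms.
#' @param loocv `"best"` (default) or `"all"`.
#' @return The selected `sri_model` with leave-one-out `stats`; the ranked
#'   pair list is attached as attribute `ranking`.
#' @export
fit_sri_models <- function(plots, response, top_n = 100,
                           forms = c("linear", "exponential", "polynomial2"),
                           loocv = c("best", "all")) {
  loocv <- match.arg(loocv)
  ranked <- rank_sri(plots, response, top_n = top_n)
  cands <- list()
  for (k in seq_len(nrow(ranked))) {
    for (fm in forms) {
      m <- withCallingHandlers(
        fit_candidate(plots, c(ranked$i[k], ranked$j[k]), response, fm,
                      loocv = (loocv == "all")),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!is.null(m)) cands[[length(cands) + 1]] <- m
    }
  }
  if (length(cands) == 0) stop_fm("no fittable SRI candidates")
  if (loocv == "best") {
    aic <- vapply(cands, `[[`, numeric(1), "aic")
    tied <- which(aic <= min(aic) + 1e-8)
    for (ti in tied) {
      m <- cands[[ti]]
      cands[[ti]] <- fit_candidate(plots, m$pair, response, m$form, loocv = TRUE)
    }
  }
  best <- select_best(cands)
  if (is.null(best$stats)) {
    best <- fit_candidate(plots, best$pair, response, best$form, loocv = TRUE)
  }
  attr(best, "ranking") <- ranked
  best
}

#' Fully constrained linear spectral unmixing with a dominance mask
#'
#' Per cell, endmember fractions minimise the squared spectral residual
#' subject to non-negativity and sum-to-one. The solver enumerates active
#' sets (exact for small libraries): for every non-empty endmember subset
#' the equality-constrained least-squares solution is computed in closed
#' form and the feasible solution with the smallest residual is kept. The
#' grass mask is `grass fraction >= threshold` (boundary included).
#'
#' @param cube Reflectance array (rows x cols x bands) or a `scene`.
#' @param library An [endmember_library()] (endmembers x bands).
#' @param threshold Dominance threshold for the mask (default 0.5).
#' @return List: `fractions` (rows x cols x endmembers), `mask` (logical
#'   matrix, TRUE = grass-dominated), `residual` (matrix of per-cell
#'   residual sums of squares).
#' @export
unmix_lsu <- function(cube, library, threshold = 0.5) {
  if (inherits(cube, "scene")) cube <- cube$reflectance
  E <- unclass(library)
  K <- nrow(E); nb <- ncol(E)
  if (dim(cube)[3] != nb) stop_fm("cube band count does not match the library")
  if (nb < K) stop_fm("need at least as many bands as endmembers")
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    if (abs(stats::cor(E[a, ], E[b, ])) > 0.99999) {
      stop_fm("collinear endmember spectra: ", rownames(E)[a], " and ", rownames(E)[b])
    }
  }
  nr <- dim(cube)[1]; nc <- dim(cube)[2]
  R <- matrix(cube, nr * nc, nb)  # cells x bands
  ncell <- nrow(R)
  best_res <- rep(Inf, ncell)
  best_F <- matrix(0, ncell, K)
  for (mask_bits in 1:(2^K - 1)) {
    S <- which(bitwAnd(mask_bits, 2^(seq_len(K) - 1)) > 0)
    k <- length(S)
    Es <- E[S, , drop = FALSE]
    G <- tcrossprod(Es)
    M <- rbind(cbind(2 * G, 1), c(rep(1, k), 0))
    sol <- tryCatch(solve(M, rbind(2 * Es %*% t(R), 1)), error = function(cnd) NULL)
    if (is.null(sol)) next
    Fs <- sol[seq_len(k), , drop = FALSE]  # k x cells
    feasible <- colSums(Fs < -1e-9) == 0
    if (!any(feasible)) next
    resid <- colSums((crossprod(Es, Fs) - t(R))^2)
    improve <- feasible & resid < best_res - 1e-12
    if (any(improve)) {
      best_res[improve] <- resid[improve]
      best_F[improve, ] <- 0
      best_F[improve, S] <- t(Fs[, improve, drop = FALSE])
    }
  }
  best_F[best_F < 0] <- 0
  fractions <- array(best_F, dim = c(nr, nc, K), dimnames = list(NULL, NULL, rownames(E)))
  g <- match("grass", rownames(E))
  mask <- matrix(best_F[, g] >= threshold - 1e-9, nr, nc)
  list(fractions = fractions, mask = mask, residual = matrix(best_res, nr, nc))
}

#' Predict a resource layer from a fitted SRI model
#'
#' Applies the model to each masked-in cell's band ratio; masked-out cells
#' become NA and predictions are floor-clipped at zero.
#'
#' @param model An `sri_model`.
#' @param cube Reflectance array or `scene`.
#' @param mask Logical matrix (TRUE = predict); NULL predicts everywhere.
#' @param origin,res Grid metadata (taken from a `scene` input).
#' @return Object of class `resource_layer`: `values` matrix, `response`,
#'   `mask`, `origin`, `res`.
#' @export
predict_raster <- function(model, cube, mask = NULL, origin = c(0, 0), res = 2) {
  if (inherits(cube, "scene")) {
    origin <- cube$origin; res <- cube$res; cube <- cube$reflectance
  }
  nb <- dim(cube)[3]
  if (any(model$pair > nb)) stop_fm("model band pair outside cube")
  num <- cube[, , model$pair[1]]
  den <- cube[, , model$pair[2]]
  sri <- num / den
  sri[!is.finite(sri)] <- NA
  vals <- predict_form(model$form, model$coef, sri)
  vals[vals < 0] <- 0
  if (!is.null(mask)) vals[!mask] <- NA
  structure(list(values = vals, response = model$response, mask = mask,
                 origin = origin, res = res),
            class = "resource_layer")
}

#' Combine biomass and nitrogen layers into a resource raster
#'
#' @param biomass_model,nitrogen_model Fitted `sri_model`s.
#' @param cube Reflectance array or `scene`.
#' @param mask Grass mask from [unmix_lsu()].
#' @return Object of class `resource_raster`: `biomass`, `nitrogen`
#'   matrices, `mask`, `origin`, `res`.
#' @export
build_resource_raster <- function(biomass_model, nitrogen_model, cube, mask = NULL) {
  bl <- predict_raster(biomass_model, cube, mask)
  nl <- predict_raster(nitrogen_model, cube, mask)
  structure(list(biomass = bl$values, nitrogen = nl$values, mask = mask,
                 origin = bl$origin, res = bl$res),
            class = "resource_raster")
}
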