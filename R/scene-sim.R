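# Synthetic hyperspectral grassland scenes with planted ground truth.
#
# A scene is a reflectance cube over a 2 m grid in which two band ratios
# carry, exactly and before mixing/noise, the configured biomass and
# nitrogen relations. Non-grass endmembers (forest, rock, snow, water) are
# mixed in spatially coherent blobs, and per-band smooth variation plus
# white sensor noise corrupt all other ratios, so the planted pairs are
# identifiable but not trivially so.

ENDMEMBER_LABELS <- c("grass", "forest", "rock", "snow", "water")

# smooth synthetic reflectance curves (wavelength in nm)
endmember_curve <- function(label, wl) {
  switch(label,
    grass  = 0.04 + 0.06 * exp(-((wl - 550) / 45)^2) +
             0.45 * stats::plogis((wl - 715) / 25) * exp(-((wl - 1100) / 1600)^2),
    forest = 0.03 + 0.28 * stats::plogis((wl - 720) / 30) * exp(-((wl - 1000) / 1500)^2),
    rock   = 0.12 + 1e-4 * (wl - 400),
    snow   = 0.05 + 0.90 * exp(-((wl - 400) / 1400)^2),
    water  = 0.005 + 0.08 * exp(-(wl - 400) / 300),
    stop_fm("unknown endmember label: ", label)
  )
}

#' Endmember spectral library
#'
#' @param wavelengths Band-centre wavelengths in nm.
#' @param labels Endmember labels; defaults to grass, forest, rock, snow, water.
#' @return Matrix (endmembers x bands) with row names, class `endmember_library`.
#' @export
endmember_library <- function(wavelengths, labels = ENDMEMBER_LABELS) {
  spectra <- t(vapply(labels, endmember_curve, numeric(length(wavelengths)), wl = wavelengths))
  structure(spectra, wavelengths = wavelengths, class = c("endmember_library", "matrix"))
}

# Gaussian-smoothed white noise, standardised to sample mean 0 / sd 1.
# corr_cells is the kernel sd in cells; reflection padding avoids edge bias.
smooth_field <- function(nr, nc, corr_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_cells >= 0.5) {
    half <- max(1L, ceiling(3 * corr_cells))
    k <- stats::dnorm(seq(-half, half), sd = corr_cells)
    k <- k / sum(k)
    smooth_vec <- function(x) {
      n <- length(x)
      # symmetric extension long enough for any kernel half-width
      ext <- x
      while (length(ext) < n + 2 * half) ext <- c(rev(x), ext, rev(x))
      start <- (length(ext) - n) %/% 2
      xp <- ext[(start - half + 1):(start + n + half)]
      y <- stats::filter(xp, k, sides = 2)
      as.numeric(y[(half + 1):(half + n)])
    }
    z <- apply(z, 2, smooth_vec)
    z <- t(apply(z, 1, smooth_vec))
  }
  (z - mean(z)) / stats::sd(z)
}

relation_apply <- function(relation, x) {
  cf <- relation$coef
  switch(relation$form,
    linear      = cf[1] + cf[2] * x,
    exponential = cf[1] * exp(cf[2] * x),
    polynomial2 = cf[1] + cf[2] * x + cf[3] * x^2,
    stop_fm("unknown relation form: ", relation$form)
  )
}

# inverse on the increasing branch; errors name the offending coefficients
relation_invert <- function(relation, y) {
  cf <- relation$coef
  bad <- function() {
    stop_fm("relation ", relation$form, " with coefficients (",
            paste(signif(cf, 6), collapse = ", "),
            ") produces a non-positive or undefined band ratio")
  }
  x <- switch(relation$form,
    linear = (y - cf[1]) / cf[2],
    exponential = {
      if (cf[1] <= 0 || any(y <= 0)) bad()
      log(y / cf[1]) / cf[2]
    },
    polynomial2 = {
      disc <- cf[2]^2 - 4 * cf[3] * (cf[1] - y)
      if (any(disc < 0)) bad()
      r1 <- (-cf[2] + sqrt(disc)) / (2 * cf[3])
      r2 <- (-cf[2] - sqrt(disc)) / (2 * cf[3])
      if (cf[3] < 0) pmin(r1, r2) else pmax(r1, r2)
    },
    stop_fm("unknown relation form: ", relation$form)
  )
  if (any(!is.finite(x)) || any(x <= 0)) bad()
  x
}

#' Configuration for a synthetic hyperspectral scene
#'
#' Defaults reproduce the resource statistics of the study valley
#' (fresh-weight biomass mean 295.26, SD 230.10 g m^-2; nitrogen mean 2.11,
#' SD 0.53 %) on a 2 m grid. The biomass-ratio relation is exponential with
#' a large dynamic range and the nitrogen relation an increasing concave
#' quadratic, giving both strong, distinguishable curvature.
#'
#' @param n_rows,n_cols Grid size (2 m cells).
#' @param n_bands Number of spectral bands (wavelengths spread 400-2400 nm).
#' @param biomass_field,n_field Lists with `mean`, `sd` and `corr_length`
#'   (metres) describing the spatial truth fields. Biomass is generated
#'   lognormal (positive support), nitrogen Gaussian clipped to [0.3, 4.3].
#' @param biomass_band_pair,n_band_pair Planted (numerator, denominator)
#'   band indices; the two pairs must be disjoint. Defaults pick bands
#'   nearest 883/676 nm (biomass) and 1159/1021 nm (nitrogen).
#' @param biomass_relation,n_relation Lists with `form` (one of `linear`,
#'   `exponential`, `polynomial2`) and `coef`.
#' @param noise_sd Additive reflectance noise SD (reflectance units).
#' @param band_variation_sd Relative SD of smooth per-band reflectance
#'   variation (degrades non-planted ratios).
#' @param brightness_sd Relative SD of a common brightness field (cancels in
#'   all ratios).
#' @param nongrass_threshold Threshold on the standardised blob fields above
#'   which forest/rock/snow/water weight accrues; higher = more grass.
#' @param res Cell size in metres.
#' @param seed Integer seed.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(n_rows = 100, n_cols = 100, n_bands = 30,
                         biomass_field = list(mean = 295.26, sd = 230.10, corr_length = 30),
                         n_field = list(mean = 2.11, sd = 0.53, corr_length = 30),
                         biomass_band_pair = NULL, n_band_pair = NULL,
                         biomass_relation = list(form = "exponential", coef = c(4, 3)),
                         n_relation = list(form = "polynomial2", coef = c(-0.4, 5.2, -1.4)),
                         noise_sd = 0.01, band_variation_sd = 0.08,
                         brightness_sd = 0.12, nongrass_threshold = 1.2,
                         res = 2, seed = 1L) {
  if (!is_count(n_rows) || !is_count(n_cols) || n_rows < 4 || n_cols < 4) {
    stop_fm("scene must be at least 4 x 4 cells")
  }
  if (!is_count(n_bands) || n_bands < 4) stop_fm("need at least 4 bands")
  wl <- seq(400, 2400, length.out = n_bands)
  used <- integer(0)
  nearest_band <- function(target) {
    free <- setdiff(seq_len(n_bands), used)
    b <- free[which.min(abs(wl[free] - target))]
    used <<- c(used, b)
    b
  }
  if (is.null(biomass_band_pair)) {
    biomass_band_pair <- c(nearest_band(883), nearest_band(676))
  } else used <- biomass_band_pair
  if (is.null(n_band_pair)) n_band_pair <- c(nearest_band(1159), nearest_band(1021))
  check_pair <- function(p, nm) {
    if (length(p) != 2 || !all(p %in% seq_len(n_bands)) || p[1] == p[2]) {
      stop_fm(nm, " must be two distinct band indices in 1..", n_bands)
    }
  }
  check_pair(biomass_band_pair, "biomass_band_pair")
  check_pair(n_band_pair, "n_band_pair")
  if (length(intersect(biomass_band_pair, n_band_pair)) > 0) {
    stop_fm("biomass and nitrogen band pairs must be disjoint")
  }
  if (!is_number(noise_sd) || noise_sd < 0) stop_fm("noise_sd must be >= 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, n_bands = n_bands,
                 wavelengths = wl,
                 biomass_field = biomass_field, n_field = n_field,
                 biomass_band_pair = biomass_band_pair, n_band_pair = n_band_pair,
                 biomass_relation = biomass_relation, n_relation = n_relation,
                 noise_sd = noise_sd, band_variation_sd = band_variation_sd,
                 brightness_sd = brightness_sd, nongrass_threshold = nongrass_threshold,
                 res = res, seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate a synthetic scene with known ground truth
#'
#' Grass-cell reflectance is constructed so that, before endmember mixing and
#' sensor noise, the planted numerator/denominator ratio equals the inverse
#' of the configured biomass (and nitrogen) relation exactly. Per-cell
#' endmember fractions lie on the unit simplex and the cube is non-negative.
#'
#' @param config A [scene_config()].
#' @return Object of class `scene`: reflectance array (rows x cols x bands),
#'   `grass_reflectance` (pre-mixing grass spectra), `fractions`
#'   (rows x cols x 5), truth matrices `biomass` and `nitrogen`, the
#'   endmember library, wavelengths, grid origin/res and the config.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) stop_fm("config must be a scene_config")
  nr <- config$n_rows; nc <- config$n_cols; nb <- config$n_bands
  wl <- config$wavelengths
  lib <- endmember_library(wl)
  with_seed(config$seed, {
    corr_b <- config$biomass_field$corr_length / config$res
    corr_n <- config$n_field$corr_length / config$res

    # biomass: lognormal transform of a smooth Gaussian field, affinely
    # rescaled so sample mean/sd match the configuration exactly
    zb <- smooth_field(nr, nc, corr_b)
    m <- config$biomass_field$mean; s <- config$biomass_field$sd
    sig2 <- log(1 + (s / m)^2)
    raw <- exp(log(m) - sig2 / 2 + sqrt(sig2) * zb)
    biomass <- m + (raw - mean(raw)) / stats::sd(raw) * s
    # keep the field inside the invertible range of the planted relation
    b_floor <- if (config$biomass_relation$form == "exponential") {
      1.15 * config$biomass_relation$coef[1]
    } else 1
    biomass[biomass < b_floor] <- b_floor

    zn <- smooth_field(nr, nc, corr_n)
    nitrogen <- config$n_field$mean + config$n_field$sd * zn
    n_hi <- 4.3
    if (config$n_relation$form == "polynomial2" && config$n_relation$coef[3] < 0) {
      cf <- config$n_relation$coef
      n_hi <- min(n_hi, cf[1] - cf[2]^2 / (4 * cf[3]) - 1e-3)
    }
    nitrogen[nitrogen < 0.3] <- 0.3
    nitrogen[nitrogen > n_hi] <- n_hi

    sri_b <- relation_invert(config$biomass_relation, biomass)
    sri_n <- relation_invert(config$n_relation, nitrogen)

    brightness <- 1 + config$brightness_sd * smooth_field(nr, nc, corr_b)
    brightness[brightness < 0.5] <- 0.5

    grass <- array(0, dim = c(nr, nc, nb))
    for (b in seq_len(nb)) {
      v <- 1 + config$band_variation_sd * smooth_field(nr, nc, corr_b)
      v[v < 0.2] <- 0.2
      grass[, , b] <- lib["grass", b] * brightness * v
    }
    ib <- config$biomass_band_pair[1]; jb <- config$biomass_band_pair[2]
    in_ <- config$n_band_pair[1]; jn <- config$n_band_pair[2]
    grass[, , ib] <- sri_b * grass[, , jb]
    grass[, , in_] <- sri_n * grass[, , jn]

    # endmember fraction blobs: quadratic weight above a threshold of a
    # smooth field per non-grass class; grass gets a constant floor weight
    wsum <- matrix(0.35, nr, nc)
    wts <- list(grass = matrix(0.35, nr, nc))
    for (k in ENDMEMBER_LABELS[-1]) {
      u <- smooth_field(nr, nc, 1.5 * corr_b)
      w <- pmax(0, u - config$nongrass_threshold)^2
      wts[[k]] <- w
      wsum <- wsum + w
    }
    fractions <- array(0, dim = c(nr, nc, length(ENDMEMBER_LABELS)),
                       dimnames = list(NULL, NULL, ENDMEMBER_LABELS))
    for (k in ENDMEMBER_LABELS) fractions[, , k] <- wts[[k]] / wsum

    reflectance <- array(0, dim = c(nr, nc, nb))
    for (b in seq_len(nb)) {
      rb <- fractions[, , "grass"] * grass[, , b]
      for (k in ENDMEMBER_LABELS[-1]) rb <- rb + fractions[, , k] * lib[k, b]
      if (config$noise_sd > 0) rb <- rb + stats::rnorm(nr * nc, sd = config$noise_sd)
      rb[rb < 0] <- 0
      reflectance[, , b] <- rb
    }

    structure(list(reflectance = reflectance, grass_reflectance = grass,
                   fractions = fractions, biomass = biomass, nitrogen = nitrogen,
                   endmembers = lib, wavelengths = wl,
                   origin = c(0, 0), res = config$res, config = config),
              class = "scene")
  })
}

# centre coordinates of cell (row, col); origin is the lower-left corner and
# y grows with row index
cell_centre <- function(origin, res, row, col) {
  cbind(x = origin[1] + (col - 0.5) * res, y = origin[2] + (row - 0.5) * res)
}

#' Sample ground-truth plots from a scene
#'
#' Emulates field plots harvested under an airborne acquisition: each plot is
#' a `window` x `window` block of pure-grass cells; the record holds the
#' arithmetic mean spectrum over the block and the block means of true
#' biomass and nitrogen.
#'
#' @param scene A [generate_scene()] result.
#' @param n_plots Number of plots (the study years used 51 to 100).
#' @param seed Integer seed.
#' @param window Odd block edge length in cells; default 3 (a 6 m plot of
#'   2 m pixels). `window = 1` gives single-cell records.
#' @return Data frame with plot id, centre row/col and x/y, band columns
#'   `b01`... and truth columns `biomass`, `nitrogen`.
#' @export
sample_plots <- function(scene, n_plots = 51, seed = 1L, window = 3) {
  if (!inherits(scene, "scene")) stop_fm("scene must be a scene object")
  if (!is_count(n_plots) || n_plots < 1) stop_fm("n_plots must be a positive integer")
  if (!is_count(window) || window %% 2 != 1) stop_fm("window must be odd")
  half <- (window - 1) / 2
  nr <- dim(scene$reflectance)[1]; nc <- dim(scene$reflectance)[2]
  grass_pure <- scene$fractions[, , "grass"] >= 1 - 1e-9
  ok <- matrix(FALSE, nr, nc)
  rows <- (1 + half):(nr - half); cols <- (1 + half):(nc - half)
  for (r in rows) for (cl in cols) {
    ok[r, cl] <- all(grass_pure[(r - half):(r + half), (cl - half):(cl + half)])
  }
  cand <- which(ok, arr.ind = TRUE)
  if (nrow(cand) < n_plots) {
    stop_fm("scene too small or too little pure grass for ", n_plots, " plots (",
            nrow(cand), " candidate centres)")
  }
  with_seed(seed, {
    # greedy thinning so plot windows do not overlap
    perm <- sample(nrow(cand))
    chosen <- matrix(NA_integer_, 0, 2)
    for (i in perm) {
      rc <- cand[i, ]
      if (nrow(chosen) == 0 ||
          all(pmax(abs(chosen[, 1] - rc[1]), abs(chosen[, 2] - rc[2])) >= window)) {
        chosen <- rbind(chosen, rc)
        if (nrow(chosen) == n_plots) break
      }
    }
    if (nrow(chosen) < n_plots) {
      stop_fm("could not place ", n_plots, " non-overlapping plots")
    }
    nb <- dim(scene$reflectance)[3]
    spec <- matrix(0, n_plots, nb)
    biom <- numeric(n_plots); nitr <- numeric(n_plots)
    for (p in seq_len(n_plots)) {
      r <- chosen[p, 1]; cl <- chosen[p, 2]
      rr <- (r - half):(r + half); cc <- (cl - half):(cl + half)
      spec[p, ] <- apply(scene$reflectance[rr, cc, , drop = FALSE], 3, mean)
      biom[p] <- mean(scene$biomass[rr, cc])
      nitr[p] <- mean(scene$nitrogen[rr, cc])
    }
    colnames(spec) <- sprintf("b%02d", seq_len(nb))
    ctr <- cell_centre(scene$origin, scene$res, chosen[, 1], chosen[, 2])
    out <- data.frame(plot_id = seq_len(n_plots), row = chosen[, 1], col = chosen[, 2],
                      x = ctr[, "x"], y = ctr[, "y"],
                      biomass = biom, nitrogen = nitr)
    cbind(out, as.data.frame(spec))
  })
}

#' Extract the spectral matrix from a plot table
#' @param plots A [sample_plots()] data frame.
#' @return Numeric matrix, plots x bands.
#' @export
plot_spectra <- function(plots) {
  as.matrix(plots[, grep("^b[0-9]+$", names(plots)), drop = FALSE])
}

#' Species cell-use preference on the baseline-category logit scale
#'
#' Coefficients act on rescaled biomass (BiomRS = biomass / 100) and
#' nitrogen (%) and govern the log relative use intensity of raster cells.
#'
#' @param species Label; one of chamois, ibex, red_deer.
#' @param intercept,b_biomrs,b_n,b_interaction Logit coefficients.
#' @return Object of class `species_preference`.
#' @export
species_preference <- function(species, intercept = 0, b_biomrs = 0, b_n = 0,
                               b_interaction = 0) {
  if (!species %in% c("chamois", "ibex", "red_deer")) {
    stop_fm("species must be chamois, ibex or red_deer")
  }
  structure(list(species = species,
                 coef = c(intercept = intercept, b_biomrs = b_biomrs,
                          b_n = b_n, b_interaction = b_interaction)),
            class = "species_preference")
}

#' Default species preferences
#'
#' Chamois is the reference (all-zero) class; ibex weights nitrogen strongly,
#' red deer weights the biomass-nitrogen interaction, matching the published
#' preference structure of the three species (chamois low biomass, ibex high
#' nitrogen, red deer high biomass).
#' @return Named list of three [species_preference()] objects.
#' @export
default_species_preferences <- function() {
  list(
    chamois  = species_preference("chamois"),
    ibex     = species_preference("ibex", intercept = -8.7218, b_biomrs = 1.0043,
                                  b_n = 3.6048, b_interaction = -0.1314),
    red_deer = species_preference("red_deer", intercept = 2.2434, b_biomrs = -0.1548,
                                  b_n = -2.4917, b_interaction = 0.5535)
  )
}

pref_eta <- function(pref, biom_rs, nitrogen) {
  cf <- pref$coef
  cf["intercept"] + cf["b_biomrs"] * biom_rs + cf["b_n"] * nitrogen +
    cf["b_interaction"] * biom_rs * nitrogen
}

#' Simulate species' use of raster cells under planted preferences
#'
#' Cells are sampled (with replacement) with probability proportional to
#' exp(eta_s) over grass-dominated cells, where eta_s is the species'
#' preference logit evaluated at true BiomRS and nitrogen. Because each
#' species normalises its own weights, the implied baseline-category-logit
#' slope coefficients equal the planted slope differences (non-reference
#' minus reference) exactly; intercepts shift by the log normalising
#' constants. The implied coefficients are attached as an attribute.
#'
#' @param scene A [generate_scene()] result.
#' @param prefs List of exactly three [species_preference()] objects
#'   (chamois, ibex, red_deer).
#' @param n_cells_per_species Observations per species.
#' @param seed Integer seed.
#' @return Data frame with columns `species`, `individual`, `x`, `y`,
#'   `biomass`, `biom_rs`, `nitrogen`; attributes `footprints` (per-species
#'   convex hull rings) and `implied_coefficients` (2 x 4 matrix).
#' @export
simulate_species_usage <- function(scene, prefs, n_cells_per_species = 1000, seed = 1L) {
  if (!inherits(scene, "scene")) stop_fm("scene must be a scene object")
  if (length(prefs) != 3) stop_fm("exactly three species preferences required")
  sp_names <- vapply(prefs, `[[`, character(1), "species")
  if (!setequal(sp_names, c("chamois", "ibex", "red_deer"))) {
    stop_fm("preferences must cover chamois, ibex and red_deer exactly")
  }
  if (!is_count(n_cells_per_species) || n_cells_per_species < 1) {
    stop_fm("each species must receive at least one cell")
  }
  grass <- which(scene$fractions[, , "grass"] >= 0.5, arr.ind = TRUE)
  if (nrow(grass) == 0) stop_fm("no grass-dominated cells in scene")
  biom <- scene$biomass[grass]
  nitr <- scene$nitrogen[grass]
  biom_rs <- biom / 100
  ctr <- cell_centre(scene$origin, scene$res, grass[, 1], grass[, 2])
  names(prefs) <- sp_names
  ord <- c("chamois", "ibex", "red_deer")
  with_seed(seed, {
    rows <- list(); foot <- list()
    logz <- numeric(3); names(logz) <- ord
    for (sp in ord) {
      eta <- pref_eta(prefs[[sp]], biom_rs, nitr)
      w <- exp(eta - max(eta))
      if (!any(w > 0)) stop_fm("species ", sp, " received zero usable cells")
      logz[sp] <- log(mean(w)) + max(eta)
      idx <- sample(length(w), n_cells_per_species, replace = TRUE, prob = w)
      rows[[sp]] <- data.frame(species = sp, individual = paste0(sp, "_1"),
                               x = ctr[idx, "x"], y = ctr[idx, "y"],
                               biomass = biom[idx], biom_rs = biom_rs[idx],
                               nitrogen = nitr[idx], stringsAsFactors = FALSE)
      ring <- convex_ring(ctr[idx, "x"], ctr[idx, "y"])
      foot[[sp]] <- if (is.null(ring)) list() else list(ring)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    implied <- t(vapply(c("ibex", "red_deer"), function(sp) {
      d <- prefs[[sp]]$coef - prefs[["chamois"]]$coef
      d["intercept"] <- d["intercept"] - (logz[sp] - logz["chamois"])
      d
    }, numeric(4)))
    attr(tab, "footprints") <- foot
    attr(tab, "implied_coefficients") <- implied
    tab
  })
}

#' Draw species labels from a baseline-category logit model
#'
#' Given cell covariates and a 2 x 4 coefficient matrix (rows: ibex and
#' red_deer versus chamois; columns: intercept, BiomRS, N, BiomRS:N), labels
#' are drawn from the implied three-class probabilities. This is the exact
#' data-generating process of the multinomial model and is used for
#' coefficient-recovery and likelihood-ratio-test calibration checks.
#'
#' @param biom_rs,nitrogen Numeric covariate vectors.
#' @param coefs 2 x 4 numeric matrix.
#' @param seed Integer seed.
#' @return Factor with levels chamois, ibex, red_deer.
#' @export
simulate_mnl_labels <- function(biom_rs, nitrogen, coefs, seed = 1L) {
  stopifnot(length(biom_rs) == length(nitrogen), is.matrix(coefs),
            nrow(coefs) == 2, ncol(coefs) == 4)
  X <- cbind(1, biom_rs, nitrogen, biom_rs * nitrogen)
  eta <- X %*% t(coefs)
  p <- cbind(1, exp(eta))
  p <- p / rowSums(p)
  with_seed(seed, {
    lab <- apply(p, 1, function(pr) sample.int(3, 1, prob = pr))
    factor(c("chamois", "ibex", "red_deer")[lab],
           levels = c("chamois", "ibex", "red_deer"))
  })
}

#' Intercepts that balance expected class sizes
#'
#' For slope coefficients `coefs` (2 x 4), returns the matrix with
#' intercepts adjusted by fixed-point iteration so the three classes have
#' (near-)equal expected frequencies over the supplied covariates.
#' @param biom_rs,nitrogen Covariate vectors.
#' @param coefs 2 x 4 coefficient matrix.
#' @return The coefficient matrix with adjusted intercepts.
#' @export
balanced_intercepts <- function(biom_rs, nitrogen, coefs) {
  X <- cbind(1, biom_rs, nitrogen, biom_rs * nitrogen)
  for (it in 1:50) {
    eta <- X %*% t(coefs)
    p <- cbind(1, exp(eta))
    p <- p / rowSums(p)
    shares <- colMeans(p)
    if (max(abs(shares - 1 / 3)) < 1e-6) break
    coefs[, 1] <- coefs[, 1] + log((1 / 3) / shares[2:3]) - log((1 / 3) / shares[1])
  }
  coefs
}
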