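# End-to-end orchestration: synthetic valley -> screening -> behavioural
# maps -> resource maps -> species comparison.

#' Configuration for an end-to-end synthetic study
#'
#' Defines one synthetic "valley": a hyperspectral scene with planted
#' biomass/nitrogen truth, three ungulate species whose cell preferences
#' follow the published coefficient structure, and a trajectory model whose
#' foraging patches are placed by those preferences, so each species'
#' behavioural map concentrates where its preferred resources are.
#'
#' @param scene A [scene_config()]; the default is a 400 x 400 cell
#'   (800 x 800 m) scene with 12 bands, a deliberately scaled-down valley.
#' @param n_plots Ground plots used to calibrate the spectral models.
#' @param prefs Three [species_preference()] objects
#'   (default [default_species_preferences()]).
#' @param n_individuals Collared individuals per species.
#' @param n_patches Foraging patches per individual.
#' @param patch_radius Patch radius in metres.
#' @param step_scale Maximum displacement per fix interval, metres.
#' @param n_days,fix_interval Trajectory length (days) and fix interval (s).
#' @param ivg Inter-visit gap for revisitation, seconds (default 12 h).
#' @param cfa_level Core-foraging-area isopleth level (default 0.3).
#' @param target_ptsh Target proportion of time-selected hulls for s.
#' @param top_n SRI shortlist size.
#' @param buffer Sensitivity buffer in metres (default 6).
#' @param margin_cells Patch centres keep this many cells from the scene
#'   edge so trajectories stay on the raster.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `study_config`.
#' @export
study_config <- function(scene = NULL, n_plots = 51,
                         prefs = default_species_preferences(),
                         n_individuals = 3, n_patches = 6, patch_radius = 80,
                         step_scale = 250, n_days = 43, fix_interval = 14400,
                         ivg = 43200, cfa_level = 0.3, target_ptsh = 0.60,
                         top_n = 100, buffer = 6, margin_cells = 75, seed = 1L) {
  if (is.null(scene)) {
    scene <- scene_config(n_rows = 400, n_cols = 400, n_bands = 12,
                          biomass_field = list(mean = 295.26, sd = 230.10, corr_length = 60),
                          n_field = list(mean = 2.11, sd = 0.53, corr_length = 60),
                          seed = seed)
  }
  structure(list(scene = scene, n_plots = n_plots, prefs = prefs,
                 n_individuals = n_individuals, n_patches = n_patches,
                 patch_radius = patch_radius, step_scale = step_scale,
                 n_days = n_days, fix_interval = fix_interval, ivg = ivg,
                 cfa_level = cfa_level, target_ptsh = target_ptsh,
                 top_n = top_n, buffer = buffer, margin_cells = margin_cells,
                 seed = as.integer(seed)),
            class = "study_config")
}

# derive a stage seed from the master seed, kept within 32-bit range
stage_seed <- function(seed, k) (as.integer(seed) * 97L + k) %% 2100000000L

#' Default candidate grid for the cumulative-distance parameter a
#'
#' Candidates span fractions and multiples of the median cumulative TSD to
#' each point's `k_target` nearest neighbours, so the grid brackets hulls
#' from a handful of points up to several dozen.
#' @param traj Trajectory data frame.
#' @param s TSD time weighting.
#' @param k_target Neighbour count anchoring the grid (default 25).
#' @return Ascending numeric candidate vector.
#' @export
default_a_candidates <- function(traj, s, k_target = 25) {
  v_max <- max_observed_speed(traj)
  D <- tsd_matrix(traj, s, v_max)
  n <- nrow(D)
  k <- min(k_target, n - 1)
  cum_k <- vapply(seq_len(n), function(i) {
    di <- sort(D[i, -i], partial = k)[seq_len(k)]
    sum(sort(di))
  }, numeric(1))
  a_mid <- stats::median(cum_k)
  a_mid * c(0.25, 0.4, 0.6, 0.85, 1.2, 1.7, 2.4)
}

# sample patch centres for one individual by species preference over cells
sample_patches <- function(scene, pref, n_patches, radius, margin_cells, seed,
                           temperature = 1.5) {
  nr <- dim(scene$biomass)[1]; nc <- dim(scene$biomass)[2]
  grass <- scene$fractions[, , "grass"] >= 0.5
  ok <- matrix(FALSE, nr, nc)
  ok[(margin_cells + 1):(nr - margin_cells), (margin_cells + 1):(nc - margin_cells)] <- TRUE
  cand <- which(grass & ok, arr.ind = TRUE)
  if (nrow(cand) < n_patches) stop_fm("not enough eligible cells for patch placement")
  # tempering spreads patches over the preference gradient; signs preserved
  eta <- pref_eta(pref, scene$biomass[cand] / 100, scene$nitrogen[cand]) / temperature
  w <- exp(eta - max(eta))
  ctr <- cell_centre(scene$origin, scene$res, cand[, 1], cand[, 2])
  with_seed(seed, {
    chosen <- integer(0)
    # progressively relax the separation if the preferred area is too small
    min_sep <- 2.2 * radius
    for (round in 1:5) {
      guard <- 0
      while (length(chosen) < n_patches && guard < 4000) {
        pick <- sample(nrow(cand), 1, prob = w)
        if (length(chosen) == 0 ||
            all(sqrt((ctr[chosen, "x"] - ctr[pick, "x"])^2 +
                     (ctr[chosen, "y"] - ctr[pick, "y"])^2) >= min_sep)) {
          chosen <- c(chosen, pick)
        }
        guard <- guard + 1
      }
      if (length(chosen) == n_patches) break
      min_sep <- min_sep * 0.7
    }
    if (length(chosen) < n_patches) stop_fm("could not place ", n_patches,
                                            " separated patches")
    data.frame(x = ctr[chosen, "x"], y = ctr[chosen, "y"],
               radius = radius, weight = 1)
  })
}

#' Run the full synthetic study end to end
#'
#' Generates the scene; calibrates biomass and nitrogen SRI models on
#' sampled plots; unmixes and masks non-grassland; predicts the resource
#' raster; simulates, screens and maps each individual's trajectory;
#' extracts resource cells under the core foraging areas; selects among the
#' five multinomial models; and computes calibration, discrimination and
#' buffer-sensitivity diagnostics. Fully determined by the configuration
#' seed.
#'
#' @param config A [study_config()].
#' @param verbose Print stage progress.
#' @return Object of class `study_report`; see Details in the vignette.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(cnd) {
      stop_fm("stage '", name, "' failed: ", conditionMessage(cnd))
    })
  }

  say("scene")
  scene <- stage("scene", generate_scene(config$scene))

  say("spectral models")
  plots <- stage("plots", sample_plots(scene, config$n_plots,
                                       seed = stage_seed(seed, 2L)))
  biomass_model <- stage("biomass model",
                         fit_sri_models(plots, "biomass", top_n = config$top_n))
  nitrogen_model <- stage("nitrogen model",
                          fit_sri_models(plots, "nitrogen", top_n = config$top_n))

  say("unmixing")
  um <- stage("unmixing", unmix_lsu(scene, scene$endmembers))
  raster <- stage("prediction",
                  build_resource_raster(biomass_model, nitrogen_model, scene, um$mask))

  say("trajectories and behavioural maps")
  sp_order <- c("chamois", "ibex", "red_deer")
  prefs <- config$prefs
  names(prefs) <- vapply(prefs, `[[`, character(1), "species")
  cfas <- list(); tlocoh_params <- list(); k <- 10L
  for (sp in sp_order) {
    for (ind in seq_len(config$n_individuals)) {
      k <- k + 1L
      id <- paste0(sp, "_", ind)
      patches <- stage(paste0("patches ", id),
                       sample_patches(scene, prefs[[sp]], config$n_patches,
                                      config$patch_radius, config$margin_cells,
                                      seed = stage_seed(seed, k)))
      tc <- trajectory_config(n_days = config$n_days,
                              fix_interval = config$fix_interval,
                              patches = patches, step_scale = config$step_scale,
                              seed = stage_seed(seed, 1000L + k))
      traj <- stage(paste0("trajectory ", id), simulate_trajectory(tc, id = id))
      traj <- stage(paste0("screening ", id), {
        rs <- resample_fixes(traj, config$fix_interval)
        fl <- screen_errors(rs)
        rs[!fl$flag, , drop = FALSE]
      })
      iso <- stage(paste0("tlocoh ", id), {
        ssel <- select_s(traj, target_ptsh = config$target_ptsh)
        asel <- select_a(traj, ssel$s, default_a_candidates(traj, ssel$s),
                         level = config$cfa_level, ivg = config$ivg)
        cfg <- hull_config(method = "a", a = asel$a, ivg = config$ivg,
                           levels = config$cfa_level)
        iso <- tlocoh_isopleths(traj, ssel$s, cfg)
        tlocoh_params[[id]] <- list(s = ssel$s, ptsh = ssel$ptsh, a = asel$a,
                                    stabilised = asel$stabilised)
        iso
      })
      cfas[[id]] <- export_cfa(iso, level = config$cfa_level,
                               species = sp, individual = id)
    }
  }

  say("species comparison")
  obs <- stage("extraction", extract_cells(raster, cfas))
  comparison <- stage("model selection", compare_models(obs))
  best_fit <- comparison$fits[[comparison$best]]
  inter_fit <- comparison$fits[["interaction"]]
  diagnostics <- stage("diagnostics", list(
    hosmer_lemeshow = lapply(1:2, function(lg)
      suppressWarnings(hosmer_lemeshow_logit(inter_fit, obs, lg))),
    auc = vapply(1:2, function(lg) auc_logit(inter_fit, obs, lg), numeric(1))
  ))
  sensitivity <- stage("buffer sensitivity",
                       buffer_sensitivity(raster, cfas, buffer = config$buffer))

  valley <- data.frame(species = "valley",
                       n = sum(um$mask),
                       mean_biomass = mean(raster$biomass[um$mask]),
                       sd_biomass = stats::sd(raster$biomass[um$mask]),
                       min_biomass = min(raster$biomass[um$mask]),
                       max_biomass = max(raster$biomass[um$mask]),
                       mean_nitrogen = mean(raster$nitrogen[um$mask]),
                       sd_nitrogen = stats::sd(raster$nitrogen[um$mask]),
                       min_nitrogen = min(raster$nitrogen[um$mask]),
                       max_nitrogen = max(raster$nitrogen[um$mask]))
  resource_table <- rbind(valley, summarise_resources(obs))
  rownames(resource_table) <- NULL

  model_cards <- lapply(list(biomass = biomass_model, nitrogen = nitrogen_model),
    function(m) list(response = m$response, pair = unname(m$pair), form = m$form,
                     coef = as.list(m$coef),
                     theils_u = m$stats$theils_u, adj_r2 = m$stats$adj_r2,
                     rmse = m$stats$rmse,
                     pct_within_20pct_rmse = m$stats$pct_within_20pct_rmse,
                     aic = m$aic))

  structure(list(config = config, scene = scene,
                 plots = plots, spectral_models = list(biomass = biomass_model,
                                                       nitrogen = nitrogen_model),
                 model_cards = model_cards, unmixing = um, raster = raster,
                 cfas = cfas, tlocoh_params = tlocoh_params,
                 observations = obs, comparison = comparison,
                 best_model = best_fit, diagnostics = diagnostics,
                 sensitivity = sensitivity, resource_table = resource_table),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic foraging study report\n")
  cat("  scene:", paste(dim(x$scene$reflectance), collapse = " x "),
      "(cells x cells x bands), res", x$scene$res, "m\n")
  cat("  spectral models:\n")
  for (m in x$model_cards) {
    cat(sprintf("    %-8s pair (%d/%d) %-12s Theil's U %.3f adj R2 %.3f RMSE %.3g\n",
                m$response, m$pair[1], m$pair[2], m$form, m$theils_u, m$adj_r2, m$rmse))
  }
  cat("  observations:", nrow(x$observations), "cells;",
      "best model:", x$comparison$best, "\n")
  cat("  AUC logit 1 (chamois vs ibex):", round(x$diagnostics$auc[1], 3),
      " logit 2 (chamois vs red deer):", round(x$diagnostics$auc[2], 3), "\n")
  cat("  buffer sensitivity: min p =", round(min(x$sensitivity$table$p), 3), "\n")
  invisible(x)
}
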