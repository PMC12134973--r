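scenario_mode_layers <- function(landscape, biotic_sets, ssp, mode) {
  abiotic <- if (mode %in% c("abiotic_biotic", "abiotic")) {
    resolve_layers(landscape, ssp)
  } else {
    resolve_layers(landscape, "current")
  }
  biotic <- if (mode %in% c("abiotic_biotic", "biotic")) {
    biotic_sets[[ssp]]
  } else {
    biotic_sets[["current"]]
  }
  if (is.null(biotic)) abort(sprintf("missing biotic layer set for '%s'.", ssp))
  c(abiotic, biotic_matrices(biotic, include_binary = TRUE))
}

#' Project the fitted distribution model under scenarios and change modes
#'
#' Produces the current prediction plus one run per scenario x change
#' mode. In `"abiotic"` mode the biotic layers are pinned to current
#' values; in `"biotic"` mode the abiotic layers are pinned; in
#' `"abiotic_biotic"` both change. All predictions reuse the
#' current-conditions threshold unchanged and are masked to cells within
#' `buffer_km` of the current thresholded distribution (masked cells are
#' `NA`), so biotic layers are never extrapolated far beyond the region
#' with diet information.
#'
#' @param fit A `bear_sdm_fit`.
#' @param landscape A `landscape` with scenario stacks.
#' @param biotic_sets Named list of `biotic_layers` sets keyed
#'   `"current"` and by scenario id.
#' @param threshold Presence/absence cutoff (from
#'   [threshold_and_evaluate()]).
#' @param subpop_map Character matrix of subpopulation ids.
#' @param buffer_km Mask radius around the current distribution (default
#'   200).
#' @param modes Change modes to run.
#' @return An object of class `scenario_runs`: list with `current`
#'   (prob + binary matrices), `runs` (list of per-run entries), `mask`,
#'   `threshold`.
#' @export
project_scenarios <- function(fit, landscape, biotic_sets, threshold,
                              subpop_map, buffer_km = 200,
                              modes = c("abiotic_biotic", "abiotic", "biotic")) {
  cur_layers <- scenario_mode_layers(landscape, biotic_sets, "current", "abiotic")
  prob_cur <- predict_distribution(fit, cur_layers, subpop_map)
  bin_cur <- (prob_cur >= threshold) * 1
  pres <- which(bin_cur == 1, arr.ind = TRUE)
  if (nrow(pres) == 0) abort("current prediction has no presence cells.")
  mask <- if (buffer_km >= sum(dim(bin_cur))) {
    matrix(TRUE, nrow(bin_cur), ncol(bin_cur))
  } else {
    d <- distance_to_cells(nrow(bin_cur), ncol(bin_cur),
                           pres[, 1], pres[, 2], buffer_km)
    d <= buffer_km
  }
  ssps <- names(landscape$scenarios)
  runs <- list()
  for (ssp in ssps) {
    for (mode in modes) {
      lyr <- scenario_mode_layers(landscape, biotic_sets, ssp, mode)
      prob <- predict_distribution(fit, lyr, subpop_map)
      prob[!mask] <- NA_real_
      runs[[paste(ssp, mode, sep = "|")]] <- list(
        scenario = ssp, mode = mode, prob = prob,
        binary = (prob >= threshold) * 1
      )
    }
  }
  prob_cur_masked <- prob_cur
  prob_cur_masked[!mask] <- NA_real_
  structure(
    list(
      current = list(scenario = "current", mode = "current",
                     prob = prob_cur_masked,
                     binary = (prob_cur_masked >= threshold) * 1),
      runs = runs, mask = mask, threshold = threshold,
      buffer_km = buffer_km
    ),
    class = "scenario_runs"
  )
}

one_range_row <- function(binary, cur_binary, sel, protected, occupied,
                          cell_area) {
  pred <- sum(binary[sel] == 1, na.rm = TRUE)
  cur <- sum(cur_binary[sel] == 1, na.rm = TRUE)
  tibble(
    area_km2 = pred * cell_area,
    pct_change = if (cur > 0) 100 * (pred - cur) / cur else NA_real_,
    pct_protected = if (pred > 0 && !is.null(protected)) {
      100 * sum(binary[sel] == 1 & protected[sel], na.rm = TRUE) / pred
    } else {
      NA_real_
    },
    pct_occupied = if (pred > 0 && !is.null(occupied)) {
      100 * sum(binary[sel] == 1 & occupied[sel], na.rm = TRUE) / pred
    } else {
      NA_real_
    }
  )
}

#' Range-change descriptors per scenario run and subpopulation
#'
#' For every run (including current): the thresholded range area in km^2,
#' the percent change relative to the current run, the percentage of the
#' predicted range inside protected areas, and the percentage of the
#' predicted range currently occupied (containing observed presences) —
#' overall and per subpopulation.
#'
#' @param runs A `scenario_runs` object.
#' @param subpop_map Character matrix of subpopulation ids.
#' @param protected Optional logical matrix (TRUE = protected).
#' @param occupied Optional logical matrix of currently occupied cells.
#' @param cell_area_km2 Area of one cell (default 1).
#' @return Tibble: `scenario`, `mode`, `subpop` (`"overall"` plus each
#'   subpopulation), `area_km2`, `pct_change`, `pct_protected`,
#'   `pct_occupied`.
#' @export
range_descriptors <- function(runs, subpop_map, protected = NULL,
                              occupied = NULL, cell_area_km2 = 1) {
  mask <- runs$mask
  if (any(is.na(subpop_map[mask]))) {
    abort("subpop_map does not cover the prediction mask.")
  }
  all_runs <- c(list(current = runs$current), runs$runs)
  subpops <- sort(unique(as.vector(subpop_map)))
  purrr::map_dfr(all_runs, function(r) {
    purrr::map_dfr(c("overall", subpops), function(sp) {
      sel <- if (sp == "overall") mask else mask & subpop_map == sp
      dplyr::bind_cols(
        tibble(scenario = r$scenario, mode = r$mode, subpop = sp),
        one_range_row(r$binary, runs$current$binary, sel, protected,
                      occupied, cell_area_km2)
      )
    })
  })
}

#' Sensitivity of the model to uncertainty in the biotic layers
#'
#' Refits the model with the biotic predictors replaced by their lower and
#' then their upper uncertainty bounds (e.g. the spread across habitat-
#' model ensemble members), and reports the coefficient shifts and the
#' Pearson correlation between each bound run's prediction map and the
#' original prediction.
#'
#' @param fit A `bear_sdm_fit` including biotic predictors.
#' @param data The fitting data (as passed to [fit_bayes_model()]).
#' @param lower,upper Named lists of bound matrices for every biotic
#'   predictor of the fit.
#' @param layers Named list of current layers for prediction (abiotic +
#'   biotic).
#' @param subpop_map Character matrix of subpopulation ids.
#' @param seed Integer seed for the refits; defaults to the original
#'   fit's seed (common random numbers, so identical bounds reproduce the
#'   original posterior exactly).
#' @return A list of class `biotic_sensitivity` with `report` (tibble:
#'   bound, prediction_correlation), `coefficients` (original vs bound
#'   posterior means) and `fits`.
#' @export
sensitivity_biotic <- function(fit, data, lower, upper, layers, subpop_map,
                               seed = NULL) {
  seed <- seed %||% fit$seed
  bv <- fit$data$biotic_vars
  if (length(bv) == 0) abort("fit has no biotic predictors.")
  for (v in bv) {
    if (is.null(lower[[v]]) || is.null(upper[[v]])) {
      abort(sprintf("bounds missing for biotic predictor '%s'.", v))
    }
    if (any(lower[[v]] > upper[[v]], na.rm = TRUE)) {
      abort("bounds inverted: lower exceeds upper somewhere.")
    }
  }
  base_prob <- predict_distribution(fit, layers, subpop_map)
  refit_with <- function(bounds, stream) {
    d <- data
    for (v in bv) d[[v]] <- bounds[[v]][cbind(d$row, d$col)]
    fit_bayes_model(
      d, variant = fit$variant,
      climate_vars = fit$data$climate_vars,
      landuse_vars = fit$data$landuse_vars,
      biotic_vars = bv,
      priors = if (fit$hierarchical) {
        structure(fit$priors |>
                    filter(.data$prior_source == "historical") |>
                    select(term = "term", mean = "prior_mean", sd = "prior_sd"),
                  standardization = fit$standardization,
                  class = c("prior_set", "tbl_df", "tbl", "data.frame"))
      } else {
        NULL
      },
      hierarchical = fit$hierarchical,
      random_intercept = fit$random_intercept,
      chains = fit$sampler$chains, adapt = fit$sampler$adapt,
      warmup = fit$sampler$warmup, iter = fit$sampler$iter,
      seed = seed
    )
  }
  fits <- list(lower = refit_with(lower, 1), upper = refit_with(upper, 2))
  report <- purrr::map_dfr(c("lower", "upper"), function(b) {
    lyr <- layers
    for (v in bv) lyr[[v]] <- (if (b == "lower") lower else upper)[[v]]
    prob <- predict_distribution(fits[[b]], lyr, subpop_map)
    tibble(
      bound = b,
      prediction_correlation = cor(as.vector(prob), as.vector(base_prob),
                                   use = "complete.obs")
    )
  })
  coefs <- tibble(
    term = fit$terms,
    original = colMeans(fit$draws_beta),
    lower = colMeans(fits$lower$draws_beta)[fit$terms],
    upper = colMeans(fits$upper$draws_beta)[fit$terms]
  )
  structure(list(report = report, coefficients = coefs, fits = fits),
            class = "biotic_sensitivity")
}

#' Ensemble-spread bounds for a set of suitability maps
#'
#' Builds per-species lower and upper suitability surfaces from the spread
#' of ensemble-member predictions (pointwise min and max across members,
#' i.e. the extreme quantiles available from a small member set), for use
#' as biotic-layer uncertainty bounds in [sensitivity_biotic()].
#'
#' @param models Named list of [fit_ensemble()] models keyed by species.
#' @param landscape Layer source for prediction.
#' @param scenario Scenario name (default current).
#' @return List with `lower` and `upper`: named lists of matrices.
#' @export
suitability_bounds <- function(models, landscape, scenario = NULL) {
  lower <- list()
  upper <- list()
  for (sp in names(models)) {
    member_maps <- lapply(names(models[[sp]]$members), function(nm) {
      predict_suitability(models[[sp]], landscape, scenario, members = nm)
    })
    lower[[sp]] <- Reduce(pmin, member_maps)
    upper[[sp]] <- Reduce(pmax, member_maps)
  }
  list(lower = lower, upper = upper)
}
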