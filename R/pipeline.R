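#' Default synthetic food-species pool
#'
#' Ten food species spanning the five food categories, with energy
#' correction factors increasing from plant to animal matter and two
#' human-derived resources (which, like unmodellable species in real
#' pipelines, get no habitat model).
#'
#' @return Tibble: `species_id`, `category`, `origin`, `cf_e`, `wild`.
#' @export
default_food_pool <- function() {
  tibble(
    species_id = sprintf("food_%02d", 1:10),
    category = c("reproductive plants", "reproductive plants", "reproductive plants",
                 "vegetative plants", "vegetative plants", "unknown plants",
                 "invertebrates", "invertebrates", "vertebrates", "vertebrates"),
    origin = c(rep("wild", 8), "human-derived", "human-derived"),
    cf_e = c(1.5, 1.8, 1.2, 1.0, 0.9, 1.1, 3.0, 2.6, 5.2, 4.8),
    wild = c(rep(TRUE, 8), FALSE, FALSE)
  )
}

#' Default true coefficients of the synthetic focal-species model
#'
#' The generating logistic model combines bell-shaped climate responses,
#' linear land-use effects (negative for urban cover, positive for forest
#' and natural landscape) and linear biotic effects (positive for most
#' food categories, mildly negative for invertebrates).
#'
#' @return List with `intercept`, `hist_intercept`, `climate`, `landuse`,
#'   `biotic`.
#' @export
default_focal_model <- function() {
  list(
    intercept = -0.3,
    hist_intercept = -0.1,
    climate = list(
      Clim_3 = c(0.5, -0.45), Clim_4 = c(-0.35, -0.3),
      Clim_8 = c(0.7, -0.5), Clim_9 = c(0.25, -0.2)
    ),
    landuse = c("Urban" = -0.7, "Broadleaved Forest" = 0.45,
                "Coniferous Forest" = 0.3, "Natural Landscape" = 0.5),
    biotic = c("Biotic_reproductive_plants" = 0.8,
               "Biotic_vertebrates" = 0.6,
               "Biotic_vegetative_plants" = 0.3,
               "Biotic_invertebrates" = -0.25)
  )
}

random_food_niches <- function(pool, climate_layers, landuse_layers, seed,
                               intercept = -2.4) {
  withr::with_seed(seed, {
    lapply(pool$species_id, function(sp) {
      vars <- c(sample(climate_layers, 2), sample(landuse_layers, 1))
      coefs <- lapply(vars, function(v) {
        c(rnorm(1, 0, 0.9), -abs(rnorm(1, 0.35, 0.25)))
      })
      names(coefs) <- vars
      true_niche(sp, coefs, intercept = intercept + rnorm(1, 0, 0.3))
    })
  })
}

random_subpop_shares <- function(pool, subpops, seed) {
  withr::with_seed(seed, {
    shares <- lapply(subpops, function(sp) {
      w <- stats::rgamma(nrow(pool), shape = 1.2)
      setNames(w / sum(w), pool$species_id)
    })
    names(shares) <- subpops
    shares
  })
}

#' Run the full synthetic trophic-distribution study
#'
#' Generates a landscape with scenarios, food-species occurrences and
#' their ensemble habitat models, synthetic diet studies with rV
#' imputation and energy correction, subpopulation diets, quantitative
#' and binary biotic layers (current + scenarios), focal-species
#' occurrences from a known truth, the coarse historical range and its
#' Bayesian prior model, the fine-scale hierarchical Bayesian model, the
#' 90th-percentile presence threshold, and (optionally) scenario
#' projections with range descriptors.
#'
#' Problem sizes default to a desk-scale study: a 100 x 100 km landscape,
#' 10 food species, 32 diet studies across 4 subpopulations, roughly
#' 2,000 training presences, and reduced MCMC settings.
#'
#' @param seed Integer seed driving every random component.
#' @param dims Grid dimensions `c(nrow, ncol)`.
#' @param coarse_factor Fine-to-coarse aggregation factor for the
#'   historical range (default 5, giving a 20 x 20 coarse grid).
#' @param subpop_blocks Subpopulation partition `c(rows, cols)`.
#' @param cap Presence cap per subpopulation (default 625, so 4
#'   subpopulations yield about 2,500 presences and 2,000 training
#'   presences).
#' @param studies_per_subpop Diet studies per subpopulation.
#' @param food_presence_cap Presence-cell cap per food species before
#'   habitat modelling.
#' @param sampler MCMC settings for the fine-scale model.
#' @param variants Model variants to fit (subset of `"abiotic_biotic"`,
#'   `"abiotic"`, `"biotic"`, `"null"`).
#' @param do_projections Also run scenario projections and range
#'   descriptors.
#' @return A list with every intermediate product; see the vignette for a
#'   guided tour.
#' @export
run_synthetic_study <- function(seed = 1,
                                dims = c(100, 100),
                                coarse_factor = 5,
                                subpop_blocks = c(2, 2),
                                cap = 625,
                                studies_per_subpop = 8,
                                food_presence_cap = 700,
                                sampler = list(chains = 2, adapt = 300,
                                               warmup = 400, iter = 600),
                                variants = "abiotic_biotic",
                                do_projections = FALSE) {
  seed <- stopifnot_scalar_seed(seed)
  cfg <- landscape_config(nrow = dims[1], ncol = dims[2],
                          seed = child_seed(seed, 1))
  land <- generate_landscape(cfg)
  subpop_map <- make_subpop_map(dims[1], dims[2],
                                subpop_blocks[1], subpop_blocks[2])
  subpops <- sort(unique(as.vector(subpop_map)))

  # --- food species: occurrences and ensemble habitat models -------------
  pool <- default_food_pool()
  wild <- pool$species_id[pool$wild]
  niches <- random_food_niches(pool |> filter(.data$wild),
                               cfg$climate_layers,
                               setdiff(cfg$landuse_layers, "Natural Landscape"),
                               seed = child_seed(seed, 2))
  food <- generate_food_species(niches, land, seed = child_seed(seed, 3),
                                points_per_cell = 1.2)
  scen_names <- names(land$scenarios)
  food_models <- list()
  suitability <- setNames(
    lapply(c("current", scen_names), function(s) list()),
    c("current", scen_names)
  )
  for (i in seq_along(wild)) {
    sp <- wild[i]
    pres <- grid_presences(food$occurrences, sp)
    if (attr(pres, "excluded")) next
    if (nrow(pres) > food_presence_cap) {
      pres <- withr::with_seed(child_seed(seed, 100 + i), {
        pres |> dplyr::slice_sample(n = food_presence_cap)
      })
    }
    abs_cells <- sample_pseudoabsences_annulus(
      pres, dims[1], dims[2], seed = child_seed(seed, 200 + i)
    )
    pa <- assemble_pa_table(pres, abs_cells, land)
    vars <- select_species_variables(
      pa, c(cfg$climate_layers, cfg$landuse_layers)
    )
    mdl <- fit_ensemble(pa, vars, seed = child_seed(seed, 300 + i),
                        species = sp, nrounds = 40)
    food_models[[sp]] <- mdl
    for (s in names(suitability)) {
      suitability[[s]][[sp]] <- predict_suitability(mdl, land, scenario = s)
    }
  }

  # --- diet studies -> subpopulation energy shares -----------------------
  dcfg <- diet_config(
    pool |> select("species_id", "category", "origin", "cf_e"),
    random_subpop_shares(pool, subpops, child_seed(seed, 4)),
    studies_per_subpop = studies_per_subpop
  )
  diet_raw <- generate_diet_studies(dcfg, subpop_map, seed = child_seed(seed, 5))
  diet <- impute_rv(diet_raw, n_bootstrap = 500, seed = child_seed(seed, 6))
  diet <- compute_redec(diet)
  subpop_diet <- aggregate_subpopulation_diet(diet)

  # --- biotic layers (current + scenarios, diets held fixed) -------------
  biotic_sets <- setNames(
    lapply(c("current", scen_names), function(s) {
      suppressWarnings(
        build_biotic_layer_set(subpop_diet, suitability[[s]], subpop_map,
                               scenario = s)
      )
    }),
    c("current", scen_names)
  )

  # --- focal species truth, occurrence sample, historical priors --------
  truth <- default_focal_model()
  focal <- generate_focal_occurrences(
    truth, land, biotic_matrices(biotic_sets$current, include_binary = FALSE),
    subpop_map, seed = child_seed(seed, 7), coarse_factor = coarse_factor
  )
  sample <- prepare_occurrences(focal$presences, subpop_map, cap = cap,
                                seed = child_seed(seed, 8))

  coarse_climate <- lapply(
    setNames(cfg$climate_layers, cfg$climate_layers),
    function(nm) block_aggregate(gs_layer(land$current, nm), coarse_factor)
  )
  coarse_sample <- stratified_sample_range(
    focal$range_grid, coarse_climate, n_bins = 2,
    seed = child_seed(seed, 9)
  )
  priors <- fit_historical_model(coarse_sample, chains = sampler$chains,
                                 adapt = sampler$adapt, warmup = sampler$warmup,
                                 iter = sampler$iter,
                                 seed = child_seed(seed, 10))

  # --- fine-scale data and model fits ------------------------------------
  cur_biotic <- biotic_matrices(biotic_sets$current, include_binary = FALSE)
  all_layers <- c(resolve_layers(land, "current"), cur_biotic)
  data_all <- dplyr::bind_cols(
    as_tibble(sample),
    as_tibble(lapply(all_layers, function(m) m[cbind(sample$row, sample$col)]))
  )
  train <- data_all |> filter(.data$set == "train")

  landuse_vars <- select_glmm_variables(
    train, cfg$landuse_layers, k = 4
  )
  biotic_vars <- select_glmm_variables(
    train, setdiff(names(cur_biotic), "Bio_All_species"), k = 4
  )

  fits <- list()
  for (v in variants) {
    fits[[v]] <- fit_bayes_model(
      train, variant = v,
      climate_vars = cfg$climate_layers,
      landuse_vars = as.character(landuse_vars),
      biotic_vars = as.character(biotic_vars),
      priors = if (v %in% c("abiotic_biotic", "abiotic")) priors else NULL,
      chains = sampler$chains, adapt = sampler$adapt,
      warmup = sampler$warmup, iter = sampler$iter,
      seed = child_seed(seed, 20 + match(v, c("abiotic_biotic", "abiotic",
                                              "biotic", "null")))
    )
  }
  best <- fits[[1]]

  # threshold/evaluation needs validation cells too: refit predictions on
  # the full sample using the training fit's coefficients
  eval_fit <- best
  eval_X <- bear_design(
    data_all, best$data$climate_vars, best$data$landuse_vars,
    best$data$biotic_vars, best$standardization
  )
  eta <- eval_X %*% colMeans(best$draws_beta)
  if (best$random_intercept) {
    u <- colMeans(best$draws_u)[as.character(data_all$subpop)]
    u[is.na(u)] <- 0
    eta <- eta + u
  }
  eval_fit$fitted <- plogis(as.vector(eta))
  eval_fit$data$y <- data_all$y
  eval_fit$data$cells <- data_all |> select("row", "col", "subpop", "set")
  threshold_eval <- threshold_and_evaluate(eval_fit)

  out <- list(
    seed = seed, config = cfg, landscape = land, subpop_map = subpop_map,
    food = food, food_models = food_models, suitability = suitability,
    diet = diet, subpop_diet = subpop_diet, biotic_sets = biotic_sets,
    focal = focal, sample = sample, coarse_sample = coarse_sample,
    priors = priors, fits = fits,
    landuse_vars = landuse_vars, biotic_vars = biotic_vars,
    threshold_eval = threshold_eval
  )
  if (do_projections) {
    runs <- project_scenarios(best, land, biotic_sets,
                              threshold_eval$threshold, subpop_map)
    protected <- withr::with_seed(child_seed(seed, 30), {
      matrix(runif(prod(dims)) < 0.25, dims[1], dims[2])
    })
    occupied <- matrix(FALSE, dims[1], dims[2])
    occupied[cbind(sample$row[sample$y == 1], sample$col[sample$y == 1])] <- TRUE
    out$projections <- runs
    out$range_report <- range_descriptors(runs, subpop_map, protected, occupied)
  }
  out
}
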