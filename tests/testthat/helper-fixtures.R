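suppressPackageStartupMessages({
  library(dplyr)
})

# small landscape shared by cheap tests
small_landscape <- function(seed = 42, nrow = 60, ncol = 60, length_scale = 6) {
  generate_landscape(landscape_config(nrow = nrow, ncol = ncol,
                                      length_scale = length_scale, seed = seed))
}

# minimal hand-built diet table: two studies, explicit values
hand_diet <- function() {
  tibble(
    study_id = rep(c("s1", "s2"), each = 2),
    subpop = "SP1",
    row = 5, col = 5,
    sample_type = "scat",
    Z = rep(c(100L, 50L), each = 2),
    item_id = c("s1_a", "s1_b", "s2_a", "s2_b"),
    species_id = c("sp_a", "sp_b", "sp_a", "sp_b"),
    category = c("vertebrates", "reproductive plants",
                 "vertebrates", "reproductive plants"),
    origin = c("wild", "wild", "wild", "human-derived"),
    f = c(6L, 4L, 5L, 5L),
    rF = c(0.6, 0.4, 0.5, 0.5),
    v = c(60, 40, 50, 50),
    rV = c(0.6, 0.4, 0.5, 0.5),
    CF_E = 1
  )
}

# a default diet configuration over the standard pool on a 2x2 partition
default_diet_fixture <- function(studies_per_subpop = 8,
                                 missing_rv_fraction = 0.3) {
  pool <- default_food_pool()
  shares <- setNames(
    lapply(1:4, function(i) setNames(rep(0.1, 10), pool$species_id)),
    paste0("SP", 1:4)
  )
  diet_config(pool |> select(species_id, category, origin, cf_e), shares,
              studies_per_subpop = studies_per_subpop,
              missing_rv_fraction = missing_rv_fraction)
}

fast_sampler <- list(chains = 2, adapt = 150, warmup = 150, iter = 300)

# --- shared Bayesian simulation replicates ----------------------------------
# One synthetic "study" at reduced scale: autocorrelated landscape, two
# biotic energy surfaces built from known suitability fields, focal
# occurrences from a known abiotic + biotic logistic truth, a coarse
# historical range, the transferred-prior fit and its reduced alternatives.
# Shared (and cached) between the WAIC-ordering and the coverage checks.
bayes_truth <- function() {
  list(
    intercept = -0.2,
    hist_intercept = 0,
    climate = list(Clim_3 = c(0.5, -0.4), Clim_8 = c(0.7, -0.5)),
    landuse = c("Urban" = -0.5),
    biotic = c("Biotic_A" = 0.9, "Biotic_B" = 0.5)
  )
}

simulate_bayes_replicate <- function(seed, n_cells = 2000,
                                     sampler = fast_sampler,
                                     fit_extra_variants = TRUE) {
  land <- small_landscape(seed = child_seed_t(seed, 1))
  sm <- make_subpop_map(60, 60, 2, 2)
  biotic <- withr::with_seed(child_seed_t(seed, 2), {
    list(
      Biotic_A = plogis(1.2 * eltonsdm:::gaussian_random_field(60, 60, 6)),
      Biotic_B = plogis(eltonsdm:::gaussian_random_field(60, 60, 5))
    )
  })
  truth <- bayes_truth()
  focal <- generate_focal_occurrences(truth, land, biotic, sm,
                                      seed = child_seed_t(seed, 3),
                                      coarse_factor = 3)
  # a random-cell sample of the generating model: the likelihood is then
  # correctly specified, so posterior recovery of the coefficients is a
  # fair calibration check (the pseudo-absence protocol, which biases
  # slopes by construction, has its own contract tests)
  ymat <- matrix(0L, 60, 60)
  ymat[cbind(focal$presences$row, focal$presences$col)] <- 1L
  cells <- withr::with_seed(child_seed_t(seed, 4), {
    idx <- sample.int(3600, n_cells)
    tibble(row = ((idx - 1) %% 60) + 1, col = ((idx - 1) %/% 60) + 1)
  })
  sample <- cells |>
    mutate(subpop = sm[cbind(row, col)], y = ymat[cbind(row, col)],
           set = "train")
  coarse_climate <- lapply(
    setNames(names(truth$climate), names(truth$climate)),
    function(nm) block_aggregate(gs_layer(land$current, nm), 3)
  )
  coarse <- stratified_sample_range(focal$range_grid, coarse_climate,
                                    vars = names(truth$climate), n_bins = 2,
                                    seed = child_seed_t(seed, 5))
  priors <- fit_historical_model(coarse, vars = names(truth$climate),
                                 chains = sampler$chains,
                                 adapt = sampler$adapt,
                                 warmup = sampler$warmup, iter = sampler$iter,
                                 seed = child_seed_t(seed, 6))
  layers <- c(land$current$layers, biotic)
  data <- bind_cols(
    sample,
    tibble::as_tibble(lapply(layers, function(m) m[cbind(sample$row, sample$col)]))
  )
  fit_v <- function(variant, hier) {
    fit_bayes_model(
      data, variant = variant,
      climate_vars = names(truth$climate),
      landuse_vars = names(truth$landuse),
      biotic_vars = names(truth$biotic),
      priors = if (hier) priors else NULL, hierarchical = hier,
      chains = sampler$chains, adapt = sampler$adapt,
      warmup = sampler$warmup, iter = sampler$iter,
      seed = child_seed_t(seed, 7)
    )
  }
  fits <- list(abiotic_biotic = fit_v("abiotic_biotic", TRUE))
  if (fit_extra_variants) {
    fits$abiotic <- fit_v("abiotic", TRUE)
    fits$null <- fit_v("null", FALSE)
  }
  list(seed = seed, landscape = land, subpop_map = sm, biotic = biotic,
       truth = truth, focal = focal, data = data, priors = priors,
       fits = fits)
}

child_seed_t <- function(seed, stream) eltonsdm:::child_seed(seed, stream)

# the full synthetic study (t-scale setup), computed once per session
.pipeline_cache <- new.env(parent = emptyenv())
acceptance_pipeline <- function(seed = 1) {
  key <- paste0("run_", seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- suppressWarnings(run_synthetic_study(seed = seed))
  }
  .pipeline_cache[[key]]
}

# cache: the replicate list grows on demand and is shared across checks
.bayes_rep_cache <- new.env(parent = emptyenv())
bayes_replicates <- function(n_reps = 20) {
  reps <- .bayes_rep_cache$reps %||% list()
  while (length(reps) < n_reps) {
    k <- length(reps) + 1
    reps[[k]] <- suppressWarnings(simulate_bayes_replicate(1000 + k))
    .bayes_rep_cache$reps <- reps
  }
  reps[seq_len(n_reps)]
}

# express the generating coefficients in the fitted (standardized) design
# coordinates: if the fit standardizes x as z' = (x - c')/s' while the truth
# used z = (x - c)/s, then z = a z' + d with a = s'/s, d = (c' - c)/s, and
#   b1 z + b2 z^2 = (b1 a + 2 b2 a d) z' + (b2 a^2) z'^2 + (b1 d + b2 d^2)
implied_true_beta <- function(truth, std_truth, std_fit, terms) {
  beta <- setNames(rep(0, length(terms)), terms)
  beta["(Intercept)"] <- truth$intercept
  shift <- function(v, b1, b2 = 0) {
    ct <- std_truth[std_truth$variable == v, ]
    cf <- std_fit[std_fit$variable == v, ]
    a <- cf$scale / ct$scale
    d <- (cf$center - ct$center) / ct$scale
    list(lin = b1 * a + 2 * b2 * a * d, quad = b2 * a^2,
         const = b1 * d + b2 * d^2)
  }
  for (v in names(truth$climate)) {
    tr <- shift(v, truth$climate[[v]][1], truth$climate[[v]][2])
    beta[v] <- tr$lin
    beta[paste0(v, "_sq")] <- tr$quad
    beta["(Intercept)"] <- beta["(Intercept)"] + tr$const
  }
  for (v in names(truth$landuse)) {
    tr <- shift(v, truth$landuse[[v]])
    beta[v] <- tr$lin
    beta["(Intercept)"] <- beta["(Intercept)"] + tr$const
  }
  for (v in names(truth$biotic %||% c())) {
    tr <- shift(v, truth$biotic[[v]])
    beta[v] <- tr$lin
    beta["(Intercept)"] <- beta["(Intercept)"] + tr$const
  }
  beta
}

`%||%` <- function(x, y) if (is.null(x)) y else x
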