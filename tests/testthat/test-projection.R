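projection_fixture <- function() {
  rep <- bayes_replicates(1)[[1]]
  land <- rep$landscape
  sm <- rep$subpop_map
  diet <- tibble(
    subpop = rep(sort(unique(as.vector(sm))), each = 2),
    species_id = rep(c("sp_a", "sp_b"), 4),
    category = rep(c("vertebrates", "reproductive plants"), 4),
    origin = "wild",
    redec = rep(c(0.6, 0.4), 4)
  )
  class(diet) <- c("subpop_diet", class(diet))
  hs_current <- list(sp_a = rep$biotic$Biotic_A, sp_b = rep$biotic$Biotic_B)
  sets <- list(current = build_biotic_layer_set(diet, hs_current, sm))
  for (s in names(land$scenarios)) {
    hs_s <- list(sp_a = pmin(rep$biotic$Biotic_A * 0.8, 1),
                 sp_b = pmin(rep$biotic$Biotic_B * 0.9, 1))
    sets[[s]] <- build_biotic_layer_set(diet, hs_s, sm, scenario = s)
  }
  # refit on layers whose names match the projection layer sets
  dat <- rep$data
  bm <- biotic_matrices(sets$current)
  dat$Biotic_vertebrates <- bm$Biotic_vertebrates[cbind(dat$row, dat$col)]
  dat$Biotic_reproductive_plants <-
    bm$Biotic_reproductive_plants[cbind(dat$row, dat$col)]
  fit <- suppressWarnings(fit_bayes_model(
    dat, variant = "abiotic_biotic",
    climate_vars = names(rep$truth$climate),
    landuse_vars = names(rep$truth$landuse),
    biotic_vars = c("Biotic_vertebrates", "Biotic_reproductive_plants"),
    priors = rep$priors,
    chains = fast_sampler$chains, adapt = fast_sampler$adapt,
    warmup = fast_sampler$warmup, iter = fast_sampler$iter,
    seed = 77
  ))
  list(rep = rep, land = land, sm = sm, sets = sets, fit = fit, data = dat)
}

.proj_cache <- new.env(parent = emptyenv())
get_projection_fixture <- function() {
  if (is.null(.proj_cache$fx)) .proj_cache$fx <- projection_fixture()
  .proj_cache$fx
}

test_that("scenario projection pins the non-changing blocks and masks by distance", {
  fx <- get_projection_fixture()
  thr <- quantile(fx$fit$fitted, 0.5, names = FALSE)
  runs <- project_scenarios(fx$fit, fx$land, fx$sets, thr, fx$sm,
                            buffer_km = 200)
  expect_length(runs$runs, 9) # 3 SSPs x 3 modes
  # identity: a "scenario" equal to current reproduces the current map
  land_id <- fx$land
  land_id$scenarios <- list(same = land_id$current)
  sets_id <- fx$sets["current"]
  sets_id$same <- fx$sets$current
  runs_id <- project_scenarios(fx$fit, land_id, sets_id, thr, fx$sm)
  expect_equal(runs_id$runs[["same|abiotic_biotic"]]$prob,
               runs_id$current$prob)

  # abiotic-only mode is invariant to arbitrary biotic perturbation
  sets_pert <- fx$sets
  for (s in setdiff(names(sets_pert), "current")) {
    sets_pert[[s]]$quantitative <- lapply(sets_pert[[s]]$quantitative,
                                          function(m) m * 0 + 99)
    sets_pert[[s]]$all_species <- sets_pert[[s]]$all_species * 0 + 99
  }
  runs_pert <- project_scenarios(fx$fit, fx$land, sets_pert, thr, fx$sm)
  for (s in names(fx$land$scenarios)) {
    key <- paste0(s, "|abiotic")
    expect_equal(runs_pert$runs[[key]]$prob, runs$runs[[key]]$prob)
  }

  # a small buffer masks every predicted presence beyond it (brute force)
  runs_small <- project_scenarios(fx$fit, fx$land, fx$sets, thr, fx$sm,
                                  buffer_km = 8)
  cur <- which(runs_small$current$binary == 1, arr.ind = TRUE)
  r1 <- runs_small$runs[[1]]$binary
  pred <- which(!is.na(r1) & r1 == 1, arr.ind = TRUE)
  if (nrow(pred) > 0) {
    dmin <- apply(pred, 1, function(p) {
      min(sqrt((p[1] - cur[, 1])^2 + (p[2] - cur[, 2])^2))
    })
    expect_true(all(dmin <= 8))
  }
})

test_that("range descriptors recover exact areas, changes and protected fractions", {
  fx <- get_projection_fixture()
  thr <- quantile(fx$fit$fitted, 0.5, names = FALSE)
  runs <- project_scenarios(fx$fit, fx$land, fx$sets, thr, fx$sm)
  # future identical to current: zero change everywhere
  runs0 <- runs
  same <- runs$current
  same$scenario <- "X"; same$mode <- "abiotic_biotic"
  runs0$runs <- list("X|abiotic_biotic" = same)
  rep0 <- range_descriptors(runs0, fx$sm,
                            protected = matrix(TRUE, 60, 60))
  expect_true(all(rep0$pct_change == 0, na.rm = TRUE))
  expect_true(all(rep0$pct_protected == 100, na.rm = TRUE))

  # halving the presence cells halves the overall area
  half <- runs$current
  half$scenario <- "X"; half$mode <- "abiotic_biotic"
  pres <- which(half$binary == 1)
  drop <- pres[seq(1, length(pres), by = 2)]
  half$binary[drop] <- 0
  runs_h <- runs
  runs_h$runs <- list("X|abiotic_biotic" = half)
  rep_h <- range_descriptors(runs_h, fx$sm)
  overall <- rep_h |> filter(subpop == "overall", scenario == "X")
  n_cur <- sum(runs$current$binary == 1, na.rm = TRUE)
  expect_equal(overall$area_km2, n_cur - length(drop))
  expect_equal(overall$pct_change, 100 * (-length(drop)) / n_cur)
  # areas are additive over subpopulations
  by_sp <- rep_h |> filter(subpop != "overall", scenario == "X")
  expect_equal(sum(by_sp$area_km2), overall$area_km2)
})

test_that("biotic sensitivity is exact at identical bounds and stable under small ones", {
  fx <- get_projection_fixture()
  layers <- c(fx$land$current$layers, biotic_matrices(fx$sets$current))
  bv <- fx$fit$data$biotic_vars
  orig <- layers[bv]
  # identical bounds reproduce the original posterior exactly
  sens0 <- suppressWarnings(sensitivity_biotic(
    fx$fit, fx$data, lower = orig, upper = orig, layers = layers,
    subpop_map = fx$sm
  ))
  expect_equal(sens0$report$prediction_correlation, c(1, 1))
  expect_equal(nrow(sens0$report), 2)
  expect_length(sens0$fits, 2)

  # +/- 1% perturbation keeps prediction maps nearly unchanged
  lo <- lapply(orig, function(m) m * 0.99)
  up <- lapply(orig, function(m) m * 1.01)
  sens <- suppressWarnings(sensitivity_biotic(
    fx$fit, fx$data, lower = lo, upper = up, layers = layers,
    subpop_map = fx$sm
  ))
  expect_true(all(sens$report$prediction_correlation > 0.99))
  expect_error(
    sensitivity_biotic(fx$fit, fx$data, lower = up, upper = lo,
                       layers = layers, subpop_map = fx$sm),
    "inverted"
  )
})

test_that("suitability bounds bracket the ensemble prediction", {
  land <- small_landscape(seed = 50)
  z <- as.vector(scale(as.vector(gs_layer(land$current, "Clim_8"))))
  withr::with_seed(6, idx <- sample(3600, 500))
  pa <- tibble(row = ((idx - 1) %% 60) + 1, col = ((idx - 1) %/% 60) + 1)
  pa$y <- withr::with_seed(7, rbinom(500, 1, plogis(1.3 * z[idx])))
  pa <- dplyr::bind_cols(pa, gs_values_at(land$current, pa, "Clim_8"))
  m <- fit_ensemble(pa, "Clim_8", seed = 8, species = "sp")
  b <- suitability_bounds(list(sp = m), land)
  mid <- predict_suitability(m, land)
  expect_true(all(b$lower$sp <= mid + 1e-9))
  expect_true(all(b$upper$sp >= mid - 1e-9))
})
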