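test_that("gridding collapses duplicates, is idempotent, and flags sparse species", {
  occ <- tibble(species_id = "sp",
                x = c(rep(2.3, 10), 5.1, 7.9), # 10 points in one cell
                y = c(rep(3.7, 10), 5.5, 2.2))
  pres <- grid_presences(occ, min_cells = 50)
  expect_equal(nrow(pres), 3)
  expect_true(attr(pres, "excluded"))
  # idempotence: gridding the gridded cells changes nothing
  again <- grid_presences(pres |> mutate(species_id = "sp"), min_cells = 50)
  expect_equal(as.data.frame(again[c("row", "col")]),
               as.data.frame(pres[c("row", "col")]))
  # 49 vs 50 cells around the exclusion threshold
  occ49 <- tibble(species_id = "sp", row = 1:49, col = 1)
  expect_true(attr(grid_presences(occ49), "excluded"))
  occ50 <- tibble(species_id = "sp", row = 1:50, col = 1)
  expect_false(attr(grid_presences(occ50), "excluded"))
  expect_error(grid_presences(occ |> filter(FALSE)), "no occurrences")
})

test_that("annulus pseudo-absences respect the distance band and count contract", {
  withr::with_seed(8, {
    pres <- tibble(row = sample(20:40, 12), col = sample(20:40, 12)) |>
      dplyr::distinct()
  })
  ab <- sample_pseudoabsences_annulus(pres, 60, 60, seed = 3)
  expect_equal(nrow(ab), nrow(pres))
  # brute-force nearest-presence distances all in (3, 10]
  dmin <- apply(ab, 1, function(a) {
    min(sqrt((a[1] - pres$row)^2 + (a[2] - pres$col)^2))
  })
  expect_true(all(dmin > 3 & dmin <= 10))
  # never coincides with a presence cell
  expect_equal(nrow(dplyr::inner_join(ab, pres, by = c("row", "col"))), 0)
  expect_identical(ab, sample_pseudoabsences_annulus(pres, 60, 60, seed = 3))
  # degenerate: single presence on a tiny map truncates the annulus
  expect_error(
    sample_pseudoabsences_annulus(tibble(row = 2, col = 2), 4, 4,
                                  inner_km = 3, outer_km = 10, seed = 1),
    "insufficient"
  )
})

test_that("variable selection ranks the generating gradient first and dedups clones", {
  land <- small_landscape(seed = 12)
  hits <- 0
  for (k in 1:100) {
    withr::with_seed(2000 + k, {
      cells <- tibble(row = sample(1:60, 400, TRUE),
                      col = sample(1:60, 400, TRUE))
      z <- scale(gs_layer(land$current, "Clim_8")[cbind(cells$row, cells$col)])[, 1]
      cells$y <- rbinom(400, 1, plogis(1.4 * z))
    })
    pa <- dplyr::bind_cols(cells,
                           gs_values_at(land$current, cells))
    sel <- select_species_variables(pa, c("Clim_3", "Clim_4", "Clim_8",
                                          "Clim_9", "Urban"))
    hits <- hits + (sel[1] == "Clim_8")
  }
  expect_gte(hits / 100, 0.95)

  # identical layers: exactly one survives the correlation filter
  pa2 <- tibble(y = rep(0:1, 50), a = rnorm(100)) |> mutate(b = a, c = rnorm(100))
  sel2 <- select_species_variables(pa2, c("a", "b", "c"))
  expect_length(intersect(c("a", "b"), sel2), 1)
  # <= 6 candidates supplied: all (uncorrelated) candidates retained
  expect_setequal(as.character(select_species_variables(pa2, c("a", "c"))),
                  c("a", "c"))
})

test_that("the ensemble separates a clean niche and stays honest under shuffled labels", {
  land <- small_landscape(seed = 13)
  z <- scale(as.vector(gs_layer(land$current, "Clim_8")))[, 1]
  withr::with_seed(3, {
    idx <- sample(3600, 700)
  })
  pa <- tibble(
    row = ((idx - 1) %% 60) + 1, col = ((idx - 1) %/% 60) + 1,
    y = as.integer(z[idx] > 0) # perfectly separable by Clim_8
  )
  pa <- dplyr::bind_cols(pa, gs_values_at(land$current, pa,
                                          c("Clim_8", "Clim_3")))
  m <- fit_ensemble(pa, c("Clim_8", "Clim_3"), seed = 5, species = "sep")
  expect_gte(m$evaluation$tss, 0.95)
  expect_equal(sum(m$weights), 1)
  expect_true(all(m$weights >= 0))

  # shuffled labels: mean TSS across seeds is near zero
  tss <- vapply(1:30, function(k) {
    pa_s <- pa
    pa_s$y <- withr::with_seed(5000 + k, sample(pa$y))
    fit_ensemble(pa_s, c("Clim_8", "Clim_3"), seed = k)$evaluation$tss
  }, numeric(1))
  expect_lt(abs(mean(tss)), 0.1)
})

test_that("suitability prediction is bounded, current-identical, and monotone where the model is", {
  land <- small_landscape(seed = 14)
  z <- as.vector(scale(as.vector(gs_layer(land$current, "Clim_8"))))
  withr::with_seed(4, idx <- sample(3600, 600))
  pa <- tibble(row = ((idx - 1) %% 60) + 1, col = ((idx - 1) %/% 60) + 1)
  pa$y <- withr::with_seed(5, rbinom(600, 1, plogis(1.2 * z[idx])))
  pa <- dplyr::bind_cols(pa, gs_values_at(land$current, pa, "Clim_8"))
  m <- fit_ensemble(pa, "Clim_8", seed = 6, species = "mono")
  hs <- predict_suitability(m, land)
  expect_true(all(hs >= 0 & hs <= 1))
  expect_identical(hs, predict_suitability(m, land, scenario = "current"))
  # constant layers give a constant map
  const <- list(Clim_8 = matrix(10, 10, 10))
  expect_equal(sd(predict_suitability(m, const)), 0)
  # monotone gradient: prediction increases with the layer (rank correlation)
  grad <- list(Clim_8 = matrix(seq(0, 20, length.out = 100), 10, 10))
  p <- predict_suitability(m, grad)
  expect_gt(cor(as.vector(grad$Clim_8), as.vector(p), method = "spearman"), 0.9)
  expect_error(predict_suitability(m, list(Other = matrix(1, 2, 2))),
               "missing layer")
})

test_that("recovered skill across synthetic species clears the ensemble sanity floor", {
  land <- small_landscape(seed = 15, nrow = 80, ncol = 80)
  cfg <- land$config
  pool <- tibble(species_id = sprintf("s%02d", 1:20), wild = TRUE)
  niches <- eltonsdm:::random_food_niches(
    pool, cfg$climate_layers,
    setdiff(cfg$landuse_layers, "Natural Landscape"),
    seed = 21
  )
  food <- generate_food_species(niches, land, seed = 22, points_per_cell = 1)
  tss <- c()
  for (sp in pool$species_id) {
    pres <- grid_presences(food$occurrences, sp)
    if (attr(pres, "excluded")) next
    if (nrow(pres) > 500) {
      pres <- withr::with_seed(23, dplyr::slice_sample(pres, n = 500))
    }
    ab <- tryCatch(
      sample_pseudoabsences_annulus(pres, 80, 80, seed = 24),
      error = function(e) NULL
    )
    if (is.null(ab)) next
    pa <- assemble_pa_table(pres, ab, land)
    vars <- select_species_variables(pa, c(cfg$climate_layers,
                                           cfg$landuse_layers))
    m <- fit_ensemble(pa, vars, seed = 25, species = sp, nrounds = 30)
    tss <- c(tss, m$evaluation$tss)
  }
  expect_gte(length(tss), 10)
  expect_gte(mean(tss), 0.4)
})
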