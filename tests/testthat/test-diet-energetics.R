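test_that("imputation leaves complete studies untouched and honours exact linear relations", {
  d <- hand_diet()
  out <- impute_rv(d, n_bootstrap = 50, seed = 1)
  expect_equal(out$rV, d$rV)
  expect_false(any(out$rv_imputed))

  # rV identically equal to rF in complete studies -> imputed rV equals rF
  d2 <- bind_rows(
    d,
    tibble(
      study_id = "s3", subpop = "SP1", row = 5, col = 5,
      sample_type = "scat", Z = 80L,
      item_id = c("s3_a", "s3_b", "s3_c"),
      species_id = c("sp_a", "sp_b", "sp_c"),
      category = "vertebrates", origin = "wild",
      f = c(2L, 3L, 5L), rF = c(0.2, 0.3, 0.5),
      v = NA_real_, rV = NA_real_, CF_E = 1
    )
  )
  out2 <- impute_rv(d2, n_bootstrap = 50, seed = 1)
  imp <- out2 |> filter(study_id == "s3")
  expect_true(all(imp$rv_imputed))
  expect_equal(imp$rV, imp$rF, tolerance = 1e-9)
  expect_equal(sum(imp$rV), 1, tolerance = 1e-9)
  # observed values never altered by imputation
  expect_equal(out2 |> filter(study_id != "s3") |> pull(rV),
               d$rV)
  expect_error(impute_rv(d2 |> mutate(rV = NA_real_)), "at least 2")
})

test_that("bootstrap interval of the generator's correlation covers the target in most replicates", {
  cfg <- default_diet_fixture()
  sm <- make_subpop_map(60, 60, 2, 2)
  hits <- 0
  for (k in 1:50) {
    d <- generate_diet_studies(cfg, sm, seed = 600 + k)
    rep <- attr(impute_rv(d, n_bootstrap = 200, seed = k),
                "correlation_report")
    hits <- hits + (rep$ci_lower <= 0.86 && 0.86 <= rep$ci_upper)
  }
  expect_gte(hits / 50, 0.9)
})

test_that("rEDEC follows the energy-correction equation", {
  # two items, rEDC = (0.6, 0.4), CF_E = (2, 1) -> rEDEC = (0.75, 0.25)
  d <- hand_diet() |> filter(study_id == "s1") |>
    mutate(CF_E = c(2, 1))
  out <- compute_redec(d)
  expect_equal(out$rEDEC, c(0.75, 0.25))
  expect_equal(out$rEDC, c(0.6, 0.4))

  # equal CF -> rEDEC equals rEDC; invariance under common scaling of CF
  d1 <- compute_redec(hand_diet())
  expect_equal(d1$rEDEC, d1$rEDC)
  d_scaled <- compute_redec(hand_diet() |> mutate(CF_E = CF_E * 7.3))
  expect_equal(d_scaled$rEDEC, d1$rEDEC)

  # normalization within every study
  cfg <- default_diet_fixture()
  sm <- make_subpop_map(60, 60, 2, 2)
  big <- compute_redec(impute_rv(generate_diet_studies(cfg, sm, seed = 3),
                                 n_bootstrap = 50, seed = 1))
  sums <- big |> group_by(study_id) |> summarise(s = sum(rEDEC))
  expect_true(all(abs(sums$s - 1) < 1e-9))

  # CF lookup: item-specific beats category default; absence errors
  cf_tbl <- tibble(category = c("vertebrates", "reproductive plants"),
                   cf_e = c(5, 1))
  out_cat <- compute_redec(hand_diet() |> select(-CF_E), cf_table = cf_tbl)
  expect_equal(out_cat$CF_E, c(5, 1, 5, 1))
  expect_error(
    compute_redec(hand_diet() |> select(-CF_E),
                  cf_table = tibble(category = "vertebrates", cf_e = 5)),
    "missing CF_E"
  )
})

test_that("subpopulation aggregation is the Z-weighted mean with absent species at zero", {
  # two studies, Z = (100, 50), species shares (0.3, 0) -> 0.2
  d <- tibble(
    study_id = c("s1", "s1", "s2"),
    subpop = "SP1", row = 1, col = 1, sample_type = "scat",
    Z = c(100L, 100L, 50L),
    item_id = c("i1", "i2", "i3"),
    species_id = c("target", "other", "other"),
    category = c("vertebrates", "vertebrates", "vertebrates"),
    origin = "wild",
    f = 1L, rF = c(0.3, 0.7, 1), v = 1, rV = c(0.3, 0.7, 1), CF_E = 1
  )
  d <- compute_redec(d)
  agg <- aggregate_subpopulation_diet(d)
  expect_equal(agg$redec[agg$species_id == "target"],
               (100 * 0.3 + 50 * 0) / 150)
  # single-study subpopulation: aggregation is the identity
  one <- compute_redec(hand_diet() |> filter(study_id == "s1"))
  agg1 <- aggregate_subpopulation_diet(one)
  expect_equal(sort(agg1$redec), sort(one$rEDEC))
  # weights: equal Z equals the unweighted mean
  deq <- d |> mutate(Z = 100L) |> compute_redec()
  aggeq <- aggregate_subpopulation_diet(deq)
  expect_equal(aggeq$redec[aggeq$species_id == "target"], mean(c(0.3, 0)))
  # unresolved remainder: genus-level items leave a gap
  dg <- compute_redec(d |> mutate(species_id = ifelse(item_id == "i2",
                                                      NA, species_id)))
  aggg <- aggregate_subpopulation_diet(dg)
  unres <- attr(aggg, "unresolved")
  expect_equal(sum(aggg$redec) + unres$unresolved, 1, tolerance = 1e-9)
  expect_error(aggregate_subpopulation_diet(d, subpops = "SP9"), "no studies")
})

test_that("category and origin shares sum to one and match hand-summed labels", {
  d <- compute_redec(hand_diet())
  cs <- classify_items(d)
  s1cat <- cs |> filter(study_id == "s1", dimension == "category")
  expect_equal(sum(s1cat$share), 1)
  expect_equal(s1cat$share[s1cat$label == "vertebrates"], 0.6)
  s2orig <- cs |> filter(study_id == "s2", dimension == "origin")
  expect_equal(s2orig$share[s2orig$label == "human-derived"], 0.5)
  # permutation invariance
  cs_perm <- classify_items(d[c(3, 1, 4, 2), ])
  expect_equal(
    cs |> arrange(study_id, dimension, label),
    cs_perm |> arrange(study_id, dimension, label)
  )
  # single-category study
  dv <- compute_redec(hand_diet() |> mutate(category = "vertebrates"))
  cv <- classify_items(dv) |> filter(dimension == "category")
  expect_true(all(cv$share == 1))
  expect_error(classify_items(d |> mutate(category = "fungi", rEDEC = rEDEC)),
               "unknown category")
})
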