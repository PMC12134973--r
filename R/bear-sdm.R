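#' Environmentally stratified sampling of the coarse historical range
#'
#' Builds strata by quantile-binning each coarse climate variable and
#' intersecting the bins; within every stratum containing both historical
#' presences and absences, an equal number of each class
#' (`min(n_presence, n_absence)`) is drawn. Strata lacking a class are
#' skipped and logged.
#'
#' @param range_grid Coarse 0/1 matrix of historical presence.
#' @param coarse_climate Named list of coarse climate matrices (must
#'   include the variables in `vars`).
#' @param vars Climate variables defining the strata.
#' @param n_bins Quantile bins per variable (default 3).
#' @param seed Integer seed.
#' @return Tibble of sampled coarse cells: `row`, `col`, `y`, `stratum`
#'   and the climate values; skipped strata are attached as attribute
#'   `"skipped"`.
#' @export
stratified_sample_range <- function(range_grid, coarse_climate,
                                    vars = c("Clim_3", "Clim_4", "Clim_8", "Clim_9"),
                                    n_bins = 3, seed = 1) {
  missing <- setdiff(vars, names(coarse_climate))
  if (length(missing) > 0) {
    abort(sprintf("coarse climate missing: %s", paste(missing, collapse = ", ")))
  }
  cells <- which(!is.na(range_grid), arr.ind = TRUE)
  tbl <- tibble(row = cells[, 1], col = cells[, 2],
                y = range_grid[cells])
  for (v in vars) tbl[[v]] <- coarse_climate[[v]][cells]
  bins <- lapply(vars, function(v) {
    br <- unique(quantile(tbl[[v]], probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) return(rep(1L, nrow(tbl)))
    as.integer(cut(tbl[[v]], br, include.lowest = TRUE))
  })
  tbl$stratum <- do.call(paste, c(bins, sep = "-"))
  withr::with_seed(stopifnot_scalar_seed(seed), {
    sampled <- list()
    skipped <- character()
    for (s in sort(unique(tbl$stratum))) {
      sub <- tbl |> filter(.data$stratum == s)
      n1 <- sum(sub$y == 1); n0 <- sum(sub$y == 0)
      if (n1 == 0 || n0 == 0) {
        skipped <- c(skipped, s)
        next
      }
      m <- min(n1, n0)
      pick <- c(sample(which(sub$y == 1), m), sample(which(sub$y == 0), m))
      sampled[[s]] <- sub[pick, ]
    }
  })
  if (length(sampled) == 0) abort("no stratum contains both classes.")
  structure(bind_rows(sampled), skipped = skipped)
}

# ---- JAGS machinery ---------------------------------------------------------

jags_logistic_code <- function(random_intercept) {
  ranef <- if (random_intercept) "
  for (k in 1:G) { u[k] ~ dnorm(0, tau_u) }
  sigma_u ~ dt(0, pow(2.5, -2), 3) T(0,)
  tau_u <- pow(sigma_u, -2)" else ""
  eta_u <- if (random_intercept) " + u[g[i]]" else ""
  sprintf("
model {
  for (i in 1:N) {
    y[i] ~ dbern(p[i])
    logit(p[i]) <- inprod(X[i,], beta)%s
  }
  for (j in 1:P) { beta[j] ~ dnorm(mu[j], prec[j]) }%s
}", eta_u, ranef)
}

run_jags_logistic <- function(X, y, g = NULL, prior_mean, prior_sd,
                              chains = 4, adapt = 500, warmup = 1000,
                              iter = 1000, seed = 1) {
  random_intercept <- !is.null(g)
  dat <- list(y = y, X = X, N = length(y), P = ncol(X),
              mu = prior_mean, prec = 1 / prior_sd^2)
  if (random_intercept) {
    dat$g <- as.integer(g)
    dat$G <- max(as.integer(g))
  }
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = child_seed(seed, ch))
  })
  monitor <- c("beta", if (random_intercept) c("u", "sigma_u"))
  jm <- rjags::jags.model(
    textConnection(jags_logistic_code(random_intercept)),
    data = dat, inits = inits, n.chains = chains, n.adapt = adapt,
    quiet = TRUE
  )
  stats::update(jm, n.iter = warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitor, n.iter = iter,
                              progress.bar = "none")
  # JAGS drops the index on length-1 monitored vectors
  coda::as.mcmc.list(lapply(samp, function(ch) {
    cn <- colnames(ch)
    cn[cn == "beta"] <- "beta[1]"
    cn[cn == "u"] <- "u[1]"
    colnames(ch) <- cn
    ch
  }))
}

# per-parameter convergence diagnostics from an mcmc.list
mcmc_diagnostics <- function(samples, names_map = NULL) {
  combined <- as.matrix(samples)
  rhat <- tryCatch({
    if (length(samples) >= 2) {
      coda::gelman.diag(samples, autoburnin = FALSE,
                        multivariate = FALSE)$psrf[, 1]
    } else {
      rep(NA_real_, ncol(combined))
    }
  }, error = function(e) rep(NA_real_, ncol(combined)))
  neff <- coda::effectiveSize(samples)
  term <- colnames(combined)
  if (!is.null(names_map)) {
    mapped <- names_map[term]
    term <- ifelse(is.na(mapped), term, mapped)
  }
  tibble(
    parameter = colnames(combined),
    term = term,
    mean = colMeans(combined),
    sd = apply(combined, 2, sd),
    q10 = apply(combined, 2, quantile, 0.10),
    q50 = apply(combined, 2, quantile, 0.50),
    q90 = apply(combined, 2, quantile, 0.90),
    rhat = unname(rhat[colnames(combined)]),
    n_eff = unname(neff[colnames(combined)]),
    mcse = .data$sd / sqrt(pmax(.data$n_eff, 1))
  )
}

# WAIC from an n x S pointwise log-likelihood matrix
waic_from_loglik <- function(ll) {
  s <- ncol(ll)
  max_ll <- apply(ll, 1, max)
  lppd_i <- max_ll + log(rowMeans(exp(ll - max_ll)))
  p_i <- apply(ll, 1, var)
  waic_i <- -2 * (lppd_i - p_i)
  list(
    waic = sum(waic_i),
    se = sqrt(nrow(ll) * var(waic_i)),
    lppd = sum(lppd_i),
    p_waic = sum(p_i),
    pointwise = waic_i
  )
}

#' Fit the Bayesian historical-range model and extract transferable priors
#'
#' A Bayesian binomial GLM (logit link) of historical presence on the four
#' standardized climate variables with linear and quadratic terms, under
#' weakly-informative defaults (normal(0, 2.5) slopes, normal(0, 5)
#' intercept). The posterior mean and SD of every coefficient form the
#' prior set transferred to the fine-scale models; the standardization
#' constants are recorded so fine-scale design matrices use the identical
#' scaling.
#'
#' @param sample Coarse presence/absence tibble from
#'   [stratified_sample_range()] (columns `y` and the climate variables).
#' @param vars Climate variable names.
#' @param chains,adapt,warmup,iter MCMC settings.
#' @param seed Integer seed.
#' @return A tibble of class `prior_set` (`term`, `mean`, `sd`) with
#'   attributes `standardization` (variable, center, scale) and
#'   `diagnostics`.
#' @export
fit_historical_model <- function(sample,
                                 vars = c("Clim_3", "Clim_4", "Clim_8", "Clim_9"),
                                 chains = 4, adapt = 500, warmup = 1000,
                                 iter = 1000, seed = 1) {
  if (length(unique(sample$y)) < 2) abort("sample needs both classes.")
  std <- standardize_tbl(sample[vars])
  Z <- as.matrix(std$values)
  X <- cbind(1, Z, Z^2)
  terms <- c("(Intercept)", vars, paste0(vars, "_sq"))
  colnames(X) <- terms
  prior_mean <- rep(0, ncol(X))
  prior_sd <- c(5, rep(2.5, ncol(X) - 1))
  samp <- run_jags_logistic(X, sample$y, g = NULL, prior_mean, prior_sd,
                            chains = chains, adapt = adapt, warmup = warmup,
                            iter = iter, seed = seed)
  names_map <- setNames(terms, paste0("beta[", seq_along(terms), "]"))
  diag <- mcmc_diagnostics(samp, names_map)
  out <- diag |> select(term = "term", mean = "mean", sd = "sd")
  attr(out, "standardization") <- std$constants
  attr(out, "diagnostics") <- diag
  class(out) <- c("prior_set", class(out))
  out
}

# largest-remainder allocation of per-group training counts so the total
# equals round(frac * sum(counts)) exactly
allocate_train_counts <- function(counts, frac) {
  target <- round(frac * sum(counts))
  base <- floor(frac * counts)
  rem <- frac * counts - base
  extra <- target - sum(base)
  ord <- order(-rem, names(counts))
  add <- integer(length(counts))
  if (extra > 0) add[ord[seq_len(extra)]] <- 1L
  setNames(as.integer(base + add), names(counts))
}

#' Prepare the focal-species presence / pseudo-absence sample
#'
#' Grids raw occurrences to unique 1-km presence cells, removes cells on a
#' non-terrestrial mask, caps presences per subpopulation by a uniform
#' seeded subsample (default 2000), draws an equal number of
#' pseudo-absence cells per subpopulation from non-presence terrestrial
#' cells within `pa_buffer_km` of that subpopulation's presences, and
#' splits presences and pseudo-absences 80/20 into training and validation
#' sets, stratified by subpopulation (largest-remainder allocation, so the
#' training total equals `round(train_frac * N)` exactly).
#'
#' @param occurrences Tibble with `row`/`col` cells or `x`/`y` points.
#' @param subpop_map Character matrix of subpopulation ids.
#' @param mask Optional logical matrix (`TRUE` = terrestrial); `NULL`
#'   keeps every cell.
#' @param cap Maximum presences per subpopulation (default 2000).
#' @param train_frac Training fraction (default 0.8).
#' @param pa_buffer_km Pseudo-absence buffer radius (default 5).
#' @param seed Integer seed.
#' @return Tibble of class `occurrence_sample`: `row`, `col`, `subpop`,
#'   `y` (1 presence / 0 pseudo-absence), `set` (`"train"` /
#'   `"validation"`).
#' @export
prepare_occurrences <- function(occurrences, subpop_map, mask = NULL,
                                cap = 2000, train_frac = 0.8,
                                pa_buffer_km = 5, seed = 1) {
  occ <- occurrences
  if (!all(c("row", "col") %in% names(occ))) {
    occ <- occ |> mutate(row = ceiling(.data$y), col = ceiling(.data$x))
  }
  cells <- occ |> dplyr::distinct(.data$row, .data$col)
  cells$subpop <- subpop_map[cbind(cells$row, cells$col)]
  cells <- cells |> filter(!is.na(.data$subpop))
  if (!is.null(mask)) {
    cells <- cells |> filter(mask[cbind(.data$row, .data$col)])
  }
  if (nrow(cells) == 0) abort("no presence cells remain after masking.")
  counts <- table(cells$subpop)
  if (any(counts == 0)) abort("a subpopulation has zero presences.")

  withr::with_seed(stopifnot_scalar_seed(seed), {
    pres <- cells |>
      group_by(.data$subpop) |>
      dplyr::slice_sample(n = cap) |>
      ungroup()

    pres_idx <- matrix(FALSE, nrow(subpop_map), ncol(subpop_map))
    pres_idx[cbind(cells$row, cells$col)] <- TRUE # all presence cells excluded
    land_ok <- if (is.null(mask)) TRUE else mask

    abs_list <- list()
    for (sp in sort(unique(pres$subpop))) {
      psp <- pres |> filter(.data$subpop == sp)
      d <- distance_to_cells(nrow(subpop_map), ncol(subpop_map),
                             psp$row, psp$col, pa_buffer_km)
      ok <- d <= pa_buffer_km & d > 0 & !pres_idx
      if (!is.null(mask)) ok <- ok & mask
      cand <- which(ok, arr.ind = TRUE)
      need <- nrow(psp)
      if (nrow(cand) < need) {
        abort(sprintf(
          "insufficient pseudo-absence candidates for %s: need %d, have %d.",
          sp, need, nrow(cand)
        ))
      }
      pick <- sample.int(nrow(cand), need)
      abs_list[[sp]] <- tibble(row = cand[pick, 1], col = cand[pick, 2],
                               subpop = sp)
      pres_idx[cand[pick, , drop = FALSE]] <- TRUE # no reuse across subpops
    }
    absences <- bind_rows(abs_list)

    split_one <- function(tbl) {
      cnt <- table(tbl$subpop)
      tr_n <- allocate_train_counts(
        setNames(as.integer(cnt), names(cnt)), train_frac
      )
      tbl |>
        group_by(.data$subpop) |>
        mutate(set = {
          n_tr <- tr_n[[dplyr::cur_group()$subpop]]
          s <- rep("validation", n())
          s[sample.int(n(), n_tr)] <- "train"
          s
        }) |>
        ungroup()
    }
    out <- bind_rows(
      split_one(pres |> mutate(y = 1L)),
      split_one(absences |> mutate(y = 0L))
    )
  })
  structure(out, class = c("occurrence_sample", class(out)),
            seed = seed, cap = cap, train_frac = train_frac,
            pa_buffer_km = pa_buffer_km)
}

#' Grid-presence yield per monitored individual
#'
#' Small reporting helper: the mean number of filtered presence cells
#' contributed per known individual.
#'
#' @param n_presences Number of presence cells.
#' @param n_individuals Number of individuals.
#' @param digits Rounding (default 1).
#' @return A one-row tibble.
#' @export
presences_per_individual <- function(n_presences, n_individuals, digits = 1) {
  tibble(
    n_presences = n_presences,
    n_individuals = n_individuals,
    presences_per_individual = round(n_presences / n_individuals, digits)
  )
}

#' Select uncorrelated predictors by univariable mixed-model AIC
#'
#' Ranks candidate predictors by the AIC of univariable binomial GLMMs
#' (logit link, subpopulation random intercept), then greedily keeps the
#' best-ranked candidates whose absolute correlation with every kept
#' predictor stays at or below `cor_threshold`, up to `k`.
#'
#' @param data Tibble with `y`, `subpop`, and candidate columns.
#' @param candidates Candidate column names.
#' @param k Number of predictors to keep (default 4).
#' @param cor_threshold Pairwise correlation cap (default 0.7).
#' @return Character vector of selected names, ranking attached as
#'   attribute `"ranking"`.
#' @export
select_glmm_variables <- function(data, candidates, k = 4, cor_threshold = 0.7) {
  ranking <- purrr::map_dfr(candidates, function(v) {
    x <- scale(data[[v]])[, 1]
    aic <- if (sd(data[[v]]) == 0) Inf else {
      fit <- suppressMessages(suppressWarnings(
        lme4::glmer(y ~ x + (1 | subpop), data = mutate(data, x = x),
                    family = binomial())
      ))
      AIC(fit)
    }
    tibble(variable = v, aic = aic)
  }) |> arrange(.data$aic, .data$variable)
  selected <- character()
  for (v in ranking$variable) {
    if (!is.finite(ranking$aic[ranking$variable == v])) next
    if (length(selected) > 0) {
      r <- vapply(selected, function(s) {
        suppressWarnings(abs(cor(data[[v]], data[[s]])))
      }, numeric(1))
      if (any(r > cor_threshold, na.rm = TRUE)) next
    }
    selected <- c(selected, v)
    if (length(selected) >= k) break
  }
  structure(selected, ranking = ranking)
}

bear_terms <- function(climate_vars, landuse_vars, biotic_vars) {
  clim <- if (length(climate_vars) > 0) {
    as.vector(rbind(climate_vars, paste0(climate_vars, "_sq")))
  } else {
    character(0)
  }
  c("(Intercept)", clim, landuse_vars, biotic_vars)
}

# build the fine-scale design matrix; climate gets quadratic terms
bear_design <- function(values, climate_vars, landuse_vars, biotic_vars,
                        standardization) {
  vars <- c(climate_vars, landuse_vars, biotic_vars)
  z <- standardize_tbl(values[vars], standardization)$values
  cols <- list(`(Intercept)` = rep(1, nrow(values)))
  for (v in climate_vars) {
    cols[[v]] <- z[[v]]
    cols[[paste0(v, "_sq")]] <- z[[v]]^2
  }
  for (v in c(landuse_vars, biotic_vars)) cols[[v]] <- z[[v]]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Fit a Bayesian binomial GLMM for the focal-species distribution
#'
#' Full-posterior sampling (Gibbs/Metropolis via JAGS) of a logit model of
#' presence on standardized predictors with a subpopulation random
#' intercept. Four predictor-block variants are supported: climate
#' (linear + quadratic) plus land use plus biotic (`"abiotic_biotic"`),
#' climate plus land use (`"abiotic"`), biotic only (`"biotic"`), and the
#' intercept-only `"null"`. When `hierarchical = TRUE` the intercept and
#' climate coefficients take the historical-model posterior (a
#' [fit_historical_model()] prior set) as informative priors, used
#' unmodified; every other coefficient gets the weakly-informative default
#' (normal(0, 2.5); intercept normal(0, 5)). Climate predictors are
#' standardized with the historical constants so transferred priors refer
#' to the same coordinate system. WAIC is computed from the pointwise
#' posterior log-likelihood; convergence is flagged by split-chain Rhat.
#'
#' @param data Tibble with `y`, `subpop` and predictor columns (e.g. the
#'   training rows of an [prepare_occurrences()] sample joined to layer
#'   values).
#' @param variant One of `"abiotic_biotic"`, `"abiotic"`, `"biotic"`,
#'   `"null"`.
#' @param climate_vars,landuse_vars,biotic_vars Predictor names per block.
#' @param priors Optional `prior_set` from [fit_historical_model()].
#' @param hierarchical Use the historical priors for intercept + climate
#'   (requires `priors` and a climate-containing variant).
#' @param random_intercept Include the subpopulation random intercept
#'   (default TRUE).
#' @param chains,adapt,warmup,iter MCMC settings (defaults 4 chains,
#'   1000 warmup, 1000 sampling draws).
#' @param rhat_max Convergence threshold on split-chain Rhat (default
#'   1.05).
#' @param seed Integer seed.
#' @return An object of class `bear_sdm_fit`.
#' @export
fit_bayes_model <- function(data,
                            variant = c("abiotic_biotic", "abiotic", "biotic", "null"),
                            climate_vars = c("Clim_3", "Clim_4", "Clim_8", "Clim_9"),
                            landuse_vars = character(),
                            biotic_vars = character(),
                            priors = NULL,
                            hierarchical = !is.null(priors),
                            random_intercept = TRUE,
                            chains = 4, adapt = 500, warmup = 1000, iter = 1000,
                            rhat_max = 1.05, seed = 1) {
  variant <- match.arg(variant)
  use_climate <- variant %in% c("abiotic_biotic", "abiotic")
  use_landuse <- variant %in% c("abiotic_biotic", "abiotic")
  use_biotic <- variant %in% c("abiotic_biotic", "biotic")
  cv <- if (use_climate) climate_vars else character()
  lv <- if (use_landuse) landuse_vars else character()
  bv <- if (use_biotic) biotic_vars else character()
  if (hierarchical && is.null(priors)) {
    abort("hierarchical = TRUE requires a prior_set.")
  }
  if (hierarchical && !use_climate) {
    abort("only climate-containing variants can use historical priors.")
  }

  # standardization: climate reuses the historical constants when priors
  # are transferred; other blocks are standardized on the fitting data
  std_hist <- if (!is.null(priors)) attr(priors, "standardization") else NULL
  std_parts <- list()
  if (use_climate) {
    std_parts$climate <- if (hierarchical && !is.null(std_hist)) {
      std_hist |> filter(.data$variable %in% cv)
    } else {
      standardize_tbl(data[cv])$constants
    }
  }
  for (blk in list(lv, bv)) {
    if (length(blk) > 0) {
      std_parts[[length(std_parts) + 1]] <- standardize_tbl(data[blk])$constants
    }
  }
  standardization <- bind_rows(std_parts)

  terms <- bear_terms(cv, lv, bv)
  n <- nrow(data)

  prior_mean <- setNames(rep(0, length(terms)), terms)
  prior_sd <- setNames(rep(2.5, length(terms)), terms)
  prior_sd["(Intercept)"] <- 5
  prior_source <- setNames(rep("default", length(terms)), terms)
  if (hierarchical) {
    for (i in seq_len(nrow(priors))) {
      tm <- priors$term[i]
      if (tm %in% terms && (tm == "(Intercept)" ||
                            grepl(paste(cv, collapse = "|"), tm))) {
        prior_mean[tm] <- priors$mean[i]
        prior_sd[tm] <- priors$sd[i]
        prior_source[tm] <- "historical"
      }
    }
  }

  subpop_levels <- sort(unique(as.character(data$subpop %||% "all")))
  if (n == 0) {
    # prior-predictive limit: no likelihood, sample the priors directly
    withr::with_seed(stopifnot_scalar_seed(seed), {
      S <- chains * iter
      beta <- sapply(terms, function(tm) rnorm(S, prior_mean[tm], prior_sd[tm]))
    })
    diag <- tibble(
      parameter = terms, term = terms,
      mean = colMeans(beta), sd = apply(beta, 2, sd),
      q10 = apply(beta, 2, quantile, 0.1),
      q50 = apply(beta, 2, quantile, 0.5),
      q90 = apply(beta, 2, quantile, 0.9),
      rhat = NA_real_, n_eff = NA_real_, mcse = NA_real_
    )
    return(structure(
      list(variant = variant, hierarchical = hierarchical,
           random_intercept = FALSE, terms = terms,
           draws_beta = beta, draws_u = NULL, subpop_levels = character(),
           waic = NULL, diagnostics = diag,
           priors = tibble(term = terms, prior_mean = unname(prior_mean),
                           prior_sd = unname(prior_sd),
                           prior_source = unname(prior_source)),
           standardization = standardization,
           data = NULL, fitted = NULL, converged = NA, seed = seed),
      class = "bear_sdm_fit"
    ))
  }

  X <- bear_design(data, cv, lv, bv, standardization)
  g <- if (random_intercept && "subpop" %in% names(data)) {
    factor(as.character(data$subpop), levels = subpop_levels)
  } else {
    NULL
  }
  samp <- run_jags_logistic(
    X, data$y, g = if (is.null(g)) NULL else as.integer(g),
    prior_mean = unname(prior_mean), prior_sd = unname(prior_sd),
    chains = chains, adapt = adapt, warmup = warmup, iter = iter, seed = seed
  )
  if (!is.null(g)) {
    # sweep reparameterization: the global intercept and the random
    # intercepts are only jointly identified, so report the swept
    # quantities (intercept + mean(u), u - mean(u)); the linear predictor
    # is unchanged
    u_cols <- paste0("u[", seq_along(subpop_levels), "]")
    samp <- coda::as.mcmc.list(lapply(samp, function(ch) {
      m <- as.matrix(ch)
      u_bar <- rowMeans(m[, u_cols, drop = FALSE])
      m[, "beta[1]"] <- m[, "beta[1]"] + u_bar
      m[, u_cols] <- m[, u_cols] - u_bar
      coda::mcmc(m, start = stats::start(ch), thin = coda::thin(ch))
    }))
  }
  names_map <- c(
    setNames(terms, paste0("beta[", seq_along(terms), "]")),
    if (!is.null(g)) setNames(paste0("u[", subpop_levels, "]"),
                              paste0("u[", seq_along(subpop_levels), "]")),
    if (!is.null(g)) c("sigma_u" = "sigma_u")
  )
  diag <- mcmc_diagnostics(samp, names_map)
  combined <- as.matrix(samp)
  beta <- combined[, paste0("beta[", seq_along(terms), "]"), drop = FALSE]
  colnames(beta) <- terms
  draws_u <- NULL
  eta <- X %*% t(beta)
  if (!is.null(g)) {
    u_cols <- paste0("u[", seq_along(subpop_levels), "]")
    draws_u <- combined[, u_cols, drop = FALSE]
    colnames(draws_u) <- subpop_levels
    eta <- eta + t(draws_u)[as.integer(g), , drop = FALSE]
  }
  pr <- plogis(eta)
  eps <- 1e-12
  ll <- ifelse(matrix(data$y, nrow(eta), ncol(eta)) == 1,
               log(pmax(pr, eps)), log(pmax(1 - pr, eps)))
  waic <- waic_from_loglik(ll)
  fitted <- rowMeans(pr)

  beta_diag <- diag |> filter(.data$parameter %in%
                                paste0("beta[", seq_along(terms), "]"))
  converged <- all(is.na(beta_diag$rhat)) ||
    all(beta_diag$rhat <= rhat_max, na.rm = TRUE)
  if (!converged) {
    warn(sprintf("fit flagged non-converged: max Rhat = %.3f",
                 max(beta_diag$rhat, na.rm = TRUE)))
  }

  structure(
    list(
      variant = variant, hierarchical = hierarchical,
      random_intercept = !is.null(g), terms = terms,
      draws_beta = beta, draws_u = draws_u, subpop_levels = subpop_levels,
      waic = waic, diagnostics = diag,
      priors = tibble(term = terms, prior_mean = unname(prior_mean),
                      prior_sd = unname(prior_sd),
                      prior_source = unname(prior_source)),
      standardization = standardization,
      data = list(
        y = data$y,
        cells = data[intersect(c("row", "col", "subpop", "set"), names(data))],
        climate_vars = cv, landuse_vars = lv, biotic_vars = bv
      ),
      fitted = fitted,
      sampler = list(chains = chains, adapt = adapt, warmup = warmup,
                     iter = iter),
      converged = converged, seed = seed
    ),
    class = "bear_sdm_fit"
  )
}

#' @export
print.bear_sdm_fit <- function(x, ...) {
  cat(sprintf(
    "<bear_sdm_fit> variant: %s | %s priors | %s\n",
    x$variant,
    if (x$hierarchical) "historical (informative)" else "weakly-informative",
    if (is.null(x$waic)) "prior-predictive (no data)" else
      sprintf("WAIC = %.1f (SE %.1f)%s", x$waic$waic, x$waic$se,
              if (isTRUE(x$converged)) "" else " [non-converged]")
  ))
  invisible(x)
}

#' Compare fitted models by WAIC
#'
#' Sorted ascending by WAIC; differences to the best model carry standard
#' errors computed from the pointwise WAIC contributions.
#'
#' @param models Named list of `bear_sdm_fit` objects fitted to the
#'   identical response vector.
#' @return Tibble: `model`, `variant`, `waic`, `se`, `delta_waic`,
#'   `delta_se`.
#' @export
compare_waic <- function(models) {
  ys <- lapply(models, function(m) m$data$y)
  for (i in seq_along(ys)[-1]) {
    if (!identical(ys[[1]], ys[[i]])) {
      abort("models were not fitted to the identical response vector.")
    }
  }
  nm <- names(models) %||% vapply(models, function(m) m$variant, "")
  tbl <- tibble(
    model = nm,
    variant = vapply(models, function(m) m$variant, ""),
    waic = vapply(models, function(m) m$waic$waic, 1),
    se = vapply(models, function(m) m$waic$se, 1)
  ) |> arrange(.data$waic)
  best <- models[[which(nm == tbl$model[1])[1]]]
  tbl$delta_waic <- unname(vapply(tbl$model, function(m) {
    sum(models[[m]]$waic$pointwise - best$waic$pointwise)
  }, 1))
  tbl$delta_se <- unname(vapply(tbl$model, function(m) {
    d <- models[[m]]$waic$pointwise - best$waic$pointwise
    sqrt(length(d) * var(d))
  }, 1))
  tbl
}

#' Threshold the fitted model at the 90th-percentile training presence
#'
#' The presence/absence cutoff is the predicted probability below which
#' 10% of training presences fall (the 10th percentile of training-
#' presence scores), so by construction the training true-positive rate is
#' 0.90 up to one presence's worth of discreteness. Evaluation reports
#' TPR and TNR on the training and validation sets.
#'
#' @param fit A `bear_sdm_fit` with stored data.
#' @param percentile Percentile of training presences retained above the
#'   cutoff (default 90).
#' @return A list of class `bear_threshold`: `threshold`, `evaluation`
#'   (tibble of set, tpr, tnr), `predictions`.
#' @export
threshold_and_evaluate <- function(fit, percentile = 90) {
  if (is.null(fit$data)) abort("fit carries no data to evaluate.")
  cells <- fit$data$cells
  if (!"set" %in% names(cells)) {
    abort("fit data has no train/validation labels.")
  }
  pred <- fit$fitted
  if (sd(pred) == 0) warn("all predictions identical; threshold degenerate.")
  train_pres <- pred[cells$set == "train" & fit$data$y == 1]
  if (length(train_pres) < 10) abort("need at least 10 training presences.")
  thr <- quantile(train_pres, probs = 1 - percentile / 100, type = 1,
                  names = FALSE)
  ev <- purrr::map_dfr(c("train", "validation"), function(s) {
    sel <- cells$set == s
    tibble(
      set = s,
      tpr = mean(pred[sel & fit$data$y == 1] >= thr),
      tnr = mean(pred[sel & fit$data$y == 0] < thr),
      n_presences = sum(sel & fit$data$y == 1),
      n_absences = sum(sel & fit$data$y == 0)
    )
  })
  structure(
    list(threshold = thr, percentile = percentile, evaluation = ev,
         predictions = dplyr::bind_cols(
           cells, tibble(y = fit$data$y, pred = pred, above = pred >= thr)
         )),
    class = "bear_threshold"
  )
}

#' Predict the focal-species probability surface from a fitted model
#'
#' Plug-in prediction at the posterior mean coefficients (and posterior
#' mean subpopulation intercepts; unseen subpopulations get 0).
#'
#' @param fit A `bear_sdm_fit`.
#' @param layers Named list of matrices (or a [grid_stack()] /
#'   `landscape`) supplying every predictor of the fit.
#' @param subpop_map Character matrix of subpopulation ids (required when
#'   the fit has a random intercept).
#' @return Matrix of presence probabilities.
#' @export
predict_distribution <- function(fit, layers, subpop_map = NULL) {
  lyr <- resolve_layers(layers)
  vars <- c(fit$data$climate_vars, fit$data$landuse_vars, fit$data$biotic_vars)
  missing <- setdiff(vars, names(lyr))
  if (length(missing) > 0) {
    abort(sprintf("missing layer(s): %s", paste(missing, collapse = ", ")))
  }
  dims <- if (length(vars) > 0) dim(lyr[[vars[1]]]) else dim(subpop_map)
  if (is.null(dims)) abort("cannot infer grid dimensions.")
  vals <- as_tibble(lapply(lyr[vars], as.vector))
  if (length(vars) == 0) vals <- tibble(.rows = prod(dims))
  X <- bear_design(vals, fit$data$climate_vars, fit$data$landuse_vars,
                   fit$data$biotic_vars, fit$standardization)
  beta_hat <- colMeans(fit$draws_beta)
  eta <- as.vector(X %*% beta_hat)
  if (fit$random_intercept) {
    if (is.null(subpop_map)) abort("subpop_map required for random-intercept fits.")
    u_hat <- colMeans(fit$draws_u)
    u_cell <- u_hat[as.vector(subpop_map)]
    u_cell[is.na(u_cell)] <- 0
    eta <- eta + u_cell
  }
  matrix(plogis(eta), dims[1], dims[2])
}
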