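#' Collapse occurrence points to unique presence cells
#'
#' Spatial filtering: every 1-km cell containing at least one occurrence
#' point becomes a single presence, removing duplicate records. Species
#' with fewer than `min_cells` presence cells are flagged as excluded from
#' habitat modelling.
#'
#' @param occurrences Tibble of occurrence points with either `row`/`col`
#'   cell indices or continuous `x`/`y` coordinates (km; cell =
#'   `ceiling`).
#' @param species Optional species id used to filter a multi-species table.
#' @param min_cells Exclusion threshold (default 50 presence cells).
#' @return A tibble of unique presence cells (`row`, `col`) with
#'   attributes `species_id`, `n_cells` and `excluded`.
#' @export
grid_presences <- function(occurrences, species = NULL, min_cells = 50) {
  occ <- occurrences
  if (!is.null(species)) occ <- occ |> filter(.data$species_id == species)
  if (nrow(occ) == 0) abort("no occurrences to grid.")
  if (!all(c("row", "col") %in% names(occ))) {
    occ <- occ |> mutate(row = ceiling(.data$y), col = ceiling(.data$x))
  }
  cells <- occ |>
    dplyr::distinct(.data$row, .data$col) |>
    arrange(.data$row, .data$col)
  structure(cells,
            species_id = species %||% occ$species_id[1] %||% NA_character_,
            n_cells = nrow(cells),
            excluded = nrow(cells) < min_cells)
}

#' Sample pseudo-absence cells from an annulus around presences
#'
#' Candidate cells lie strictly farther than `inner_km` and at most
#' `outer_km` from the nearest presence cell; the same number of
#' pseudo-absences as presences is drawn uniformly without replacement.
#' This mirrors presence-data spatial bias into the background sample.
#'
#' @param presences Tibble of presence cells (`row`, `col`).
#' @param nrow,ncol Grid dimensions.
#' @param inner_km,outer_km Annulus bounds in km (defaults 3 and 10).
#' @param seed Integer seed.
#' @return Tibble of pseudo-absence cells (`row`, `col`).
#' @export
sample_pseudoabsences_annulus <- function(presences, nrow, ncol,
                                          inner_km = 3, outer_km = 10, seed = 1) {
  d <- distance_to_cells(nrow, ncol, presences$row, presences$col, outer_km)
  cand <- which(d > inner_km & d <= outer_km, arr.ind = TRUE)
  need <- base::nrow(presences)
  if (base::nrow(cand) < need) {
    abort(sprintf(
      "insufficient pseudo-absence candidates: need %d, annulus holds %d.",
      need, base::nrow(cand)
    ))
  }
  withr::with_seed(stopifnot_scalar_seed(seed), {
    idx <- sample.int(base::nrow(cand), need)
  })
  tibble(row = cand[idx, 1], col = cand[idx, 2]) |>
    arrange(.data$row, .data$col)
}

#' Assemble a presence / pseudo-absence table with layer values
#'
#' @param presences,absences Cell tibbles (`row`, `col`).
#' @param landscape A `landscape` or [grid_stack()].
#' @param layers Layer names to extract (default: all).
#' @return Tibble with `row`, `col`, `y` (1/0) and one column per layer.
#' @export
assemble_pa_table <- function(presences, absences, landscape,
                              layers = NULL) {
  gs <- if (inherits(landscape, "landscape")) landscape$current else landscape
  layers <- layers %||% names(gs$layers)
  cells <- bind_rows(
    presences |> mutate(y = 1L),
    absences |> mutate(y = 0L)
  )
  dplyr::bind_cols(cells, gs_values_at(gs, cells, layers))
}

#' Select candidate layers for one species' habitat model
#'
#' Ranks layers by the AIC of univariable binomial GLMs with linear and
#' quadratic effects, then greedily keeps the best-ranked layers whose
#' pairwise correlation with every already-kept layer stays at or below
#' `cor_threshold`, up to `max_vars`. Ties in AIC break deterministically
#' by layer name.
#'
#' @param pa_table Output of [assemble_pa_table()] (must contain both
#'   classes in `y`).
#' @param candidates Candidate layer column names.
#' @param cor_threshold Pairwise absolute-correlation cap (default 0.7).
#' @param max_vars Maximum variables kept (default 6).
#' @return Character vector of selected names with the full AIC ranking as
#'   attribute `"ranking"`.
#' @export
select_species_variables <- function(pa_table, candidates,
                                     cor_threshold = 0.7, max_vars = 6) {
  if (length(unique(pa_table$y)) < 2) abort("pa_table needs both classes.")
  ranking <- purrr::map_dfr(candidates, function(v) {
    x <- pa_table[[v]]
    aic <- if (sd(x) == 0) Inf else {
      AIC(glm(pa_table$y ~ x + I(x^2), family = binomial()))
    }
    tibble(variable = v, aic = aic)
  }) |> arrange(.data$aic, .data$variable)
  selected <- character()
  for (v in ranking$variable) {
    if (!is.finite(ranking$aic[ranking$variable == v])) next
    if (length(selected) > 0) {
      r <- vapply(selected, function(s) {
        suppressWarnings(abs(cor(pa_table[[v]], pa_table[[s]])))
      }, numeric(1))
      if (any(r > cor_threshold, na.rm = TRUE)) next
    }
    selected <- c(selected, v)
    if (length(selected) >= max_vars) break
  }
  if (length(selected) < 1) abort("no candidate variable survived filtering.")
  structure(selected, ranking = ranking)
}

# maximized true skill statistic and its threshold over a prediction vector
best_tss <- function(pred, y) {
  ths <- sort(unique(pred))
  if (length(ths) > 200) ths <- quantile(pred, seq(0, 1, length.out = 200),
                                         names = FALSE)
  tss <- vapply(ths, function(t) {
    sens <- mean(pred[y == 1] >= t)
    spec <- mean(pred[y == 0] < t)
    sens + spec - 1
  }, numeric(1))
  i <- which.max(tss)
  list(tss = tss[i], threshold = ths[i],
       sensitivity = mean(pred[y == 1] >= ths[i]),
       specificity = mean(pred[y == 0] < ths[i]))
}

ensemble_features <- function(values, variables, constants) {
  z <- standardize_tbl(values[variables], constants)$values
  m <- cbind(as.matrix(z), as.matrix(z)^2)
  colnames(m) <- c(variables, paste0(variables, "__sq"))
  m
}

#' Fit a two-member ensemble habitat model
#'
#' A documented, reproducible simplification of large ensemble platforms:
#' two member learners — a ridge-regularized logistic regression on linear
#' + quadratic standardized features (lambda by 5-fold cross-validation)
#' and gradient-boosted trees — are fitted on a stratified 80/20
#' train/test split, weighted by their true skill statistic (TSS) on the
#' held-out fold, and combined as a weighted mean probability. The
#' ensemble's binarization threshold maximizes held-out TSS. A member that
#' fails to fit is dropped with a warning; if all fail, an error is
#' raised.
#'
#' @param pa_table Presence/absence table (see [assemble_pa_table()]).
#' @param variables Predictor columns (see [select_species_variables()]).
#' @param split Training fraction of the stratified split (default 0.8).
#' @param seed Integer seed.
#' @param species Species id recorded in the model.
#' @param nrounds Boosting rounds for the tree member (default 60).
#' @return An object of class `ensemble_sdm`.
#' @export
fit_ensemble <- function(pa_table, variables, split = 0.8, seed = 1,
                         species = NULL, nrounds = 60) {
  y <- pa_table$y
  if (sum(y == 1) < 2 || sum(y == 0) < 2) abort("need both classes to fit.")
  withr::with_seed(stopifnot_scalar_seed(seed), {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    tr <- c(sample(idx1, round(split * length(idx1))),
            sample(idx0, round(split * length(idx0))))
  })
  te <- setdiff(seq_along(y), tr)
  if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
    abort("both classes must appear in train and test splits.")
  }
  constants <- standardize_tbl(pa_table[tr, variables, drop = FALSE])$constants
  X <- ensemble_features(pa_table, variables, constants)

  members <- list()
  fit_member <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      warn(sprintf("ensemble member '%s' failed and was dropped: %s",
                   name, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) members[[name]] <<- res
  }
  withr::with_seed(child_seed(seed, 1), fit_member("glmnet_ridge", function() {
    cv <- glmnet::cv.glmnet(X[tr, ], y[tr], family = "binomial", alpha = 0,
                            nfolds = 5)
    list(
      fit = cv,
      predict = function(newX) {
        as.numeric(predict(cv, newX, s = "lambda.min", type = "response"))
      }
    )
  }))
  withr::with_seed(child_seed(seed, 2), fit_member("xgboost", function() {
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr]),
      nrounds = nrounds
    )
    list(fit = bst, predict = function(newX) {
      as.numeric(predict(bst, newX))
    })
  }))
  if (length(members) == 0) abort("all ensemble members failed to fit.")

  skill <- purrr::map_dfr(names(members), function(nm) {
    pred <- members[[nm]]$predict(X[te, , drop = FALSE])
    s <- best_tss(pred, y[te])
    tibble(member = nm, tss = s$tss, sensitivity = s$sensitivity,
           specificity = s$specificity)
  })
  w <- pmax(skill$tss, 0)
  w <- if (sum(w) == 0) rep(1 / length(w), length(w)) else w / sum(w)
  names(w) <- skill$member

  ens_pred <- Reduce(`+`, purrr::imap(
    members, function(m, nm) w[nm] * m$predict(X[te, , drop = FALSE])
  ))
  ev <- best_tss(ens_pred, y[te])

  structure(
    list(
      species_id = species,
      variables = variables,
      constants = constants,
      members = members,
      member_skill = skill,
      weights = w,
      threshold = ev$threshold,
      evaluation = tibble(sensitivity = ev$sensitivity,
                          specificity = ev$specificity, tss = ev$tss),
      split = split, seed = seed
    ),
    class = "ensemble_sdm"
  )
}

#' @export
print.ensemble_sdm <- function(x, ...) {
  cat(sprintf("<ensemble_sdm> %s | members: %s | TSS = %.3f\n",
              x$species_id %||% "?", paste(names(x$members), collapse = ", "),
              x$evaluation$tss))
  invisible(x)
}

#' Predict habitat suitability over a layer stack
#'
#' Weighted-mean member probability per cell; cells with missing layer
#' values propagate `NA`.
#'
#' @param model An [fit_ensemble()] model.
#' @param landscape A `landscape`, [grid_stack()], or named list of layer
#'   matrices providing the model's variables.
#' @param scenario Scenario name to select from a `landscape` (default:
#'   current layers).
#' @param members Optional subset of member names to use (equal-weight
#'   renormalization over the subset); default all.
#' @return A suitability matrix with values in \[0, 1\].
#' @export
predict_suitability <- function(model, landscape, scenario = NULL,
                                members = NULL) {
  gs <- resolve_layers(landscape, scenario)
  missing <- setdiff(model$variables, names(gs))
  if (length(missing) > 0) {
    abort(sprintf("missing layer(s): %s", paste(missing, collapse = ", ")))
  }
  dims <- dim(gs[[model$variables[1]]])
  vals <- as_tibble(lapply(gs[model$variables], as.vector))
  X <- ensemble_features(vals, model$variables, model$constants)
  use <- members %||% names(model$members)
  w <- model$weights[use]
  w <- w / sum(w)
  ok <- complete.cases(X)
  pred <- rep(NA_real_, nrow(X))
  pred[ok] <- Reduce(`+`, purrr::imap(
    model$members[use], function(m, nm) w[nm] * m$predict(X[ok, , drop = FALSE])
  ))
  matrix(pred, dims[1], dims[2])
}

# accept landscape / grid_stack / bare named list of matrices
resolve_layers <- function(landscape, scenario = NULL) {
  if (inherits(landscape, "landscape")) {
    gs <- if (is.null(scenario) || identical(scenario, "current")) {
      landscape$current
    } else {
      if (!scenario %in% names(landscape$scenarios)) {
        abort(sprintf("unknown scenario '%s'.", scenario))
      }
      landscape$scenarios[[scenario]]
    }
    return(gs$layers)
  }
  if (inherits(landscape, "grid_stack")) return(landscape$layers)
  landscape
}
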