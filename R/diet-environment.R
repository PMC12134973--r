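#' Mean environmental covariates within a buffer around study sites
#'
#' For each site, averages every layer over the grid cells whose center
#' lies strictly within `radius_km` of the site's cell center. With the
#' default 18-km radius on a 1-km grid an interior buffer contains 1005
#' cells (pi * 18^2 = 1017.9 km^2); buffers truncated by the grid edge
#' contain fewer.
#'
#' @param landscape A `landscape` or [grid_stack()].
#' @param sites Data frame with `row` and `col` (cell coordinates); other
#'   columns (e.g. `study_id`) are carried through.
#' @param radius_km Buffer radius in km (default 18).
#' @return A tibble: the site columns, `n_cells`, and one column per layer
#'   holding the buffer mean.
#' @export
extract_buffer_covariates <- function(landscape, sites, radius_km = 18) {
  gs <- if (inherits(landscape, "landscape")) landscape$current else landscape
  if (any(sites$row < 1 | sites$row > gs$nrow |
          sites$col < 1 | sites$col > gs$ncol)) {
    abort("site outside grid bounds.")
  }
  w <- ceiling(radius_km)
  off <- expand.grid(dr = -w:w, dc = -w:w)
  off <- off[off$dr^2 + off$dc^2 < radius_km^2, ] # strict: center within radius
  rows <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    rr <- sites$row[i] + off$dr
    cc <- sites$col[i] + off$dc
    keep <- rr >= 1 & rr <= gs$nrow & cc >= 1 & cc <= gs$ncol
    idx <- cbind(rr[keep], cc[keep])
    vals <- lapply(gs$layers, function(m) mean(m[idx]))
    tibble(n_cells = sum(keep), !!!vals)
  })
  dplyr::bind_cols(as_tibble(sites), rows)
}

#' Iterative variance-inflation-factor filter
#'
#' Repeatedly drops the covariate with the largest VIF (computed as
#' `1 / (1 - R^2)` from the regression of that covariate on all others)
#' until every VIF is at or below `threshold`. Perfectly collinear
#' variables have infinite VIF and are dropped first.
#'
#' @param covariates Data frame of numeric covariates.
#' @param threshold Maximum acceptable VIF (default 10).
#' @return Character vector of retained variable names; the drop log (a
#'   tibble of `variable`, `vif`, `step`) is attached as attribute
#'   `"dropped"` and the final VIFs as attribute `"vif"`.
#' @export
vif_filter <- function(covariates, threshold = 10) {
  covariates <- as_tibble(covariates) |> dplyr::select(dplyr::where(is.numeric))
  if (ncol(covariates) < 2) abort("need at least 2 covariates.")
  if (nrow(covariates) <= ncol(covariates)) {
    abort("need more rows than covariates to compute VIF.")
  }
  vif_of <- function(vars) {
    vapply(vars, function(v) {
      r2 <- suppressWarnings(summary(lm(
        as.formula(paste0("`", v, "` ~ .")),
        data = covariates[vars]
      ))$r.squared) # a perfect fit (infinite VIF) is expected and handled
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  vars <- names(covariates)
  dropped <- tibble(variable = character(), vif = numeric(), step = integer())
  step <- 0L
  repeat {
    vifs <- vif_of(vars)
    if (max(vifs) <= threshold) break
    step <- step + 1L
    worst <- names(which.max(vifs))
    dropped <- bind_rows(dropped,
                         tibble(variable = worst, vif = unname(vifs[worst]),
                                step = step))
    vars <- setdiff(vars, worst)
    if (length(vars) == 1) break
  }
  final_vif <- if (length(vars) >= 2) vif_of(vars) else setNames(1, vars)
  structure(vars, dropped = dropped,
            vif = tibble(variable = names(final_vif), vif = unname(final_vif)))
}

aicc_lm <- function(fit, n) {
  k <- length(coef(fit)) + 1 # + residual variance
  if (n - k - 1 <= 0) return(NA_real_)
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets linear models with AICc-based conditional model averaging
#'
#' Fits an ordinary linear model for every subset of the supplied
#' covariates (up to `max_terms` terms), ranks candidates by AICc, and
#' averages coefficients over the models within `delta_max` AICc of the
#' best using conditional (subset) averaging: each term is averaged only
#' over the models that contain it, with Akaike weights renormalized over
#' that subset. Unconditional standard errors include the between-model
#' variance component. Candidates too small for AICc
#' (`n - k - 1 <= 0`) are skipped and logged.
#'
#' @param data Data frame containing the response and covariates.
#' @param response Name of the response column.
#' @param covariates Covariate names (typically the [vif_filter()] output).
#' @param max_terms Maximum number of terms per candidate model (default:
#'   all covariates, capped at 8 to bound the subset enumeration).
#' @param delta_max AICc window defining the best-model subset (default 3).
#' @return An object of class `averaged_model` with elements `response`,
#'   `candidates` (tibble of all fitted subsets with AICc, delta and
#'   weight), `coefficients` (averaged estimates, unconditional SEs,
#'   z-based p-values, plus the best single model's t-test p-values) and
#'   `retained`.
#' @export
fit_averaged_models <- function(data, response, covariates,
                                max_terms = NULL, delta_max = 3) {
  stopifnot(all(c(response, covariates) %in% names(data)))
  if (!all(is.finite(data[[response]]))) abort("response must be finite.")
  max_terms <- min(max_terms %||% length(covariates), length(covariates), 8)
  subsets <- list(character(0))
  for (k in seq_len(max_terms)) {
    subsets <- c(subsets, utils::combn(covariates, k, simplify = FALSE))
  }
  n <- nrow(data)
  fits <- list()
  cand <- list()
  skipped <- character()
  for (i in seq_along(subsets)) {
    terms <- subsets[[i]]
    fml <- if (length(terms) == 0) {
      as.formula(paste0("`", response, "` ~ 1"))
    } else {
      as.formula(paste0("`", response, "` ~ ",
                        paste0("`", terms, "`", collapse = " + ")))
    }
    fit <- lm(fml, data = data)
    aicc <- aicc_lm(fit, n)
    if (is.na(aicc)) {
      skipped <- c(skipped, paste(terms, collapse = "+"))
      next
    }
    fits[[length(fits) + 1]] <- fit
    cand[[length(cand) + 1]] <- tibble(
      model_id = length(fits),
      terms = paste(terms, collapse = " + "),
      n_terms = length(terms),
      aicc = aicc
    )
  }
  if (length(fits) == 0) abort("no candidate model could be fitted.")
  candidates <- bind_rows(cand) |>
    mutate(delta = .data$aicc - min(.data$aicc)) |>
    arrange(.data$aicc, .data$terms)
  best_set <- candidates |> filter(.data$delta < delta_max)
  w <- exp(-best_set$delta / 2)
  best_set$weight <- w / sum(w)
  candidates <- candidates |>
    left_join(best_set |> select("model_id", "weight"), by = "model_id") |>
    mutate(weight = tidyr::replace_na(.data$weight, 0))

  all_terms <- c("(Intercept)", covariates)
  coefs <- purrr::map_dfr(all_terms, function(tm) {
    rows <- purrr::map_dfr(seq_len(nrow(best_set)), function(j) {
      fit <- fits[[best_set$model_id[j]]]
      sm <- summary(fit)$coefficients
      if (!tm %in% rownames(sm)) return(NULL)
      tibble(weight = best_set$weight[j],
             estimate = sm[tm, 1], se = sm[tm, 2])
    })
    if (nrow(rows) == 0) return(NULL)
    wsum <- sum(rows$weight)
    wc <- rows$weight / wsum
    est <- sum(wc * rows$estimate)
    se <- sum(wc * sqrt(rows$se^2 + (rows$estimate - est)^2))
    tibble(term = tm, estimate = est, std_error = se,
           n_models = nrow(rows), weight_sum = wsum,
           statistic = est / se,
           p_value = 2 * stats::pnorm(-abs(est / se)))
  })
  best_fit <- fits[[candidates$model_id[1]]]
  best_sm <- summary(best_fit)$coefficients
  coefs$p_best_model <- best_sm[match(coefs$term, rownames(best_sm)), 4]

  structure(
    list(response = response, candidates = candidates, coefficients = coefs,
         retained = covariates, skipped = skipped, delta_max = delta_max,
         n = n),
    class = "averaged_model"
  )
}

#' @export
print.averaged_model <- function(x, ...) {
  cat(sprintf("<averaged_model> response: %s | %d candidate models, %d in the AICc<%g set\n",
              x$response, nrow(x$candidates), sum(x$candidates$weight > 0),
              x$delta_max))
  print(x$coefficients)
  invisible(x)
}

#' Diet diversity indices over food-category shares
#'
#' Shannon `H = -sum(p log p)`, Simpson `D = 1 - sum(p^2)` and inverse
#' Simpson `1 / sum(p^2)` per study, computed with \pkg{vegan}.
#'
#' @param shares Tibble with `study_id`, `label` (or `category`) and
#'   `share` columns; shares must be non-negative and sum to 1 per study.
#' @return A tibble: `study_id`, `shannon`, `simpson`, `inv_simpson`.
#' @export
diet_diversity <- function(shares) {
  if ("category" %in% names(shares) && !"label" %in% names(shares)) {
    shares <- shares |> dplyr::rename(label = "category")
  }
  if (any(shares$share < 0)) abort("negative share.")
  wide <- shares |>
    select("study_id", "label", "share") |>
    tidyr::pivot_wider(names_from = "label", values_from = "share",
                       values_fill = 0)
  m <- as.matrix(wide[-1])
  tibble(
    study_id = wide$study_id,
    shannon = as.numeric(vegan::diversity(m, index = "shannon")),
    simpson = as.numeric(vegan::diversity(m, index = "simpson")),
    inv_simpson = as.numeric(vegan::diversity(m, index = "invsimpson"))
  )
}
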