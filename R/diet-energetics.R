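#' Pooled rF-rV correlation with a percentile bootstrap interval
#'
#' Pools the food items of all studies reporting both relative frequency
#' (rF) and relative volume (rV) and reports the Pearson correlation with a
#' seeded percentile bootstrap 95% interval over items.
#'
#' @param diet Diet table (one row per item; see [generate_diet_studies()]
#'   for the column contract).
#' @param n_bootstrap Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap resampling.
#' @param conf Interval coverage (default 0.95).
#' @return A one-row tibble: `r`, `ci_lower`, `ci_upper`, `n_items`,
#'   `n_bootstrap`.
#' @export
rf_rv_correlation <- function(diet, n_bootstrap = 1000, seed = 1, conf = 0.95) {
  complete <- diet |> filter(!is.na(.data$rF), !is.na(.data$rV))
  if (nrow(complete) < 3) abort("need at least 3 items with both rF and rV.")
  if (sd(complete$rF) == 0) abort("degenerate fit: rF has zero variance.")
  r <- cor(complete$rF, complete$rV)
  withr::with_seed(stopifnot_scalar_seed(seed), {
    boot <- vapply(seq_len(n_bootstrap), function(i) {
      idx <- sample.int(nrow(complete), replace = TRUE)
      suppressWarnings(cor(complete$rF[idx], complete$rV[idx]))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  tibble(
    r = r, ci_lower = ci[1], ci_upper = ci[2],
    n_items = nrow(complete), n_bootstrap = n_bootstrap
  )
}

#' Impute missing relative volumes from relative frequencies
#'
#' Studies often report only the frequency of occurrence of food items.
#' This fits an ordinary least-squares relationship `rV ~ rF` on the pooled
#' items of studies reporting both quantities, predicts rV for items of
#' incomplete studies, clips predictions at zero, and renormalizes the
#' imputed rV within each study to sum to 1. Observed rV values are never
#' altered. The pooled correlation report (with bootstrap interval) is
#' attached as attribute `"correlation_report"`.
#'
#' @inheritParams rf_rv_correlation
#' @return The diet table with complete `rV` and a logical `rv_imputed`
#'   column flagging imputed items.
#' @export
impute_rv <- function(diet, n_bootstrap = 1000, seed = 1) {
  study_complete <- diet |>
    group_by(.data$study_id) |>
    summarise(complete = !anyNA(.data$rV), .groups = "drop")
  complete_ids <- study_complete$study_id[study_complete$complete]
  if (length(complete_ids) < 2) {
    abort("cannot impute: need at least 2 studies reporting both rF and rV.")
  }
  report <- rf_rv_correlation(
    diet |> filter(.data$study_id %in% complete_ids),
    n_bootstrap = n_bootstrap, seed = seed
  )
  pooled <- diet |> filter(.data$study_id %in% complete_ids)
  fit <- lm(rV ~ rF, data = pooled)

  rv_hat <- pmax(unname(coef(fit)[1] + coef(fit)[2] * diet$rF), 0)
  out <- diet |>
    mutate(rv_imputed = is.na(.data$rV)) |>
    mutate(rV = ifelse(.data$rv_imputed, rv_hat, .data$rV)) |>
    group_by(.data$study_id) |>
    mutate(rV = if (any(.data$rv_imputed)) .data$rV / sum(.data$rV) else .data$rV) |>
    ungroup()
  attr(out, "correlation_report") <- report
  attr(out, "truth") <- attr(diet, "truth")
  out
}

# CF lookup: item-specific value, else category default, else error
lookup_cf <- function(diet, cf_table, column) {
  if (is.null(cf_table)) {
    if (!column %in% names(diet)) {
      abort(sprintf("no cf_table supplied and no %s column present.", column))
    }
    return(diet[[column]])
  }
  cf_col <- tolower(column)
  if (!cf_col %in% names(cf_table)) {
    abort(sprintf("cf_table has no '%s' column.", cf_col))
  }
  out <- rep(NA_real_, nrow(diet))
  for (key in c("item_id", "species_id", "category")) {
    if (key %in% names(cf_table) && key %in% names(diet)) {
      m <- match(diet[[key]], cf_table[[key]])
      fill <- is.na(out) & !is.na(m)
      out[fill] <- cf_table[[cf_col]][m[fill]]
    }
  }
  if (anyNA(out)) {
    abort(sprintf("missing %s for item(s): %s", column,
                  paste(head(diet$item_id[is.na(out)], 5), collapse = ", ")))
  }
  out
}

#' Compute corrected and energy-weighted diet shares
#'
#' Converts relative volumes into the relative estimated dietary energy
#' content of each item: the corrected relative content is
#' `rEDC_i = rV_i` (optionally volume-corrected by `CF_V` and renormalized
#' per study), and `rEDEC_i = CF_Ei * rEDC_i / sum_j(CF_Ej * rEDC_j)`
#' within each study. Correction factors are looked up item-first, then by
#' category.
#'
#' @param diet Diet table with complete `rV` (see [impute_rv()]).
#' @param cf_table Optional tibble of correction factors with columns
#'   `cf_e` (and optionally `cf_v`) keyed by `item_id`, `species_id`
#'   and/or `category`. When `NULL`, the table's own `CF_E` column is used
#'   and no volume correction is applied.
#' @return The diet table with `rEDC` and `rEDEC` columns, both summing to
#'   1 within each study.
#' @export
compute_redec <- function(diet, cf_table = NULL) {
  if (anyNA(diet$rV)) {
    abort("rV is incomplete; run impute_rv() first.")
  }
  cf_e <- lookup_cf(diet, cf_table, "CF_E")
  has_cfv <- (!is.null(cf_table) && "cf_v" %in% names(cf_table)) ||
    (is.null(cf_table) && "CF_V" %in% names(diet))
  out <- diet
  out$CF_E <- cf_e
  if (has_cfv) {
    out$CF_V <- lookup_cf(diet, cf_table, "CF_V")
    out <- out |>
      group_by(.data$study_id) |>
      mutate(rEDC = (.data$CF_V * .data$rV) / sum(.data$CF_V * .data$rV)) |>
      ungroup()
  } else {
    out$rEDC <- out$rV
  }
  out <- out |>
    group_by(.data$study_id) |>
    mutate(rEDEC = {
      w <- .data$CF_E * .data$rEDC
      if (sum(w) <= 0) abort("all CF_E * rEDC are zero in a study.")
      w / sum(w)
    }) |>
    ungroup()
  attr(out, "correlation_report") <- attr(diet, "correlation_report")
  attr(out, "truth") <- attr(diet, "truth")
  out
}

#' Per-study energy shares by food category and by origin
#'
#' @param diet Diet table with `rEDEC` (see [compute_redec()]).
#' @return A tibble with columns `study_id`, `dimension` (`"category"` or
#'   `"origin"`), `label` and `share`; shares sum to 1 per study and
#'   dimension.
#' @export
classify_items <- function(diet) {
  if (!"rEDEC" %in% names(diet)) abort("rEDEC missing; run compute_redec() first.")
  bad <- setdiff(unique(diet$category), FOOD_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("unknown category label(s): %s", paste(bad, collapse = ", ")))
  }
  cat_shares <- diet |>
    group_by(.data$study_id, label = .data$category) |>
    summarise(share = sum(.data$rEDEC), .groups = "drop") |>
    mutate(dimension = "category")
  origin_shares <- diet |>
    group_by(.data$study_id, label = .data$origin) |>
    summarise(share = sum(.data$rEDEC), .groups = "drop") |>
    mutate(dimension = "origin")
  bind_rows(cat_shares, origin_shares) |>
    select("study_id", "dimension", "label", "share")
}

#' Representative subpopulation diet from study-level energy shares
#'
#' For each food species S within a subpopulation, computes the
#' sampling-effort-weighted mean share
#' `rEDEC_Subp,S = sum_i(Z_i * rEDEC_S,i) / sum_i(Z_i)` over all diet
#' studies i of the subpopulation, treating the share as 0 in studies where
#' the species is absent. Items not resolved to species contribute to the
#' unresolved remainder (and to category totals) but not to the per-species
#' map.
#'
#' @param diet Diet table with `rEDEC`.
#' @param subpops Subpopulations to aggregate (default: all present).
#' @return A tibble of class `subpop_diet` with columns `subpop`,
#'   `species_id`, `category`, `origin`, `redec`. Per-subpopulation
#'   category totals, origin splits and the unresolved remainder are
#'   attached as attributes `"categories"`, `"origin"` and `"unresolved"`.
#' @export
aggregate_subpopulation_diet <- function(diet, subpops = NULL) {
  if (!"rEDEC" %in% names(diet)) abort("rEDEC missing; run compute_redec() first.")
  subpops <- subpops %||% sort(unique(diet$subpop))
  missing_sp <- setdiff(subpops, unique(diet$subpop))
  if (length(missing_sp) > 0) {
    abort(sprintf("no studies in subpopulation(s): %s",
                  paste(missing_sp, collapse = ", ")))
  }
  diet <- diet |> filter(.data$subpop %in% subpops)
  study_z <- diet |> dplyr::distinct(.data$subpop, .data$study_id, .data$Z)

  species_level <- diet |>
    filter(!is.na(.data$species_id)) |>
    group_by(.data$subpop, .data$study_id, .data$species_id,
             .data$category, .data$origin) |>
    summarise(redec_study = sum(.data$rEDEC), .groups = "drop")

  out <- species_level |>
    dplyr::distinct(.data$subpop, .data$species_id, .data$category, .data$origin) |>
    left_join(
      tidyr::crossing(study_z) |> dplyr::rename(z = "Z"),
      by = "subpop", relationship = "many-to-many"
    ) |>
    left_join(species_level,
              by = c("subpop", "study_id", "species_id", "category", "origin")) |>
    mutate(redec_study = tidyr::replace_na(.data$redec_study, 0)) |>
    group_by(.data$subpop, .data$species_id, .data$category, .data$origin) |>
    summarise(redec = sum(.data$z * .data$redec_study) / sum(.data$z),
              .groups = "drop")

  weighted_share <- function(d, by) {
    d |>
      group_by(.data$subpop, .data$study_id, .data$Z, label = .data[[by]]) |>
      summarise(share = sum(.data$rEDEC), .groups = "drop") |>
      tidyr::complete(tidyr::nesting(!!rlang::sym("subpop"),
                                     !!rlang::sym("study_id"),
                                     !!rlang::sym("Z")),
                      .data$label, fill = list(share = 0)) |>
      group_by(.data$subpop, .data$label) |>
      summarise(share = sum(.data$Z * .data$share) / sum(.data$Z),
                .groups = "drop")
  }
  attr(out, "categories") <- weighted_share(diet, "category")
  attr(out, "origin") <- weighted_share(diet, "origin")
  attr(out, "unresolved") <- out |>
    group_by(.data$subpop) |>
    summarise(resolved = sum(.data$redec), .groups = "drop") |>
    mutate(unresolved = 1 - .data$resolved)
  class(out) <- c("subpop_diet", class(out))
  out
}

#' Energy shares by food category within subpopulations
#' @param x A `subpop_diet` (see [aggregate_subpopulation_diet()]).
#' @return Tibble `subpop`, `label`, `share`.
#' @export
diet_category_shares <- function(x) attr(x, "categories")

#' Energy shares by wild / human-derived origin within subpopulations
#' @param x A `subpop_diet`.
#' @return Tibble `subpop`, `label`, `share`.
#' @export
diet_origin_shares <- function(x) attr(x, "origin")
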