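#' Configuration for synthetic diet studies
#'
#' Defines the per-subpopulation species pools with true dietary-energy
#' shares, the target correlation between relative frequency (rF) and
#' relative volume (rV), per-study sampling-unit counts, energy correction
#' factors, and the fraction of studies in which rV is masked as missing.
#'
#' @param species_pool Tibble with `species_id`, `category` (one of the
#'   five food categories), `origin` (`"wild"` or `"human-derived"`) and
#'   `cf_e` (energy correction factor).
#' @param subpop_shares Named list: for each subpopulation id, a named
#'   numeric vector of true energy shares over species ids (each summing
#'   to 1).
#' @param target_correlation Target pooled Pearson correlation between rF
#'   and rV, in (0, 1].
#' @param studies_per_subpop Number of studies generated per subpopulation.
#' @param z_range Range `c(min, max)` of sampling-unit counts Z (scats or
#'   stomachs per study) drawn uniformly.
#' @param missing_rv_fraction Fraction of studies whose rV fields are
#'   masked entirely (rounded to a whole number of studies).
#' @return A list of class `diet_config`.
#' @export
diet_config <- function(species_pool, subpop_shares,
                        target_correlation = 0.86,
                        studies_per_subpop = 3,
                        z_range = c(30, 300),
                        missing_rv_fraction = 0.3) {
  stopifnot(is.data.frame(species_pool))
  need <- c("species_id", "category", "origin", "cf_e")
  if (!all(need %in% names(species_pool))) {
    abort(sprintf("species_pool must have columns %s.", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(species_pool$category), FOOD_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("unknown food categories: %s", paste(bad, collapse = ", ")))
  }
  if (target_correlation <= 0 || target_correlation > 1) {
    abort("target_correlation must be in (0, 1].")
  }
  for (sp in names(subpop_shares)) {
    s <- subpop_shares[[sp]]
    if (abs(sum(s) - 1) > 1e-8) {
      abort(sprintf("true energy shares for %s must sum to 1.", sp))
    }
    if (!all(names(s) %in% species_pool$species_id)) {
      abort(sprintf("shares for %s reference species missing from the pool.", sp))
    }
  }
  structure(
    list(
      species_pool = as_tibble(species_pool),
      subpop_shares = subpop_shares,
      target_correlation = target_correlation,
      studies_per_subpop = studies_per_subpop,
      z_range = z_range,
      missing_rv_fraction = missing_rv_fraction
    ),
    class = "diet_config"
  )
}

#' Generate synthetic diet-study tables
#'
#' Each study draws food-item occurrence counts from a multinomial whose
#' cell probabilities are the subpopulation's true energy shares divided by
#' the energy correction factors (so that applying the correction factors
#' downstream recovers the true shares in expectation). rV is generated as
#' the renormalized sum of rF and Gaussian noise whose scale is solved
#' numerically so the realized pooled rF-rV correlation matches the
#' configured target; a fixed fraction of studies then has rV masked as
#' missing. Studies are placed at random cells of their subpopulation.
#'
#' @param config A [diet_config()].
#' @param subpop_map Character matrix of subpopulation ids.
#' @param seed Integer seed.
#' @return A tibble with one row per food item and columns `study_id`,
#'   `subpop`, `row`, `col`, `sample_type`, `Z`, `item_id`, `species_id`,
#'   `category`, `origin`, `f`, `rF`, `v`, `rV`, `CF_E`. The generating
#'   configuration is attached as attribute `"truth"`.
#' @export
generate_diet_studies <- function(config, subpop_map, seed) {
  stopifnot(inherits(config, "diet_config"))
  missing_sp <- setdiff(names(config$subpop_shares), unique(as.vector(subpop_map)))
  if (length(missing_sp) > 0) {
    abort(sprintf("subpopulations not in subpop_map: %s",
                  paste(missing_sp, collapse = ", ")))
  }
  pool <- config$species_pool
  withr::with_seed(stopifnot_scalar_seed(seed), {
    studies <- list()
    sid <- 0
    for (sp in names(config$subpop_shares)) {
      shares <- config$subpop_shares[[sp]]
      cf <- setNames(pool$cf_e, pool$species_id)[names(shares)]
      # sampling probabilities: shares back-transformed through CF_E
      u <- (shares / cf) / sum(shares / cf)
      cells <- which(subpop_map == sp, arr.ind = TRUE)
      for (k in seq_len(config$studies_per_subpop)) {
        sid <- sid + 1
        z <- sample(seq(config$z_range[1], config$z_range[2]), 1)
        if (z < 1) abort("sampling-unit count Z must be >= 1.")
        f <- as.vector(rmultinom(1, size = round(2 * z), prob = u))
        keep <- f > 0
        if (!any(keep)) keep[which.max(u)] <- TRUE
        loc <- cells[sample(nrow(cells), 1), ]
        ids <- names(shares)[keep]
        fk <- f[keep]
        studies[[sid]] <- tibble(
          study_id = sprintf("study_%03d", sid),
          subpop = sp,
          row = unname(loc[1]), col = unname(loc[2]),
          sample_type = sample(c("scat", "stomach"), 1, prob = c(0.8, 0.2)),
          Z = z,
          item_id = paste0(sprintf("study_%03d", sid), "_", ids),
          species_id = ids,
          category = setNames(pool$category, pool$species_id)[ids],
          origin = setNames(pool$origin, pool$species_id)[ids],
          f = fk,
          rF = fk / sum(fk)
        )
      }
    }
    tbl <- bind_rows(studies)

    # rV = renormalized rF + Gaussian noise; the noise scale is solved so
    # the realized pooled correlation equals the target exactly (before the
    # small distortion from clipping and renormalization)
    eps <- rnorm(nrow(tbl))
    eps <- eps - mean(eps)
    target <- config$target_correlation
    rv_of <- function(s) {
      raw <- pmax(tbl$rF + s * eps, 0)
      raw / stats::ave(raw, tbl$study_id, FUN = sum)
    }
    if (target >= 1) {
      tbl$rV <- rv_of(0)
    } else {
      # solve the noise scale on the clipped + renormalized values so the
      # realized pooled correlation hits the target
      fsig <- function(s) {
        v <- suppressWarnings(cor(tbl$rF, rv_of(s)))
        if (!is.finite(v)) v <- 0 # extreme noise: treat as uncorrelated
        v - target
      }
      upper <- sd(tbl$rF) * sqrt(1 / target^2 - 1) * 2
      while (fsig(upper) > 0) upper <- upper * 2
      s <- stats::uniroot(fsig, c(0, upper))$root
      tbl$rV <- rv_of(s)
    }
    tbl <- tbl |> mutate(v = .data$rV * 100)

    study_ids <- unique(tbl$study_id)
    n_missing <- round(config$missing_rv_fraction * length(study_ids))
    masked <- sample(study_ids, n_missing)
    tbl <- tbl |>
      mutate(
        v = ifelse(.data$study_id %in% masked, NA_real_, .data$v),
        rV = ifelse(.data$study_id %in% masked, NA_real_, .data$rV),
        CF_E = setNames(pool$cf_e, pool$species_id)[.data$species_id]
      )
    attr(tbl, "truth") <- list(config = config, seed = seed, masked = masked)
    tbl
  })
}
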