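#' Define a true environmental niche for a synthetic food species
#'
#' The niche is a logistic regression on standardized landscape layers with
#' linear and quadratic terms; it is the ground truth that habitat-model
#' recovery tests check against.
#'
#' @param species_id Species identifier.
#' @param coefs Named list mapping layer names to `c(linear, quadratic)`
#'   coefficients on the standardized layer.
#' @param intercept Intercept on the logit scale (controls prevalence).
#' @param mobility Unused placeholder flag.
#' @return A list of class `true_niche`.
#' @export
true_niche <- function(species_id, coefs, intercept = 0, mobility = FALSE) {
  stopifnot(is.list(coefs), length(coefs) >= 1)
  if (!all(vapply(coefs, length, 1L) == 2) || !all(is.finite(unlist(coefs))) ||
      !is.finite(intercept)) {
    abort("niche coefficients must be finite `c(linear, quadratic)` pairs.")
  }
  structure(
    list(species_id = species_id, coefs = coefs, intercept = intercept,
         mobility = mobility),
    class = "true_niche"
  )
}

niche_probability <- function(niche, gs, constants) {
  missing <- setdiff(names(niche$coefs), names(gs$layers))
  if (length(missing) > 0) {
    abort(sprintf("niche references missing layer(s): %s",
                  paste(missing, collapse = ", ")))
  }
  eta <- matrix(niche$intercept, gs$nrow, gs$ncol)
  for (nm in names(niche$coefs)) {
    cc <- constants[constants$variable == nm, ]
    z <- (gs_layer(gs, nm) - cc$center) / cc$scale
    b <- niche$coefs[[nm]]
    eta <- eta + b[1] * z + b[2] * z^2
  }
  plogis(eta)
}

#' Simulate point occurrences of food species from known niches
#'
#' Each cell of the current landscape is occupied with the probability given
#' by the species' logistic niche; occupied cells emit one or more jittered
#' occurrence points (emulating raw, spatially redundant occurrence
#' records). Species whose realized presence-cell count falls below
#' `min_cells` are flagged, mirroring the exclusion rule applied before
#' habitat modelling.
#'
#' @param niches List of [true_niche()] objects.
#' @param landscape A `landscape` (from [generate_landscape()]) or a
#'   [grid_stack()] of current layers.
#' @param seed Integer seed.
#' @param points_per_cell Mean number of extra occurrence points per
#'   occupied cell (points are `1 + rpois(points_per_cell - 1)`).
#' @param min_cells Presence-cell threshold below which a species is
#'   flagged as excluded (default 50).
#' @return A list with `occurrences` (tibble: `species_id`, `x`, `y`,
#'   `row`, `col`) and `truth` (tibble of generating coefficients,
#'   realized presence-cell counts and exclusion flags).
#' @export
generate_food_species <- function(niches, landscape, seed,
                                  points_per_cell = 1.5, min_cells = 50) {
  if (length(niches) == 0) abort("`niches` must be non-empty.")
  gs <- if (inherits(landscape, "landscape")) landscape$current else landscape
  constants <- gs_standardization(gs)
  withr::with_seed(stopifnot_scalar_seed(seed), {
    occ <- list()
    truth <- list()
    for (ni in niches) {
      p <- niche_probability(ni, gs, constants)
      y <- matrix(rbinom(length(p), 1, p), nrow(p), ncol(p))
      cells <- which(y == 1, arr.ind = TRUE)
      n_cells <- nrow(cells)
      pts <- NULL
      if (n_cells > 0) {
        n_pts <- 1L + stats::rpois(n_cells, max(points_per_cell - 1, 0))
        rows <- rep(cells[, 1], n_pts)
        cols <- rep(cells[, 2], n_pts)
        pts <- tibble(
          species_id = ni$species_id,
          x = cols - runif(length(cols)),
          y = rows - runif(length(rows)),
          row = rows, col = cols
        )
      }
      occ[[ni$species_id]] <- pts
      truth[[ni$species_id]] <- tibble(
        species_id = ni$species_id,
        term = c("(Intercept)",
                 paste0(rep(names(ni$coefs), each = 2),
                        rep(c("", "_sq"), length(ni$coefs)))),
        value = c(ni$intercept, unlist(ni$coefs, use.names = FALSE)),
        n_presence_cells = n_cells,
        excluded = n_cells < min_cells
      )
    }
    list(occurrences = bind_rows(occ), truth = bind_rows(truth))
  })
}

#' Simulate focal-species occurrences and a coarse historical range
#'
#' Fine-grid presence/absence is drawn from a logistic model with known
#' abiotic (climate linear + quadratic, land-use linear) and biotic (linear)
#' coefficients on standardized layers. The coarse historical range is
#' derived from a climate-only version of the same truth: cell-wise
#' presence probabilities of the climate-only model are block-aggregated to
#' the coarse grid and a historical presence is drawn per coarse cell, so
#' historical information is correlated with, but not identical to, the
#' fine-scale truth.
#'
#' @param true_model List with `intercept`, `climate` (named list of
#'   `c(linear, quadratic)`), `landuse` (named numeric, linear), `biotic`
#'   (named numeric, linear, referring to biotic layer names), and
#'   optionally `hist_intercept` for the climate-only truth.
#' @param landscape A `landscape` or current [grid_stack()].
#' @param biotic Named list of biotic layer matrices (may be empty).
#' @param subpop_map Character matrix of subpopulation ids (see
#'   [make_subpop_map()]).
#' @param seed Integer seed.
#' @param coarse_factor Fine-to-coarse aggregation factor (default 50,
#'   matching a 50-km coarse grid over 1-km cells).
#' @return A list with `presences` (tibble `row`, `col`, `subpop`),
#'   `prob` (fine matrix of true presence probabilities), `range_grid`
#'   (coarse 0/1 matrix), `truth` (coefficients and standardization).
#' @export
generate_focal_occurrences <- function(true_model, landscape, biotic = list(),
                                       subpop_map, seed, coarse_factor = 50) {
  gs <- if (inherits(landscape, "landscape")) landscape$current else landscape
  for (nm in names(biotic)) {
    if (!all(dim(biotic[[nm]]) == c(gs$nrow, gs$ncol))) {
      abort("biotic layers are not co-registered with the landscape.")
    }
  }
  abiotic_vars <- c(names(true_model$climate), names(true_model$landuse))
  constants <- gs_standardization(gs, abiotic_vars)
  bio_constants <- tibble(
    variable = names(biotic),
    center = vapply(biotic, mean, numeric(1)),
    scale = vapply(biotic, function(m) {
      s <- sd(m)
      if (!is.finite(s) || s == 0) 1 else s
    }, numeric(1))
  )
  std <- bind_rows(constants, bio_constants)

  zmat <- function(nm) {
    cc <- std[std$variable == nm, ]
    src <- if (nm %in% names(biotic)) biotic[[nm]] else gs_layer(gs, nm)
    (src - cc$center) / cc$scale
  }
  eta_clim <- matrix(0, gs$nrow, gs$ncol)
  for (nm in names(true_model$climate)) {
    b <- true_model$climate[[nm]]
    z <- zmat(nm)
    eta_clim <- eta_clim + b[1] * z + b[2] * z^2
  }
  eta <- eta_clim + true_model$intercept
  for (nm in names(true_model$landuse)) {
    eta <- eta + true_model$landuse[[nm]] * zmat(nm)
  }
  for (nm in names(true_model$biotic %||% numeric())) {
    if (!nm %in% names(biotic)) {
      abort(sprintf("true model references missing biotic layer '%s'.", nm))
    }
    eta <- eta + true_model$biotic[[nm]] * zmat(nm)
  }
  p <- plogis(eta)
  p_hist <- plogis((true_model$hist_intercept %||% true_model$intercept) + eta_clim)

  withr::with_seed(stopifnot_scalar_seed(seed), {
    y <- matrix(rbinom(length(p), 1, p), nrow(p), ncol(p))
    coarse_p <- block_aggregate(p_hist, coarse_factor)
    range_grid <- matrix(
      rbinom(length(coarse_p), 1, coarse_p),
      nrow(coarse_p), ncol(coarse_p)
    )
  })
  cells <- which(y == 1, arr.ind = TRUE)
  presences <- tibble(
    row = cells[, 1], col = cells[, 2],
    subpop = subpop_map[cells]
  )
  list(
    presences = presences,
    prob = p,
    range_grid = range_grid,
    truth = list(model = true_model, standardization = std,
                 coarse_factor = coarse_factor, seed = seed)
  )
}
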