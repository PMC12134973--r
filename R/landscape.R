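#' Configuration for a synthetic landscape
#'
#' Describes the grid, the climate and land-use layers, the spatial
#' autocorrelation of the generated fields, and the scenario perturbations.
#' The four climate layers carry bioclim-style semantics: isothermality
#' (`Clim_3`), temperature seasonality (`Clim_4`), and mean temperature of
#' the wettest (`Clim_8`) and driest (`Clim_9`) quarters. Land-use layers
#' are per-cell fractions in \[0, 1\]; `Natural Landscape` is derived as an
#' 11 x 11 km moving-window mean of a natural / non-natural cell indicator.
#'
#' @param nrow,ncol Grid dimensions in 1-km cells.
#' @param climate_layers Names of the climate layers.
#' @param landuse_layers Names of the land-use fraction layers.
#' @param length_scale Autocorrelation length scale of the generated fields,
#'   in km (sd of the Gaussian smoothing kernel).
#' @param scenarios Named list; each element is a list with optional `add`
#'   and `mul` named numeric vectors of per-layer additive deltas /
#'   multiplicative factors.
#' @param climate_base Named list mapping each climate layer to `c(mean, sd)`
#'   on its natural units.
#' @param natural_urban_cutoff Urban fraction below which a cell counts as
#'   natural for the `Natural Landscape` window.
#' @param seed Integer seed recorded in the output metadata.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 100, ncol = 100,
                             climate_layers = c("Clim_3", "Clim_4", "Clim_8", "Clim_9"),
                             landuse_layers = c("Urban", "Broadleaved Forest",
                                                "Coniferous Forest", "Natural Landscape"),
                             length_scale = 8,
                             scenarios = default_scenarios(),
                             climate_base = list(
                               Clim_3 = c(32, 5), Clim_4 = c(620, 140),
                               Clim_8 = c(10, 5), Clim_9 = c(13, 6)
                             ),
                             natural_urban_cutoff = 0.2,
                             seed = 1L) {
  if (nrow <= 0 || ncol <= 0) abort("grid dimensions must be positive.")
  if (length(scenarios) == 0) abort("at least one scenario must be specified.")
  structure(
    list(
      nrow = nrow, ncol = ncol,
      climate_layers = climate_layers,
      landuse_layers = landuse_layers,
      length_scale = length_scale,
      scenarios = scenarios,
      climate_base = climate_base,
      natural_urban_cutoff = natural_urban_cutoff,
      seed = stopifnot_scalar_seed(seed)
    ),
    class = "landscape_config"
  )
}

#' Default coupled climate / land-use scenario perturbations
#'
#' Three shared socioeconomic pathways with monotonically increasing
#' warming, seasonality, and urbanization, and decreasing forest cover.
#' Deltas are additive on climate and urban fraction; forest fractions are
#' scaled multiplicatively.
#'
#' @return Named list of scenario specifications.
#' @export
default_scenarios <- function() {
  list(
    "SSP1-2.6" = list(
      add = c(Clim_8 = 1.0, Clim_9 = 1.1, Clim_4 = 20, Clim_3 = -0.4, Urban = 0.02),
      mul = c("Broadleaved Forest" = 0.98, "Coniferous Forest" = 0.97)
    ),
    "SSP3-6.0" = list(
      add = c(Clim_8 = 2.1, Clim_9 = 2.3, Clim_4 = 50, Clim_3 = -0.9, Urban = 0.05),
      mul = c("Broadleaved Forest" = 0.92, "Coniferous Forest" = 0.90)
    ),
    "SSP5-8.5" = list(
      add = c(Clim_8 = 3.5, Clim_9 = 3.9, Clim_4 = 85, Clim_3 = -1.5, Urban = 0.08),
      mul = c("Broadleaved Forest" = 0.85, "Coniferous Forest" = 0.82)
    )
  )
}

#' Generate a synthetic landscape with current and scenario layer stacks
#'
#' Climate layers are spatially autocorrelated Gaussian fields rescaled to
#' their configured mean and sd; land-use fractions are inverse-logit
#' transforms of autocorrelated fields; `Natural Landscape` is the 11 x 11
#' moving-window mean of the natural-cell indicator. Scenario stacks apply
#' the configured additive / multiplicative deltas, recompute
#' `Natural Landscape` from the perturbed urban fraction, and clip fraction
#' layers to \[0, 1\] (with a warning when clipping occurs).
#'
#' @param config A [landscape_config()].
#' @return A list of class `landscape` with elements `current` (a
#'   [grid_stack()]), `scenarios` (named list of grid stacks) and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  withr::with_seed(config$seed, {
    nr <- config$nrow; nc <- config$ncol
    layers <- list()
    for (nm in config$climate_layers) {
      f <- gaussian_random_field(nr, nc, config$length_scale)
      base <- config$climate_base[[nm]] %||% c(0, 1)
      layers[[nm]] <- base[1] + base[2] * f
    }
    # land-use fractions; Natural Landscape is derived, not simulated
    frac_names <- setdiff(config$landuse_layers, "Natural Landscape")
    frac_shift <- c("Urban" = -2.2, "Broadleaved Forest" = -1.0,
                    "Coniferous Forest" = -1.2)
    for (nm in frac_names) {
      f <- gaussian_random_field(nr, nc, config$length_scale)
      layers[[nm]] <- plogis(1.3 * f + (frac_shift[nm] %||% -1.0))
    }
    if ("Natural Landscape" %in% config$landuse_layers) {
      layers[["Natural Landscape"]] <-
        natural_landscape_layer(layers[["Urban"]], config$natural_urban_cutoff)
    }
    current <- grid_stack(layers, meta = list(seed = config$seed, config = config))
    scen <- purrr::imap(config$scenarios, function(spec, nm) {
      apply_scenario(current, spec, config)
    })
    structure(
      list(current = current, scenarios = scen, config = config),
      class = "landscape"
    )
  })
}

natural_landscape_layer <- function(urban, cutoff) {
  indicator <- (urban < cutoff) * 1
  moving_window_mean(indicator, half_width = 5L) # 11 x 11 km window
}

apply_scenario <- function(current, spec, config) {
  layers <- current$layers
  for (nm in names(spec$add %||% numeric())) {
    if (nm %in% names(layers)) layers[[nm]] <- layers[[nm]] + spec$add[[nm]]
  }
  for (nm in names(spec$mul %||% numeric())) {
    if (nm %in% names(layers)) layers[[nm]] <- layers[[nm]] * spec$mul[[nm]]
  }
  fracs <- setdiff(config$landuse_layers, "Natural Landscape")
  clipped <- FALSE
  for (nm in fracs) {
    m <- layers[[nm]]
    if (any(m < 0 | m > 1)) clipped <- TRUE
    layers[[nm]] <- pmin(pmax(m, 0), 1)
  }
  if (clipped) warn("scenario deltas pushed a fraction layer outside [0, 1]; clipped.")
  if ("Natural Landscape" %in% config$landuse_layers) {
    nl <- natural_landscape_layer(layers[["Urban"]], config$natural_urban_cutoff)
    if ("Natural Landscape" %in% names(spec$add %||% numeric())) {
      nl <- nl + spec$add[["Natural Landscape"]]
    }
    layers[["Natural Landscape"]] <- pmin(pmax(nl, 0), 1)
  }
  grid_stack(layers, cell_km = current$cell_km, meta = current$meta)
}

#' Partition a grid into contiguous rectangular subpopulations
#'
#' @param nrow,ncol Grid dimensions.
#' @param blocks_r,blocks_c Number of partitions along rows / columns; the
#'   product is the number of subpopulations, labelled `"SP1"`, `"SP2"`, ...
#'   row-major.
#' @return Character matrix of subpopulation ids.
#' @export
make_subpop_map <- function(nrow, ncol, blocks_r = 2, blocks_c = 2) {
  ri <- ceiling(seq_len(nrow) / (nrow / blocks_r))
  ci <- ceiling(seq_len(ncol) / (ncol / blocks_c))
  ids <- outer(ri, ci, function(a, b) (a - 1) * blocks_c + b)
  matrix(paste0("SP", ids), nrow, ncol)
}
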