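sanitize_category <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Quantitative dietary-energy layer for one food category
#'
#' Within each subpopulation, the layer value at a cell is the sum over the
#' category's food species of the subpopulation's representative energy
#' share multiplied by that species' habitat suitability at the cell:
#' `layer(x) = sum_S rEDEC_Subp,S * HS_S(x)`. Species with a positive
#' share but no suitability map are skipped with a warning (mirroring
#' species that could not be modelled); cells outside every subpopulation
#' are `NA`.
#'
#' @param diet A `subpop_diet` (see [aggregate_subpopulation_diet()]).
#' @param suitability Named list of suitability matrices keyed by
#'   species id.
#' @param category Food category.
#' @param subpop_map Character matrix of subpopulation ids (`NA` outside).
#' @return A matrix.
#' @export
build_quantitative_layer <- function(diet, suitability, category, subpop_map) {
  build_energy_layer(diet, suitability, category, subpop_map, binary = FALSE)
}

#' Binary interaction layer for one food category
#'
#' As [build_quantitative_layer()], but each species observed in the
#' subpopulation's diet contributes its habitat suitability with weight 1
#' instead of its energy share.
#'
#' @inheritParams build_quantitative_layer
#' @return A matrix.
#' @export
build_binary_layer <- function(diet, suitability, category, subpop_map) {
  build_energy_layer(diet, suitability, category, subpop_map, binary = TRUE)
}

build_energy_layer <- function(diet, suitability, category, subpop_map,
                               binary) {
  dims <- dim(subpop_map)
  for (nm in names(suitability)) {
    if (!all(dim(suitability[[nm]]) == dims)) {
      abort("suitability rasters are not co-registered with subpop_map.")
    }
  }
  out <- matrix(0, dims[1], dims[2])
  out[is.na(subpop_map)] <- NA_real_
  d <- diet |> filter(.data$category == !!category, .data$redec > 0)
  skipped <- setdiff(unique(d$species_id), names(suitability))
  if (length(skipped) > 0) {
    warn(sprintf("no suitability map for %d species (skipped): %s",
                 length(skipped), paste(head(skipped, 5), collapse = ", ")))
    d <- d |> filter(.data$species_id %in% names(suitability))
  }
  for (sp in unique(d$subpop)) {
    in_sp <- !is.na(subpop_map) & subpop_map == sp
    dd <- d |> filter(.data$subpop == sp)
    for (i in seq_len(nrow(dd))) {
      wgt <- if (binary) 1 else dd$redec[i]
      hs <- suitability[[dd$species_id[i]]]
      out[in_sp] <- out[in_sp] + wgt * hs[in_sp]
    }
  }
  out
}

#' Build the full set of biotic-interaction layers
#'
#' Produces, for every food category present in the subpopulation diets,
#' the quantitative energy layer (`Biotic_<category>`) and the binary
#' interaction layer (`Biotic_binary_<category>`), plus the all-species
#' total energy layer `Bio_All_species` (the sum of the quantitative
#' category layers). Scenario sets are built from scenario suitabilities
#' with current diets held fixed.
#'
#' @inheritParams build_quantitative_layer
#' @param scenario Scenario label recorded in the set (default
#'   `"current"`).
#' @return An object of class `biotic_layers`: a list with `quantitative`
#'   and `binary` (named lists of matrices), `all_species` (matrix),
#'   `categories`, and `scenario`.
#' @export
build_biotic_layer_set <- function(diet, suitability, subpop_map,
                                   scenario = "current") {
  cats <- intersect(FOOD_CATEGORIES, unique(diet$category))
  quant <- list()
  binr <- list()
  for (cc in cats) {
    quant[[paste0("Biotic_", sanitize_category(cc))]] <-
      build_quantitative_layer(diet, suitability, cc, subpop_map)
    binr[[paste0("Biotic_binary_", sanitize_category(cc))]] <-
      build_binary_layer(diet, suitability, cc, subpop_map)
  }
  all_species <- Reduce(`+`, quant)
  structure(
    list(quantitative = quant, binary = binr, all_species = all_species,
         categories = cats, scenario = scenario),
    class = "biotic_layers"
  )
}

#' @export
print.biotic_layers <- function(x, ...) {
  cat(sprintf("<biotic_layers> scenario %s | %d categories: %s\n",
              x$scenario, length(x$categories),
              paste(x$categories, collapse = ", ")))
  invisible(x)
}

#' Named list of all biotic layer matrices in a set
#'
#' @param x A `biotic_layers` set.
#' @param include_binary Include the binary variants (default TRUE).
#' @return Named list of matrices (quantitative, optionally binary, plus
#'   `Bio_All_species`).
#' @export
biotic_matrices <- function(x, include_binary = TRUE) {
  out <- x$quantitative
  if (include_binary) out <- c(out, x$binary)
  out$Bio_All_species <- x$all_species
  out
}

#' Compare quantitative and binary interaction proxies by AIC
#'
#' For each food category, fits two univariable binomial GLMs (logit link,
#' linear + quadratic) of focal-species presence on the quantitative and
#' on the binary layer value, and reports both AICs; the lower AIC is
#' flagged best. A layer constant over the sample is flagged degenerate.
#'
#' @param pa_cells Tibble of cells with `row`, `col`, `y`.
#' @param biotic A `biotic_layers` set (or list with `quantitative` /
#'   `binary` named lists of matrices).
#' @return Tibble: `category`, `aic_quantitative`, `aic_binary`, `best`,
#'   `degenerate`.
#' @export
compare_proxies <- function(pa_cells, biotic) {
  idx <- cbind(pa_cells$row, pa_cells$col)
  purrr::map_dfr(seq_along(biotic$quantitative), function(i) {
    q <- biotic$quantitative[[i]][idx]
    b <- biotic$binary[[i]][idx]
    cat_name <- biotic$categories[i]
    fit_aic <- function(x) {
      if (sd(x) == 0) return(NA_real_)
      AIC(glm(pa_cells$y ~ x + I(x^2), family = binomial()))
    }
    aq <- fit_aic(q)
    ab <- fit_aic(b)
    tibble(
      category = cat_name,
      aic_quantitative = aq,
      aic_binary = ab,
      best = dplyr::case_when(
        is.na(aq) || is.na(ab) ~ NA_character_,
        aq <= ab ~ "quantitative",
        TRUE ~ "binary"
      ),
      degenerate = is.na(aq) | is.na(ab)
    )
  })
}
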