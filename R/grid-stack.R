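#' Co-registered raster layers on an abstract equal-area grid
#'
#' A `grid_stack` holds named numeric matrices sharing one grid: rows and
#' columns index 1-km cells of an equal-area Cartesian grid (origin top-left,
#' cell centers on the integer lattice). It is the package's lightweight
#' container for climate, land-use, suitability and biotic-energy surfaces;
#' there is no projection machinery because all operations are defined on
#' the equal-area grid itself.
#'
#' @param layers Named list of numeric matrices with identical dimensions.
#' @param cell_km Cell side length in km (default 1).
#' @param meta Optional list of metadata (seed, config, provenance).
#' @return An object of class `grid_stack`.
#' @export
grid_stack <- function(layers, cell_km = 1, meta = list()) {
  if (length(layers) == 0 || is.null(names(layers)) || any(names(layers) == "")) {
    abort("`layers` must be a non-empty named list of matrices.")
  }
  dims <- unique(lapply(layers, dim))
  if (length(dims) != 1) abort("all layers must share the same dimensions.")
  structure(
    list(
      layers = layers,
      nrow = nrow(layers[[1]]),
      ncol = ncol(layers[[1]]),
      cell_km = cell_km,
      meta = meta
    ),
    class = "grid_stack"
  )
}

#' @export
print.grid_stack <- function(x, ...) {
  cat(sprintf(
    "<grid_stack> %d x %d cells (%g km), %d layer(s)\n",
    x$nrow, x$ncol, x$cell_km, length(x$layers)
  ))
  cat("  ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
names.grid_stack <- function(x) names(x$layers)

#' Extract one layer matrix from a grid stack
#' @param x A `grid_stack`.
#' @param name Layer name.
#' @return A numeric matrix.
#' @export
gs_layer <- function(x, name) {
  if (!name %in% names(x$layers)) {
    abort(sprintf("layer '%s' not found in grid_stack.", name))
  }
  x$layers[[name]]
}

#' Convert a grid stack to a long tibble
#'
#' @param x A `grid_stack`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `layer`, `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.grid_stack <- function(x, ...) {
  purrr::map_dfr(names(x$layers), function(nm) {
    m <- x$layers[[nm]]
    tibble(
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      layer = nm,
      value = as.vector(m)
    )
  })
}

#' Values of selected layers at a set of cells
#'
#' @param x A `grid_stack`.
#' @param cells Data frame with `row` and `col` columns.
#' @param layers Character vector of layer names (default: all).
#' @return A tibble with one column per layer, rows aligned with `cells`.
#' @export
gs_values_at <- function(x, cells, layers = names(x$layers)) {
  if (any(cells$row < 1 | cells$row > x$nrow | cells$col < 1 | cells$col > x$ncol)) {
    abort("some cells fall outside the grid.")
  }
  idx <- cbind(cells$row, cells$col)
  out <- lapply(layers, function(nm) gs_layer(x, nm)[idx])
  names(out) <- layers
  as_tibble(out)
}

#' Aggregate a fine matrix into coarse blocks
#'
#' Blocks are `factor` x `factor` groups of fine cells anchored at the
#' top-left corner; ragged trailing blocks keep their partial cell sets, so
#' the coarse grid has `ceiling(dim / factor)` rows and columns.
#'
#' @param m Numeric matrix.
#' @param factor Integer block edge (e.g. 50 for a 50-km coarse grid over
#'   1-km cells).
#' @param fun Summary applied within each block (default `mean`).
#' @return A coarse matrix.
#' @export
block_aggregate <- function(m, factor, fun = mean) {
  stopifnot(factor >= 1)
  ri <- ceiling(seq_len(nrow(m)) / factor)
  ci <- ceiling(seq_len(ncol(m)) / factor)
  out <- matrix(NA_real_, max(ri), max(ci))
  for (i in seq_len(max(ri))) {
    for (j in seq_len(max(ci))) {
      out[i, j] <- fun(m[ri == i, ci == j])
    }
  }
  out
}

# moving-window mean over a (2h+1)x(2h+1) window via a summed-area table;
# edges are truncated to the available cells
moving_window_mean <- function(m, half_width) {
  nr <- nrow(m); nc <- ncol(m)
  sat <- matrix(0, nr + 1, nc + 1)
  sat[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - half_width, 1); r2 <- pmin(seq_len(nr) + half_width, nr)
  c1 <- pmax(seq_len(nc) - half_width, 1); c2 <- pmin(seq_len(nc) + half_width, nc)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    a <- sat[r2 + 1, c2[j] + 1] - sat[r1, c2[j] + 1] -
      sat[r2 + 1, c1[j]] + sat[r1, c1[j]]
    out[, j] <- a / ((r2 - r1 + 1) * (c2[j] - c1[j] + 1))
  }
  out
}

# spatially autocorrelated Gaussian field: white noise smoothed with a
# separable Gaussian kernel (sd = length_scale cells), then re-standardized.
# Edge effects are corrected by normalizing with the smoothed constant field.
gaussian_random_field <- function(nrow, ncol, length_scale) {
  z <- matrix(rnorm(nrow * ncol), nrow, ncol)
  if (length_scale <= 0) return(z)
  half <- max(1L, ceiling(3 * length_scale))
  k <- exp(-((-half:half)^2) / (2 * length_scale^2))
  k <- k / sum(k)
  smooth1 <- function(m) {
    # convolve each column, then each row, with edge renormalization
    conv <- function(v) {
      n <- length(v)
      padded <- c(rep(0, half), v, rep(0, half))
      ones <- c(rep(0, half), rep(1, n), rep(0, half))
      num <- stats::filter(padded, k, sides = 2)[(half + 1):(half + n)]
      den <- stats::filter(ones, k, sides = 2)[(half + 1):(half + n)]
      as.numeric(num / den)
    }
    m <- apply(m, 2, conv)
    t(apply(t(m), 2, conv))
  }
  s <- smooth1(z)
  (s - mean(s)) / sd(s)
}

#' Grid-wide standardization constants for a set of layers
#'
#' @param x A `grid_stack`.
#' @param layers Layer names.
#' @return A tibble with `variable`, `center`, `scale`.
#' @export
gs_standardization <- function(x, layers = names(x$layers)) {
  tibble(
    variable = layers,
    center = unname(vapply(layers, function(nm) mean(gs_layer(x, nm)),
                           numeric(1))),
    scale = unname(vapply(layers, function(nm) {
      s <- sd(gs_layer(x, nm))
      if (!is.finite(s) || s == 0) 1 else s
    }, numeric(1)))
  )
}

#' Write / read a grid stack as plain-text CSV rasters
#'
#' One CSV file per layer (a bare numeric matrix, no header) plus a
#' `layers.csv` manifest. This is the package's generic raster interchange
#' format; conversion to and from GIS formats is left to dedicated tools.
#'
#' @param x A `grid_stack`.
#' @param dir Directory to write into (created if missing).
#' @return `dir`, invisibly.
#' @export
write_grid_stack <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(x$layers)) {
    utils::write.table(
      x$layers[[nm]],
      file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".csv")),
      sep = ",", row.names = FALSE, col.names = FALSE
    )
  }
  utils::write.csv(
    data.frame(layer = names(x$layers), cell_km = x$cell_km),
    file.path(dir, "layers.csv"),
    row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_grid_stack
#' @export
read_grid_stack <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "layers.csv"))
  layers <- lapply(manifest$layer, function(nm) {
    as.matrix(utils::read.table(
      file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".csv")),
      sep = ",", header = FALSE
    ))
  })
  layers <- lapply(layers, function(m) {
    dimnames(m) <- NULL
    m
  })
  names(layers) <- manifest$layer
  grid_stack(layers, cell_km = manifest$cell_km[1])
}

#' Plot grid-stack layers as raster panels
#'
#' @param object A `grid_stack`.
#' @param layers Layers to draw (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.grid_stack <- function(object, layers = names(object$layers), ...) {
  df <- as_tibble(object) |> filter(.data$layer %in% layers)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "col (km)", y = "row (km)", fill = NULL)
}
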