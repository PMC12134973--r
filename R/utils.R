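#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows bind_cols pull left_join row_number n desc across all_of
#' @importFrom stats rnorm runif rbinom quantile sd var cor coef lm glm AIC
#'   binomial plogis qlogis predict as.formula setNames median complete.cases
#'   rmultinom aggregate qnorm
#' @importFrom utils head
NULL

# food categories used throughout; order is the canonical display order
FOOD_CATEGORIES <- c(
  "reproductive plants", "vegetative plants", "unknown plants",
  "invertebrates", "vertebrates"
)

`%||%` <- rlang::`%||%`

stopifnot_scalar_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  as.integer(seed)
}

# derive a stream-specific child seed so independent draws don't collide
# (double arithmetic: the product can exceed the 32-bit integer range)
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 7919) %%
               2147483647)
}

# cells are (row, col) with centers on the integer lattice; distances in km
cell_distance <- function(r1, c1, r2, c2) {
  sqrt((r1 - r2)^2 + (c1 - c2)^2)
}

# minimum distance from every grid cell to a set of target cells, computed
# by relaxing a window of radius `max_km` around each target. Cells farther
# than `max_km` from all targets keep Inf.
distance_to_cells <- function(nrow, ncol, rows, cols, max_km) {
  stopifnot(length(rows) == length(cols), length(rows) >= 1)
  d <- matrix(Inf, nrow, ncol)
  w <- ceiling(max_km)
  off <- expand.grid(dr = -w:w, dc = -w:w)
  off$dist <- sqrt(off$dr^2 + off$dc^2)
  off <- off[off$dist <= max_km, ]
  for (k in seq_along(rows)) {
    rr <- rows[k] + off$dr
    cc <- cols[k] + off$dc
    keep <- rr >= 1 & rr <= nrow & cc >= 1 & cc <= ncol
    idx <- cbind(rr[keep], cc[keep])
    d[idx] <- pmin(d[idx], off$dist[keep])
  }
  d
}

# standardize columns, returning constants so the same scaling can be reused
standardize_tbl <- function(x, constants = NULL) {
  if (is.null(constants)) {
    constants <- tibble(
      variable = colnames(x),
      center = unname(vapply(x, mean, numeric(1))),
      scale = unname(vapply(x, function(v) {
        s <- sd(v)
        if (!is.finite(s) || s == 0) 1 else s
      }, numeric(1)))
    )
  }
  z <- x
  for (i in seq_len(nrow(constants))) {
    v <- constants$variable[i]
    if (v %in% colnames(z)) {
      z[[v]] <- (z[[v]] - constants$center[i]) / constants$scale[i]
    }
  }
  list(values = z, constants = constants)
}
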