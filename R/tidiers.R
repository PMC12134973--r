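#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy the coefficient table of an averaged linear model
#' @param x An `averaged_model`.
#' @param ... Unused.
#' @return Tibble of averaged coefficients.
#' @exportS3Method generics::tidy
tidy.averaged_model <- function(x, ...) x$coefficients

#' One-row summary of an averaged linear model
#' @param x An `averaged_model`.
#' @param ... Unused.
#' @return One-row tibble.
#' @exportS3Method generics::glance
glance.averaged_model <- function(x, ...) {
  tibble(
    response = x$response,
    n = x$n,
    n_candidates = nrow(x$candidates),
    n_best_set = sum(x$candidates$weight > 0),
    best_aicc = min(x$candidates$aicc)
  )
}

#' Posterior coefficient summaries of a Bayesian distribution model
#' @param x A `bear_sdm_fit`.
#' @param conf_level Credible-interval mass (default 0.9, reported as
#'   `conf.low` / `conf.high`).
#' @param ... Unused.
#' @return Tibble: term, estimate, std.error, credible bounds, prior
#'   provenance and convergence diagnostics.
#' @exportS3Method generics::tidy
tidy.bear_sdm_fit <- function(x, conf_level = 0.9, ...) {
  a <- (1 - conf_level) / 2
  tibble(
    term = x$terms,
    estimate = colMeans(x$draws_beta),
    std.error = apply(x$draws_beta, 2, sd),
    conf.low = apply(x$draws_beta, 2, quantile, a),
    conf.high = apply(x$draws_beta, 2, quantile, 1 - a)
  ) |>
    left_join(x$priors, by = "term") |>
    left_join(
      x$diagnostics |> select("term", "rhat", "n_eff", "mcse"),
      by = "term"
    )
}

#' One-row fit summary of a Bayesian distribution model
#' @param x A `bear_sdm_fit`.
#' @param ... Unused.
#' @return One-row tibble with WAIC, effective parameters and convergence.
#' @exportS3Method generics::glance
glance.bear_sdm_fit <- function(x, ...) {
  tibble(
    variant = x$variant,
    hierarchical = x$hierarchical,
    n = if (is.null(x$data)) 0L else length(x$data$y),
    waic = if (is.null(x$waic)) NA_real_ else x$waic$waic,
    waic_se = if (is.null(x$waic)) NA_real_ else x$waic$se,
    p_waic = if (is.null(x$waic)) NA_real_ else x$waic$p_waic,
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_n_eff = suppressWarnings(min(x$diagnostics$n_eff, na.rm = TRUE)),
    converged = x$converged
  )
}

#' Tidy an ensemble habitat model's member skill table
#' @param x An `ensemble_sdm`.
#' @param ... Unused.
#' @return Tibble of member skill and weight.
#' @exportS3Method generics::tidy
tidy.ensemble_sdm <- function(x, ...) {
  x$member_skill |> mutate(weight = unname(x$weights[.data$member]))
}

#' One-row summary of an ensemble habitat model
#' @param x An `ensemble_sdm`.
#' @param ... Unused.
#' @return One-row tibble with held-out sensitivity, specificity and TSS.
#' @exportS3Method generics::glance
glance.ensemble_sdm <- function(x, ...) {
  dplyr::bind_cols(
    tibble(species_id = x$species_id %||% NA_character_,
           n_members = length(x$members),
           n_variables = length(x$variables)),
    x$evaluation
  )
}

#' Coefficient interval plot for a Bayesian distribution model
#' @param object A `bear_sdm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bear_sdm_fit <- function(object, ...) {
  td <- tidy(object) |> filter(.data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate,
                                   stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "posterior estimate (90% CrI)", y = NULL,
                  title = sprintf("%s model coefficients", object$variant))
}

#' Range-change bar plot across scenarios and change modes
#' @param report Output of [range_descriptors()].
#' @param subpop Subpopulation to show (default `"overall"`).
#' @return A ggplot object.
#' @export
plot_range_change <- function(report, subpop = "overall") {
  df <- report |>
    filter(.data$subpop == !!subpop, .data$mode != "current")
  ggplot2::ggplot(df, ggplot2::aes(.data$scenario, .data$pct_change,
                                   fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "% range change vs current",
                  fill = "change mode")
}
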