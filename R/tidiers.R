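#' Tidy a simulation into its per-iteration time series
#'
#' @param x a `biofilm_sim`.
#' @param ... unused.
#' @return Tibble with one row per iteration: population tallies
#'   (`n_susceptible`, `n_infected`, `n_resistant`, `n_phage`), front
#'   height, biomass, and the event ledger columns used for conservation
#'   audits.
#' @export
tidy.biofilm_sim <- function(x, ...) x$timeseries

#' One-row summary of a replicate run
#'
#' @param x a `biofilm_sim`.
#' @param ... unused.
#' @export
glance.biofilm_sim <- function(x, ...) x$record

#' @export
tidy.biofilm_sweep <- function(x, ...) x$replicates

#' @export
glance.biofilm_sweep <- function(x, ...) x$heatmap

#' Population dynamics plot for a replicate run
#'
#' @param object a `biofilm_sim`.
#' @param ... unused.
#' @return A ggplot of population counts over time (days), with the
#'   infection (first-pulse) time marked when present.
#' @export
autoplot.biofilm_sim <- function(object, ...) {
  ts <- object$timeseries |>
    dplyr::select("time_h", "n_susceptible", "n_infected", "n_resistant",
                  "n_phage") |>
    tidyr::pivot_longer(-"time_h", names_to = "population",
                        names_prefix = "n_", values_to = "count")
  p <- ggplot2::ggplot(ts, ggplot2::aes(.data$time_h / 24, .data$count,
                                        colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "time (d)", y = "count",
                  title = "Phage-biofilm population dynamics")
  tinf <- object$record$infection_time_h
  if (!is.na(tinf)) {
    p <- p + ggplot2::geom_vline(xintercept = tinf / 24, linetype = "dashed")
  }
  p
}

#' Selection heatmap for a sweep
#'
#' Mean change in resistant frequency after phage exposure per sweep cell,
#' on the nutrient x initial-frequency plane (additional swept factors are
#' facetted). Blue cells (positive) with red cells (negative) at high
#' initial frequency indicate negative frequency-dependent selection.
#'
#' @param object a `biofilm_sweep`.
#' @param ... unused.
#' @export
autoplot.biofilm_sweep <- function(object, ...) {
  hm <- object$heatmap
  p <- ggplot2::ggplot(hm, ggplot2::aes(factor(round(.data$f0, 3)),
                                        factor(round(.data$nutrient, 2)),
                                        fill = .data$mean_df)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "royalblue", midpoint = 0,
                                  na.value = "grey80") +
    ggplot2::labs(x = "initial resistant frequency",
                  y = "bulk nutrient (mg/L)",
                  fill = expression(Delta * f))
  extra <- c(length(unique(hm$cost)) > 1, length(unique(hm$interaction)) > 1,
             length(unique(hm$removal)) > 1)
  if (any(extra)) {
    vars <- c("cost", "interaction", "removal")[extra]
    p <- p + ggplot2::facet_wrap(vars, labeller = ggplot2::label_both)
  }
  p
}
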