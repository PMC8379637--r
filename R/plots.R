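#' Plot a lower-bound curve
#'
#' @param object A `pc_bound_curve` from [bound_curve()].
#' @param ... Unused.
#' @return A ggplot of cost against rate (tests per individual).
#' @export
autoplot.pc_bound_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$rate_tpi, .data$cost_per_individual)) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::labs(x = "rate [tests per individual]",
                  y = "expected cost per individual",
                  title = "Information-theoretic lower bound") +
    ggplot2::theme_minimal()
}

#' Plot per-subpopulation rate-cost frontiers
#'
#' @param object A `pc_frontier` from [build_frontier()].
#' @param label_vertices Label frontier vertices with their strategy
#'   notation (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot with one frontier per subpopulation.
#' @export
autoplot.pc_frontier <- function(object, label_vertices = TRUE, ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(.data$rate, .data$cost, colour = .data$name)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rate [tests per individual]",
                  y = "expected cost per individual",
                  colour = "subpopulation",
                  title = "Achievable rate-cost frontier") +
    ggplot2::theme_minimal()
  if (label_vertices) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                                vjust = -0.6, size = 2.8,
                                show.legend = FALSE)
  }
  p
}

#' Rate-cost overview chart for a scenario
#'
#' Overlays, for one scenario, the information-theoretic lower bound, the
#' cost achieved by optimally combined pooled strategies, and the cost
#' achieved by individual testing only, as functions of the test budget
#' expressed in tests per individual.
#'
#' @param x A [scenario()] or subpopulation data frame.
#' @param n_points Number of budgets at which the achievable curves are
#'   evaluated (default 40).
#' @param max_k,max_group Search bounds for the pooled-strategy curve;
#'   scenario defaults apply.
#' @return A ggplot.
#' @examples
#' \donttest{
#' plot_rate_cost(example35_scenario(), n_points = 20)
#' }
#' @export
plot_rate_cost <- function(x, n_points = 40, max_k = NULL,
                           max_group = NULL) {
  sp <- as_subpops(x)
  n_total <- sum(sp$size)
  rates <- seq(0, 1, length.out = n_points)
  achieved <- function(strats) {
    purrr::map_dfr(rates, function(r) {
      a <- allocate_budget(x, budget_tests = r * n_total, max_k = max_k,
                           max_group = max_group, strategies = strats)
      tibble::tibble(rate_tpi = r, cost_per_individual = a$cost_per_individual)
    })
  }
  curves <- dplyr::bind_rows(
    dplyr::mutate(achieved("ksg"), curve = "optimal combination (kSG)"),
    dplyr::mutate(achieved("individual"), curve = "individual testing"),
    bound_curve(sp, n_samples = 400) |>
      dplyr::select("rate_tpi", "cost_per_individual") |>
      dplyr::mutate(curve = "lower bound")
  )
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$rate_tpi, .data$cost_per_individual,
                               colour = .data$curve,
                               linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "rate [tests per individual]",
                  y = "expected cost per individual",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
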