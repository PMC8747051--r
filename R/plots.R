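#' Forest plot of the association results
#'
#' Odds ratios with 95% intervals for each exposure, faceted by outcome,
#' per-round and overall estimates distinguished by colour.
#'
#' @param object A `kinfeed_suite`.
#' @param statistic Which estimates to show: `"aor"` (default) or
#'   `"cor"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinfeed_suite <- function(object, statistic = c("aor", "cor"), ...) {
  statistic <- match.arg(statistic)
  d <- object$associations |>
    dplyr::filter(.data$statistic == !!statistic,
                  .data$round != "overall_unweighted") |>
    dplyr::mutate(kind = ifelse(.data$round == "overall", "pooled", "per round"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$term,
                                  colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high),
                             position = ggplot2::position_dodge2(width = 0.6)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome), scales = "free_x") +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL, colour = NULL)
}

#' Plot the ego network of one household
#'
#' Alters arranged on a circle around the ego; edge width proportional
#' to the normalised kinship tie weight (absent ties not drawn).
#'
#' @param net An `ego_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ego_network <- function(net, ...) {
  n <- nrow(net$alters)
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  nodes <- tibble::tibble(
    id = c(net$ego$member_id, net$alters$member_id),
    label = c("ego", net$alters$relationship_to_head),
    x = c(0, cos(theta)), y = c(0, sin(theta)))
  idx <- which(upper.tri(net$Z), arr.ind = TRUE)
  edges <- tibble::tibble(from = idx[, 1], to = idx[, 2],
                          w = net$Z[idx]) |>
    dplyr::filter(.data$w > 0) |>
    dplyr::mutate(x = nodes$x[.data$from], y = nodes$y[.data$from],
                  xend = nodes$x[.data$to], yend = nodes$y[.data$to])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$w),
                          colour = "grey60") +
    ggplot2::scale_linewidth(range = c(0.2, 1.4), limits = c(0, 1)) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$label),
                       vjust = -1.1, size = 3) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "kin tie")
}

#' Plot the eligibility exclusion flow
#'
#' Horizontal bar chart of the cohort-selection cascade counts.
#'
#' @param flow Tibble from [eligibility_flow()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_exclusion_flow <- function(flow, ...) {
  d <- dplyr::mutate(flow, stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), hjust = -0.15, size = 3) +
    ggplot2::labs(x = "children", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
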