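#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_jitter geom_hline
#'   geom_vline labs facet_wrap scale_y_continuous theme_minimal
NULL

#' Plot the ranked target-function profile of a fit
#'
#' Target function against solution rank; a wide gap between the best pose
#' and the first structurally distinct one is what validation measures.
#'
#' @param object An `nmr2_fit`.
#' @param n Number of top solutions shown (default 50).
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nmr2_fit <- function(object, n = 50, ...) {
  df <- head(object$solutions, n)
  ggplot(df, aes(x = .data$rank, y = .data$tf)) +
    geom_point() +
    labs(x = "solution rank", y = expression(tf ~ (ring(A)^2)),
         title = "Ranked assignment solutions") +
    theme_minimal()
}

#' Success-rate and contrast overview of a benchmark report
#'
#' Bar chart of the success rate per condition with the per-case target
#' function contrasts overlaid as points (finite values only).
#'
#' @param object An `nmr2_report`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.nmr2_report <- function(object, ...) {
  summ <- dplyr::filter(object$summary, .data$scope == "all")
  summ$condition <- condition_label(summ)
  rows <- object$rows
  rows$condition <- condition_label(rows)
  ggplot(summ, aes(x = .data$condition)) +
    geom_col(aes(y = .data$success_rate), fill = "steelblue", alpha = 0.6) +
    geom_jitter(data = dplyr::filter(rows, is.finite(.data$tfc)),
                aes(y = pmin(.data$tfc / max(.data$tfc[is.finite(.data$tfc)],
                                             1), 1)),
                width = 0.15, size = 0.8) +
    scale_y_continuous("success rate",
                       sec.axis = ggplot2::dup_axis(name = "TFC (scaled)")) +
    labs(x = NULL, title = "Benchmark overview by condition") +
    theme_minimal()
}

condition_label <- function(df) {
  paste0(round(100 * df$tolerance_fraction), "%",
         ifelse(df$partial_assignment, " +PA", ""))
}

#' Topology-parameter success scatter
#'
#' Scatter of the ligand topology parameters `r_l` against `r_w`, colored
#' by outcome and faceted by condition; the empirical convergence boundary
#' `r_l + r_w = 2` is drawn as a diagonal.
#'
#' @param rows Benchmark row tibble (`nmr2_report$rows`).
#' @return A ggplot.
#' @export
plot_topology_scatter <- function(rows) {
  rows <- as_tibble(rows)
  rows$condition <- condition_label(rows)
  ggplot(rows, aes(x = .data$r_l, y = .data$r_w,
                   color = .data$success)) +
    geom_point() +
    ggplot2::geom_abline(intercept = 2, slope = -1, linetype = 2) +
    facet_wrap(~condition) +
    labs(x = expression(r[l]), y = expression(r[w]),
         color = "success",
         title = "Convergence vs ligand topology") +
    theme_minimal()
}
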