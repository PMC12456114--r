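#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Reshape a trajectory to long (tidy) form
#'
#' One row per (replicate, generation, score), with the introgressed
#' fraction `1 - S_Q` reported as `introgression` alongside the five scores.
#'
#' @param trajectory A `breeding_trajectory` tibble.
#' @return A long tibble with columns `generation`, grouping columns present
#'   in the input (`replicate`, `strategy`, `compliance`), `score`, `value`.
#' @export
trajectory_long <- function(trajectory) {
  tr <- tibble::as_tibble(trajectory)
  tr$introgression <- 1 - tr$S_Q
  tidyr::pivot_longer(tr,
                      cols = dplyr::any_of(c("S_Q", "S_H", "S_K", "S_PH",
                                             "S_PK", "introgression")),
                      names_to = "score", values_to = "value")
}

#' Summarise final-generation scores of a trajectory
#'
#' @param trajectory A `breeding_trajectory` tibble (possibly with
#'   `strategy`/`compliance` columns from [run_strategy_comparison()]).
#' @return One row per strategy/compliance group: mean final scores over
#'   replicates, plus `final_introgression = 1 - mean(S_Q)`.
#' @export
trajectory_summary <- function(trajectory) {
  tr <- tibble::as_tibble(trajectory)
  grp <- intersect(c("strategy", "compliance", "parameter", "value",
                     "measure"), names(tr))
  tr |>
    dplyr::filter(.data$generation == max(.data$generation)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(c("S_Q", "S_H", "S_K", "S_PH", "S_PK")), mean),
      n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(final_introgression = 1 - .data$S_Q)
}

#' Plot score trajectories over generations
#'
#' Draws one panel per score (introgressed fraction `1 - S_Q`,
#' heterozygosity, kinship and their ancestry-masked versions), with one
#' line per replicate and per strategy/compliance combination if present.
#'
#' @param object A `breeding_trajectory` tibble.
#' @param scores Which scores to draw (default all six).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot breeding_trajectory
#' @export
autoplot.breeding_trajectory <- function(object,
                                         scores = c("introgression", "S_H",
                                                    "S_K", "S_PH", "S_PK"),
                                         ...) {
  long <- trajectory_long(object) |>
    dplyr::filter(.data$score %in% scores)
  aes_args <- list(x = rlang::sym("generation"), y = rlang::sym("value"))
  if ("strategy" %in% names(long)) aes_args$colour <- rlang::sym("strategy")
  if ("replicate" %in% names(long)) {
    long$grp <- interaction(long$replicate,
                            long[["strategy"]] %||% "",
                            long[["compliance"]] %||% "")
    aes_args$group <- rlang::sym("grp")
  }
  ggplot2::ggplot(long, do.call(ggplot2::aes, aes_args)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~score, scales = "free_y") +
    ggplot2::labs(x = "generation of the breeding program", y = "score") +
    ggplot2::theme_minimal()
}

#' @export
plot.breeding_trajectory <- function(x, ...) print(autoplot.breeding_trajectory(x, ...))

#' Plot a sensitivity-sweep summary
#'
#' Final-generation score means with 25-75% quantile ribbons against the
#' swept parameter value, one colour per score, faceted by selection
#' measure.
#'
#' @param sweep Result of [run_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  s <- sweep$summary
  long <- tidyr::pivot_longer(
    s, cols = dplyr::matches("^S_[A-Z]+_(mean|q25|q75)$"),
    names_to = c("score", "stat"), names_pattern = "(S_[A-Z]+)_(.*)",
    values_to = "val") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "val")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$mean,
                                     colour = .data$score,
                                     fill = .data$score)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = unique(s$parameter), y = "final score") +
    ggplot2::theme_minimal()
}
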