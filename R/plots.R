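#' Pool subtype composition per condition
#'
#' Sums the per-well subtype counts of each condition and converts them to
#' proportions of viable nuclei.
#'
#' @param wells per-well summaries from [summarize_wells()].
#' @param pair marker pair used in the summary.
#' @return long tibble: `condition`, `category`, `n`, `proportion`.
#' @export
composition_by_condition <- function(wells, pair = c("ctip2", "satb2")) {
  cats <- c(paste0(pair, "_only"), "dual", "unlabeled")
  cols <- paste0("n_", cats)
  wells %>%
    group_by(.data$condition) %>%
    summarise(dplyr::across(dplyr::all_of(c("n_viable", cols)), sum),
              .groups = "drop") %>%
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "category",
                        names_prefix = "n_", values_to = "n") %>%
    mutate(category = factor(.data$category, levels = cats),
           proportion = .data$n / .data$n_viable)
}

#' Composition pie charts
#'
#' One pie per condition showing the relative proportions of CTIP2-only,
#' SATB2-only, dual-expressing and unlabeled viable nuclei.
#'
#' @param composition long tibble from [composition_by_condition()] or
#'   [composition_proportions()].
#' @return a ggplot object whose data equal the input proportions exactly.
#' @export
plot_composition <- function(composition) {
  facet_var <- if ("condition" %in% names(composition)) "condition" else "well"
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = "", y = .data$proportion, fill = .data$category)) +
    ggplot2::geom_col(width = 1, colour = "white", linewidth = 0.3) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::facet_wrap(facet_var) +
    ggplot2::scale_fill_manual(values = c("#2e7d32", "#c62828", "#f9a825", "grey80")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "subtype") +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
}

#' Ranked normalised-ratio bar chart
#'
#' Compound-level bar chart of the normalised refinement ratio, ordered by
#' value, coloured by the triage stage reached; an empty record set yields an
#' empty chart with axes only.
#'
#' @param records a `triage_result` from [run_triage()].
#' @return a ggplot object.
#' @export
plot_ranked_ratios <- function(records) {
  records <- as_tibble(records)
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = stats::reorder(paste(.data$compound,
                                                             .data$dose_uM),
                                                       -.data$norm_ratio),
                                    y = .data$norm_ratio,
                                    fill = .data$stage_reached)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "compound (dose uM)", y = "normalised refinement ratio",
                  fill = "stage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (nrow(records)) p <- p + ggplot2::geom_col()
  p
}

#' @export
autoplot.triage_result <- function(object, ...) plot_ranked_ratios(object)

#' Autoplot methods
#'
#' @param object an object produced by this package.
#' @param ... unused.
#' @name autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
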