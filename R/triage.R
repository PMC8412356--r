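#' Three-level candidate selection criteria
#'
#' The screen's sequential selection, applied after toxicity exclusion:
#' level 1 keeps compounds whose normalised refinement ratio strictly exceeds
#' `min_norm_ratio`; level 2 keeps those that maintain or increase total
#' CTIP2+ counts (`norm_ctip2_total >= min_norm_ctip2`, the 0.8 default
#' tolerating counting noise on the maintain side); level 3 keeps those that
#' maintain or decrease total SATB2+ counts
#' (`norm_satb2_total <= max_norm_satb2`).
#'
#' The enhancement cutoff defaults to 1.5: a null compound's normalised ratio
#' is centred on 1, so a cutoff at 1 would call half of all inert compounds
#' enhancing by chance; 1.5 sits several relative standard errors above the
#' null at screen-scale per-condition cell counts while remaining far below
#' genuine enhancer effects (see the methods vignette for the power
#' calculation).
#'
#' @param min_norm_ratio level-1 cutoff (strictly greater required).
#' @param min_norm_ctip2 level-2 cutoff (at least this).
#' @param max_norm_satb2 level-3 cutoff (at most this).
#' @return a `triage_criteria` object.
#' @export
triage_criteria <- function(min_norm_ratio = 1.5, min_norm_ctip2 = 0.8,
                            max_norm_satb2 = 1.0) {
  for (v in c(min_norm_ratio, min_norm_ctip2, max_norm_satb2))
    if (!is.numeric(v) || v < 0) stop_bad("triage cutoffs must be non-negative")
  structure(list(min_norm_ratio = min_norm_ratio,
                 min_norm_ctip2 = min_norm_ctip2,
                 max_norm_satb2 = max_norm_satb2),
            class = "triage_criteria")
}

TRIAGE_STAGES <- c("excluded_toxicity", "failed_L1", "failed_L2", "failed_L3", "hit")

#' Run the three-level candidate triage
#'
#' Aggregates normalised well summaries per compound and dose (replicate
#' wells averaged; the worst toxicity grade across a compound-dose's wells is
#' carried), then applies, in order: toxicity exclusion, ratio enhancement
#' (L1), CTIP2 preservation (L2) and SATB2 reduction (L3). Each compound-dose
#' reaches exactly one stage. Hits are ranked by descending normalised ratio,
#' ties broken by ascending normalised SATB2 total, then by compound id.
#'
#' @param wells normalised per-well summaries (see
#'   [add_screen_normalizations()]) restricted to or including compound
#'   wells; control wells (missing `compound`) are ignored.
#' @param qc graded per-well QC from [grade_well_toxicity()].
#' @param criteria a [triage_criteria()].
#' @return a `triage_result` tibble: one row per compound and dose with the
#'   aggregated metrics, `qc_grade`, `stage_reached` and `rank` (hits only).
#' @export
run_triage <- function(wells, qc, criteria = triage_criteria()) {
  wells <- as_tibble(wells)
  need <- c("norm_ratio", "norm_ctip2_total", "norm_satb2_total")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop_bad("well summaries lack normalised column(s): %s", paste(miss, collapse = ", "))
  if (!"compound" %in% names(wells)) stop_bad("well summaries need a `compound` column")
  wells <- filter(wells, !is.na(.data$compound))
  if (!"dose_uM" %in% names(wells)) wells$dose_uM <- NA_real_
  if (!"ratio_defined" %in% names(wells)) wells$ratio_defined <- TRUE
  qc_grade <- qc %>% select(dplyr::all_of(c("well", "grade")))
  wells <- left_join(wells, qc_grade, by = "well")
  if (anyNA(wells$grade)) stop_bad("missing QC grade for well(s): %s",
                                   paste(wells$well[is.na(wells$grade)], collapse = ", "))
  agg <- wells %>%
    group_by(.data$compound, .data$dose_uM) %>%
    summarise(n_wells = dplyr::n(),
              qc_grade = sort(.data$grade, decreasing = TRUE)[1],
              norm_ratio = mean(.data$norm_ratio[.data$ratio_defined], na.rm = TRUE),
              norm_ctip2_total = mean(.data$norm_ctip2_total, na.rm = TRUE),
              norm_satb2_total = mean(.data$norm_satb2_total, na.rm = TRUE),
              .groups = "drop")
  agg <- agg %>%
    mutate(stage_reached = factor(dplyr::case_when(
      .data$qc_grade != "none" ~ "excluded_toxicity",
      !(.data$norm_ratio > criteria$min_norm_ratio) ~ "failed_L1",
      !(.data$norm_ctip2_total >= criteria$min_norm_ctip2) ~ "failed_L2",
      !(.data$norm_satb2_total <= criteria$max_norm_satb2) ~ "failed_L3",
      TRUE ~ "hit"), levels = TRIAGE_STAGES))
  hits <- agg$stage_reached == "hit"
  agg$rank <- NA_integer_
  if (any(hits)) {
    ord <- order(-agg$norm_ratio[hits], agg$norm_satb2_total[hits],
                 agg$compound[hits])
    agg$rank[which(hits)[ord]] <- seq_len(sum(hits))
  }
  agg <- arrange(agg, .data$compound, .data$dose_uM)
  class(agg) <- c("triage_result", class(agg))
  agg
}

#' Summarise a triage run
#'
#' @param records a `triage_result` from [run_triage()].
#' @return a `triage_report`: `stage_counts` (all five stages, zero-filled)
#'   and `hits` (ranked hit records).
#' @export
triage_report <- function(records) {
  counts <- tibble(stage_reached = factor(TRIAGE_STAGES, levels = TRIAGE_STAGES)) %>%
    left_join(count(records, .data$stage_reached), by = "stage_reached") %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
  hits <- records %>% filter(.data$stage_reached == "hit") %>% arrange(.data$rank)
  structure(list(stage_counts = counts, hits = as_tibble(hits)),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat("Screen triage\n")
  for (i in seq_len(nrow(x$stage_counts)))
    cat(sprintf("  %-18s %d\n", x$stage_counts$stage_reached[i], x$stage_counts$n[i]))
  if (nrow(x$hits)) {
    cat("Ranked hits:\n")
    for (i in seq_len(nrow(x$hits)))
      cat(sprintf("  #%d %s (dose %s uM): norm ratio %.3f, CTIP2 %.3f, SATB2 %.3f\n",
                  x$hits$rank[i], x$hits$compound[i],
                  format(x$hits$dose_uM[i]), x$hits$norm_ratio[i],
                  x$hits$norm_ctip2_total[i], x$hits$norm_satb2_total[i]))
  } else cat("No hits.\n")
  invisible(x)
}

#' Write a triage report as JSON
#'
#' @param report a [triage_report()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_triage_report <- function(report, path) {
  jsonlite::write_json(list(stage_counts = report$stage_counts,
                            hits = report$hits),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
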