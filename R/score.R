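#' Summarise classified nuclei per well
#'
#' Pools counts across all fields of each well before any ratio computation
#' (the refinement ratio is a ratio of pooled counts, not a mean of per-field
#' ratios), and computes the subtype composition for one ordered marker pair:
#' A-only, B-only, dual and unlabeled counts, marker-positive totals, and the
#' refinement ratio `R = n_A_only / n_dual`. Wells with `n_dual = 0` get an
#' undefined (`NA`) ratio and are flagged, never imputed.
#'
#' @param classified viable, classified nuclei (see [classify_nuclei()]) with
#'   a `well` column; plate-map columns (`condition`, `compound`, `dose_uM`,
#'   `replicate`) are carried through when present.
#' @param pair ordered marker pair, default `c("ctip2", "satb2")`.
#' @return a tibble with one row per well: counts, totals, `ratio` and
#'   `ratio_defined`.
#' @export
summarize_wells <- function(classified, pair = c("ctip2", "satb2")) {
  classified <- as_tibble(classified)
  sub_col <- paste0("subtype_", pair[1], "_", pair[2])
  if (!sub_col %in% names(classified))
    stop_bad("missing subtype column `%s`; run classify_nuclei() first", sub_col)
  if (!"well" %in% names(classified)) stop_bad("classified nuclei need a `well` column")
  lv <- c(paste0(pair, "_only"), "dual", "unlabeled")
  carry <- intersect(c("condition", "compound", "dose_uM", "replicate"),
                     names(classified))
  classified$._st <- classified[[sub_col]]
  out <- classified %>%
    group_by(.data$well) %>%
    summarise(dplyr::across(dplyr::all_of(carry), dplyr::first),
              n_viable = dplyr::n(),
              n_a_only = sum(.data$._st == lv[1]),
              n_b_only = sum(.data$._st == lv[2]),
              n_dual = sum(.data$._st == lv[3]),
              n_unlabeled = sum(.data$._st == lv[4]),
              .groups = "drop") %>%
    mutate(n_a_total = .data$n_a_only + .data$n_dual,
           n_b_total = .data$n_b_only + .data$n_dual,
           ratio = ifelse(.data$n_dual > 0, .data$n_a_only / .data$n_dual, NA_real_),
           ratio_defined = .data$n_dual > 0)
  names(out)[names(out) == "n_a_only"] <- paste0("n_", lv[1])
  names(out)[names(out) == "n_b_only"] <- paste0("n_", lv[2])
  names(out)[names(out) == "n_a_total"] <- paste0("n_", pair[1], "_total")
  names(out)[names(out) == "n_b_total"] <- paste0("n_", pair[2], "_total")
  out
}

#' Normalise per-well values to a baseline condition
#'
#' Divides a per-well metric by the mean of that metric over the baseline
#' condition's wells (undefined values are excluded from the baseline mean).
#' The screen's three metrics use their own baselines: refinement ratio to
#' the untreated condition, total CTIP2+ counts to the Fezf2 modRNA
#' condition, total SATB2+ counts to the GFP modRNA condition.
#'
#' @param wells per-well tibble with a `condition` column.
#' @param value column to normalise (tidy-eval).
#' @param baseline_condition condition label supplying the baseline.
#' @param out_col name of the normalised column (default `norm_<value>`).
#' @return `wells` with the normalised column appended.
#' @export
normalize_to_baseline <- function(wells, value, baseline_condition,
                                  out_col = NULL) {
  wells <- as_tibble(wells)
  if (!"condition" %in% names(wells)) stop_bad("wells need a `condition` column")
  v <- rlang::eval_tidy(rlang::enquo(value), wells)
  col_name <- out_col %||% paste0("norm_", rlang::as_name(rlang::enquo(value)))
  base <- v[wells$condition == baseline_condition]
  base <- base[is.finite(base)]
  if (!length(base))
    stop_bad("baseline condition `%s` has no defined values", baseline_condition)
  m <- mean(base)
  if (m == 0) stop_bad("baseline mean for `%s` is zero", baseline_condition)
  wells[[col_name]] <- v / m
  wells
}

#' Apply the screen's three normalizations
#'
#' Adds `norm_ratio` (ratio normalised to the untreated condition),
#' `norm_ctip2_total` (CTIP2-positive totals normalised to the Fezf2 modRNA
#' condition) and `norm_satb2_total` (SATB2-positive totals normalised to the
#' GFP modRNA condition).
#'
#' @param wells per-well summary from [summarize_wells()] with plate-map
#'   columns.
#' @param baselines named character vector mapping the three metrics to their
#'   baseline conditions.
#' @return `wells` with the three normalised columns.
#' @export
add_screen_normalizations <- function(wells,
                                      baselines = c(ratio = "untreated",
                                                    ctip2 = "fezf2_modrna",
                                                    satb2 = "gfp_modrna")) {
  wells %>%
    normalize_to_baseline(.data$ratio, baselines[["ratio"]], out_col = "norm_ratio") %>%
    normalize_to_baseline(.data$n_ctip2_total, baselines[["ctip2"]],
                          out_col = "norm_ctip2_total") %>%
    normalize_to_baseline(.data$n_satb2_total, baselines[["satb2"]],
                          out_col = "norm_satb2_total")
}

#' Subtype composition proportions of a well
#'
#' Converts the four subtype counts of a [summarize_wells()] row into
#' fractions of viable nuclei (they sum to 1 exactly).
#'
#' @param summary per-well summary tibble.
#' @param pair the marker pair used in the summary.
#' @return a long tibble: `well`, `category`, `n`, `proportion`.
#' @export
composition_proportions <- function(summary, pair = c("ctip2", "satb2")) {
  summary <- as_tibble(summary)
  if (any(summary$n_viable == 0)) stop_bad("composition undefined for wells with 0 viable nuclei")
  cats <- c(paste0(pair, "_only"), "dual", "unlabeled")
  cols <- paste0("n_", cats)
  miss <- setdiff(cols, names(summary))
  if (length(miss)) stop_bad("summary lacks column(s): %s", paste(miss, collapse = ", "))
  keep <- intersect(c("well", "condition", "compound", "dose_uM"), names(summary))
  summary %>%
    select(dplyr::all_of(c(keep, "n_viable", cols))) %>%
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "category",
                        names_prefix = "n_", values_to = "n") %>%
    mutate(category = factor(.data$category, levels = cats),
           proportion = .data$n / .data$n_viable)
}

#' Compare a metric between two conditions
#'
#' Unpaired two-sample Student t-test (pooled variance; Welch available via
#' `var_equal = FALSE`), two-sided, on per-replicate values, with group means
#' and standard errors of the mean, and significance marks at p < 0.05 (`*`)
#' and p < 0.01 (`**`).
#'
#' @param values_a,values_b numeric vectors of per-replicate values (>= 2
#'   each).
#' @param labels names of the two groups.
#' @param var_equal pooled-variance Student t (default) vs Welch.
#' @return a `condition_test` object; see [tidy.condition_test()].
#' @export
compare_conditions <- function(values_a, values_b, labels = c("A", "B"),
                               var_equal = TRUE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop_bad("each group needs at least 2 replicate values")
  ht <- t.test(values_a, values_b, var.equal = var_equal)
  p <- ht$p.value
  structure(list(labels = labels,
                 n = c(length(values_a), length(values_b)),
                 mean = c(mean(values_a), mean(values_b)),
                 sem = c(sd(values_a) / sqrt(length(values_a)),
                         sd(values_b) / sqrt(length(values_b))),
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = p,
                 significance = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
                 method = if (var_equal) "Student" else "Welch"),
            class = "condition_test")
}

#' @export
print.condition_test <- function(x, ...) {
  cat(sprintf("Unpaired %s t-test: %s vs %s\n", x$method, x$labels[1], x$labels[2]))
  cat(sprintf("  %s: mean %.4g +/- %.3g sem (n = %d)\n", x$labels[1], x$mean[1],
              x$sem[1], x$n[1]))
  cat(sprintf("  %s: mean %.4g +/- %.3g sem (n = %d)\n", x$labels[2], x$mean[2],
              x$sem[2], x$n[2]))
  cat(sprintf("  t = %.4f, df = %.4g, p = %.4g %s\n", x$statistic, x$df,
              x$p_value, x$significance))
  invisible(x)
}

#' Tidy a condition comparison
#'
#' @param x a `condition_test`.
#' @param ... unused.
#' @return one-row tibble with group means/SEMs, t, df, p and significance.
#' @export
tidy.condition_test <- function(x, ...) {
  tibble(group_a = x$labels[1], group_b = x$labels[2],
         n_a = x$n[1], n_b = x$n[2],
         mean_a = x$mean[1], mean_b = x$mean[2],
         sem_a = x$sem[1], sem_b = x$sem[2],
         estimate = x$mean[1] - x$mean[2],
         statistic = x$statistic, df = x$df, p_value = x$p_value,
         significance = x$significance)
}

#' @rdname tidy.condition_test
#' @export
glance.condition_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         method = paste(x$method, "two-sample t-test"))
}

#' Turn a fitted object into a tidy tibble
#' @param x an object.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary of a fitted object
#' @param x an object.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")
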