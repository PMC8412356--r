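#' Per-nucleus viability criteria
#'
#' The published selection for viable nuclei: object area strictly between
#' `area_min` and `area_max` um^2, object width strictly greater than
#' `width_min` um, and mean Hoechst intensity strictly below `hoechst_max`.
#' Boundary values are excluded, matching the printed strict inequalities.
#'
#' @param area_min,area_max area window, um^2 (defaults 33 and 100).
#' @param width_min minimum ellipse minor-axis width, um (default 3.7).
#' @param hoechst_max maximum mean Hoechst intensity (default 900).
#' @return a `viability_criteria` object.
#' @export
viability_criteria <- function(area_min = 33, area_max = 100, width_min = 3.7,
                               hoechst_max = 900) {
  if (!(area_min < area_max)) stop_bad("area_min must be < area_max")
  check_positive(width_min, "width_min")
  check_positive(hoechst_max, "hoechst_max")
  structure(list(area_min = area_min, area_max = area_max,
                 width_min = width_min, hoechst_max = hoechst_max),
            class = "viability_criteria")
}

#' Apply the viability criteria to measured candidates
#'
#' Adds a logical `viable` column and, for excluded candidates, an
#' `exclude_reason` holding the first failing criterion in the fixed order
#' `area` (fragments and adjacent double nuclei), `width`, `intensity`
#' (pyknotic / condensed chromatin).
#'
#' @param candidates tibble with `area_um2`, `width_um` and a mean-Hoechst
#'   column.
#' @param criteria a [viability_criteria()].
#' @param hoechst_col name of the mean-Hoechst column.
#' @return the input tibble with `viable` and `exclude_reason` columns; rows
#'   are never dropped, so viable + excluded partition the input.
#' @examples
#' x <- tibble::tibble(area_um2 = c(50, 120), width_um = c(5, 6),
#'                     mean_hoechst = c(500, 400))
#' filter_viable(x)
#' @export
filter_viable <- function(candidates, criteria = viability_criteria(),
                          hoechst_col = "mean_hoechst") {
  candidates <- as_tibble(candidates)
  need <- c("area_um2", "width_um", hoechst_col)
  miss <- setdiff(need, names(candidates))
  if (length(miss)) stop_bad("candidates lack column(s): %s", paste(miss, collapse = ", "))
  a <- candidates$area_um2; w <- candidates$width_um; h <- candidates[[hoechst_col]]
  area_ok <- a > criteria$area_min & a < criteria$area_max
  width_ok <- w > criteria$width_min
  intens_ok <- h < criteria$hoechst_max
  reason <- dplyr::case_when(!area_ok ~ "area", !width_ok ~ "width",
                             !intens_ok ~ "intensity", TRUE ~ NA_character_)
  mutate(candidates, viable = area_ok & width_ok & intens_ok,
         exclude_reason = reason)
}

#' Toxicity grading cutoffs
#'
#' A well is graded `severe` when its viable count drops below
#' `severe_count_frac` of the control median or its pyknotic fraction exceeds
#' `severe_pyk`; `moderate` under the analogous looser cutoffs; otherwise
#' `none`. These operationalise the blinded visual toxicity screen (globally
#' reduced counts, excess pyknotic nuclei or debris) as reproducible
#' quantitative rules.
#'
#' @param severe_count_frac,moderate_count_frac viable-count depression
#'   cutoffs relative to the control median.
#' @param severe_pyk,moderate_pyk pyknotic-fraction cutoffs.
#' @return a `toxicity_cutoffs` object.
#' @export
toxicity_cutoffs <- function(severe_count_frac = 0.4, moderate_count_frac = 0.7,
                             severe_pyk = 0.30, moderate_pyk = 0.15) {
  stopifnot(severe_count_frac <= moderate_count_frac, severe_pyk >= moderate_pyk)
  structure(list(severe_count_frac = severe_count_frac,
                 moderate_count_frac = moderate_count_frac,
                 severe_pyk = severe_pyk, moderate_pyk = moderate_pyk),
            class = "toxicity_cutoffs")
}

#' Per-well QC metrics
#'
#' Summarises [filter_viable()] output per well: candidate and viable counts,
#' viable fraction, pyknotic fraction (candidates below the minimum viable
#' area with mean Hoechst at or above the intensity cutoff) and debris
#' fraction (sub-minimum-area objects discarded during detection, over all
#' detected objects).
#'
#' @param candidates tibble from [filter_viable()] with a `well` column.
#' @param criteria the [viability_criteria()] used.
#' @param hoechst_col name of the mean-Hoechst column.
#' @param debris_counts optional named vector (well -> number of
#'   sub-minimum-area discards reported by [find_nuclei()]).
#' @return a tibble with one row per well.
#' @export
well_qc_report <- function(candidates, criteria = viability_criteria(),
                           hoechst_col = "mean_hoechst", debris_counts = NULL) {
  if (!"well" %in% names(candidates)) stop_bad("candidates need a `well` column")
  if (!"viable" %in% names(candidates))
    candidates <- filter_viable(candidates, criteria, hoechst_col)
  h <- candidates[[hoechst_col]]
  candidates$._pyk <- candidates$area_um2 < criteria$area_min & h >= criteria$hoechst_max
  out <- candidates %>%
    group_by(.data$well) %>%
    summarise(candidate_count = dplyr::n(),
              viable_count = sum(.data$viable),
              viable_fraction = mean(.data$viable),
              pyknotic_fraction = mean(.data$._pyk),
              .groups = "drop")
  debris <- if (is.null(debris_counts)) rep(0, nrow(out)) else
    as.numeric(debris_counts[out$well])
  debris[is.na(debris)] <- 0
  out$debris_fraction <- as.numeric(debris) /
    pmax(1, out$candidate_count + as.numeric(debris))
  out
}

#' Grade wells for compound toxicity
#'
#' Applies the [toxicity_cutoffs()] to each well's viable count and pyknotic
#' fraction, relative to the median viable count of the designated control
#' wells.
#'
#' @param qc per-well tibble from [well_qc_report()], optionally carrying a
#'   `condition` column.
#' @param controls character vector of control well ids; if omitted, wells
#'   whose `condition` equals `control_condition` are used.
#' @param control_condition condition label marking control wells (default
#'   the DMSO vehicle condition).
#' @param cutoffs a [toxicity_cutoffs()].
#' @return `qc` with an added ordered factor `grade`
#'   (`none < moderate < severe`).
#' @export
grade_well_toxicity <- function(qc, controls = NULL, control_condition = "dmso",
                                cutoffs = toxicity_cutoffs()) {
  qc <- as_tibble(qc)
  if (is.null(controls)) {
    if (!"condition" %in% names(qc))
      stop_bad("supply `controls` or a `condition` column")
    controls <- qc$well[qc$condition %in% control_condition]
  }
  ctrl <- qc[qc$well %in% controls, ]
  if (nrow(ctrl) == 0L) stop_bad("no control wells present; grading is undefined")
  med <- median(ctrl$viable_count)
  grade <- dplyr::case_when(
    qc$viable_count < cutoffs$severe_count_frac * med |
      qc$pyknotic_fraction > cutoffs$severe_pyk ~ "severe",
    qc$viable_count < cutoffs$moderate_count_frac * med |
      qc$pyknotic_fraction > cutoffs$moderate_pyk ~ "moderate",
    TRUE ~ "none")
  mutate(qc, grade = factor(grade, levels = c("none", "moderate", "severe"),
                            ordered = TRUE))
}
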