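#' Simulate one well's nuclei at the statistical layer
#'
#' Draws a cell population and shapes it like the measured-candidate table
#' that segmentation would produce (`mean_<marker>` columns holding the true
#' mean intensities), bypassing image rendering. Useful for fast power
#' exploration and for benchmarking the scoring and triage logic at scale;
#' the image-rendering path exercises the identical downstream code.
#'
#' @param model a [population_model()].
#' @param effect a [compound_effect()].
#' @param n_cells expected number of candidate nuclei (Poisson-distributed).
#' @param well well id attached to the rows.
#' @return a tibble shaped like [filter_viable()] input with true-subtype
#'   ground-truth columns retained.
#' @export
simulate_well_nuclei <- function(model, effect = compound_effect(), n_cells = 1000,
                                 well = "W01") {
  n <- rpois(1, n_cells)
  cells <- sample_population(model, effect, n)
  cells %>%
    mutate(well = well, .before = 1) %>%
    rename(mean_hoechst = "hoechst", mean_ctip2 = "ctip2",
           mean_satb2 = "satb2", mean_ctip1 = "ctip1",
           true_subtype = "subtype", true_viable = "viable")
}

#' Simulate a whole screen plate at the statistical layer
#'
#' Applies [simulate_well_nuclei()] to every well of a plate map, seeding
#' each well deterministically from `seed`.
#'
#' @param plate_map well table with `well`, `condition`, `compound`,
#'   `dose_uM`.
#' @param models named list of [population_model()] keyed by condition.
#' @param effects named list keyed by compound (see [generate_plate()]).
#' @param cells_per_well expected candidate nuclei per well.
#' @param seed integer seed for the whole plate.
#' @return per-nucleus tibble for all wells, joined with the plate map.
#' @export
simulate_screen_nuclei <- function(plate_map, models, effects = list(),
                                   cells_per_well = 1250, seed = 1) {
  rows <- vector("list", nrow(plate_map))
  for (i in seq_len(nrow(plate_map))) {
    set.seed(child_seed(seed, i))
    model <- resolve_model(models, plate_map$condition[i])
    eff <- resolve_effect(effects, plate_map$compound[i], plate_map$dose_uM[i])
    rows[[i]] <- simulate_well_nuclei(model, eff, cells_per_well,
                                      well = plate_map$well[i])
  }
  bind_rows(rows) %>%
    left_join(plate_map, by = "well")
}

#' Score a plate of measured nuclei
#'
#' The shared analysis backbone: viability filtering, per-well QC and
#' toxicity grading, marker classification of viable nuclei, per-well
#' summaries and the three screen normalizations.
#'
#' @param nuclei per-nucleus tibble (`well`, `area_um2`, `width_um`,
#'   `mean_*` columns) from segmentation or
#'   [simulate_screen_nuclei()].
#' @param plate_map the plate's well table.
#' @param criteria a [viability_criteria()].
#' @param policy a [threshold_policy()].
#' @param cutoffs a [toxicity_cutoffs()].
#' @param control_condition condition used as the toxicity-grading control.
#' @param pair marker pair for the subtype summary.
#' @param debris_counts optional named per-well debris counts.
#' @return a list: `nuclei` (flagged and classified), `qc` (graded per-well
#'   QC), `wells` (normalised per-well summaries).
#' @export
score_plate <- function(nuclei, plate_map, criteria = viability_criteria(),
                        policy = threshold_policy(),
                        cutoffs = toxicity_cutoffs(),
                        control_condition = "dmso",
                        pair = c("ctip2", "satb2"), debris_counts = NULL) {
  flagged <- filter_viable(nuclei, criteria)
  qc <- well_qc_report(flagged, criteria, debris_counts = debris_counts) %>%
    left_join(select(plate_map, dplyr::all_of(c("well", "condition"))), by = "well") %>%
    grade_well_toxicity(control_condition = control_condition, cutoffs = cutoffs)
  viable <- flagged %>% filter(.data$viable) %>% classify_nuclei(policy)
  map_cols <- intersect(c("condition", "compound", "dose_uM", "replicate"),
                        names(plate_map))
  viable <- viable %>%
    select(-dplyr::any_of(map_cols)) %>%
    left_join(select(plate_map, dplyr::all_of(c("well", map_cols))), by = "well")
  wells <- summarize_wells(viable, pair = pair)
  if (all(c("ctip2", "satb2") %in% pair)) wells <- add_screen_normalizations(wells)
  list(nuclei = viable, qc = qc, wells = wells)
}

#' Simulate, score and triage a benchmark screen plate
#'
#' Builds a single-dose benchmark plate with planted compound effects
#' (`n_enhancers` refinement enhancers, `n_toxic` severely toxic compounds,
#' the rest inert), simulates it at the statistical layer, scores it and runs
#' the triage. Used to characterise the screen's operating characteristics.
#'
#' @param seed integer seed.
#' @param n_compounds library size.
#' @param n_enhancers compounds with `refinement_shift = delta`.
#' @param n_toxic compounds with severe toxicity.
#' @param delta refinement shift of the planted enhancers.
#' @param cells_per_well expected candidate nuclei per well.
#' @param replicates replicate wells per compound.
#' @param model population model shared by all conditions (default
#'   primary-neuron-like).
#' @param criteria a [triage_criteria()].
#' @return a list: `records` (triage result), `report`, `planted` (named
#'   list of planted enhancer/toxic compound ids), `scored` (the
#'   [score_plate()] output).
#' @export
triage_benchmark <- function(seed = 1, n_compounds = 30, n_enhancers = 3,
                             n_toxic = 5, delta = 0.5, cells_per_well = 1250,
                             replicates = 2, model = primary_population_model(),
                             criteria = triage_criteria()) {
  map <- screen_plate_map(n_compounds = n_compounds, doses = 1,
                          replicates = replicates, controls_each = 6)
  ids <- sprintf("C%02d", seq_len(n_compounds))
  enh <- ids[seq_len(n_enhancers)]
  tox <- ids[n_enhancers + seq_len(n_toxic)]
  effects <- setNames(vector("list", n_compounds), ids)
  for (id in ids) {
    effects[[id]] <- if (id %in% enh) compound_effect(refinement_shift = delta)
    else if (id %in% tox) compound_effect(toxicity = "severe")
    else compound_effect()
  }
  models <- setNames(rep(list(model), length(CONDITIONS)), CONDITIONS)
  nuclei <- simulate_screen_nuclei(map, models, effects,
                                   cells_per_well = cells_per_well, seed = seed)
  scored <- score_plate(nuclei, map)
  records <- run_triage(scored$wells, scored$qc, criteria)
  list(records = records, report = triage_report(records),
       planted = list(enhancers = enh, toxic = tox), scored = scored)
}
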