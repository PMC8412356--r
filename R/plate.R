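CONDITIONS <- c("untreated", "dmso", "gfp_modrna", "fezf2_modrna", "compound_fezf2")

#' Plate design
#'
#' @param wells tibble with columns `well`, `condition`, `compound`
#'   (`NA` for control wells), `dose_uM`, `replicate`.
#' @param fields_per_well number of imaging fields per well (default 20,
#'   the number of randomly sampled fields per well in the screen design).
#' @param image_spec an [image_spec()].
#' @param seed top-level integer seed; every random draw of the plate flows
#'   from it.
#' @return a `plate_design` object.
#' @export
plate_design <- function(wells, fields_per_well = 20, image_spec = scpnscreen::image_spec(),
                         seed = 1) {
  wells <- as_tibble(wells)
  req <- c("well", "condition", "compound", "dose_uM", "replicate")
  miss <- setdiff(req, names(wells))
  if (length(miss)) stop_bad("wells is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(wells$well)) stop_bad("well ids must be unique")
  bad <- setdiff(unique(wells$condition), CONDITIONS)
  if (length(bad)) stop_bad("unknown condition label(s): %s", paste(bad, collapse = ", "))
  if (fields_per_well < 1) stop_bad("fields_per_well must be >= 1")
  structure(list(wells = wells, fields_per_well = as.integer(fields_per_well),
                 image_spec = image_spec, seed = as.integer(seed)),
            class = "plate_design")
}

well_ids_96 <- function(n) {
  ids <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  if (n > length(ids)) stop_bad("design needs %d wells; a 96-well plate holds 96", n)
  ids[seq_len(n)]
}

#' Build a screening plate map
#'
#' Lays out control wells (untreated, DMSO vehicle, GFP modRNA and Fezf2
#' modRNA) followed by compound wells (compound + Fezf2 modRNA), each compound
#' present at every dose in the designed number of replicate wells. The
#' library screen used duplicate wells at 10, 1 and 0.1 micromolar;
#' single-dose designs (1 uM, as analyzed) are obtained with `doses = 1`.
#'
#' @param n_compounds number of library compounds.
#' @param doses dose levels in micromolar.
#' @param replicates replicate wells per compound and dose.
#' @param controls_each control wells per control condition.
#' @param compound_ids optional compound names (default `C01`, `C02`, ...).
#' @return a tibble usable as the `wells` argument of [plate_design()].
#' @export
screen_plate_map <- function(n_compounds = 10, doses = c(10, 1, 0.1),
                             replicates = 2, controls_each = 3,
                             compound_ids = NULL) {
  compound_ids <- compound_ids %||% sprintf("C%02d", seq_len(n_compounds))
  stopifnot(length(compound_ids) == n_compounds)
  ctrl <- tidyr::expand_grid(condition = CONDITIONS[1:4],
                             replicate = seq_len(controls_each)) %>%
    mutate(compound = NA_character_, dose_uM = NA_real_)
  cmpd <- tidyr::expand_grid(compound = compound_ids, dose_uM = doses,
                             replicate = seq_len(replicates)) %>%
    mutate(condition = "compound_fezf2")
  map <- bind_rows(ctrl, cmpd)
  map$well <- well_ids_96(nrow(map))
  dplyr::select(map, dplyr::all_of(c("well", "condition", "compound", "dose_uM", "replicate")))
}

resolve_effect <- function(effects, compound, dose) {
  if (is.na(compound) || compound == "") return(compound_effect())
  eff <- effects[[compound]]
  if (is.null(eff)) stop_bad("no compound effect defined for `%s`", compound)
  if (is.function(eff)) eff <- eff(dose)
  if (!inherits(eff, "compound_effect"))
    stop_bad("effect for `%s` must be a compound_effect or function(dose)", compound)
  eff
}

resolve_model <- function(models, condition) {
  mdl <- models[[condition]]
  if (is.null(mdl)) stop_bad("no population model defined for condition `%s`", condition)
  if (!inherits(mdl, "population_model"))
    stop_bad("model for `%s` must be a population_model", condition)
  mdl
}

#' Default per-condition population models for a screen plate
#'
#' All conditions share the same base population; `kind = "mes"` uses the
#' continuum (mES-derived-like) population for every condition and
#' `kind = "primary"` the trimodal primary-neuron-like population.
#' @param kind `"mes"` or `"primary"`.
#' @return named list of [population_model()]s keyed by condition.
#' @export
screen_models <- function(kind = c("mes", "primary")) {
  kind <- match.arg(kind)
  base <- if (kind == "mes") mes_population_model() else primary_population_model()
  setNames(rep(list(base), length(CONDITIONS)), CONDITIONS)
}

#' Generate a synthetic screening plate
#'
#' Draws every well of a [plate_design()]: per field, a Poisson number of
#' candidate nuclei from the condition's [population_model()] under the
#' well compound's [compound_effect()], placed with hard-core spacing plus
#' clumped pairs, and (optionally) rendered to multichannel images. The whole
#' plate is reproducible from `design$seed`.
#'
#' @param design a [plate_design()].
#' @param models named list of [population_model()] keyed by condition.
#' @param effects named list keyed by compound id; each entry is a
#'   [compound_effect()] or a `function(dose_uM)` returning one.
#' @param dir optional output directory; when given, TIFF channels,
#'   `ground_truth.csv` and `plate_map.csv` are written there.
#' @param render if `FALSE`, skip image rendering (ground truth only); the
#'   placement and population draws are identical either way.
#' @param clump_fraction,min_spacing_um placement parameters, see
#'   [place_cells()].
#' @return a list with `truth` (ground-truth tibble, one row per nucleus),
#'   `plate_map` (the design's well table), and `images` (named list
#'   `"<well>_f<field>"` of [field_image()]s, when rendered in memory).
#' @export
generate_plate <- function(design, models, effects = list(), dir = NULL,
                           render = TRUE, clump_fraction = 0.10,
                           min_spacing_um = 9) {
  stopifnot(inherits(design, "plate_design"))
  wells <- design$wells
  spec <- design$image_spec
  # fail early if any referenced condition/compound lacks a model/effect
  for (cond in unique(wells$condition)) resolve_model(models, cond)
  for (i in seq_len(nrow(wells)))
    resolve_effect(effects, wells$compound[i], wells$dose_uM[i])

  truth <- vector("list", nrow(wells))
  images <- list()
  for (i in seq_len(nrow(wells))) {
    w <- wells$well[i]
    model <- resolve_model(models, wells$condition[i])
    eff <- resolve_effect(effects, wells$compound[i], wells$dose_uM[i])
    set.seed(child_seed(design$seed, i))
    per_field <- vector("list", design$fields_per_well)
    for (f in seq_len(design$fields_per_well)) {
      n <- rpois(1, model$density)
      cells <- sample_population(model, eff, n)
      cells <- place_cells(cells, spec, min_spacing_um = min_spacing_um,
                           clump_fraction = clump_fraction)
      if (render) {
        img <- render_field(cells, spec)
        if (!is.null(dir)) write_field_images(img, dir, w, f)
        else images[[sprintf("%s_f%d", w, f)]] <- img
      }
      if (nrow(cells))
        per_field[[f]] <- mutate(cells, well = w, field = f, .before = 1)
    }
    truth[[i]] <- bind_rows(per_field)
  }
  truth <- bind_rows(truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(truth, file.path(dir, "ground_truth.csv"), progress = FALSE)
    readr::write_csv(wells, file.path(dir, "plate_map.csv"), progress = FALSE)
  }
  list(truth = truth, plate_map = wells,
       images = if (render && is.null(dir)) images else NULL)
}
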