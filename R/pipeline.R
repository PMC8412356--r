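#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis in one validated object.
#' All defaults equal the published values where one exists (detection
#' parameters, viability criteria, intensity bands); the rest are this
#' package's documented choices. Serialisable to/from YAML with
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param image_dir directory holding `<well>_f<field>_<channel>.tif` files.
#' @param plate_map path to the plate-map CSV (columns `well`, `condition`,
#'   `compound`, `dose_uM`, `replicate`).
#' @param output_dir where stage outputs are written.
#' @param fields_per_well fields imaged per well.
#' @param pixel_scale micrometres per pixel of the input images.
#' @param channels named character vector mapping channel file names to
#'   markers (`hoechst` must map to `hoechst`).
#' @param segmentation a [segmentation_params()].
#' @param qc a [viability_criteria()].
#' @param toxicity a [toxicity_cutoffs()].
#' @param classification a [threshold_policy()].
#' @param triage a [triage_criteria()].
#' @param control_condition toxicity-grading control condition.
#' @param seed integer seed recorded in the manifest (the analysis itself is
#'   deterministic; only plate simulation consumes randomness).
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(image_dir, plate_map, output_dir,
                            fields_per_well = 1, pixel_scale = 0.65,
                            channels = CHANNEL_MARKERS,
                            segmentation = segmentation_params(),
                            qc = viability_criteria(),
                            toxicity = toxicity_cutoffs(),
                            classification = threshold_policy(),
                            triage = triage_criteria(),
                            control_condition = "dmso", seed = 1L) {
  if (!"hoechst" %in% names(channels) || channels[["hoechst"]] != "hoechst")
    stop_bad("channels must map a `hoechst` channel to the `hoechst` marker")
  structure(list(image_dir = image_dir, plate_map = plate_map,
                 output_dir = output_dir,
                 fields_per_well = as.integer(fields_per_well),
                 pixel_scale = pixel_scale, channels = channels,
                 segmentation = segmentation, qc = qc, toxicity = toxicity,
                 classification = classification, triage = triage,
                 control_condition = control_condition, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_to_list <- function(config) {
  list(paths = list(image_dir = config$image_dir, plate_map = config$plate_map,
                    output_dir = config$output_dir),
       fields_per_well = config$fields_per_well,
       pixel_scale = config$pixel_scale,
       channels = as.list(config$channels),
       segmentation = unclass(config$segmentation),
       qc = unclass(config$qc),
       toxicity = unclass(config$toxicity),
       classification = list(mode = config$classification$mode,
                             fraction = config$classification$fraction,
                             bands = lapply(unclass(config$classification$bands),
                                            function(b) list(low = b$low, high = b$high))),
       triage = unclass(config$triage),
       control_condition = config$control_condition,
       seed = config$seed)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  bands <- do.call(intensity_bands, lapply(x$classification$bands, function(b)
    list(low = as.numeric(b$low), high = as.numeric(b$high))))
  pipeline_config(
    image_dir = x$paths$image_dir, plate_map = x$paths$plate_map,
    output_dir = x$paths$output_dir, fields_per_well = x$fields_per_well,
    pixel_scale = x$pixel_scale, channels = unlist(x$channels),
    segmentation = do.call(segmentation_params, x$segmentation),
    qc = do.call(viability_criteria, x$qc),
    toxicity = do.call(toxicity_cutoffs, x$toxicity),
    classification = threshold_policy(mode = x$classification$mode,
                                      fraction = x$classification$fraction,
                                      bands = bands),
    triage = do.call(triage_criteria, x$triage),
    control_condition = x$control_condition, seed = x$seed)
}

#' Load and validate a plate map
#'
#' @param path CSV file (or data frame) with columns `well`, `condition`,
#'   `compound`, `dose_uM`, `replicate`.
#' @return a validated tibble.
#' @export
load_plate_map <- function(path) {
  map <- if (is.data.frame(path)) as_tibble(path)
  else readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("well", "condition", "compound", "dose_uM", "replicate")
  miss <- setdiff(req, names(map))
  if (length(miss)) stop_bad("plate map is missing column(s): %s",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(map$well))
    stop_bad("duplicate well id(s): %s",
             paste(unique(map$well[duplicated(map$well)]), collapse = ", "))
  bad <- setdiff(unique(map$condition), CONDITIONS)
  if (length(bad)) stop_bad("unknown condition label(s): %s (known: %s)",
                            paste(bad, collapse = ", "),
                            paste(CONDITIONS, collapse = ", "))
  map$compound <- as.character(map$compound)
  map
}

md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Images to tables: segmentation of every field, per-nucleus measurement,
#' viability filtering, per-well QC and toxicity grading, marker
#' classification, well summaries with the three screen normalizations, and
#' candidate triage. Writes `nuclei.csv`, `wells.csv`, `qc.csv`,
#' `stats.csv` (condition comparisons of the refinement ratio),
#' `triage.csv`, `triage.json` and `manifest.json` into the output
#' directory. Deterministic for fixed config and inputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage outputs plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  map <- load_plate_map(config$plate_map)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character(0)
  timings <- list()

  # stage 1: segmentation + measurement
  t0 <- Sys.time()
  marker_of <- config$channels
  per_well <- vector("list", nrow(map))
  debris <- setNames(integer(nrow(map)), map$well)
  for (i in seq_len(nrow(map))) {
    w <- map$well[i]
    rows <- vector("list", config$fields_per_well)
    for (f in seq_len(config$fields_per_well)) {
      img <- read_field_images(config$image_dir, w, f,
                               channels = names(marker_of),
                               pixel_scale = config$pixel_scale)
      nuc <- find_nuclei(img, config$segmentation)
      debris[w] <- debris[w] + attr(nuc, "n_debris")
      attr(nuc, "labels") <- NULL
      # rename channel means to marker means
      for (ch in names(marker_of)) {
        mk <- marker_of[[ch]]
        if (mk != ch)
          names(nuc)[names(nuc) == paste0("mean_", ch)] <- paste0("mean_", mk)
      }
      rows[[f]] <- mutate(nuc, well = w, field = f, .before = 1)
    }
    per_well[[i]] <- bind_rows(rows)
  }
  nuclei <- bind_rows(per_well)
  timings$segmentation <- as.numeric(Sys.time() - t0, units = "secs")

  # stage 2: QC, classification, scoring
  t0 <- Sys.time()
  scored <- score_plate(nuclei, map, criteria = config$qc,
                        policy = config$classification,
                        cutoffs = config$toxicity,
                        control_condition = config$control_condition,
                        debris_counts = debris)
  n_undef <- sum(!scored$wells$ratio_defined)
  if (n_undef > 0)
    warnings <- c(warnings, sprintf("%d well(s) with undefined refinement ratio", n_undef))
  timings$scoring <- as.numeric(Sys.time() - t0, units = "secs")

  # stage 3: condition statistics (refinement ratio, conditions vs untreated)
  t0 <- Sys.time()
  stats_tbl <- condition_stats(scored$wells)
  timings$stats <- as.numeric(Sys.time() - t0, units = "secs")

  # stage 4: triage
  t0 <- Sys.time()
  records <- run_triage(scored$wells, scored$qc, config$triage)
  report <- triage_report(records)
  timings$triage <- as.numeric(Sys.time() - t0, units = "secs")

  out <- config$output_dir
  readr::write_csv(scored$nuclei, file.path(out, "nuclei.csv"), progress = FALSE)
  readr::write_csv(scored$wells, file.path(out, "wells.csv"), progress = FALSE)
  readr::write_csv(scored$qc, file.path(out, "qc.csv"), progress = FALSE)
  readr::write_csv(stats_tbl, file.path(out, "stats.csv"), progress = FALSE)
  readr::write_csv(as_tibble(records), file.path(out, "triage.csv"), progress = FALSE)
  write_triage_report(report, file.path(out, "triage.json"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("scpnscreen")),
    config_hash = md5_of_object(config_to_list(config)),
    seed = config$seed,
    stage_rows = list(wells = nrow(map), nuclei = nrow(scored$nuclei),
                      viable = sum(scored$qc$viable_count),
                      well_summaries = nrow(scored$wells),
                      triage_records = nrow(records)),
    timings_sec = lapply(timings, function(t) round(t, 3)),
    total_sec = round(as.numeric(Sys.time() - t_start, units = "secs"), 3),
    warnings = as.list(warnings))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(nuclei = scored$nuclei, qc = scored$qc, wells = scored$wells,
                 stats = stats_tbl, triage = records, report = report,
                 manifest = manifest))
}

#' Per-condition replicate statistics of the refinement ratio
#'
#' Mean, SEM and an unpaired Student t-test of each condition's per-well
#' normalised ratios against a reference condition.
#'
#' @param wells normalised well summaries.
#' @param value column to compare (default `norm_ratio`).
#' @param reference reference condition (default untreated).
#' @return a tibble, one row per non-reference condition with >= 2 wells.
#' @export
condition_stats <- function(wells, value = "norm_ratio", reference = "untreated") {
  v <- wells[[value]]
  ref <- v[wells$condition == reference & is.finite(v)]
  conds <- setdiff(unique(wells$condition), reference)
  rows <- list()
  for (cond in conds) {
    g <- v[wells$condition == cond & is.finite(v)]
    if (length(g) < 2 || length(ref) < 2) next
    ct <- compare_conditions(g, ref, labels = c(cond, reference))
    rows[[cond]] <- mutate(tidy(ct), condition = cond, metric = value, .before = 1)
  }
  bind_rows(rows)
}

#' Generate the summary figures
#'
#' Writes the composition pie charts and the ranked normalised-ratio bar
#' chart from the pipeline's tables; plotted values equal the table values
#' exactly.
#'
#' @param outputs list returned by [run_pipeline()] (or a compatible list
#'   with `wells` and `triage`).
#' @param dir output directory for `composition.pdf` and `ranked_ratio.pdf`.
#' @return invisibly, the file paths.
#' @export
make_figures <- function(outputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- plot_composition(composition_by_condition(outputs$wells))
  p2 <- plot_ranked_ratios(outputs$triage)
  f1 <- file.path(dir, "composition.pdf")
  f2 <- file.path(dir, "ranked_ratio.pdf")
  ggplot2::ggsave(f1, p1, width = 7, height = 5)
  ggplot2::ggsave(f2, p2, width = 8, height = 4.5)
  invisible(c(f1, f2))
}
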