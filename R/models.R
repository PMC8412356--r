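#' Marker intensity component parameters
#'
#' Location/spread pairs (intensity units on the 12-bit scale) for the
#' negative, low and high expression components of one transcription-factor
#' marker, plus the probability that a marker-positive nucleus belongs to the
#' high component. In `trimodal` populations (primary cortical neurons)
#' intensities are drawn from the matching component; in `continuum`
#' populations (mES-derived neurons) positive nuclei draw from a single broad
#' right-skewed distribution instead.
#'
#' @param negative,low,high numeric length-2 vectors `c(location, spread)`.
#' @param p_high probability that a positive nucleus is a high expressor.
#' @return a `marker_component` list.
#' @export
marker_component <- function(negative, low, high, p_high = 0.6) {
  comp <- list(negative = as.numeric(negative), low = as.numeric(low),
               high = as.numeric(high), p_high = p_high)
  for (nm in c("negative", "low", "high")) {
    v <- comp[[nm]]
    if (length(v) != 2L || any(!is.finite(v)) || any(v < 0))
      stop_bad("marker component `%s` needs non-negative c(location, spread)", nm)
  }
  if (!(comp$negative[1] < comp$low[1] && comp$low[1] < comp$high[1]))
    stop_bad("component locations must be strictly ordered negative < low < high")
  check_fraction(p_high, "p_high")
  structure(comp, class = "marker_component")
}

default_marker_components <- function() {
  list(
    ctip2 = marker_component(c(15, 8),  c(120, 12), c(360, 45),  p_high = 0.7),
    satb2 = marker_component(c(20, 10), c(300, 50), c(800, 120), p_high = 0.6),
    ctip1 = marker_component(c(12, 6),  c(70, 8),   c(180, 40),  p_high = 0.6)
  )
}

#' Generative model of a well's cell population
#'
#' Describes the mixture of nucleus subtypes, marker intensity components,
#' nucleus morphology and field density that the synthetic plate generator
#' draws from. `subtype_fractions` are the fractions, among viable nuclei, of
#' CTIP2-only, SATB2-only, CTIP2/SATB2 dual-positive and unlabeled cells.
#'
#' @param mode `"trimodal"` (primary-neuron-like, distinct negative/low/high
#'   intensity components) or `"continuum"` (mES-like, near-continuum of
#'   intensities for positive nuclei).
#' @param fraction_viable fraction of candidate nuclei that meet the viability
#'   criteria (default 0.6, the baseline fraction of viable nuclei per field).
#' @param subtype_fractions named or positional numeric vector
#'   `(ctip2_only, satb2_only, dual, unlabeled)` summing to 1.
#' @param marker_components named list of [marker_component()] for
#'   `ctip2`, `satb2`, `ctip1`.
#' @param area_mean,area_sd viable nucleus area distribution, um^2.
#' @param ecc_range eccentricity range of the elliptical nucleus outline.
#' @param density expected candidate nuclei per imaging field.
#' @param p_ctip1 named probabilities that a nucleus of each subtype is
#'   CTIP1-positive (CTIP1 marks callosal-type identity and tracks SATB2).
#' @return a `population_model` list.
#' @seealso [primary_population_model()], [mes_population_model()]
#' @export
population_model <- function(mode = c("trimodal", "continuum"),
                             fraction_viable = 0.6,
                             subtype_fractions = c(ctip2_only = 0.05,
                                                   satb2_only = 0.15,
                                                   dual = 0.20,
                                                   unlabeled = 0.60),
                             marker_components = default_marker_components(),
                             area_mean = 55, area_sd = 10,
                             ecc_range = c(0, 0.6),
                             density = 150,
                             p_ctip1 = c(ctip2_only = 0.1, satb2_only = 0.6,
                                         dual = 0.7, unlabeled = 0.1)) {
  mode <- match.arg(mode)
  check_fraction(fraction_viable, "fraction_viable")
  sf <- as.numeric(subtype_fractions)
  if (length(sf) != 4L || any(sf < 0) || any(sf > 1))
    stop_bad("subtype_fractions must be four fractions in [0, 1]")
  if (abs(sum(sf) - 1) > 1e-9)
    stop_bad("subtype_fractions must sum to 1 (got %.12f)", sum(sf))
  names(sf) <- c("ctip2_only", "satb2_only", "dual", "unlabeled")
  if (!all(c("ctip2", "satb2", "ctip1") %in% names(marker_components)))
    stop_bad("marker_components must name ctip2, satb2 and ctip1")
  check_positive(area_mean, "area_mean"); check_positive(area_sd, "area_sd")
  check_positive(density, "density")
  if (length(ecc_range) != 2L || any(ecc_range < 0) || any(ecc_range >= 1) ||
      ecc_range[1] > ecc_range[2])
    stop_bad("ecc_range must be an increasing pair in [0, 1)")
  structure(list(mode = mode, fraction_viable = fraction_viable,
                 subtype_fractions = sf, marker_components = marker_components,
                 area_mean = area_mean, area_sd = area_sd,
                 ecc_range = ecc_range, density = density,
                 p_ctip1 = as.numeric(p_ctip1[c("ctip2_only", "satb2_only",
                                                "dual", "unlabeled")]) |>
                   setNames(c("ctip2_only", "satb2_only", "dual", "unlabeled"))),
            class = "population_model")
}

#' Primary-neuron-like population (trimodal labeling)
#'
#' Defaults reproduce the baseline composition of dissociated E12.5 cortical
#' cultures: ~25% CTIP2-positive and ~35% SATB2-positive nuclei, with the
#' majority of each immunostained population co-expressing both markers, and
#' distinct negative/low/high intensity components per marker.
#' @param ... overrides passed to [population_model()].
#' @return a `population_model`.
#' @export
primary_population_model <- function(...) {
  population_model(mode = "trimodal", ...)
}

#' mES-derived-like population (intensity continuum)
#'
#' Defaults reproduce the baseline composition of mES-derived neocortical-like
#' cultures: ~10% CTIP2-positive and ~20% SATB2-positive nuclei, with positive
#' nuclei drawing from a near-continuum of labeling intensities.
#' @param ... overrides passed to [population_model()].
#' @return a `population_model`.
#' @export
mes_population_model <- function(...) {
  args <- list(...)
  defaults <- list(mode = "continuum",
                   subtype_fractions = c(ctip2_only = 0.03, satb2_only = 0.13,
                                         dual = 0.07, unlabeled = 0.77))
  do.call(population_model, modifyList(defaults, args))
}

#' Treatment effect of one compound
#'
#' `refinement_shift` (delta) is the fraction of CTIP2/SATB2 dual-positive
#' cells converted to CTIP2-only cells (subtype refinement); conversion
#' conserves the total CTIP2-positive fraction. Toxicity removes a
#' `kill_fraction` share of cells and renders a `pyknotic_fraction` share of
#' survivors small and Hoechst-bright.
#'
#' @param refinement_shift fraction of dual-positive cells converted, in
#'   `[0, 1]`.
#' @param toxicity `"none"`, `"moderate"` or `"severe"`. With `"none"`,
#'   `kill_fraction` and `pyknotic_fraction` must be 0.
#' @param kill_fraction,pyknotic_fraction fractions in `[0, 1]`. Defaults for
#'   moderate toxicity are 0.45/0.20 and for severe 0.70/0.35.
#' @return a `compound_effect` list.
#' @export
compound_effect <- function(refinement_shift = 0,
                            toxicity = c("none", "moderate", "severe"),
                            kill_fraction = NULL, pyknotic_fraction = NULL) {
  toxicity <- match.arg(toxicity)
  defaults <- switch(toxicity,
                     none = c(0, 0), moderate = c(0.45, 0.20), severe = c(0.70, 0.35))
  kill_fraction <- kill_fraction %||% defaults[1]
  pyknotic_fraction <- pyknotic_fraction %||% defaults[2]
  check_fraction(refinement_shift, "refinement_shift")
  check_fraction(kill_fraction, "kill_fraction")
  check_fraction(pyknotic_fraction, "pyknotic_fraction")
  if (toxicity == "none" && (kill_fraction != 0 || pyknotic_fraction != 0))
    stop_bad("toxicity = \"none\" requires kill_fraction = pyknotic_fraction = 0")
  structure(list(refinement_shift = refinement_shift, toxicity = toxicity,
                 kill_fraction = kill_fraction,
                 pyknotic_fraction = pyknotic_fraction),
            class = "compound_effect")
}

#' Shift subtype fractions by a refinement effect
#'
#' Applies the conversion of dual-positive cells to CTIP2-only cells:
#' `f'_ctip2_only = f_ctip2_only + delta * f_dual`,
#' `f'_dual = (1 - delta) * f_dual`. SATB2-only and unlabeled fractions are
#' untouched, so `f'_ctip2_only + f'_dual = f_ctip2_only + f_dual` exactly.
#'
#' @param fractions numeric vector `(ctip2_only, satb2_only, dual, unlabeled)`.
#' @param delta conversion fraction in `[0, 1]`.
#' @return adjusted named fractions, still summing to 1.
#' @export
adjust_subtype_fractions <- function(fractions, delta) {
  check_fraction(delta, "delta")
  f <- as.numeric(fractions)
  if (length(f) != 4L || any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop_bad("fractions must be four non-negative values summing to 1")
  out <- c(ctip2_only = f[1] + delta * f[3], satb2_only = f[2],
           dual = (1 - delta) * f[3], unlabeled = f[4])
  out
}

#' Field image acquisition parameters
#'
#' Geometry and camera model for simulated fields: a 12-bit dynamic range
#' (0-4095) stored in 16-bit TIFF containers, so that the printed intensity
#' criteria (e.g. Hoechst < 900, SATB2-high 500-1500) are on-scale, and a
#' 675 x 512 px field at 0.65 um/px, a typical 20x camera field.
#'
#' @param width_px,height_px field size in pixels.
#' @param pixel_scale micrometres per pixel.
#' @param bit_depth simulated camera bit depth (intensity ceiling
#'   `2^bit_depth - 1`).
#' @param background mean background level, intensity units.
#' @param noise_sd Gaussian read-noise spread, intensity units.
#' @return an `image_spec` list.
#' @export
image_spec <- function(width_px = 675, height_px = 512, pixel_scale = 0.65,
                       bit_depth = 12, background = 20, noise_sd = 5) {
  if (width_px < 8 || height_px < 8) stop_bad("image dimensions must be >= 8 px")
  check_positive(pixel_scale, "pixel_scale")
  check_positive(bit_depth, "bit_depth")
  check_positive(background, "background", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 pixel_scale = pixel_scale, bit_depth = as.integer(bit_depth),
                 background = background, noise_sd = noise_sd),
            class = "image_spec")
}

#' Refinement shift at a given dose
#'
#' Simple saturating (Hill, coefficient 1) dose-response used by the plate
#' generator to make the dual-to-CTIP2-only conversion dose dependent:
#' `delta(dose) = delta_max * dose / (dose + ec50)`.
#'
#' @param delta_max asymptotic conversion fraction.
#' @param dose_uM dose in micromolar.
#' @param ec50_uM half-maximal dose, micromolar.
#' @return a conversion fraction in `[0, delta_max]`.
#' @export
dose_response_shift <- function(delta_max, dose_uM, ec50_uM = 0.5) {
  check_fraction(delta_max, "delta_max")
  if (any(dose_uM < 0)) stop_bad("dose_uM must be non-negative")
  check_positive(ec50_uM, "ec50_uM")
  delta_max * dose_uM / (dose_uM + ec50_uM)
}
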