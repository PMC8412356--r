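# truncated-normal draw via inverse CDF: one uniform per value, so draw count
# (and hence RNG stream position) does not depend on rejection luck
rtnorm <- function(n, mean, sd, lo = 0, hi = Inf) {
  if (n == 0L) return(numeric(0))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  stats::qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# morphology and Hoechst intensity per viability class; candidate nuclei that
# fail the viability criteria are a mixture of small dim fragments, oversized
# doublets, pyknotic (small, condensed, Hoechst-bright) nuclei and
# normally-sized but abnormally bright nuclei
VIABILITY_CLASSES <- c("viable", "fragment", "doublet", "pyknotic", "bright")
NONVIABLE_MIX <- c(fragment = 0.45, doublet = 0.30, pyknotic = 0.125, bright = 0.125)

sample_morphology <- function(class, model) {
  n <- length(class)
  area <- numeric(n); hoechst <- numeric(n)
  idx <- split(seq_len(n), factor(class, levels = VIABILITY_CLASSES))
  am <- model$area_mean; as_ <- model$area_sd
  if (length(i <- idx$viable))   { area[i] <- rtnorm(length(i), am, as_, 36, 95)
                                   hoechst[i] <- rtnorm(length(i), 500, 80, 250, 850) }
  if (length(i <- idx$fragment)) { area[i] <- rtnorm(length(i), 20, 5, 8, 32)
                                   hoechst[i] <- rtnorm(length(i), 450, 100, 150, 850) }
  if (length(i <- idx$doublet))  { area[i] <- rtnorm(length(i), 120, 15, 102, 170)
                                   hoechst[i] <- rtnorm(length(i), 500, 80, 250, 850) }
  if (length(i <- idx$pyknotic)) { area[i] <- rtnorm(length(i), 22, 4, 10, 32)
                                   hoechst[i] <- rtnorm(length(i), 1300, 150, 950, 2500) }
  if (length(i <- idx$bright))   { area[i] <- rtnorm(length(i), am, as_, 36, 95)
                                   hoechst[i] <- rtnorm(length(i), 1100, 120, 950, 2000) }
  list(area = area, hoechst = hoechst)
}

# draw per-nucleus mean intensity for one marker given positivity
sample_marker_intensity <- function(positive, comp, mode) {
  n <- length(positive)
  value <- numeric(n); component <- character(n)
  neg <- which(!positive); pos <- which(positive)
  if (mode == "trimodal") {
    value[neg] <- rtnorm(length(neg), comp$negative[1], comp$negative[2], 0)
    component[neg] <- "negative"
    if (length(pos)) {
      is_high <- runif(length(pos)) < comp$p_high
      value[pos[is_high]] <- rtnorm(sum(is_high), comp$high[1], comp$high[2], 0)
      value[pos[!is_high]] <- rtnorm(sum(!is_high), comp$low[1], comp$low[2], 0)
      component[pos] <- ifelse(is_high, "high", "low")
    }
  } else {
    # continuum: negatives from a gamma around the negative location, positives
    # from one broad right-skewed log-normal spanning the low and high bands
    value[neg] <- stats::rgamma(length(neg), shape = 2, scale = comp$negative[1] / 2)
    component[neg] <- "negative"
    if (length(pos)) {
      mlog <- log(sqrt(comp$low[1] * comp$high[1]))
      value[pos] <- stats::rlnorm(length(pos), meanlog = mlog, sdlog = 0.6)
      component[pos] <- ifelse(value[pos] >= comp$high[1], "high", "low")
    }
  }
  list(value = value, component = component)
}

#' Sample a population of true cell records
#'
#' Draws `n` candidate nuclei from a [population_model()] under a
#' [compound_effect()]. The effect first shifts the subtype mixture
#' (dual-positive cells convert to CTIP2-only at rate `refinement_shift`, see
#' [adjust_subtype_fractions()]), then removes a `kill_fraction` share of
#' cells, then converts a `pyknotic_fraction` share of survivors to pyknotic
#' morphology (area below the viable minimum, elevated Hoechst).
#'
#' @param model a [population_model()].
#' @param effect a [compound_effect()]; default is no effect.
#' @param n number of candidate nuclei to draw before any killing.
#' @param seed optional integer; when given, the draw is reproducible.
#' @return a tibble with one row per surviving nucleus: `cell_id`, `subtype`,
#'   `viability_class`, `viable`, `area_um2`, `width_um`, `eccentricity`,
#'   true mean intensities `hoechst`, `ctip2`, `satb2`, `ctip1` and true
#'   components `comp_ctip2`, `comp_satb2`, `comp_ctip1`.
#' @examples
#' cells <- sample_population(primary_population_model(), n = 500, seed = 1)
#' mean(cells$subtype %in% c("ctip2_only", "dual"))  # ~0.25 CTIP2-positive
#' @export
sample_population <- function(model, effect = compound_effect(), n, seed = NULL) {
  stopifnot(inherits(model, "population_model"), inherits(effect, "compound_effect"))
  if (!is.numeric(n) || length(n) != 1L || n < 0) stop_bad("`n` must be a count >= 0")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  empty <- tibble(cell_id = integer(), subtype = character(),
                  viability_class = character(), viable = logical(),
                  area_um2 = numeric(), width_um = numeric(), eccentricity = numeric(),
                  hoechst = numeric(), ctip2 = numeric(), satb2 = numeric(),
                  ctip1 = numeric(), comp_ctip2 = character(),
                  comp_satb2 = character(), comp_ctip1 = character())
  if (n == 0L) return(empty)

  # viability class, then subtype from the effect-adjusted mixture
  viable <- runif(n) < model$fraction_viable
  class <- character(n)
  class[viable] <- "viable"
  n_nv <- sum(!viable)
  class[!viable] <- sample(names(NONVIABLE_MIX), n_nv, replace = TRUE,
                           prob = NONVIABLE_MIX)
  fr <- adjust_subtype_fractions(model$subtype_fractions, effect$refinement_shift)
  subtype <- sample(names(fr), n, replace = TRUE, prob = fr)

  # toxicity: kill, then render a share of survivors pyknotic
  keep <- runif(n) >= effect$kill_fraction
  if (effect$pyknotic_fraction > 0) {
    make_pyk <- keep & runif(n) < effect$pyknotic_fraction
    class[make_pyk] <- "pyknotic"
  }

  morph <- sample_morphology(class, model)
  ecc <- runif(n, model$ecc_range[1], model$ecc_range[2])
  # width = full minor axis of an ellipse with the given area and eccentricity
  width <- 2 * sqrt(morph$area * sqrt(1 - ecc^2) / pi)

  ctip2_pos <- subtype %in% c("ctip2_only", "dual")
  satb2_pos <- subtype %in% c("satb2_only", "dual")
  p1 <- model$p_ctip1[subtype]
  ctip1_pos <- runif(n) < p1
  mc <- model$marker_components
  i2 <- sample_marker_intensity(ctip2_pos, mc$ctip2, model$mode)
  is2 <- sample_marker_intensity(satb2_pos, mc$satb2, model$mode)
  i1 <- sample_marker_intensity(ctip1_pos, mc$ctip1, model$mode)

  out <- tibble(cell_id = seq_len(n), subtype = subtype,
                viability_class = class, viable = class == "viable",
                area_um2 = morph$area, width_um = width, eccentricity = ecc,
                hoechst = morph$hoechst, ctip2 = i2$value, satb2 = is2$value,
                ctip1 = i1$value, comp_ctip2 = i2$component,
                comp_satb2 = is2$component, comp_ctip1 = i1$component)
  out[keep, , drop = FALSE]
}
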