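#' Published intensity bands per marker
#'
#' Contiguous low/high mean-intensity bands (intensity units) delineating
#' low and high expressors of each transcription factor. The low band's upper
#' edge equals the high band's lower edge; the shared boundary belongs to
#' high, and values above the high band are counted as high rather than
#' discarded (the brightest expressors are real).
#'
#' @param ctip2,satb2,ctip1 length-2 lists/vectors: `low = c(lo, hi)`,
#'   `high = c(lo, hi)` per marker, supplied as `list(low =, high =)`.
#' @return an `intensity_bands` object: per marker, `low` and `high` ranges.
#' @export
intensity_bands <- function(ctip2 = list(low = c(50, 150), high = c(150, 700)),
                            satb2 = list(low = c(150, 500), high = c(500, 1500)),
                            ctip1 = list(low = c(50, 90), high = c(90, 400))) {
  bands <- list(ctip2 = ctip2, satb2 = satb2, ctip1 = ctip1)
  for (mk in names(bands)) {
    b <- bands[[mk]]
    lo <- as.numeric(b$low); hi <- as.numeric(b$high)
    if (length(lo) != 2 || length(hi) != 2 || !(lo[1] < lo[2]) ||
        lo[2] != hi[1] || !(hi[1] < hi[2]))
      stop_bad("bands for `%s` must satisfy low.lo < low.hi = high.lo < high.hi", mk)
    bands[[mk]] <- list(low = lo, high = hi)
  }
  structure(bands, class = "intensity_bands")
}

#' Marker thresholding policy
#'
#' Two selectable policies for converting a nucleus's mean marker intensity
#' to an expression call: `fixed_bands` uses the published per-marker
#' low/high bands; `fraction_of_max` calls a nucleus positive when its mean
#' exceeds `fraction` (default 0.2) of the maximum mean intensity observed
#' among the other nuclei of the same well, reported as `low` (no high tier).
#'
#' @param mode `"fixed_bands"` (default, reproduces the screen bands) or
#'   `"fraction_of_max"`.
#' @param fraction calibration fraction in (0, 1), used in `fraction_of_max`
#'   mode.
#' @param bands an [intensity_bands()], used in `fixed_bands` mode.
#' @return a `threshold_policy` object.
#' @export
threshold_policy <- function(mode = c("fixed_bands", "fraction_of_max"),
                             fraction = 0.2, bands = intensity_bands()) {
  mode <- match.arg(mode)
  check_fraction(fraction, "fraction", closed_low = FALSE, closed_high = FALSE)
  stopifnot(inherits(bands, "intensity_bands"))
  structure(list(mode = mode, fraction = fraction, bands = bands),
            class = "threshold_policy")
}

#' Calibrate a positivity threshold from observed means
#'
#' `threshold = fraction * max(mean_intensities)`, computed per well and per
#' marker.
#'
#' @param mean_intensities non-empty numeric vector of per-nucleus means for
#'   one marker in one well.
#' @param fraction calibration fraction (default 0.2).
#' @return the threshold intensity.
#' @examples
#' calibrate_threshold(c(10, 400, 1000), 0.2)  # 200
#' @export
calibrate_threshold <- function(mean_intensities, fraction = 0.2) {
  if (!length(mean_intensities) || all(!is.finite(mean_intensities)))
    stop_bad("cannot calibrate a threshold from an empty intensity list")
  check_fraction(fraction, "fraction", closed_low = FALSE, closed_high = FALSE)
  fraction * max(mean_intensities, na.rm = TRUE)
}

MARKER_CALLS <- c("negative", "low", "high")

#' Classify marker expression of nuclei
#'
#' In `fixed_bands` mode: `negative` below the low band, `low` within it,
#' `high` from the shared band boundary upward (values above the high band
#' clamp to `high`). In `fraction_of_max` mode: `negative` below the
#' calibrated threshold, otherwise `low`.
#'
#' @param mean numeric vector of per-nucleus mean intensities.
#' @param marker marker name present in the policy's bands.
#' @param policy a [threshold_policy()].
#' @param threshold optional precomputed threshold for `fraction_of_max`
#'   mode; when omitted it is calibrated from `mean` itself.
#' @return factor with levels `negative`, `low`, `high`.
#' @export
classify_marker <- function(mean, marker, policy = threshold_policy(),
                            threshold = NULL) {
  stopifnot(inherits(policy, "threshold_policy"))
  if (policy$mode == "fixed_bands") {
    b <- policy$bands[[marker]]
    if (is.null(b)) stop_bad("unknown marker `%s`", marker)
    call <- ifelse(mean >= b$high[1], "high",
                   ifelse(mean >= b$low[1], "low", "negative"))
  } else {
    thr <- threshold %||% calibrate_threshold(mean, policy$fraction)
    call <- ifelse(mean >= thr, "low", "negative")
  }
  factor(call, levels = MARKER_CALLS)
}

#' Combine two marker calls into a subtype call
#'
#' A nucleus is positive for a marker when its call is `low` or `high`.
#' The ordered pair (A, B) maps to `A_only`, `B_only`, `dual` or `unlabeled`.
#'
#' @param call_a,call_b factors from [classify_marker()] for markers A and B.
#' @param labels the two subtype names used for single-positive calls.
#' @return factor with levels `labels[1]`, `labels[2]`, `dual`, `unlabeled`.
#' @export
assign_subtype <- function(call_a, call_b, labels = c("a_only", "b_only")) {
  pos_a <- call_a %in% c("low", "high")
  pos_b <- call_b %in% c("low", "high")
  out <- dplyr::case_when(pos_a & !pos_b ~ labels[1],
                          pos_b & !pos_a ~ labels[2],
                          pos_a & pos_b ~ "dual",
                          TRUE ~ "unlabeled")
  factor(out, levels = c(labels, "dual", "unlabeled"))
}

#' Classify all nuclei of a plate
#'
#' Adds per-marker expression calls (`call_<marker>`) and pairwise subtype
#' calls for the screen's two marker axes, CTIP2/SATB2 and CTIP2/CTIP1
#' (`subtype_ctip2_satb2`, `subtype_ctip2_ctip1`). In `fraction_of_max` mode
#' thresholds are calibrated per well and per marker.
#'
#' @param nuclei tibble with `mean_<marker>` columns (and a `well` column for
#'   per-well calibration).
#' @param policy a [threshold_policy()].
#' @param markers marker names to call.
#' @return `nuclei` with added call and subtype columns.
#' @export
classify_nuclei <- function(nuclei, policy = threshold_policy(),
                            markers = c("ctip2", "satb2", "ctip1")) {
  nuclei <- as_tibble(nuclei)
  markers <- intersect(markers, sub("^mean_", "", grep("^mean_", names(nuclei), value = TRUE)))
  if (!length(markers)) stop_bad("no mean_<marker> columns found")
  for (mk in markers) {
    means <- nuclei[[paste0("mean_", mk)]]
    if (policy$mode == "fraction_of_max" && "well" %in% names(nuclei)) {
      call <- factor(rep(NA_character_, nrow(nuclei)), levels = MARKER_CALLS)
      for (w in unique(nuclei$well)) {
        i <- nuclei$well == w
        call[i] <- classify_marker(means[i], mk, policy)
      }
    } else {
      call <- classify_marker(means, mk, policy)
    }
    nuclei[[paste0("call_", mk)]] <- call
  }
  pairs <- list(c("ctip2", "satb2"), c("ctip2", "ctip1"))
  for (p in pairs) {
    if (!all(p %in% markers)) next
    nuclei[[paste0("subtype_", p[1], "_", p[2])]] <-
      assign_subtype(nuclei[[paste0("call_", p[1])]],
                     nuclei[[paste0("call_", p[2])]],
                     labels = paste0(p, "_only"))
  }
  nuclei
}
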