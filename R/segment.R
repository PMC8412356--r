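#' Nucleus detection parameters
#'
#' The five published detection parameters with fixed semantics:
#' `common_threshold` is the global foreground threshold as a fraction of the
#' robust (99.9th percentile) Hoechst maximum; `min_area` (um^2) discards
#' nuclear fragments; `split_factor` (um) is the minimum separation of
#' distance-transform seeds before clump splitting keeps them distinct;
#' `individual_threshold` refines each object's boundary at that fraction of
#' the object's own peak Hoechst intensity; `contrast` discards objects whose
#' mean-over-local-background contrast, relative to the robust maximum, is
#' too low.
#'
#' @param common_threshold fraction in (0, 1].
#' @param min_area minimum object area, um^2.
#' @param split_factor seed-merging distance, um (0 disables merging).
#' @param individual_threshold fraction in (0, 1].
#' @param contrast minimum relative contrast, fraction.
#' @param robust_max_quantile quantile defining the robust maximum
#'   (hot-pixel-resistant; set to 1 for the absolute maximum).
#' @param smooth_sigma Gaussian sigma (px) used to stabilise
#'   distance-transform maxima before seed detection.
#' @return a `segmentation_params` object.
#' @export
segmentation_params <- function(common_threshold = 0.1, min_area = 10,
                                split_factor = 5.0, individual_threshold = 0.5,
                                contrast = 0.05, robust_max_quantile = 0.999,
                                smooth_sigma = 1) {
  check_fraction(common_threshold, "common_threshold", closed_low = FALSE)
  check_positive(min_area, "min_area")
  check_positive(split_factor, "split_factor", strict = FALSE)
  check_fraction(individual_threshold, "individual_threshold", closed_low = FALSE)
  check_fraction(contrast, "contrast")
  check_fraction(robust_max_quantile, "robust_max_quantile", closed_low = FALSE)
  structure(list(common_threshold = common_threshold, min_area = min_area,
                 split_factor = split_factor,
                 individual_threshold = individual_threshold,
                 contrast = contrast, robust_max_quantile = robust_max_quantile,
                 smooth_sigma = smooth_sigma),
            class = "segmentation_params")
}

robust_max <- function(x, q) as.numeric(quantile(x, q, names = FALSE))

#' Threshold the Hoechst channel into a foreground mask
#'
#' Pixels whose Hoechst value is at least `common_threshold` times the robust
#' maximum (99.9th percentile) of the channel are foreground. A channel with
#' a non-positive robust maximum yields an empty mask.
#'
#' @param image a [field_image()] with a `hoechst` channel.
#' @param params a [segmentation_params()].
#' @return a logical matrix.
#' @export
binarize_nuclei <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "field_image"))
  h <- image$channels$hoechst
  if (is.null(h)) stop_bad("image has no `hoechst` channel")
  rm_ <- robust_max(h, params$robust_max_quantile)
  if (rm_ <= 0) return(matrix(FALSE, nrow(h), ncol(h)))
  h >= params$common_threshold * rm_
}

# strict-order local maxima of the (smoothed) distance transform
distance_seeds <- function(mask, smooth_sigma) {
  dm <- as.matrix(EBImage::distmap(mask * 1))
  dsm <- dm
  if (smooth_sigma > 0) {
    br <- EBImage::makeBrush(2 * ceiling(2 * smooth_sigma) + 1, shape = "Gaussian",
                             sigma = smooth_sigma)
    dsm <- as.matrix(EBImage::filter2(dm, br, boundary = "replicate"))
  }
  nmax <- as.matrix(EBImage::dilate(dsm, EBImage::makeBrush(5, shape = "box")))
  which(mask & dm > 0.5 & dsm >= nmax - 1e-7)
}

# merge candidate seeds closer than split_px (single linkage); keep, per
# cluster, the candidate with the deepest distance value (ties: raster order)
merge_seeds <- function(cand_idx, dm, nrow_m, split_px) {
  if (!length(cand_idx)) return(integer(0))
  rr <- (cand_idx - 1L) %% nrow_m + 1L
  cc <- (cand_idx - 1L) %/% nrow_m + 1L
  if (length(cand_idx) == 1L || split_px <= 0) {
    grp <- seq_along(cand_idx)
  } else {
    hc <- stats::hclust(stats::dist(cbind(rr, cc)), method = "single")
    grp <- stats::cutree(hc, h = split_px * (1 - 1e-9))
  }
  depth <- dm[cand_idx]
  keep <- vapply(split(seq_along(cand_idx), grp), function(ii) {
    ii[order(-depth[ii], cand_idx[ii])][1]
  }, integer(1))
  sort(cand_idx[unname(keep)])
}

# largest connected component of `sub` (logical) containing `anchor_idx`,
# falling back to the component of the submask's peak if the anchor was lost
component_containing <- function(sub, anchor_idx) {
  lab <- as.matrix(EBImage::bwlabel(sub))
  id <- lab[anchor_idx]
  if (id == 0) {
    ids <- lab[lab > 0]
    if (!length(ids)) return(sub & FALSE)
    id <- as.integer(names(which.max(table(ids))))
  }
  lab == id
}

#' Split touching nuclei and label candidate objects
#'
#' Connected foreground is divided by seeded region growing on the distance
#' transform: seeds are distance-transform maxima, merged when closer than
#' `split_factor` micrometres. Each region's boundary is then refined by
#' re-thresholding at `individual_threshold` times that region's peak Hoechst
#' value (keeping the component that contains the peak); regions are
#' discarded when their area falls below `min_area` or when
#' `(region mean - local background) / robust maximum` falls below
#' `contrast`, with the local background taken as the median Hoechst
#' intensity in a 2 um annulus around the region. Surviving regions are
#' relabelled 1..K in raster order of their first pixel.
#'
#' @param mask logical matrix from [binarize_nuclei()].
#' @param image the [field_image()] the mask came from.
#' @param params a [segmentation_params()].
#' @return an integer label matrix; attribute `n_debris` counts regions
#'   discarded by the minimum-area rule.
#' @export
split_and_label <- function(mask, image, params = segmentation_params()) {
  stopifnot(inherits(image, "field_image"))
  h <- image$channels$hoechst
  H <- nrow(h); W <- ncol(h)
  out <- matrix(0L, H, W)
  if (!any(mask)) return(structure(out, n_debris = 0L))
  ps <- image$pixel_scale
  dm <- as.matrix(EBImage::distmap(mask * 1))
  seeds_idx <- merge_seeds(distance_seeds(mask, params$smooth_sigma), dm, H,
                           params$split_factor / ps)
  if (!length(seeds_idx)) return(structure(out, n_debris = 0L))
  seeds <- matrix(0L, H, W)
  seeds[seeds_idx] <- seq_along(seeds_idx)
  labels <- as.matrix(EBImage::propagate(dm, seeds, mask = mask, lambda = 1e8))

  rm_ <- robust_max(h, params$robust_max_quantile)
  ann_px <- max(1L, ceiling(2 / ps))  # 2 um annulus for local background
  n_debris <- 0L
  kept <- list()
  for (id in seq_along(seeds_idx)) {
    idx <- which(labels == id)
    if (!length(idx)) next
    rr <- (idx - 1L) %% H + 1L; cc <- (idx - 1L) %/% H + 1L
    r0 <- max(1L, min(rr) - ann_px - 1L); r1 <- min(H, max(rr) + ann_px + 1L)
    c0 <- max(1L, min(cc) - ann_px - 1L); c1 <- min(W, max(cc) + ann_px + 1L)
    sub <- labels[r0:r1, c0:c1] == id
    hsub <- h[r0:r1, c0:c1]
    peak <- max(hsub[sub])
    refined <- sub & (hsub >= params$individual_threshold * peak)
    if (!any(refined)) { n_debris <- n_debris + 1L; next }
    peak_idx <- which(refined & hsub == max(hsub[refined]))[1]
    refined <- component_containing(refined, peak_idx)
    area <- sum(refined) * ps^2
    if (area < params$min_area) { n_debris <- n_debris + 1L; next }
    # contrast: region mean vs median background in a 2 um annulus, excluding
    # all foreground pixels
    ring <- as.matrix(EBImage::dilate(refined * 1,
                                      EBImage::makeBrush(2L * ann_px + 1L,
                                                         shape = "disc"))) > 0
    bgpx <- hsub[ring & !(mask[r0:r1, c0:c1])]
    bg <- if (length(bgpx)) median(bgpx) else 0
    if ((mean(hsub[refined]) - bg) / rm_ < params$contrast) next
    kept[[length(kept) + 1L]] <- list(rows = r0:r1, cols = c0:c1, m = refined)
  }
  if (!length(kept)) return(structure(out, n_debris = n_debris))
  # deterministic labelling: raster order (column-major) of each region's
  # first pixel
  first_px <- vapply(kept, function(k) {
    idx <- which(k$m)
    rr <- (idx - 1L) %% nrow(k$m) + k$rows[1]
    cc <- (idx - 1L) %/% nrow(k$m) + k$cols[1]
    min((cc - 1L) * H + rr)
  }, numeric(1))
  for (new_id in seq_along(kept)) {
    k <- kept[[order(first_px)[new_id]]]
    blk <- out[k$rows, k$cols]
    blk[k$m] <- new_id
    out[k$rows, k$cols] <- blk
  }
  structure(out, n_debris = n_debris)
}

#' Measure labelled nuclei
#'
#' Per region: area as pixel count times `pixel_scale^2`; width as the minor
#' axis of the intensity-weighted best-fit ellipse (um); centroid in
#' 0-based pixel coordinates (x = column, y = row); and the mean intensity of
#' every channel over the region mask.
#'
#' @param labels integer label matrix from [split_and_label()].
#' @param image the matching [field_image()].
#' @return a tibble with one row per region: `label`, `x_px`, `y_px`,
#'   `area_um2`, `width_um`, `mean_<channel>` columns.
#' @export
measure_candidates <- function(labels, image) {
  stopifnot(inherits(image, "field_image"))
  if (!all(dim(labels) == dim(image$channels[[1]])))
    stop_bad("label raster and channel dimensions differ")
  nlab <- max(labels)
  cols <- c("label", "x_px", "y_px", "area_um2", "width_um",
            paste0("mean_", names(image$channels)))
  if (nlab == 0L) {
    empty <- as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
    empty$label <- integer(0)
    return(empty)
  }
  ps <- image$pixel_scale
  mom <- EBImage::computeFeatures.moment(labels, ref = image$channels$hoechst)
  mom <- matrix(mom, nrow = nlab, dimnames = list(NULL, colnames(mom)))
  counts <- tabulate(labels[labels > 0], nbins = nlab)
  out <- tibble(label = seq_len(nlab),
                x_px = mom[, "m.cy"] - 1,   # EBImage: first index = row
                y_px = mom[, "m.cx"] - 1,
                area_um2 = counts * ps^2,
                width_um = mom[, "m.majoraxis"] *
                  sqrt(1 - mom[, "m.eccentricity"]^2) * ps)
  fg <- labels > 0
  lab_fg <- labels[fg]
  for (ch in names(image$channels)) {
    v <- image$channels[[ch]][fg]
    out[[paste0("mean_", ch)]] <- as.numeric(rowsum(v, lab_fg)[, 1]) / counts
  }
  out
}

#' Detect and measure nuclei in a field
#'
#' Composition of [binarize_nuclei()], [split_and_label()] and
#' [measure_candidates()]; deterministic for fixed input.
#'
#' @param image a [field_image()].
#' @param params a [segmentation_params()].
#' @return the candidate tibble from [measure_candidates()], with the label
#'   matrix in attribute `labels` and the minimum-area discard count in
#'   attribute `n_debris`.
#' @export
find_nuclei <- function(image, params = segmentation_params()) {
  mask <- binarize_nuclei(image, params)
  labels <- split_and_label(mask, image, params)
  out <- measure_candidates(labels, image)
  attr(out, "labels") <- labels
  attr(out, "n_debris") <- attr(labels, "n_debris")
  out
}
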