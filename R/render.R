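#' Multichannel field image container
#'
#' @param channels named list of numeric matrices (rows = y, columns = x),
#'   all of identical dimensions.
#' @param pixel_scale micrometres per pixel (> 0).
#' @param bit_depth camera bit depth.
#' @return a `field_image` object.
#' @export
field_image <- function(channels, pixel_scale, bit_depth = 12) {
  if (!length(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop_bad("channels must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    stop_bad("all channels must share identical dimensions")
  check_positive(pixel_scale, "pixel_scale")
  structure(list(channels = channels, pixel_scale = pixel_scale,
                 bit_depth = as.integer(bit_depth)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> %d x %d px @ %.3g um/px, %d-bit; channels: %s\n",
              d[2], d[1], x$pixel_scale, x$bit_depth,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# channel -> marker correspondence used throughout the simulator:
# UV/Hoechst plus the 488/546/647 laser lines
CHANNEL_MARKERS <- c(hoechst = "hoechst", ch488 = "ctip2",
                     ch546 = "satb2", ch647 = "ctip1")

#' Place sampled cells in a field
#'
#' Assigns centroids by Poisson placement with a hard-core minimum spacing,
#' except for a configurable fraction of nuclei placed as clumped pairs at
#' sub-diameter distances (to exercise clump splitting), plus a random
#' ellipse orientation per nucleus.
#'
#' @param cells tibble from [sample_population()].
#' @param spec an [image_spec()].
#' @param margin_um minimum distance of centroids from the field border.
#' @param min_spacing_um hard-core spacing between non-clumped nuclei.
#' @param clump_fraction fraction of nuclei belonging to clumped pairs.
#' @param clump_dist_um range of centre-to-centre distance within a clump.
#' @return `cells` with added `x_um`, `y_um`, `theta` columns.
#' @export
place_cells <- function(cells, spec, margin_um = 8, min_spacing_um = 9,
                        clump_fraction = 0.10, clump_dist_um = c(6.5, 8.5)) {
  stopifnot(inherits(spec, "image_spec"))
  n <- nrow(cells)
  w_um <- spec$width_px * spec$pixel_scale
  h_um <- spec$height_px * spec$pixel_scale
  if (w_um <= 2 * margin_um || h_um <= 2 * margin_um)
    stop_bad("field too small for the placement margin")
  if (n == 0L)
    return(dplyr::mutate(cells, x_um = numeric(0), y_um = numeric(0),
                         theta = numeric(0)))
  n_pairs <- min(floor(clump_fraction * n / 2), floor(n / 2))
  n_anchor <- n - n_pairs
  ax <- numeric(n_anchor); ay <- numeric(n_anchor)
  for (i in seq_len(n_anchor)) {
    for (try in 1:200) {
      px <- runif(1, margin_um, w_um - margin_um)
      py <- runif(1, margin_um, h_um - margin_um)
      if (i == 1L) break
      d2 <- (ax[seq_len(i - 1)] - px)^2 + (ay[seq_len(i - 1)] - py)^2
      if (min(d2) >= min_spacing_um^2) break
    }
    ax[i] <- px; ay[i] <- py
  }
  x <- ax; y <- ay
  if (n_pairs > 0) {
    r <- runif(n_pairs, clump_dist_um[1], clump_dist_um[2])
    ang <- runif(n_pairs, 0, 2 * pi)
    sx <- pmin(pmax(ax[seq_len(n_pairs)] + r * cos(ang), margin_um), w_um - margin_um)
    sy <- pmin(pmax(ay[seq_len(n_pairs)] + r * sin(ang), margin_um), h_um - margin_um)
    x <- c(x, sx); y <- c(y, sy)
  }
  dplyr::mutate(cells, x_um = x, y_um = y, theta = runif(n, 0, pi),
                clumped = c(rep(c(TRUE, FALSE), c(n_pairs, n_anchor - n_pairs)),
                            rep(TRUE, n_pairs)))
}

#' Render a multichannel field image
#'
#' Each cell contributes a smooth-edged (sub-pixel anti-aliased) elliptical
#' nucleus footprint of its true area to the Hoechst channel at its true
#' Hoechst intensity, and the same footprint to each marker channel at its
#' true mean marker intensity, over a noisy background. Pixel values are
#' clamped to the camera's dynamic range and quantized to integers.
#'
#' @param cells tibble from [place_cells()] (needs `x_um`, `y_um`, `theta`,
#'   `area_um2`, `eccentricity` and intensity columns `hoechst`, `ctip2`,
#'   `satb2`, `ctip1`).
#' @param spec an [image_spec()].
#' @return a [field_image()] with channels `hoechst`, `ch488`, `ch546`,
#'   `ch647`.
#' @export
render_field <- function(cells, spec) {
  stopifnot(inherits(spec, "image_spec"))
  ps <- spec$pixel_scale
  W <- spec$width_px; H <- spec$height_px
  n <- nrow(cells)
  if (n > 0) {
    if (!all(c("x_um", "y_um", "theta") %in% names(cells)))
      stop_bad("cells must carry x_um/y_um/theta; see place_cells()")
    if (any(cells$x_um < 0 | cells$x_um > W * ps | cells$y_um < 0 |
            cells$y_um > H * ps))
      stop_bad("cell centroids must fall inside the field")
  }
  chans <- setNames(rep(list(matrix(0, H, W)), 4), names(CHANNEL_MARKERS))
  if (n > 0) {
    intens <- cbind(cells$hoechst, cells$ctip2, cells$satb2, cells$ctip1)
    for (i in seq_len(n)) {
      a_px <- sqrt(cells$area_um2[i] / (pi * sqrt(1 - cells$eccentricity[i]^2))) / ps
      b_px <- (cells$area_um2[i] / pi) / (a_px * ps^2)  # so that pi*a*b = area
      cx <- cells$x_um[i] / ps + 0.5  # pixel-centred: pixel k covers [k-1, k)
      cy <- cells$y_um[i] / ps + 0.5
      ext <- ceiling(a_px) + 2L
      cols <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext))
      rows <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext))
      dx <- rep(cols - cx, each = length(rows))
      dy <- rep(rows - cy, times = length(cols))
      th <- cells$theta[i]
      u <- (cos(th) * dx + sin(th) * dy) / a_px
      v <- (-sin(th) * dx + cos(th) * dy) / b_px
      rho <- sqrt(u^2 + v^2)
      # signed edge distance in px; coverage ramps over ~1 px, half at rho = 1
      d_px <- (rho - 1) * sqrt(a_px * b_px)
      cov <- pmin(pmax(0.5 - d_px, 0), 1)
      if (!any(cov > 0)) next
      for (k in 1:4) {
        if (intens[i, k] <= 0) next
        chans[[k]][rows, cols] <- chans[[k]][rows, cols] +
          matrix(cov * intens[i, k], length(rows), length(cols))
      }
    }
  }
  ceiling_val <- 2^spec$bit_depth - 1
  npx <- H * W
  for (k in names(chans)) {
    noisy <- chans[[k]] + spec$background + rnorm(npx, 0, spec$noise_sd)
    chans[[k]] <- matrix(pmin(pmax(round(noisy), 0), ceiling_val), H, W)
  }
  field_image(chans, pixel_scale = ps, bit_depth = spec$bit_depth)
}

#' Write/read one field's channels as single-channel TIFF files
#'
#' Files are named `<well>_f<field>_<channel>.tif` and store integer
#' intensities in 16-bit containers.
#'
#' @param img a [field_image()].
#' @param dir output directory (created if missing).
#' @param well,field well id and field index used in the file names.
#' @return invisibly, the written file paths.
#' @export
write_field_images <- function(img, dir, well, field) {
  stopifnot(inherits(img, "field_image"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(img$channels)) {
    p <- file.path(dir, sprintf("%s_f%d_%s.tif", well, field, ch))
    tiff::writeTIFF(img$channels[[ch]] / 65535, p, bits.per.sample = 16,
                    compression = "none")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_field_images
#' @param channels channel names to read.
#' @param pixel_scale,bit_depth calibration to attach to the result.
#' @export
read_field_images <- function(dir, well, field,
                              channels = names(CHANNEL_MARKERS),
                              pixel_scale = 0.65, bit_depth = 12) {
  chans <- list()
  for (ch in channels) {
    p <- file.path(dir, sprintf("%s_f%d_%s.tif", well, field, ch))
    if (!file.exists(p))
      stop_bad("missing image for well %s, field %d, channel %s (%s)",
               well, field, ch, p)
    m <- tiff::readTIFF(p, as.is = TRUE)
    chans[[ch]] <- m
  }
  field_image(chans, pixel_scale = pixel_scale, bit_depth = bit_depth)
}
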