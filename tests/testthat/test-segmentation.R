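test_that("binarization follows the robust-maximum threshold rule", {
  blank <- field_image(list(hoechst = matrix(0, 60, 60)), pixel_scale = 0.65)
  expect_false(any(binarize_nuclei(blank)))

  img <- disk_field(list(list(x = 30, y = 30, r = 10, value = 1000)), H = 60, W = 60)
  mask <- binarize_nuclei(img)      # threshold 0.1 x robust max: the disk itself
  expect_identical(mask, img$channels$hoechst == 1000)

  no_hoechst <- field_image(list(ch488 = matrix(1, 10, 10)), pixel_scale = 0.65)
  expect_error(binarize_nuclei(no_hoechst), "hoechst")
})

test_that("clump splitting separates close nuclei and drops fragments", {
  params <- segmentation_params()
  one <- disk_field(list(list(x = 60, y = 60, r = 9, value = 800)), H = 120, W = 120)
  lab1 <- split_and_label(binarize_nuclei(one), one, params)
  expect_identical(max(lab1), 1L)

  # two overlapping disks of radius 4 um with centres 7 um apart: 7 um exceeds
  # the 5 um split factor, so they must be resolved as 2 nuclei
  r_px <- 4 / 0.65; d_px <- 7 / 0.65
  two <- disk_field(list(list(x = 55, y = 60, r = r_px, value = 800),
                         list(x = 55 + d_px, y = 60, r = r_px, value = 800)),
                    H = 120, W = 120)
  lab2 <- split_and_label(binarize_nuclei(two), two, params)
  expect_identical(max(lab2), 2L)

  # a fragment of 8 um^2 (below the 10 um^2 area rule) is discarded
  r_frag <- sqrt(8 / pi) / 0.65
  frag <- disk_field(list(list(x = 60, y = 60, r = r_frag, value = 800)),
                     H = 120, W = 120)
  lab3 <- split_and_label(binarize_nuclei(frag), frag, params)
  expect_identical(max(lab3), 0L)
  expect_identical(attr(lab3, "n_debris"), 1L)
})

test_that("measurement reports exact means, calibrated areas and centroids", {
  img <- disk_field(list(list(x = 40, y = 30, r = 8, value = 700),
                         list(x = 40, y = 30, r = 8, value = 123.5,
                              channel = "ch488")),
                    H = 60, W = 80)
  labels <- matrix(0L, 60, 80)
  labels[img$channels$hoechst > 0] <- 1L
  m <- measure_candidates(labels, img)
  expect_identical(nrow(m), 1L)
  expect_identical(m$mean_ch488, 123.5)       # constant region: mean exact
  expect_identical(m$mean_hoechst, 700)
  expect_equal(m$area_um2, sum(labels) * 0.65^2)
  expect_lt(abs(m$x_px - 39), 0.3)            # 0-based centre of the disk
  expect_lt(abs(m$y_px - 29), 0.3)

  # a 120-pixel region at 0.65 um/px measures 50.7 um^2
  lab2 <- matrix(0L, 60, 80); lab2[11:20, 21:32] <- 1L
  expect_equal(measure_candidates(lab2, img)$area_um2, 120 * 0.65^2)

  none <- matrix(0L, 60, 80)
  expect_identical(nrow(measure_candidates(none, img)), 0L)
  expect_error(measure_candidates(matrix(0L, 5, 5), img), "dimensions")
})

test_that("without touching nuclei, splitting equals connected components", {
  set.seed(31)
  spec <- image_spec(width_px = 300, height_px = 240)
  model <- primary_population_model()
  cells <- sample_population(model, n = 25, seed = 31)
  cells <- place_cells(cells, spec, min_spacing_um = 16, clump_fraction = 0)
  img <- render_field(cells, spec)
  # boundary refinement and acceptance rules disabled: the labelling itself
  # must coincide exactly with plain connected-component labelling
  relaxed <- segmentation_params(min_area = 1, individual_threshold = 0.01,
                                 contrast = 0)
  mask <- binarize_nuclei(img, relaxed)
  got <- canonical_labels(split_and_label(mask, img, relaxed))
  want <- canonical_labels(as.matrix(EBImage::bwlabel(mask)))
  expect_identical(got, want)
})

test_that("candidate count is monotone in min_area and contrast", {
  set.seed(32)
  spec <- image_spec(width_px = 400, height_px = 300)
  cells <- place_cells(sample_population(primary_population_model(), n = 60,
                                         seed = 32), spec)
  img <- render_field(cells, spec)
  n_by_area <- vapply(c(10, 30, 60), function(a)
    nrow(find_nuclei(img, segmentation_params(min_area = a))), numeric(1))
  expect_true(all(diff(n_by_area) <= 0))
  n_by_contrast <- vapply(c(0.05, 0.25, 0.6), function(ct)
    nrow(find_nuclei(img, segmentation_params(contrast = ct))), numeric(1))
  expect_true(all(diff(n_by_contrast) <= 0))
})

test_that("marker means shift by exactly an added constant", {
  set.seed(33)
  spec <- image_spec(width_px = 250, height_px = 200)
  cells <- place_cells(sample_population(primary_population_model(), n = 20,
                                         seed = 33), spec, clump_fraction = 0)
  img <- render_field(cells, spec)
  base <- find_nuclei(img)
  shifted_img <- img
  shifted_img$channels$ch488 <- img$channels$ch488 + 50
  shifted <- find_nuclei(shifted_img)
  expect_equal(shifted$mean_ch488, base$mean_ch488 + 50)
  expect_identical(shifted$mean_hoechst, base$mean_hoechst)
})

test_that("detection is deterministic and accurate on a default-density field", {
  set.seed(34)
  spec <- image_spec()
  cells <- place_cells(sample_population(primary_population_model(), n = 150,
                                         seed = 34), spec)
  img <- render_field(cells, spec)
  nuc1 <- find_nuclei(img)
  nuc2 <- find_nuclei(img)
  expect_identical(nuc1, nuc2)

  m <- match_detections(cells[, c("x_um", "y_um")], candidate_xy_um(nuc1))
  expect_gte(m$precision, 0.95)
  expect_gte(m$recall, 0.95)
})
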