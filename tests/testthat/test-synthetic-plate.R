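test_that("refinement shift converts dual to CTIP2-only and conserves their sum", {
  f <- c(ctip2_only = 0.05, satb2_only = 0.15, dual = 0.20, unlabeled = 0.60)
  for (delta in c(0, 0.1, 0.25, 0.5, 0.75, 1)) {
    g <- adjust_subtype_fractions(f, delta)
    expect_identical(g[["ctip2_only"]], 0.05 + delta * 0.20)
    expect_identical(g[["dual"]], (1 - delta) * 0.20)
    # conversion, not creation: exact conservation
    expect_identical(g[["ctip2_only"]] + g[["dual"]], f[["ctip2_only"]] + f[["dual"]])
    expect_identical(g[["satb2_only"]], f[["satb2_only"]])
    expect_equal(sum(g), 1)
  }
  shifts <- vapply(seq(0, 1, 0.25),
                   function(d) adjust_subtype_fractions(f, d)[["ctip2_only"]],
                   numeric(1))
  expect_true(all(diff(shifts) > 0))           # strictly increasing in delta
  duals <- vapply(seq(0, 1, 0.25),
                  function(d) adjust_subtype_fractions(f, d)[["dual"]], numeric(1))
  expect_true(all(diff(duals) < 0))
  expect_error(adjust_subtype_fractions(c(0.5, 0.5, 0.2, 0.2), 0), "summing")
  expect_error(adjust_subtype_fractions(f, 1.2), "interval")
})

test_that("model and effect constructors validate their invariants", {
  expect_error(population_model(subtype_fractions = c(0.3, 0.3, 0.3, 0.2)), "sum to 1")
  expect_error(population_model(fraction_viable = 1.4), "interval")
  expect_error(marker_component(c(100, 5), c(50, 5), c(200, 5)), "ordered")
  expect_error(marker_component(c(-5, 5), c(50, 5), c(200, 5)), "non-negative")
  expect_error(compound_effect(toxicity = "none", kill_fraction = 0.2), "requires")
  expect_error(compound_effect(refinement_shift = -0.1), "interval")
  eff <- compound_effect(toxicity = "severe")
  expect_identical(eff$kill_fraction, 0.7)
  expect_identical(eff$pyknotic_fraction, 0.35)
})

test_that("sample_population draws the effect-adjusted subtype mixture", {
  model <- primary_population_model()
  expect_identical(nrow(sample_population(model, n = 0)), 0L)

  n <- 10000
  cells <- sample_population(model, n = n, seed = 101)
  # baseline positivity: 25% CTIP2+ and 35% SATB2+ (20-30% / 30-40% baselines)
  p2 <- mean(cells$subtype %in% c("ctip2_only", "dual"))
  ps <- mean(cells$subtype %in% c("satb2_only", "dual"))
  expect_lt(abs(p2 - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(ps - 0.35), 3 * sqrt(0.35 * 0.65 / n))

  shifted <- sample_population(model, compound_effect(refinement_shift = 0.5),
                               n = n, seed = 102)
  f_co <- mean(shifted$subtype == "ctip2_only")
  f_dual <- mean(shifted$subtype == "dual")
  expect_lt(abs(f_co - 0.15), 3 * sqrt(0.15 * 0.85 / n))
  expect_lt(abs(f_dual - 0.10), 3 * sqrt(0.10 * 0.90 / n))
})

test_that("toxicity kills cells and renders survivors pyknotic", {
  model <- primary_population_model()
  n <- 8000
  eff <- compound_effect(toxicity = "severe")       # kill 0.7, pyknotic 0.35
  cells <- sample_population(model, eff, n = n, seed = 103)
  expect_lt(abs(nrow(cells) - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7))
  pyk <- mean(cells$viability_class == "pyknotic")
  # converted survivors plus the baseline pyknotic share of the remainder
  expected_pyk <- 0.35 + (1 - 0.35) * 0.4 * 0.125
  expect_lt(abs(pyk - expected_pyk), 3 * sqrt(expected_pyk * (1 - expected_pyk) / nrow(cells)))
  expect_true(all(cells$area_um2[cells$viability_class == "pyknotic"] < 33))
  expect_true(all(cells$hoechst[cells$viability_class == "pyknotic"] >= 900))

  base <- sample_population(model, n = n, seed = 104)
  expect_lt(abs(mean(base$viable) - 0.6), 3 * sqrt(0.6 * 0.4 / n))
})

test_that("population draws are seed-reproducible and seed-sensitive", {
  model <- mes_population_model()
  a <- sample_population(model, n = 500, seed = 7)
  b <- sample_population(model, n = 500, seed = 7)
  expect_identical(a, b)
  c <- sample_population(model, n = 500, seed = 8)
  expect_false(identical(a$ctip2, c$ctip2))
})

test_that("rendered fields have faithful backgrounds and footprints", {
  spec <- image_spec(width_px = 200, height_px = 200)
  set.seed(5)
  empty <- render_field(sample_population(primary_population_model(), n = 0), spec)
  npx <- 200 * 200
  for (ch in names(empty$channels))
    expect_lt(abs(mean(empty$channels[[ch]]) - spec$background),
              3 * spec$noise_sd / sqrt(npx) + 0.01)

  # one nucleus of known area: pixel count above the footprint half-maximum,
  # times pixel-scale^2, recovers the true area within 10%
  quiet <- image_spec(width_px = 120, height_px = 120, background = 0, noise_sd = 0)
  cells <- tibble::tibble(x_um = 39, y_um = 39, theta = 0.7, area_um2 = 50,
                          eccentricity = 0.3, hoechst = 600, ctip2 = 300,
                          satb2 = 0, ctip1 = 0)
  img <- render_field(cells, quiet)
  n_half <- sum(img$channels$hoechst > 300)
  expect_lt(abs(n_half * quiet$pixel_scale^2 - 50), 5)
  # zero-intensity marker channels stay at background
  expect_true(all(img$channels$ch546 == 0))

  set.seed(9)
  noisy <- render_field(dplyr::mutate(cells, ctip2 = 0), spec)
  expect_lt(abs(mean(noisy$channels$ch488) - spec$background), 0.1)

  expect_error(render_field(dplyr::mutate(cells, x_um = 1e5), quiet), "inside")
  expect_error(image_spec(pixel_scale = -1), "positive")
})

test_that("generate_plate is bit-reproducible and Poisson-dense", {
  map <- screen_plate_map(n_compounds = 1, doses = 1, replicates = 2,
                          controls_each = 1)
  small <- image_spec(width_px = 180, height_px = 140)
  design <- plate_design(map, fields_per_well = 1, image_spec = small, seed = 21)
  models <- screen_models("primary")
  models <- lapply(models, function(m) { m$density <- 25; m })
  effects <- list(C01 = compound_effect())
  g1 <- generate_plate(design, models, effects)
  g2 <- generate_plate(design, models, effects)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$images, g2$images)

  # per-field counts match the design density in mean
  d2 <- plate_design(map[1, ], fields_per_well = 100, image_spec = small, seed = 22)
  g3 <- generate_plate(d2, models, effects, render = FALSE)
  counts <- table(factor(g3$truth$field, levels = 1:100))
  expect_lt(abs(mean(counts) - 25), 3 * sqrt(25 / 100))

  expect_error(generate_plate(design, models["untreated"], effects), "no population model")
  expect_error(generate_plate(design, models, list()), "no compound effect")
})

test_that("screen plate maps put every compound at every dose in replicate", {
  map <- screen_plate_map(n_compounds = 10, doses = c(10, 1, 0.1), replicates = 2,
                          controls_each = 3)
  expect_identical(nrow(map), 12L + 60L)
  expect_false(anyDuplicated(map$well) > 0)
  per <- dplyr::count(dplyr::filter(map, !is.na(compound)), compound, dose_uM)
  expect_true(all(per$n == 2))
  expect_identical(nrow(per), 30L)   # 10 compounds x 3 doses
  expect_error(plate_design(map[c(1, 1, 2), ], seed = 1), "unique")
})
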