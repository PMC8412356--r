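test_that("well summaries pool counts and define the refinement ratio", {
  s1 <- summarize_wells(make_classified("A01", 10, 0, 10, 0))
  expect_identical(s1$n_viable, 20L)
  expect_identical(s1$ratio, 1)
  s2 <- summarize_wells(make_classified("A01", 30, 0, 15, 0))
  expect_identical(s2$ratio, 2)
  expect_identical(s2$n_ctip2_total, 45L)
  s3 <- summarize_wells(make_classified("A01", 5, 2, 0, 3))
  expect_true(is.na(s3$ratio))
  expect_false(s3$ratio_defined)
  # partition identity holds exactly
  s <- summarize_wells(make_classified("A01", 7, 11, 13, 17))
  expect_identical(s$n_ctip2_only + s$n_satb2_only + s$n_dual + s$n_unlabeled,
                   s$n_viable)
})

test_that("baseline normalization is exact, scale-free and guarded", {
  wells <- tibble::tibble(condition = rep(c("untreated", "compound_fezf2"), each = 3),
                          ratio = c(0.2, 0.25, 0.3, 0.5, 0.6, 0.7))
  norm <- normalize_to_baseline(wells, ratio, "untreated")
  expect_identical(mean(norm$norm_ratio[norm$condition == "untreated"]), 1)
  scaled <- normalize_to_baseline(dplyr::mutate(wells, ratio = ratio * 3.7),
                                  ratio, "untreated")
  expect_equal(scaled$norm_ratio, norm$norm_ratio)
  expect_error(normalize_to_baseline(wells, ratio, "dmso"), "no defined values")
  expect_error(normalize_to_baseline(dplyr::mutate(wells, ratio = 0), ratio,
                                     "untreated"), "zero")
})

test_that("composition proportions are exact fractions summing to one", {
  s <- summarize_wells(make_classified("A01", 5, 15, 20, 60))
  pr <- composition_proportions(s)
  expect_equal(pr$proportion[match(c("ctip2_only", "satb2_only", "dual", "unlabeled"),
                                   as.character(pr$category))],
               c(0.05, 0.15, 0.20, 0.60))
  expect_lt(abs(sum(pr$proportion) - 1), 1e-12)
  s0 <- dplyr::mutate(s, n_viable = 0L)
  expect_error(composition_proportions(s0), "0 viable")
})

test_that("generated wells recover the model's composition fractions", {
  set.seed(61)
  well <- simulate_well_nuclei(primary_population_model(), n_cells = 6000)
  viable <- dplyr::filter(filter_viable(well), viable)
  pr <- composition_proportions(summarize_wells(classify_nuclei(viable)))
  truth <- c(ctip2_only = 0.05, satb2_only = 0.15, dual = 0.20, unlabeled = 0.60)
  n <- nrow(viable)
  for (cat in names(truth)) {
    p <- pr$proportion[as.character(pr$category) == cat]
    tol <- 3 * sqrt(truth[[cat]] * (1 - truth[[cat]]) / n) + 0.01  # + band-call error
    expect_lt(abs(p - truth[[cat]]), tol)
  }
})

test_that("condition comparison matches the pooled-variance closed form", {
  ct <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_identical(ct$statistic, 0)
  expect_identical(ct$p_value, 1)

  ct2 <- compare_conditions(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ct2$statistic, -sqrt(3 / 2), tolerance = 1e-12)  # -1.2247...
  expect_identical(ct2$df, 4)

  set.seed(62)
  for (i in 1:200) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1))
    want <- pooled_t_oracle(a, b)
    got <- compare_conditions(a, b)
    expect_lt(abs(got$statistic - want$t), 1e-10)
    expect_lt(abs(got$p_value - want$p), 1e-10)
    expect_identical(got$df, want$df)
  }
  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
})

test_that("tidy and glance summarise a condition test", {
  ct <- compare_conditions(c(1.2, 1.4, 1.1), c(0.8, 0.9, 1.0),
                           labels = c("CHIC-35", "DMSO"))
  td <- tidy(ct)
  expect_identical(nrow(td), 1L)
  expect_identical(td$group_a, "CHIC-35")
  expect_identical(td$estimate, mean(c(1.2, 1.4, 1.1)) - mean(c(0.8, 0.9, 1.0)))
  expect_true(all(c("statistic", "df", "p_value", "significance") %in% names(td)))
  gl <- glance(ct)
  expect_match(gl$method, "Student")
  ct_star <- compare_conditions(c(10, 11, 12), c(1, 2, 3))
  expect_identical(ct_star$significance, "**")
})

test_that("the pooled ratio converges to its closed form and rises with delta", {
  f_co <- 0.05; f_dual <- 0.20
  n <- 6000
  model <- primary_population_model()
  ratios <- c()
  for (delta in c(0, 0.5)) {
    cells <- sample_population(model, compound_effect(refinement_shift = delta),
                               n = round(n / 0.6 / 0.995), seed = 63 + round(100 * delta))
    nuclei <- dplyr::rename(cells, mean_hoechst = hoechst, mean_ctip2 = ctip2,
                            mean_satb2 = satb2, mean_ctip1 = ctip1)
    nuclei$well <- "W1"
    viable <- dplyr::filter(filter_viable(nuclei), viable)
    s <- summarize_wells(classify_nuclei(viable))
    p1 <- f_co + delta * f_dual; p2 <- (1 - delta) * f_dual
    want <- p1 / p2
    se <- ratio_delta_se(nrow(viable), p1, p2)
    expect_lt(abs(s$ratio - want), 3 * se + 0.03)  # + band-call error allowance
    ratios <- c(ratios, s$ratio)
  }
  expect_true(all(diff(ratios) > 0))
})
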