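fake_wells <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r)
    tibble::tibble(well = r[[1]], compound = r[[2]], dose_uM = 1,
                   norm_ratio = r[[3]], norm_ctip2_total = r[[4]],
                   norm_satb2_total = r[[5]], ratio_defined = TRUE)))
}
fake_qc <- function(wells, grades) {
  tibble::tibble(well = wells,
                 grade = factor(grades, levels = c("none", "moderate", "severe"),
                                ordered = TRUE))
}

test_that("stage assignment follows the ordered criteria", {
  wells <- fake_wells(
    list("A01", "enh", 1.6, 0.9, 0.8),
    list("A02", "lowratio", 1.2, 1.0, 0.9),
    list("A03", "ctip2loss", 2.0, 0.5, 0.9),
    list("A04", "satb2up", 2.0, 1.0, 1.3),
    list("A05", "toxic", 3.0, 1.0, 0.5))
  qc <- fake_qc(sprintf("A%02d", 1:5), c("none", "none", "none", "none", "severe"))
  rec <- run_triage(wells, qc)
  got <- setNames(as.character(rec$stage_reached), rec$compound)
  expect_identical(got[["enh"]], "hit")
  expect_identical(got[["lowratio"]], "failed_L1")
  expect_identical(got[["ctip2loss"]], "failed_L2")
  expect_identical(got[["satb2up"]], "failed_L3")
  expect_identical(got[["toxic"]], "excluded_toxicity")
  # every compound-dose reaches exactly one stage
  expect_identical(nrow(rec), 5L)
  expect_false(anyNA(rec$stage_reached))

  # with the enhancement cutoff at 1.0, a compound just above parity becomes a
  # hit (norm ratio 1.5 / CTIP2 0.9 / SATB2 0.8 passes all three levels)
  loose <- run_triage(fake_wells(list("A01", "c", 1.5, 0.9, 0.8)),
                      fake_qc("A01", "none"),
                      triage_criteria(min_norm_ratio = 1.0))
  expect_identical(as.character(loose$stage_reached), "hit")
  # ... while the default cutoff treats the same compound as not enhancing
  strict <- run_triage(fake_wells(list("A01", "c", 1.5, 0.9, 0.8)),
                       fake_qc("A01", "none"))
  expect_identical(as.character(strict$stage_reached), "failed_L1")
})

test_that("hits are ranked by ratio, then SATB2 reduction, then id", {
  wells <- fake_wells(
    list("A01", "b", 2.5, 1.0, 0.7),
    list("A02", "a", 2.5, 1.0, 0.7),
    list("A03", "c", 3.0, 1.0, 0.9),
    list("A04", "d", 2.5, 1.0, 0.6))
  qc <- fake_qc(sprintf("A%02d", 1:4), rep("none", 4))
  rec <- run_triage(wells, qc)
  ranked <- rec$compound[order(rec$rank)]
  expect_identical(ranked, c("c", "d", "a", "b"))
})

test_that("hit sets shrink as criteria tighten", {
  set.seed(71)
  wells <- do.call(fake_wells, lapply(1:20, function(i)
    list(sprintf("A%02d", i), sprintf("C%02d", i), runif(1, 0.5, 3),
         runif(1, 0.6, 1.2), runif(1, 0.5, 1.3))))
  qc <- fake_qc(sprintf("A%02d", 1:20), rep("none", 20))
  prev <- NULL
  for (thr in c(1.0, 1.5, 2.0, 2.5)) {
    hits <- with(run_triage(wells, qc, triage_criteria(min_norm_ratio = thr)),
                 compound[stage_reached == "hit"])
    if (!is.null(prev)) expect_true(all(hits %in% prev))
    prev <- hits
  }
  prev <- NULL
  for (ct in c(1.2, 1.0, 0.8)) {
    hits <- with(run_triage(wells, qc, triage_criteria(min_norm_ctip2 = ct)),
                 compound[stage_reached == "hit"])
    if (!is.null(prev)) expect_true(all(prev %in% hits))  # loosening L2 only grows
    prev <- hits
  }
})

test_that("a null plate yields zero hits", {
  bm <- triage_benchmark(seed = 72, n_enhancers = 0, n_toxic = 0)
  expect_identical(nrow(bm$report$hits), 0L)
  counts <- bm$report$stage_counts
  expect_identical(sum(counts$n), 30L)
})

test_that("planted enhancers and toxic compounds are recovered", {
  hits_exact <- 0; tox_ok <- 0
  seeds <- 1:5
  for (s in seeds) {
    bm <- triage_benchmark(seed = s)
    hits <- sort(bm$report$hits$compound)
    hits_exact <- hits_exact + identical(hits, sort(bm$planted$enhancers))
    excl <- bm$records$compound[bm$records$stage_reached == "excluded_toxicity"]
    tox_ok <- tox_ok + all(bm$planted$toxic %in% excl)
  }
  expect_gte(hits_exact, length(seeds) - 1)
  expect_equal(tox_ok, length(seeds))
})

test_that("triage reports are complete and deterministic", {
  empty_wells <- fake_wells(list("A01", "c", 2, 1, 0.8))[0, ]
  empty_rec <- run_triage(empty_wells, fake_qc(character(0), character(0)))
  expect_identical(sum(triage_report(empty_rec)$stage_counts$n), 0L)
  bm <- triage_benchmark(seed = 73, n_compounds = 8, n_enhancers = 1, n_toxic = 1)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_triage_report(bm$report, f1)
  write_triage_report(triage_report(bm$records), f2)
  expect_identical(readLines(f1), readLines(f2))
})
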