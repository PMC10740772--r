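test_that("default scenario encodes the study cohorts and null controls", {
  sc <- default_scenario()
  expect_equal(sc$n_per_cohort, c(HC = 19L, MS = 33L, AD = 21L))
  expect_equal(sc$age_mean, 69.5)
  for (L in PPOLE_LAYERS) {
    expect_true(all(sc$effect$HC[[L]] == 0))
    expect_true(all(sc$effect$AD$ONL == 0)) # no ONL thinning in AD
    expect_true(all(sc$baseline[[L]] - sc$effect$MS[[L]] > 0))
    expect_true(all(sc$baseline[[L]] - sc$effect$AD[[L]] > 0))
  }
})

test_that("scenario constructor rejects invalid configurations", {
  sc <- default_scenario()
  neg <- sc$effect
  neg$MS$GCL[1, 1] <- -1
  expect_error(synthetic_scenario(sc$name, sc$n_per_cohort, sc$baseline,
                                  neg, 4, 3), "non-negative")
  hc <- sc$effect
  hc$HC$GCL[2, 2] <- 1
  expect_error(synthetic_scenario(sc$name, sc$n_per_cohort, sc$baseline,
                                  hc, 4, 3), "HC effect")
  big <- sc$effect
  big$MS$GCL[] <- 1e4
  expect_error(synthetic_scenario(sc$name, sc$n_per_cohort, sc$baseline,
                                  big, 4, 3), "positive")
})

test_that("expected folded AUROCs hit the calibration targets exactly", {
  parc <- default_parcellation()
  sc <- default_scenario(parc)
  expect_equal(scenario_expected_auroc(sc, "MS", "AD", "ONL", "PARAFOVEAL",
                                       parc), 0.85, tolerance = 0.01)
  expect_equal(scenario_expected_auroc(sc, "HC", "MS", "GCL", "PMB", parc),
               0.95, tolerance = 0.01)
  expect_equal(scenario_expected_auroc(sc, "HC", "AD", "GCL", "PMB", parc),
               0.93, tolerance = 0.01)
  expect_equal(scenario_expected_auroc(sc, "HC", "AD", "ONL", "PARAFOVEAL",
                                       parc), 0.5)
  for (rg in PPOLE_REGIONS)
    expect_lt(scenario_expected_auroc(sc, "HC", "MS", "RNFL", rg, parc), 0.7)
})

test_that("generation is deterministic in the seed and sensitive to it", {
  sc <- scenario_with_n(5)
  a <- generate_cohorts(sc)
  b <- generate_cohorts(sc)
  expect_identical(a, b)
  sc2 <- scenario_with_n(5, seed = 777L)
  c <- generate_cohorts(sc2)
  expect_false(identical(a, c))
  # the generator must not disturb the caller's RNG stream
  withr::with_seed(1, before <- runif(1))
  withr::with_seed(1, { invisible(generate_cohorts(sc)); after <- runif(1) })
  expect_identical(before, after)
})

test_that("noise-free controls reproduce the baseline exactly", {
  sc <- default_scenario()
  sc0 <- synthetic_scenario(sc$name, c(HC = 2L, MS = 1L, AD = 1L),
                            sc$baseline, sc$effect, 0, 0, seed = 9L)
  subs <- normalize_subjects(generate_cohorts(sc0, eyes_per_subject = 2))
  hc <- Filter(function(s) s$cohort == "HC", subs)
  for (s in hc) for (g in s$grids)
    expect_equal(g$cells, sc0$baseline[[g$layer]])
})

test_that("grid counts, laterality and quality follow the generator contract", {
  sc <- scenario_with_n(4)
  one <- generate_cohorts(sc, eyes_per_subject = 1)
  expect_length(one, 12)
  eyes <- vapply(one, function(s) s$grids[[1]]$eye, character(1))
  expect_true(all(c("OD", "OS") %in% eyes)) # alternating laterality
  expect_equal(vapply(one, function(s) length(s$grids), integer(1)),
               rep(4L, 12))
  two <- generate_cohorts(sc, eyes_per_subject = 2)
  expect_equal(vapply(two, function(s) length(s$grids), integer(1)),
               rep(8L, 12))
  quals <- unlist(lapply(two, function(s)
    vapply(s$grids, `[[`, numeric(1), "quality")))
  expect_true(all(quals >= 26 & quals <= 40))
  expect_error(generate_cohorts(sc, eyes_per_subject = 3), "1 or 2")
  # the low-quality hook produces grids the filter then removes
  lo <- generate_cohorts(sc, low_quality_fraction = 1)
  expect_true(all(unlist(lapply(lo, function(s)
    vapply(s$grids, `[[`, numeric(1), "quality"))) <= 25))
})

test_that("zero effects give null AUROCs at n = 100 per group", {
  parc <- default_parcellation()
  sc <- default_scenario(parc, seed = 202L)
  null_sc <- synthetic_scenario("null", c(HC = 100L, MS = 100L, AD = 100L),
                                sc$baseline,
                                list(HC = sc$effect$HC, MS = sc$effect$HC,
                                     AD = sc$effect$HC),
                                sc$sigma_subject, sc$sigma_cell,
                                seed = 202L)
  subs <- normalize_subjects(generate_cohorts(null_sc))
  tab <- run_comparison(subs, comparison_spec("HC_vs_MS", "HC", "MS",
                                              ci_method = "hanley"), parc)
  expect_true(all(tab$results$auroc_folded >= 0.5))
  expect_true(all(tab$results$auroc_folded <= 0.58))
})

test_that("cohort mean differences recover the region-averaged effect", {
  parc <- default_parcellation()
  sc <- scenario_with_n(150, seed = 310L)
  subs <- normalize_subjects(generate_cohorts(sc))
  obs <- regionize_cohort(subs, parc)
  for (case in list(c("GCL", "PMB"), c("ONL", "PARAFOVEAL"))) {
    sel <- obs[obs$layer == case[1] & obs$region == case[2], ]
    hc <- sel$mean_thickness[sel$cohort == "HC"]
    ms <- sel$mean_thickness[sel$cohort == "MS"]
    diff_obs <- mean(hc) - mean(ms)
    cells <- parc$regions[[case[2]]]
    diff_true <- mean(sc$effect$MS[[case[1]]][cells])
    se <- sqrt(var(hc) / length(hc) + var(ms) / length(ms))
    expect_lt(abs(diff_obs - diff_true), 2 * se + 1e-9)
  }
})

test_that("scaling up the effects never lowers an expected folded AUROC", {
  parc <- default_parcellation()
  sc <- default_scenario(parc)
  sc_up <- scale_effects(sc, 1.2)
  for (L in PPOLE_LAYERS) for (rg in PPOLE_REGIONS) {
    expect_gte(scenario_expected_auroc(sc_up, "HC", "MS", L, rg, parc),
               scenario_expected_auroc(sc, "HC", "MS", L, rg, parc))
  }
})

test_that("scenarios round-trip through JSON", {
  sc <- scenario_with_n(3)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$n_per_cohort, sc$n_per_cohort)
  expect_equal(back$baseline, sc$baseline)
  expect_equal(back$effect, sc$effect)
  # JSON carries ~17 significant digits; cohorts agree to numeric precision
  expect_equal(generate_cohorts(back), generate_cohorts(sc),
               tolerance = 1e-12)
})
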