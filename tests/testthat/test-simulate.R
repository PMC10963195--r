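test_that("the generator honours its bookkeeping contract deterministically", {
  co <- simulate_cohort(seed = 5)
  expect_equal(nrow(co), 690)
  flow <- cohort_flow(co)
  expect_equal(flow$n_cluster, 288)
  expect_equal(flow$n_full_panel, 169)
  expect_equal(sum(!is.na(co$tsh)), 411)
  expect_equal(flow$n_survival, 568)

  expect_identical(simulate_cohort(seed = 5), co)
  expect_false(identical(simulate_cohort(seed = 6), co))

  expect_error(simulate_cohort(n_panel = 100, n_full_panel = 150), "n_full_panel")
  expect_error(simulate_cohort(n_total = 50, n_panel = 100), "n_panel")

  cfg <- attr(co, "generator_config")
  expect_equal(cfg$seed, 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_generator_config(co, path)
  expect_equal(jsonlite::read_json(path)$n_panel, 288)
})

test_that("per-component marginals converge to the configured targets", {
  co <- simulate_cohort(n_total = 20000, n_panel = 20000, n_full_panel = 20000,
                        n_tsh = 20000, n_outcome = 20000, seed = 30)
  p <- cluster_mixture_params()
  z75 <- stats::qnorm(0.75)
  for (cl in 1:3) {
    sub <- co[co$true_cluster == cl, ]
    expect_equal(stats::median(sub$tsh), p$tsh_median[cl], tolerance = 0.05)
    expect_equal(stats::median(sub$ft4), p$ft4_median[cl], tolerance = 0.03)
    # quartiles implied by the median + IQR-ratio parameterization
    sd_tsh <- log(p$tsh_q3[cl] / p$tsh_q1[cl]) / (2 * z75)
    sd_ft4 <- log(p$ft4_q3[cl] / p$ft4_q1[cl]) / (2 * z75)
    expect_equal(stats::quantile(sub$tsh, 0.25)[[1]],
                 p$tsh_median[cl] * exp(-z75 * sd_tsh), tolerance = 0.05)
    expect_equal(stats::quantile(sub$ft4, 0.75)[[1]],
                 p$ft4_median[cl] * exp(z75 * sd_ft4), tolerance = 0.05)
    # FT3 is produced through the deiodinase relation, so recomputing GD
    # from the panel recovers the drawn GD distribution (up to the 5%
    # multiplicative noise)
    gd <- spina_gd(sub$ft3, sub$ft4)
    expect_equal(stats::median(gd), p$gd_median[cl], tolerance = 0.05)
  }
  expect_equal(as.numeric(table(co$true_cluster) / 20000),
               c(0.27, 0.12, 0.61), tolerance = 0.05)
})

test_that("high-output FT4 medians over replicates stay inside the reported IQR", {
  meds <- vapply(1:20, function(s) {
    co <- simulate_cohort(seed = 100 + s)
    stats::median(co$ft4[co$true_cluster == 2], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(meds > 22.2 & meds < 28.6))
})

test_that("WMW power machinery: size equals level, large effects saturate, power grows with n", {
  size <- wmw_power(effect = 0, n_per_group = 50, reps = 2000, seed = 41)
  expect_lt(abs(size$power - 0.05), 0.02)

  big <- wmw_power(effect = 2, n_per_group = 50, reps = 300, seed = 42)
  expect_gt(big$power, 0.99)

  grid <- vapply(c(10, 25, 60), function(n) {
    wmw_power(effect = 0.8, n_per_group = n, reps = 400, seed = 43)$power
  }, numeric(1))
  expect_true(all(diff(grid) > -0.05))  # monotone within Monte-Carlo error
  expect_gt(grid[3], grid[1])

  expect_error(wmw_power(0, reps = 50), "reps")
})

test_that("the full pipeline runs end to end and is reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  suppressMessages(suppressWarnings({
    res1 <- run_pipeline(simulate = TRUE, seed = 14, rom_reps = 50,
                         k_range = 2:4, output_dir = dir1)
    res2 <- run_pipeline(simulate = TRUE, seed = 14, rom_reps = 50,
                         k_range = 2:4, output_dir = dir2)
  }))
  expect_s3_class(res1, "thyro_pipeline")
  expect_true(all(c("cohort", "flow", "comparisons", "cutoffs", "cox") %in%
                    names(res1)))
  expect_true("endotype" %in% names(res1$cohort))
  expect_true("cluster" %in% names(res1$cohort))

  # rerun with identical config and seed -> byte-identical artifacts
  f1 <- file.path(dir1, "cohort_annotated.csv")
  f2 <- file.path(dir2, "cohort_annotated.csv")
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(file.path(dir1, "flow.json")))

  # the survival stack ran: KM by cluster label or cutoff strata exist
  expect_true(!is.null(res1$km_cutoffs) && length(res1$km_cutoffs) > 0)
})
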