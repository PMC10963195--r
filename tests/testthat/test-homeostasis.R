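# Expected values below are frozen from hand evaluation of the closed
# forms with the default constants (binding term 1 + K41*TBG + K42*TTR =
# 6901; T3 binding term 1 + K30*TBG = 601).

test_that("SPINA-GT reproduces hand-evaluated values and the printed cluster medians", {
  expect_equal(spina_gt(1.0, 14.1), 4.01379, tolerance = 1e-5)
  expect_equal(spina_gt(0.9, 24.3), 7.48103, tolerance = 1e-5)
  expect_equal(spina_gt(2.8, 13.5), 2.03130, tolerance = 1e-5)

  # function-of-medians lands within 10% of the reported per-cluster
  # median secretory capacities
  gt <- spina_gt(c(2.8, 0.9, 1.0), c(13.5, 24.3, 14.1))
  expect_true(all(abs(gt - c(1.9, 7.6, 4.2)) / c(1.9, 7.6, 4.2) < 0.10))

  # linear in FT4, undefined at TSH = 0, NA-propagating
  expect_equal(spina_gt(1.7, 28), 2 * spina_gt(1.7, 14), tolerance = 1e-12)
  expect_true(is.na(spina_gt(0, 14)))
  expect_true(is.na(spina_gt(NA, 14)))
})

test_that("SPINA-GT is monotone: decreasing in TSH, increasing in FT4", {
  tsh_grid <- seq(0.1, 10, length.out = 25)
  ft4_grid <- seq(5, 40, length.out = 25)
  for (ft4 in c(8, 14, 25)) {
    expect_true(all(diff(spina_gt(tsh_grid, ft4)) < 0))
  }
  for (tsh in c(0.5, 1, 5)) {
    expect_true(all(diff(spina_gt(tsh, ft4_grid)) > 0))
  }
})

test_that("SPINA-GD reproduces hand-evaluated values and is linear in FT3", {
  expect_equal(spina_gd(4.0, 14.1), 26.23096, tolerance = 1e-5)
  # within 10% of the reported normal-output cluster median
  expect_lt(abs(spina_gd(4.0, 14.1) - 25.6) / 25.6, 0.10)
  expect_equal(spina_gd(2.25, 14.1), spina_gd(4.5, 14.1) / 2, tolerance = 1e-12)
  # decreasing in FT4 at fixed FT3 (substrate below the Michaelis constant)
  expect_lt(spina_gd(4.5, 24.3), spina_gd(4.5, 14.1))
  expect_true(is.na(spina_gd(4.0, 0)))
})

test_that("JTI and TTSI match their closed forms", {
  expect_equal(jostel_tsh_index(1.0, 0), 0)
  expect_equal(jostel_tsh_index(2.8, 13.5), 2.845369, tolerance = 1e-6)
  expect_equal(jostel_tsh_index(1.0, 14.1), 1.896450, tolerance = 1e-6)
  expect_true(is.na(jostel_tsh_index(0, 14)))

  k <- spina_constants()
  expect_equal(ttsi(1.0, k$ft4_upper_ref), 100)
  expect_equal(ttsi(0, 14), 0)
  expect_equal(ttsi(2.8, 13.5, spina_constants(ft4_upper_ref = 22)),
               171.8182, tolerance = 1e-6)
})

test_that("unit-dialect conversion before computation changes nothing", {
  tsh <- c(0.5, 1.2, 3.3)
  ft4_ngdl <- c(0.9, 1.09, 1.8)
  ft3_pgml <- c(2.1, 3.0, 4.0)
  gt_direct <- spina_gt(tsh, ft4_ngdl * 12.87)
  gd_direct <- spina_gd(ft3_pgml * 1.536, ft4_ngdl * 12.87)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(patient_id = c("a", "b", "c"), tsh = tsh,
                                  ft4 = ft4_ngdl, ft3 = ft3_pgml,
                                  died = FALSE, followup_days = 1), path)
  co <- read_cohort(path, unit_dialect = "conventional_ngdl_pgml")
  expect_equal(spina_gt(co$tsh, co$ft4), gt_direct, tolerance = 1e-12)
  expect_equal(spina_gd(co$ft3, co$ft4), gd_direct, tolerance = 1e-12)
})

test_that("empirical TFQI is centred, bounded and quantile-consistent", {
  # subject 5 sits at the median of both axes -> exactly 0
  tsh <- 1:9
  ft4 <- c(20, 12, 18, 13, 16, 19, 14, 17, 15)
  v <- tfqi(tsh, ft4)
  expect_equal(v[5], 0)
  expect_true(all(v >= -1 & v <= 1))

  set.seed(42)
  tsh <- rlnorm(101, 0, 0.5)
  ft4 <- rlnorm(101, log(14), 0.2)
  v <- tfqi(tsh, ft4)
  # rank-sum identity: cohort mean is 0 (exactly, absent ties)
  expect_equal(mean(v), 0, tolerance = 1e-12)
  # reduced central sensitivity (high FT4 quantile together with a high
  # TSH quantile) approaches +1 as n grows; the mirror image approaches -1
  j <- which.max(ft4)
  tsh[j] <- max(tsh) * 2
  expect_gt(tfqi(tsh, ft4)[j], 0.97)
  j2 <- which.min(ft4)
  tsh[j2] <- min(tsh) / 2
  expect_lt(tfqi(tsh, ft4)[j2], -0.97)
  expect_error(tfqi(1, 14), "at least 2")
})

test_that("parametric TFQI uses the Gaussian reference on ln TSH and FT4", {
  v <- tfqi(c(1, 14), c(14, 14), reference = "parametric",
            tsh_meanlog = 0, tsh_sdlog = 0.5, ft4_mean = 14, ft4_sd = 2)
  # subject at both reference centres: 0.5 - (1 - 0.5) = 0
  expect_equal(v[1], 0, tolerance = 1e-12)
  expect_error(tfqi(c(1, 2), c(14, 15), reference = "parametric"),
               "parametric")
})

test_that("levothyroxine gates the secretory capacity, never the other indices", {
  co <- add_thyroid_indices(tiny_cohort())
  on_lt <- which(co$on_levothyroxine)
  expect_true(all(is.na(co$spina_gt[on_lt])))
  expect_false(is.na(co$jti[on_lt]))   # tsh+ft4 present for p2
  expect_false(is.na(co$ttsi[on_lt]))
  # and more broadly on the generator
  sim <- add_thyroid_indices(simulate_cohort(seed = 4))
  expect_true(all(is.na(sim$spina_gt[sim$on_levothyroxine])))
  expect_true(all(sim$tfqi >= -1 & sim$tfqi <= 1, na.rm = TRUE))
})
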