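test_that("classification rules and their precedence match the pattern definitions", {
  r <- reference_ranges()  # TSH 0.4-4.0, FT4 10-23, FT3 3.1-6.8
  lab <- function(...) as.character(classify_endotype(...)$endotype)

  expect_equal(lab(0.1, 30), "primary_thyrotoxicosis")
  expect_equal(lab(1.2, 14, 2.0), "tacitus")
  expect_equal(lab(1.2, 14, 4.2), "normal")
  expect_equal(lab(6.0, 8.0), "primary_hypothyroidism")
  expect_equal(lab(5.0, 25, 4.5), "type2_allostatic")

  # thyrotoxicosis outranks TACITUS: suppressed TSH + high FT4 + low FT3
  expect_equal(lab(0.1, 30, 2.0), "primary_thyrotoxicosis")
  # elevated FT4 with in-range TSH: type 2 under the non-suppressed
  # default, unclassifiable under the strict elevated-TSH variant
  expect_equal(lab(1.2, 25, 4.5), "type2_allostatic")
  expect_equal(lab(1.2, 25, 4.5, type2_variant = "strict"), "unclassifiable")
  # but a reduced FT3 routes that panel to TACITUS instead
  expect_equal(lab(1.2, 25, 2.0), "tacitus")

  res <- classify_endotype(c(NA, 1.2), c(14, NA))
  expect_equal(as.character(res$endotype), rep("unclassifiable", 2))
  expect_equal(res$reason, rep("incomplete panel", 2))

  # normal by available evidence is flagged
  res <- classify_endotype(1.2, 14, NA)
  expect_equal(as.character(res$endotype), "normal")
  expect_match(res$reason, "available evidence")
})

test_that("labels form a partition and are invariant to unit conversion", {
  set.seed(7)
  n <- 300
  tsh <- rlnorm(n, 0, 1)
  ft4 <- rlnorm(n, log(15), 0.35)
  ft3 <- rlnorm(n, log(4), 0.3)
  res <- classify_endotype(tsh, ft4, ft3)
  expect_false(anyNA(res$endotype))
  expect_equal(length(res$endotype), n)

  # converting inputs between dialects before classification changes nothing
  res2 <- classify_endotype(tsh, (ft4 / 12.87) * 12.87, (ft3 / 1.536) * 1.536)
  expect_equal(res$endotype, res2$endotype)
})

test_that("endotype frequencies partition into survivor strata", {
  co <- add_endotype(simulate_cohort(seed = 8))
  freq <- endotype_frequencies(co, by = "died")
  overall <- dplyr::filter(freq, stratum == "overall")
  strat <- dplyr::filter(freq, stratum != "overall")
  expect_equal(sum(overall$pct), 100, tolerance = 1e-9)

  # stratified counts never exceed, and (for outcome-complete labels) sum
  # to at most, the overall counts
  sums <- dplyr::summarise(dplyr::group_by(strat, endotype),
                           n = sum(n), .groups = "drop")
  merged <- dplyr::left_join(overall, sums, by = "endotype",
                             suffix = c("_all", "_strat"))
  expect_true(all(merged$n_strat <= merged$n_all))

  # single-label cohort -> 100%
  one <- tibble::tibble(endotype = factor(rep("tacitus", 5),
                                          levels = levels(co$endotype)))
  f1 <- endotype_frequencies(one)
  expect_equal(f1$pct, 100)
  expect_equal(f1$n, 5L)
})

test_that("survivor-stratified class table reproduces the printed percentages", {
  # class counts among survivors (n=69) and non-survivors (n=38) as printed:
  # normal 21/5, tacitus 26/19, type2 10/2, thyrotoxicosis 10/11, hypo 2/1
  labels <- c(rep("normal", 21 + 5), rep("tacitus", 26 + 19),
              rep("type2_allostatic", 10 + 2),
              rep("primary_thyrotoxicosis", 10 + 11),
              rep("primary_hypothyroidism", 2 + 1))
  died <- c(rep(FALSE, 21), rep(TRUE, 5), rep(FALSE, 26), rep(TRUE, 19),
            rep(FALSE, 10), rep(TRUE, 2), rep(FALSE, 10), rep(TRUE, 11),
            rep(FALSE, 2), rep(TRUE, 1))
  co <- tibble::tibble(endotype = factor(labels), died = died)
  freq <- endotype_frequencies(co, by = "died")
  get <- function(lab, strat) freq$pct[freq$endotype == lab & freq$stratum == strat]
  expect_equal(round(get("normal", "died=TRUE")), 13)           # 5/38
  expect_equal(round(get("primary_thyrotoxicosis", "died=TRUE")), 29)  # 11/38
  expect_equal(round(get("normal", "died=FALSE")), 30)          # 21/69
})
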