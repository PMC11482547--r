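test_that("pearson correlation matches hand-evaluated values", {
  expect_equal(pearson_correlation(paired_series(1:4, c(10, 20, 30, 40), c(10, 20, 30, 40))), 1.0)
  expect_equal(pearson_correlation(paired_series(1:3, c(10, 20, 30), c(30, 20, 10))), -1.0)
  # product-moment formula by hand for x=(1,2,3), y=(1,2,4): 0.98198...
  expect_equal(pearson_correlation(paired_series(1:3, c(1, 2, 3), c(1, 2, 4))),
               0.9819805, tolerance = 1e-3)
  expect_error(pearson_correlation(paired_series(1:3, c(5, 5, 5), c(1, 2, 3))),
               class = "lumen_degenerate_error")
})

test_that("lin_ccc reproduces hand-evaluated and limiting cases", {
  x <- c(3, 7, 12, 20, 41)
  expect_equal(lin_ccc(x, x), 1.0)
  # rho = 1, population variances 2/3 each, mean shift 1 -> 2*(2/3)/(4/3+1)
  expect_equal(lin_ccc(c(0, 1, 2), c(1, 2, 3)), 4 / 7, tolerance = 1e-12)
  expect_error(lin_ccc(c(1, 1, 1), c(1, 2, 3)), class = "lumen_degenerate_error")
})

test_that("lin_ccc equals term-by-term formula evaluation on small integer series", {
  for (s in small_integer_series()) {
    expect_equal(lin_ccc(s$x, s$y), ccc_oracle(s$x, s$y), tolerance = 1e-12)
  }
})

test_that("concordance obeys Lin's inequality, symmetry and shift monotonicity", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      x <- runif(n, 0, 100)
      y <- pmin(pmax(x + rnorm(n, 0, 10), 0), 100)
      s <- paired_series(seq_len(n), x, y)
      expect_lte(abs(lin_ccc(s)), abs(pearson_correlation(s)) + 1e-12)
      swapped <- paired_series(seq_len(n), y, x)
      expect_equal(lin_ccc(swapped), lin_ccc(s), tolerance = 1e-12)
    }
  })
  # adding a constant offset degrades concordance, monotonically in |offset|
  x <- c(10, 25, 40, 55, 70, 85)
  shifts <- c(0, 2, 5, 10, 15)
  cccs <- vapply(shifts, function(c) lin_ccc(x, x + c), numeric(1))
  expect_equal(cccs[1], 1)
  expect_true(all(diff(cccs) < 0))
})

test_that("confidence intervals behave as an asymptotic z-transform interval", {
  ci0 <- ccc_confidence_interval(0, n = 30, level = 0.95)
  expect_equal(ci0[["ci_low"]], -ci0[["ci_high"]], tolerance = 1e-12)

  ci_small <- ccc_confidence_interval(0.9, n = 50, level = 0.95)
  ci_large <- ccc_confidence_interval(0.9, n = 500, level = 0.95)
  expect_lt(diff(ci_large), diff(ci_small))

  expect_equal(unname(ccc_confidence_interval(1, n = 50)), c(1, 1))
  expect_error(ccc_confidence_interval(0.5, n = 2), class = "lumen_degenerate_error")

  s <- coronary_series()
  summ <- agreement_summary(s)
  expect_lte(summ$ci_low, summ$ccc)
  expect_lte(summ$ccc, summ$ci_high)
  expect_lte(abs(summ$ccc), abs(summ$pearson))
})

test_that("a stratum covering everything reproduces the overall summary", {
  s <- coronary_series()
  overall <- agreement_summary(s)
  full <- stratified_agreement(s, 0, 100, membership = "eye")
  expect_equal(full$ccc, overall$ccc, tolerance = 1e-12)
  expect_equal(full$n, overall$n)
})

test_that("stratum membership rules subset as documented", {
  s <- coronary_series()
  for (rule in c("eye", "digital", "both", "either")) {
    got <- stratified_agreement(s, 60, 80, membership = rule)$n
    ine <- s$eye_percent >= 60 & s$eye_percent <= 80
    ind <- s$digital_percent >= 60 & s$digital_percent <= 80
    want <- sum(switch(rule, eye = ine, digital = ind,
                       both = ine & ind, either = ine | ind))
    expect_equal(got, want)
  }
  err <- tryCatch(stratified_agreement(s, 0, 5, membership = "eye"),
                  lumen_degenerate_error = function(e) e)
  expect_s3_class(err, "lumen_degenerate_error")
  expect_equal(err$n, 0L)
})

test_that("threshold discrepancies partition into upward and downward", {
  x <- c(10, 40, 60, 80)
  same <- paired_series(1:4, x, x)
  d0 <- threshold_discrepancies(same, 70)
  expect_length(d0$discrepant_sections, 0)

  withr::with_seed(5, {
    for (rep in 1:10) {
      n <- 30
      s <- paired_series(seq_len(n), runif(n, 0, 100), runif(n, 0, 100))
      d <- threshold_discrepancies(s, 70)
      expect_setequal(c(d$upward, d$downward), d$discrepant_sections)
      expect_length(intersect(d$upward, d$downward), 0)
      # straddle definition holds for every flagged pair
      flagged <- s[s$section_id %in% d$discrepant_sections, ]
      expect_true(all(pmin(flagged$eye_percent, flagged$digital_percent) <= 70 &
                        pmax(flagged$eye_percent, flagged$digital_percent) >= 70))
    }
  })
})

test_that("paired series validation rejects malformed input", {
  expect_error(paired_series(c(1, 1), c(10, 20), c(10, 20)),
               class = "lumen_validation_error")
  expect_error(paired_series(1:2, c(10, 101), c(10, 20)),
               class = "lumen_validation_error")
  expect_error(lin_ccc(paired_series("a", 50, 60)),
               class = "lumen_degenerate_error")
})
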