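# With microns_per_pixel = 1000 one pixel^2 is exactly 1 mm^2, which makes
# the mm^2 rules easy to pin down with unit-square geometry.
mm_ann <- function(ideal_mm2, residual_mm2, id = "t") {
  ideal <- vessel_polygon(c(0, ideal_mm2, ideal_mm2, 0), c(0, 0, 1, 1))
  res <- if (residual_mm2 > 0) {
    region_set(vessel_polygon(c(0, residual_mm2, residual_mm2, 0), c(0, 0, 1, 1)))
  } else {
    region_set()
  }
  vessel_annotation(id, ideal, res, microns_per_pixel = 1000)
}

test_that("percent occlusion and risk flags follow the area ratio", {
  m <- measure_stenosis(mm_ann(10, 2.5))
  expect_equal(m$ideal_area_mm2, 10)
  expect_equal(m$residual_area_mm2, 2.5)
  expect_equal(m$percent_occlusion_lo, 75.0)
  expect_true(m$hemodynamically_significant)  # 75 > 70
  expect_false(m$scd_supportive)              # strict: 75 is not > 75
  expect_true(m$high_risk_plaque)             # 2.5 < 4

  # residual identical to ideal, ideal >= 4 mm^2: fully patent, no flags
  ideal <- vessel_polygon(c(0, 10, 10, 0), c(0, 0, 1, 1))
  a <- vessel_annotation("patent", ideal, region_set(ideal), microns_per_pixel = 1000)
  m0 <- measure_stenosis(a)
  expect_equal(m0$percent_occlusion_lo, 0.0)
  expect_false(m0$hemodynamically_significant)
  expect_false(m0$scd_supportive)
  expect_false(m0$high_risk_plaque)

  # empty residual set: complete occlusion
  m100 <- measure_stenosis(mm_ann(10, 0))
  expect_equal(m100$percent_occlusion_lo, 100.0)
  expect_equal(m100$residual_area_mm2, 0)
})

test_that("risk thresholds are strict inequalities", {
  expect_equal(unname(classify_risk(70.0, residual_area_mm2 = 10)),
               c(FALSE, FALSE, FALSE))
  expect_equal(unname(classify_risk(76.0, residual_area_mm2 = 5)),
               c(TRUE, TRUE, FALSE))
  expect_equal(unname(classify_risk(99.0, residual_area_mm2 = 0.1)),
               c(TRUE, TRUE, TRUE))
  expect_equal(unname(classify_risk(75.0, residual_area_mm2 = 4)),
               c(TRUE, FALSE, FALSE)) # both boundaries excluded
})

test_that("residual overlaps and leakage are repaired, never rejected", {
  ideal <- vessel_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10))
  # two overlapping channels, one leaking outside the ideal contour
  res <- region_set(
    vessel_polygon(c(1, 4, 4, 1), c(1, 1, 4, 4)),
    vessel_polygon(c(2, 5, 5, 2), c(2, 2, 5, 5)),
    vessel_polygon(c(8, 12, 12, 8), c(8, 8, 12, 12))
  )
  a <- vessel_annotation("messy", ideal, res, microns_per_pixel = 1000)
  m <- measure_stenosis(a)
  # union(9 + 9 - 4) + clipped corner 4 = 18
  expect_equal(m$residual_area_mm2, 18, tolerance = 1e-6)
  expect_lte(m$residual_area_mm2, m$ideal_area_mm2)
})

test_that("percent residual and percent occlusion always sum to 100", {
  withr::with_seed(7, {
    for (rep in 1:8) {
      r_in <- runif(1, 5, 45)
      a <- vessel_annotation("p", circle_poly(50, 50, 50),
                             region_set(circle_poly(50, 50, r_in)),
                             microns_per_pixel = runif(1, 0.5, 20))
      m <- measure_stenosis(a)
      expect_equal(m$percent_residual + m$percent_occlusion_lo, 100)
    }
  })
})

test_that("uniform rescaling changes areas by s^2 but not the occlusion", {
  p_id <- circle_poly(0, 0, 40)
  p_res <- circle_poly(5, 0, 20)
  base <- measure_stenosis(vessel_annotation("b", p_id, region_set(p_res),
                                             microns_per_pixel = 4))
  s <- 3.7
  scaled <- measure_stenosis(vessel_annotation(
    "s",
    vessel_polygon(s * p_id$x, s * p_id$y),
    region_set(vessel_polygon(s * p_res$x, s * p_res$y)),
    microns_per_pixel = 4))
  expect_equal(scaled$ideal_area_mm2, s^2 * base$ideal_area_mm2, tolerance = 1e-9)
  expect_equal(scaled$percent_occlusion_lo, base$percent_occlusion_lo,
               tolerance = 1e-9)
})

test_that("degenerate inputs raise typed measurement errors", {
  expect_error(vessel_annotation("x", unit_square(), region_set(),
                                 microns_per_pixel = 0),
               class = "lumen_validation_error")
  expect_error(measure_stenosis("not an annotation"),
               class = "lumen_validation_error")
})
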