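test_that("a concentric channel at 75% occlusion has half the lamina radius", {
  v <- generate_vessel(vessel_spec("concentric", target_lo = 75,
                                   lamina_semi_axes = c(100, 100),
                                   lamina_center = c(128, 128), seed = 1))
  expect_equal(v$true_lo, 75, tolerance = 0.5)
  res <- v$annotation$residual_lumen[[1]]
  radii <- sqrt((res$x - 128)^2 + (res$y - 128)^2)
  expect_equal(mean(radii), 50, tolerance = 0.5) # (r/R)^2 = 0.25 forces r = R/2
})

test_that("extreme targets degenerate cleanly", {
  for (m in c("concentric", "eccentric_crescent", "slit", "recanalized")) {
    v0 <- generate_vessel(vessel_spec(m, target_lo = 0, seed = 2))
    # residual = ideal up to the polygon clipper's integer-grid resolution
    expect_equal(v0$true_lo, 0, tolerance = 1e-5)
    v100 <- generate_vessel(vessel_spec(m, target_lo = 100, seed = 2))
    expect_equal(v100$true_lo, 100)
    expect_length(v100$annotation$residual_lumen, 0L)
  }
  expect_error(vessel_spec("slit", target_lo = 30), class = "lumen_validation_error")
  expect_error(vessel_spec("recanalized", target_lo = 20),
               class = "lumen_validation_error")
})

test_that("generated geometry hits the analytic occlusion target", {
  cases <- rbind(
    expand.grid(morphology = c("concentric", "eccentric_crescent"),
                target = c(35, 55, 75, 90, 97), stringsAsFactors = FALSE),
    expand.grid(morphology = "slit",
                target = c(55, 75, 90, 97), stringsAsFactors = FALSE),
    # several large channels cannot be packed disjointly at low occlusion,
    # so recanalized targets stay in the high range the morphology supports
    expand.grid(morphology = "recanalized",
                target = c(80, 90, 97, 99), stringsAsFactors = FALSE))
  for (i in seq_len(nrow(cases))) {
    v <- generate_vessel(vessel_spec(cases$morphology[i],
                                     target_lo = cases$target[i],
                                     lamina_semi_axes = c(110, 95),
                                     lamina_center = c(130, 130),
                                     seed = 100 + i))
    expect_lt(abs(v$true_lo - cases$target[i]), 0.5)
  }
})

test_that("recanalized channels are equal-area and count as specified", {
  v <- generate_vessel(vessel_spec("recanalized", target_lo = 97,
                                   n_channels = 3, seed = 5))
  rs <- v$annotation$residual_lumen
  expect_length(rs, 3L)
  a_id <- polygon_area(v$annotation$ideal_lumen)
  areas <- vapply(rs, polygon_area, numeric(1))
  expect_equal(areas / a_id, rep(0.01, 3), tolerance = 1e-6)
})

test_that("generation, rendering and observer draws are seed-deterministic", {
  spec <- vessel_spec("recanalized", target_lo = 92, n_channels = 4,
                      noise_sd = 5, seed = 31)
  v1 <- generate_vessel(spec)
  v2 <- generate_vessel(spec)
  expect_identical(v1$annotation$residual_lumen, v2$annotation$residual_lumen)
  expect_identical(render_vessel(v1), render_vessel(v2))
  expect_identical(simulate_observer(rep(70, 10), "slit", seed = 9),
                   simulate_observer(rep(70, 10), "slit", seed = 9))
})

test_that("rendering produces the documented tonal structure", {
  v <- generate_vessel(vessel_spec("concentric", target_lo = 75, seed = 3))
  img <- render_vessel(v)
  expect_setequal(unique(as.integer(img)), c(30L, 130L, 200L, 235L))

  # pixel-counting oracle: bright fraction inside the ring ~ residual fraction
  inside <- img == 130L | img == 235L
  bright_frac <- sum(img == 235L) / sum(inside)
  expect_equal(bright_frac, 1 - v$true_lo / 100, tolerance = 0.01)
})

test_that("image files round-trip in both supported formats", {
  v <- generate_vessel(vessel_spec("slit", target_lo = 80, seed = 4))
  img <- render_vessel(v)
  for (ext in c(".png", ".tiff")) {
    path <- tempfile(fileext = ext)
    write_vessel_image(img, path)
    back <- read_vessel_image(path)
    expect_equal(unname(dim(back)), unname(dim(img)))
    expect_true(all(back == img))
  }
})

test_that("the observer model applies bias, noise, grid and clamping", {
  flat <- observer_model(bias_by_morphology = c(concentric = 0,
                                                eccentric_crescent = 0,
                                                slit = 0, recanalized = 0),
                         noise_sd_percent = 0, rounding_grid = 5)
  expect_equal(simulate_observer(c(62, 70, 99), "concentric", flat), c(60, 70, 100))

  slit_biased <- observer_model(noise_sd_percent = 0, rounding_grid = 5)
  expect_equal(simulate_observer(60, "slit", slit_biased), 70) # 60 + 8 -> grid 5
  # default biases: slit positive, polymorphous negative
  expect_gt(slit_biased$bias_by_morphology[["slit"]], 0)
  expect_lt(slit_biased$bias_by_morphology[["concentric"]], 0)

  noisy <- observer_model(bias_by_morphology = c(concentric = -8,
                                                 eccentric_crescent = -8,
                                                 slit = 8, recanalized = -8),
                          noise_sd_percent = 5, rounding_grid = 1)
  draws <- simulate_observer(rep(60, 200), "concentric", noisy, seed = 21)
  expect_lt(abs(mean(draws - 60 + 8)), 1) # noise is centred
  expect_true(all(draws >= 0 & draws <= 100))

  expect_error(observer_model(rounding_grid = 2), class = "lumen_validation_error")
  expect_error(simulate_observer(50, "spiral", flat), class = "lumen_validation_error")
})

test_that("simulated cohorts have the advertised shape and fidelity", {
  truth <- cohort_truth(sample_vessel_specs(50, seed = 77))
  expect_equal(nrow(truth), 50L)
  expect_true(all(truth$true_lo >= 0 & truth$true_lo <= 100))

  zero_model <- observer_model(bias_by_morphology = c(concentric = 0,
                                                      eccentric_crescent = 0,
                                                      slit = 0, recanalized = 0),
                               noise_sd_percent = 0, rounding_grid = 1)
  s0 <- generate_cohort(50, zero_model, seed = 77, truth = truth)
  expect_gte(lin_ccc(s0), 0.999)

  # noisier observers agree less, replicated over seeds
  for (seed in c(101, 202, 303)) {
    tr <- cohort_truth(sample_vessel_specs(120, seed = seed))
    ccc2 <- lin_ccc(generate_cohort(truth = tr, seed = seed,
                                    model = observer_model(noise_sd_percent = 2)))
    ccc15 <- lin_ccc(generate_cohort(truth = tr, seed = seed,
                                     model = observer_model(noise_sd_percent = 15)))
    expect_lt(ccc15, ccc2)
  }
})

test_that("injected observer biases are recoverable by regression", {
  # keep targets away from the 100% boundary: clamping censors the +8 slit
  # bias when true occlusion + bias + noise exceeds 100
  specs <- withr::with_seed(4040, {
    morph <- rep(c("concentric", "eccentric_crescent", "slit", "recanalized"),
                 length.out = 500)
    lapply(seq_along(morph), function(i) {
      lo <- if (morph[i] == "recanalized") runif(1, 80, 85) else runif(1, 55, 80)
      vessel_spec(morph[i], target_lo = lo,
                  seed = sample.int(.Machine$integer.max - 1L, 1))
    })
  })
  truth <- cohort_truth(specs)
  model <- observer_model(noise_sd_percent = 5, rounding_grid = 1)
  s <- generate_cohort(truth = truth, model = model, seed = 4040)
  diffs <- s$eye_percent - s$digital_percent
  fit <- stats::lm(diffs ~ 0 + factor(truth$morphology))
  est <- stats::coef(fit)
  names(est) <- sub("factor\\(truth\\$morphology\\)", "", names(est))
  for (m in names(model$bias_by_morphology)) {
    expect_lt(abs(est[[m]] - model$bias_by_morphology[[m]]), 1)
  }
})
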