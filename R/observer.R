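#' Simulated pathologist observer
#'
#' Visual estimation of stenosis is systematically shape-dependent:
#' residual lumens with concentric or eccentric polymorphous shapes tend to
#' be under-estimated by eye relative to morphometry, while slit-like
#' lumens tend to be over-estimated. The observer model is an additive
#' per-morphology bias (percentage points of occlusion) plus Gaussian
#' noise, rounded to the observer's reporting grid and clamped to
#' `[0, 100]`. The default magnitudes (+/- 8 pp, noise sd 5 pp, 5% grid)
#' are package parameters chosen to be of the order reported for trained
#' observers, not measured constants.
#'
#' @param bias_by_morphology Named numeric vector of additive biases with
#'   entries for all four morphologies; by default slit is positive and the
#'   polymorphous shapes negative.
#' @param noise_sd_percent Non-negative noise standard deviation (pp).
#' @param rounding_grid Reporting grid in percent: 1 or 5.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(bias_by_morphology = c(concentric = -8,
                                                  eccentric_crescent = -8,
                                                  slit = 8,
                                                  recanalized = -8),
                           noise_sd_percent = 5,
                           rounding_grid = 5L) {
  need <- c("concentric", "eccentric_crescent", "slit", "recanalized")
  if (!all(need %in% names(bias_by_morphology))) {
    abort_validation("bias_by_morphology needs entries for all four morphologies")
  }
  if (!is.finite(noise_sd_percent) || noise_sd_percent < 0) {
    abort_validation("noise_sd_percent must be non-negative")
  }
  rounding_grid <- as.integer(rounding_grid)
  if (!rounding_grid %in% c(1L, 5L)) {
    abort_validation("rounding_grid must be 1 or 5 percent")
  }
  structure(list(bias_by_morphology = bias_by_morphology[need],
                 noise_sd_percent = noise_sd_percent,
                 rounding_grid = rounding_grid),
            class = "observer_model")
}

#' Draw simulated eye estimates for known occlusions
#'
#' `eye = clamp(round_to_grid(true_lo + bias[morphology] + N(0, noise_sd)))`.
#' Vectorized over `true_lo` (with `morphology` recycled); one seeded
#' generator per call, no global RNG state is disturbed.
#'
#' @param true_lo Numeric vector of true percent occlusions.
#' @param morphology Morphology class(es) of the sections.
#' @param model An [observer_model()].
#' @param seed Integer seed.
#' @return Numeric vector of simulated eye estimates in `[0, 100]`.
#' @export
simulate_observer <- function(true_lo, morphology, model = observer_model(), seed = 1L) {
  if (!inherits(model, "observer_model")) abort_validation("expected an observer_model")
  morphology <- rep_len(as.character(morphology), length(true_lo))
  unknown <- setdiff(unique(morphology), names(model$bias_by_morphology))
  if (length(unknown)) {
    abort_validation(paste0("unknown morphology: ", paste(unknown, collapse = ", ")))
  }
  bias <- unname(model$bias_by_morphology[morphology])
  noise <- if (model$noise_sd_percent > 0) {
    withr::with_seed(as.integer(seed),
                     stats::rnorm(length(true_lo), 0, model$noise_sd_percent))
  } else {
    numeric(length(true_lo))
  }
  est <- true_lo + bias + noise
  g <- model$rounding_grid
  est <- g * round(est / g)
  pmin(pmax(est, 0), 100)
}

#' Sample synthetic vessel specifications for a cohort
#'
#' Morphologies are drawn uniformly from the four classes; target
#' occlusions are uniform over the range each morphology supports
#' (`[30, 99]` for concentric and crescentic vessels — the span seen in
#' autopsy series — `[50, 99]` for slits, `[80, 99]` for recanalized
#' plaques, whose channels must stay small enough to place); lamina
#' semi-axes vary around 100 px with mild ellipticity; recanalized vessels
#' get 1-4 channels. Deterministic given `seed`.
#'
#' @param n Number of vessels.
#' @param seed Integer seed.
#' @param noise_sd Rendering noise passed through to each spec.
#' @return A list of `n` [vessel_spec()] objects.
#' @export
sample_vessel_specs <- function(n, seed = 1L, noise_sd = 0) {
  n <- as.integer(n)
  if (is.na(n) || n < 1) abort_validation("n must be a positive integer")
  withr::with_seed(as.integer(seed), {
    morph <- sample(c("concentric", "eccentric_crescent", "slit", "recanalized"),
                    n, replace = TRUE)
    lo_min <- c(concentric = 30, eccentric_crescent = 30, slit = 50, recanalized = 80)
    lo <- stats::runif(n, lo_min[morph], 99)
    a <- stats::runif(n, 80, 120)
    b <- a * stats::runif(n, 0.85, 1)
    k <- sample(1:4, n, replace = TRUE)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      vessel_spec(morphology = morph[i], target_lo = lo[i],
                  lamina_semi_axes = c(a[i], b[i]),
                  lamina_center = c(140, 140),
                  n_channels = k[i],
                  noise_sd = noise_sd,
                  seed = seeds[i])
    })
  })
}

#' Ground-truth cohort: generate vessels and measure them
#'
#' @param specs A list of [vessel_spec()]s, e.g. from
#'   [sample_vessel_specs()].
#' @return A `data.frame` with `section_id`, `morphology`, `true_lo`
#'   (the digitally measured occlusion of each generated annotation), and
#'   the generated vessels in attribute `"vessels"`.
#' @export
cohort_truth <- function(specs) {
  vessels <- lapply(specs, generate_vessel)
  df <- data.frame(
    section_id = sprintf("S%03d", seq_along(vessels)),
    morphology = vapply(vessels, function(v) v$spec$morphology, character(1)),
    true_lo = vapply(vessels, function(v) v$true_lo, numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(df, "vessels") <- vessels
  df
}

#' Simulate a paired eye/digital cohort
#'
#' The synthetic analogue of a paired study table: the digital column is
#' the measured occlusion of each generated vessel and the eye column the
#' simulated observer's estimate. Reproducible given `seed`.
#'
#' @param n Number of vessels.
#' @param model An [observer_model()].
#' @param seed Integer seed for both vessel sampling and observer noise.
#' @param truth Optionally a precomputed [cohort_truth()] table, so that
#'   several observer models can be applied to the same vessels.
#' @return A [paired_series()] (digital = measured, eye = simulated).
#' @export
generate_cohort <- function(n = 50, model = observer_model(), seed = 1L, truth = NULL) {
  if (is.null(truth)) {
    truth <- cohort_truth(sample_vessel_specs(n, seed = seed))
  }
  # distinct stream for the observer so its noise is not entangled with the
  # spec-sampling draws; kept below 2^31
  obs_seed <- (as.integer(seed) + 500009L) %% .Machine$integer.max
  eye <- simulate_observer(truth$true_lo, truth$morphology, model, seed = obs_seed)
  paired_series(truth$section_id, eye, truth$true_lo)
}
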