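#' Parametric specification of a synthetic arterial cross-section
#'
#' Describes one simulated elastic-stained coronary section: the internal
#' elastic lamina as an ellipse (semi-axes in pixels), one of four residual
#' lumen morphologies seen in sub-occluded arteries, a target percent lumen
#' occlusion, the scan calibration, and the image noise level. The four
#' morphologies are: `concentric` (annular plaque, central channel),
#' `eccentric_crescent` (plaque growing from one wall, crescent-shaped
#' channel), `slit` (a thin slit-like channel, only meaningful for
#' occlusions of at least 50%), and `recanalized` (several small
#' recanalization channels through an occlusive plaque, at least 50%
#' occlusion so the channels stay placeable).
#'
#' @param morphology One of `"concentric"`, `"eccentric_crescent"`,
#'   `"slit"`, `"recanalized"`.
#' @param target_lo Target percent lumen occlusion in `[0, 100]`.
#' @param lamina_semi_axes Ellipse semi-axes (px), each at least 20 so the
#'   half-pixel contour discretization stays well below the generator's
#'   0.5-percentage-point accuracy contract.
#' @param lamina_center Ellipse centre (px), image convention.
#' @param n_channels Number of recanalization channels (recanalized only).
#' @param microns_per_pixel Calibration; the default 4 um/px corresponds to
#'   a typical 20x scan.
#' @param noise_sd Gaussian intensity noise (8-bit grey levels) added when
#'   rendering.
#' @param seed Integer seed; generation, rendering and observer draws are
#'   deterministic given the spec and this seed.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(morphology = c("concentric", "eccentric_crescent",
                                       "slit", "recanalized"),
                        target_lo = 75,
                        lamina_semi_axes = c(100, 100),
                        lamina_center = c(128, 128),
                        n_channels = 3L,
                        microns_per_pixel = 4,
                        noise_sd = 0,
                        seed = 1L) {
  morphology <- match.arg(morphology)
  if (!is.finite(target_lo) || target_lo < 0 || target_lo > 100) {
    abort_validation("target_lo must lie in [0, 100]")
  }
  if (morphology %in% c("slit", "recanalized") && target_lo > 0 && target_lo < 50) {
    abort_validation(sprintf(
      "target_lo = %g is not attainable with %s morphology (needs >= 50 or exactly 0)",
      target_lo, morphology))
  }
  if (length(lamina_semi_axes) != 2 || any(!is.finite(lamina_semi_axes)) ||
      any(lamina_semi_axes < 20)) {
    abort_validation("lamina_semi_axes must be two finite values >= 20 px")
  }
  if (length(lamina_center) != 2 || any(!is.finite(lamina_center))) {
    abort_validation("lamina_center must be two finite coordinates")
  }
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1) {
    abort_validation("n_channels must be a positive integer")
  }
  if (!is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    abort_validation("microns_per_pixel must be strictly positive")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    abort_validation("noise_sd must be non-negative")
  }
  structure(
    list(morphology = morphology, target_lo = target_lo,
         lamina_semi_axes = as.numeric(lamina_semi_axes),
         lamina_center = as.numeric(lamina_center),
         n_channels = n_channels,
         microns_per_pixel = microns_per_pixel,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "vessel_spec"
  )
}

ellipse_polygon <- function(center, semi, n = 256L, phase = 0) {
  t <- phase + 2 * pi * (seq_len(n) - 1) / n
  structure(list(x = center[1] + semi[1] * cos(t),
                 y = center[2] + semi[2] * sin(t)),
            class = "vessel_polygon")
}

# Stadium (rectangle with semicircular caps) of total rectangular length L
# and width w, centred at `center`, horizontal.
stadium_polygon <- function(center, L, w, n_arc = 64L) {
  r <- w / 2
  t_right <- seq(-pi / 2, pi / 2, length.out = n_arc)
  t_left <- seq(pi / 2, 3 * pi / 2, length.out = n_arc)
  x <- c(center[1] + L / 2 + r * cos(t_right), center[1] - L / 2 + r * cos(t_left))
  y <- c(center[2] + r * sin(t_right), center[2] + r * sin(t_left))
  structure(list(x = x, y = y), class = "vessel_polygon")
}

clip_area <- function(subject, clip, op) {
  out <- polyclip::polyclip(list(list(x = subject$x, y = subject$y)),
                            list(list(x = clip$x, y = clip$y)), op = op)
  sum(vapply(out, function(q) abs(shoelace_area(q)), numeric(1)))
}

#' Generate a ground-truth synthetic vessel annotation
#'
#' Constructs the ideal-lumen ellipse and a residual-lumen geometry whose
#' measured occlusion matches `spec$target_lo`: the concentric channel is a
#' scaled copy of the lamina (exact), the crescent and slit widths are
#' solved by root-finding on the actual polygon areas (exact to the root
#' tolerance), and recanalized channels are equal-area polygonal discs
#' placed by seeded rejection sampling inside the lamina with a
#' non-overlap gap. A target of 0 degenerates to residual = ideal for every
#' morphology; a target of 100 yields an empty region set.
#'
#' @param spec A [vessel_spec()].
#' @return A list with `annotation` (a [vessel_annotation()]), `true_lo`
#'   (the measured occlusion of that annotation, within 0.5 percentage
#'   points of the target) and `spec`.
#' @export
generate_vessel <- function(spec) {
  if (!inherits(spec, "vessel_spec")) abort_validation("expected a vessel_spec")
  ctr <- spec$lamina_center
  ab <- spec$lamina_semi_axes
  ideal <- ellipse_polygon(ctr, ab)
  a_id <- polygon_area(ideal)
  lo <- spec$target_lo
  target_res <- a_id * (1 - lo / 100)

  residual <-
    if (lo >= 100) {
      region_set()
    } else if (lo <= 0) {
      region_set(ideal)
    } else {
      switch(spec$morphology,
        concentric = {
          s <- sqrt(1 - lo / 100)
          region_set(structure(list(x = ctr[1] + s * (ideal$x - ctr[1]),
                                    y = ctr[2] + s * (ideal$y - ctr[2])),
                               class = "vessel_polygon"))
        },
        eccentric_crescent = {
          # plaque modelled as a disc biting in from one wall; the residual
          # is what the bite leaves of the lumen
          bite_ctr <- c(ctr[1] + 0.88 * ab[1], ctr[2])
          f <- function(rd) {
            bite <- ellipse_polygon(bite_ctr, c(rd, rd), n = 192L)
            clip_area(ideal, bite, "minus") - target_res
          }
          rd <- stats::uniroot(f, c(1e-6, 3 * ab[1]), tol = 1e-7)$root
          bite <- ellipse_polygon(bite_ctr, c(rd, rd), n = 192L)
          out <- polyclip::polyclip(list(list(x = ideal$x, y = ideal$y)),
                                    list(list(x = bite$x, y = bite$y)), op = "minus")
          from_polyclip(out)
        },
        slit = {
          L <- ab[1]
          f <- function(w) {
            clip_area(stadium_polygon(ctr, L, w), ideal, "intersection") - target_res
          }
          w <- stats::uniroot(f, c(1e-6, 2 * ab[2]), tol = 1e-7)$root
          out <- polyclip::polyclip(
            list(list(x = stadium_polygon(ctr, L, w)$x, y = stadium_polygon(ctr, L, w)$y)),
            list(list(x = ideal$x, y = ideal$y)), op = "intersection")
          from_polyclip(out)
        },
        recanalized = place_channels(spec, ideal, target_res)
      )
    }

  ann <- vessel_annotation(sprintf("synthetic_%s_seed%d", spec$morphology, spec$seed),
                           ideal, residual,
                           microns_per_pixel = spec$microns_per_pixel)
  m <- measure_stenosis(ann)
  if (abs(m$percent_occlusion_lo - lo) > 0.5) {
    abort_generation(sprintf(
      "generated %s vessel missed its target occlusion (%.2f vs %.2f)",
      spec$morphology, m$percent_occlusion_lo, lo))
  }
  list(annotation = ann, true_lo = m$percent_occlusion_lo, spec = spec)
}

# Equal-area channel discs, seeded rejection sampling, pairwise gap and
# full containment in the lamina ellipse.
place_channels <- function(spec, ideal, target_res, gap = 6, margin = 2) {
  k <- spec$n_channels
  m <- 96L
  a_k <- target_res / k
  # radius of an m-gon with area a_k
  r <- sqrt(2 * a_k / (m * sin(2 * pi / m)))
  ab <- spec$lamina_semi_axes
  ctr <- spec$lamina_center
  free <- ab - r - margin
  if (any(free <= 0)) {
    abort_generation(sprintf(
      "recanalized target_lo = %g with %d channel(s) needs channels larger than the lamina",
      spec$target_lo, k))
  }
  centers <- withr::with_seed(spec$seed, {
    pts <- matrix(NA_real_, k, 2)
    placed <- 0L
    tries <- 0L
    while (placed < k && tries < 5000L) {
      tries <- tries + 1L
      u <- sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      cand <- c(ctr[1] + free[1] * u * cos(th), ctr[2] + free[2] * u * sin(th))
      ok <- placed == 0L ||
        all(sqrt((pts[seq_len(placed), 1] - cand[1])^2 +
                 (pts[seq_len(placed), 2] - cand[2])^2) >= 2 * r + gap)
      if (ok) {
        placed <- placed + 1L
        pts[placed, ] <- cand
      }
    }
    if (placed < k) {
      abort_generation(sprintf(
        "could not place %d non-overlapping channels for target_lo = %g (seed %d)",
        k, spec$target_lo, spec$seed))
    }
    pts
  })
  region_set(lapply(seq_len(k), function(i) {
    ellipse_polygon(centers[i, ], c(r, r), n = m)
  }))
}
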