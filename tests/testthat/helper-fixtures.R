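# Shared fixtures and independent oracles.

unit_square <- function(dx = 0, dy = 0, side = 1) {
  vessel_polygon(c(0, side, side, 0) + dx, c(0, 0, side, side) + dy)
}

circle_poly <- function(cx, cy, r, n = 256) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  vessel_polygon(cx + r * cos(t), cy + r * sin(t))
}

# Term-by-term evaluation of the concordance formula
# 2 * rho * sd_x * sd_y / (var_x + var_y + (mean_x - mean_y)^2)
# with population moments; kept deliberately independent of lin_ccc().
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  var_x <- sum((x - mx)^2) / n
  var_y <- sum((y - my)^2) / n
  rho <- sum((x - mx) * (y - my)) / n / (sqrt(var_x) * sqrt(var_y))
  2 * rho * sqrt(var_x) * sqrt(var_y) / (var_x + var_y + (mx - my)^2)
}

# A fixed battery of small-integer paired series of length 2..6 with
# non-degenerate columns, for oracle-equivalence checks.
small_integer_series <- function(n_cases = 150, seed = 424243) {
  withr::with_seed(seed, {
    out <- list()
    while (length(out) < n_cases) {
      len <- sample(2:6, 1)
      x <- sample(0:10, len, replace = TRUE)
      y <- sample(0:10, len, replace = TRUE)
      if (stats::var(x) > 0 && stats::var(y) > 0) {
        out[[length(out) + 1L]] <- list(x = x, y = y)
      }
    }
    out
  })
}

measure_lo <- function(annotation) {
  measure_stenosis(annotation)$percent_occlusion_lo
}
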