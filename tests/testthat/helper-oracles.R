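# Independent oracles used by the tests; none of these call package fitters.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Closed-form Rice mean via the Laguerre-function expression, evaluated with
# exponentially scaled Bessel functions for numerical stability.
rice_mean <- function(v, sigma) {
  x <- -(v^2) / (2 * sigma^2)
  t <- -x / 2
  # L_{1/2}(x) = e^{x/2} [ (1-x) I0(-x/2) - x I1(-x/2) ]; e^{x/2} I(t) = scaled I
  lag <- (1 - x) * besselI(t, 0, expon.scaled = TRUE) -
    x * besselI(t, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * lag
}

# Brute-force grid + golden-section refinement of the log-domain SSE over the
# relaxation time, with the amplitude profiled out analytically.
oracle_monoexp_t <- function(signals, times_ms, t_range = c(1, 500)) {
  y <- log(signals)
  sse <- function(t) {
    z <- y + times_ms / t
    sum((z - mean(z))^2)
  }
  grid <- seq(t_range[1], t_range[2], by = 0.25)
  vals <- vapply(grid, sse, 0)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  stats::optimize(sse, c(lo, hi), tol = 1e-12)$minimum
}

# Small phantom configuration used throughout the unit tests.
small_config <- function(...) {
  phantom_config(grid_dim = c(48L, 48L, 3L), ...)
}

water_voxels <- function(phantom) {
  tt <- phantom$tissue_table
  phantom$labels %in% tt$id[tt$fat_fraction == 0 & tt$proton_density > 0]
}
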