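# Independent oracle for the tight-binding equilibrium: bisection
# root-finding of (a - c)(x - c) = kd * c on [0, min(a, x)]. Kept free of
# any code path used by solve_bound_complex().
bisect_bound <- function(a, x, kd, iter = 200) {
  f <- function(cc) (a - cc) * (x - cc) - kd * cc
  lo <- 0
  hi <- min(a, x)
  if (hi == 0) return(0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# A noiseless generator config for construction-level checks.
quiet_config <- function(seed = 1L, ...) {
  generator_config(seed = seed, chromatogram_noise_sd = 0,
                   sensorgram_noise_sd = 0, densitometry_cv = 0,
                   titration_cv = 0, lba_cv = 0, ...)
}

# Spike a single unit-area Gaussian into a chromatogram grid.
gaussian_trace <- function(center, sigma, area = 1,
                           time_range = c(8, 21), dt = 0.01) {
  t <- seq(time_range[1], time_range[2], by = dt)
  chromatogram(t, area * dnorm(t, center, sigma))
}
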