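# Independent quadrature oracle for the expected discounted value under
# zero-censored Gaussian delay noise: the point mass at 0 contributes v(0) = 1,
# the positive part is integrated against the normal density.
quad_edv <- function(t, alpha, beta, k, scale = "sd") {
  s <- if (scale == "sd") alpha + beta * t else sqrt(alpha + beta * t)
  if (s == 0) {
    return(1 / (1 + k * t))
  }
  # finite +/- 12 sd window: a semi-infinite domain lets integrate() miss
  # narrow density spikes entirely
  pos <- stats::integrate(function(x) stats::dnorm(x, t, s) / (1 + k * x),
                          max(0, t - 12 * s), t + 12 * s,
                          rel.tol = 1e-10)$value
  stats::pnorm(0, t, s) + pos
}

# Noise-free single-peaked response curve sampled on the probe-window bins.
gaussian_curve <- function(mu, sigma, baseline = 0, amplitude = 1,
                           window = 135, bin_width = 0.5) {
  bin_time <- seq(bin_width / 2, window - bin_width / 2, by = bin_width)
  tibble::tibble(
    bin_time = bin_time,
    mean_count = baseline + amplitude * exp(-(bin_time - mu)^2 / (2 * sigma^2))
  )
}

# Small cohort spec used where full cohort size is not the point.
tiny_spec <- function(...) {
  cohort_spec(n_birds = 4, n_families = 2, n_probe_trials = 8,
              probe_days = 4, n_samples_valuation = 2000,
              n_choice_trials = 100, ...)
}
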