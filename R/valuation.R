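#' Hyperbolic discount function
#'
#' Value of a unit reward delivered after delay `t` under hyperbolic
#' discounting, `v(t) = 1 / (1 + k t)`. With `k = 0` the function is
#' constant at 1 (no devaluation with delay).
#'
#' @param t Delay in seconds. Vectorised. Must satisfy `t > -1/k` when
#'   `k > 0` so the hyperbola's pole is avoided; typical use has `t >= 0`.
#' @param k Discount rate in 1/seconds, `k >= 0`. The default 0.54 is an
#'   empirical estimate for European starlings.
#' @return Numeric vector of discounted values in `(0, 1]` for `t >= 0`.
#' @examples
#' discount(c(0, 3, 8))
#' discount(100, k = 0)
#' @export
discount <- function(t, k = 0.54) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    abort("`k` must be a single finite number >= 0.")
  }
  if (!is.numeric(t) || any(!is.finite(t))) {
    abort("`t` must be finite numeric.")
  }
  if (k > 0 && any(t <= -1 / k)) {
    abort(sprintf("`t` must exceed -1/k = %.4g (pole of the hyperbola).", -1 / k))
  }
  1 / (1 + k * t)
}

# Standard deviation of the perceived-duration distribution at true delay t.
# The noise scale alpha + beta * t is interpreted as an sd by default; the
# "variance" interpretation takes its square root.
perception_sd <- function(t, alpha, beta, scale = c("sd", "variance")) {
  scale <- match.arg(scale)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0) {
    abort("`alpha` (fixed imprecision) must be a single finite number >= 0 for generative use.")
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0) {
    abort("`beta` (proportional imprecision) must be a single finite number >= 0 for generative use.")
  }
  s <- alpha + beta * t
  if (any(s < 0)) abort("Noise scale alpha + beta * t is negative over the requested delays.")
  if (scale == "variance") sqrt(s) else s
}

#' Sample perceived durations under a noisy internal clock
#'
#' Draws perceived durations for a true delay `t` from
#' `Normal(mean = t, sd = alpha + beta * t)` (or `sd = sqrt(alpha + beta * t)`
#' under the variance interpretation). Perceived durations below zero are
#' truncated to zero: negative delays are physically impossible, and censoring
#' keeps the draw count (and hence seeded reproducibility) fixed.
#'
#' @param t True delay, seconds (single value).
#' @param alpha Fixed imprecision: noise independent of the delay, seconds.
#' @param beta Proportional imprecision: noise per second of delay,
#'   dimensionless.
#' @param n Number of draws.
#' @param scale Whether `alpha + beta * t` is the standard deviation
#'   (`"sd"`, default) or the variance of perceived duration.
#' @param seed Optional integer seed; when supplied the caller's RNG state is
#'   left untouched.
#' @return Numeric vector of `n` non-negative perceived durations.
#' @examples
#' sample_perceived(8, alpha = 1, beta = 0.25, n = 5, seed = 1)
#' @export
sample_perceived <- function(t, alpha, beta, n,
                             scale = c("sd", "variance"), seed = NULL) {
  scale <- match.arg(scale)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t)) abort("`t` must be a single finite number.")
  if (!is.numeric(n) || length(n) != 1L || n < 1) abort("`n` must be a count >= 1.")
  s <- perception_sd(t, alpha, beta, scale)
  with_seed_maybe(seed, {
    if (s == 0) rep(t, n) else pmax(rnorm(n, mean = t, sd = s), 0)
  })
}

# Monte-Carlo mean discounted value with its standard error.
edv_mc <- function(t, alpha, beta, k, n_samples, scale = "sd") {
  draws <- sample_perceived(t, alpha, beta, n_samples, scale = scale)
  v <- discount(draws, k)
  list(value = mean(v), se = stats::sd(v) / sqrt(n_samples))
}

#' Expected discounted value of a delayed reward under timing noise
#'
#' The subjective value of a unit reward after true delay `t` for an
#' individual whose perception of `t` is noisy: the Monte-Carlo mean of the
#' hyperbolic discount function over perceived durations. Because
#' `v(t) = 1/(1 + k t)` is convex, Jensen's inequality makes this mean
#' exceed `discount(t)` whenever the clock is noisy and `k > 0`.
#'
#' @inheritParams sample_perceived
#' @param k Discount rate, 1/seconds.
#' @param n_samples Monte-Carlo draws (default 100,000).
#' @return A single value; the Monte-Carlo standard error is attached as
#'   attribute `"mc_se"`.
#' @examples
#' expected_discounted_value(8, alpha = 0, beta = 0, k = 0.54, seed = 1)
#' @export
expected_discounted_value <- function(t, alpha, beta, k = 0.54,
                                      n_samples = 1e5,
                                      scale = c("sd", "variance"),
                                      seed = NULL) {
  scale <- match.arg(scale)
  res <- with_seed_maybe(seed, edv_mc(t, alpha, beta, k, n_samples, scale))
  structure(res$value, mc_se = res$se)
}

#' Relative valuation of a smaller-sooner versus larger-later reward
#'
#' The core model quantity: how much a noisy timer inflates the value of a
#' smaller-sooner (SS) option relative to a larger-later (LL) option,
#' normalised to a perfectly precise (noiseless) timer. Writing `E[v(t)]`
#' for the noisy expected discounted value, the statistic is
#' `(E[v(ss)] / E[v(ll)]) / (v(ss) / v(ll))`, which equals 1 for a noiseless
#' clock and exceeds 1 when noise favours the sooner option. Reward
#' magnitudes cancel under this double-ratio normalisation.
#'
#' @param alpha,beta Fixed and proportional imprecision (see
#'   [sample_perceived()]).
#' @param ss_delay,ll_delay Delays to the smaller-sooner and larger-later
#'   rewards, seconds; `0 < ss_delay < ll_delay`.
#' @inheritParams expected_discounted_value
#' @return Relative valuation (dimensionless, > 0) with attribute `"mc_se"`
#'   (delta-method Monte-Carlo standard error).
#' @examples
#' relative_valuation(alpha = 2, beta = 0.01, seed = 1)
#' @export
relative_valuation <- function(alpha, beta, ss_delay = 3, ll_delay = 8,
                               k = 0.54, n_samples = 1e5,
                               scale = c("sd", "variance"), seed = NULL) {
  scale <- match.arg(scale)
  if (!(ss_delay > 0 && ll_delay > ss_delay)) {
    abort("Require 0 < ss_delay < ll_delay.")
  }
  res <- with_seed_maybe(seed, {
    ss <- edv_mc(ss_delay, alpha, beta, k, n_samples, scale)
    ll <- edv_mc(ll_delay, alpha, beta, k, n_samples, scale)
    list(ss = ss, ll = ll)
  })
  base <- discount(ss_delay, k) / discount(ll_delay, k)
  value <- (res$ss$value / res$ll$value) / base
  se <- value * sqrt((res$ss$se / res$ss$value)^2 + (res$ll$se / res$ll$value)^2)
  structure(value, mc_se = se)
}

#' Relative-valuation surface over a grid of imprecision parameters
#'
#' Evaluates [relative_valuation()] on the Cartesian product of `alpha` and
#' `beta` values, giving the model's predicted impulsivity landscape: at low
#' proportional imprecision, raising the fixed component inflates the
#' smaller-sooner option's relative value (more impulsive), while raising the
#' proportional component deflates it.
#'
#' @param alpha,beta Numeric vectors of fixed / proportional imprecision
#'   values; all entries must be `>= 0`.
#' @inheritParams relative_valuation
#' @return A tibble of class `"valuation_surface"` with columns `alpha`,
#'   `beta`, `relative_value`, `mc_se`, and attributes recording `k`, the
#'   scenario delays, `n_samples` and `seed`. Deterministic given `seed`.
#' @examples
#' prediction_surface(alpha = c(0, 2), beta = c(0.1, 1), n_samples = 1e3, seed = 1)
#' @export
prediction_surface <- function(alpha, beta, ss_delay = 3, ll_delay = 8,
                               k = 0.54, n_samples = 1e5,
                               scale = c("sd", "variance"), seed = NULL) {
  scale <- match.arg(scale)
  if (length(alpha) < 1 || length(beta) < 1) abort("Grids must be non-empty.")
  grid <- tidyr::expand_grid(alpha = as.numeric(alpha), beta = as.numeric(beta))
  bad <- which(grid$alpha < 0 | grid$beta < 0)
  if (length(bad)) {
    abort(sprintf(
      "Generatively invalid grid cell (alpha = %.3g, beta = %.3g): imprecision parameters must be >= 0.",
      grid$alpha[bad[1]], grid$beta[bad[1]]
    ))
  }
  cells <- with_seed_maybe(seed, {
    purrr::pmap(grid, function(alpha, beta) {
      rv <- relative_valuation(alpha, beta, ss_delay, ll_delay, k, n_samples, scale)
      tibble(relative_value = as.numeric(rv), mc_se = attr(rv, "mc_se"))
    })
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  structure(
    out,
    class = c("valuation_surface", class(out)),
    k = k, ss_delay = ss_delay, ll_delay = ll_delay,
    n_samples = n_samples, scale = scale, seed = seed
  )
}

#' @describeIn prediction_surface Heat-map of the relative-valuation surface.
#' @param object A `valuation_surface`.
#' @param ... Unused.
#' @method autoplot valuation_surface
#' @export
autoplot.valuation_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                       fill = .data$relative_value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Relative SS value") +
    ggplot2::labs(
      x = expression("Fixed imprecision" ~ alpha ~ "(s)"),
      y = expression("Proportional imprecision" ~ beta),
      title = sprintf(
        "Relative valuation of SS (%.3gs) vs LL (%.3gs), k = %.3g",
        attr(object, "ss_delay"), attr(object, "ll_delay"), attr(object, "k")
      )
    ) +
    ggplot2::theme_minimal()
}
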