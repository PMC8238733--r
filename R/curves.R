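#' Aggregate probe-trial rasters into mean response curves
#'
#' Implements the mean-response approach: for each bird and key, the mean
#' number of pecks per 0.5-s bin across all PROBE trials falling in the last
#' `last_n_days` recorded days for that bird.
#'
#' @param rasters Long raster tibble (see [generate_probe_raster()] /
#'   [read_rasters()]): columns `bird_id`, `trial_id`, `day`, `key`,
#'   `bin_index`, `count`, optionally `trial_type` (non-PROBE rows are
#'   dropped).
#' @param last_n_days How many of each bird's most recent days to keep
#'   (default 4, the stable end-of-training window).
#' @param bin_width Bin width in seconds (default 0.5).
#' @return Tibble: `bird_id`, `key`, `fi`, `bin_index`, `bin_time` (bin
#'   midpoint, seconds), `mean_count`, `n_trials`.
#' @examples
#' spec <- cohort_spec(n_birds = 1, n_families = 1, n_probe_trials = 4)
#' birds <- generate_cohort(spec, seed = 1)
#' curves <- aggregate_probe(generate_probe_raster(birds, spec, seed = 1))
#' dplyr::count(curves, key, fi)
#' @export
aggregate_probe <- function(rasters, last_n_days = 4, bin_width = 0.5) {
  required <- c("bird_id", "trial_id", "day", "key", "bin_index", "count")
  missing <- setdiff(required, names(rasters))
  if (length(missing)) {
    abort(paste0("`rasters` is missing columns: ", paste(missing, collapse = ", ")))
  }
  all_birds <- unique(rasters$bird_id)
  if ("trial_type" %in% names(rasters)) {
    rasters <- dplyr::filter(rasters, .data$trial_type == "PROBE")
  }
  windowed <- rasters %>%
    group_by(.data$bird_id) %>%
    filter(.data$day %in% tail(sort(unique(.data$day)), last_n_days)) %>%
    ungroup()
  empty <- setdiff(all_birds, unique(windowed$bird_id))
  if (length(empty)) {
    abort(paste0("No PROBE trials in the selected window for bird(s): ",
                 paste(empty, collapse = ", ")))
  }
  windowed %>%
    group_by(.data$bird_id, .data$key) %>%
    mutate(n_trials = n_distinct(.data$trial_id)) %>%
    group_by(.data$bird_id, .data$key, .data$bin_index, .data$n_trials) %>%
    summarise(mean_count = sum(.data$count) / .data$n_trials[1], .groups = "drop") %>%
    left_join(tri_peak_keys(), by = "key") %>%
    mutate(bin_time = (.data$bin_index + 0.5) * bin_width) %>%
    select("bird_id", "key", "fi", "bin_index", "bin_time",
           "mean_count", "n_trials") %>%
    arrange(.data$bird_id, .data$fi, .data$bin_index)
}

# Evaluate a polynomial with ascending-power coefficients by Horner's rule.
poly_eval <- function(coefs, x) {
  y <- rep(coefs[length(coefs)], length(x))
  for (i in rev(seq_len(length(coefs) - 1L))) y <- y * x + coefs[i]
  y
}

#' Fit a high-order polynomial to a mean response curve
#'
#' Unweighted least squares of `mean_count` on `bin_time`, by default a
#' 10th-order polynomial — high enough that the fitted peak tracks the
#' empirical maximum even for the sharpest response bump. For numerical
#' conditioning the time axis is affinely rescaled to `[-1, 1]` internally;
#' the rescaling is recorded on the returned object, and predictions are
#' always in original units.
#'
#' @param curve Tibble with columns `bin_time` and `mean_count` (one bird and
#'   key, as produced by [aggregate_probe()]).
#' @param order Polynomial order (default 10); must be smaller than the
#'   number of bins.
#' @param window Time window covered by the curve, seconds; used for the
#'   rescaling and as the default search window in [extract_peak()].
#' @return Object of class `"peak_polynomial"`: coefficients in ascending
#'   powers of the rescaled axis `x = (t - center) / half_range`, plus the
#'   rescaling constants, order, and window.
#' @examples
#' tc <- tibble::tibble(bin_time = seq(0.25, 134.75, 0.5),
#'                      mean_count = exp(-(bin_time - 15)^2 / 32))
#' fit <- fit_polynomial(tc)
#' predict(fit, c(10, 15, 20))
#' @export
fit_polynomial <- function(curve, order = 10, window = c(0, 135)) {
  t <- curve$bin_time
  y <- curve$mean_count
  if (length(t) <= order) abort("Need more bins than the polynomial order.")
  center <- mean(window)
  half <- diff(window) / 2
  x <- (t - center) / half
  fit <- lm(y ~ stats::poly(x, degree = order, raw = TRUE))
  cf <- coef(fit)
  if (any(!is.finite(cf))) abort("Polynomial fit is rank deficient.")
  structure(
    list(coefficients = unname(cf), center = center, half_range = half,
         order = order, window = window,
         residual_ss = sum(stats::residuals(fit)^2)),
    class = "peak_polynomial"
  )
}

#' @export
predict.peak_polynomial <- function(object, newdata, ...) {
  poly_eval(object$coefficients, (newdata - object$center) / object$half_range)
}

#' @export
print.peak_polynomial <- function(x, ...) {
  cat(sprintf("<peak_polynomial> order %d on [%g, %g] s, residual SS %.4g\n",
              x$order, x$window[1], x$window[2], x$residual_ss))
  invisible(x)
}

#' Extract Peak, Peak Rate and Spread from a fitted response curve
#'
#' The three peak-procedure timing measures: Peak is the time of the maximum
#' fitted response rate over the probe window (0.01-s grid scan refined by
#' local optimisation, ties broken toward the earliest time); Peak Rate is
#' the fitted rate at the Peak; the lower and upper bounds are the nearest
#' times either side of the Peak at which the fitted rate crosses half the
#' Peak Rate (absolute half-maximum, not baseline-subtracted); Spread is
#' their difference. When a half-maximum crossing does not exist inside the
#' window the bound is clipped to the window edge and flagged.
#'
#' @param fit A `"peak_polynomial"` from [fit_polynomial()].
#' @param window Search window in seconds (defaults to the fit's window).
#' @return One-row tibble: `peak_time`, `peak_rate`, `lower`, `upper`,
#'   `spread`, `clipped_low`, `clipped_high`.
#' @examples
#' tc <- tibble::tibble(bin_time = seq(0.25, 134.75, 0.5),
#'                      mean_count = exp(-(bin_time - 15)^2 / 32))
#' extract_peak(fit_polynomial(tc))
#' @export
extract_peak <- function(fit, window = NULL) {
  stopifnot(inherits(fit, "peak_polynomial"))
  window <- window %||% fit$window
  grid <- seq(window[1], window[2], by = 0.01)
  yhat <- predict(fit, grid)
  i_max <- which.max(yhat)
  # polish the argmax on the bracketing grid interval
  lo <- grid[max(i_max - 1L, 1L)]
  hi <- grid[min(i_max + 1L, length(grid))]
  peak_time <- grid[i_max]
  peak_rate <- yhat[i_max]
  if (hi > lo) {
    opt <- optimize(function(t) predict(fit, t), lower = lo, upper = hi,
                    maximum = TRUE, tol = 1e-8)
    if (opt$objective > peak_rate) {
      peak_time <- opt$maximum
      peak_rate <- opt$objective
    }
  }
  if (!is.finite(peak_rate) || peak_rate <= 0) {
    abort("Degenerate response curve: fitted maximum is not positive.",
          class = "timejitter_degenerate_curve")
  }
  half <- peak_rate / 2
  above <- yhat - half
  cross_before <- function(idx) {
    # last sign change below the peak
    s <- which(above[seq_len(idx - 1L)] <= 0 & above[2:idx] > 0)
    if (!length(s)) return(NULL)
    j <- max(s)
    # linear interpolation inside the 0.01-s cell
    grid[j] + 0.01 * (0 - above[j]) / (above[j + 1L] - above[j])
  }
  cross_after <- function(idx) {
    n <- length(grid)
    if (idx >= n) return(NULL)
    s <- which(above[idx:(n - 1L)] > 0 & above[(idx + 1L):n] <= 0)
    if (!length(s)) return(NULL)
    j <- idx + min(s) - 1L
    grid[j] + 0.01 * (above[j] - 0) / (above[j] - above[j + 1L])
  }
  lower <- if (i_max > 1L) cross_before(i_max) else NULL
  upper <- cross_after(i_max)
  clipped_low <- is.null(lower)
  clipped_high <- is.null(upper)
  lower <- lower %||% window[1]
  upper <- upper %||% window[2]
  tibble(
    peak_time = peak_time, peak_rate = peak_rate,
    lower = lower, upper = upper, spread = upper - lower,
    clipped_low = clipped_low, clipped_high = clipped_high
  )
}

#' Fit timing curves and extract peak measures for a whole cohort
#'
#' Maps [fit_polynomial()] and [extract_peak()] over every bird x key curve.
#' Curves whose fitted maximum is not positive are flagged (`degenerate`)
#' rather than dropped, with `NA` measures.
#'
#' @param curves Output of [aggregate_probe()].
#' @inheritParams fit_polynomial
#' @return Tibble with one row per bird x key: `bird_id`, `key`, `fi`,
#'   `peak_time`, `peak_rate`, `lower`, `upper`, `spread`, `clipped_low`,
#'   `clipped_high`, `degenerate`.
#' @examples
#' spec <- cohort_spec(n_birds = 1, n_families = 1, n_probe_trials = 4)
#' birds <- generate_cohort(spec, seed = 1)
#' curves <- aggregate_probe(generate_probe_raster(birds, spec, seed = 1))
#' fit_timing_curves(curves)
#' @export
fit_timing_curves <- function(curves, order = 10, window = c(0, 135)) {
  curves %>%
    tidyr::nest(data = -c("bird_id", "key", "fi")) %>%
    mutate(fit = purrr::map(.data$data, function(d) {
      tryCatch(
        extract_peak(fit_polynomial(d, order = order, window = window)),
        timejitter_degenerate_curve = function(e) {
          tibble(peak_time = NA_real_, peak_rate = NA_real_,
                 lower = NA_real_, upper = NA_real_, spread = NA_real_,
                 clipped_low = NA, clipped_high = NA)
        }
      )
    })) %>%
    select(-"data") %>%
    tidyr::unnest("fit") %>%
    mutate(degenerate = is.na(.data$peak_time)) %>%
    arrange(.data$bird_id, .data$fi)
}

#' Switch points predicted by optimal temporal risk assessment
#'
#' Under multiplicative (log-scale) timing noise the optimal moment to move
#' peak responding from one trained interval's key to the next falls at the
#' geometric mean of the two intervals, not their arithmetic mean.
#'
#' @param fis Trained fixed intervals, seconds (default 5, 15, 45).
#' @return Tibble with one row per adjacent pair: `from_fi`, `to_fi`,
#'   `switch_time` (geometric mean, seconds).
#' @examples
#' geometric_switch_points()
#' @export
geometric_switch_points <- function(fis = c(5, 15, 45)) {
  fis <- sort(fis)
  tibble(
    from_fi = fis[-length(fis)],
    to_fi = fis[-1],
    switch_time = sqrt(fis[-length(fis)] * fis[-1])
  )
}
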