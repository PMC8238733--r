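make_raster <- function(bird_id, trial_id, day, key, counts) {
  tibble::tibble(
    bird_id = bird_id, trial_id = trial_id, day = day, trial_type = "PROBE",
    key = key, bin_index = seq_along(counts) - 1L, count = counts
  )
}

test_that("probe aggregation averages trials within the final-days window", {
  counts <- c(0, 1, 2, 3)
  single <- aggregate_probe(make_raster("A", 1L, 1L, "LEFT", counts),
                            last_n_days = 4)
  expect_equal(single$mean_count, counts)
  expect_equal(single$fi, rep(5, 4))
  expect_equal(single$bin_time, c(0.25, 0.75, 1.25, 1.75))

  two <- dplyr::bind_rows(make_raster("A", 1L, 1L, "LEFT", counts),
                          make_raster("A", 2L, 2L, "LEFT", 3 * counts))
  expect_equal(aggregate_probe(two, last_n_days = 4)$mean_count, 2 * counts)

  # trials on days outside the last-4-day window are excluded
  six_days <- dplyr::bind_rows(lapply(1:6, function(d) {
    make_raster("A", d, d, "LEFT", rep(d, 4))
  }))
  agg <- aggregate_probe(six_days, last_n_days = 4)
  expect_equal(unique(agg$n_trials), 4L)
  expect_equal(agg$mean_count, rep(mean(3:6), 4))

  # non-PROBE trials never contribute
  with_fi <- dplyr::bind_rows(
    make_raster("A", 1L, 1L, "LEFT", counts),
    dplyr::mutate(make_raster("A", 2L, 1L, "LEFT", counts * 10),
                  trial_type = "SHORT")
  )
  expect_equal(aggregate_probe(with_fi)$mean_count, counts)
  expect_error(aggregate_probe(dplyr::mutate(six_days, trial_type = "SHORT")),
               "No PROBE trials")
})

test_that("polynomial fitting interpolates its own model class", {
  x <- seq(0.25, 134.75, 0.5)
  xr <- (x - 67.5) / 67.5
  cf <- c(0.5, -1, 2, 0.3, -0.7, 1.1, 0.2, -0.4, 0.6, -0.1, 0.8)
  y <- sapply(xr, function(z) sum(cf * z^(0:10)))
  fit <- fit_polynomial(tibble::tibble(bin_time = x, mean_count = y))
  expect_lt(max(abs(predict(fit, x) - y)), 1e-6 * diff(range(y)))

  const <- fit_polynomial(tibble::tibble(bin_time = x, mean_count = rep(2, length(x))))
  expect_equal(predict(const, c(7, 66, 130)), rep(2, 3), tolerance = 1e-8)

  bump <- gaussian_curve(mu = 30, sigma = 6)
  expect_lte(fit_polynomial(bump, order = 10)$residual_ss,
             fit_polynomial(bump, order = 2)$residual_ss)
  expect_error(fit_polynomial(bump[1:5, ], order = 10), "more bins")
})

test_that("least-squares fit matches a direct normal-equations solve", {
  curve <- gaussian_curve(mu = 20, sigma = 5)[seq(1, 270, by = 9), ]
  fit <- fit_polynomial(curve, order = 4)
  X <- outer((curve$bin_time - 67.5) / 67.5, 0:4, `^`)
  beta <- solve(crossprod(X), crossprod(X, curve$mean_count))
  expect_equal(fit$coefficients, as.numeric(beta), tolerance = 1e-8)
})

test_that("peak extraction recovers a Gaussian's location and width", {
  # order 10 resolves the bump when the fit window is commensurate with it
  fit <- fit_polynomial(gaussian_curve(mu = 15, sigma = 4, window = 30),
                        window = c(0, 30))
  pk <- extract_peak(fit)
  expect_lt(abs(pk$peak_time - 15), 0.25)
  fwhm <- 2 * sqrt(2 * log(2)) * 4
  expect_lt(abs(pk$spread - fwhm) / fwhm, 0.05)
  expect_false(pk$clipped_low || pk$clipped_high)
  expect_true(pk$lower <= pk$peak_time && pk$peak_time <= pk$upper)
})

test_that("monotone curves clip at the window edge and flag it", {
  x <- seq(0.25, 134.75, 0.5)
  fit <- fit_polynomial(tibble::tibble(bin_time = x, mean_count = 0.1 + 0.01 * x),
                        order = 3)
  pk <- extract_peak(fit)
  expect_equal(pk$peak_time, 135, tolerance = 0.02)
  expect_true(pk$clipped_high)
  expect_false(pk$clipped_low)
  expect_equal(pk$upper, 135)
})

test_that("a constant baseline inflates the half-maximum spread", {
  pk0 <- extract_peak(fit_polynomial(gaussian_curve(15, 4, baseline = 0)))
  pk1 <- extract_peak(fit_polynomial(gaussian_curve(15, 4, baseline = 0.5)))
  expect_gt(pk1$spread, pk0$spread)
})

test_that("degenerate curves are flagged rather than dropped", {
  x <- seq(0.25, 134.75, 0.5)
  neg <- tibble::tibble(bin_time = x, mean_count = rep(-1, length(x)))
  expect_error(extract_peak(fit_polynomial(neg)),
               class = "timejitter_degenerate_curve")
  curves <- dplyr::bind_rows(
    dplyr::mutate(gaussian_curve(15, 4), bird_id = "OK", key = "CENTRE", fi = 15),
    dplyr::mutate(neg, bird_id = "BAD", key = "CENTRE", fi = 15)
  )
  peaks <- fit_timing_curves(curves)
  expect_equal(nrow(peaks), 2L)
  expect_false(peaks$degenerate[peaks$bird_id == "OK"])
  expect_true(peaks$degenerate[peaks$bird_id == "BAD"])
  expect_true(is.na(peaks$spread[peaks$bird_id == "BAD"]))
})

test_that("the analysis chain recovers peak location and spread on clean cohorts", {
  spec <- cohort_spec(n_birds = 3, n_families = 1, baseline_rate = 0,
                      peak_amplitude = 3, n_probe_trials = 40)
  birds <- generate_cohort(spec, seed = 51)
  res <- analyse_rasters(generate_probe_raster(birds, spec, seed = 52))
  peaks <- dplyr::inner_join(res$peaks, birds, by = "bird_id")
  expect_lte(median(abs(peaks$peak_time - peaks$fi)), 1)
  truth <- peaks$alpha_true + peaks$beta_true * peaks$fi
  expect_lte(median(abs(peaks$spread - truth) / truth), 0.15)
  # spread grows with the interval for every bird with beta > 0
  growth <- peaks %>%
    dplyr::group_by(bird_id) %>%
    dplyr::summarise(mono = all(diff(spread[order(fi)]) > 0))
  expect_true(all(growth$mono[peaks$beta_true[match(growth$bird_id, peaks$bird_id)] > 0]))
})

test_that("refined argmax dominates the grid scan", {
  fit <- fit_polynomial(gaussian_curve(mu = 22.3, sigma = 3))
  pk <- extract_peak(fit)
  grid <- seq(0, 135, 0.01)
  expect_gte(pk$peak_rate, max(predict(fit, grid)))
})
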