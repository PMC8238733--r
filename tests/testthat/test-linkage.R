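test_that("within-FI standardization yields mean 0, sd 1, and is idempotent", {
  withr::local_seed(71)
  d <- tidyr::expand_grid(bird_id = sprintf("B%02d", 1:10), fi = c(5, 15, 45)) %>%
    dplyr::mutate(spread = 2 + fi * 1.3 + rnorm(30))
  z <- standardize_by_fi(d, spread)
  by_fi <- z %>%
    dplyr::group_by(fi) %>%
    dplyr::summarise(m = mean(spread_z), s = sd(spread_z))
  expect_true(all(abs(by_fi$m) < 1e-12))
  expect_equal(by_fi$s, rep(1, 3), tolerance = 1e-12)
  z2 <- standardize_by_fi(dplyr::select(z, fi, spread = spread_z), spread)
  expect_equal(z2$spread_z, z$spread_z, tolerance = 1e-12)
  two <- tibble::tibble(fi = c(5, 5), spread = c(1, 3))
  expect_equal(sort(standardize_by_fi(two, spread)$spread_z),
               c(-1, 1) / sqrt(2), tolerance = 1e-10)
  expect_error(standardize_by_fi(tibble::tibble(fi = c(5, 5), spread = c(2, 2)),
                                 spread), "FI 5")
})

test_that("imprecision-spread correlations behave at the limits", {
  withr::local_seed(72)
  # beta_hat perfectly determines spread_45 here -> r = 1
  est <- tibble::tibble(
    bird_id = sprintf("B%02d", 1:20),
    alpha_hat = rnorm(20), beta_hat = rnorm(20, 1.4, 0.5)
  ) %>%
    dplyr::mutate(alpha_truncated = pmax(alpha_hat, 0),
                  spread_5 = rnorm(20), spread_15 = rnorm(20),
                  spread_45 = beta_hat)
  ct <- imprecision_spread_correlations(est)
  expect_equal(ct$r[ct$var1 == "beta_hat" & ct$var2 == "spread_45"], 1,
               tolerance = 1e-10)
  # independent large-sample columns have near-zero correlation
  big <- tibble::tibble(
    bird_id = as.character(1:10000),
    alpha_hat = rnorm(10000), beta_hat = rnorm(10000)
  ) %>%
    dplyr::mutate(alpha_truncated = alpha_hat, spread_5 = rnorm(10000),
                  spread_15 = rnorm(10000), spread_45 = rnorm(10000))
  ct_big <- imprecision_spread_correlations(big)
  expect_true(all(abs(ct_big$r) < 0.05))
  # a constant column gives NA rather than an error
  con <- dplyr::mutate(est, spread_5 = 1)
  ct_con <- imprecision_spread_correlations(con)
  expect_true(all(is.na(ct_con$r[ct_con$var2 == "spread_5"])))
})

test_that("the impulsivity model reproduces a direct mixed-model fit", {
  withr::local_seed(73)
  n <- 24
  meta <- tibble::tibble(
    bird_id = sprintf("B%02d", 1:n),
    sex = sample(rep(c("F", "M"), n / 2)),
    family_id = paste0("F", rep(1:6, length.out = n))
  )
  est <- tibble::tibble(bird_id = meta$bird_id,
                        alpha_hat = rnorm(n, 3, 2),
                        beta_hat = rnorm(n, 1.4, 0.5))
  choices <- tibble::tibble(bird_id = meta$bird_id,
                            proportion_ss = plogis(rnorm(n, 0, 0.5)))
  m <- fit_impulsivity_model(choices, est, meta, predictor = "beta")
  d <- dplyr::inner_join(dplyr::inner_join(choices, est, "bird_id"), meta, "bird_id")
  d$imprecision_z <- as.numeric(scale(d$beta_hat))
  ref <- lmerTest::lmer(proportion_ss ~ imprecision_z + sex + (1 | family_id),
                        data = d, REML = FALSE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
  expect_equal(tidy(m)$estimate, unname(lme4::fixef(ref)), tolerance = 1e-10)
  expect_equal(tidy(m)$p_value, coef(summary(ref))[, "Pr(>|t|)"],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(glance(m)$n, n)
  expect_s3_class(tidy(m, "ran_pars"), "tbl_df")
})

test_that("choices generated from the valuation model recover the negative beta effect", {
  spec <- cohort_spec(n_samples_valuation = 2e4)
  birds <- generate_cohort(spec, seed = 74)
  choices <- generate_choices(birds, spec, seed = 75)
  # use the true parameters as predictors to isolate the linkage stage
  est <- tibble::tibble(bird_id = birds$bird_id,
                        alpha_hat = birds$alpha_true,
                        beta_hat = birds$beta_true)
  m <- fit_impulsivity_model(choices, est, birds, predictor = "beta")
  td <- tidy(m)
  expect_lt(td$estimate[td$term == "imprecision_z"], 0)
  expect_lt(td$p_value[td$term == "imprecision_z"], 0.05)
})

test_that("treatment models recover injected effects and prune the interaction", {
  withr::local_seed(76)
  spec <- cohort_spec()
  birds <- generate_cohort(spec, seed = 77)
  peaks <- tidyr::expand_grid(bird_id = birds$bird_id, fi = c(5, 15, 45)) %>%
    dplyr::left_join(tibble::tibble(fi = c(5, 15, 45),
                                    key = c("LEFT", "CENTRE", "RIGHT")),
                     by = "fi") %>%
    dplyr::left_join(dplyr::select(birds, bird_id, amount), by = "bird_id") %>%
    dplyr::mutate(
      spread = 3 + 1.3 * fi + rnorm(dplyr::n(), 0, 0.15 * fi) +
        ifelse(amount == "Lean", 0.6 * 0.15 * fi, 0),
      peak_time = fi + rnorm(dplyr::n(), 0, 0.1 * fi),
      peak_rate = 2 + rnorm(dplyr::n(), 0, 0.2),
      degenerate = FALSE
    ) %>%
    dplyr::select(-amount)
  est <- fit_imprecision(peaks)
  models <- fit_treatment_models(est, peaks, birds)
  td <- tidy(models$spread)
  expect_false(any(grepl(":", td$term)))           # null interaction pruned
  lean <- td[td$term == "amountLean", ]
  expect_gt(lean$estimate, 0)                      # injected Lean effect
  expect_lt(lean$p_value, 0.05)
  em <- treatment_means(models$spread, "amount")
  expect_equal(nrow(em), 2L)
  expect_gt(em$emmean[em$amount == "Lean"], em$emmean[em$amount == "Plenty"])
  # peak-rate model keeps the key term on the raw rate scale
  expect_true(any(grepl("^key", tidy(models$peak_rate)$term)))
})

test_that("a strongly interacting design keeps its interaction term", {
  withr::local_seed(78)
  spec <- cohort_spec()
  birds <- generate_cohort(spec, seed = 79)
  est <- tibble::tibble(
    bird_id = birds$bird_id,
    alpha_hat = rnorm(28, 0, 0.3) +
      ifelse(birds$amount == "Lean" & birds$effort == "Hard", 3, 0),
    beta_hat = rnorm(28)
  )
  peaks <- tidyr::expand_grid(bird_id = birds$bird_id, fi = c(5, 15, 45)) %>%
    dplyr::mutate(key = c("LEFT", "CENTRE", "RIGHT")[match(fi, c(5, 15, 45))],
                  spread = 3 + 1.3 * fi + rnorm(dplyr::n()),
                  peak_time = fi + rnorm(dplyr::n(), 0, 0.5),
                  peak_rate = 2 + rnorm(dplyr::n(), 0, 0.1),
                  degenerate = FALSE)
  models <- fit_treatment_models(est, peaks, birds)
  expect_true(any(grepl(":", tidy(models$fixed_imprecision)$term)))
})

test_that("variance components separate stable individuals from noise", {
  withr::local_seed(80)
  n <- 40
  meta <- tibble::tibble(bird_id = sprintf("B%02d", 1:n),
                         family_id = paste0("F", rep(1:8, 5)))
  # near-identical halves: variance is individual (or family), not residual
  vals <- rnorm(n)
  dup <- tibble::tibble(bird_id = rep(meta$bird_id, 2),
                        half = rep(c("early", "late"), each = n),
                        alpha_hat = rep(vals, 2) + rnorm(2 * n, 0, 1e-4),
                        beta_hat = rep(vals, 2) + rnorm(2 * n, 0, 1e-4))
  vc <- consistency_components(dup, meta)
  expect_true(all(vc$var_residual_pct < 1))
  expect_true(all(vc$var_individual_pct > 50))
  expect_equal(vc$var_individual_pct + vc$var_family_pct + vc$var_residual_pct,
               rep(100, 2), tolerance = 0.1)
  # independently re-drawn halves: no individual signal
  indep <- dplyr::mutate(dup, alpha_hat = rnorm(2 * n), beta_hat = rnorm(2 * n))
  vc2 <- consistency_components(indep, meta)
  expect_true(all(vc2$var_individual_pct < 30))
})

test_that("split-half analysis reruns the chain per half and partitions variance", {
  spec <- cohort_spec(n_birds = 10, n_families = 5, n_probe_trials = 24,
                      probe_days = 4)
  birds <- generate_cohort(spec, seed = 81)
  rasters <- generate_probe_raster(birds, spec, seed = 82)
  sh <- split_half_consistency(rasters, birds)
  expect_equal(sort(unique(sh$half_estimates$half)), c("early", "late"))
  expect_equal(nrow(sh$half_estimates), 20L)
  expect_equal(sh$components$var_individual_pct + sh$components$var_family_pct +
                 sh$components$var_residual_pct, rep(100, 2), tolerance = 0.1)
  # birds without 4 probe days are excluded with a warning
  short <- dplyr::filter(rasters, !(bird_id == birds$bird_id[1] & day > 2))
  expect_warning(split_half_consistency(short, birds), "fewer than 4")
})

test_that("the null type-I study rejects at the nominal rate scale", {
  t1 <- run_type1_study(n_sims = 50, seed = 83)
  expect_equal(nrow(t1), 50L)
  expect_true(all(t1$p_value >= 0 & t1$p_value <= 1))
  expect_lt(mean(t1$reject), 0.2)
})
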