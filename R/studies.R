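#' Run the full analysis chain on a simulated or loaded cohort
#'
#' Convenience wrapper: rasters -> mean curves -> polynomial peak fits ->
#' imprecision decomposition.
#'
#' @param rasters Probe raster tibble.
#' @param last_n_days,order Passed to [aggregate_probe()] /
#'   [fit_timing_curves()].
#' @return List with `curves`, `peaks`, `estimates`.
#' @export
analyse_rasters <- function(rasters, last_n_days = 4, order = 10) {
  curves <- aggregate_probe(rasters, last_n_days = last_n_days)
  peaks <- fit_timing_curves(curves, order = order)
  usable <- filter(peaks, !peaks$degenerate)
  complete <- usable %>%
    group_by(.data$bird_id) %>%
    filter(n_distinct(.data$fi) == 3L) %>%
    ungroup()
  dropped <- setdiff(unique(peaks$bird_id), unique(complete$bird_id))
  if (length(dropped)) {
    warn(paste0("Excluding bird(s) without usable fits at all three FIs: ",
                paste(dropped, collapse = ", ")))
  }
  list(curves = curves, peaks = peaks,
       estimates = fit_imprecision(complete))
}

#' Parameter-recovery study on replicated synthetic cohorts
#'
#' For each replicate: simulate a cohort, run the complete analysis chain,
#' and record (i) Spearman rank correlations between the true and estimated
#' imprecision components and (ii) the standardized proportional-imprecision
#' coefficient (and p-value) from the impulsivity mixed model fitted to the
#' cohort's generated choices. Under the valuation model, higher
#' proportional imprecision deflates the smaller-sooner option's relative
#' value, so the recovered coefficient should be negative.
#'
#' @param n_reps Number of replicate cohorts.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; replicate r uses `seed + r - 1`.
#' @return Tibble with one row per replicate: `rep`, `spearman_alpha`,
#'   `spearman_beta`, `beta_coefficient`, `beta_p_value`,
#'   `alpha_coefficient`.
#' @export
run_recovery_study <- function(n_reps = 1, spec = cohort_spec(), seed = 1) {
  purrr::map(seq_len(n_reps), function(r) {
    sim <- simulate_cohort(spec, seed = seed + r - 1L)
    res <- analyse_rasters(sim$rasters)
    truth <- select(sim$birds, "bird_id", "alpha_true", "beta_true")
    est <- inner_join(res$estimates, truth, by = "bird_id")
    m_beta <- fit_impulsivity_model(sim$choices, res$estimates, sim$birds,
                                    predictor = "beta")
    m_alpha <- fit_impulsivity_model(sim$choices, res$estimates, sim$birds,
                                     predictor = "alpha")
    coef_of <- function(m) {
      td <- tidy(m)
      td[td$term == "imprecision_z", c("estimate", "p_value")]
    }
    cb <- coef_of(m_beta)
    ca <- coef_of(m_alpha)
    tibble(
      rep = r,
      spearman_alpha = cor(est$alpha_true, est$alpha_hat, method = "spearman"),
      spearman_beta = cor(est$beta_true, est$beta_hat, method = "spearman"),
      beta_coefficient = cb$estimate,
      beta_p_value = cb$p_value,
      alpha_coefficient = ca$estimate
    )
  }) %>% dplyr::bind_rows()
}

#' Estimator coupling between fixed and proportional imprecision
#'
#' With only three FIs, the OLS intercept and slope of the Spread-vs-FI line
#' share measurement error: any error that steepens the estimated slope
#' depresses the estimated intercept, so `cor(alpha_hat, beta_hat)` is
#' pushed negative even when the true components are uncorrelated. This
#' experiment simulates cohorts whose true correlation is zero in a
#' sparse-data regime (few probe trials per bird, so single-cohort
#' measurement error is visible) and reports the per-cohort estimate
#' correlations; their mean isolates the estimator artefact from cohort
#' sampling noise.
#'
#' @param n_cohorts Number of replicate cohorts (default 30).
#' @param spec A [cohort_spec()]; defaults to the standard cohort with
#'   `alpha_beta_corr = 0` and `n_probe_trials = 4`.
#' @param seed Integer seed; cohort c uses `seed + c - 1`.
#' @return Tibble: `cohort`, `r_alpha_beta_hat`, `r_alpha_beta_true`.
#' @export
coupling_experiment <- function(n_cohorts = 30,
                                spec = cohort_spec(alpha_beta_corr = 0,
                                                   n_probe_trials = 4),
                                seed = 1) {
  purrr::map(seq_len(n_cohorts), function(cc) {
    birds <- generate_cohort(spec, seed = seed + cc - 1L)
    rasters <- generate_probe_raster(birds, spec, seed = seed + cc - 1L + 10000L)
    est <- analyse_rasters(rasters)$estimates
    est <- inner_join(est, birds, by = "bird_id")
    tibble(
      cohort = cc,
      r_alpha_beta_hat = cor(est$alpha_hat, est$beta_hat),
      r_alpha_beta_true = cor(est$alpha_true, est$beta_true)
    )
  }) %>% dplyr::bind_rows()
}

#' Type-I error of the impulsivity mixed model under the null
#'
#' Simulates cohorts in which the imprecision predictor has exactly zero
#' effect on choice: the predictor is drawn independently of the outcome,
#' which is family intercept plus residual noise. Each simulated cohort is
#' fitted with [fit_impulsivity_model()] and the rejection indicator
#' (Satterthwaite p < `level` on the predictor) recorded, so the empirical
#' rejection rate estimates the test's type-I error.
#'
#' @param n_sims Number of simulated cohorts.
#' @param n_birds,n_families Cohort dimensions (defaults 27 birds — one bird
#'   missing impulsivity data — in 8 families).
#' @param family_sd,resid_sd Standard deviations of the family intercepts
#'   and residual noise on the proportion-choice scale.
#' @param level Nominal significance level.
#' @param seed Integer seed.
#' @return Tibble: `sim`, `p_value`, `reject`.
#' @export
run_type1_study <- function(n_sims = 500, n_birds = 27, n_families = 8,
                            family_sd = 0.05, resid_sd = 0.1,
                            level = 0.05, seed = 1) {
  with_seed_maybe(seed, {
    purrr::map(seq_len(n_sims), function(s) {
      fam <- paste0("F", (seq_len(n_birds) - 1L) %% n_families + 1L)
      fam_eff <- rnorm(n_families, 0, family_sd)
      meta <- tibble(
        bird_id = sprintf("B%02d", seq_len(n_birds)),
        sex = rep(c("F", "M"), length.out = n_birds),
        family_id = fam
      )
      estimates <- tibble(bird_id = meta$bird_id,
                          alpha_hat = rnorm(n_birds),
                          beta_hat = rnorm(n_birds))
      choices <- tibble(
        bird_id = meta$bird_id,
        proportion_ss = 0.5 + fam_eff[as.integer(sub("F", "", fam))] +
          rnorm(n_birds, 0, resid_sd)
      )
      m <- fit_impulsivity_model(choices, estimates, meta, predictor = "beta")
      td <- tidy(m)
      p <- td$p_value[td$term == "imprecision_z"]
      tibble(sim = s, p_value = p, reject = p < level)
    }) %>% dplyr::bind_rows()
  })
}
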