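#' Specification of a synthetic tri-peak cohort
#'
#' Collects every parameter of the synthetic-data generator. Defaults emulate
#' a cohort of 28 hand-reared starlings from 8 natal families in a 2x2
#' developmental design (food Amount: Lean/Plenty crossed with begging
#' Effort: Easy/Hard), trained on fixed intervals of 5/15/45 s with probe
#' trials of 135 s, and previously tested on a smaller-sooner (1 pellet,
#' 3 s) versus larger-later (2 pellets, 8 s) choice task. Per-bird true
#' imprecision parameters are drawn from a bivariate normal whose means and
#' cohort-level standard deviations (`3.76` and `1.18 * sqrt(28)` seconds for
#' the fixed component; `1.40` and `0.12 * sqrt(28)` for the proportional
#' component) match reported cohort summaries, then clipped at zero for
#' generative validity.
#'
#' @param n_birds,n_families Cohort size and number of natal families.
#' @param alpha_mean,alpha_sd Mean/SD of true fixed imprecision, seconds.
#' @param beta_mean,beta_sd Mean/SD of true proportional imprecision.
#' @param alpha_beta_corr True correlation between the two components.
#' @param baseline_rate Baseline peck rate, pecks per 0.5-s bin.
#' @param peak_amplitude Peak height above baseline, pecks per 0.5-s bin.
#' @param n_probe_trials Probe trials per bird.
#' @param probe_days Number of days the probe trials are spread over.
#' @param fis Trained fixed intervals, seconds, mapped to keys LEFT, CENTRE,
#'   RIGHT in order.
#' @param window Probe-trial duration, seconds.
#' @param bin_width Recording bin width, seconds.
#' @param ss_delay,ll_delay,ss_magnitude,ll_magnitude Choice scenario:
#'   delays (s) and reward magnitudes (pellets) of the smaller-sooner and
#'   larger-later options.
#' @param k Hyperbolic discount rate, 1/seconds.
#' @param choice_temperature Softmax temperature of the value-based choice
#'   rule (value units); smaller is more deterministic.
#' @param n_choice_trials Free-choice trials per bird.
#' @param n_samples_valuation Monte-Carlo draws per delay when computing
#'   option values for choice generation.
#' @param scale Interpretation of `alpha + beta * t` (see
#'   [sample_perceived()]).
#' @return A list of class `"cohort_spec"`.
#' @examples
#' spec <- cohort_spec(n_birds = 8, n_probe_trials = 4)
#' spec$n_birds
#' @export
cohort_spec <- function(n_birds = 28, n_families = 8,
                        alpha_mean = 3.76, alpha_sd = 1.18 * sqrt(28),
                        beta_mean = 1.40, beta_sd = 0.12 * sqrt(28),
                        alpha_beta_corr = 0,
                        baseline_rate = 0.05, peak_amplitude = 2,
                        n_probe_trials = 60, probe_days = 4,
                        fis = c(5, 15, 45), window = 135, bin_width = 0.5,
                        ss_delay = 3, ll_delay = 8,
                        ss_magnitude = 1, ll_magnitude = 2,
                        k = 0.54, choice_temperature = 0.2,
                        n_choice_trials = 240,
                        n_samples_valuation = 1e5,
                        scale = c("sd", "variance")) {
  scale <- match.arg(scale)
  if (n_birds < n_families || n_families < 1) {
    abort("Require n_birds >= n_families >= 1.")
  }
  if (abs(alpha_beta_corr) > 1) abort("`alpha_beta_corr` must lie in [-1, 1].")
  if (length(fis) != 3L || any(fis <= 0)) abort("`fis` must be three positive intervals.")
  structure(as.list(environment()), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d birds, %d families, 2x2 Amount x Effort design\n",
              x$n_birds, x$n_families))
  cat(sprintf("  alpha ~ N(%.3g, %.3g^2), beta ~ N(%.3g, %.3g^2), corr %.2g (clipped at 0)\n",
              x$alpha_mean, x$alpha_sd, x$beta_mean, x$beta_sd, x$alpha_beta_corr))
  cat(sprintf("  %d probe trials over %d days; FIs %s s; %d choice trials\n",
              x$n_probe_trials, x$probe_days,
              paste(x$fis, collapse = "/"), x$n_choice_trials))
  invisible(x)
}

# Unique 4-letter colour-band-style bird codes, deterministic under the
# surrounding seed.
make_bird_ids <- function(n) {
  ids <- character(0)
  while (length(ids) < n) {
    more <- replicate(n - length(ids),
                      paste(sample(LETTERS, 4, replace = TRUE), collapse = ""))
    ids <- unique(c(ids, more))
  }
  ids[seq_len(n)]
}

#' Generate a synthetic cohort with known imprecision parameters
#'
#' Creates bird metadata (id, sex, natal family, developmental treatments)
#' together with each bird's true fixed (`alpha_true`, seconds) and
#' proportional (`beta_true`) timing imprecision. Birds are assigned
#' round-robin to families and balanced across the 2x2 Amount x Effort
#' design; `(alpha, beta)` pairs are drawn from the specified bivariate
#' normal and clipped at zero.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per bird: `bird_id`, `sex`, `family_id`,
#'   `amount`, `effort`, `alpha_true`, `beta_true`.
#' @examples
#' generate_cohort(cohort_spec(n_birds = 8, n_families = 4), seed = 1)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed_maybe(seed, {
    n <- spec$n_birds
    combos <- tidyr::expand_grid(amount = c("Lean", "Plenty"),
                                 effort = c("Easy", "Hard"))
    # balanced counts, shuffled so sex/treatments/families are not confounded
    idx <- sample(rep(seq_len(4L), length.out = n))
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    rho <- spec$alpha_beta_corr
    tibble(
      bird_id = make_bird_ids(n),
      sex = sample(rep(c("F", "M"), length.out = n)),
      family_id = paste0("F", (seq_len(n) - 1L) %% spec$n_families + 1L),
      amount = combos$amount[idx],
      effort = combos$effort[idx],
      alpha_true = pmax(spec$alpha_mean + spec$alpha_sd * z1, 0),
      beta_true = pmax(
        spec$beta_mean + spec$beta_sd * (rho * z1 + sqrt(1 - rho^2) * z2), 0
      )
    ) %>%
      # a pair clipped to (0, 0) would be a perfect timer with a zero-width
      # response curve; keep such birds generatively valid but near-perfect
      mutate(beta_true = ifelse(.data$alpha_true == 0 & .data$beta_true == 0,
                                1e-3, .data$beta_true))
  })
}

#' Expected peck-rate curve on one key during a probe trial
#'
#' The generator's response model: a Gaussian bump over a flat baseline,
#' centred on the trained fixed interval `fi`, whose full width at half
#' maximum equals the bird's timing-noise scale `alpha + beta * fi`. This
#' ties the Spread estimand of the analysis chain directly to the bird's
#' generative imprecision (up to baseline-induced inflation).
#'
#' @param t Time since trial start, seconds (vectorised).
#' @param alpha,beta The bird's imprecision parameters.
#' @param fi Trained fixed interval, seconds.
#' @param baseline_rate,peak_amplitude Rate parameters, pecks per 0.5-s bin.
#' @return Expected pecks per 0.5-s bin at each `t`.
#' @examples
#' probe_rate_curve(c(5, 15, 45), alpha = 4, beta = 1.06, fi = 45)
#' @export
probe_rate_curve <- function(t, alpha, beta, fi,
                             baseline_rate = 0.05, peak_amplitude = 2) {
  sigma <- (alpha + beta * fi) / (2 * sqrt(2 * log(2)))
  if (!is.finite(sigma) || sigma <= 0) {
    abort(sprintf("Rate-curve width must be positive (alpha = %.3g, beta = %.3g, fi = %.3g).",
                  alpha, beta, fi))
  }
  baseline_rate + peak_amplitude * exp(-(t - fi)^2 / (2 * sigma^2))
}

#' Generate probe-trial peck rasters for a cohort
#'
#' For every bird, probe trial and key, draws Poisson peck counts in 0.5-s
#' bins over the 135-s probe window from the bird's expected rate curve
#' ([probe_rate_curve()]). Keys map to fixed intervals as LEFT = 5 s,
#' CENTRE = 15 s, RIGHT = 45 s; trials are spread round-robin across
#' `spec$probe_days` days.
#'
#' @param birds Cohort tibble from [generate_cohort()] (needs `bird_id`,
#'   `alpha_true`, `beta_true`).
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return Long tibble: `bird_id`, `trial_id`, `day`, `trial_type`
#'   (always `"PROBE"`), `key`, `bin_index` (0-based, half-open bins
#'   `[i * 0.5, (i + 1) * 0.5)`), `count`.
#' @examples
#' spec <- cohort_spec(n_birds = 2, n_families = 1, n_probe_trials = 2)
#' birds <- generate_cohort(spec, seed = 1)
#' generate_probe_raster(birds, spec, seed = 1)
#' @export
generate_probe_raster <- function(birds, spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_bins <- as.integer(spec$window / spec$bin_width)
  mids <- (seq_len(n_bins) - 0.5) * spec$bin_width
  keys <- tri_peak_keys()
  keys$fi <- spec$fis
  n_trials <- spec$n_probe_trials
  if (n_trials == 0) {
    return(tibble(bird_id = character(), trial_id = integer(), day = integer(),
                  trial_type = character(), key = character(),
                  bin_index = integer(), count = integer()))
  }
  days <- (seq_len(n_trials) - 1L) %% spec$probe_days + 1L
  with_seed_maybe(seed, {
    purrr::pmap(
      list(birds$bird_id, birds$alpha_true, birds$beta_true),
      function(id, a, b) {
        purrr::pmap(keys, function(key, fi) {
          rate <- probe_rate_curve(mids, a, b, fi,
                                   spec$baseline_rate, spec$peak_amplitude)
          tibble(
            bird_id = id,
            trial_id = rep(seq_len(n_trials), each = n_bins),
            day = rep(days, each = n_bins),
            trial_type = "PROBE",
            key = key,
            bin_index = rep(seq_len(n_bins) - 1L, times = n_trials),
            count = rpois(n_trials * n_bins, rep(rate, times = n_trials))
          )
        }) %>% dplyr::bind_rows()
      }
    ) %>% dplyr::bind_rows()
  })
}

#' Generate intertemporal-choice outcomes from the valuation model
#'
#' Each bird's option values are computed from its own noisy clock:
#' `V_ss = ss_magnitude * E[v(ss_delay)]` and
#' `V_ll = ll_magnitude * E[v(ll_delay)]` via
#' [expected_discounted_value()] under `(alpha_true, beta_true, k)`. The
#' per-trial probability of choosing the smaller-sooner option is
#' `plogis((V_ss - V_ll) / choice_temperature)` and the number of SS choices
#' is a Binomial draw, so downstream recovery of the model's directional
#' predictions is testable end to end.
#'
#' @inheritParams generate_probe_raster
#' @return Tibble: `bird_id`, `n_choice_trials`, `n_ss_choices`,
#'   `proportion_ss`, plus the latent `value_ss`, `value_ll` and `p_ss`.
#' @examples
#' spec <- cohort_spec(n_birds = 2, n_families = 1, n_samples_valuation = 1e3)
#' birds <- generate_cohort(spec, seed = 1)
#' generate_choices(birds, spec, seed = 1)
#' @export
generate_choices <- function(birds, spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.numeric(spec$choice_temperature) || spec$choice_temperature <= 0) {
    abort("`choice_temperature` must be > 0.")
  }
  if (spec$n_choice_trials < 1) abort("`n_choice_trials` must be >= 1.")
  with_seed_maybe(seed, {
    vals <- purrr::map2(birds$alpha_true, birds$beta_true, function(a, b) {
      v_ss <- spec$ss_magnitude * as.numeric(expected_discounted_value(
        spec$ss_delay, a, b, spec$k, spec$n_samples_valuation, spec$scale))
      v_ll <- spec$ll_magnitude * as.numeric(expected_discounted_value(
        spec$ll_delay, a, b, spec$k, spec$n_samples_valuation, spec$scale))
      c(v_ss, v_ll)
    })
    v_ss <- purrr::map_dbl(vals, 1)
    v_ll <- purrr::map_dbl(vals, 2)
    p_ss <- plogis((v_ss - v_ll) / spec$choice_temperature)
    n_ss <- rbinom(nrow(birds), spec$n_choice_trials, p_ss)
    tibble(
      bird_id = birds$bird_id,
      n_choice_trials = spec$n_choice_trials,
      n_ss_choices = n_ss,
      proportion_ss = n_ss / spec$n_choice_trials,
      value_ss = v_ss,
      value_ll = v_ll,
      p_ss = p_ss
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_cohort()], [generate_probe_raster()] and
#' [generate_choices()] under a single seed.
#'
#' @inheritParams generate_cohort
#' @return List with elements `birds`, `rasters`, `choices`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_birds = 2, n_families = 1,
#'                                    n_probe_trials = 2,
#'                                    n_samples_valuation = 1e3), seed = 1)
#' names(sim)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  with_seed_maybe(seed, {
    birds <- generate_cohort(spec)
    rasters <- generate_probe_raster(birds, spec)
    choices <- generate_choices(birds, spec)
    list(birds = birds, rasters = rasters, choices = choices)
  })
}
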