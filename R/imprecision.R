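#' Decompose Spread against fixed interval into fixed and proportional imprecision
#'
#' For each bird, ordinary least squares of Spread (seconds) on the trained
#' fixed interval duration over the three FIs. The intercept `alpha_hat` is
#' the bird's fixed imprecision — the component of timing noise independent
#' of the interval — and the slope `beta_hat` is its proportional
#' imprecision, the rate at which noise grows with the interval. `alpha_hat`
#' may come out negative (an estimation artefact of extrapolating three
#' points to FI = 0); a truncated version with negatives set to zero is
#' carried alongside, and both are retained for downstream analyses.
#'
#' @param peaks Peak-measure tibble from [fit_timing_curves()] (columns
#'   `bird_id`, `fi`, `spread`; extra columns are ignored). Every bird must
#'   have all three FIs with finite non-negative spreads.
#' @param fis The trained fixed intervals expected per bird.
#' @return Tibble, one row per bird: `alpha_hat`, `beta_hat`,
#'   `alpha_truncated`, `r_squared` of the 3-point line, wide spreads
#'   (`spread_5` etc.) and per-FI coefficients of variation
#'   (`cv_5` = spread / FI, etc.).
#' @examples
#' pts <- tibble::tibble(bird_id = "A", fi = c(5, 15, 45),
#'                       spread = 4 + 1.06 * c(5, 15, 45))
#' fit_imprecision(pts)
#' @export
fit_imprecision <- function(peaks, fis = c(5, 15, 45)) {
  pts <- peaks %>%
    select("bird_id", "fi", "spread") %>%
    filter(is.finite(.data$spread))
  missing <- pts %>%
    group_by(.data$bird_id) %>%
    summarise(miss = paste(setdiff(fis, .data$fi), collapse = ", "),
              .groups = "drop") %>%
    filter(.data$miss != "")
  if (nrow(missing)) {
    abort(paste0(
      "Missing FI spread(s): ",
      paste(sprintf("%s (FI %s)", missing$bird_id, missing$miss), collapse = "; ")
    ))
  }
  if (any(pts$spread < 0)) abort("Spreads must be >= 0.")
  est <- pts %>%
    tidyr::nest(data = -"bird_id") %>%
    mutate(res = purrr::map(.data$data, function(d) {
      fit <- lm(spread ~ fi, data = d)
      tss <- sum((d$spread - mean(d$spread))^2)
      rss <- sum(stats::residuals(fit)^2)
      tibble(
        alpha_hat = unname(coef(fit)[1]),
        beta_hat = unname(coef(fit)[2]),
        r_squared = if (tss == 0) 1 else 1 - rss / tss
      )
    })) %>%
    select(-"data") %>%
    tidyr::unnest("res")
  wide <- pts %>%
    mutate(fi = as.integer(.data$fi)) %>%
    tidyr::pivot_wider(names_from = "fi", values_from = "spread",
                       names_prefix = "spread_")
  cvs <- pts %>%
    mutate(cv = .data$spread / .data$fi, fi = as.integer(.data$fi)) %>%
    select(-"spread") %>%
    tidyr::pivot_wider(names_from = "fi", values_from = "cv",
                       names_prefix = "cv_")
  est %>%
    select("bird_id", "alpha_hat", "beta_hat", "r_squared") %>%
    left_join(wide, by = "bird_id") %>%
    left_join(cvs, by = "bird_id") %>%
    truncate_alpha()
}

#' Truncate negative fixed-imprecision estimates at zero
#'
#' Negative fixed imprecision is physically impossible, so a truncated copy
#' of the estimate (`alpha_truncated = max(alpha_hat, 0)`) is added for
#' sensitivity analyses; `alpha_hat` itself and `beta_hat` are untouched.
#'
#' @param estimates Tibble with an `alpha_hat` column.
#' @return The same tibble with `alpha_truncated` added (placed after
#'   `beta_hat` when present).
#' @examples
#' truncate_alpha(tibble::tibble(bird_id = "A", alpha_hat = -2.1))
#' @export
truncate_alpha <- function(estimates) {
  if (!"alpha_hat" %in% names(estimates)) abort("`estimates` needs an `alpha_hat` column.")
  out <- mutate(estimates, alpha_truncated = pmax(.data$alpha_hat, 0))
  if ("beta_hat" %in% names(out)) {
    out <- dplyr::relocate(out, "alpha_truncated", .after = "beta_hat")
  }
  out
}

#' Scalar-variance diagnostics for a cohort of peak fits
#'
#' Scalar expectancy theory's scalar-variance property implies a constant
#' coefficient of variation, CV = Spread / FI, across interval durations.
#' This diagnostic computes the per-bird, per-FI CVs; fits a linear mixed
#' model of CV on FI category (reference SHORT = 5 s, random intercept per
#' bird, maximum likelihood) whose MEDIUM and LONG contrasts quantify
#' departures from constancy; and tests the cohort means of `alpha_hat` and
#' `beta_hat` against zero with one-sample t tests. A positive fixed
#' imprecision makes CV = alpha / FI + beta fall with FI, so a negative LONG
#' contrast is the signature of fixed imprecision in the cohort.
#'
#' @inheritParams fit_imprecision
#' @return List of class `"scalar_variance_diag"`: `cv` (long per-bird CV
#'   table), `cv_summary` (mean and SE per FI), `contrasts` (MEDIUM and LONG
#'   vs SHORT: estimate, SE, df, t, p), `t_tests` (alpha/beta means vs 0),
#'   and the fitted `model`.
#' @examples
#' pts <- tidyr::expand_grid(bird_id = c("A", "B"), fi = c(5, 15, 45)) %>%
#'   dplyr::mutate(spread = c(10, 25, 66, 12, 28, 70)[dplyr::row_number()])
#' scalar_variance_diagnostics(pts)$contrasts
#' @export
scalar_variance_diagnostics <- function(peaks, fis = c(5, 15, 45)) {
  if (dplyr::n_distinct(peaks$bird_id) < 2) abort("Need at least 2 birds.")
  labels <- c("SHORT", "MEDIUM", "LONG")
  cv <- peaks %>%
    filter(is.finite(.data$spread)) %>%
    mutate(
      cv = .data$spread / .data$fi,
      fi_cat = factor(labels[match(.data$fi, sort(fis))], levels = labels)
    ) %>%
    select("bird_id", "fi", "fi_cat", "cv")
  cv_summary <- cv %>%
    group_by(.data$fi, .data$fi_cat) %>%
    summarise(mean_cv = mean(.data$cv), se_cv = sd(.data$cv) / sqrt(n()),
              n = n(), .groups = "drop")
  est <- fit_imprecision(peaks, fis)
  t_tests <- dplyr::bind_rows(
    tidy_t_test(est$alpha_hat, "fixed imprecision (alpha_hat)"),
    tidy_t_test(est$beta_hat, "proportional imprecision (beta_hat)")
  )
  contrasts <- NULL
  model <- NULL
  if (sd(cv$cv) > 0) {
    model <- lmerTest::lmer(cv ~ fi_cat + (1 | bird_id), data = cv, REML = FALSE)
    sm <- coef(summary(model))
    rows <- grep("^fi_cat", rownames(sm))
    contrasts <- tibble(
      contrast = sub("^fi_cat", "", rownames(sm)[rows]),
      estimate = sm[rows, "Estimate"],
      std_error = sm[rows, "Std. Error"],
      df = sm[rows, "df"],
      statistic = sm[rows, "t value"],
      p_value = sm[rows, "Pr(>|t|)"]
    )
  }
  structure(
    list(cv = cv, cv_summary = cv_summary, contrasts = contrasts,
         t_tests = t_tests, model = model),
    class = "scalar_variance_diag"
  )
}

tidy_t_test <- function(x, label) {
  if (sd(x) == 0) {
    return(tibble(measure = label, mean = mean(x), se = 0,
                  statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  tt <- t.test(x, mu = 0)
  tibble(measure = label, mean = mean(x), se = sd(x) / sqrt(length(x)),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' @export
print.scalar_variance_diag <- function(x, ...) {
  cat("Scalar-variance diagnostics\n")
  cat("CV = Spread / FI by interval:\n")
  print(x$cv_summary)
  if (!is.null(x$contrasts)) {
    cat("\nMixed-model contrasts vs SHORT:\n")
    print(x$contrasts)
  }
  cat("\nCohort means vs 0:\n")
  print(x$t_tests)
  invisible(x)
}
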