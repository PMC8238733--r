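#' Standardize a measure within each fixed interval
#'
#' Z-scores a per-bird, per-FI measure to the mean and standard deviation of
#' its own FI, so measures taken at different interval durations become
#' comparable before pooling across keys.
#'
#' @param data Tibble with an `fi` column and the measure column.
#' @param col Name of the column to standardize (string or bare name).
#' @param suffix Suffix for the new column (default `"_z"`).
#' @return `data` with an added column `<col>_z`; within every FI that column
#'   has mean 0 and sample sd 1.
#' @examples
#' standardize_by_fi(tibble::tibble(fi = c(5, 5, 15, 15),
#'                                  spread = c(8, 12, 20, 30)), spread)
#' @export
standardize_by_fi <- function(data, col, suffix = "_z") {
  col <- rlang::as_name(rlang::ensym(col))
  if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
  sds <- data %>%
    group_by(.data$fi) %>%
    summarise(sd = sd(.data[[col]]), n = n(), .groups = "drop")
  if (any(sds$n < 2)) abort("Need at least 2 birds per FI to standardize.")
  if (any(sds$sd == 0)) {
    abort(paste0("Zero standard deviation at FI ",
                 paste(sds$fi[sds$sd == 0], collapse = ", "),
                 "; cannot standardize."))
  }
  data %>%
    group_by(.data$fi) %>%
    mutate("{col}{suffix}" := (.data[[col]] - mean(.data[[col]])) / sd(.data[[col]])) %>%
    ungroup()
}

#' Correlations of imprecision components with per-FI spreads
#'
#' Pearson correlations (with p-values) between the fixed (`alpha_hat`) and
#' proportional (`beta_hat`) imprecision estimates and the Spread at each of
#' the three FIs, plus the correlation between the two components
#' themselves. Constant columns yield `NA` correlations rather than errors.
#'
#' @param estimates Output of [fit_imprecision()] (needs `alpha_hat`,
#'   `beta_hat` and the wide `spread_*` columns).
#' @param truncated Use `alpha_truncated` instead of `alpha_hat`.
#' @return Tidy tibble: `var1`, `var2`, `r`, `p_value`, `n`.
#' @export
imprecision_spread_correlations <- function(estimates, truncated = FALSE) {
  if (nrow(estimates) < 3) abort("Need at least 3 birds.")
  alpha_col <- if (truncated) "alpha_truncated" else "alpha_hat"
  spread_cols <- grep("^spread_", names(estimates), value = TRUE)
  pairs <- dplyr::bind_rows(
    tidyr::expand_grid(var1 = c(alpha_col, "beta_hat"), var2 = spread_cols),
    tibble(var1 = alpha_col, var2 = "beta_hat")
  )
  purrr::pmap(pairs, function(var1, var2) {
    x <- estimates[[var1]]
    y <- estimates[[var2]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble(var1 = var1, var2 = var2, r = NA_real_,
                    p_value = NA_real_, n = sum(ok)))
    }
    ct <- cor.test(x[ok], y[ok])
    tibble(var1 = var1, var2 = var2, r = unname(ct$estimate),
           p_value = ct$p.value, n = sum(ok))
  }) %>% dplyr::bind_rows()
}

# Wrap a fitted lmerTest model with reporting metadata.
new_timing_model <- function(fit, model_id, response, data) {
  structure(
    list(fit = fit, model_id = model_id, response = response,
         n = nrow(data), data = data,
         singular = lme4::isSingular(fit),
         df_method = "Satterthwaite"),
    class = "timing_model"
  )
}

#' Mixed model linking timing imprecision to choice impulsivity
#'
#' Fits the primary inferential model: proportion of smaller-sooner choices
#' regressed on one standardized imprecision component plus sex, with a
#' random intercept for natal family, by maximum likelihood. The fixed and
#' proportional components are too collinear to enter together, so the
#' predictor is entered singly. P-values use Satterthwaite degrees of
#' freedom. Birds missing from any input are dropped listwise.
#'
#' @param choices Tibble with `bird_id`, `proportion_ss`.
#' @param estimates Output of [fit_imprecision()].
#' @param meta Bird metadata with `bird_id`, `sex`, `family_id`.
#' @param predictor `"alpha"` (fixed) or `"beta"` (proportional) imprecision.
#' @param truncated For `predictor = "alpha"`, use the truncated variant.
#' @return A `"timing_model"`; see [tidy.timing_model()] /
#'   [glance.timing_model()]. A singular random-effects fit (family variance
#'   estimated at the zero boundary) is reported, not an error, and flagged
#'   in `glance()`.
#' @export
fit_impulsivity_model <- function(choices, estimates, meta,
                                  predictor = c("alpha", "beta"),
                                  truncated = FALSE) {
  predictor <- match.arg(predictor)
  col <- switch(predictor,
                alpha = if (truncated) "alpha_truncated" else "alpha_hat",
                beta = "beta_hat")
  data <- choices %>%
    inner_join(select(estimates, "bird_id", dplyr::all_of(col)), by = "bird_id") %>%
    inner_join(select(meta, "bird_id", "sex", "family_id"), by = "bird_id") %>%
    filter(is.finite(.data$proportion_ss), is.finite(.data[[col]]))
  if (nrow(data) < 5) abort("Too few birds with complete data.")
  data$imprecision_z <- as.numeric(scale(data[[col]]))
  fit <- lmerTest::lmer(
    proportion_ss ~ imprecision_z + sex + (1 | family_id),
    data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  new_timing_model(
    fit,
    model_id = paste0("impulsivity_", predictor, if (truncated) "_truncated" else ""),
    response = "proportion_ss", data = data
  )
}

#' Mixed models of developmental treatments on timing measures
#'
#' The treatment battery: standardized fixed and proportional imprecision
#' regressed on the developmental treatments Amount (Lean vs Plenty) and
#' Effort (Hard vs Easy) plus sex, with a random intercept for natal family;
#' and per-key Spread, Peak (both standardized within FI) and Peak Rate
#' (raw scale, with Key as an additional fixed effect) with random
#' intercepts for family and for bird nested in family. Each model starts
#' with the Amount x Effort interaction and drops it when non-significant at
#' `prune_p` (sequential removal of non-significant interactions).
#'
#' @param estimates Output of [fit_imprecision()].
#' @param peaks Output of [fit_timing_curves()].
#' @param meta Bird metadata (`bird_id`, `sex`, `family_id`, `amount`,
#'   `effort`).
#' @param prune_p Significance threshold for retaining the interaction.
#' @return Named list of `"timing_model"` objects:
#'   `fixed_imprecision`, `proportional_imprecision`, `spread`, `peak`,
#'   `peak_rate`.
#' @export
fit_treatment_models <- function(estimates, peaks, meta, prune_p = 0.05) {
  needed <- c("bird_id", "sex", "family_id", "amount", "effort")
  missing <- setdiff(needed, names(meta))
  if (length(missing)) {
    abort(paste0("`meta` is missing columns: ", paste(missing, collapse = ", ")))
  }
  meta <- meta %>%
    mutate(amount = factor(.data$amount, levels = c("Plenty", "Lean")),
           effort = factor(.data$effort, levels = c("Easy", "Hard")))

  bird_data <- estimates %>%
    inner_join(select(meta, dplyr::all_of(needed)), by = "bird_id") %>%
    mutate(alpha_z = as.numeric(scale(.data$alpha_hat)),
           beta_z = as.numeric(scale(.data$beta_hat)))
  key_data <- peaks %>%
    filter(!.data$degenerate) %>%
    standardize_by_fi(spread) %>%
    standardize_by_fi(peak_time) %>%
    inner_join(select(meta, dplyr::all_of(needed)), by = "bird_id") %>%
    mutate(key = factor(.data$key, levels = c("LEFT", "CENTRE", "RIGHT")))

  fit_pruned <- function(response, extra, data, nested, model_id) {
    re <- if (nested) "(1 | family_id) + (1 | family_id:bird_id)" else "(1 | family_id)"
    full <- stats::as.formula(paste(
      response, "~ amount * effort + sex", extra, "+", re))
    fit <- lmerTest::lmer(full, data = data, REML = FALSE,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
    sm <- coef(summary(fit))
    int_row <- grep(":", rownames(sm))
    if (length(int_row) && all(sm[int_row, "Pr(>|t|)"] >= prune_p)) {
      reduced <- stats::as.formula(paste(
        response, "~ amount + effort + sex", extra, "+", re))
      fit <- lmerTest::lmer(reduced, data = data, REML = FALSE,
                            control = lme4::lmerControl(check.conv.singular = "ignore"))
    }
    new_timing_model(fit, model_id, response, data)
  }

  list(
    fixed_imprecision = fit_pruned("alpha_z", "", bird_data, FALSE,
                                   "treatment_fixed_imprecision"),
    proportional_imprecision = fit_pruned("beta_z", "", bird_data, FALSE,
                                          "treatment_proportional_imprecision"),
    spread = fit_pruned("spread_z", "", key_data, TRUE, "treatment_spread"),
    peak = fit_pruned("peak_time_z", "", key_data, TRUE, "treatment_peak"),
    peak_rate = fit_pruned("peak_rate", "+ key", key_data, TRUE,
                           "treatment_peak_rate")
  )
}

#' Estimated marginal means for a treatment term
#'
#' @param model A `"timing_model"`.
#' @param term Bare or quoted name of the factor (e.g. `"amount"`).
#' @return Tibble of estimated marginal means with SEs and 95% CIs.
#' @export
treatment_means <- function(model, term) {
  stopifnot(inherits(model, "timing_model"))
  em <- emmeans::emmeans(model$fit, stats::as.formula(paste0("~", term)),
                         lmer.df = "satterthwaite")
  as_tibble(as.data.frame(em))
}

#' @rdname fit_impulsivity_model
#' @param x,object A `"timing_model"`.
#' @param effects `"fixed"` for fixed-effect coefficients (Satterthwaite df
#'   and p-values) or `"ran_pars"` for random-effect standard deviations.
#' @param ... Unused.
#' @export
tidy.timing_model <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    sm <- coef(summary(x$fit))
    tibble(
      term = rownames(sm),
      estimate = unname(sm[, "Estimate"]),
      std_error = unname(sm[, "Std. Error"]),
      df = unname(sm[, "df"]),
      statistic = unname(sm[, "t value"]),
      p_value = unname(sm[, "Pr(>|t|)"])
    )
  } else {
    vc <- as.data.frame(lme4::VarCorr(x$fit))
    tibble(term = paste0(vc$grp, ifelse(is.na(vc$var1), "", paste0(".", vc$var1))),
           variance = vc$vcov, std_dev = vc$sdcor)
  }
}

#' @rdname fit_impulsivity_model
#' @method glance timing_model
#' @export
glance.timing_model <- function(x, ...) {
  tibble(
    model_id = x$model_id, response = x$response, n = x$n,
    df_method = x$df_method, singular = x$singular,
    logLik = as.numeric(stats::logLik(x$fit)),
    AIC = stats::AIC(x$fit)
  )
}

#' @rdname fit_impulsivity_model
#' @export
print.timing_model <- function(x, ...) {
  cat(sprintf("<timing_model> %s: %s, n = %d (%s df%s)\n",
              x$model_id, x$response, x$n, x$df_method,
              if (x$singular) "; singular random effects" else ""))
  print(tidy(x))
  invisible(x)
}
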