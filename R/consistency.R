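#' Variance components of repeated imprecision estimates
#'
#' Given two (or more) estimates of a measure per bird, partitions its
#' variance into individual identity, natal family, and residual components
#' using a mixed model with crossed random intercepts for bird and family
#' (maximum likelihood). Percentages are each component's share of the total
#' modelled variance.
#'
#' @param half_estimates Tibble with columns `bird_id`, `half`, and the
#'   measure columns named in `measures`.
#' @param meta Bird metadata with `bird_id`, `family_id`.
#' @param measures Character vector of measure columns to analyse.
#' @return Tibble: `measure`, `var_individual_pct`, `var_family_pct`,
#'   `var_residual_pct` (each >= 0, summing to 100).
#' @export
consistency_components <- function(half_estimates, meta,
                                   measures = c("alpha_hat", "beta_hat")) {
  data <- inner_join(half_estimates,
                     select(meta, "bird_id", "family_id"), by = "bird_id")
  purrr::map(measures, function(m) {
    d <- filter(data, is.finite(.data[[m]]))
    fit <- lmerTest::lmer(
      stats::as.formula(paste(m, "~ 1 + (1 | bird_id) + (1 | family_id)")),
      data = d, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- setNames(vc$vcov, vc$grp)
    total <- sum(v)
    tibble(
      measure = m,
      var_individual_pct = 100 * v[["bird_id"]] / total,
      var_family_pct = 100 * v[["family_id"]] / total,
      var_residual_pct = 100 * v[["Residual"]] / total
    )
  }) %>% dplyr::bind_rows()
}

#' Split-half consistency of imprecision estimates
#'
#' Splits each bird's probe trials into the final two recorded days and the
#' two days before those, reruns the whole curve-fitting and decomposition
#' chain on each half independently, and partitions the variance of the
#' resulting fixed and proportional imprecision estimates into individual,
#' family and residual components. High individual shares indicate that
#' imprecision is a stable individual attribute rather than session noise.
#'
#' @param rasters Probe raster tibble (see [aggregate_probe()]); each bird
#'   needs at least 4 recorded days.
#' @param meta Bird metadata with `bird_id`, `family_id`.
#' @param order Polynomial order passed to the curve fits.
#' @return A list of class `"split_half_consistency"`: `components` (the
#'   variance-component table from [consistency_components()]) and
#'   `half_estimates` (per-bird, per-half `alpha_hat` / `beta_hat`).
#' @export
split_half_consistency <- function(rasters, meta, order = 10) {
  days <- rasters %>%
    distinct(.data$bird_id, .data$day) %>%
    group_by(.data$bird_id) %>%
    summarise(n_days = n(), .groups = "drop")
  short <- days$bird_id[days$n_days < 4]
  if (length(short)) {
    warn(paste0("Excluding bird(s) with fewer than 4 probe days: ",
                paste(short, collapse = ", ")))
    rasters <- filter(rasters, !.data$bird_id %in% short)
  }
  if (!nrow(rasters)) abort("No birds with at least 4 probe days.")
  halves <- rasters %>%
    group_by(.data$bird_id) %>%
    mutate(half = ifelse(
      .data$day %in% tail(sort(unique(.data$day)), 2), "late", "early"
    )) %>%
    ungroup() %>%
    # restrict the early half to the 2 days immediately before the late ones
    group_by(.data$bird_id, .data$half) %>%
    filter(.data$day %in% tail(sort(unique(.data$day)), 2)) %>%
    ungroup()
  half_estimates <- purrr::map(c("early", "late"), function(h) {
    halves %>%
      filter(.data$half == h) %>%
      aggregate_probe(last_n_days = 2) %>%
      fit_timing_curves(order = order) %>%
      fit_imprecision() %>%
      mutate(half = h)
  }) %>% dplyr::bind_rows()
  structure(
    list(
      components = consistency_components(half_estimates, meta),
      half_estimates = half_estimates
    ),
    class = "split_half_consistency"
  )
}

#' @export
print.split_half_consistency <- function(x, ...) {
  cat("Split-half variance components (% of total):\n")
  print(x$components)
  invisible(x)
}
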