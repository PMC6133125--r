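#' Per-measurement recovery rates
#'
#' Recovery is the measured odor concentration divided by the assigned
#' value for that measurement; its log10 is the deviation on the odor-level
#' scale. Assigned values are derived from each measurement's dosed mass
#' concentration and the component threshold, as in [score_study()].
#'
#' @param measurements Measurement table.
#' @param thresholds Consensus-threshold table covering the components (see
#'   [consensus_thresholds()]); components with a fixed threshold in
#'   `config` do not need a row.
#' @param config [component_config()]; fixed thresholds are honoured when
#'   `use_fixed` is `TRUE`.
#' @param use_fixed Use fixed standard thresholds where configured
#'   (default `TRUE`).
#' @return Measurement table with columns `assigned` (ou_E/m3), `recovery`
#'   and `log10_recovery` appended; grouping keys preserved.
#' @export
recoveries <- function(measurements, thresholds, config = component_config(),
                       use_fixed = TRUE) {
  measurements <- validate_measurements(measurements)
  comps <- unique(measurements$component)
  c0 <- setNames(rep(NA_real_, length(comps)), comps)
  for (k in comps) {
    row <- config[config$component == k, ]
    if (use_fixed && nrow(row) == 1 && !is.na(row$fixed_threshold)) {
      c0[k] <- row$fixed_threshold
    } else {
      thr <- thresholds[thresholds$component == k, ]
      if (nrow(thr) == 0) {
        stop_olfpt(sprintf("no threshold available for component '%s'", k),
                   class = "olfpt_missing_threshold_error")
      }
      c0[k] <- thr$c0
    }
  }
  assigned <- assigned_value(measurements$dosed_mass_conc_ug_m3,
                             unname(c0[measurements$component]))
  dplyr::mutate(
    measurements,
    assigned = assigned,
    recovery = .data$measured_odor_conc_oue_m3 / assigned,
    log10_recovery = log10(.data$recovery)
  )
}

#' Per-test recovery summaries
#'
#' Summarises each (test, component) dosage: the mean assigned odor
#' concentration, the mean measured odor concentration, the relative
#' standard deviation of the measured concentrations (percent, sample SD
#' over mean), and the quartiles of the log10 recoveries
#' (linear-interpolation quantiles, R type 7).
#'
#' @inheritParams recoveries
#' @return Tibble with one row per (test_id, component): `n`,
#'   `X_mean_assigned`, `X_mean_measured`, `rel_sd_pct`, `log_recovery_q1`,
#'   `log_recovery_median`, `log_recovery_q3`.
#' @export
recovery_summary <- function(measurements, thresholds, config = component_config(),
                             use_fixed = TRUE) {
  rec <- recoveries(measurements, thresholds, config = config, use_fixed = use_fixed)
  out <- rec |>
    dplyr::group_by(.data$test_id, .data$component) |>
    dplyr::summarise(
      n = dplyr::n(),
      X_mean_assigned = mean(.data$assigned),
      X_mean_measured = mean(.data$measured_odor_conc_oue_m3),
      sd_measured = sd(.data$measured_odor_conc_oue_m3),
      log_recovery_q1 = quantile(.data$log10_recovery, 0.25, type = 7, names = FALSE),
      log_recovery_median = quantile(.data$log10_recovery, 0.50, type = 7, names = FALSE),
      log_recovery_q3 = quantile(.data$log10_recovery, 0.75, type = 7, names = FALSE),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    bad <- out[out$n < 2, ]
    stop_olfpt(sprintf("group of size 1 (SD undefined): %s / %s",
                       bad$test_id[1], bad$component[1]),
               class = "olfpt_validation_error")
  }
  out$rel_sd_pct <- 100 * out$sd_measured / out$X_mean_measured
  out$sd_measured <- NULL
  out[c("test_id", "component", "n", "X_mean_assigned", "X_mean_measured",
        "rel_sd_pct", "log_recovery_q1", "log_recovery_median", "log_recovery_q3")]
}

#' ISO 5725-2 variance components on the log10 threshold scale
#'
#' One-way analysis of variance of the log10 implied thresholds with the
#' laboratory -- the (test, participant) combination -- as grouping factor,
#' with the unbalanced-design correction: the within-laboratory variance
#' `s_w^2` is the pooled within-group mean square; the between-laboratory
#' variance is `s_L^2 = max(0, (MS_between - s_w^2) / n_bar)` with the
#' effective replicate count
#' `n_bar = (sum(n_i) - sum(n_i^2) / sum(n_i)) / (p - 1)`; the
#' reproducibility variance is their sum, `s_R^2 = s_w^2 + s_L^2`. Negative
#' between-laboratory estimates are truncated at zero. Data from all tests a
#' component was dosed in are pooled into one decomposition.
#'
#' @inheritParams recoveries
#' @param component Component to decompose.
#' @return One-row tibble: `component`, `n_labs`, `n_results`, `s_w`, `s_L`,
#'   `s_R` (log10 units) and the expanded-uncertainty fields of
#'   [expanded_uncertainty()] (`U95_log`, `U95_db`, `rel_low`, `rel_high`).
#' @export
estimate_variance_components <- function(measurements, component) {
  measurements <- validate_measurements(measurements)
  v <- implied_thresholds(measurements, component)
  m <- measurements[measurements$component == component, ]
  lab <- factor(paste(m$test_id, m$participant_id, sep = "/"))
  n_i <- tabulate(lab)
  p <- nlevels(lab)
  if (p < 2 || any(n_i < 2)) {
    stop_olfpt(sprintf("component '%s': need >= 2 labs with >= 2 replicates each", component),
               class = "olfpt_validation_error")
  }
  # the F test is irrelevant here (only the mean squares are used); a
  # zero-residual fit would warn about an unreliable F statistic
  aov_tab <- suppressWarnings(anova(lm(v ~ lab)))
  ms_between <- aov_tab[["Mean Sq"]][1]
  s_w2 <- aov_tab[["Mean Sq"]][2]
  N <- sum(n_i)
  n_bar <- (N - sum(n_i^2) / N) / (p - 1)
  s_L2 <- max(0, (ms_between - s_w2) / n_bar)
  s_R <- sqrt(s_w2 + s_L2)
  eu <- expanded_uncertainty(s_R)
  tibble::tibble(
    component = component, n_labs = p, n_results = N,
    s_w = sqrt(s_w2), s_L = sqrt(s_L2), s_R = s_R,
    U95_log = 2 * s_R, U95_db = eu$U95_db,
    rel_low = eu$rel_low, rel_high = eu$rel_high
  )
}

#' Variance components for every component of a study
#'
#' @inheritParams estimate_variance_components
#' @param components Components to decompose; default all present.
#' @return Tibble, one row per component (see
#'   [estimate_variance_components()]).
#' @export
variance_components_table <- function(measurements, components = NULL) {
  measurements <- validate_measurements(measurements)
  if (is.null(components)) components <- sort(unique(measurements$component))
  dplyr::bind_rows(lapply(components, function(k) {
    estimate_variance_components(measurements, k)
  }))
}

#' Expanded (k = 2) uncertainty of a single olfactometric measurement
#'
#' With reproducibility standard deviation `s_R` on the log10 scale, the
#' expanded uncertainty is `U_0.95 = 2 s_R` in log10 units, i.e.
#' `20 s_R` dB on the odor-level scale (odor level = 10 log10 of a
#' concentration ratio). On the linear scale it is the relative interval
#' `[100 * 10^(-2 s_R), 100 * 10^(2 s_R)]` percent; the bounds are exact
#' reciprocals (their product is 10^4 before rounding). For reporting,
#' round the dB value to 2 decimals and the bounds to integer percent.
#'
#' @param s_R Reproducibility standard deviation, log10 units (>= 0,
#'   vectorized).
#' @return Tibble with `s_R`, `U95_log`, `U95_db`, `rel_low`, `rel_high`
#'   (unrounded).
#' @examples
#' expanded_uncertainty(0.1721)  # 3.44 dB, about 45--220 %
#' @export
expanded_uncertainty <- function(s_R) {
  if (any(!is.finite(s_R) | s_R < 0)) {
    stop_olfpt("expanded_uncertainty: s_R must be >= 0", class = "olfpt_validation_error")
  }
  U95_log <- 2 * s_R
  tibble::tibble(
    s_R = s_R,
    U95_log = U95_log,
    U95_db = 10 * U95_log,
    rel_low = 100 * 10^(-U95_log),
    rel_high = 100 * 10^(U95_log)
  )
}

#' 95\% bound on the ratio of two measurements under reproducibility
#' conditions
#'
#' The factor by which two independent single measurements of the same
#' material in different laboratories differ in at most 95\% of cases:
#' `10^(2 * sqrt(2) * s_R)` (the difference of two independent log10 values
#' has standard deviation `sqrt(2) s_R`).
#'
#' @inheritParams expanded_uncertainty
#' @return Dimensionless factor (>= 1).
#' @examples
#' reproducibility_factor(0.208)  # about 3.9, reported as "factor 4"
#' @export
reproducibility_factor <- function(s_R) {
  if (any(!is.finite(s_R) | s_R < 0)) {
    stop_olfpt("reproducibility_factor: s_R must be >= 0", class = "olfpt_validation_error")
  }
  10^(2 * sqrt(2) * s_R)
}

#' Fraction of recoveries inside a margin
#'
#' Share of per-measurement recoveries lying inside `[low, high]`
#' (inclusive), per component. The default margin 50--200\% is the band the
#' EN 13725 repeatability criterion implies around an assigned value.
#'
#' @param recovery_table Output of [recoveries()].
#' @param low,high Margin bounds as recovery fractions (default 0.5 and 2).
#' @return Tibble with `component`, `n` and `fraction_within`.
#' @export
within_margin_fraction <- function(recovery_table, low = 0.5, high = 2.0) {
  if (!is.data.frame(recovery_table) || nrow(recovery_table) == 0) {
    stop_olfpt("within_margin_fraction: empty recovery table", class = "olfpt_empty_error")
  }
  recovery_table |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      n = dplyr::n(),
      fraction_within = mean(.data$recovery >= low & .data$recovery <= high),
      .groups = "drop"
    )
}
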