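#' Component scoring configuration
#'
#' Per-component settings for the proficiency assessment: an optional fixed
#' odor threshold (components whose threshold a standard defines are scored
#' against that value rather than the consensus; for n-butanol EN 13725 sets
#' 123 ug/m3), the base proficiency criterion `base_sigma` (log10 units,
#' generally 0.10) and the relative standard uncertainty of the dosed mass
#' concentration `u_ck` (1.01\% here, determined by the dosing rig).
#'
#' @param component Character vector of component labels.
#' @param fixed_threshold Numeric vector (ug/m3), `NA` where no fixed value
#'   exists.
#' @param base_sigma Base criterion, log10 units (recycled).
#' @param u_ck Relative uncertainty of the dosed mass concentration
#'   (recycled).
#' @return Tibble with one row per component.
#' @export
component_config <- function(component = c("AAC", "ETX", "NBU", "PIG", "RLI", "THT"),
                             fixed_threshold = ifelse(component == "NBU", 123, NA_real_),
                             base_sigma = 0.10, u_ck = 0.0101) {
  cfg <- tibble::tibble(
    component = component,
    fixed_threshold = as.numeric(fixed_threshold),
    base_sigma = as.numeric(base_sigma),
    u_ck = as.numeric(u_ck)
  )
  ok_thr <- is.na(cfg$fixed_threshold) | cfg$fixed_threshold > 0
  if (!all(ok_thr) || any(cfg$base_sigma <= 0) || any(cfg$u_ck < 0 | cfg$u_ck >= 1)) {
    stop_olfpt("component_config: fixed_threshold must be > 0 when set, base_sigma > 0, u_ck in [0, 1)",
               class = "olfpt_validation_error")
  }
  if (anyDuplicated(cfg$component)) {
    stop_olfpt("component_config: duplicate component", class = "olfpt_validation_error")
  }
  cfg
}

#' Assigned odor concentration for a measurement
#'
#' The assigned value is the dosed mass concentration divided by the
#' component's odor threshold: the odor concentration a perfectly accurate
#' laboratory would report.
#'
#' @param c_ik Dosed mass concentration, ug/m3 (vectorized).
#' @param c0_k Odor threshold of the component, ug/m3.
#' @return Assigned odor concentration, ou_E/m3.
#' @examples
#' assigned_value(73800, 123)  # 600 ou_E/m3
#' @export
assigned_value <- function(c_ik, c0_k) {
  if (any(!is.finite(c_ik) | c_ik <= 0) || any(!is.finite(c0_k) | c0_k <= 0)) {
    stop_olfpt("assigned_value: concentrations must be finite and > 0",
               class = "olfpt_validation_error")
  }
  c_ik / c0_k
}

#' Combined relative uncertainty of an assigned value
#'
#' Quadrature combination of the relative uncertainty of the dosed mass
#' concentration and the relative standard uncertainty of the consensus
#' threshold. For a component with a fixed (standard-defined) threshold the
#' threshold term is zero.
#'
#' @param u_ck Relative uncertainty of the dosed mass concentration, in
#'   `[0, 1)`.
#' @param u_c0_rel Relative standard uncertainty of the threshold, in
#'   `[0, 1)`.
#' @return Combined relative uncertainty `sqrt(u_ck^2 + u_c0_rel^2)`.
#' @export
combined_uncertainty <- function(u_ck, u_c0_rel) {
  if (any(!is.finite(u_ck) | u_ck < 0 | u_ck >= 1) ||
      any(!is.finite(u_c0_rel) | u_c0_rel < 0 | u_c0_rel >= 1)) {
    stop_olfpt("combined_uncertainty: inputs must lie in [0, 1)",
               class = "olfpt_validation_error")
  }
  sqrt(u_ck^2 + u_c0_rel^2)
}

#' Adapt the proficiency criterion to the assigned-value uncertainty
#'
#' A z-score is only fit for purpose if the uncertainty of the assigned
#' value is small against the criterion. The criterion is therefore floored
#' at `(1 / 0.3) * log10(1 + u_k)`: whenever that bound exceeds the base
#' criterion, the criterion is widened (adapted) to it, so that
#' `sigma_k >= (1/0.3) log10(1 + u_k)` always holds.
#'
#' @param u_k Combined relative uncertainty of the assigned value (>= 0),
#'   vectorized.
#' @param base_sigma Base criterion, log10 units (default 0.10).
#' @return Tibble with columns `u_k`, `sigma_k` and `adapted` (`TRUE` where
#'   the floor was active).
#' @export
adapt_sigma <- function(u_k, base_sigma = 0.10) {
  if (any(!is.finite(u_k) | u_k < 0)) {
    stop_olfpt("adapt_sigma: u_k must be >= 0", class = "olfpt_validation_error")
  }
  t <- (1 / 0.3) * log10(1 + u_k)
  tibble::tibble(u_k = u_k, sigma_k = pmax(base_sigma, t), adapted = t > base_sigma)
}

#' z-score of a single olfactometric result
#'
#' Log10 deviation of the measured from the assigned odor concentration,
#' scaled by the proficiency criterion:
#' `z = log10(x_ik / X_ik) / sigma_k`.
#'
#' @param x_ik Measured odor concentration, ou_E/m3 (vectorized).
#' @param X_ik Assigned odor concentration, ou_E/m3.
#' @param sigma_k Proficiency criterion, log10 units (> 0).
#' @return Dimensionless z-score; 0 iff `x_ik == X_ik`.
#' @export
z_score <- function(x_ik, X_ik, sigma_k) {
  if (any(!is.finite(x_ik) | x_ik <= 0) || any(!is.finite(X_ik) | X_ik <= 0)) {
    stop_olfpt("z_score: concentrations must be finite and > 0",
               class = "olfpt_validation_error")
  }
  if (any(!is.finite(sigma_k) | sigma_k <= 0)) {
    stop_olfpt("z_score: sigma_k must be > 0", class = "olfpt_validation_error")
  }
  log10(x_ik / X_ik) / sigma_k
}

#' Score a whole study
#'
#' Builds the per-measurement z-score table for a study: every measurement
#' gets an assigned value from its dosed mass concentration and the
#' component's threshold (the fixed standard value where one is configured,
#' the robust consensus estimate otherwise), and a z-score against the
#' component's adapted criterion.
#'
#' @param measurements Measurement table.
#' @param thresholds Consensus-threshold table from [consensus_thresholds()]
#'   covering every scored component (components with a fixed threshold in
#'   `config` may be absent).
#' @param config [component_config()] table; components absent from it are
#'   scored with its defaults (`base_sigma`, `u_ck`) and no fixed threshold.
#' @param u_convention How the relative threshold uncertainty entering the
#'   criterion adaptation is derived from the consensus fit:
#'   `"linear_upper"` (default) uses the upper-limit definition
#'   `(c0_high/c0 - 1)/2`; `"log"` uses `10^u_log - 1`.
#' @param use_fixed Score against fixed standard thresholds where configured
#'   (default `TRUE`); set `FALSE` to score every component against its
#'   consensus value.
#' @return List of class `olfpt_scores` with elements `criteria` (per
#'   component: threshold used, `u_k`, `sigma_k`, `adapted`) and `z_records`
#'   (per measurement: assigned, measured, z).
#' @export
score_study <- function(measurements, thresholds, config = component_config(),
                        u_convention = c("linear_upper", "log"), use_fixed = TRUE) {
  u_convention <- match.arg(u_convention)
  measurements <- validate_measurements(measurements)
  comps <- sort(unique(measurements$component))
  criteria <- dplyr::bind_rows(lapply(comps, function(k) {
    row <- config[config$component == k, ]
    if (nrow(row) == 0) {
      row <- tibble::tibble(component = k, fixed_threshold = NA_real_,
                            base_sigma = config$base_sigma[1] %||% 0.10,
                            u_ck = config$u_ck[1] %||% 0.0101)
    }
    fixed <- use_fixed && !is.na(row$fixed_threshold)
    if (fixed) {
      c0 <- row$fixed_threshold
      u_c0 <- 0
    } else {
      thr <- thresholds[thresholds$component == k, ]
      if (nrow(thr) == 0) {
        stop_olfpt(sprintf("no threshold available for component '%s'", k),
                   class = "olfpt_missing_threshold_error")
      }
      c0 <- thr$c0
      u_c0 <- switch(u_convention,
        linear_upper = thr$u_c0_rel,
        log = 10^thr$u_log - 1
      )
    }
    u_k <- combined_uncertainty(row$u_ck, u_c0)
    ad <- adapt_sigma(u_k, row$base_sigma)
    tibble::tibble(component = k, threshold_used = c0, threshold_fixed = fixed,
                   u_k = u_k, sigma_k = ad$sigma_k, adapted = ad$adapted)
  }))
  crit <- criteria[match(measurements$component, criteria$component), ]
  assigned <- assigned_value(measurements$dosed_mass_conc_ug_m3, crit$threshold_used)
  z_records <- tibble::tibble(
    test_id = measurements$test_id,
    participant_id = measurements$participant_id,
    component = measurements$component,
    replicate = measurements$replicate,
    assigned = assigned,
    measured = measurements$measured_odor_conc_oue_m3,
    z = z_score(measurements$measured_odor_conc_oue_m3, assigned, crit$sigma_k)
  )
  structure(list(criteria = criteria, z_records = z_records), class = "olfpt_scores")
}

#' @export
print.olfpt_scores <- function(x, ...) {
  cat(sprintf("<olfpt_scores> %d z-score record(s), %d component(s)\n",
              nrow(x$z_records), nrow(x$criteria)))
  print(x$criteria)
  invisible(x)
}

#' Pass/fail verdicts per participant
#'
#' For each participant and component, the mean of the absolute z-scores of
#' the replicates is the component score; the component is passed when that
#' mean is strictly below 3 (a mean of exactly 3 fails). A participant
#' passes overall only if every scored component passed.
#'
#' @param z_records Per-measurement z-score table, e.g.
#'   `score_study(...)$z_records`.
#' @return List with `per_component` (test, participant, component,
#'   `mean_abs_z`, `passed`), `overall` (test, participant,
#'   `overall_passed`), and the cohort `pass_rate` (fraction of participants
#'   passing overall).
#' @export
verdicts <- function(z_records) {
  if (!is.data.frame(z_records) || nrow(z_records) == 0) {
    stop_olfpt("verdicts: empty z-score table", class = "olfpt_empty_error")
  }
  per_component <- z_records |>
    dplyr::group_by(.data$test_id, .data$participant_id, .data$component) |>
    dplyr::summarise(mean_abs_z = mean(abs(.data$z)), .groups = "drop") |>
    dplyr::mutate(passed = .data$mean_abs_z < 3)
  overall <- per_component |>
    dplyr::group_by(.data$test_id, .data$participant_id) |>
    dplyr::summarise(overall_passed = all(.data$passed), .groups = "drop")
  list(
    per_component = per_component,
    overall = overall,
    pass_rate = mean(overall$overall_passed)
  )
}

#' Correlation of component scores with a reference substance
#'
#' Pearson correlation between participants' mean component scores
#' (`mean_abs_z`) for a component and for the reference substance, paired
#' within (test, participant). Used to probe whether performance on the
#' olfactometric reference (n-butanol) predicts performance on other
#' odorants.
#'
#' @param per_component Per-participant component scores, e.g.
#'   `verdicts(...)$per_component`.
#' @param component Component to correlate with the reference.
#' @param reference Reference substance label (default `"NBU"`).
#' @return Pearson correlation coefficient.
#' @export
reference_correlation <- function(per_component, component, reference = "NBU") {
  a <- per_component[per_component$component == component,
                     c("test_id", "participant_id", "mean_abs_z")]
  b <- per_component[per_component$component == reference,
                     c("test_id", "participant_id", "mean_abs_z")]
  pairs <- merge(a, b, by = c("test_id", "participant_id"),
                 suffixes = c("_component", "_reference"))
  if (nrow(pairs) < 3) {
    stop_olfpt(sprintf("need >= 3 paired participants for '%s' vs '%s'", component, reference),
               class = "olfpt_validation_error")
  }
  cor(pairs$mean_abs_z_component, pairs$mean_abs_z_reference)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
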