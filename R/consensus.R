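#' Per-measurement implied odor thresholds
#'
#' Each olfactometric measurement implies an estimate of the component's odor
#' threshold: the dosed mass concentration divided by the measured odor
#' concentration, i.e. the mass concentration that would correspond to
#' 1 ou_E/m3. All downstream consensus and variance statistics work on the
#' log10 of these implied thresholds.
#'
#' @param measurements A measurement table (see [validate_measurements()]).
#' @param component Component label to extract.
#' @return Numeric vector of log10 implied thresholds, in log10(ug/m3), one
#'   per measurement row, in row order.
#' @export
implied_thresholds <- function(measurements, component) {
  measurements <- validate_measurements(measurements)
  m <- measurements[measurements$component == component, ]
  if (nrow(m) == 0) {
    stop_olfpt(sprintf("no measurements for component '%s'", component),
               class = "olfpt_empty_error")
  }
  log10(m$dosed_mass_conc_ug_m3 / m$measured_odor_conc_oue_m3)
}

#' Robust mean and standard deviation (ISO 13528 Algorithm A)
#'
#' Iteratively winsorized location/scale estimate. Starting from the median
#' and the scaled median absolute deviation (`1.483 * MAD`), values are
#' clamped to `m* +/- 1.5 s*`, then `m*` is updated to the mean and `s*` to
#' `1.134` times the standard deviation of the clamped values, until both
#' estimates change by less than `tol` in relative terms (or `max_iter`
#' passes). The scheme tolerates gross outliers: a value far outside
#' `m* +/- 1.5 s*` contributes only its clamped counterpart.
#'
#' Degenerate starts: if all values are identical the result is that value
#' with `s* = 0` and no iteration; if the MAD is zero but the values are not
#' all equal (more than half the sample at one point), the classical standard
#' deviation seeds the first iteration.
#'
#' @param values Numeric vector, at least 3 values. In this package these are
#'   log10 implied thresholds, but the routine is scale-agnostic.
#' @param tol Relative convergence tolerance for both `m*` and `s*`
#'   (default 1e-4).
#' @param max_iter Iteration cap (default 100).
#' @return Named list with `m_star`, `s_star` and the number of iterations
#'   performed (`iterations`).
#' @examples
#' robust_mean_sd(c(-1, 0, 1))$m_star  # 0 by symmetry
#' @export
robust_mean_sd <- function(values, tol = 1e-4, max_iter = 100L) {
  if (!is.numeric(values) || length(values) < 3) {
    stop_olfpt("robust_mean_sd needs at least 3 numeric values",
               class = "olfpt_validation_error")
  }
  if (any(!is.finite(values))) {
    stop_olfpt("values must be finite", class = "olfpt_validation_error")
  }
  if (all(values == values[1])) {
    return(list(m_star = values[1], s_star = 0, iterations = 0L))
  }
  m <- median(values)
  s <- 1.483 * median(abs(values - m))
  if (s == 0) s <- sd(values)
  rel_change <- function(new, old) {
    if (new == old) 0 else abs(new - old) / max(abs(old), abs(new), .Machine$double.eps)
  }
  iter <- 0L
  for (i in seq_len(max_iter)) {
    iter <- i
    delta <- 1.5 * s
    w <- pmin(pmax(values, m - delta), m + delta)
    m_new <- mean(w)
    s_new <- 1.134 * sd(w)
    converged <- rel_change(m_new, m) < tol && rel_change(s_new, s) < tol
    m <- m_new
    s <- s_new
    if (converged || s == 0) break
  }
  list(m_star = m, s_star = s, iterations = iter)
}

#' Robust consensus odor threshold for one component
#'
#' Applies [robust_mean_sd()] to the log10 implied thresholds of all
#' measurements of a component, attaches the ISO 13528 standard uncertainty
#' of a consensus assigned value, `u = 1.25 s* / sqrt(n)`, and
#' back-transforms. The k = 2 interval is geometrically symmetric on the
#' linear scale (`c0_high / c0 == c0 / c0_low`); because the linear-scale
#' uncertainty is skewed towards the upper limit, the relative standard
#' uncertainty `u_c0_rel` is defined from the upper limit as
#' `(c0_high / c0 - 1) / 2`.
#'
#' @inheritParams implied_thresholds
#' @param n_basis Which count enters `sqrt(n)`: `"measurements"` (default;
#'   every individual result counts, the convention used when all results of
#'   all tests are pooled) or `"participant_means"` (one unit per
#'   participant-test combination).
#' @return One-row tibble with columns `component`, `n_results`, `n_basis`,
#'   `m_star`, `s_star`, `u_log` (all log10 scale), and the back-transformed
#'   `c0`, `c0_low`, `c0_high` (ug/m3) plus `u_c0_rel`.
#' @export
consensus_threshold <- function(measurements, component,
                                n_basis = c("measurements", "participant_means")) {
  n_basis <- match.arg(n_basis)
  measurements <- validate_measurements(measurements)
  v <- implied_thresholds(measurements, component)
  rob <- robust_mean_sd(v)
  m <- measurements[measurements$component == component, ]
  n <- switch(n_basis,
    measurements = length(v),
    participant_means = nrow(unique(m[c("test_id", "participant_id")]))
  )
  u_log <- 1.25 * rob$s_star / sqrt(n)
  tibble::tibble(
    component = component,
    n_results = length(v),
    n_basis = n,
    m_star = rob$m_star,
    s_star = rob$s_star,
    u_log = u_log,
    c0 = 10^rob$m_star,
    c0_low = 10^(rob$m_star - 2 * u_log),
    c0_high = 10^(rob$m_star + 2 * u_log),
    u_c0_rel = (10^(2 * u_log) - 1) / 2
  )
}

#' Consensus thresholds for all (or selected) components
#'
#' @inheritParams consensus_threshold
#' @param components Character vector of components; default all present.
#' @return Tibble with one row per component (see [consensus_threshold()]).
#' @export
consensus_thresholds <- function(measurements, components = NULL,
                                 n_basis = c("measurements", "participant_means")) {
  n_basis <- match.arg(n_basis)
  measurements <- validate_measurements(measurements)
  if (is.null(components)) components <- sort(unique(measurements$component))
  dplyr::bind_rows(lapply(components, function(k) {
    consensus_threshold(measurements, k, n_basis = n_basis)
  }))
}
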