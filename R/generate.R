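#' Generate a synthetic inter-laboratory olfactometric dataset
#'
#' Draws one complete study from the measurement model the downstream
#' evaluation assumes. For participant p of a test, a standardized laboratory
#' effect is drawn once (or once per component when `bias_per_component` is
#' set) and scaled by the component's between-laboratory standard deviation
#' `s_L_true` to give the bias `b_p`. Each individual measurement of
#' component k then receives a dosed mass concentration
#' `c_ik = nominal * (1 + d)` with `d` uniform within the relative dosing
#' drift, and a measured odor concentration with
#'
#' `log10(x_ik) = log10(c_ik / c_0k) + b_p + e`,  `e ~ N(0, s_w_true)`.
#'
#' With all noise scales and the drift at zero every measured odor
#' concentration equals `nominal / c_0k` exactly.
#'
#' Randomness is fully reproducible: one root seed spawns an independent
#' substream per (test, participant), so adding a test or participant never
#' shifts the draws of the others, and row order never affects the values.
#'
#' @param config An [study_config()] object.
#' @param seed Integer root seed.
#' @return A validated measurement tibble (see [validate_measurements()]);
#'   participants are labelled `P01`, `P02`, ... within each test.
#' @examples
#' cfg <- default_study_config()
#' m <- generate_study(cfg, seed = 1)
#' nrow(m)  # 456
#' @export
generate_study <- function(config, seed) {
  config <- validate_study_config(config)
  if (length(seed) != 1 || !is.finite(seed) || seed != as.integer(seed)) {
    stop_olfpt("seed must be a single integer", class = "olfpt_config_error")
  }
  seed <- as.integer(seed)
  reps <- config$replicates
  drift <- config$dosing_drift_rel
  blocks <- list()
  for (ti in seq_along(config$tests)) {
    tspec <- config$tests[[ti]]
    comps <- names(tspec$dosing)
    n_rows <- length(comps) * reps
    for (pi in seq_len(tspec$n_participants)) {
      set.seed(child_seed(seed, ti, pi))
      u_shared <- rnorm(1)
      c_ik <- numeric(n_rows)
      x_ik <- numeric(n_rows)
      at <- 0L
      for (comp in comps) {
        u <- if (config$bias_per_component) rnorm(1) else u_shared
        b <- u * config$s_L_true[[comp]]
        log_c0 <- log10(config$true_thresholds[[comp]])
        d <- if (drift > 0) runif(reps, -drift, drift) else numeric(reps)
        e <- rnorm(reps) * config$s_w_true[[comp]]
        idx <- at + seq_len(reps)
        c_ik[idx] <- tspec$dosing[[comp]] * (1 + d)
        x_ik[idx] <- 10^(log10(c_ik[idx]) - log_c0 + b + e)
        at <- at + reps
      }
      blocks[[length(blocks) + 1]] <- tibble::tibble(
        test_id = tspec$test_id,
        participant_id = sprintf("P%02d", pi),
        component = rep(comps, each = reps),
        replicate = rep(seq_len(reps), times = length(comps)),
        dosed_mass_conc_ug_m3 = c_ik,
        measured_odor_conc_oue_m3 = x_ik
      )
    }
  }
  validate_measurements(dplyr::bind_rows(blocks))
}

# Deterministic substream seed per (test, participant); kept within 32-bit
# integer range. Distinct primes keep (ti, pi) pairs from colliding for any
# realistic study size.
#' @keywords internal
child_seed <- function(seed, ti, pi) {
  s <- (as.double(seed) %% 1000003) * 1009 + ti * 7919 + pi * 104729
  as.integer(s %% 2147483647)
}
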