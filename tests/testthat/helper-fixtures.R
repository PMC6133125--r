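# Small study configs used across the test files.

toy_config <- function(s_w = 0.07, s_L = 0.20, drift = 0.02,
                       n_labs = 4, replicates = 3, n_tests = 1,
                       dosing = c(A = 1000, B = 5000),
                       thresholds = c(A = 10, B = 50)) {
  tests <- lapply(seq_len(n_tests), function(i) {
    list(test_id = sprintf("T%d", i), n_participants = n_labs, dosing = dosing)
  })
  study_config(
    tests = tests,
    true_thresholds = thresholds,
    s_w_true = setNames(rep(s_w, length(dosing)), names(dosing)),
    s_L_true = setNames(rep(s_L, length(dosing)), names(dosing)),
    dosing_drift_rel = drift,
    replicates = replicates
  )
}

noise_free_config <- function(...) toy_config(s_w = 0, s_L = 0, drift = 0, ...)

# Measurement table with prescribed log10 implied thresholds per lab:
# dosed mass is fixed at 1 so that measured = 10^(-v) gives implied = v.
measurements_from_implied <- function(values_by_lab, component = "A") {
  rows <- lapply(names(values_by_lab), function(lab) {
    v <- values_by_lab[[lab]]
    tibble::tibble(
      test_id = "T1", participant_id = lab, component = component,
      replicate = seq_along(v),
      dosed_mass_conc_ug_m3 = 1,
      measured_odor_conc_oue_m3 = 10^(-v)
    )
  })
  do.call(rbind, rows)
}

# Brute-force one-way ANOVA variance decomposition (independent oracle):
# explicit loops, no lm()/anova().
anova_oracle <- function(values_by_lab) {
  p <- length(values_by_lab)
  n_i <- vapply(values_by_lab, length, integer(1))
  N <- sum(n_i)
  means <- vapply(values_by_lab, mean, numeric(1))
  grand <- sum(unlist(values_by_lab)) / N
  ss_within <- 0
  for (g in values_by_lab) for (x in g) ss_within <- ss_within + (x - mean(g))^2
  ss_between <- 0
  for (i in seq_len(p)) ss_between <- ss_between + n_i[i] * (means[i] - grand)^2
  ms_within <- ss_within / (N - p)
  ms_between <- ss_between / (p - 1)
  n_bar <- (N - sum(n_i^2) / N) / (p - 1)
  s_w2 <- ms_within
  s_L2 <- max(0, (ms_between - s_w2) / n_bar)
  list(s_w = sqrt(s_w2), s_L = sqrt(s_L2), s_R = sqrt(s_w2 + s_L2))
}

# Literal step-by-step transcription of the iteratively winsorized
# robust-mean procedure (independent oracle for robust_mean_sd).
algorithm_a_oracle <- function(v, tol = 1e-4, max_iter = 100) {
  if (all(v == v[1])) return(list(m = v[1], s = 0))
  m <- median(v)
  s <- 1.483 * median(abs(v - m))
  if (s == 0) s <- sd(v)
  for (it in seq_len(max_iter)) {
    delta <- 1.5 * s
    w <- v
    for (j in seq_along(w)) {
      if (w[j] < m - delta) w[j] <- m - delta
      if (w[j] > m + delta) w[j] <- m + delta
    }
    m2 <- sum(w) / length(w)
    s2 <- 1.134 * sqrt(sum((w - m2)^2) / (length(w) - 1))
    rel <- function(a, b) if (a == b) 0 else abs(a - b) / max(abs(a), abs(b))
    done <- rel(m2, m) < tol && rel(s2, s) < tol
    m <- m2
    s <- s2
    if (done || s == 0) break
  }
  list(m = m, s = s)
}
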