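test_that("assigned values are dosed mass over threshold", {
  expect_equal(assigned_value(123, 123), 1)
  expect_equal(assigned_value(73800, 123), 600)
  expect_equal(assigned_value(246, 123), 2)
  expect_error(assigned_value(-1, 123), class = "olfpt_validation_error")
  expect_error(assigned_value(123, 0), class = "olfpt_validation_error")
})

test_that("assigned-value uncertainties combine in quadrature", {
  expect_equal(combined_uncertainty(0.0101, 0), 0.0101)
  expect_equal(combined_uncertainty(0, 0), 0)
  expect_equal(combined_uncertainty(0.03, 0.04), 0.05)
  expect_error(combined_uncertainty(1, 0), class = "olfpt_validation_error")
})

test_that("the criterion is floored by the assigned-value uncertainty", {
  a <- adapt_sigma(0.0101, base_sigma = 0.10)
  expect_equal(a$sigma_k, 0.10)
  expect_false(a$adapted)
  expect_equal((1 / 0.3) * log10(1 + 0.0101), 0.0145479, tolerance = 1e-6)
  expect_equal(adapt_sigma(0, 0.10)$sigma_k, 0.10)
  # uncertainty large enough to widen the criterion
  u_big <- 10^(0.3 * 0.13) - 1
  a2 <- adapt_sigma(u_big, base_sigma = 0.10)
  expect_equal(a2$sigma_k, 0.13, tolerance = 1e-12)
  expect_true(a2$adapted)
  # the floor always holds after adaptation
  u <- seq(0, 0.5, by = 0.01)
  out <- adapt_sigma(u, 0.10)
  expect_true(all(out$sigma_k >= (1 / 0.3) * log10(1 + u) - 1e-15))
  expect_true(all(out$sigma_k >= 0.10))
})

test_that("z-scores are scaled log10 ratios", {
  expect_equal(z_score(600, 600, 0.1), 0)
  expect_equal(z_score(1200, 600, 0.1), log10(2) / 0.1, tolerance = 1e-12)
  expect_equal(z_score(300, 600, 0.1), -log10(2) / 0.1, tolerance = 1e-12)
  expect_error(z_score(1, 1, 0), class = "olfpt_validation_error")
})

test_that("doubling the criterion halves every z-score", {
  set.seed(4)
  x <- 10^runif(50, 0, 3)
  X <- 10^runif(50, 0, 3)
  expect_equal(z_score(x, X, 0.2), z_score(x, X, 0.1) / 2, tolerance = 1e-12)
})

test_that("|z| < 3 at sigma 0.10 corresponds to recoveries inside 10^(+/-0.3)", {
  X <- 100
  inside <- X * 10^0.3 * 0.999
  outside <- X * 10^0.3 * 1.001
  expect_lt(abs(z_score(inside, X, 0.1)), 3)
  expect_gt(abs(z_score(outside, X, 0.1)), 3)
  # the band is roughly 50% to 200%
  expect_equal(10^-0.3, 0.501, tolerance = 1e-3)
  expect_equal(10^0.3, 1.995, tolerance = 1e-3)
})

test_that("component verdicts use the mean absolute z with a strict cut at 3", {
  z_records <- tibble::tibble(
    test_id = "T1",
    participant_id = rep(c("P01", "P02"), each = 6),
    component = rep(rep(c("A", "B"), each = 3), 2),
    replicate = rep(1:3, 4),
    assigned = 100,
    measured = 100,
    z = c(1, 2, 3,  0, 0, 0,   3, 3, 3,  0, 0, 0)
  )
  v <- verdicts(z_records)
  p1a <- v$per_component[v$per_component$participant_id == "P01" &
                           v$per_component$component == "A", ]
  expect_equal(p1a$mean_abs_z, 2)
  expect_true(p1a$passed)
  p2a <- v$per_component[v$per_component$participant_id == "P02" &
                           v$per_component$component == "A", ]
  expect_equal(p2a$mean_abs_z, 3)
  expect_false(p2a$passed)  # exactly 3 fails
  # one failed component fails the participant overall
  expect_identical(v$overall$overall_passed, c(TRUE, FALSE))
  expect_equal(v$pass_rate, 0.5)
  expect_error(verdicts(z_records[0, ]), class = "olfpt_empty_error")
})

test_that("a noise-free study scored at the generator truth passes with z = 0", {
  cfg <- noise_free_config()
  m <- generate_study(cfg, seed = 1)
  thr <- consensus_thresholds(m)
  sc <- score_study(m, thr, config = component_config(component = names(cfg$true_thresholds)),
                    use_fixed = FALSE)
  expect_equal(sc$z_records$z, rep(0, nrow(m)), tolerance = 1e-9)
  v <- verdicts(sc$z_records)
  expect_equal(v$pass_rate, 1)
})

test_that("fixed standard thresholds override the consensus where configured", {
  m <- generate_study(default_study_config(), seed = 8)
  thr <- consensus_thresholds(m)
  sc <- score_study(m, thr)
  crit <- sc$criteria
  expect_equal(crit$threshold_used[crit$component == "NBU"], 123)
  expect_true(crit$threshold_fixed[crit$component == "NBU"])
  expect_equal(crit$u_k[crit$component == "NBU"], 0.0101)
  other <- crit[crit$component != "NBU", ]
  expect_equal(other$threshold_used,
               thr$c0[match(other$component, thr$component)])
  # without fixed thresholds NBU is scored against its consensus value
  sc2 <- score_study(m, thr, use_fixed = FALSE)
  expect_equal(sc2$criteria$threshold_used[sc2$criteria$component == "NBU"],
               thr$c0[thr$component == "NBU"])
})

test_that("the threshold-uncertainty convention flag changes u_k as documented", {
  m <- generate_study(default_study_config(), seed = 8)
  thr <- consensus_thresholds(m)
  lin <- score_study(m, thr, u_convention = "linear_upper")$criteria
  lg <- score_study(m, thr, u_convention = "log")$criteria
  k <- which(lin$component == "THT")
  u_log <- thr$u_log[thr$component == "THT"]
  expect_equal(lg$u_k[k], combined_uncertainty(0.0101, 10^u_log - 1), tolerance = 1e-12)
  expect_equal(lin$u_k[k],
               combined_uncertainty(0.0101, thr$u_c0_rel[thr$component == "THT"]),
               tolerance = 1e-12)
  expect_gt(lin$u_k[k], lg$u_k[k])  # upper-limit definition is the wider one
})

test_that("reference correlation matches the direct Pearson formula", {
  scores <- tibble::tibble(
    test_id = "T1",
    participant_id = rep(sprintf("P%02d", 1:5), 2),
    component = rep(c("NBU", "THT"), each = 5),
    mean_abs_z = c(0.5, 1.2, 2.8, 0.9, 1.7,   1.1, 0.4, 2.2, 2.9, 0.3)
  )
  a <- scores$mean_abs_z[6:10]
  b <- scores$mean_abs_z[1:5]
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(reference_correlation(scores, "THT"), r_hand, tolerance = 1e-12)
  # identical and negated score vectors
  scores2 <- scores
  scores2$mean_abs_z[6:10] <- scores2$mean_abs_z[1:5]
  expect_equal(reference_correlation(scores2, "THT"), 1, tolerance = 1e-12)
  scores3 <- scores
  scores3$mean_abs_z[6:10] <- -scores3$mean_abs_z[1:5]
  expect_equal(reference_correlation(scores3, "THT"), -1, tolerance = 1e-12)
  expect_error(reference_correlation(scores[c(1, 2, 6, 7), ], "THT"),
               class = "olfpt_validation_error")
})
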