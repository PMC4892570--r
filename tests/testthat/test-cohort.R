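test_that("without jumps the capacity bound keeps every curve occult", {
  coh <- simulate_cohort(no_jump_config(n = 200))
  out <- coh$outcomes
  # k_decay0 = k_growth/2 gives carrying capacity e^2 ~ 7.4 cells
  expect_true(all(is.na(out$t_detect_10)))
  expect_true(all(is.na(out$t_detect_0.5)))
  expect_true(all(is.na(out$t_lethal)))
  expect_true(all(out$n_jumps_total == 0L))
  expect_length(jump_count_histogram(coh, "detect"), 0)
  expect_length(jump_count_histogram(coh, "lethal"), 0)
})

test_that("cohort simulation is deterministic and order-independent", {
  cfg <- small_config(n = 60, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$jump_times, b$jump_times)
  # a single curve resimulated out of cohort order reproduces its row
  one <- simulate_curve(cfg, 37)
  expect_identical(one$k_growth, a$outcomes$k_growth[37])
  expect_identical(unname(one$t_cross[["10"]]) / 365.25,
                   a$outcomes$t_detect_10[37])
  # a different seed gives a different cohort
  expect_false(identical(
    simulate_cohort(small_config(n = 60, seed = 124))$outcomes, a$outcomes))
})

test_that("per-curve crossing times are ordered and bounded", {
  coh <- simulate_cohort(small_config(n = 400, seed = 5))
  out <- coh$outcomes
  det_cols <- paste0("t_detect_", c("0.5", "1", "1.5", "10"))
  td <- as.matrix(out[det_cols])
  # detection time non-decreasing in threshold, on curves where both defined
  for (j in 1:3) {
    both <- !is.na(td[, j]) & !is.na(td[, j + 1])
    expect_true(all(td[both, j] <= td[both, j + 1]))
  }
  # detection strictly precedes lethality
  both <- !is.na(td[, 4]) & !is.na(out$t_lethal)
  expect_gt(sum(both), 0)
  expect_true(all(td[both, 4] < out$t_lethal[both]))
  # nothing is recorded beyond the last simulated period
  t_max <- coh$config$n_periods * coh$config$step_days / 365.25
  expect_true(all(td[!is.na(td)] <= t_max))
  expect_true(all(out$t_lethal[!is.na(out$t_lethal)] <= t_max))
  # no curve beats the pure-exponential lower bound ln(1e10)/k_growth
  reached <- !is.na(td[, 4])
  lb <- log(1e10) / out$k_growth[reached] / 365.25
  expect_true(all(td[reached, 4] >= lb))
})

test_that("jump bookkeeping matches the recorded event times", {
  coh <- simulate_cohort(small_config(n = 150, seed = 9))
  out <- coh$outcomes
  for (i in seq_len(nrow(out))) {
    jt <- coh$jump_times[[i]]
    expect_identical(out$n_jumps_total[i], length(jt))
    if (!is.na(out$t_detect_10[i]))
      expect_identical(out$jumps_detect_10[i],
                       sum(jt <= out$t_detect_10[i]))
    if (!is.na(out$t_lethal[i]))
      expect_identical(out$jumps_lethal[i], sum(jt <= out$t_lethal[i]))
  }
  # k_decay only ever shrinks, so jumps at lethality >= jumps at detection
  both <- !is.na(out$jumps_detect_10) & !is.na(out$jumps_lethal)
  expect_true(all(out$jumps_lethal[both] >= out$jumps_detect_10[both]))
})

test_that("window of opportunity covers exactly the dual-endpoint curves", {
  coh <- simulate_cohort(small_config(n = 300, seed = 21))
  out <- coh$outcomes
  w <- window_of_opportunity(coh, 10)
  both <- !is.na(out$t_detect_10) & !is.na(out$t_lethal)
  expect_length(w, sum(both))
  expect_true(all(w > 0))
  expect_equal(w, (out$t_lethal - out$t_detect_10)[both])
  # a curve pair with prescribed times gives the plain difference
  expect_equal(window_of_opportunity(
    toy_cohort(c(16.4, 31.2, 35.0), c(19.3, 32.6, NA))), c(2.9, 1.4))
})

test_that("empirical_cdf builds a right-continuous step function", {
  e <- empirical_cdf(5)
  expect_equal(e$table, data.frame(value = 5, fraction = 1))
  e <- empirical_cdf(c(1, 2, 2, 4))
  expect_equal(e$table$value, c(1, 2, 4))
  expect_equal(e$table$fraction, c(0.25, 0.75, 1))
  expect_equal(e$fun(c(0.9, 1, 3.9, 4)), c(0, 0.25, 0.75, 1))
  expect_error(empirical_cdf(numeric(0)), "at least one")
  expect_error(empirical_cdf(NA_real_), "at least one")
  # median read from the CDF equals the summary median
  coh <- simulate_cohort(small_config(n = 200, seed = 2))
  td <- coh$outcomes$t_detect_10
  td <- td[!is.na(td)]
  e <- empirical_cdf(td)
  expect_equal(min(e$table$value[e$table$fraction >= 0.5]),
               stats::quantile(td, 0.5, type = 1)[[1]])
})

test_that("step-end crossing mode rounds crossings up to period boundaries", {
  cfg_c <- small_config(n = 80, seed = 31)
  cfg_s <- small_config(n = 80, seed = 31, crossing = "step_end")
  a <- simulate_cohort(cfg_c)$outcomes
  b <- simulate_cohort(cfg_s)$outcomes
  step_y <- 28 / 365.25
  for (cn in c("t_detect_10", "t_lethal")) {
    got <- !is.na(a[[cn]])
    expect_identical(got, !is.na(b[[cn]]))
    expect_true(all(b[[cn]][got] >= a[[cn]][got]))
    expect_true(all(b[[cn]][got] - a[[cn]][got] <= step_y + 1e-12))
    # rounded values sit on period boundaries
    k <- b[[cn]][got] * 365.25 / 28
    expect_equal(k, round(k), tolerance = 1e-8)
  }
})

test_that("configuration validation enforces threshold and rate sanity", {
  expect_error(simulation_config(rate_set = numeric(0)), "non-empty")
  expect_error(simulation_config(rate_set = c(0.01, -0.2)), "positive")
  expect_error(simulation_config(lethal_threshold_cm3 = 5), "exceed")
  expect_error(simulation_config(detection_thresholds_cm3 = numeric(0)),
               "positive")
  cfg <- simulation_config()
  expect_identical(cfg$n_periods, as.integer(ceiling(38.5 * 365.25 / 28)))
})
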