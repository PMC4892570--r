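test_that("visit schedules are arithmetic and horizon-bounded", {
  p5 <- monitoring_protocol(5)
  expect_equal(visit_schedule(1, p5, 38.5), seq(1, 36, by = 5))
  p05 <- monitoring_protocol(0.5)
  v <- visit_schedule(4.9, p05, 38.5)
  expect_length(v, floor((38.5 - 4.9) / 0.5) + 1)  # 68 visits
  expect_true(all(diff(v) > 0))
  expect_lte(max(v), 38.5)
  expect_equal(visit_schedule(40, p05, 38.5), numeric(0))
})

test_that("random first visits are uniform on the protocol window", {
  coh <- toy_cohort(rep(NA_real_, 2e4), rep(NA_real_, 2e4))
  s <- screening_summary(coh, monitoring_protocol(1), seed = 17)
  t0 <- s$first_visits
  expect_true(all(t0 >= 0 & t0 <= 5))
  ks <- suppressWarnings(stats::ks.test(t0, "punif", 0, 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("classification follows the occult / detected / succumbed definitions", {
  coh <- toy_cohort(
    t_detect = c(NA, 10.0, 10.0, 2.0, 36.0, 36.0),
    t_lethal = c(NA, 10.4, 12.0, 2.5, NA, 37.0))
  # annual visits anchored at t0 = 0.8: ..., 9.8, 10.8, ...
  cl <- classify_curves(coh, monitoring_protocol(1), first_visits = 0.8)
  expect_equal(as.character(cl$status),
               c("occult",     # never detectable
                 "succumbed",  # both crossings inside (9.8, 10.8)
                 "detected",   # visit 10.8 falls in the window
                 "succumbed",  # detectable and lethal before first visit
                 "detected",   # no lethal crossing within horizon
                 "detected"))  # visit 36.8 precedes lethality at 37.0
  expect_equal(cl$detecting_visit_time[3], 10.8)
  expect_true(is.na(cl$detecting_visit_time[2]))
  # a visit landing exactly on the lethal instant still detects
  cl2 <- classify_curves(toy_cohort(9.0, 10.8), monitoring_protocol(1),
                         first_visits = 0.8)
  expect_equal(as.character(cl2$status), "detected")
})

test_that("screening proportions partition the cohort for every protocol", {
  coh <- simulate_cohort(small_config(n = 250, seed = 41))
  for (f in c(0.5, 1, 2, 5)) {
    s <- screening_summary(coh, monitoring_protocol(f, 10))
    expect_equal(sum(s$proportions), 1)
    expect_equal(sum(s$counts), 250)
    expect_named(s$proportions, c("occult", "detected", "succumbed"))
    # occult fraction is protocol-independent: it is a property of the curve
    expect_equal(s$proportions[["occult"]],
                 mean(is.na(coh$outcomes$t_detect_10)))
  }
  # continuous monitoring from time zero lets no curve slip through
  s0 <- screening_summary(coh, monitoring_protocol(28 / 365.25, 10),
                          first_visits = 0)
  expect_equal(s0$proportions[["succumbed"]], 0)
})

test_that("nested frequencies with shared first visits nest the succumbed sets", {
  coh <- simulate_cohort(small_config(n = 300, seed = 43))
  set.seed(99)
  t0 <- runif(300, 0, 5)
  succ <- lapply(c(0.5, 1, 2, 4), function(f) {
    cl <- classify_curves(coh, monitoring_protocol(f, 10), t0)
    which(cl$status == "succumbed")
  })
  # coarser visits are a subset of finer ones, so misses can only grow
  for (k in 1:3) expect_true(all(succ[[k]] %in% succ[[k + 1]]))
})

test_that("with shared schedules a more sensitive threshold never creates a miss", {
  coh <- simulate_cohort(small_config(n = 300, seed = 47))
  set.seed(7)
  t0 <- runif(300, 0, 5)
  thr <- c(0.5, 1, 1.5, 10)
  succ <- lapply(thr, function(x) {
    cl <- classify_curves(coh, monitoring_protocol(2, x), t0)
    which(cl$status == "succumbed")
  })
  for (k in 1:3) expect_true(all(succ[[k]] %in% succ[[k + 1]]))
})

test_that("the sensitivity grid is monotone under paired schedules", {
  coh <- simulate_cohort(small_config(n = 300, seed = 53))
  g <- sensitivity_grid(coh, frequencies_years = c(0.5, 1, 2, 4),
                        thresholds_cm3 = c(0.5, 1, 1.5, 10),
                        schedules = "paired")
  expect_equal(nrow(g), 16)
  expect_equal(g$pct_occult + g$pct_detected + g$pct_succumbed,
               rep(100, 16))
  # along nested frequencies at fixed threshold
  for (x in c(0.5, 1, 1.5, 10)) {
    col <- g$pct_succumbed[g$threshold_cm3 == x][order(
      g$frequency_years[g$threshold_cm3 == x])]
    expect_true(all(diff(col) >= 0))
  }
  # along thresholds at fixed frequency
  for (f in c(0.5, 1, 2, 4)) {
    row <- g$pct_succumbed[g$frequency_years == f][order(
      g$threshold_cm3[g$frequency_years == f])]
    expect_true(all(diff(row) >= 0))
  }
  # baseline-difference columns are zero on their own baselines
  expect_true(all(g$diff_vs_baseline_threshold[g$threshold_cm3 == 10] == 0))
  expect_true(all(g$diff_vs_baseline_frequency[g$frequency_years == 0.5] == 0))
  # grid entry equals the stand-alone summary under the same paired draws
  s <- screening_summary(coh, monitoring_protocol(0.5, 10),
                         first_visits = attr(g, "shared_t0"))
  expect_equal(g$pct_succumbed[g$frequency_years == 0.5 &
                                 g$threshold_cm3 == 10],
               100 * s$proportions[["succumbed"]])
})
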