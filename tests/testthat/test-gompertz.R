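test_that("gompertz_cells matches its closed-form anchor points", {
  p <- growth_params(0.0133, 0.00665)
  expect_equal(gompertz_cells(0, p), 1)
  # equal rates: capacity e, approached monotonically
  pe <- growth_params(0.01, 0.01)
  expect_equal(gompertz_cells(1e6, pe), exp(1), tolerance = 1e-12)
  # at the inflection time the count is e^(kg/kd - 1) = e here
  ip <- inflection_point(p)
  expect_equal(ip$t_i, log(2) / 0.00665, tolerance = 1e-12)
  expect_equal(gompertz_cells(ip$t_i, p), exp(1), tolerance = 1e-12)
  # cross-check the inflection value against the numerical ODE
  expect_equal(ode_cells(ip$t_i, 1, 0.0133, 0.00665), exp(1),
               tolerance = 1e-6)
})

test_that("inflection and carrying-capacity identities hold for random parameters", {
  set.seed(42)
  for (i in 1:50) {
    kg <- runif(1, 0.002, 0.05)
    p <- growth_params(kg, kg / runif(1, 1.1, 30))
    ip <- inflection_point(p)
    expect_equal(gompertz_cells(ip$t_i, p), ip$n_i,
                 tolerance = 1e-12)
    expect_equal(carrying_capacity(p), exp(1) * ip$n_i, tolerance = 1e-12)
  }
  # equal rates: no interior inflection, t_i = 0 returned as-is
  ip0 <- inflection_point(growth_params(0.01, 0.01))
  expect_equal(ip0$t_i, 0)
  expect_equal(ip0$n_i, 1)
})

test_that("gompertz_cells is monotone in time and in both rates", {
  p <- growth_params(0.0133, 0.00665)
  tt <- seq(0, 2000, by = 50)
  expect_true(all(diff(gompertz_cells(tt, p)) > 0))
  t1 <- 400
  expect_gt(gompertz_cells(t1, growth_params(0.02, 0.00665)),
            gompertz_cells(t1, p))
  expect_lt(gompertz_cells(t1, growth_params(0.0133, 0.009)),
            gompertz_cells(t1, p))
})

test_that("segment propagation agrees with the numerical ODE oracle", {
  set.seed(7)
  n_cases <- 1000
  for (i in seq_len(n_cases)) {
    kg <- runif(1, 0.002, 0.05)
    ratio <- runif(1, 1.2, 25)
    p <- growth_params(kg, kg / ratio)
    cap <- exp(ratio)
    n_s <- exp(runif(1, 0, 0.9 * ratio))
    dt <- runif(1, 1, 3000)
    t_s <- runif(1, 0, 5000)
    expect_equal(segment_cells(t_s + dt, t_s, n_s, p),
                 ode_cells(dt, n_s, p$k_growth, p$k_decay),
                 tolerance = 1e-6)
    # bounded by the capacity, up to double rounding of the outer exp
    expect_lte(segment_cells(t_s + dt, t_s, n_s, p), cap * (1 + 1e-14))
  }
})

test_that("segment propagation is continuous and reduces to the one-cell solution", {
  p <- growth_params(0.0133, 0.002)
  expect_equal(segment_cells(123, 123, 55, p), 55)
  tt <- c(0, 10, 400, 2000)
  expect_equal(segment_cells(tt, 0, 1, p), gompertz_cells(tt, p))
  expect_error(segment_cells(10, 0, 1e20, growth_params(0.01, 0.005)),
               "carrying capacity")
})

test_that("crossing_time inverts segment_cells and respects the capacity bound", {
  set.seed(99)
  for (i in 1:200) {
    kg <- runif(1, 0.002, 0.05)
    ratio <- runif(1, 2, 40)
    p <- growth_params(kg, kg / ratio)
    n_s <- exp(runif(1, 0, 0.5 * ratio))
    thr <- exp(runif(1, log(n_s) + 0.05, 0.98 * ratio))
    tc <- crossing_time(thr, 0, n_s, p)
    expect_equal(segment_cells(tc, 0, n_s, p), thr, tolerance = 1e-9)
  }
  p <- growth_params(0.0133, 0.00665)
  expect_true(is.na(crossing_time(carrying_capacity(p), 0, 1, p)))
  expect_true(is.na(crossing_time(1e10, 0, 1, p)))  # capacity e^2
  expect_error(crossing_time(5, 0, 10, p), "exceed")
  # near-zero decay: crossing approaches the pure-exponential time ln(N)/kg
  p0 <- growth_params(0.0448, 1e-9)
  expect_equal(crossing_time(1e10, 0, 1, p0), log(1e10) / 0.0448,
               tolerance = 1e-4)
})

test_that("volume, diameter and cell-count conversions are exact", {
  expect_equal(volume_to_diameter(10), 2.673, tolerance = 5e-4)
  expect_equal(volume_to_diameter(1000), 12.407, tolerance = 5e-5)
  expect_equal(cells_to_volume(1e9), 1)
  expect_equal(volume_to_cells(10), 1e10)
  expect_equal(diameter_to_volume(volume_to_diameter(3.7)), 3.7,
               tolerance = 1e-12)
  expect_error(volume_to_diameter(-1), "positive")
  expect_error(cells_to_volume(0), "positive")
})

test_that("parameter validation rejects non-positive or non-finite rates", {
  expect_error(growth_params(0, 0.01), "k_growth")
  expect_error(growth_params(0.01, -1), "k_decay")
  expect_error(growth_params(Inf, 0.01), "k_growth")
  expect_error(growth_params(0.01, 0.005, n0 = 0.5), "n0")
  expect_error(gompertz_cells(-1, growth_params(0.01, 0.005)), "t")
})
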