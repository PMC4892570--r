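# small, fast configurations shared across tests

small_config <- function(n = 100, seed = 11, ...) {
  simulation_config(n_curves = n, seed = seed, ...)
}

no_jump_config <- function(n = 100, seed = 11) {
  simulation_config(n_curves = n, seed = seed,
                    jump = jump_config(alpha_mean = 0, alpha_range = c(0, 0)))
}

# hand-built cohort with prescribed detection/lethal times (years), for
# exercising the monitoring classifier on exact scenarios
toy_cohort <- function(t_detect, t_lethal, threshold_cm3 = 10) {
  cfg <- simulation_config(n_curves = length(t_detect),
                           detection_thresholds_cm3 = threshold_cm3,
                           seed = 1)
  lab <- format(threshold_cm3, trim = TRUE, drop0trailing = TRUE)
  out <- data.frame(curve_id = seq_along(t_detect),
                    k_growth = 0.0133, alpha = NA_real_,
                    n_jumps_total = 0L)
  out[[paste0("t_detect_", lab)]] <- t_detect
  out[[paste0("jumps_detect_", lab)]] <- NA_integer_
  out$t_lethal <- t_lethal
  out$jumps_lethal <- NA_integer_
  structure(list(outcomes = out,
                 jump_times = rep(list(numeric(0)), length(t_detect)),
                 config = cfg),
            class = "hgsoc_cohort")
}

# numerical oracle: integrate dN/dt = N (kg - kd log N) with deSolve
ode_cells <- function(t, n0, k_growth, k_decay, rtol = 1e-10) {
  f <- function(t, y, parms) list(y * (k_growth - k_decay * log(y)))
  out <- deSolve::lsoda(y = n0, times = c(0, t), func = f, parms = NULL,
                        rtol = rtol, atol = 1e-8 * n0)
  unname(out[nrow(out), 2])
}
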