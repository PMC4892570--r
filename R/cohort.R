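DAYS_PER_YEAR <- 365.25

#' Cohort simulation configuration
#'
#' Assembles every condition of a Monte Carlo natural-history run: cohort
#' size, time discretization, the set of initial growth rates, the initial
#' saturation-rate fraction, volume thresholds, the jump process and the
#' master seed.
#'
#' Each curve starts from one malignant cell with `k_growth` sampled
#' uniformly from `rate_set` and `k_decay = kdecay0_fraction * k_growth`
#' (default one half, so the initial carrying capacity is e^2, about 7.4
#' cells: growth is over almost immediately unless jumps intervene). Time
#' advances in `step_days` periods; the horizon is `horizon_years` and the
#' number of periods is derived as `ceiling(horizon_years * 365.25 /
#' step_days)`, so crossings are accepted up to the end of the last period
#' covering the horizon.
#'
#' @param n_curves Number of independent curves. Default 1000.
#' @param step_days Period length, days. Default 28 (one menstrual cycle).
#' @param horizon_years Simulation horizon since inception of the first
#'   malignant cell. Default 38.5 (a cumulative lifetime of menstrual
#'   cycling).
#' @param rate_set Initial growth rates (day^-1) sampled uniformly per
#'   curve. Default [default_rate_fixture()].
#' @param kdecay0_fraction Initial `k_decay` as a fraction of `k_growth`.
#'   Default 0.5.
#' @param detection_thresholds_cm3 Detection volume thresholds recorded in a
#'   single pass. Default `c(0.5, 1, 1.5, 10)`; 10 cm^3 is the baseline TVU
#'   detectability volume.
#' @param lethal_threshold_cm3 Life-threatening volume. Default 1000 cm^3;
#'   reaching it terminates a curve.
#' @param cells_per_cm3 Cells per cm^3. Default 1e9.
#' @param jump A [jump_config()].
#' @param seed Master seed (integer). Every curve derives an independent
#'   substream from it, so results are reproducible and order-independent.
#' @param crossing `"continuous"` (default): threshold crossings resolved
#'   analytically inside a period; `"step_end"`: rounded up to the end of
#'   the period in which they occur.
#' @return An object of class `"hgsoc_sim_config"`.
#' @examples
#' cfg <- simulation_config(n_curves = 10, seed = 1)
#' cfg$n_periods
#' @export
simulation_config <- function(n_curves = 1000,
                              step_days = 28,
                              horizon_years = 38.5,
                              rate_set = default_rate_fixture(),
                              kdecay0_fraction = 0.5,
                              detection_thresholds_cm3 = c(0.5, 1, 1.5, 10),
                              lethal_threshold_cm3 = 1000,
                              cells_per_cm3 = 1e9,
                              jump = jump_config(step_days = step_days),
                              seed = 1L,
                              crossing = c("continuous", "step_end")) {
  crossing <- match.arg(crossing)
  if (!is.numeric(n_curves) || length(n_curves) != 1L || n_curves < 1)
    stop("'n_curves' must be a positive count")
  if (!is.numeric(rate_set) || length(rate_set) == 0L)
    stop("'rate_set' must be a non-empty numeric vector (day^-1)")
  if (any(!is.finite(rate_set)) || any(rate_set <= 0))
    stop("'rate_set' rates must be positive and finite")
  if (!is.numeric(kdecay0_fraction) || kdecay0_fraction <= 0)
    stop("'kdecay0_fraction' must be positive")
  if (!is.numeric(step_days) || step_days <= 0 ||
      !is.numeric(horizon_years) || horizon_years <= 0)
    stop("'step_days' and 'horizon_years' must be positive")
  if (!inherits(jump, "hgsoc_jump_config"))
    stop("'jump' must be created by jump_config()")
  thr <- sort(unique(as.numeric(detection_thresholds_cm3)))
  if (length(thr) == 0L || any(!is.finite(thr)) || any(thr <= 0))
    stop("'detection_thresholds_cm3' must be positive volumes")
  if (!is.numeric(lethal_threshold_cm3) || lethal_threshold_cm3 <= max(thr))
    stop("'lethal_threshold_cm3' must exceed every detection threshold")
  if (any(thr * cells_per_cm3 <= 1))
    stop("thresholds must exceed the single founding cell")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer")
  n_periods <- as.integer(ceiling(horizon_years * DAYS_PER_YEAR / step_days))
  structure(list(
    n_curves = as.integer(n_curves), step_days = step_days,
    horizon_years = horizon_years, n_periods = n_periods,
    rate_set = as.numeric(rate_set), kdecay0_fraction = kdecay0_fraction,
    detection_thresholds_cm3 = thr,
    lethal_threshold_cm3 = lethal_threshold_cm3,
    cells_per_cm3 = cells_per_cm3, jump = jump,
    seed = as.integer(seed), crossing = crossing),
    class = "hgsoc_sim_config")
}

#' @export
print.hgsoc_sim_config <- function(x, ...) {
  cat(sprintf(
    "HGSOC cohort simulation: %d curves, %g-day periods, %.1f-year horizon (%d periods)\n",
    x$n_curves, x$step_days, x$horizon_years, x$n_periods))
  cat(sprintf("  rate set (n = %d): median %.4g /day, range %.4g-%.4g\n",
              length(x$rate_set), stats::median(x$rate_set),
              min(x$rate_set), max(x$rate_set)))
  cat(sprintf("  detection thresholds: %s cm^3; lethal: %g cm^3; seed %d\n",
              paste(x$detection_thresholds_cm3, collapse = ", "),
              x$lethal_threshold_cm3, x$seed))
  print(x$jump)
  invisible(x)
}

# per-element threshold labels, stable regardless of companions in the vector
.thr_labels <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, drop0trailing = TRUE),
         character(1))
}

# independent, order-invariant substream seed for curve i under master seed s
.curve_seed <- function(seed, i, stream = 0L) {
  v <- (abs(as.double(seed)) %% 2147483647) * 48271 +
    as.double(i) * 7919 + as.double(stream) * 104729
  as.integer(v %% 2147483646) + 1L
}

#' Simulate one natural-history curve
#'
#' Draws the curve's initial growth rate and per-period jump probability,
#' generates the jump schedule over all periods, and propagates the
#' piecewise-Gompertz trajectory in closed form between jumps, recording the
#' continuous-time first crossing of every configured volume threshold.
#' Simulation ends at the life-threatening crossing or at the horizon,
#' whichever comes first.
#'
#' Per-curve draw order on the substream derived from `cfg$seed` and
#' `curve_id`: growth-rate index, jump probability (one draw, or one per
#' period under `"per_step"`), the per-period trigger uniforms, then one
#' uniform per triggered jump.
#'
#' @param cfg A [simulation_config()].
#' @param curve_id Positive integer identifying the curve; determines its
#'   random substream.
#' @return A list: `curve_id`, `k_growth`, `alpha` (`NA` under per-step
#'   redraw), `jump_times` (days, jumps applied before termination),
#'   `t_cross` (named vector, days, `NA` where never reached; the last
#'   element is the lethal threshold) and `n_jumps_at` (jumps applied when
#'   each crossing occurred).
#' @export
simulate_curve <- function(cfg, curve_id) {
  stopifnot(inherits(cfg, "hgsoc_sim_config"))
  set.seed(.curve_seed(cfg$seed, curve_id))
  k_growth <- cfg$rate_set[sample.int(length(cfg$rate_set), 1L)]
  jc <- cfg$jump
  alpha <- if (jc$redraw == "per_curve") {
    rep(sample_alpha(1L, jc), cfg$n_periods)
  } else {
    sample_alpha(cfg$n_periods, jc)
  }
  triggered <- jump_occurs(alpha)
  jump_times <- (which(triggered) - 1) * cfg$step_days  # period starts
  u <- stats::runif(length(jump_times))
  res <- .propagate_curve(
    k_growth = k_growth,
    k_decay0 = cfg$kdecay0_fraction * k_growth,
    jump_times = jump_times, jump_u = u,
    t_end = cfg$n_periods * cfg$step_days,
    log_thresholds = log(c(cfg$detection_thresholds_cm3,
                           cfg$lethal_threshold_cm3) * cfg$cells_per_cm3),
    step_days = cfg$step_days, crossing = cfg$crossing)
  names(res$t_cross) <- names(res$n_jumps_at) <-
    .thr_labels(c(cfg$detection_thresholds_cm3, cfg$lethal_threshold_cm3))
  list(curve_id = curve_id, k_growth = k_growth,
       alpha = if (jc$redraw == "per_curve") alpha[1] else NA_real_,
       jump_times = res$jump_times, t_cross = res$t_cross,
       n_jumps_at = res$n_jumps_at)
}

# closed-form piecewise propagation in log-cell space; thresholds ascending,
# last one terminal
.propagate_curve <- function(k_growth, k_decay0, jump_times, jump_u, t_end,
                             log_thresholds, step_days, crossing) {
  n_thr <- length(log_thresholds)
  t_cross <- rep(NA_real_, n_thr)
  n_jumps_at <- rep(NA_integer_, n_thr)
  kd <- k_decay0
  t_s <- 0
  log_n <- 0
  ji <- 1L
  n_jumps <- length(jump_times)
  applied <- 0L
  terminated_at <- NA_real_
  repeat {
    # apply any jump scheduled at the current time
    while (ji <= n_jumps && jump_times[ji] <= t_s) {
      kd <- update_kdecay(kd, jump_u[ji])
      applied <- applied + 1L
      ji <- ji + 1L
    }
    t_e <- if (ji <= n_jumps) min(jump_times[ji], t_end) else t_end
    a <- k_growth / kd
    for (j in seq_len(n_thr)) {
      if (!is.na(t_cross[j]) || log_thresholds[j] >= a) next
      tc <- t_s + log((a - log_n) / (a - log_thresholds[j])) / kd
      if (tc <= t_e) {
        t_cross[j] <- if (crossing == "step_end")
          min(ceiling(tc / step_days) * step_days, t_end) else tc
        n_jumps_at[j] <- applied
        if (j == n_thr) terminated_at <- tc
      }
    }
    if (!is.na(terminated_at) || t_e >= t_end) break
    log_n <- a + (log_n - a) * exp(-kd * (t_e - t_s))
    t_s <- t_e
  }
  kept <- if (is.na(terminated_at)) applied else
    sum(jump_times[seq_len(applied)] <= terminated_at)
  list(t_cross = t_cross, n_jumps_at = n_jumps_at,
       jump_times = jump_times[seq_len(kept)])
}

#' Simulate a cohort of natural-history curves
#'
#' Runs [simulate_curve()] for `cfg$n_curves` independent curves and
#' assembles per-curve outcomes. All times in the outcome table are in
#' years (365.25 days per year).
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `"hgsoc_cohort"`: a list with
#'   \describe{
#'     \item[`outcomes`]{data frame with one row per curve: `curve_id`,
#'       `k_growth`, `alpha`, `n_jumps_total`, one `t_detect_<v>` and
#'       `jumps_detect_<v>` column per detection threshold `<v>` (cm^3),
#'       and `t_lethal`, `jumps_lethal`. Times in years; `NA` where the
#'       threshold was never reached.}
#'     \item[`jump_times`]{list of per-curve jump event times (years).}
#'     \item[`config`]{the configuration echo.}
#'   }
#' @examples
#' coh <- simulate_cohort(simulation_config(n_curves = 50, seed = 7))
#' summary(coh)
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "hgsoc_sim_config"))
  curves <- lapply(seq_len(cfg$n_curves), function(i) simulate_curve(cfg, i))
  thr <- cfg$detection_thresholds_cm3
  labs <- .thr_labels(thr)
  n_det <- length(thr)
  t_cross <- t(vapply(curves, `[[`, numeric(n_det + 1L), "t_cross"))
  n_jat <- t(vapply(curves, `[[`, integer(n_det + 1L), "n_jumps_at"))
  outcomes <- data.frame(
    curve_id = vapply(curves, `[[`, integer(1), "curve_id"),
    k_growth = vapply(curves, `[[`, numeric(1), "k_growth"),
    alpha = vapply(curves, `[[`, numeric(1), "alpha"),
    n_jumps_total = vapply(curves, function(x) length(x$jump_times),
                           integer(1)),
    check.names = FALSE)
  for (j in seq_len(n_det)) {
    outcomes[[paste0("t_detect_", labs[j])]] <- t_cross[, j] / DAYS_PER_YEAR
    outcomes[[paste0("jumps_detect_", labs[j])]] <- n_jat[, j]
  }
  outcomes$t_lethal <- t_cross[, n_det + 1L] / DAYS_PER_YEAR
  outcomes$jumps_lethal <- n_jat[, n_det + 1L]
  structure(list(
    outcomes = outcomes,
    jump_times = lapply(curves, function(x) x$jump_times / DAYS_PER_YEAR),
    config = cfg),
    class = "hgsoc_cohort")
}

# resolve a detection threshold to its outcome column label
.thr_label <- function(cohort, detection_threshold_cm3) {
  thr <- cohort$config$detection_thresholds_cm3
  j <- which(abs(thr - detection_threshold_cm3) < 1e-12)
  if (length(j) != 1L)
    stop("detection threshold ", detection_threshold_cm3,
         " cm^3 was not simulated; configured: ", paste(thr, collapse = ", "))
  .thr_labels(thr[j])
}

#' Detection times of a cohort at a given threshold
#'
#' @param cohort An `"hgsoc_cohort"`.
#' @param detection_threshold_cm3 One of the configured detection
#'   thresholds. Default 10.
#' @return Numeric vector (years), `NA` for curves never reaching it.
#' @export
detection_times <- function(cohort, detection_threshold_cm3 = 10) {
  stopifnot(inherits(cohort, "hgsoc_cohort"))
  cohort$outcomes[[paste0("t_detect_",
                          .thr_label(cohort, detection_threshold_cm3))]]
}

#' Window of opportunity between detectability and lethality
#'
#' For every curve that reaches both the detection threshold and the
#' life-threatening threshold, the elapsed time between the two crossings —
#' the interval during which screening can still catch a non-lethal tumor.
#' Curves reaching only one (or neither) threshold are excluded.
#'
#' @inheritParams detection_times
#' @return Numeric vector of positive durations (years), one per curve
#'   reaching both endpoints.
#' @export
window_of_opportunity <- function(cohort, detection_threshold_cm3 = 10) {
  td <- detection_times(cohort, detection_threshold_cm3)
  tl <- cohort$outcomes$t_lethal
  w <- tl - td
  w[!is.na(w)]
}

#' Empirical cumulative distribution function
#'
#' Right-continuous step CDF of a sample, as a table of the sorted support
#' with cumulative fractions, plus the step function itself.
#'
#' @param values Non-empty numeric vector (NAs dropped).
#' @return A list with `table` (data frame `value`, `fraction`) and `fun`
#'   (the [stats::ecdf()] step function).
#' @examples
#' empirical_cdf(c(1, 2, 2, 4))$table
#' @export
empirical_cdf <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("'values' must contain at least one number")
  f <- stats::ecdf(values)
  v <- sort(unique(values))
  list(table = data.frame(value = v, fraction = f(v)), fun = f)
}

#' Histogram of jump counts at an endpoint
#'
#' Among curves reaching the chosen endpoint, tabulates the number of
#' saturation-rate jumps that had occurred by the time of the crossing.
#'
#' @param cohort An `"hgsoc_cohort"`.
#' @param endpoint `"detect"` or `"lethal"`.
#' @param detection_threshold_cm3 Threshold used when
#'   `endpoint = "detect"`. Default 10.
#' @return A `table` of counts indexed by number of jumps (empty if no
#'   curve reaches the endpoint).
#' @export
jump_count_histogram <- function(cohort, endpoint = c("detect", "lethal"),
                                 detection_threshold_cm3 = 10) {
  stopifnot(inherits(cohort, "hgsoc_cohort"))
  endpoint <- match.arg(endpoint)
  n <- if (endpoint == "lethal") cohort$outcomes$jumps_lethal else
    cohort$outcomes[[paste0("jumps_detect_",
                            .thr_label(cohort, detection_threshold_cm3))]]
  table(n[!is.na(n)])
}

#' @export
summary.hgsoc_cohort <- function(object, detection_threshold_cm3 = NULL, ...) {
  out <- object$outcomes
  thr <- object$config$detection_thresholds_cm3
  if (is.null(detection_threshold_cm3))
    detection_threshold_cm3 <- max(thr)
  stat3 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(n = 0, median = NA, min = NA, max = NA))
    c(n = length(x), median = stats::median(x), min = min(x), max = max(x))
  }
  det <- t(vapply(.thr_labels(thr), function(l)
    stat3(out[[paste0("t_detect_", l)]]), numeric(4)))
  rownames(det) <- paste0(.thr_labels(thr), " cm^3")
  wop <- window_of_opportunity(object, detection_threshold_cm3)
  jd <- out[[paste0("jumps_detect_",
                    .thr_label(object, detection_threshold_cm3))]]
  res <- list(
    n_curves = nrow(out),
    detection = det,
    lethal = stat3(out$t_lethal),
    wop = stat3(wop),
    wop_threshold_cm3 = detection_threshold_cm3,
    occult_fraction = mean(is.na(
      out[[paste0("t_detect_", .thr_label(object, detection_threshold_cm3))]])),
    jumps_at_detect = stat3(as.numeric(jd)),
    jumps_at_lethal = stat3(as.numeric(out$jumps_lethal)))
  class(res) <- "summary.hgsoc_cohort"
  res
}

#' @export
print.summary.hgsoc_cohort <- function(x, ...) {
  cat(sprintf("HGSOC cohort, n = %d curves\n", x$n_curves))
  cat("Time to detection (years) by threshold:\n")
  print(round(x$detection, 2))
  cat(sprintf("Time to life-threatening volume: n = %d, median %.2f, range %.2f-%.2f\n",
              x$lethal["n"], x$lethal["median"], x$lethal["min"],
              x$lethal["max"]))
  cat(sprintf("Window of opportunity at %g cm^3: n = %d, median %.2f, range %.2f-%.2f years\n",
              x$wop_threshold_cm3, x$wop["n"], x$wop["median"], x$wop["min"],
              x$wop["max"]))
  cat(sprintf("Occult at %g cm^3: %.1f%%\n", x$wop_threshold_cm3,
              100 * x$occult_fraction))
  cat(sprintf("Jumps at detection: median %g (range %g-%g); at lethality: median %g (range %g-%g)\n",
              x$jumps_at_detect["median"], x$jumps_at_detect["min"],
              x$jumps_at_detect["max"], x$jumps_at_lethal["median"],
              x$jumps_at_lethal["min"], x$jumps_at_lethal["max"]))
  invisible(x)
}

#' @export
print.hgsoc_cohort <- function(x, ...) {
  cat(sprintf("HGSOC simulated cohort: %d curves (seed %d)\n",
              nrow(x$outcomes), x$config$seed))
  print(summary(x))
  invisible(x)
}
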