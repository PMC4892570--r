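#' Gompertz growth parameters
#'
#' Bundle the kinetic parameters of a Gompertzian tumor growth law
#' \deqn{dN/dt = N (k_{growth} - k_{decay} \log N),}
#' whose solution from a single founding cell is
#' \eqn{N(t) = N_0 \exp[(k_{growth}/k_{decay})(1 - e^{-k_{decay} t})]}.
#' `k_growth` is the initial growth rate constant and `k_decay` the growth
#' saturation rate; both are in units of day^-1. The carrying capacity is
#' \eqn{N(\infty) = N_0\, e^{k_{growth}/k_{decay}}}.
#'
#' @param k_growth Initial growth rate constant (day^-1), positive.
#' @param k_decay Growth saturation rate (day^-1), positive.
#' @param n0 Initial cell count, >= 1. Default 1 (a single malignant cell).
#' @return An object of class `"hgsoc_params"`: a list with elements
#'   `k_growth`, `k_decay`, `n0`.
#' @examples
#' p <- growth_params(0.0133, 0.00665)
#' carrying_capacity(p)  # e^2 ~ 7.39 cells
#' @export
growth_params <- function(k_growth, k_decay, n0 = 1) {
  if (!is.numeric(k_growth) || length(k_growth) != 1L || !is.finite(k_growth) ||
      k_growth <= 0)
    stop("'k_growth' must be a single positive finite number (day^-1)")
  if (!is.numeric(k_decay) || length(k_decay) != 1L || !is.finite(k_decay) ||
      k_decay <= 0)
    stop("'k_decay' must be a single positive finite number (day^-1)")
  if (!is.numeric(n0) || length(n0) != 1L || !is.finite(n0) || n0 < 1)
    stop("'n0' must be a single finite number >= 1")
  structure(list(k_growth = k_growth, k_decay = k_decay, n0 = n0),
            class = "hgsoc_params")
}

#' @export
print.hgsoc_params <- function(x, ...) {
  cat(sprintf(
    "Gompertz parameters: k_growth = %g /day, k_decay = %g /day, N0 = %g\n",
    x$k_growth, x$k_decay, x$n0))
  cat(sprintf("  carrying capacity: %g cells\n", carrying_capacity(x)))
  invisible(x)
}

as_growth_params <- function(p) {
  if (inherits(p, "hgsoc_params")) return(p)
  if (is.list(p) && all(c("k_growth", "k_decay") %in% names(p)))
    return(growth_params(p$k_growth, p$k_decay, if (is.null(p$n0)) 1 else p$n0))
  stop("'p' must be created by growth_params()")
}

#' Gompertz cell count at time t
#'
#' Closed-form cell count of a Gompertz trajectory started from `p$n0` cells
#' at time 0. Strictly increasing in `t` and bounded above by the carrying
#' capacity `p$n0 * exp(k_growth/k_decay)` (which may overflow to `Inf` for
#' very small `k_decay`; use [log_segment_cells()] for log-scale work).
#'
#' @param t Time since inception of the first malignant cell (days),
#'   vectorized, >= 0.
#' @param p Growth parameters from [growth_params()].
#' @return Cell count(s) at `t`.
#' @examples
#' p <- growth_params(0.0133, 0.00665)
#' gompertz_cells(0, p)                       # N0 = 1
#' gompertz_cells(inflection_point(p)$t_i, p) # e, the inflection count
#' @export
gompertz_cells <- function(t, p) {
  p <- as_growth_params(p)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and >= 0 (days)")
  a <- p$k_growth / p$k_decay
  p$n0 * exp(a * (1 - exp(-p$k_decay * t)))
}

#' Carrying capacity of a Gompertz trajectory
#'
#' @param p Growth parameters from [growth_params()].
#' @return `n0 * exp(k_growth/k_decay)`, the asymptotic cell count.
#' @export
carrying_capacity <- function(p) {
  p <- as_growth_params(p)
  p$n0 * exp(p$k_growth / p$k_decay)
}

#' Inflection point of a Gompertz trajectory
#'
#' The time and cell count at which growth deceleration sets in:
#' \eqn{t_i = \ln(k_{growth}/k_{decay}) / k_{decay}} and
#' \eqn{N_i = e^{k_{growth}/k_{decay} - 1}} (for a single founding cell).
#' The carrying capacity exceeds the inflection count by exactly a factor
#' of \eqn{e}. When `k_growth <= k_decay` the returned `t_i` is <= 0:
#' the trajectory from one cell has no interior inflection, and the value
#' is returned as-is for the caller to interpret.
#'
#' @param p Growth parameters from [growth_params()].
#' @return A list with `t_i` (days) and `n_i` (cells, for `n0 = 1`).
#' @examples
#' inflection_point(growth_params(0.0133, 0.00665)) # t_i = ln(2)/0.00665
#' @export
inflection_point <- function(p) {
  p <- as_growth_params(p)
  list(t_i = log(p$k_growth / p$k_decay) / p$k_decay,
       n_i = exp(p$k_growth / p$k_decay - 1))
}

#' Gompertz propagation from an arbitrary segment start
#'
#' Solution of the Gompertz ODE with initial condition `N(t_s) = n_s`:
#' \deqn{\log N(t) = A + (\log n_s - A) e^{-k_{decay}(t - t_s)},
#'   \quad A = k_{growth}/k_{decay}.}
#' This is the propagator used between jumps of the saturation rate: after a
#' jump the trajectory continues from its current size under the updated
#' parameters, continuously in time. With `t_s = 0`, `n_s = n0 = 1` it
#' reduces to [gompertz_cells()].
#'
#' @param t Evaluation time(s), days, `>= t_s`.
#' @param t_s Segment start time, days.
#' @param n_s Cell count at `t_s` (>= 1, below the segment carrying capacity).
#' @param p Growth parameters from [growth_params()] (`n0` is ignored here).
#' @return Cell count(s) at `t`.
#' @seealso [log_segment_cells()] for the overflow-safe log-scale version.
#' @export
segment_cells <- function(t, t_s, n_s, p) {
  exp(log_segment_cells(t, t_s, log(n_s), p))
}

#' Log-scale Gompertz segment propagation
#'
#' @param t Evaluation time(s), days, `>= t_s`.
#' @param t_s Segment start time, days.
#' @param log_n_s Natural log of the cell count at `t_s`.
#' @param p Growth parameters from [growth_params()].
#' @return `log` cell count(s) at `t`.
#' @rdname segment_cells
#' @export
log_segment_cells <- function(t, t_s, log_n_s, p) {
  p <- as_growth_params(p)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < t_s))
    stop("'t' must be finite and >= t_s")
  if (!is.finite(log_n_s) || log_n_s < 0)
    stop("segment start count must be finite and >= 1 cell")
  a <- p$k_growth / p$k_decay
  if (log_n_s > a)
    stop("segment start count exceeds the carrying capacity of its parameters")
  a + (log_n_s - a) * exp(-p$k_decay * (t - t_s))
}

#' Continuous-time threshold crossing within a Gompertz segment
#'
#' Analytic inverse of [segment_cells()]: the time at which a trajectory
#' started at `n_s` cells at `t_s` reaches `threshold` cells,
#' \deqn{t = t_s + \frac{1}{k_{decay}}
#'   \log\frac{A - \log n_s}{A - \log(threshold)},}
#' or `NA` when the threshold is at or above the segment carrying capacity
#' `exp(A)` and is therefore never reached under the current parameters.
#'
#' @param threshold Target cell count, `> n_s`.
#' @param t_s Segment start time, days.
#' @param n_s Cell count at `t_s`.
#' @param p Growth parameters from [growth_params()].
#' @return Crossing time in days, or `NA_real_` if unreachable.
#' @examples
#' p <- growth_params(0.0133, 0.00665 / 32)  # after several jumps
#' tc <- crossing_time(1e10, 0, 1, p)
#' segment_cells(tc, 0, 1, p) / 1e10         # 1, to numerical precision
#' @export
crossing_time <- function(threshold, t_s, n_s, p) {
  p <- as_growth_params(p)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite cell count")
  if (threshold <= n_s)
    stop("'threshold' must exceed the segment start count 'n_s'")
  a <- p$k_growth / p$k_decay
  l_thr <- log(threshold)
  if (l_thr >= a) return(NA_real_)
  t_s + log((a - log(n_s)) / (a - l_thr)) / p$k_decay
}

#' Cell count / tumor volume / spherical diameter conversions
#'
#' Unit conversions used throughout: `cells_per_cm3` cells per cubic
#' centimetre (default 1e9, i.e. 10 cm^3 is 1e10 cells), and the spherical
#' diameter of a volume `v`, `2 * (3 v / 4 pi)^(1/3)`. The 10 cm^3 baseline
#' TVU detection volume corresponds to a 2.673 cm diameter, the 1000 cm^3
#' life-threatening volume to 12.407 cm.
#'
#' @param n Cell count(s), positive.
#' @param v Tumor volume(s) in cm^3, positive.
#' @param cells_per_cm3 Conversion constant, cells per cm^3. Default `1e9`.
#' @return The converted quantity.
#' @examples
#' volume_to_diameter(10)        # 2.673 cm
#' cells_to_volume(1e9)          # 1 cm^3
#' @name conversions
NULL

#' @rdname conversions
#' @export
cells_to_volume <- function(n, cells_per_cm3 = 1e9) {
  if (any(!is.finite(n)) || any(n <= 0)) stop("'n' must be positive and finite")
  if (!is.numeric(cells_per_cm3) || cells_per_cm3 <= 0)
    stop("'cells_per_cm3' must be positive")
  n / cells_per_cm3
}

#' @rdname conversions
#' @export
volume_to_cells <- function(v, cells_per_cm3 = 1e9) {
  if (any(!is.finite(v)) || any(v <= 0)) stop("'v' must be positive and finite")
  v * cells_per_cm3
}

#' @rdname conversions
#' @export
volume_to_diameter <- function(v) {
  if (any(!is.finite(v)) || any(v <= 0)) stop("'v' must be positive and finite")
  2 * (3 * v / (4 * pi))^(1 / 3)
}

#' @rdname conversions
#' @export
diameter_to_volume <- function(v) {
  if (any(!is.finite(v)) || any(v <= 0)) stop("diameter must be positive")
  (4 * pi / 3) * (v / 2)^3
}
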