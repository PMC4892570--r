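#' TVU monitoring protocol
#'
#' A transvaginal-ultrasound monitoring protocol: the first visit falls
#' uniformly inside `first_visit_window_years` (default the first five
#' years after inception of the first malignant cell), subsequent visits
#' repeat every `frequency_years`. Specificity and compliance are
#' structural: no false positives, no off-schedule visits.
#'
#' @param frequency_years Inter-visit interval, years (e.g. 0.5 for
#'   semiannual, 1 for annual, 2 for biennial).
#' @param detection_threshold_cm3 Volume at which a visit detects the
#'   tumor. Default 10.
#' @param first_visit_window_years Two numbers, the support of the uniform
#'   first-visit offset. Default `c(0, 5)`.
#' @return An object of class `"hgsoc_protocol"`.
#' @export
monitoring_protocol <- function(frequency_years,
                                detection_threshold_cm3 = 10,
                                first_visit_window_years = c(0, 5)) {
  if (!is.numeric(frequency_years) || length(frequency_years) != 1L ||
      frequency_years <= 0)
    stop("'frequency_years' must be a single positive number")
  if (!is.numeric(detection_threshold_cm3) || detection_threshold_cm3 <= 0)
    stop("'detection_threshold_cm3' must be positive")
  w <- as.numeric(first_visit_window_years)
  if (length(w) != 2L || any(!is.finite(w)) || w[1] < 0 || w[1] > w[2])
    stop("'first_visit_window_years' must be ordered non-negative bounds")
  structure(list(frequency_years = frequency_years,
                 detection_threshold_cm3 = detection_threshold_cm3,
                 first_visit_window_years = w),
            class = "hgsoc_protocol")
}

#' Visit schedule of a monitoring protocol
#'
#' @param t0_years First visit time (years); draw it uniformly from the
#'   protocol's first-visit window for a random schedule.
#' @param protocol A [monitoring_protocol()].
#' @param horizon_years Last time a visit can take place.
#' @return Strictly increasing vector of visit times (years) up to the
#'   horizon.
#' @examples
#' visit_schedule(1, monitoring_protocol(5), 38.5)  # 1, 6, ..., 36
#' @export
visit_schedule <- function(t0_years, protocol, horizon_years) {
  stopifnot(inherits(protocol, "hgsoc_protocol"))
  if (t0_years > horizon_years) return(numeric(0))
  seq(t0_years, horizon_years, by = protocol$frequency_years)
}

# first visit at or after time tt, given first visit t0 and interval f
.first_visit_at_or_after <- function(tt, t0, f) {
  ifelse(tt <= t0, t0, t0 + ceiling((tt - t0) / f) * f)
}

#' Classify curves under a monitoring protocol
#'
#' Three-way, exhaustive classification of every simulated curve:
#' \describe{
#'   \item{occult}{never reaches the protocol's detection volume within the
#'     simulation horizon.}
#'   \item{succumbed}{reaches the life-threatening volume strictly before
#'     the first scheduled visit at or after its detection crossing — both
#'     thresholds fall between consecutive visits (or before the first
#'     visit), so monitoring never sees a detectable, non-lethal tumor.}
#'   \item{detected}{caught by a visit inside its window of opportunity. A
#'     curve whose detection crossing is within the horizon but whose
#'     catching visit falls beyond it is still `detected` when the lethal
#'     volume is not reached within the horizon: tumor volume is
#'     non-decreasing, so detection at that visit is certain.}
#' }
#' A visit at exactly the lethal-crossing instant counts as detection
#' (strict inequality, a measure-zero tie-break).
#'
#' @param cohort An `"hgsoc_cohort"` whose configuration includes the
#'   protocol's detection threshold.
#' @param protocol A [monitoring_protocol()].
#' @param first_visits Vector of per-curve first-visit times (years),
#'   recycled if length 1.
#' @return A data frame with `curve_id`, `status` (factor occult /
#'   detected / succumbed) and `detecting_visit_time` (years; `NA` unless
#'   detected).
#' @export
classify_curves <- function(cohort, protocol, first_visits) {
  stopifnot(inherits(cohort, "hgsoc_cohort"),
            inherits(protocol, "hgsoc_protocol"))
  td <- detection_times(cohort, protocol$detection_threshold_cm3)
  tl <- cohort$outcomes$t_lethal
  n <- length(td)
  t0 <- rep_len(first_visits, n)
  t_star <- .first_visit_at_or_after(td, t0, protocol$frequency_years)
  status <- rep("detected", n)
  status[!is.na(tl) & tl < t_star] <- "succumbed"
  status[is.na(td)] <- "occult"
  data.frame(
    curve_id = cohort$outcomes$curve_id,
    status = factor(status, levels = c("occult", "detected", "succumbed")),
    detecting_visit_time = ifelse(status == "detected", t_star, NA_real_))
}

#' Screening outcome proportions under a protocol
#'
#' Draws an independent uniform first-visit time for every curve and
#' reports the occult / detected / succumbed proportions.
#'
#' @param cohort An `"hgsoc_cohort"`.
#' @param protocol A [monitoring_protocol()].
#' @param seed Seed for the first-visit draws. Default derives one from the
#'   cohort's master seed so repeated calls are reproducible.
#' @param first_visits Optional explicit per-curve first-visit times
#'   (years), bypassing the random draw (used for paired schedules).
#' @return A list with `proportions` (named numeric, sums to 1), `counts`,
#'   `classification` (the per-curve data frame) and `first_visits`.
#' @examples
#' coh <- simulate_cohort(simulation_config(n_curves = 100, seed = 3))
#' screening_summary(coh, monitoring_protocol(1))$proportions
#' @export
screening_summary <- function(cohort, protocol, seed = NULL,
                              first_visits = NULL) {
  stopifnot(inherits(cohort, "hgsoc_cohort"))
  n <- nrow(cohort$outcomes)
  if (is.null(first_visits)) {
    if (is.null(seed))
      seed <- .curve_seed(cohort$config$seed,
                          round(1e3 * protocol$frequency_years), stream = 1L)
    set.seed(seed)
    w <- protocol$first_visit_window_years
    first_visits <- stats::runif(n, w[1], w[2])
  }
  cl <- classify_curves(cohort, protocol, first_visits)
  counts <- table(cl$status)
  list(proportions = stats::setNames(as.numeric(counts) / n, names(counts)),
       counts = counts, classification = cl, first_visits = first_visits)
}

#' Succumbed-percentage grid over frequencies and thresholds
#'
#' Evaluates every combination of monitoring frequency and detection
#' threshold on one simulated cohort and reports the percentage of curves
#' succumbed (both thresholds crossed between consecutive visits), together
#' with the difference against the baseline threshold (largest, usually 10
#' cm^3) and the baseline frequency (smallest, usually semiannual).
#'
#' With `schedules = "paired"` a single per-curve first-visit time is
#' shared across all grid cells, which makes the monotonicity of the grid
#' exact when frequencies are nested: the visits of a coarser frequency are
#' then a subset of the finer one's. `"independent"` (default) redraws
#' first visits per cell, matching independently simulated protocols.
#'
#' @param cohort An `"hgsoc_cohort"` simulated with all `thresholds_cm3`.
#' @param frequencies_years Monitoring frequencies. Default
#'   `c(0.5, 1, 2, 3, 4, 5)`.
#' @param thresholds_cm3 Detection thresholds. Default `c(0.5, 1, 1.5, 10)`.
#' @param schedules `"independent"` or `"paired"`.
#' @param seed Seed for first-visit draws; defaults to a stream derived
#'   from the cohort seed.
#' @param first_visit_window_years Passed to [monitoring_protocol()].
#' @return Data frame with one row per (frequency, threshold):
#'   `frequency_years`, `threshold_cm3`, `pct_occult`, `pct_detected`,
#'   `pct_succumbed`, `diff_vs_baseline_threshold`,
#'   `diff_vs_baseline_frequency` (percentage points).
#' @export
sensitivity_grid <- function(cohort,
                             frequencies_years = c(0.5, 1, 2, 3, 4, 5),
                             thresholds_cm3 = c(0.5, 1, 1.5, 10),
                             schedules = c("independent", "paired"),
                             seed = NULL,
                             first_visit_window_years = c(0, 5)) {
  stopifnot(inherits(cohort, "hgsoc_cohort"))
  schedules <- match.arg(schedules)
  n <- nrow(cohort$outcomes)
  if (is.null(seed)) seed <- .curve_seed(cohort$config$seed, 0L, stream = 2L)
  set.seed(seed)
  w <- first_visit_window_years
  shared_t0 <- stats::runif(n, w[1], w[2])
  grid <- expand.grid(frequency_years = frequencies_years,
                      threshold_cm3 = thresholds_cm3,
                      KEEP.OUT.ATTRS = FALSE)
  pct <- matrix(NA_real_, nrow(grid), 3,
                dimnames = list(NULL, c("occult", "detected", "succumbed")))
  for (i in seq_len(nrow(grid))) {
    prot <- monitoring_protocol(grid$frequency_years[i],
                                grid$threshold_cm3[i], w)
    t0 <- if (schedules == "paired") shared_t0 else
      stats::runif(n, w[1], w[2])
    cl <- classify_curves(cohort, prot, t0)
    pct[i, ] <- as.numeric(table(cl$status)) / n * 100
  }
  out <- cbind(grid, pct_occult = pct[, 1], pct_detected = pct[, 2],
               pct_succumbed = pct[, 3])
  base_thr <- max(thresholds_cm3)
  base_freq <- min(frequencies_years)
  base_by_freq <- out$pct_succumbed[out$threshold_cm3 == base_thr][
    match(out$frequency_years, frequencies_years)]
  base_by_thr <- out$pct_succumbed[out$frequency_years == base_freq][
    match(out$threshold_cm3, thresholds_cm3)]
  out$diff_vs_baseline_threshold <- out$pct_succumbed - base_by_freq
  out$diff_vs_baseline_frequency <- out$pct_succumbed - base_by_thr
  if (schedules == "paired") attr(out, "shared_t0") <- shared_t0
  out
}
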