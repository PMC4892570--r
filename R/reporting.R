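#' Read a run configuration from YAML or JSON
#'
#' The file mirrors [simulation_config()]: top-level keys `n_curves`,
#' `step_days`, `horizon_years`, `kdecay0_fraction`,
#' `detection_thresholds_cm3`, `lethal_threshold_cm3`, `cells_per_cm3`,
#' `seed`, `crossing`, an optional `rate_set` (inline list) or `rate_file`
#' (path to a one-rate-per-line text file, resolved relative to the
#' configuration file), and an optional `jump` block with [jump_config()]
#' keys (`alpha_mean`, `alpha_sdlog`, `alpha_range`, `redraw`,
#' `alpha_meanlog`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `"hgsoc_sim_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration must be a mapping of keys")
  jump_keys <- c("alpha_mean", "alpha_sdlog", "alpha_range", "redraw",
                 "alpha_meanlog", "step_days")
  jump_args <- raw$jump
  if (!is.null(jump_args)) {
    bad <- setdiff(names(jump_args), jump_keys)
    if (length(bad)) stop("unknown jump configuration keys: ",
                          paste(bad, collapse = ", "))
    if (!is.null(jump_args$alpha_range))
      jump_args$alpha_range <- as.numeric(unlist(jump_args$alpha_range))
  }
  if (!is.null(raw$rate_file)) {
    rf <- raw$rate_file
    if (!file.exists(rf)) rf <- file.path(dirname(path), raw$rate_file)
    raw$rate_set <- read_rate_set(rf)
  }
  args <- raw[intersect(names(raw),
                        names(formals(simulation_config)))]
  if (!is.null(args$rate_set)) args$rate_set <- as.numeric(unlist(args$rate_set))
  if (!is.null(args$detection_thresholds_cm3))
    args$detection_thresholds_cm3 <-
      as.numeric(unlist(args$detection_thresholds_cm3))
  if (!is.null(jump_args)) {
    if (is.null(jump_args$step_days) && !is.null(args$step_days))
      jump_args$step_days <- args$step_days
    args$jump <- do.call(jump_config, jump_args)
  }
  known <- c(names(formals(simulation_config)), "jump", "rate_file")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  do.call(simulation_config, args)
}

.config_echo <- function(cfg) {
  jc <- cfg$jump
  list(n_curves = cfg$n_curves, step_days = cfg$step_days,
       horizon_years = cfg$horizon_years, n_periods = cfg$n_periods,
       rate_set = cfg$rate_set, kdecay0_fraction = cfg$kdecay0_fraction,
       detection_thresholds_cm3 = cfg$detection_thresholds_cm3,
       lethal_threshold_cm3 = cfg$lethal_threshold_cm3,
       cells_per_cm3 = cfg$cells_per_cm3, seed = cfg$seed,
       crossing = cfg$crossing,
       jump = list(alpha_mean = jc$alpha_mean, alpha_sdlog = jc$alpha_sdlog,
                   alpha_range = jc$alpha_range, redraw = jc$redraw,
                   alpha_meanlog = jc$alpha_meanlog,
                   alpha_mean_effective = jc$alpha_mean_effective))
}

.write_manifest <- function(out_dir, cfg, files) {
  manifest <- list(
    package = "hgsocsim",
    version = as.character(utils::packageVersion("hgsocsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = .config_echo(cfg),
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run a cohort simulation and write its report files
#'
#' Simulates the configured cohort and writes, under `out_dir`:
#' `curves.csv` (per-curve outcomes, times in years at two decimals, rates
#' at four significant digits), `summary.json` (full-precision medians,
#' ranges and counts), `cdf_detection.csv`, `cdf_lethal.csv`, `cdf_wop.csv`
#' (empirical CDF tables at the baseline threshold),
#' `jump_histograms.csv`, and `manifest.json` (configuration echo, seed,
#' version, file inventory). On error, partially written outputs are
#' removed.
#'
#' @param config An `"hgsoc_sim_config"` or the path of a YAML/JSON
#'   configuration file.
#' @param out_dir Output directory, created if needed.
#' @param seed Optional master-seed override.
#' @param n_curves Optional cohort-size override.
#' @return Invisibly, the `"hgsoc_cohort"`.
#' @export
run_cohort <- function(config, out_dir, seed = NULL, n_curves = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  stopifnot(inherits(cfg, "hgsoc_sim_config"))
  if (!is.null(seed) || !is.null(n_curves)) {
    cfg_args <- .config_echo(cfg)
    cfg_args$jump <- cfg$jump
    cfg_args$n_periods <- NULL
    if (!is.null(seed)) cfg_args$seed <- seed
    if (!is.null(n_curves)) cfg_args$n_curves <- n_curves
    cfg <- do.call(simulation_config, cfg_args)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c("curves.csv", "summary.json", "cdf_detection.csv",
             "cdf_lethal.csv", "cdf_wop.csv", "jump_histograms.csv",
             "manifest.json")
  on_fail <- function(e) {
    unlink(file.path(out_dir, files))
    stop(e)
  }
  coh <- tryCatch({
    coh <- simulate_cohort(cfg)
    out <- coh$outcomes
    thr <- cfg$detection_thresholds_cm3
    base <- max(thr)
    rounded <- out
    time_cols <- c(grep("^t_detect_", names(out), value = TRUE), "t_lethal")
    for (cn in time_cols) rounded[[cn]] <- round(out[[cn]], 2)
    rounded$k_growth <- signif(out$k_growth, 4)
    rounded$alpha <- signif(out$alpha, 4)
    utils::write.csv(rounded, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
    s <- unclass(summary(coh, detection_threshold_cm3 = base))
    s$detection <- cbind(data.frame(threshold_cm3 = thr),
                         as.data.frame(s$detection))
    # named vectors serialize as bare arrays; keep the names as JSON keys
    for (nm in c("lethal", "wop", "jumps_at_detect", "jumps_at_lethal"))
      s[[nm]] <- as.list(s[[nm]])
    jsonlite::write_json(
      list(summary = s, config = .config_echo(cfg)),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    td <- detection_times(coh, base)
    wop <- window_of_opportunity(coh, base)
    write_cdf <- function(x, f) {
      x <- x[!is.na(x)]
      tab <- if (length(x)) empirical_cdf(x)$table else
        data.frame(value = numeric(0), fraction = numeric(0))
      utils::write.csv(tab, file.path(out_dir, f), row.names = FALSE)
    }
    write_cdf(td, "cdf_detection.csv")
    write_cdf(out$t_lethal, "cdf_lethal.csv")
    write_cdf(wop, "cdf_wop.csv")
    hist_df <- do.call(rbind, lapply(c("detect", "lethal"), function(ep) {
      h <- jump_count_histogram(coh, ep, base)
      if (length(h) == 0L) return(NULL)
      data.frame(endpoint = ep, n_jumps = as.integer(names(h)),
                 n_curves = as.integer(h))
    }))
    if (is.null(hist_df))
      hist_df <- data.frame(endpoint = character(0), n_jumps = integer(0),
                            n_curves = integer(0))
    utils::write.csv(hist_df, file.path(out_dir, "jump_histograms.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, cfg, files)
    coh
  }, error = on_fail)
  invisible(coh)
}

#' Run the screening evaluation and write its tables
#'
#' Simulates the configured cohort once, then evaluates TVU monitoring on
#' it. Writes under `out_dir`: `screening_by_frequency.csv` (occult /
#' detected / succumbed percentages at the baseline threshold across
#' monitoring frequencies), `sensitivity_grid.csv` (succumbed percentages
#' over the frequency-by-threshold grid with baseline differences), and
#' `manifest.json`.
#'
#' @inheritParams run_cohort
#' @param frequencies_years Monitoring frequencies. Default
#'   `c(5, 4, 3, 2, 1, 0.5)`.
#' @param schedules `"independent"` (default) or `"paired"`; see
#'   [sensitivity_grid()].
#' @return Invisibly, a list with elements `by_frequency` and `grid`.
#' @export
run_screening <- function(config, out_dir, seed = NULL, n_curves = NULL,
                          frequencies_years = c(5, 4, 3, 2, 1, 0.5),
                          schedules = c("independent", "paired")) {
  schedules <- match.arg(schedules)
  cfg <- if (is.character(config)) read_run_config(config) else config
  stopifnot(inherits(cfg, "hgsoc_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c("screening_by_frequency.csv", "sensitivity_grid.csv",
             "manifest.json")
  res <- tryCatch({
    coh <- simulate_cohort(if (is.null(seed) && is.null(n_curves)) cfg else {
      a <- .config_echo(cfg)
      a$jump <- cfg$jump
      a$n_periods <- NULL
      if (!is.null(seed)) a$seed <- seed
      if (!is.null(n_curves)) a$n_curves <- n_curves
      do.call(simulation_config, a)
    })
    base <- max(cfg$detection_thresholds_cm3)
    by_freq <- do.call(rbind, lapply(frequencies_years, function(f) {
      p <- screening_summary(coh, monitoring_protocol(f, base))$proportions
      data.frame(frequency_years = f, pct_occult = 100 * p[["occult"]],
                 pct_detected = 100 * p[["detected"]],
                 pct_succumbed = 100 * p[["succumbed"]])
    }))
    utils::write.csv(by_freq, file.path(out_dir, "screening_by_frequency.csv"),
                     row.names = FALSE)
    grid <- sensitivity_grid(coh, sort(frequencies_years),
                             cfg$detection_thresholds_cm3,
                             schedules = schedules)
    utils::write.csv(grid, file.path(out_dir, "sensitivity_grid.csv"),
                     row.names = FALSE)
    .write_manifest(out_dir, coh$config, files)
    list(by_frequency = by_freq, grid = grid, cohort = coh)
  }, error = function(e) {
    unlink(file.path(out_dir, files))
    stop(e)
  })
  invisible(res)
}

#' Estimate growth rates from a measurement CSV
#'
#' Reads a CSV of bi-dimensional tumor measurements (columns `a_cm`,
#' `b_cm`, `status`, `t_days`; see [estimate_rates()]), writes the derived
#' rates as CSV (columns `case_id`, `r_cm`, `volume_cm3`, `rate_per_day`)
#' and returns them. Non-informative rows are skipped with a warning.
#'
#' @param csv_path Input CSV path.
#' @param out_path Output CSV path.
#' @param convention Radius convention, see [weighted_radius()].
#' @return Invisibly, the rates data frame.
#' @export
run_rate_estimation <- function(csv_path, out_path,
                                convention = c("geometric", "product")) {
  m <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  rates <- estimate_rates(m, convention = match.arg(convention))
  out <- rates
  out$r_cm <- signif(rates$r_cm, 4)
  out$volume_cm3 <- signif(rates$volume_cm3, 4)
  out$rate_per_day <- signif(rates$rate_per_day, 4)
  utils::write.csv(out, out_path, row.names = FALSE)
  invisible(rates)
}
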