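#' Weighted spherical radius of a bi-dimensional lesion measurement
#'
#' Reduces an ellipsoidal adnexal lesion measured by its minor- and
#' major-axis radii to an equivalent spherical radius. The default is the
#' geometric mean `sqrt(a * b)`, the standard prolate-ellipsoid-to-sphere
#' equivalence; `convention = "product"` selects the literal product `a * b`
#' for auditing alternative reductions.
#'
#' @param a Minor-axis radius, cm (vectorized, positive).
#' @param b Major-axis radius, cm (vectorized, positive).
#' @param convention `"geometric"` (default) or `"product"`.
#' @return Weighted radius in cm.
#' @examples
#' weighted_radius(1, 4)  # 2
#' @export
weighted_radius <- function(a, b, convention = c("geometric", "product")) {
  convention <- match.arg(convention)
  if (any(!is.finite(a)) || any(a <= 0) || any(!is.finite(b)) || any(b <= 0))
    stop("axis radii must be positive and finite")
  switch(convention, geometric = sqrt(a * b), product = a * b)
}

#' Volume of a sphere of radius r
#'
#' @param r Radius, cm (vectorized, positive).
#' @return Volume `4*pi/3 * r^3` in cm^3.
#' @export
sphere_volume <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("'r' must be positive and finite")
  (4 * pi / 3) * r^3
}

#' Normal ovarian volume upper limits
#'
#' Upper limits of normal ovarian volume: 20 cm^3 premenopausal, 10 cm^3
#' postmenopausal. A diagnosed tumor volume is only informative as a growth
#' lower bound when it exceeds the normal volume for the patient's
#' menopausal status.
#'
#' @param premenopausal Upper limit, cm^3. Default 20.
#' @param postmenopausal Upper limit, cm^3. Default 10.
#' @return Named numeric vector `c(pre = ..., post = ...)`.
#' @export
normal_ovarian_volumes <- function(premenopausal = 20, postmenopausal = 10) {
  if (premenopausal <= 0 || postmenopausal <= 0)
    stop("normal ovarian volumes must be positive")
  c(pre = premenopausal, post = postmenopausal)
}

#' Lower-bound initial growth rate from a diagnosed tumor volume
#'
#' A lesion no larger than the normal ovarian volume `T` days before
#' diagnosis that presents with volume `v_diag` at diagnosis grew at least
#' at the exponential rate
#' \deqn{k \ge [\ln v_{diag} - \ln v_{normal}] / T \quad (day^{-1}).}
#'
#' @param v_diag Tumor volume at diagnosis, cm^3.
#' @param v_normal Normal ovarian volume for the menopausal status, cm^3.
#' @param t_days Days between the last non-suspicious examination and
#'   diagnosis, positive.
#' @return Lower-bound rate in day^-1.
#' @examples
#' lower_bound_rate(10 * exp(1), 10, 100)  # 0.01 /day
#' @export
lower_bound_rate <- function(v_diag, v_normal, t_days) {
  if (any(!is.finite(v_diag)) || any(v_diag <= 0))
    stop("'v_diag' must be positive and finite")
  if (any(!is.finite(v_normal)) || any(v_normal <= 0))
    stop("'v_normal' must be positive and finite")
  if (any(!is.finite(t_days)) || any(t_days <= 0))
    stop("'t_days' must be positive and finite")
  if (any(v_diag <= v_normal))
    stop("diagnosed volume does not exceed the normal ovarian volume; ",
         "the measurement is not informative as a growth lower bound")
  (log(v_diag) - log(v_normal)) / t_days
}

#' Estimate lower-bound growth rates from bi-dimensional measurements
#'
#' Applies the full reduction to a table of clinical measurements: weighted
#' radius, spherical volume, and lower-bound rate against the normal ovarian
#' volume for the case's menopausal status. Rows whose diagnosed volume does
#' not exceed the normal volume are dropped with a warning (they carry no
#' lower-bound information), not an error.
#'
#' @param measurements A data frame with columns `a_cm`, `b_cm`,
#'   `status` (`"pre"`/`"post"`, or an age in years: under 50 is mapped to
#'   premenopausal, 50 and over to postmenopausal) and `t_days`.
#' @param normals Named vector from [normal_ovarian_volumes()].
#' @param convention Radius convention, see [weighted_radius()].
#' @return A data frame with columns `case_id`, `r_cm`, `volume_cm3`,
#'   `rate_per_day`, one row per informative measurement.
#' @examples
#' m <- data.frame(a_cm = 2, b_cm = 3, status = "post", t_days = 180)
#' estimate_rates(m)
#' @export
estimate_rates <- function(measurements, normals = normal_ovarian_volumes(),
                           convention = c("geometric", "product")) {
  convention <- match.arg(convention)
  req <- c("a_cm", "b_cm", "status", "t_days")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements)))
    stop("'measurements' must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(measurements) == 0L) stop("'measurements' has no rows")
  if (any(measurements$a_cm > measurements$b_cm))
    stop("'a_cm' (minor axis) must not exceed 'b_cm' (major axis)")
  status <- as.character(measurements$status)
  age_like <- suppressWarnings(as.numeric(status))
  status <- ifelse(is.na(age_like), status,
                   ifelse(age_like < 50, "pre", "post"))
  if (!all(status %in% c("pre", "post")))
    stop("'status' must be 'pre', 'post', or an age in years")
  r <- weighted_radius(measurements$a_cm, measurements$b_cm, convention)
  v <- sphere_volume(r)
  v_norm <- unname(normals[status])
  ok <- v > v_norm
  if (any(!ok))
    warning(sum(!ok), " measurement(s) dropped: diagnosed volume does not ",
            "exceed the normal ovarian volume")
  out <- data.frame(
    case_id = seq_len(nrow(measurements))[ok],
    r_cm = r[ok],
    volume_cm3 = v[ok],
    rate_per_day = (log(v[ok]) - log(v_norm[ok])) / measurements$t_days[ok])
  rownames(out) <- NULL
  out
}

#' Built-in fixture of nine initial growth rates
#'
#' The cohort simulator samples each curve's initial growth rate uniformly
#' from nine clinically derived lower-bound rates. Only three order
#' statistics of the source rates are available (minimum 0.0014, median
#' 0.0133, maximum 0.0448 day^-1), so the fixture reconstructs the remaining
#' six values by geometric interpolation within each half:
#' `0.0014 * (0.0133/0.0014)^(i/4)` and `0.0133 * (0.0448/0.0133)^(i/4)` for
#' `i = 1, 2, 3`. This is a synthetic stand-in constrained to reproduce the
#' published minimum, median and maximum; a user-supplied rate table (see
#' [read_rate_set()]) overrides it.
#'
#' @return Sorted numeric vector of nine rates, day^-1.
#' @examples
#' default_rate_fixture()
#' @export
default_rate_fixture <- function() {
  lo <- 0.0014; mid <- 0.0133; hi <- 0.0448
  c(lo * (mid / lo)^((0:4) / 4), mid * (hi / mid)^((1:4) / 4))
}

#' Read a rate set from a plain-text file
#'
#' One rate (day^-1) per line; blank lines and `#` comments are ignored.
#'
#' @param path File path.
#' @return Numeric vector of positive rates.
#' @export
read_rate_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no rates found in '", path, "'")
  rates <- suppressWarnings(as.numeric(lines))
  if (any(is.na(rates)) || any(rates <= 0))
    stop("'", path, "' must contain one positive rate (day^-1) per line")
  rates
}
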