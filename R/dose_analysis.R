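#' Biologically effective dose
#'
#' BED = n d (1 + d / (alpha/beta)) for `n` fractions of `d` Gy.
#'
#' @param n fraction count (>= 0).
#' @param d dose per fraction in Gy (>= 0).
#' @param alpha_beta alpha/beta ratio in Gy (default 10).
#' @return BED in Gy.
#' @examples
#' bed(30, 2)  # 72 Gy
#' @export
bed <- function(n, d, alpha_beta = 10) {
  stopifnot(n >= 0, all(d >= 0), alpha_beta > 0)
  n * d * (1 + d / alpha_beta)
}

#' Extra dose per fraction equivalent to extra fractions
#'
#' During accelerated repopulation a tumour needs `m_extra` additional
#' 2 Gy fractions beyond the isoeffect schedule. This converts those extra
#' fractions into the uniform dose escalation per fraction, applied over
#' the `n_ar` fractions delivered after repopulation onset, that carries
#' the same biologically effective dose:
#' solve `n_ar (d0 + delta)(1 + (d0 + delta)/ab) = (n_ar + m) d0 (1 + d0/ab)`
#' for the positive root `delta`.
#'
#' @param n_ar number of fractions delivered while accelerated
#'   repopulation is active (>= 1).
#' @param m_extra extra fractions needed at the baseline dose (>= 0; may
#'   be fractional when averaging over replicates).
#' @param d0 baseline dose per fraction in Gy.
#' @param alpha_beta alpha/beta ratio in Gy.
#' @return extra dose per fraction in Gy (>= 0).
#' @export
extra_dose_per_fraction <- function(n_ar, m_extra, d0 = 2, alpha_beta = 10) {
  stopifnot(n_ar >= 1, m_extra >= 0, d0 >= 0, alpha_beta > 0)
  target <- (n_ar + m_extra) * d0 * (1 + d0 / alpha_beta) / n_ar
  # x (1 + x/ab) = target  =>  x^2 + ab x - ab target = 0
  x <- (-alpha_beta + sqrt(alpha_beta^2 + 4 * alpha_beta * target)) / 2
  max(x - d0, 0)
}

#' Fraction count predicted by the linear-quadratic model
#'
#' The first fraction after which fewer than 1.000 cells are expected to
#' remain: the smallest integer n with `N0 SF(d)^n < 1`. Used as the
#' closed-form comparator for the simulated stem-cell endpoint.
#'
#' @param n0 initial cell number (>= 1).
#' @param d dose per fraction in Gy (> 0).
#' @param params a [radiobiology_params()].
#' @return integer fraction count.
#' @export
lq_fraction_count <- function(n0, d, params = radiobiology_params()) {
  stopifnot(n0 >= 1)
  sf <- survival_fraction(d, params)
  if (sf >= 1) stop("surviving fraction is 1; fraction count undefined")
  n <- ceiling(log(n0) / -log(sf))
  # guard against floating-point boundary cases
  while (n0 * sf^n >= 1) n <- n + 1
  while (n > 1 && n0 * sf^(n - 1) < 1) n <- n - 1
  as.integer(n)
}

#' Tumour volume doubling time from a growth time series
#'
#' Least-squares slope of log(count) against time over a count window,
#' the standard estimator for the exponential phase of tumour growth.
#'
#' @param time_h times in hours.
#' @param count live cell counts (same length).
#' @param window count range `c(lo, hi)` delimiting the fitted window
#'   (defaults to the whole series).
#' @return doubling time in days.
#' @export
doubling_time <- function(time_h, count, window = range(count)) {
  stopifnot(length(time_h) == length(count), length(time_h) >= 2)
  keep <- count >= window[1] & count <= window[2] & count > 0
  if (sum(keep) < 2) stop("fewer than two points in the doubling-time window")
  x <- time_h[keep]
  y <- log(count[keep])
  if (max(y) - min(y) < log(2)) {
    warning("doubling-time window spans less than one doubling")
  }
  slope <- stats::coef(stats::lm(y ~ x))[[2]]
  if (slope <= 0) stop("series is not growing over the requested window")
  log(2) / slope / 24
}
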