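#' Promoter-reporter activity
#'
#' Luminescence of a lux-reporter culture normalized to its optical density
#' at 730 nm, the unit in which promoter activities are compared across
#' strains and conditions.
#'
#' @param luminescence Luminescence reading(s), arbitrary units, >= 0.
#' @param od730 Optical density at 730 nm, > 0.
#' @return Activity in luminescence per OD unit (vectorized).
#' @examples
#' promoter_activity(500, 0.25)  # 2000
#' @export
promoter_activity <- function(luminescence, od730) {
  if (any(od730 <= 0)) stop("od730 must be > 0")
  if (any(luminescence < 0)) stop("luminescence must be >= 0")
  luminescence / od730
}

#' Fold induction of a promoter under stress
#'
#' Ratio of stress to standard-condition activity. A background activity
#' (e.g. from a reporter-free control strain) may optionally be subtracted
#' from both terms first; the default is no subtraction because the
#' background of the control strain is negligibly low in all conditions.
#'
#' @param activity_stress,activity_standard Activities from
#'   [promoter_activity()].
#' @param background Background activity subtracted from both (default 0).
#' @return Fold induction (vectorized).
#' @examples
#' fold_induction(220, 100)                   # 2.2
#' fold_induction(230, 110, background = 10)  # 2.2
#' @export
fold_induction <- function(activity_stress, activity_standard, background = 0) {
  a <- activity_stress - background
  b <- activity_standard - background
  if (any(b <= 0)) stop("standard-condition activity (after background) must be > 0")
  a / b
}

#' Dilution-corrected growth curve
#'
#' Cultures are diluted whenever the measured OD730 would exceed the linear
#' range; each dilution factor attaches to the measurement it immediately
#' precedes. The corrected OD at time t is the measured OD multiplied by the
#' product of all dilution factors applied at or before t, restoring a
#' continuous growth curve.
#'
#' @param od730_measured Measured OD730 values, > 0, in time order.
#' @param dilution_factor Factor >= 1 applied immediately before each
#'   measurement (1 = no dilution).
#' @return Corrected OD730 values.
#' @examples
#' corrected_growth_curve(c(0.1, 0.3, 0.2), c(1, 1, 4))  # 0.1 0.3 0.8
#' @export
corrected_growth_curve <- function(od730_measured, dilution_factor) {
  if (length(od730_measured) != length(dilution_factor))
    stop("od730_measured and dilution_factor must have equal length")
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  if (any(od730_measured <= 0)) stop("od730_measured must be > 0")
  od730_measured * cumprod(dilution_factor)
}

#' Exponential growth rate from a corrected curve
#'
#' Ordinary least-squares slope of natural-log corrected OD versus time, in
#' day^-1; a culture doubling daily grows at ln(2) = 0.693 day^-1.
#'
#' @param time_days Time points in days, strictly increasing.
#' @param od_corrected Corrected OD730 values, > 0.
#' @param window Optional length-2 time interval restricting the fit.
#' @return Growth rate in day^-1.
#' @examples
#' growth_rate(0:3, 0.1 * 2^(0:3))  # ~0.693
#' @export
growth_rate <- function(time_days, od_corrected, window = NULL) {
  if (length(time_days) != length(od_corrected))
    stop("time_days and od_corrected must have equal length")
  if (any(diff(time_days) <= 0)) stop("time_days must be strictly increasing")
  if (!is.null(window)) {
    keep <- time_days >= window[1] & time_days <= window[2]
    time_days <- time_days[keep]
    od_corrected <- od_corrected[keep]
  }
  if (length(time_days) < 3L) stop("need >= 3 points in the fitting window")
  if (any(od_corrected <= 0)) stop("od must be > 0 for a log-linear fit")
  unname(stats::coef(stats::lm(log(od_corrected) ~ time_days))[2])
}
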