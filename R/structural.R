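# Structural model: piecewise two-compartment IV-infusion kinetics.
#
# Time is in days throughout (a 30-min infusion has duration 1/48 day),
# amounts in mg, volumes in L. Dividing mg by L gives mg/L, numerically
# identical to ug/mL (the 10^3 ug/mg and 10^3 mL/L factors cancel), so
# concentrations are reported in ug/mL without further conversion.

# normalize a dose specification to data.frame(time, amt, duration)
as_dose_table <- function(doses) {
  d <- as.data.frame(doses)
  if (!all(c("time", "amt") %in% names(d)))
    stop("doses must have columns 'time' and 'amt'")
  if (is.null(d$duration)) d$duration <- INFUSION_30MIN
  if (any(d$amt <= 0)) stop("dose amounts must be positive")
  if (any(d$duration <= 0)) stop("infusion durations must be positive")
  d[order(d$time), , drop = FALSE]
}

# normalize a parameter timeline to data.frame(start, cl, vc, q, vp)
as_param_timeline <- function(pt) {
  if (is.list(pt) && !is.data.frame(pt) && all(c("cl", "vc", "q", "vp") %in% names(pt)))
    pt <- data.frame(start = -Inf, cl = pt$cl, vc = pt$vc, q = pt$q, vp = pt$vp)
  pt <- as.data.frame(pt)
  if (is.null(pt$start)) pt$start <- -Inf
  if (!all(c("start", "cl", "vc", "q", "vp") %in% names(pt)))
    stop("params_timeline must have columns start, cl, vc, q, vp")
  if (any(pt$cl <= 0 | pt$vc <= 0 | pt$q < 0 | pt$vp <= 0))
    stop("parameters must be positive (q may be zero) on every segment")
  pt[order(pt$start), , drop = FALSE]
}

# Build contiguous segments covering the requested times: boundaries at dose
# starts/ends and parameter-change knots. Returns the inputs expected by the
# compiled propagator.
build_segments <- function(doses, knots, t) {
  t0 <- min(0, t, doses$time, knots[is.finite(knots)])
  bp <- sort(unique(c(t0, doses$time, doses$time + doses$duration,
                      knots[is.finite(knots)])))
  ends <- c(bp[-1], max(bp[length(bp)], max(t)) + 1)
  mid <- (bp + ends) / 2
  rate <- vapply(mid, function(m)
    sum(doses$amt[doses$time <= m & m < doses$time + doses$duration] /
          doses$duration[doses$time <= m & m < doses$time + doses$duration]),
    numeric(1))
  list(t0 = bp, mid = mid, rate = rate,
       obs_seg = findInterval(t, bp) - 1L)
}

#' Two-compartment linear infusion concentrations
#'
#' Central-compartment concentration of the two-compartment model with
#' zero-order (infusion) input and first-order elimination, evaluated from
#' the closed-form biexponential solution. Parameters may change over time
#' (piecewise-constant segments); compartment amounts are carried across
#' segment boundaries so the profile is continuous, and doses superpose
#' within the linear model.
#'
#' @param t Times (days, relative to first dose) at which to evaluate; must
#'   be non-negative. Times before the first dose return 0.
#' @param doses Data frame with columns `time` (infusion start, days), `amt`
#'   (mg) and optionally `duration` (days; default 1/48, a 30-min infusion).
#' @param params Either a list with elements `cl`, `vc`, `q`, `vp` (constant
#'   parameters, e.g. from [individual_params()]) or a data frame with
#'   columns `start`, `cl`, `vc`, `q`, `vp` giving piecewise-constant
#'   parameter segments (each row applies from `start` onwards).
#' @return Numeric vector of concentrations (ug/mL) at `t`.
#' @examples
#' p <- individual_params(pk_params(), reference_covariates())
#' conc_2cmt_linear(c(1/48, 1, 7, 14), data.frame(time = 0, amt = 300), p)
#' @export
conc_2cmt_linear <- function(t, doses, params) {
  if (any(t < 0)) stop("negative evaluation times are not allowed")
  doses <- as_dose_table(doses)
  pt <- as_param_timeline(params)
  seg <- build_segments(doses, knots = pt$start, t = t)
  idx <- pmax(findInterval(seg$mid, pt$start), 1L)
  .profile_piecewise_cpp(seg$t0, seg$rate, pt$cl[idx], pt$vc[idx],
                         pt$q[idx], pt$vp[idx], t, seg$obs_seg)
}

#' Two-compartment concentrations with parallel Michaelis-Menten elimination
#'
#' Numerical (adaptive Runge-Kutta) solution of the two-compartment infusion
#' model whose elimination is `CL*C + Vmax*C/(Km + C)`. With `vmax = 0` this
#' reduces to the linear model of [conc_2cmt_linear()].
#'
#' @inheritParams conc_2cmt_linear
#' @param vmax Maximum Michaelis-Menten elimination rate (mg/day), `>= 0`.
#' @param km Concentration at half-maximal elimination (ug/mL), `> 0`.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return Numeric vector of concentrations (ug/mL) at `t`.
#' @export
conc_2cmt_mm <- function(t, doses, params, vmax, km,
                         rtol = 1e-10, atol = 1e-12) {
  if (any(t < 0)) stop("negative evaluation times are not allowed")
  if (vmax < 0 || km <= 0) stop("vmax must be >= 0 and km > 0")
  doses <- as_dose_table(doses)
  pt <- as_param_timeline(params)
  seg <- build_segments(doses, knots = pt$start, t = t)
  idx <- pmax(findInterval(seg$mid, pt$start), 1L)
  .profile_mm_cpp(seg$t0, seg$rate, pt$cl[idx], pt$vc[idx], pt$q[idx],
                  pt$vp[idx], vmax, km, t, seg$obs_seg, rtol, atol)
}

#' Assign dosing occasions to observations
#'
#' A new occasion starts whenever a dose is administered with subsequent PK
#' observations before the next dose. Each observation is labelled with the
#' index of the most recent prior-or-equal dose; observations before the
#' first dose get label 0 (pre-dose) and are flagged. Doses with no
#' observation before the next dose do not contribute an occasion-level
#' random-effect dimension: the `kappa_levels` attribute lists the occasion
#' labels that do.
#'
#' @param dose_times Sorted dose administration times for one subject.
#' @param obs_times Sorted observation times for the same subject.
#' @return Integer vector of occasion labels per observation, with attributes
#'   `kappa_levels` (occasion labels carrying an IOV random effect) and
#'   `predose` (logical, observations before the first dose).
#' @examples
#' assign_occasions(c(0, 14), c(1, 7, 15))
#' @export
assign_occasions <- function(dose_times, obs_times) {
  if (is.unsorted(dose_times) || is.unsorted(obs_times))
    stop("dose_times and obs_times must be sorted ascending")
  lab <- findInterval(obs_times, dose_times)
  structure(as.integer(lab),
            kappa_levels = sort(unique(lab[lab > 0L])),
            predose = lab == 0L)
}

#' Next-observation-carried-backward interpolation
#'
#' Interpolates a time-stamped covariate series by carrying the next observed
#' value backward: the value at time `t` is the earliest observation at a
#' time `>= t`; beyond the last observation the last value is carried
#' forward.
#'
#' @param times Sorted observation times of the series.
#' @param values Observed values at `times`.
#' @param query Times at which to interpolate.
#' @return Values of the series at `query`.
#' @examples
#' nocb_interpolate(c(0, 10), c(70, 65), c(0, 5, 10, 12))
#' @export
nocb_interpolate <- function(times, values, query) {
  if (!length(times)) stop("empty covariate series")
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (is.unsorted(times)) stop("series times must be sorted ascending")
  idx <- findInterval(query, times, left.open = TRUE) + 1L
  values[pmin(idx, length(values))]
}
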