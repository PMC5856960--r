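#' Quasi-steady wall shear stress field
#'
#' Distributed wall shear stress on the lumen wall under a quasi-steady
#' Poiseuille closure: at each instant the flow is treated as fully developed
#' in a rigid tube of local radius, giving
#' \eqn{\tau(s, t) = 4 \mu Q(t) / (\pi r(s)^3)} (CGS: dyn/cm^2), signed with
#' the instantaneous flow direction. The flow is taken uniform along the
#' modeled segment (incompressible, no side branches). Magnitudes are
#' approximate relative to a 3D solution; orderings across geometries sharing
#' a flow are the quantity of interest.
#'
#' @param geom a `vessel_geometry`.
#' @param flow one-cycle flow waveform: a `flow_waveform` (see
#'   [fixture_flow_waveform()]) or data frame with columns `time` (s) and
#'   `flow` (mL/s).
#' @param fluid a `fluid_properties` object.
#' @param n_s number of axial samples across the evaluation span.
#' @param span arclength interval to sample; defaults to the aneurysm span
#'   (full vessel for an unmorphed control).
#' @return object of class `wss_field`: list with `s` (cm), `time` (s),
#'   `tau` (matrix n_s x n_t, dyn/cm^2), `period`, `geom`.
#' @export
wss_field <- function(geom, flow, fluid = fluid_properties(), n_s = 401L,
                      span = NULL) {
  stopifnot(inherits(geom, "vessel_geometry"),
            inherits(fluid, "fluid_properties"))
  flow <- as_flow_waveform(flow)
  if (is.null(span)) span <- geom$span %||% c(0, total_length(geom$path))
  s <- seq(span[1L], span[2L], length.out = n_s)
  r <- geom$r_fun(s)
  # mL/s == cm^3/s, so no unit conversion is needed in CGS
  tau <- (4 * fluid$viscosity / pi) * outer(1 / r^3, flow$flow)
  structure(list(s = s, time = flow$time, tau = tau,
                 period = attr(flow, "period") %||% max(flow$time),
                 geom = geom),
            class = "wss_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field> %d axial x %d time samples over [%.2f, %.2f] cm, period %.3f s\n",
              length(x$s), length(x$time), min(x$s), max(x$s), x$period))
  invisible(x)
}

#' Time-averaged wall shear stress
#'
#' \eqn{TAWSS(s) = \frac{1}{T}\int_0^T |\tau(s,t)|\,dt} by trapezoid
#' quadrature on the field's time grid, plus the surface-area-weighted mean
#' over the field span (the aneurysm-averaged TAWSS reported per case).
#'
#' @param field a `wss_field` spanning exactly one cycle.
#' @return list with `s`, `tawss` (per-position, dyn/cm^2) and `mean`
#'   (area-weighted aneurysm mean, dyn/cm^2).
#' @export
tawss <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  t <- field$time
  prof <- apply(abs(field$tau), 1L, .trapz, x = t) / field$period
  w <- .area_weights(field$geom, field$s)
  list(s = field$s, tawss = prof, mean = sum(w * prof) / sum(w))
}

# Local surface-area weights on an axial grid: trapezoid weights of the
# surface-of-revolution integrand 2*pi*r*sqrt(1 + r'^2).
.area_weights <- function(geom, s) {
  f <- 2 * pi * geom$r_fun(s) * sqrt(1 + geom$drds_fun(s)^2)
  ds <- diff(s)
  w <- numeric(length(s))
  w[1L] <- ds[1L] / 2
  w[length(s)] <- ds[length(ds)] / 2
  if (length(s) > 2L) w[2:(length(s) - 1L)] <- (ds[-length(ds)] + ds[-1L]) / 2
  f * w
}

#' Low-WSS surface-area fraction
#'
#' Percentage of the surface area of the span where TAWSS is strictly below a
#' threshold; ties at the threshold count as not-exposed. Areas are computed by
#' surface-of-revolution quadrature weights on the TAWSS grid.
#'
#' @param geom a `vessel_geometry`.
#' @param tawss_profile list with `s` and `tawss` as returned by [tawss()],
#'   defined on the span of interest.
#' @param threshold dyn/cm^2, positive.
#' @return percentage in [0, 100]
#' @export
low_wss_area_fraction <- function(geom, tawss_profile, threshold) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (threshold <= 0) stop("input error: threshold must be positive")
  w <- .area_weights(geom, tawss_profile$s)
  # clamp away sub-ulp summation overshoot
  min(100, max(0, 100 * sum(w[tawss_profile$tawss < threshold]) / sum(w)))
}

#' Oscillatory shear index
#'
#' \eqn{OSI(s) = 0.5\,(1 - |\int \tau\,dt| / \int |\tau|\,dt)}; 0 for purely
#' unidirectional shear, 0.5 for pure oscillation, defined as 0 where the
#' shear vanishes identically.
#'
#' @param field a `wss_field` spanning one cycle.
#' @return list with `s`, `osi` (per-position) and `max` over the span.
#' @export
osi <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  t <- field$time
  num <- abs(apply(field$tau, 1L, .trapz, x = t))
  den <- apply(abs(field$tau), 1L, .trapz, x = t)
  v <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  v <- pmin(pmax(v, 0), 0.5)
  list(s = field$s, osi = v, max = max(v))
}

#' Residence-time surrogate
#'
#' Volume-turnover time of the aneurysm: lumen volume of the span divided by
#' the cycle-mean flow. A reduced-order surrogate for Lagrangian particle
#' residence time; longer turnover indicates stronger flow stagnation.
#'
#' @param geom a `vessel_geometry`.
#' @param flow one-cycle flow waveform (positive cycle mean required).
#' @param span arclength interval; defaults to the aneurysm span.
#' @return seconds
#' @export
residence_time <- function(geom, flow, span = NULL) {
  stopifnot(inherits(geom, "vessel_geometry"))
  flow <- as_flow_waveform(flow)
  if (is.null(span)) span <- geom$span %||% c(0, total_length(geom$path))
  q_mean <- .trapz(flow$time, flow$flow) /
    (attr(flow, "period") %||% max(flow$time))
  if (q_mean <= 0)
    stop("undefined-residence error: cycle-mean flow must be positive")
  lumen_volume(geom, span[1L], span[2L]) / q_mean
}

#' Summarize aneurysm hemodynamic metrics
#'
#' Computes the per-case metric set: area-averaged TAWSS over the aneurysm,
#' surface-area percentages below the 4 and 1 dyn/cm^2 thresholds, maximum
#' OSI, and the residence-time surrogate.
#'
#' @param geom a `vessel_geometry`.
#' @param flow one-cycle coronary flow waveform (mL/s).
#' @param fluid a `fluid_properties` object.
#' @param thresholds low-WSS thresholds in dyn/cm^2, decreasing (default 4, 1).
#' @param n_s axial samples over the span.
#' @return object of class `hemodynamic_metrics`: list with `case_id`,
#'   `tawss_mean`, `area_wss4`, `area_wss1`, `osi_max`, `residence_time`.
#' @export
summarize_hemodynamics <- function(geom, flow, fluid = fluid_properties(),
                                   thresholds = c(4, 1), n_s = 401L) {
  stopifnot(length(thresholds) == 2L, all(thresholds > 0),
            thresholds[1L] > thresholds[2L])
  field <- wss_field(geom, flow, fluid, n_s = n_s)
  ta <- tawss(field)
  a_hi <- low_wss_area_fraction(geom, ta, thresholds[1L])
  a_lo <- low_wss_area_fraction(geom, ta, thresholds[2L])
  stopifnot(a_lo <= a_hi + 1e-9)   # threshold nesting invariant
  m <- list(case_id = geom$spec$case_id,
            tawss_mean = ta$mean,
            area_wss4 = a_hi,
            area_wss1 = a_lo,
            osi_max = osi(field)$max,
            residence_time = residence_time(geom, flow))
  structure(m, class = "hemodynamic_metrics")
}

#' @export
print.hemodynamic_metrics <- function(x, ...) {
  cat(sprintf("<hemodynamic_metrics> %s: TAWSS %.2f dyn/cm^2, Area<4: %.1f%%, Area<1: %.1f%%, OSI_max %.3f, PRT %.2f s\n",
              x$case_id, x$tawss_mean, x$area_wss4, x$area_wss1, x$osi_max,
              x$residence_time))
  invisible(x)
}

#' @export
as.data.frame.hemodynamic_metrics <- function(x, ...) {
  data.frame(case_id = x$case_id, tawss = x$tawss_mean,
             area_wss4 = x$area_wss4, area_wss1 = x$area_wss1,
             osi_max = x$osi_max, residence_time_s = x$residence_time)
}
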