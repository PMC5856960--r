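#' Clinical targets for LPN tuning
#'
#' Patient-level quantities the lumped-parameter circulation is tuned to
#' reproduce: heart rate, brachial systolic/diastolic pressure, stroke volume,
#' body surface area and the fraction of cardiac output delivered to the
#' modeled coronary branch.
#'
#' @param heart_rate beats/min.
#' @param systolic_pressure,diastolic_pressure mmHg; systolic > diastolic.
#' @param stroke_volume mL.
#' @param body_surface_area m^2.
#' @param coronary_flow_fraction fraction of cardiac output, in (0, 0.15).
#' @return object of class `clinical_targets`
#' @examples
#' clinical_targets(75, 120, 80, 70, 1.8, 0.04)
#' @export
clinical_targets <- function(heart_rate, systolic_pressure, diastolic_pressure,
                             stroke_volume, body_surface_area = 1.7,
                             coronary_flow_fraction = 0.04) {
  x <- list(heart_rate = heart_rate,
            systolic_pressure = systolic_pressure,
            diastolic_pressure = diastolic_pressure,
            stroke_volume = stroke_volume,
            body_surface_area = body_surface_area,
            coronary_flow_fraction = coronary_flow_fraction)
  if (any(vapply(x, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1))))
    stop("all clinical targets must be positive scalars")
  if (systolic_pressure <= diastolic_pressure)
    stop("systolic pressure must exceed diastolic pressure")
  if (coronary_flow_fraction >= 0.15)
    stop("coronary_flow_fraction must lie in (0, 0.15)")
  structure(x, class = "clinical_targets")
}

#' @export
print.clinical_targets <- function(x, ...) {
  cat(sprintf("<clinical_targets> HR %g bpm, BP %g/%g mmHg, SV %g mL, BSA %g m^2, coronary fraction %g\n",
              x$heart_rate, x$systolic_pressure, x$diastolic_pressure,
              x$stroke_volume, x$body_surface_area, x$coronary_flow_fraction))
  invisible(x)
}

#' Blood fluid properties
#'
#' Density and dynamic viscosity of blood modeled as an incompressible
#' Newtonian fluid; defaults are the standard CGS values 1.06 g/cc and
#' 0.04 poise (dyn s/cm^2).
#'
#' @param density g/cc.
#' @param viscosity poise.
#' @return object of class `fluid_properties`
#' @export
fluid_properties <- function(density = 1.06, viscosity = 0.04) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Construct / validate an LPN parameter set
#'
#' Circuit element values of the closed-loop lumped-parameter network. Units:
#' resistances mmHg s/mL, compliances mL/mmHg, elastances mmHg/mL, volumes mL.
#' `gamma` is the intramyocardial pressure scale: the tissue pressure loading
#' the intramyocardial compliance is `gamma * P_lv(t)`.
#'
#' @param params named list of circuit elements (see [default_parameters()]
#'   for the full field set).
#' @return object of class `lpn_parameters`
#' @export
lpn_parameters <- function(params) {
  req <- c("E_max", "E_min", "V0", "t_sys_coef", "R_mv", "R_av",
           "R_p", "C_sys", "R_d", "Ra", "Ca", "Ra_micro", "Cim", "Rv",
           "gamma", "C_ven", "R_venret", "C_la", "valve_eps")
  missing <- setdiff(req, names(params))
  if (length(missing))
    stop("missing LPN parameters: ", paste(missing, collapse = ", "))
  params <- params[req]
  pos <- setdiff(req, "gamma")
  if (any(vapply(params[pos], function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("spec error: all resistances, compliances, elastances and intervals must be strictly positive")
  if (params$gamma < 0 || params$gamma > 1)
    stop("gamma must lie in [0, 1]")
  if (params$E_max <= params$E_min) stop("E_max must exceed E_min")
  structure(params, class = "lpn_parameters")
}

#' Physiologically scaled starting parameters
#'
#' Builds an LPN parameter set scaled to a patient's clinical targets by
#' zero-order circuit relations: total systemic resistance from mean arterial
#' pressure over cardiac output (MAP = diastolic + pulse/3), arterial
#' compliance from stroke volume over pulse pressure, coronary branch
#' resistance from current division so the branch draws
#' `coronary_flow_fraction` of cardiac output, and ventricular elastance from
#' systolic pressure over stroke volume. These are starting values; [lpn_tune()]
#' refines them against the simulated waveforms.
#'
#' @param targets a `clinical_targets` object.
#' @return an `lpn_parameters` object
#' @export
default_parameters <- function(targets) {
  stopifnot(inherits(targets, "clinical_targets"))
  co <- targets$stroke_volume * targets$heart_rate / 60      # mL/s
  pp <- targets$systolic_pressure - targets$diastolic_pressure
  map <- targets$diastolic_pressure + pp / 3
  p_ven <- 5                                 # reference venous pressure, mmHg
  f <- targets$coronary_flow_fraction
  r_sys <- (map - p_ven) / ((1 - f) * co)
  r_cor <- (map - p_ven) / (f * co)
  c_sys <- targets$stroke_volume / pp
  sv_scale <- targets$stroke_volume / 70
  lpn_parameters(list(
    E_max = targets$systolic_pressure / (0.6 * targets$stroke_volume),
    E_min = 0.06 / sv_scale,
    V0 = 5 * sv_scale,
    t_sys_coef = 0.3,
    R_mv = 0.008, R_av = 0.006,
    R_p = 0.07 * r_sys, C_sys = c_sys, R_d = 0.93 * r_sys,
    # coronary chain split in standard proximal/microcirculatory/venous
    # proportions 0.32 : 0.52 : 0.16
    Ra = 0.32 * r_cor, Ca = 0.008 * c_sys,
    Ra_micro = 0.52 * r_cor, Cim = 0.05 * c_sys, Rv = 0.16 * r_cor,
    gamma = 0.5,
    C_ven = 30 * c_sys, R_venret = 0.03 * r_sys,
    C_la = 4 * sv_scale,
    valve_eps = 0.1
  ))
}

# Smooth valve opening: steep logistic in the pressure drop. eps in mmHg.
.valve_sig <- function(dp, eps) 1 / (1 + exp(-dp / eps))

# Two-phase shifted-cosine elastance activation over systolic interval t_sys.
# Returns activation a(t) in [0,1] and its time derivative.
.activation <- function(tc, t_sys) {
  inside <- tc < t_sys
  a <- ifelse(inside, 0.5 * (1 - cos(2 * pi * tc / t_sys)), 0)
  da <- ifelse(inside, (pi / t_sys) * sin(2 * pi * tc / t_sys), 0)
  cbind(a, da)
}

# State vector: V_lv, P_ao, P_ca, P_cim, P_ven, P_la
.lpn_rhs <- function(t, y, p) {
  act <- .activation(t %% p$period, p$t_sys)
  E <- p$E_min + p$dE * act[1L]
  dEdt <- p$dE * act[2L]
  V <- y[1L]; P_ao <- y[2L]; P_ca <- y[3L]; P_cim <- y[4L]
  P_ven <- y[5L]; P_la <- y[6L]
  P_lv <- E * (V - p$V0)
  dp_mv <- P_la - P_lv
  Q_mv <- dp_mv / p$R_mv * .valve_sig(dp_mv, p$valve_eps)
  dp_av <- P_lv - P_ao
  Q_av <- dp_av / (p$R_av + p$R_p) * .valve_sig(dp_av, p$valve_eps)
  Q_sys <- (P_ao - P_ven) / p$R_d
  Q_cor <- (P_ao - P_ca) / p$Ra
  Q_m <- (P_ca - P_cim) / p$Ra_micro
  Q_v <- (P_cim - P_ven) / p$Rv
  Q_vr <- (P_ven - P_la) / p$R_venret
  dV <- Q_mv - Q_av
  dP_lv <- dEdt * (V - p$V0) + E * dV
  list(c(dV,
         (Q_av - Q_sys - Q_cor) / p$C_sys,
         (Q_cor - Q_m) / p$Ca,
         (Q_m - Q_v) / p$Cim + p$gamma * dP_lv,
         (Q_sys + Q_v - Q_vr) / p$C_ven,
         (Q_vr - Q_mv) / p$C_la))
}

# Recompute algebraic channels (pressures, flows) from integrated states.
.lpn_channels <- function(times, Y, p) {
  act <- .activation(times %% p$period, p$t_sys)
  E <- p$E_min + p$dE * act[, 1L]
  P_lv <- E * (Y[, "V_lv"] - p$V0)
  dp_mv <- Y[, "P_la"] - P_lv
  dp_av <- P_lv - Y[, "P_ao"]
  data.frame(
    time = times,
    P_ao = Y[, "P_ao"], P_lv = P_lv, V_lv = Y[, "V_lv"],
    Q_av = dp_av / (p$R_av + p$R_p) * .valve_sig(dp_av, p$valve_eps),
    Q_mv = dp_mv / p$R_mv * .valve_sig(dp_mv, p$valve_eps),
    Q_cor = (Y[, "P_ao"] - Y[, "P_ca"]) / p$Ra,
    Q_sys = (Y[, "P_ao"] - Y[, "P_ven"]) / p$R_d,
    P_ca = Y[, "P_ca"], P_cim = Y[, "P_cim"],
    P_ven = Y[, "P_ven"], P_la = Y[, "P_la"]
  )
}

.lpn_initial_state <- function(params, targets_map = 90, sv = 70) {
  c(V_lv = params$V0 + 1.6 * sv,
    P_ao = targets_map, P_ca = targets_map, P_cim = 0.6 * targets_map,
    P_ven = 8, P_la = 10)
}

# trapezoid rule on an ordered grid
.trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + y[-1L])) / 2

#' Simulate the closed-loop LPN
#'
#' Integrates the 6-state closed loop -- time-varying-elastance left ventricle,
#' smoothed-diode mitral/aortic valves, proximal-R / C / distal-R systemic
#' Windkessel, a coronary branch (Ra - Ca - Ra_micro - Cim - Rv) whose
#' intramyocardial compliance is loaded by the tissue pressure
#' `gamma * P_lv(t)`, and a venous capacitor returning through a
#' constant-elastance atrium -- cycle by cycle until consecutive aortic
#' pressure cycles agree within `tol` (periodic steady state) or `n_cycles`
#' is exhausted. Integration uses adaptive lsoda (rtol 1e-6, atol 1e-8);
#' `dt` only sets the output grid.
#'
#' @param params an `lpn_parameters` object.
#' @param heart_rate beats/min; the cycle period is 60/heart_rate s.
#' @param n_cycles maximum cycles to integrate (>= 2).
#' @param dt output time step, s; default gives 500 steps per cycle.
#' @param tol relative cycle-to-cycle convergence tolerance on aortic pressure.
#' @param init optional initial state vector (warm start).
#' @param until_converged stop at the first converged cycle (default) or always
#'   run all `n_cycles`.
#' @return object of class `lpn_run`: list with `waveforms` (final-cycle
#'   `waveform_set` data frame: time, P_ao, P_lv, V_lv, Q_av, Q_mv, Q_cor,
#'   Q_sys, node pressures), `history` (all cycles, with `cycle` column),
#'   `converged`, `convergence_cycle`, `final_state`, `params`, `heart_rate`.
#' @export
lpn_simulate <- function(params, heart_rate, n_cycles = 20L, dt = NULL,
                         tol = 0.01, init = NULL, until_converged = TRUE) {
  params <- lpn_parameters(params)
  stopifnot(heart_rate > 0, n_cycles >= 2L)
  period <- 60 / heart_rate
  if (is.null(dt)) dt <- period / 500
  steps <- max(50L, as.integer(round(period / dt)))
  p <- c(unclass(params),
         list(period = period,
              t_sys = params$t_sys_coef * sqrt(period),
              dE = params$E_max - params$E_min))
  y <- if (is.null(init)) .lpn_initial_state(params) else init
  names(y) <- c("V_lv", "P_ao", "P_ca", "P_cim", "P_ven", "P_la")
  times <- seq(0, period, length.out = steps + 1L)
  cycles <- vector("list", n_cycles)
  prev_pao <- NULL
  converged <- FALSE
  conv_cycle <- NA_integer_
  k_last <- n_cycles
  for (k in seq_len(n_cycles)) {
    sol <- deSolve::ode(y, times, .lpn_rhs, p, method = "lsoda",
                        rtol = 1e-6, atol = 1e-8)
    Y <- sol[, -1L, drop = FALSE]
    if (any(!is.finite(Y)) || max(abs(Y)) > 1e7)
      stop("solver error: LPN integration diverged (check parameter magnitudes)")
    y <- Y[nrow(Y), ]
    cycles[[k]] <- Y
    pao <- Y[, "P_ao"]
    if (!is.null(prev_pao)) {
      delta <- max(abs(pao - prev_pao)) / max(abs(pao))
      if (!converged && delta < tol) {
        converged <- TRUE
        conv_cycle <- k
        if (until_converged) { k_last <- k; break }
      }
    }
    prev_pao <- pao
    k_last <- k
  }
  cycles <- cycles[seq_len(k_last)]
  history <- do.call(rbind, lapply(seq_along(cycles), function(k) {
    ch <- .lpn_channels(times, cycles[[k]], p)
    ch$time <- ch$time + (k - 1L) * period
    ch$cycle <- k
    ch
  }))
  wf <- .lpn_channels(times, cycles[[k_last]], p)
  class(wf) <- c("waveform_set", "data.frame")
  attr(wf, "period") <- period
  attr(wf, "t_sys") <- p$t_sys
  structure(
    list(waveforms = wf, history = history, converged = converged,
         convergence_cycle = conv_cycle, n_cycles_run = k_last,
         final_state = y, params = params, heart_rate = heart_rate),
    class = "lpn_run"
  )
}

#' @export
print.lpn_run <- function(x, ...) {
  w <- x$waveforms
  cat(sprintf("<lpn_run> HR %g bpm, %d cycle(s), %s\n", x$heart_rate,
              x$n_cycles_run,
              if (x$converged) sprintf("converged at cycle %d", x$convergence_cycle)
              else "NOT converged"))
  cat(sprintf("  aortic pressure %.1f/%.1f mmHg, SV %.1f mL, mean coronary flow %.2f mL/s\n",
              max(w$P_ao), min(w$P_ao), max(w$V_lv) - min(w$V_lv),
              mean(w$Q_cor)))
  invisible(x)
}

#' Detect periodic steady state in a multi-cycle history
#'
#' A simulation is at periodic steady state when the maximum relative
#' cycle-to-cycle change of aortic pressure over the cycle drops below `tol`.
#'
#' @param history data frame with columns `cycle` and `P_ao` on a common
#'   within-cycle grid (as returned in `lpn_run$history`).
#' @param tol relative tolerance, default 0.01.
#' @return list with `converged` (flag), `cycle` (first converged cycle index,
#'   NA if none) and `deltas` (per-cycle relative changes, starting at cycle 2).
#' @export
detect_periodic_steady_state <- function(history, tol = 0.01) {
  stopifnot(is.data.frame(history), all(c("cycle", "P_ao") %in% names(history)))
  ks <- sort(unique(history$cycle))
  if (length(ks) < 2L) stop("need at least 2 completed cycles")
  pao <- split(history$P_ao, history$cycle)
  deltas <- vapply(seq_along(ks)[-1L], function(i) {
    a <- pao[[i]]; b <- pao[[i - 1L]]
    m <- min(length(a), length(b))
    max(abs(a[1:m] - b[1:m])) / max(abs(a[1:m]))
  }, numeric(1))
  hit <- which(deltas < tol)
  list(converged = length(hit) > 0L,
       cycle = if (length(hit)) ks[-1L][hit[1L]] else NA_integer_,
       deltas = deltas)
}

#' Diastolic share of coronary flow
#'
#' Fraction of the coronary branch volume flux delivered during diastole
#' (the part of the cycle outside the systolic interval). Left coronary flow
#' is diastolic-dominant because myocardial contraction throttles systolic
#' perfusion; with the intramyocardial coupling active the fraction exceeds
#' 0.5.
#'
#' @param waveforms a `waveform_set` (one converged cycle).
#' @param systolic_interval systole duration as a fraction of the cycle;
#'   defaults to the simulation's own systolic interval.
#' @return fraction in [0, 1]
#' @export
diastolic_flow_fraction <- function(waveforms, systolic_interval = NULL) {
  stopifnot(inherits(waveforms, "waveform_set") || is.data.frame(waveforms))
  period <- attr(waveforms, "period")
  if (is.null(period)) period <- max(waveforms$time)
  if (is.null(systolic_interval)) {
    ts <- attr(waveforms, "t_sys")
    if (is.null(ts)) stop("systolic_interval not given and not recorded on waveforms")
    systolic_interval <- ts / period
  }
  t <- waveforms$time
  q <- waveforms$Q_cor
  total <- .trapz(t, q)
  if (abs(total) < 1e-9)
    stop("undefined-fraction error: total coronary flux is zero")
  t_sys <- systolic_interval * period
  # integrate flux over [t_sys, T], interpolating the window boundary exactly
  after <- t > t_sys
  td <- c(t_sys, t[after])
  qd <- c(stats::approx(t, q, t_sys)$y, q[after])
  .trapz(td, qd) / total
}

#' Tune the LPN to clinical targets
#'
#' Deterministic fixed-point tuning: each iteration simulates to periodic
#' steady state, then rescales distal+proximal systemic resistance from the
#' implied MAP/CO ratio, systemic compliance from the pulse-pressure ratio,
#' maximum elastance from the stroke-volume ratio and the coronary resistance
#' chain from the coronary-flow-fraction ratio, all with geometric damping.
#' Iteration targets a 20% safety margin inside `tol` (so downstream
#' re-simulation from any initial state stays within `tol`) and stops once
#' simulated systolic/diastolic pressure, stroke volume and coronary flow
#' fraction all sit inside that margin; exceeding `tol` after the budget is
#' an error.
#'
#' @param targets a `clinical_targets` object.
#' @param init starting `lpn_parameters`; default [default_parameters()].
#' @param tol relative matching tolerance (default 0.05).
#' @param max_iter iteration budget; exhaustion raises a tuning-failure error
#'   carrying the final residuals.
#' @param damping exponent in (0, 1] applied to each multiplicative update.
#' @param quiet suppress per-iteration messages.
#' @return tuned `lpn_parameters` with attribute `tuning` (iterations,
#'   residuals, achieved values).
#' @export
lpn_tune <- function(targets, init = default_parameters(targets), tol = 0.05,
                     max_iter = 40L, damping = 0.7, quiet = TRUE) {
  stopifnot(inherits(targets, "clinical_targets"))
  params <- lpn_parameters(init)
  hr <- targets$heart_rate
  pp_t <- targets$systolic_pressure - targets$diastolic_pressure
  map_t <- targets$diastolic_pressure + pp_t / 3
  co_t <- targets$stroke_volume * hr / 60
  state <- NULL
  res <- NULL
  best <- NULL
  for (it in seq_len(max_iter)) {
    run <- lpn_simulate(params, hr, n_cycles = 30L, tol = 2e-4,
                        init = state, until_converged = TRUE)
    state <- run$final_state
    w <- run$waveforms
    sbp <- max(w$P_ao); dbp <- min(w$P_ao)
    pp_s <- sbp - dbp
    map_s <- dbp + pp_s / 3
    sv_s <- max(w$V_lv) - min(w$V_lv)
    co_s <- sv_s * hr / 60
    f_s <- .trapz(w$time, w$Q_cor) / attr(w, "period") / co_s
    res <- c(systolic = sbp / targets$systolic_pressure - 1,
             diastolic = dbp / targets$diastolic_pressure - 1,
             stroke_volume = sv_s / targets$stroke_volume - 1,
             coronary_fraction = f_s / targets$coronary_flow_fraction - 1)
    if (!quiet)
      message(sprintf("iter %2d: BP %.1f/%.1f  SV %.1f  f_cor %.4f  max|res| %.3f",
                      it, sbp, dbp, sv_s, f_s, max(abs(res))))
    ok <- all(abs(res) < 0.8 * tol) ||
      (it == 1L && all(abs(res) < tol))   # init already matching: fixed point
    if (ok && run$converged) {
      attr(params, "tuning") <- list(
        iterations = it, residuals = res, converged = TRUE,
        achieved = c(systolic = sbp, diastolic = dbp, stroke_volume = sv_s,
                     coronary_fraction = f_s))
      return(params)
    }
    r_fac <- ((map_t / co_t) / (map_s / co_s))^damping
    c_fac <- (pp_s / pp_t)^damping
    e_fac <- (targets$stroke_volume / sv_s)^damping
    f_fac <- (f_s / targets$coronary_flow_fraction)^damping * r_fac
    upd <- unclass(params)
    upd$R_d <- upd$R_d * r_fac
    upd$R_p <- upd$R_p * r_fac
    upd$R_venret <- upd$R_venret * r_fac
    upd$C_sys <- upd$C_sys * c_fac
    upd$E_max <- max(upd$E_max * e_fac, upd$E_min * 1.5)
    upd$Ra <- upd$Ra * f_fac
    upd$Ra_micro <- upd$Ra_micro * f_fac
    upd$Rv <- upd$Rv * f_fac
    params <- lpn_parameters(upd)
  }
  stop(errorCondition(
    sprintf("tuning failed to match targets within %.0f%% in %d iterations (max residual %.1f%%)",
            100 * tol, max_iter, 100 * max(abs(res))),
    residuals = res, class = c("caahemo_tuning_error", "error")))
}

#' Windkessel branch driven by a prescribed pressure
#'
#' Integrates a single proximal-R / C / distal-R Windkessel branch under a
#' prescribed inlet pressure waveform (no heart), returning the final-cycle
#' inlet flow. Used to verify the circuit elements against the closed-form
#' first-order RC frequency response.
#'
#' @param R_p,C,R_d proximal resistance, compliance, distal resistance.
#' @param p_fun vectorized function of time returning inlet pressure (mmHg).
#' @param period forcing period, s.
#' @param n_cycles cycles to integrate (transient decays over R C).
#' @param steps output steps per cycle.
#' @param p_out outlet (venous) pressure, mmHg.
#' @return data frame: time (one cycle), P_in, P_c, Q (inlet flow, mL/s)
#' @export
windkessel_response <- function(R_p, C, R_d, p_fun, period, n_cycles = 20L,
                                steps = 500L, p_out = 0) {
  rhs <- function(t, y, p) {
    list(((p_fun(t) - y[1L]) / R_p - (y[1L] - p_out) / R_d) / C)
  }
  times <- seq(0, n_cycles * period, length.out = n_cycles * steps + 1L)
  sol <- deSolve::ode(c(P_c = p_fun(0)), times, rhs, NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-9)
  last <- times >= (n_cycles - 1L) * period
  t <- times[last] - (n_cycles - 1L) * period
  pc <- sol[last, "P_c"]
  pin <- p_fun(times[last])
  data.frame(time = t, P_in = pin, P_c = pc, Q = (pin - pc) / R_p)
}

#' Serialize parameter / target sets
#'
#' Flat `key = value` text format, one field per line; round-trips through
#' [read_lpn_parameters()] / [read_clinical_targets()].
#'
#' @param x an `lpn_parameters` or `clinical_targets` object.
#' @param file output path.
#' @export
write_flat <- function(x, file) {
  vals <- unclass(x)
  writeLines(sprintf("%s = %.15g", names(vals), unlist(vals)), file)
  invisible(file)
}

.read_flat <- function(file) {
  lines <- grep("=", readLines(file), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                  vapply(kv, `[`, "", 1L))
}

#' @rdname write_flat
#' @param file path to a flat key-value text file.
#' @export
read_lpn_parameters <- function(file) lpn_parameters(as.list(.read_flat(file)))

#' @rdname write_flat
#' @export
read_clinical_targets <- function(file) {
  v <- as.list(.read_flat(file))
  do.call(clinical_targets, v[c("heart_rate", "systolic_pressure",
                                "diastolic_pressure", "stroke_volume",
                                "body_surface_area", "coronary_flow_fraction")])
}

#' Write a waveform set as a delimited table
#'
#' @param waveforms a `waveform_set` data frame.
#' @param file output path.
#' @param sep field separator.
#' @export
write_waveforms <- function(waveforms, file, sep = "\t") {
  utils::write.table(format(as.data.frame(waveforms), digits = 10, trim = TRUE),
                     file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}
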