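test_that("clinical targets enforce their invariants", {
  expect_error(clinical_targets(75, 80, 120, 70), "systolic")
  expect_error(clinical_targets(75, 120, 80, -1), "positive")
  expect_error(clinical_targets(75, 120, 80, 70, 1.8, 0.2), "coronary")
  expect_s3_class(clinical_targets(75, 120, 80, 70), "clinical_targets")
})

test_that("default parameters follow Ohmic scaling to the targets", {
  tg <- clinical_targets(75, 120, 80, 70)
  p <- default_parameters(tg)
  co <- 70 * 75 / 60
  map <- 80 + (120 - 80) / 3
  # closed-form oracle: total systemic resistance ~ (MAP - P_ven)/CO on the
  # systemic share of cardiac output
  r_sys_expected <- (map - 5) / ((1 - tg$coronary_flow_fraction) * co)
  expect_equal(p$R_p + p$R_d, r_sys_expected, tolerance = 1e-10)

  tg2 <- clinical_targets(75, 120, 80, 140)
  p2 <- default_parameters(tg2)
  expect_equal((p2$R_p + p2$R_d) / (p$R_p + p$R_d), 0.5, tolerance = 1e-10)

  # two-resistor divider: coronary branch draws f of the output, so its
  # resistance is the systemic resistance divided by f/(1-f)
  f <- tg$coronary_flow_fraction
  r_cor <- p$Ra + p$Ra_micro + p$Rv
  expect_equal(r_cor / (p$R_p + p$R_d), (1 - f) / f, tolerance = 1e-10)
})

test_that("parameter validation rejects non-physical values", {
  tg <- default_clinical_targets()
  p <- unclass(default_parameters(tg))
  p$R_d <- -1
  expect_error(lpn_parameters(p), "positive")
  p <- unclass(default_parameters(tg)); p$gamma <- 1.2
  expect_error(lpn_parameters(p), "gamma")
  p <- unclass(default_parameters(tg)); p$E_max <- p$E_min / 2
  expect_error(lpn_parameters(p), "E_max")
})

test_that("no contraction and equalized pressures produce no flow", {
  tg <- default_clinical_targets()
  p <- unclass(default_parameters(tg))
  p$E_min <- 1
  p$E_max <- 1 + 1e-9
  p <- lpn_parameters(p)
  init <- c(V_lv = p$V0 + 30, P_ao = 30, P_ca = 30, P_cim = 30,
            P_ven = 30, P_la = 30)
  run <- lpn_simulate(p, 80, n_cycles = 2L, init = init,
                      until_converged = FALSE)
  expect_lt(abs(mean(run$waveforms$Q_av)), 1e-6)
})

test_that("windkessel branch matches the analytic RC frequency response", {
  R_p <- 0.1; C <- 1; R_d <- 1
  period <- 0.8
  omega <- 2 * pi / period
  p0 <- 90; A <- 20
  p_fun <- function(t) p0 + A * sin(omega * t)
  wk <- windkessel_response(R_p, C, R_d, p_fun, period)
  # closed-form impedance of proximal-R / C / distal-R
  Z <- R_p + R_d / (1 + 1i * omega * R_d * C)
  q_dc <- p0 / (R_p + R_d)
  H <- A / Z
  q_exact <- q_dc + Mod(H) * sin(omega * wk$time + Arg(H))
  expect_lt(max(abs(wk$Q - q_exact)) / max(abs(q_exact)), 0.01)
})

test_that("tuned run conserves mass and lands in physiologic pressure bounds", {
  tg <- default_clinical_targets()
  run <- tuned_run()
  w <- run$waveforms
  expect_true(run$converged)
  sv <- max(w$V_lv) - min(w$V_lv)
  # net ventricular volume change over the converged cycle
  expect_lt(abs(w$V_lv[nrow(w)] - w$V_lv[1]) / sv, 0.005)
  # mean inflow equals sum of mean branch outflows
  expect_lt(abs(mean(w$Q_av) - mean(w$Q_sys) - mean(w$Q_cor)) / mean(w$Q_av),
            0.005)
  # every capacitor node returns to its starting pressure
  for (ch in c("P_ao", "P_ca", "P_cim", "P_ven", "P_la")) {
    expect_lt(abs(w[[ch]][nrow(w)] - w[[ch]][1]) / max(abs(w[[ch]])), 0.005)
  }
  expect_gt(min(w$P_ao), 0.5 * tg$diastolic_pressure)
  expect_lt(max(w$P_ao), 1.5 * tg$systolic_pressure)
})

test_that("stroke volume equals integrated aortic ejection flow", {
  run <- tuned_run()
  w <- run$waveforms
  sv_vol <- max(w$V_lv) - min(w$V_lv)
  dt <- diff(w$time)
  q <- w$Q_av
  ejected <- sum(dt * (head(q, -1) + q[-1]) / 2)
  expect_lt(abs(ejected - sv_vol) / sv_vol, 0.01)
})

test_that("halving the output step leaves the cycle-mean aortic pressure unchanged", {
  tg <- default_clinical_targets()
  p <- tuned_default()
  r1 <- lpn_simulate(p, tg$heart_rate, n_cycles = 10L, until_converged = FALSE)
  r2 <- lpn_simulate(p, tg$heart_rate, n_cycles = 10L, until_converged = FALSE,
                     dt = 60 / tg$heart_rate / 1000)
  m1 <- mean(r1$waveforms$P_ao)
  m2 <- mean(r2$waveforms$P_ao)
  expect_lt(abs(m1 - m2) / m1, 0.002)
})

test_that("periodic-steady-state detection matches a synthetic decaying transient", {
  # identical consecutive cycles converge at the first comparison
  grid <- seq(0, 1, length.out = 50)
  base <- 90 + 20 * sin(2 * pi * grid)
  hist_same <- data.frame(cycle = rep(1:3, each = 50), P_ao = rep(base, 3))
  d <- detect_periodic_steady_state(hist_same)
  expect_true(d$converged)
  expect_equal(d$cycle, 2L)

  # geometric transient with known ratio: predicted first converged cycle
  rho <- 0.5; A <- 30; tol <- 0.01
  cycles <- lapply(1:12, function(k) base + A * rho^k * cos(2 * pi * grid))
  hist_g <- data.frame(cycle = rep(1:12, each = 50), P_ao = unlist(cycles))
  # independent brute-force scan over the same synthetic cycles
  first <- NA
  for (k in 2:12) {
    delta <- max(abs(cycles[[k]] - cycles[[k - 1]])) / max(abs(cycles[[k]]))
    if (delta < tol) { first <- k; break }
  }
  d_g <- detect_periodic_steady_state(hist_g, tol)
  expect_true(d_g$converged)
  expect_equal(d_g$cycle, first)

  # monotone drift never converges
  drift <- data.frame(cycle = rep(1:5, each = 50),
                      P_ao = rep(base, 5) + rep(1:5, each = 50) * 5)
  expect_false(detect_periodic_steady_state(drift)$converged)
  expect_error(detect_periodic_steady_state(drift[drift$cycle == 1, ]),
               "2 completed cycles")
})

test_that("diastolic flow fraction behaves on analytic waveforms", {
  t <- seq(0, 0.8, length.out = 401)
  const <- structure(data.frame(time = t, Q_cor = rep(2, 401)),
                     class = c("waveform_set", "data.frame"),
                     period = 0.8, t_sys = 0.25)
  expect_equal(diastolic_flow_fraction(const), 1 - 0.25 / 0.8,
               tolerance = 1e-6)

  inside <- structure(
    data.frame(time = t, Q_cor = ifelse(t > 0.4, 1, 0)),
    class = c("waveform_set", "data.frame"), period = 0.8, t_sys = 0.25)
  expect_equal(diastolic_flow_fraction(inside), 1, tolerance = 1e-6)

  zero <- structure(data.frame(time = t, Q_cor = rep(0, 401)),
                    class = c("waveform_set", "data.frame"),
                    period = 0.8, t_sys = 0.25)
  expect_error(diastolic_flow_fraction(zero), "undefined")
})

test_that("intramyocardial coupling throttles systolic coronary flow monotonically", {
  tg <- default_clinical_targets()
  p <- tuned_default()
  shares <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(g) {
    pg <- unclass(p); pg$gamma <- g
    run <- lpn_simulate(lpn_parameters(pg), tg$heart_rate, tol = 0.005)
    1 - diastolic_flow_fraction(run$waveforms)
  }, numeric(1))
  expect_true(all(diff(shares) < 0))
})

test_that("tuning is a fixed point at an already-matching parameter set", {
  tuned <- tuned_default()
  again <- lpn_tune(default_clinical_targets(), init = tuned)
  expect_equal(unclass(again)[names(unclass(tuned))], unclass(tuned),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(again, "tuning")$iterations, 1L)
})

test_that("parameter and target sets round-trip through the flat text format", {
  tg <- default_clinical_targets()
  p <- default_parameters(tg)
  f <- withr::local_tempfile(fileext = ".txt")
  write_flat(p, f)
  expect_equal(unclass(read_lpn_parameters(f)), unclass(p), tolerance = 1e-12)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_flat(tg, f2)
  expect_equal(unclass(read_clinical_targets(f2)), unclass(tg),
               tolerance = 1e-12)
})
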