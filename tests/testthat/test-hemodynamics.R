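test_that("wall shear stress follows the Poiseuille closed form", {
  cl <- straight_centerline()
  tube <- uniform_vessel(cl, baseline_diameter = 3)  # r = 0.15 cm
  flow <- fixture_flow_waveform("constant", q0 = 1.5)
  fld <- wss_field(tube, flow)
  expect_equal(unique(round(as.vector(fld$tau), 10)),
               round(4 * 0.04 * 1.5 / (pi * 0.15^3), 10))
  expect_equal(fld$tau[1, 1], 22.6354, tolerance = 1e-4)

  tube2 <- uniform_vessel(cl, baseline_diameter = 6)
  fld2 <- wss_field(tube2, flow)
  expect_equal(fld$tau[1, 1] / fld2$tau[1, 1], 8, tolerance = 1e-12)

  zero <- fixture_flow_waveform("constant", q0 = 0)
  expect_true(all(wss_field(tube, zero)$tau == 0))
})

test_that("TAWSS integrates shear magnitude over the cycle", {
  cl <- straight_centerline()
  tube <- uniform_vessel(cl, baseline_diameter = 3)
  flow <- fixture_flow_waveform("constant", q0 = 1)
  ta <- tawss(wss_field(tube, flow))
  tau0 <- 4 * 0.04 / (pi * 0.15^3)
  expect_equal(ta$tawss, rep(tau0, length(ta$s)), tolerance = 1e-12)
  expect_equal(ta$mean, tau0, tolerance = 1e-12)

  # sign reversal: half cycle +c, half -c still averages to |c|
  t <- seq(0, 0.8, length.out = 501)
  sq <- flow_waveform(t, ifelse(t < 0.4, 1, -1), 0.8)
  ta_sq <- tawss(wss_field(tube, sq))
  expect_equal(ta_sq$mean, tau0, tolerance = 1e-8)
})

test_that("TAWSS and OSI match fine-grid brute-force integration", {
  cl <- straight_centerline()
  g <- morph_aneurysm(cl, aneurysm_spec(7, 40, s_start = 1))
  mk <- function(n) fixture_flow_waveform("sinusoid", q0 = 0.8,
                                          amplitude = 1.4, n = n)
  fld <- wss_field(g, mk(500L))
  ta <- tawss(fld)$tawss
  os <- osi(fld)$osi
  # brute-force reference on a 10x finer time grid
  fldf <- wss_field(g, mk(5000L))
  tf <- fldf$time
  ref_ta <- apply(abs(fldf$tau), 1, function(y)
    sum(diff(tf) * (head(y, -1) + y[-1]) / 2)) / 0.8
  num <- abs(apply(fldf$tau, 1, function(y)
    sum(diff(tf) * (head(y, -1) + y[-1]) / 2)))
  den <- apply(abs(fldf$tau), 1, function(y)
    sum(diff(tf) * (head(y, -1) + y[-1]) / 2))
  ref_os <- 0.5 * (1 - num / den)
  expect_lt(max(abs(ta - ref_ta) / ref_ta), 0.001)
  expect_lt(max(abs(os - ref_os)), 0.001)
})

test_that("OSI hits its analytic endpoints", {
  cl <- straight_centerline()
  tube <- uniform_vessel(cl, 3)
  uni <- fixture_flow_waveform("biphasic-coronary", q0 = 1.2)
  expect_equal(osi(wss_field(tube, uni))$max, 0)

  t <- seq(0, 0.8, length.out = 501)
  rev <- flow_waveform(t, sin(2 * pi * t / 0.8), 0.8)
  o <- osi(wss_field(tube, rev))
  expect_equal(o$max, 0.5, tolerance = 1e-6)
  expect_true(all(o$osi >= 0 & o$osi <= 0.5))

  zero <- fixture_flow_waveform("constant", q0 = 0)
  expect_equal(osi(wss_field(tube, zero))$osi,
               rep(0, 401))
})

test_that("low-WSS area fractions hit trivial endpoints and a half-area oracle", {
  cl <- straight_centerline()
  g <- morph_aneurysm(cl, aneurysm_spec(8, 20, s_start = 1))
  flow <- fixture_flow_waveform("constant", q0 = 1)
  ta <- tawss(wss_field(g, flow))
  expect_equal(low_wss_area_fraction(g, ta, 1e6), 100)
  expect_equal(low_wss_area_fraction(g, ta, 1e-9), 0)
  expect_error(low_wss_area_fraction(g, ta, -1), "threshold")

  # tube whose distal half is wider: exactly the distal half-area lies below
  # a threshold between the two shear levels
  half1 <- uniform_vessel(cl, 3)
  r_lo <- 0.15; r_hi <- 0.25
  g2 <- half1
  g2$r_fun <- function(s) ifelse(s < 6, r_lo, r_hi)
  g2$drds_fun <- function(s) rep(0, length(s))
  ta2 <- tawss(wss_field(g2, flow, span = c(0, 12)))
  tau_hi <- 4 * 0.04 / (pi * r_lo^3)
  tau_lo <- 4 * 0.04 / (pi * r_hi^3)
  thr <- (tau_hi + tau_lo) / 2
  frac <- low_wss_area_fraction(g2, ta2, thr)
  # dense-grid indicator oracle: area below threshold is the wide half
  s_dense <- seq(0, 12, length.out = 40001)
  ind <- 4 * 0.04 / (pi * ifelse(s_dense < 6, r_lo, r_hi)^3) < thr
  w <- 2 * pi * ifelse(s_dense < 6, r_lo, r_hi)
  oracle <- 100 * sum(w[ind]) / sum(w)
  expect_lt(abs(frac - oracle), 0.5)
})

test_that("area fraction is monotone in threshold and nested", {
  cl <- straight_centerline()
  set.seed(11)
  for (i in 1:20) {
    g <- morph_aneurysm(cl, random_spec())
    flow <- fixture_flow_waveform("sinusoid", q0 = runif(1, 0.2, 2),
                                  amplitude = runif(1, 0, 2))
    ta <- tawss(wss_field(g, flow))
    thr <- sort(runif(5, 0.1, 30))
    fr <- vapply(thr, function(x) low_wss_area_fraction(g, ta, x), numeric(1))
    expect_true(all(diff(fr) >= 0))
    expect_true(all(fr >= 0 & fr <= 100))
  }
})

test_that("flow rescaling scales TAWSS linearly and leaves OSI unchanged", {
  cl <- straight_centerline()
  g <- morph_aneurysm(cl, aneurysm_spec(7, 40, s_start = 1))
  base <- fixture_flow_waveform("sinusoid", q0 = 1, amplitude = 1.5)
  k <- 3.7
  scaled <- flow_waveform(base$time, k * base$flow, attr(base, "period"))
  ta1 <- tawss(wss_field(g, base)); ta2 <- tawss(wss_field(g, scaled))
  expect_equal(ta2$tawss, k * ta1$tawss, tolerance = 1e-12)
  expect_equal(ta2$mean, k * ta1$mean, tolerance = 1e-12)
  expect_equal(osi(wss_field(g, scaled))$osi, osi(wss_field(g, base))$osi,
               tolerance = 1e-12)
})

test_that("residence time is volume turnover", {
  cl <- straight_centerline()
  tube <- uniform_vessel(cl, 4)   # r = 0.2
  flow <- fixture_flow_waveform("constant", q0 = 1)
  expect_equal(residence_time(tube, flow, span = c(0, 2)), pi * 0.04 * 2,
               tolerance = 1e-9)
  tube2 <- uniform_vessel(cl, 8)
  expect_equal(residence_time(tube2, flow, span = c(0, 2)) /
               residence_time(tube, flow, span = c(0, 2)), 4,
               tolerance = 1e-9)
  g <- morph_aneurysm(cl, aneurysm_spec(8, 40, s_start = 1))
  rt <- residence_time(g, flow)
  ref <- lumen_volume(g, 1, 5, n = 8000L) / 1
  expect_lt(abs(rt - ref) / ref, 0.001)

  t <- seq(0, 0.8, length.out = 201)
  backflow <- flow_waveform(t, sin(2 * pi * t / 0.8), 0.8)  # zero mean
  expect_error(residence_time(tube, backflow), "undefined-residence")
})

test_that("metric summary enforces threshold nesting and control behavior", {
  cl <- straight_centerline()
  tube <- uniform_vessel(cl, 3.5)
  fast <- fixture_flow_waveform("biphasic-coronary", q0 = 3)
  m <- summarize_hemodynamics(tube, fast)
  expect_equal(m$area_wss4, 0)
  expect_equal(m$area_wss1, 0)

  # geometry whose TAWSS sits everywhere in [1, 4)
  g <- uniform_vessel(cl, 3.5)
  q_mid <- 2.5 * pi * 0.175^3 / (4 * 0.04)   # tau = 2.5 dyn/cm^2
  m2 <- summarize_hemodynamics(g, fixture_flow_waveform("constant", q0 = q_mid))
  expect_equal(m2$area_wss4, 100)
  expect_equal(m2$area_wss1, 0)

  # the unmorphed control always shows higher mean TAWSS and lower low-WSS
  # area than any morph under identical flow
  flow <- fixture_flow_waveform("biphasic-coronary", q0 = 1.5)
  mc <- summarize_hemodynamics(tube, flow)
  for (sp in table1_cohort()$specs) {
    mm <- summarize_hemodynamics(morph_aneurysm(cl, sp), flow)
    expect_gt(mc$tawss_mean, mm$tawss_mean)
    expect_lt(mc$area_wss4, mm$area_wss4)
    expect_true(mm$area_wss1 <= mm$area_wss4)
  }
})

test_that("mean TAWSS decreases strictly with length at fixed D_max and flow", {
  cl <- straight_centerline()
  flow <- fixture_flow_waveform("biphasic-coronary", q0 = 2)
  for (dmax in c(7, 8)) {
    lens <- c(15, 25, 40, 60, 80)
    means <- vapply(lens, function(L) {
      summarize_hemodynamics(
        morph_aneurysm(cl, aneurysm_spec(dmax, L, s_start = 1)),
        flow)$tawss_mean
    }, numeric(1))
    expect_true(all(diff(means) < 0))
  }
})
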