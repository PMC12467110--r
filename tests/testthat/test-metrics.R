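test_that("phase averaging of identical cycles equals one resampled cycle", {
  f0 <- 125; fs <- 400 * f0          # integer samples per cycle
  t <- seq(0, 10 / f0 - 1 / fs, by = 1 / fs)
  Ag <- 0.1 + 0.08 * pmax(sin(2 * pi * f0 * t), 0)
  rec <- cycle_record(t, Ag = Ag, Q = 300 * pmax(sin(2 * pi * f0 * t), 0))
  pa <- phase_average(rec, n_bins = 500L)
  expect_equal(nrow(pa), 500L)
  expect_equal(attr(pa, "period"), 1 / f0, tolerance = 1e-6)
  # with identical cycles, the average equals the first cycle resampled at
  # the same phase points
  cyc <- detect_cycles(rec)
  tq <- cyc$start[1] + pa$phase * (cyc$end[1] - cyc$start[1])
  expect_equal(pa$Ag, approx(rec$t, rec$Ag, xout = tq, rule = 2)$y,
               tolerance = 1e-10)
})

test_that("antisymmetric noise cancels under phase averaging", {
  f0 <- 100; fs <- 500 * f0
  # 2.2 periods so both noisy cycles are complete detected cycles
  t <- seq(0, 2.2 / f0 - 1 / fs, by = 1 / fs)
  base <- 0.1 + 0.05 * pmax(sin(2 * pi * f0 * t), 0)
  # +/- epsilon on the two cycles, localized away from the cycle-start
  # threshold crossings so the detector stays aligned
  ph <- (t * f0) %% 1
  # compact support keeps the global extremes (hence the detection
  # threshold) and the crossing samples bit-identical across records
  window <- ifelse(abs(ph - 0.42) < 0.08,
                   cos(pi * (ph - 0.42) / 0.16)^2, 0)
  eps <- 1e-3
  sign_k <- c(1, -1, 0)[pmin(floor(t * f0), 2) + 1]
  noise <- eps * sign_k * window
  rec <- cycle_record(t, Ag = base + noise)
  pa <- phase_average(rec, n_bins = 200L)
  pa0 <- phase_average(cycle_record(t, Ag = base), n_bins = 200L)
  expect_lt(max(abs(pa$Ag - pa0$Ag)), eps * 1e-6)
})

test_that("period jitter averages toward the noise-free template", {
  set.seed(11)
  rec0 <- generate_waveforms(cycles = 12L, noise = 0)
  truth <- attr(rec0, "truth")
  f0 <- truth$f0; T <- 1 / f0; fs <- 5e4
  # one-cycle phase template from the generator
  one <- generate_waveforms(cycles = 1L, fs = fs)
  p0 <- (seq_len(nrow(one)) - 1) / nrow(one)
  ag_of <- function(ph) approx(p0, one$Ag, xout = ph, rule = 2)$y
  q_of <- function(ph) approx(p0, one$Q, xout = ph, rule = 2)$y
  # jittered pulse train: cycle k stretched by up to +/-5%
  jit <- 1 + 0.05 * (2 * runif(12) - 1)
  starts <- cumsum(c(0, T * jit))
  tt <- seq(0, starts[13] - 1 / fs, by = 1 / fs)
  kk <- findInterval(tt, starts)
  ph <- (tt - starts[kk]) / (T * jit[kk])
  rec <- cycle_record(tt, Ag = ag_of(ph), Q = q_of(ph))
  pa <- phase_average(rec, closure_floor = truth$ag_floor)
  template <- phase_average(rec0, closure_floor = truth$ag_floor)
  rms_dev <- sqrt(mean((pa$Ag - template$Ag)^2))
  # the averaged waveform deviates less than a typical single jittered
  # cycle does (phase averaging compresses the jitter)
  sel <- kk == 1
  one_cycle_dev <- sqrt(mean((ag_of((tt[sel] - starts[1]) / T) -
                              ag_of(ph[sel]))^2))
  expect_lt(rms_dev, one_cycle_dev)
})

test_that("fundamental frequency estimation is sharp", {
  fs <- 5e4
  t <- seq(0, 0.2, by = 1 / fs)
  expect_equal(fundamental_frequency(sin(2 * pi * 154 * t), fs), 154,
               tolerance = 0.5 / 154)
  x <- sin(2 * pi * 100 * t) + 0.2 * sin(2 * pi * 300 * t)
  expect_equal(fundamental_frequency(x, fs), 100, tolerance = 0.005)
  expect_error(fundamental_frequency(rep(1, 100), fs), "flat")
  # generator pulse train ground truth
  rec <- generate_waveforms(f0 = 180, cycles = 12L)
  expect_equal(fundamental_frequency(rec$Ag, fs), 180, tolerance = 0.5)
})

test_that("waveform quotients match constructed pulse geometry", {
  n <- 1000
  phase <- (seq_len(n) - 1) / n
  # trapezoidal area pulse open exactly 69% of the cycle
  Ag <- ifelse(phase < 0.05, phase / 0.05,
        ifelse(phase < 0.64, 1,
        ifelse(phase < 0.69, (0.69 - phase) / 0.05, 0)))
  # triangular flow pulse: rise 40%, fall 30%, closed 30%
  Q <- ifelse(phase < 0.4, phase / 0.4,
       ifelse(phase < 0.7, (0.7 - phase) / 0.3, 0))
  pa <- tibble::tibble(phase = phase, Ag = Ag, Q = Q)
  qt <- quotients(pa, closure_floor = 0, period = 1 / 154)
  expect_equal(qt$tau_o, 0.690, tolerance = 0.004)
  expect_equal(qt$tau_s, 4 / 3, tolerance = 0.02)
})

test_that("MFDR matches the analytic slope of a half-sine pulse", {
  n <- 1000
  phase <- (seq_len(n) - 1) / n
  T <- 1 / 154
  Q <- pmax(sin(2 * pi * phase), 0) * 400      # mL/s, open half the cycle
  pa <- tibble::tibble(phase = phase, Ag = Q / 400 * 0.1 + 0.01, Q = Q)
  qt <- quotients(pa, closure_floor = 0.01, period = T)
  mfdr_exact <- 400 * 2 * pi / T * 1e-3        # L/s^2
  expect_equal(qt$mfdr, mfdr_exact, tolerance = 0.01 * mfdr_exact)
})

test_that("SPL identities and distance extrapolation hold", {
  expect_equal(spl(rep(2e-5, 100)), 0)
  expect_equal(spl(rep(0.2, 100)), 80)
  expect_equal(spl(rep(0.2, 100), r_measure = 0.05, r_report = 0.30),
               80 - 20 * log10(6))
  # 94 dB at 5 cm reported at 30 cm
  p94 <- rep(2e-5 * 10^(94 / 20), 10)
  expect_equal(spl(p94, r_measure = 0.05, r_report = 0.30),
               94 - 20 * log10(6), tolerance = 1e-10)
  # transitivity: 5 -> 15 -> 30 equals 5 -> 30
  s1 <- spl(p94, r_measure = 0.05, r_report = 0.15)
  s2 <- s1 - 20 * log10(0.30 / 0.15)
  expect_equal(s2, spl(p94, r_measure = 0.05, r_report = 0.30),
               tolerance = 1e-12)
  expect_error(spl(numeric(0)), "empty")
})

test_that("vocal efficiency evaluates its defining formula", {
  expect_equal(vocal_efficiency(120, 1 / sqrt(4 * pi), 1, 1), 1)
  e1 <- vocal_efficiency(85, 0.05, 800, 2e-4)
  expect_equal(vocal_efficiency(85, 0.05, 800, 1e-4), 2 * e1)
  # independent spreadsheet-style evaluation on random admissible inputs
  set.seed(3)
  for (k in 1:20) {
    s <- runif(1, 40, 110); r <- runif(1, 0.01, 1)
    Pp <- runif(1, 200, 2000); Ug <- runif(1, 1e-5, 1e-3)
    expect_equal(vocal_efficiency(s, r, Pp, Ug),
                 4 * pi * r^2 * 10^((s - 120) / 10) / (Pp * Ug),
                 tolerance = 1e-12)
  }
  expect_error(vocal_efficiency(80, 0.05, 0, 1), "positive")
})

test_that("flow resistance follows its tap-pair definitions", {
  n <- 100
  taps <- tibble::tibble(p_sgs_up = rep(800, n), p_sgs_down = rep(780, n),
                         p_sub = rep(780, n), p_sup = rep(0, n))
  Q <- rep(2e-4, n)
  expect_equal(flow_resistance(taps, Q, "vf"), 780 / 2e-4)
  expect_equal(flow_resistance(taps, Q, "sgs"), 20 / 2e-4)
  expect_equal(flow_resistance(taps, Q, "total"),
               flow_resistance(taps, Q, "sgs") +
               flow_resistance(taps, Q, "vf"))
  taps0 <- tibble::tibble(p_sgs_up = rep(5, n), p_sgs_down = rep(5, n),
                          p_sub = 1, p_sup = 1)
  expect_equal(flow_resistance(taps0, Q, "sgs"), 0)
  expect_error(flow_resistance(taps, rep(0, n), "vf"), "zero")
})

test_that("area ratio and pressure-drop change follow their definitions", {
  expect_equal(area_ratio(rep(0.1, 10), severity = 0, reference_area = 1), 0.1)
  # identical glottal area, severity 0.9: ratio grows tenfold
  expect_equal(area_ratio(rep(0.1, 10), 0.9, 1) /
               area_ratio(rep(0.1, 10), 0, 1), 10)
  expect_error(area_ratio(0.1, 1, 1), "zero")
  expect_equal(pressure_drop_change(100, 100), 0)
  expect_equal(pressure_drop_change(100, 80), 20)
  set.seed(4)
  for (k in 1:10) {
    b <- runif(1, 10, 1000); cse <- runif(1, 0, b)
    expect_equal(pressure_drop_change(b, cse), (b - cse) / b * 100)
  }
  expect_error(pressure_drop_change(0, 1), "zero")
})

test_that("generator ground truth is recovered within one percent", {
  rec <- generate_waveforms(f0 = 154, tau_o = 0.69, tau_s = 1.32,
                            cycles = 10L)
  truth <- attr(rec, "truth")
  m <- phonatory_metrics(rec, closure_floor = truth$ag_floor)
  expect_equal(m$f0, truth$f0, tolerance = 0.01 * truth$f0)
  expect_equal(m$tau_o, truth$tau_o, tolerance = 0.01 * truth$tau_o)
  expect_equal(m$tau_s, truth$tau_s, tolerance = 0.01 * truth$tau_s)
  expect_equal(m$mfdr, truth$mfdr, tolerance = 0.01 * truth$mfdr)
  expect_equal(m$Q_peak, truth$q_peak, tolerance = 0.01 * truth$q_peak)
})

test_that("the metric pipeline is pure", {
  rec <- generate_waveforms(cycles = 6L, noise = 0.01, seed = 42L)
  m1 <- phonatory_metrics(rec, closure_floor = attr(rec, "truth")$ag_floor)
  m2 <- phonatory_metrics(rec, closure_floor = attr(rec, "truth")$ag_floor)
  expect_identical(m1, m2)
  # the generator itself is seed-reproducible
  rec2 <- generate_waveforms(cycles = 6L, noise = 0.01, seed = 42L)
  expect_identical(rec$Ag, rec2$Ag)
})

test_that("generator rejects inconsistent specifications", {
  expect_error(generate_waveforms(tau_o = 1), "tau_o")
  expect_error(generate_waveforms(tau_s = 0), "tau_s")
  expect_error(generate_waveforms(f0 = 0), "f0")
})
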