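#' Per-cycle phonatory time-series record
#'
#' Uniformly sampled time series feeding the phonatory, aerodynamic and
#' acoustic metrics: minimum glottal area `Ag` (cm^2), glottal exit volume
#' flow `Q` (mL/s), acoustic probe pressure `p_probe` (Pa) and the pressure
#' taps bracketing the stenosis and the glottis (Pa).
#'
#' @param t strictly increasing, uniformly sampled times (s).
#' @param Ag,Q,p_probe,p_sub,p_sup,p_sgs_up,p_sgs_down series; missing ones
#'   default to zero.
#' @return a `tbl_df` of class `phs_cycle_record`.
#' @export
cycle_record <- function(t, Ag, Q = 0, p_probe = 0, p_sub = 0, p_sup = 0,
                         p_sgs_up = 0, p_sgs_down = 0) {
  n <- length(t)
  if (n < 2L) stop("need at least two samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("t must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1]) stop("t must be uniformly sampled")
  rec <- tibble::tibble(
    t = t,
    Ag = rep(Ag, length.out = n),
    Q = rep(Q, length.out = n),
    p_probe = rep(p_probe, length.out = n),
    p_sub = rep(p_sub, length.out = n),
    p_sup = rep(p_sup, length.out = n),
    p_sgs_up = rep(p_sgs_up, length.out = n),
    p_sgs_down = rep(p_sgs_down, length.out = n))
  class(rec) <- c("phs_cycle_record", class(rec))
  rec
}

#' Detect steady oscillation cycles from the glottal-area series
#'
#' Cycle starts are rising crossings of the threshold
#' `closure_floor + 0.1 * (max(Ag) - closure_floor)`; only complete cycles
#' (between consecutive crossings) are returned.
#'
#' @param record [cycle_record()].
#' @param closure_floor residual glottal area during closure (cm^2); by
#'   default the observed series minimum.
#' @return data.frame with cycle start/end times.
#' @export
detect_cycles <- function(record, closure_floor = NULL) {
  Ag <- record$Ag; t <- record$t
  if (is.null(closure_floor)) closure_floor <- min(Ag)
  thr <- closure_floor + 0.1 * (max(Ag) - closure_floor)
  if (max(Ag) - closure_floor <= 0) stop("flat glottal-area signal: no cycles")
  up <- which(Ag[-length(Ag)] < thr & Ag[-1] >= thr)
  if (length(up) < 2L) stop("no complete cycles detected")
  # linear interpolation of the crossing instant
  tc <- t[up] + (thr - Ag[up]) / (Ag[up + 1L] - Ag[up]) * (t[up + 1L] - t[up])
  data.frame(start = tc[-length(tc)], end = tc[-1])
}

#' Phase-average multi-cycle series
#'
#' Divides each detected cycle into `n_bins` equal phase intervals and
#' averages every column of the record across cycles within each interval.
#'
#' @param record [cycle_record()].
#' @param n_bins phase bins per cycle (default 1000).
#' @param closure_floor passed to [detect_cycles()].
#' @return tibble with `phase` in [0, 1) and the phase-averaged columns;
#'   the mean cycle period is attached as attribute `"period"`.
#' @export
phase_average <- function(record, n_bins = 1000L, closure_floor = NULL) {
  cyc <- detect_cycles(record, closure_floor)
  phase <- (seq_len(n_bins) - 1) / n_bins
  cols <- setdiff(names(record), "t")
  acc <- matrix(0, n_bins, length(cols), dimnames = list(NULL, cols))
  for (k in seq_len(nrow(cyc))) {
    tq <- cyc$start[k] + phase * (cyc$end[k] - cyc$start[k])
    for (cn in cols)
      acc[, cn] <- acc[, cn] +
        stats::approx(record$t, record[[cn]], xout = tq, rule = 2)$y
  }
  acc <- acc / nrow(cyc)
  out <- tibble::as_tibble(as.data.frame(acc))
  out <- tibble::add_column(out, phase = phase, .before = 1)
  attr(out, "period") <- mean(cyc$end - cyc$start)
  attr(out, "n_cycles") <- nrow(cyc)
  out
}

#' Fundamental frequency from a periodic series
#'
#' Dominant non-DC peak of the Fourier magnitude spectrum, refined by
#' maximizing the Hann-windowed discrete-time Fourier magnitude around the
#' peak bin.
#'
#' @param x series (e.g. glottal area); a constant series is an error.
#' @param fs sampling rate (Hz).
#' @return frequency (Hz).
#' @export
fundamental_frequency <- function(x, fs) {
  x <- x - mean(x)
  if (max(abs(x)) == 0) stop("flat signal: fundamental frequency undefined")
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  X <- abs(stats::fft(x * w))[seq_len(floor(n / 2))]
  k <- which.max(X[-1]) + 1L          # skip DC
  f0_bin <- (k - 1) * fs / n
  tt <- seq(0, n - 1) / fs
  mag <- function(f) abs(sum(x * w * exp(-2i * pi * f * tt)))
  df <- fs / n
  stats::optimize(mag, c(max(f0_bin - df, df / 4), f0_bin + df),
                  maximum = TRUE)$maximum
}

#' Glottal waveform quotients and maximum flow declination rate
#'
#' From phase-averaged single-cycle waveforms: the open quotient `tau_o`
#' (fraction of the cycle with `Ag` above the closure floor plus a
#' one-percent-of-amplitude tolerance), the skewness quotient `tau_s`
#' (flow acceleration duration over deceleration duration) and the MFDR
#' (steepest negative slope of the flow waveform, centred differences on
#' the phase-averaged flow, reported as a magnitude in L/s^2 when `Q` is in
#' mL/s).
#'
#' @param pa phase-averaged waveform from [phase_average()] (columns
#'   `phase`, `Ag`, `Q`); its `"period"` attribute (or `period`) sets the
#'   time scale.
#' @param closure_floor residual closed-glottis area (cm^2); default
#'   `min(Ag)`.
#' @param period cycle duration (s); defaults to `attr(pa, "period")`.
#' @return tibble with `tau_o`, `tau_s`, `mfdr`.
#' @export
quotients <- function(pa, closure_floor = NULL, period = NULL) {
  if (is.null(period)) period <- attr(pa, "period")
  if (is.null(period)) stop("cycle period unknown; pass `period`")
  Ag <- pa$Ag; Q <- pa$Q
  n <- length(Ag)
  if (is.null(closure_floor)) closure_floor <- min(Ag)
  amp <- max(Ag) - closure_floor
  if (amp <= 0) stop("glottal area never opens: quotients undefined")
  open <- Ag > closure_floor + 0.01 * amp
  if (all(open)) warning("glottal area never closes")
  tau_o <- mean(open)
  # flow-based timings on the open (flow-active) segment, circularly
  qf <- min(Q); qamp <- max(Q) - qf
  if (qamp <= 0) stop("flow waveform is flat: skewness undefined")
  active <- Q > qf + 0.01 * qamp
  # rotate so the cycle starts at a closed->active transition
  startk <- which(!active[c(n, seq_len(n - 1L))] & active)[1]
  if (is.na(startk)) startk <- 1L
  rot <- function(z) z[((seq_len(n) + startk - 2L) %% n) + 1L]
  Qr <- rot(Q); actr <- rot(active)
  seg_end <- if (any(!actr)) which(!actr)[1] - 1L else n
  kpk <- which.max(Qr[seq_len(seg_end)])
  t_acc <- (kpk - 1) / n * period
  t_dec <- (seg_end - kpk + 1) / n * period
  tau_s <- t_acc / t_dec
  dQ <- (Qr[c(2:n, 1)] - Qr[c(n, 1:(n - 1))]) / (2 * period / n)
  mfdr <- max(-dQ) * 1e-3             # mL/s^2 -> L/s^2
  tibble::tibble(tau_o = tau_o, tau_s = tau_s, mfdr = mfdr)
}

#' Sound pressure level with 1/r distance extrapolation
#'
#' `SPL = 20 log10(RMS(p)/p0)`, extrapolated from the measurement radius to
#' a reporting radius via spherical spreading
#' (`SPL - 20 log10(r_report/r_measure)`).
#'
#' @param p acoustic pressure series (Pa).
#' @param p0 reference pressure (Pa).
#' @param r_measure,r_report measurement and reporting radii (m); if both
#'   given, the 1/r extrapolation is applied.
#' @return SPL (dB).
#' @export
spl <- function(p, p0 = 2e-5, r_measure = NULL, r_report = NULL) {
  if (length(p) == 0L) stop("empty pressure series")
  lvl <- 20 * log10(rms(p) / p0)
  if (!is.null(r_measure) && !is.null(r_report)) {
    if (r_measure <= 0 || r_report <= 0) stop("radii must be positive")
    lvl <- lvl - 20 * log10(r_report / r_measure)
  }
  lvl
}

#' Vocal efficiency
#'
#' Ratio of radiated acoustic power (from the SPL at radius `r`, referred
#' to 120 dB = 1 W/m^2) to the aerodynamic input power
#' `Ppul * Ug`: `eta_v = 4 pi r^2 10^((SPL - 120)/10) / (Ppul Ug)`.
#'
#' @param spl_db sound pressure level (dB) at radius `r`.
#' @param r radius of the SPL value (m).
#' @param Ppul pulmonary driving pressure (Pa).
#' @param Ug mean glottal flow (m^3/s).
#' @return efficiency as a fraction (multiply by 100 for percent).
#' @export
vocal_efficiency <- function(spl_db, r, Ppul, Ug) {
  if (Ppul * Ug <= 0) stop("Ppul * Ug must be positive")
  if (r <= 0) stop("radius must be positive")
  4 * pi * r^2 * 10^((spl_db - 120) / 10) / (Ppul * Ug)
}

#' Cycle-averaged flow resistance across the stenosis, glottis or both
#'
#' `FR = mean(delta p) / mean(Q)` with the pressure difference taken across
#' the requested span: `sgs` (`p_sgs_up - p_sgs_down`), `vf`
#' (`p_sub - p_sup`) or `total` (their sum). With contiguous tap pairs
#' `FR_total = FR_sgs + FR_vf` by construction.
#'
#' @param taps data.frame/tibble with the tap series (`p_sgs_up`,
#'   `p_sgs_down`, `p_sub`, `p_sup`), e.g. a [cycle_record()].
#' @param Q flow series (m^3/s, aligned with the taps).
#' @param span one of `"sgs"`, `"vf"`, `"total"`.
#' @return flow resistance (Pa s/m^3).
#' @export
flow_resistance <- function(taps, Q, span = c("sgs", "vf", "total")) {
  span <- match.arg(span)
  qm <- mean(Q)
  if (abs(qm) < 1e-300) stop("mean flow is zero: resistance undefined")
  dp <- switch(span,
               sgs = taps$p_sgs_up - taps$p_sgs_down,
               vf = taps$p_sub - taps$p_sup,
               total = (taps$p_sgs_up - taps$p_sgs_down) +
                 (taps$p_sub - taps$p_sup))
  mean(dp) / qm
}

#' Ratio of cycle-averaged glottal area to the stenosis area
#'
#' @param Ag glottal-area series (cm^2).
#' @param severity stenosis severity (area-reduction fraction, < 1).
#' @param reference_area unconstricted subglottal cross-section (cm^2).
#' @return dimensionless ratio.
#' @export
area_ratio <- function(Ag, severity, reference_area) {
  if (severity >= 1) stop("severity 1 leaves zero stenosis area")
  mean(Ag) / ((1 - severity) * reference_area)
}

#' Percentage change in trans-glottal pressure drop relative to baseline
#'
#' `(baseline - case) / baseline * 100`.
#'
#' @param dpvf_baseline,dpvf_case pressure drops (Pa).
#' @return percentage change.
#' @export
pressure_drop_change <- function(dpvf_baseline, dpvf_case) {
  if (dpvf_baseline == 0) stop("zero baseline pressure drop")
  (dpvf_baseline - dpvf_case) / dpvf_baseline * 100
}

#' Summarize a record into the standard phonatory metric set
#'
#' Convenience wrapper: phase-averages the record, then computes f0, the
#' quotients, MFDR, mean/peak flow and area, SPL and the flow resistances.
#'
#' @param record [cycle_record()].
#' @param closure_floor residual closed-glottis area (cm^2).
#' @param r_measure,r_report SPL radii (m).
#' @param Ppul pulmonary pressure (Pa) for the efficiency.
#' @return one-row tibble of metrics.
#' @export
phonatory_metrics <- function(record, closure_floor = NULL,
                              r_measure = 0.05, r_report = 0.30,
                              Ppul = 800) {
  fs <- 1 / diff(record$t[1:2])
  pa <- phase_average(record, closure_floor = closure_floor)
  f0 <- fundamental_frequency(record$Ag, fs)
  qt <- quotients(pa, closure_floor = closure_floor)
  spl_probe <- if (any(record$p_probe != 0))
    spl(record$p_probe) else NA_real_
  spl_rep <- if (is.finite(spl_probe))
    spl(record$p_probe, r_measure = r_measure, r_report = r_report) else
      NA_real_
  Q_m3 <- record$Q * 1e-6             # mL/s -> m^3/s
  etav <- if (is.finite(spl_probe) && mean(Q_m3) > 0)
    vocal_efficiency(spl_probe, r_measure, Ppul, mean(Q_m3)) else NA_real_
  tibble::tibble(
    f0 = f0, tau_o = qt$tau_o, tau_s = qt$tau_s, mfdr = qt$mfdr,
    Q_mean = mean(pa$Q), Q_peak = max(pa$Q),
    Ag_mean = mean(pa$Ag), Ag_peak = max(pa$Ag),
    spl_probe = spl_probe, spl_report = spl_rep, eta_v = etav,
    fr_sgs = flow_resistance(record, Q_m3, "sgs"),
    fr_vf = flow_resistance(record, Q_m3, "vf"),
    fr_total = flow_resistance(record, Q_m3, "total"))
}
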