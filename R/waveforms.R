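#' Synthetic glottal waveform generator with closed-form ground truth
#'
#' Builds a pulse train of quarter-sine glottal flow and area pulses with
#' exactly the requested fundamental frequency, open quotient and skewness
#' quotient, so every waveform metric has a known true value:
#' within each cycle of period `T = 1/f0` the waveform is open for
#' `tau_o * T`, rising over `t_acc = tau_s/(1+tau_s) * tau_o * T` as
#' `sin(pi s / 2)` and falling over `t_dec = tau_o * T/(1+tau_s)` as
#' `cos(pi s / 2)`; closed otherwise at the leakage floor. The end slopes
#' are finite, so threshold-based open/closed classification locates the
#' transition times accurately. The true MFDR is
#' `(q_peak - q_floor) * pi / (2 t_dec)` (in L/s^2 for mL/s input).
#'
#' Residual closure levels default to the enforced-gap leakage typical of
#' contact-regularized simulations: flow floor 21% of peak, area floor 20%
#' of peak.
#'
#' @param f0 fundamental frequency (Hz).
#' @param tau_o open quotient in (0, 1).
#' @param tau_s skewness quotient (> 0).
#' @param q_peak peak flow (mL/s).
#' @param ag_peak peak glottal area (cm^2).
#' @param q_floor,ag_floor closure leakage levels.
#' @param cycles number of cycles.
#' @param fs sampling rate (Hz).
#' @param noise standard deviation of additive Gaussian noise, as a
#'   fraction of the peak (applied to Ag and Q).
#' @param seed RNG seed for the noise (reproducible records).
#' @param p_amp optional probe-pressure amplitude (Pa): adds a damped
#'   oscillation per cycle so acoustic metrics can be exercised.
#' @return [cycle_record()] with the ground-truth metrics attached as
#'   attribute `"truth"`.
#' @export
generate_waveforms <- function(f0 = 154, tau_o = 0.69, tau_s = 1.32,
                               q_peak = 388, ag_peak = 0.138,
                               q_floor = 0.21 * q_peak,
                               ag_floor = 0.2 * ag_peak,
                               cycles = 10L, fs = 5e4, noise = 0,
                               seed = 1L, p_amp = 0) {
  if (tau_o <= 0 || tau_o >= 1) stop("tau_o must lie strictly in (0, 1)")
  if (tau_s <= 0) stop("tau_s must be positive")
  if (f0 <= 0 || fs <= 4 * f0) stop("need fs well above f0 > 0")
  T <- 1 / f0
  t_open <- tau_o * T
  t_acc <- tau_s / (1 + tau_s) * t_open
  t_dec <- t_open / (1 + tau_s)
  t <- seq(0, cycles * T - 1 / fs, by = 1 / fs)
  ph <- (t %% T)
  pulse <- function(peak, floor_) {
    y <- rep(floor_, length(t))
    r <- ph < t_acc
    y[r] <- floor_ + (peak - floor_) * sin(pi * ph[r] / (2 * t_acc))
    fseg <- ph >= t_acc & ph < t_open
    s <- (ph[fseg] - t_acc) / t_dec
    y[fseg] <- floor_ + (peak - floor_) * cos(pi * s / 2)
    y
  }
  Ag <- pulse(ag_peak, ag_floor)
  Q <- pulse(q_peak, q_floor)
  p <- if (p_amp > 0)
    p_amp * exp(-3 * ph / T) * sin(2 * pi * 3 * ph / T) else rep(0, length(t))
  if (noise > 0) {
    set.seed(seed)
    Ag <- Ag + stats::rnorm(length(t), sd = noise * ag_peak)
    Q <- Q + stats::rnorm(length(t), sd = noise * q_peak)
  }
  rec <- cycle_record(t, Ag = Ag, Q = Q, p_probe = p)
  attr(rec, "truth") <- list(
    f0 = f0, tau_o = tau_o, tau_s = tau_s,
    mfdr = (q_peak - q_floor) * pi / (2 * t_dec) * 1e-3,
    q_peak = q_peak, ag_peak = ag_peak,
    q_floor = q_floor, ag_floor = ag_floor)
  rec
}
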