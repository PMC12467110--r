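#' Source-filter transfer function of the vocal tract
#'
#' `TF(f) = dp(f) / [dQ/dt](f)`: the ratio of the discrete Fourier
#' transforms of the acoustic pressure signal and the time derivative of
#' the glottal flow (derivative taken in the time domain before the
#' transform), Hann-windowed. Bins where the source spectrum is within
#' `source_floor` of zero are masked (`NA`) rather than divided.
#'
#' @param dp acoustic pressure series (Pa), e.g. the probe signal relative
#'   to the far-field reference.
#' @param Q glottal flow series (m^3/s), aligned with `dp`.
#' @param fs sampling rate (Hz).
#' @param source_floor mask threshold as a fraction of the peak source
#'   magnitude.
#' @return tibble of class `phs_spectral_record` with columns `freq` (Hz),
#'   `tf_mag` (Pa s), `p_mag`; the number of masked bins is attached as
#'   attribute `"n_masked"`.
#' @export
transfer_function <- function(dp, Q, fs, source_floor = 1e-8) {
  n <- length(dp)
  if (length(Q) != n) stop("dp and Q must be aligned")
  if (n < 8L) stop("record too short")
  dQdt <- c(Q[2] - Q[1], (Q[3:n] - Q[1:(n - 2L)]) / 2,
            Q[n] - Q[n - 1L]) * fs
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  P <- stats::fft(dp * w)
  S <- stats::fft(dQdt * w)
  half <- seq_len(floor(n / 2))
  P <- P[half]; S <- S[half]
  mask <- Mod(S) < source_floor * max(Mod(S))
  tf <- Mod(P) / Mod(S)
  tf[mask] <- NA_real_
  out <- tibble::tibble(freq = (half - 1) * fs / n,
                        tf_mag = tf, p_mag = Mod(P))
  class(out) <- c("phs_spectral_record", class(out))
  attr(out, "n_masked") <- sum(mask)
  attr(out, "fs") <- fs
  out
}

#' Extract formant frequencies from a spectral record
#'
#' The first `n` local maxima of the transfer-function magnitude inside
#' `band`, above a prominence threshold (fraction of the in-band maximum),
#' refined by parabolic interpolation on the log magnitude. Formants are
#' returned in ascending order together with the inter-formant spacings.
#'
#' @param spec [transfer_function()] output (or any tibble with `freq` and
#'   `tf_mag`).
#' @param n number of formants requested.
#' @param band frequency band (Hz).
#' @param prominence peak threshold as a fraction of the in-band maximum.
#' @return tibble with `formant` index and `freq` (Hz); spacings
#'   `F2 - F1, ...` attached as attribute `"spacing"`. Fewer than `n`
#'   peaks yields a shorter tibble with a warning.
#' @export
find_formants <- function(spec, n = 4L, band = c(0, 4000),
                          prominence = 0.05) {
  sel <- which(spec$freq >= band[1] & spec$freq <= band[2] &
               is.finite(spec$tf_mag))
  if (length(sel) < 3L) {
    warning("no usable spectrum in band")
    return(tibble::tibble(formant = integer(0), freq = numeric(0)))
  }
  f <- spec$freq[sel]; m <- spec$tf_mag[sel]
  thr <- prominence * max(m)
  k <- which(m[-c(1, length(m))] > m[-c(length(m) - 1, length(m))] &
             m[-c(1, length(m))] >= m[-c(1, 2)]) + 1L
  k <- k[m[k] >= thr]
  if (length(k) == 0L) {
    warning("no spectral peaks above the prominence threshold")
    return(tibble::tibble(formant = integer(0), freq = numeric(0)))
  }
  if (length(k) < n)
    warning(sprintf("only %d of %d requested formants found", length(k), n))
  k <- utils::head(k, n)
  # parabolic refinement on log magnitude
  df <- stats::median(diff(f))
  fr <- vapply(k, function(j) {
    y0 <- log(m[j - 1]); y1 <- log(m[j]); y2 <- log(m[j + 1])
    den <- y0 - 2 * y1 + y2
    d <- if (den < 0) 0.5 * (y0 - y2) / den else 0
    f[j] + max(min(d, 0.5), -0.5) * df
  }, numeric(1))
  fr <- sort(fr)
  out <- tibble::tibble(formant = seq_along(fr), freq = fr)
  if (length(fr) > 1L) attr(out, "spacing") <- diff(fr)
  out
}
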