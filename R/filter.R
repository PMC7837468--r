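# zero-phase Butterworth bandpass
#
# No DSP filter-design package is available, so the classic design chain is
# implemented directly: analog lowpass Butterworth prototype -> lowpass-to-
# bandpass transform -> bilinear transform with frequency prewarping. The
# digital filter is realized as cascaded biquads (second-order sections) for
# numerical robustness and applied forward-backward (zero phase), giving an
# effective rolloff of twice the single-pass order.

# Design a digital Butterworth bandpass as second-order sections.
# Returns list(sos = n x 6 matrix [b0 b1 b2 1 a1 a2], gain = scalar applied
# once per pass).
butter_bandpass_sos <- function(order, low_hz, high_hz, fs) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop_config("need 0 < low < high < Nyquist")
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP poles

  # prewarped analog band edges
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1

  # lowpass->bandpass: each prototype pole p yields the two roots of
  # s^2 - p*bw*s + w0^2 = 0
  half <- proto * bw / 2
  disc <- sqrt(half^2 - w0^2)
  poles_a <- c(half + disc, half - disc)

  # bilinear transform
  fs2 <- 2 * fs
  poles_z <- (fs2 + poles_a) / (fs2 - poles_a)

  # pair complex-conjugate poles into biquads; zeros are order-many at z=1
  # and order-many at z=-1, one of each per section: numerator (1, 0, -1)
  cplx <- poles_z[Im(poles_z) > 1e-10]
  real_p <- Re(poles_z[abs(Im(poles_z)) <= 1e-10])
  sos <- matrix(0, nrow = 0, ncol = 6)
  for (p in cplx)
    sos <- rbind(sos, c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2))
  if (length(real_p) %% 2 != 0)
    stop_config("internal: unpaired real pole in bandpass design")
  if (length(real_p) > 0)
    for (i in seq(1, length(real_p), by = 2)) {
      p1 <- real_p[i]; p2 <- real_p[i + 1]
      sos <- rbind(sos, c(1, 0, -1, 1, -(p1 + p2), p1 * p2))
    }
  if (nrow(sos) != order)
    stop_config("internal: expected ", order, " sections, got ", nrow(sos))

  # normalize to unit gain at the (prewarped) center frequency
  wd <- 2 * atan(w0 / fs2)
  z <- exp(1i * wd)
  h <- prod(apply(sos, 1, function(s)
    (s[1] + s[2] / z + s[3] / z^2) / (s[4] + s[5] / z + s[6] / z^2)))
  list(sos = sos, gain = 1 / Mod(h))
}

# single biquad, direct form, zero initial conditions
biquad_filter <- function(b, a, x) {
  n <- length(x)
  # feedforward part (vectorized)
  v <- b[1] * x
  if (n >= 2) v[2:n] <- v[2:n] + b[2] * x[1:(n - 1)]
  if (n >= 3) v[3:n] <- v[3:n] + b[3] * x[1:(n - 2)]
  # feedback part via the C recursive filter
  as.numeric(stats::filter(v, -a[2:3], method = "recursive"))
}

sos_filter <- function(sos, gain, x) {
  y <- x * gain
  for (i in seq_len(nrow(sos)))
    y <- biquad_filter(sos[i, 1:3], sos[i, 4:6], y)
  y
}

# forward-backward (zero-phase) application with odd-reflection padding.
# The pad must outlast the slowest pole's transient (~6 time constants).
filtfilt_sos <- function(sos, gain, x) {
  n <- length(x)
  pole_mod <- sqrt(pmin(sos[, 6], 1 - 1e-9))
  ext <- min(n - 1L, as.integer(ceiling(6 / (1 - max(pole_mod)))))
  front <- 2 * x[1] - x[(ext + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - ext)]
  xp <- c(front, x, back)
  y <- sos_filter(sos, gain, xp)
  y <- rev(sos_filter(sos, gain, rev(y)))
  y[(ext + 1):(ext + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward (zero phase,
#' ~48 dB/octave effective rolloff beyond the edges), with odd-reflection
#' edge padding.
#'
#' @param segment a `mer_segment`.
#' @param low_hz,high_hz band edges, `0 < low < high < fs/2`.
#' @param order single-pass filter order (default 4).
#' @return the segment with filtered samples (same length).
#' @export
bandpass <- function(segment, low_hz, high_hz, order = 4L) {
  fs <- segment$sampling_rate_hz
  d <- butter_bandpass_sos(order, low_hz, high_hz, fs)
  segment$samples <- filtfilt_sos(d$sos, d$gain, segment$samples)
  segment
}
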