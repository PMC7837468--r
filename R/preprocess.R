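# Morlet continuous-wavelet-transform scalograms
#
# Raw segments are min-max normalized, transformed with a complex Morlet
# CWT on a dyadic scale grid (a fixed number of voices per octave), the
# magnitude restricted to the scales whose center frequencies fall in the
# requested band, and the image resized bilinearly to the classifier input
# size and min-max normalized again. An optional zero-phase Butterworth
# bandpass can be applied before the transform.

#' Morlet wavelet parameters
#'
#' @param omega0 center angular frequency of the mother wavelet
#'   (dimensionless; 6 is the standard choice, at which admissibility holds
#'   to good approximation).
#' @param voices_per_octave number of logarithmically spaced scales per
#'   frequency doubling ("resolution"); default 8.
#' @param scale_grid optional explicit vector of strictly increasing scales
#'   `a` in seconds; usually left `NULL` and built per band.
#' @return a `morlet_params` list.
#' @export
morlet_params <- function(omega0 = 6, voices_per_octave = 8,
                          scale_grid = NULL) {
  if (omega0 <= 0) stop_config("omega0 must be > 0")
  if (voices_per_octave < 1) stop_config("voices_per_octave must be >= 1")
  if (!is.null(scale_grid)) {
    if (length(scale_grid) == 0 || any(scale_grid <= 0) ||
        is.unsorted(scale_grid, strictly = TRUE))
      stop_config("scale_grid must be strictly increasing and positive")
  }
  structure(list(omega0 = omega0,
                 voices_per_octave = voices_per_octave,
                 scale_grid = scale_grid),
            class = "morlet_params")
}

#' The Morlet mother wavelet
#'
#' `psi(t) = pi^(-1/4) * exp(i*omega0*t) * exp(-t^2/2)`: a complex sinusoid
#' under a unit-variance Gaussian envelope.
#'
#' @param t time (vectorized, in units of the scale).
#' @param omega0 center angular frequency.
#' @return complex vector of wavelet values.
#' @export
morlet <- function(t, omega0 = 6) {
  if (any(!is.finite(t))) stop_config("t must be finite")
  pi^(-1 / 4) * exp(1i * omega0 * t) * exp(-t^2 / 2)
}

# center-frequency approximation linking scale and frequency: f = omega0/(2*pi*a)
scale_to_freq <- function(a, omega0 = 6) omega0 / (2 * pi * a)
freq_to_scale <- function(f, omega0 = 6) omega0 / (2 * pi * f)

#' Dyadic scale grid covering a frequency band
#'
#' Frequencies run from the band's upper edge downward in steps of
#' `2^(-1/voices_per_octave)` until the lower edge; scales are returned in
#' increasing order (decreasing frequency). Frequencies at or above Nyquist
#' are dropped.
#'
#' @param band one of `MER_BANDS`, or a numeric `c(low, high)` in Hz.
#' @param fs sampling rate in Hz.
#' @param params a [morlet_params()].
#' @return numeric vector of scales in seconds.
#' @export
scales_for_band <- function(band, fs, params = morlet_params()) {
  lim <- if (is.character(band)) band_limits(band) else as.numeric(band)
  if (length(lim) != 2 || lim[1] <= 0 || lim[2] <= lim[1])
    stop_config("band must give 0 < low < high")
  if (lim[1] >= fs / 2)
    stop_config("band lies entirely at or above the Nyquist frequency")
  v <- params$voices_per_octave
  n_oct <- log2(lim[2] / lim[1])
  freqs <- lim[2] * 2^(-(0:ceiling(n_oct * v)) / v)
  freqs <- freqs[freqs >= lim[1] * (1 - 1e-9) & freqs < fs / 2]
  if (length(freqs) == 0) stop_config("empty scale grid for this band")
  sort(freq_to_scale(freqs, params$omega0))
}

#' Complex Morlet CWT coefficients
#'
#' Discretization of `CWT(a,b) = a^(-1/2) * integral s(t) psi*((t-b)/a) dt`:
#' `W[j,k] = (dt/sqrt(a_j)) * sum_n s[n] psi*((n-k) dt / a_j)`, evaluated at
#' every `time_stride`-th sample translation by FFT convolution. The signal
#' is treated as zero outside its support (edge effects retained), and the
#' wavelet is truncated where its Gaussian envelope falls below `exp(-32)`.
#'
#' @param samples numeric signal.
#' @param fs sampling rate in Hz.
#' @param scales scale vector in seconds (e.g. from [scales_for_band()]).
#' @param omega0 Morlet center angular frequency.
#' @param time_stride keep every `time_stride`-th translation (>= 1).
#' @return complex matrix, one row per scale, one column per kept
#'   translation; attributes `frequencies` (Hz per row) and `times` (s).
#' @export
cwt_coefficients <- function(samples, fs, scales, omega0 = 6,
                             time_stride = 1L) {
  n <- length(samples)
  if (n < 2) stop_config("signal too short")
  if (length(scales) == 0) stop_config("empty scale grid")
  if (any(scale_to_freq(scales, omega0) >= fs / 2))
    stop_config("scale grid contains frequencies at or above Nyquist")
  dt <- 1 / fs
  keep <- seq(1L, n, by = as.integer(time_stride))
  out <- matrix(0i, nrow = length(scales), ncol = length(keep))
  fft_cache <- new.env(parent = emptyenv())
  for (j in seq_along(scales)) {
    a <- scales[j]
    L <- min(as.integer(ceiling(8 * a * fs)), n - 1L)
    m <- (-L):L
    g <- (dt / sqrt(a)) * Conj(morlet(-m * dt / a, omega0))
    P <- 2^ceiling(log2(n + 2 * L + 1))
    key <- as.character(P)
    if (is.null(fft_cache[[key]]))
      fft_cache[[key]] <- stats::fft(c(samples, rep(0, P - n)))
    gz <- complex(P)
    gz[1:(L + 1)] <- g[(L + 1):(2 * L + 1)]   # g[0..L]
    if (L > 0) gz[(P - L + 1):P] <- g[1:L]    # g[-L..-1] wrapped
    y <- stats::fft(fft_cache[[key]] * stats::fft(gz), inverse = TRUE) / P
    out[j, ] <- y[keep]
  }
  attr(out, "frequencies") <- scale_to_freq(scales, omega0)
  attr(out, "times") <- (keep - 1) * dt
  out
}

#' Min-max normalize a segment to [0, 1]
#'
#' @param segment a `mer_segment`.
#' @return the segment with samples affinely mapped so min = 0 and max = 1.
#' @export
normalize_signal <- function(segment) {
  x <- segment$samples
  if (any(!is.finite(x))) stop_config("segment contains non-finite samples")
  rng <- range(x)
  if (rng[1] == rng[2])
    stop_config("constant segment has no dynamic range to normalize")
  segment$samples <- (x - rng[1]) / (rng[2] - rng[1])
  segment
}

#' Scalogram of one segment in one frequency band
#'
#' Pipeline: signal min-max normalization, optional zero-phase bandpass,
#' Morlet CWT restricted to scales whose center frequencies lie in the
#' band, magnitude, bilinear resize to `image_size`, and per-image min-max
#' normalization. 60-Hz line noise is deliberately not notch-filtered.
#'
#' @param segment a `mer_segment`.
#' @param band one of `MER_BANDS`.
#' @param params a [morlet_params()].
#' @param image_size `c(height, width)` of the output image.
#' @param prefilter apply [bandpass()] at the band edges before the CWT
#'   (default `FALSE`: band selection is by CWT scale only).
#' @param signal_norm,image_norm toggles for the two normalizations.
#' @return a `scalogram`: list with `values` (height x width matrix in
#'   `[0, 1]`, rows ordered high to low frequency), `band`, `frequencies`
#'   (Hz per row), `source` (segment id).
#' @export
make_band_scalograms <- function(segment, band, params = morlet_params(),
                                 image_size = c(64, 64), prefilter = FALSE,
                                 signal_norm = TRUE, image_norm = TRUE) {
  band <- match.arg(band, MER_BANDS)
  fs <- segment$sampling_rate_hz
  if (signal_norm) segment <- normalize_signal(segment)
  if (prefilter) {
    lim <- band_limits(band)
    segment <- bandpass(segment, lim[1], min(lim[2], fs / 2 * 0.99))
  }
  scales <- scales_for_band(band, fs, params)
  n <- length(segment$samples)
  stride <- max(1L, floor(n / (4 * image_size[2])))
  w <- cwt_coefficients(segment$samples, fs, scales, params$omega0,
                        time_stride = stride)
  freqs <- attr(w, "frequencies")
  mag <- Mod(w)
  # rows high frequency first (image top), like a spectrogram
  ord <- order(freqs, decreasing = TRUE)
  mag <- mag[ord, , drop = FALSE]
  freqs <- freqs[ord]
  img <- resize_bilinear(mag, image_size[1], image_size[2])
  row_freq <- exp(resize_bilinear(matrix(log(freqs), ncol = 1),
                                  image_size[1], 1)[, 1])
  if (image_norm) {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
    else matrix(0, nrow(img), ncol(img))
  }
  structure(list(values = img, band = band, frequencies = row_freq,
                 source = segment$segment_id %||% NA_character_),
            class = "scalogram")
}

#' Full-resolution CWT scalogram
#'
#' Magnitude CWT over an explicit or band-derived scale grid, without
#' resizing; mostly a building block and diagnostic.
#'
#' @inheritParams make_band_scalograms
#' @param band optional band restriction; if `NULL`, `params$scale_grid`
#'   must be set.
#' @param time_stride column subsampling factor.
#' @return a `scalogram` with the raw magnitude matrix (rows ordered by
#'   increasing scale, i.e. decreasing frequency untouched from the grid).
#' @export
cwt <- function(segment, params = morlet_params(), band = NULL,
                time_stride = 1L) {
  fs <- segment$sampling_rate_hz
  scales <- if (!is.null(band)) scales_for_band(band, fs, params)
  else params$scale_grid
  if (is.null(scales)) stop_config("no scale grid: give `band` or set params$scale_grid")
  w <- cwt_coefficients(segment$samples, fs, scales, params$omega0,
                        time_stride = time_stride)
  structure(list(values = Mod(w), band = band,
                 frequencies = attr(w, "frequencies"),
                 times = attr(w, "times"),
                 source = segment$segment_id %||% NA_character_),
            class = "scalogram")
}

#' Bilinear image resize
#'
#' @param mat numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return resized matrix.
#' @export
resize_bilinear <- function(mat, out_h, out_w) {
  in_h <- nrow(mat); in_w <- ncol(mat)
  map <- function(out_n, in_n) {
    if (out_n == 1 || in_n == 1) return(list(i0 = rep(1L, out_n),
                                             i1 = rep(1L, out_n),
                                             w = rep(0, out_n)))
    src <- ((seq_len(out_n) - 0.5) * in_n / out_n) - 0.5
    src <- clip(src, 0, in_n - 1)
    i0 <- floor(src)
    list(i0 = as.integer(i0) + 1L,
         i1 = pmin(as.integer(i0) + 2L, in_n),
         w = src - i0)
  }
  r <- map(out_h, in_h); cc <- map(out_w, in_w)
  top <- mat[r$i0, , drop = FALSE]
  bot <- mat[r$i1, , drop = FALSE]
  vert <- top * (1 - r$w) + bot * r$w
  left <- vert[, cc$i0, drop = FALSE]
  right <- vert[, cc$i1, drop = FALSE]
  sweep(left, 2, 1 - cc$w, `*`) + sweep(right, 2, cc$w, `*`)
}
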