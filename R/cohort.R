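# synthetic MER cohort generator
#
# Emulates the structure of an STN-DBS microelectrode-recording cohort:
# per-patient multi-depth 4-s extracellular segments whose band-specific
# content is causally coupled to bilateral 6-month DBS on/off UPDRS-III
# ratios, with the contralateral (right-body) ratio more strongly driven by
# the left-hemisphere recording than the ipsilateral one.

#' Frequency bands used throughout the pipeline
#'
#' Three non-overlapping analysis bands: low (1-50 Hz, beta-range
#' oscillations and slow artifact), mid (50-500 Hz, multi-unit background),
#' and high (500-5000 Hz, spike energy).
#' @export
MER_BANDS <- c("1-50", "50-500", "500-5000")

#' Lower/upper edge of a named frequency band
#'
#' @param band one of `MER_BANDS`.
#' @return numeric length-2 vector `c(low_hz, high_hz)`.
#' @export
band_limits <- function(band) {
  band <- match.arg(band, MER_BANDS)
  switch(band,
         "1-50"     = c(1, 50),
         "50-500"   = c(50, 500),
         "500-5000" = c(500, 5000))
}

#' Configuration of a synthetic MER cohort
#'
#' @param n_patients number of patients (>= 4 so both response classes can
#'   appear in both splits).
#' @param segments_per_patient mean number of MER segments per patient.
#'   Segments are recorded at three consecutive depths spanning one lead
#'   contact, so they come in triplets sharing a clinical outcome; counts
#'   are drawn Poisson around the mean (minimum 3) unless `total_segments`
#'   pins the exact total.
#' @param total_segments optional exact total segment count, distributed as
#'   evenly as possible across patients (e.g. 696 over 34 patients gives a
#'   mean of 20.47).
#' @param duration_s segment duration in seconds (recordings are cut to 4 s).
#' @param sampling_rate_hz sampling rate in Hz (acquisition hardware runs at
#'   48 kHz; desk-scale runs may lower this).
#' @param effect_band which band's content carries the outcome-predictive
#'   signal, one of `MER_BANDS`.
#' @param effect_size separation, in units of the latent-feature SD, between
#'   the good- and moderate-response feature means.
#' @param contra_coupling weight in `[0, 1]` of the latent signal feature on
#'   the contralateral (right-body) on/off ratio.
#' @param ipsi_coupling weight in `[0, 1]` on the ipsilateral (left-body)
#'   ratio; must not exceed `contra_coupling` (left-hemisphere stimulation
#'   predominantly affects the right body side).
#' @param ratio_noise_sd SD of the independent per-side ratio noise.
#' @param bilateral_corr_target Pearson correlation targeted between the
#'   left- and right-body on/off ratios (clinically ~0.67); achieved by
#'   calibrating a shared patient-level noise term in closed form.
#' @param line_noise_60hz inject a small 60-Hz mains sinusoid (recordings
#'   were not notch-filtered).
#' @param n_test_good,n_test_moderate patients per response class held out
#'   as the test set (class taken from the contralateral label).
#' @param seed integer seed; the entire cohort is a deterministic function
#'   of the configuration.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 34,
                          segments_per_patient = 20.47,
                          total_segments = NULL,
                          duration_s = 4,
                          sampling_rate_hz = 48000,
                          effect_band = "50-500",
                          effect_size = 2,
                          contra_coupling = 1,
                          ipsi_coupling = 0.5,
                          ratio_noise_sd = 0.12,
                          bilateral_corr_target = 0.67,
                          line_noise_60hz = TRUE,
                          n_test_good = 2,
                          n_test_moderate = 2,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              segments_per_patient = segments_per_patient,
              total_segments = if (!is.null(total_segments))
                as.integer(total_segments) else NULL,
              duration_s = duration_s,
              sampling_rate_hz = sampling_rate_hz,
              effect_band = effect_band,
              effect_size = effect_size,
              contra_coupling = contra_coupling,
              ipsi_coupling = ipsi_coupling,
              ratio_noise_sd = ratio_noise_sd,
              bilateral_corr_target = bilateral_corr_target,
              line_noise_60hz = isTRUE(line_noise_60hz),
              n_test_good = as.integer(n_test_good),
              n_test_moderate = as.integer(n_test_moderate),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 4L)
    stop_config("n_patients must be >= 4 (both classes in both splits)")
  if (cfg$sampling_rate_hz <= 0 || cfg$duration_s <= 0)
    stop_config("sampling rate and duration must be positive")
  n_samp <- cfg$sampling_rate_hz * cfg$duration_s
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop_config("sampling_rate_hz * duration_s must be an integer sample count")
  if (!(cfg$effect_band %in% MER_BANDS))
    stop_config("effect_band must be one of: ", paste(MER_BANDS, collapse = ", "))
  if (cfg$ipsi_coupling < 0 || cfg$contra_coupling < cfg$ipsi_coupling)
    stop_config("need contra_coupling >= ipsi_coupling >= 0")
  if (cfg$effect_size < 0) stop_config("effect_size must be >= 0")
  if (cfg$ratio_noise_sd <= 0) stop_config("ratio_noise_sd must be > 0")
  if (abs(cfg$bilateral_corr_target) >= 1)
    stop_config("bilateral_corr_target must be in (-1, 1)")
  invisible(cfg)
}

n_segment_samples <- function(cfg) {
  as.integer(round(cfg$sampling_rate_hz * cfg$duration_s))
}

# latent-feature model constants: x = FEAT_MU + FEAT_SD*(effect_size*class + z)
FEAT_MU <- 1.0
FEAT_SD <- 0.3
RATIO_GAIN <- 0.5          # d(ratio)/dx at coupling 1
RATIO_CENTER_CONTRA <- 0.60  # centered on the right-side response threshold
RATIO_CENTER_IPSI <- 0.70    # centered on the left-side response threshold
PRE_LR_CORR <- 0.77        # pre-op left/right severity correlation emulated
OFF_LR_CORR <- 0.74        # 6-month off-stimulation left/right correlation

#' Simulate one microelectrode-recording segment
#'
#' The waveform is the sum of a 1/f-shaped broadband background, a
#' beta-band (13-30 Hz) oscillation, band-limited (50-500 Hz) multi-unit
#' background noise, a Poisson-bursting spike train convolved with a
#' biphasic ~1.2-ms spike template (spike energy in the 500-5000 Hz band),
#' and optionally a small 60-Hz mains sinusoid. The component lying in
#' `config$effect_band` has amplitude proportional to `band_feature_level`;
#' the other components stay at their base amplitude.
#'
#' @param band_feature_level non-negative scalar driving the effect-band
#'   component's amplitude.
#' @param config a [cohort_config()].
#' @param seed integer RNG state; the waveform is a deterministic function
#'   of `(band_feature_level, config, seed)`.
#' @param patient_id,depth_index provenance carried on the returned segment.
#' @return a `mer_segment`: list with `samples`, `sampling_rate_hz`,
#'   `patient_id`, `side` (always "left"; only left-hemisphere MER is
#'   analyzed), `depth_index`.
#' @export
simulate_mer_segment <- function(band_feature_level, config, seed,
                                 patient_id = "p1", depth_index = 0L) {
  validate_cohort_config(config)
  if (!is.finite(band_feature_level) || band_feature_level < 0)
    stop_config("band_feature_level must be finite and >= 0")
  n <- n_segment_samples(config)
  fs <- config$sampling_rate_hz
  dur <- config$duration_s
  lev <- band_feature_level

  amp <- c("1-50" = 0.8, "50-500" = 0.8, "500-5000" = 4.0)
  amp[config$effect_band] <- unname(amp[config$effect_band]) * lev

  x <- with_seed(seed, {
    tt <- seq(0, by = 1 / fs, length.out = n)
    # broadband 1/f background, built by spectral shaping of white noise
    w <- stats::rnorm(n)
    fr <- seq(0, fs / 2, length.out = floor(n / 2) + 1)
    shape <- 1 / sqrt(pmax(fr, 1))
    full <- c(shape, rev(shape[2:(n - length(shape) + 1)]))
    bg <- Re(stats::fft(stats::fft(w) * full, inverse = TRUE)) / n
    bg <- bg / stats::sd(bg)

    # beta oscillation (13-30 Hz), the low-band carrier
    f_beta <- stats::runif(1, 13, 30)
    beta <- sin(2 * pi * f_beta * tt + stats::runif(1, 0, 2 * pi))

    # multi-unit background: white noise brick-walled to 80-350 Hz. The
    # band is inset from the 50/500 Hz analysis-band edges because the
    # Morlet filters have relative bandwidth ~1/omega0: content at an edge
    # would bleed into the neighbouring band's scalogram and defeat
    # band-specific effect injection.
    w2 <- stats::rnorm(n)
    keep <- fr >= 80 & fr <= min(350, fs / 2)
    mask <- c(keep, rev(keep[2:(n - length(keep) + 1)]))
    mid <- Re(stats::fft(stats::fft(w2) * mask, inverse = TRUE)) / n
    if (stats::sd(mid) > 0) mid <- mid / stats::sd(mid)

    # Poisson-bursting spike train x biphasic template (~1.2 ms)
    n_bursts <- stats::rpois(1, 8 * dur)
    spike_t <- numeric(0)
    if (n_bursts > 0) {
      onsets <- stats::runif(n_bursts, 0, dur)
      for (o in onsets) {
        k <- 1 + stats::rpois(1, 3)
        isi <- 0.002 + stats::rexp(k - 1, rate = 1 / 0.004)
        spike_t <- c(spike_t, o + cumsum(c(0, isi)))
      }
    }
    train <- numeric(n)
    idx <- round(spike_t * fs) + 1
    idx <- idx[idx >= 1 & idx <= n]
    train[idx] <- 1
    tpl_t <- seq(0, 0.0012, by = 1 / fs)
    template <- sin(2 * pi * tpl_t / 0.0012) * exp(-tpl_t / 4e-4)
    spikes <- stats::convolve(train, rev(template), type = "open")
    spikes <- spikes[seq_len(n)]

    sig <- bg +
      unname(amp["1-50"]) * beta +
      unname(amp["50-500"]) * mid +
      unname(amp["500-5000"]) * spikes
    if (config$line_noise_60hz && fs > 120)
      sig <- sig + 0.1 * sin(2 * pi * 60 * tt + stats::runif(1, 0, 2 * pi))
    sig
  })

  structure(list(samples = x,
                 sampling_rate_hz = fs,
                 patient_id = patient_id,
                 side = "left",
                 depth_index = as.integer(depth_index)),
            class = "mer_segment")
}

# closed-form calibration of the shared patient-level noise variance that
# brings the (pre-clipping) left/right ratio correlation to the target.
calibrate_shared_var <- function(cfg) {
  var_x <- FEAT_SD^2 * (cfg$effect_size^2 / 4 + 1)
  sig_c <- RATIO_GAIN^2 * cfg$contra_coupling^2 * var_x
  sig_i <- RATIO_GAIN^2 * cfg$ipsi_coupling^2 * var_x
  cov0 <- RATIO_GAIN^2 * cfg$contra_coupling * cfg$ipsi_coupling * var_x
  ve <- cfg$ratio_noise_sd^2
  r_of <- function(s) (cov0 + s) / sqrt((sig_c + ve + s) * (sig_i + ve + s))
  target <- cfg$bilateral_corr_target
  if (r_of(0) >= target) {
    if (r_of(0) > target + 0.02)
      warning("latent coupling alone yields bilateral correlation ",
              round(r_of(0), 3), " > target ", target,
              "; shared noise set to 0", call. = FALSE)
    return(0)
  }
  # r_of is increasing in s towards 1, so a root exists for target < 1
  stats::uniroot(function(s) r_of(s) - target, c(0, 1e3), tol = 1e-12)$root
}

segments_per_patient_counts <- function(cfg) {
  n <- cfg$n_patients
  if (!is.null(cfg$total_segments)) {
    tot <- cfg$total_segments
    if (tot < 3L * n) stop_config("total_segments too small for one triplet each")
    base <- tot %/% n
    counts <- rep(base, n)
    extra <- tot - base * n
    if (extra > 0) counts[sample.int(n, extra)] <- base + 1L
    counts
  } else {
    pmax(3L, stats::rpois(n, cfg$segments_per_patient))
  }
}

#' Simulate a full MER cohort
#'
#' Draws per patient a binary latent response class and a continuous signal
#' feature level; bilateral DBS on/off ratios are affine in the feature
#' (weights `contra_coupling`/`ipsi_coupling`) plus a calibrated shared
#' patient-level noise (inducing the targeted left/right ratio correlation)
#' plus independent noise, clipped to `[0, 1.2]`. Pre-operative UPDRS-III
#' scores are drawn on the clinical scale (mean ~12, SD ~5 per side) and
#' independent of the ratios. Segments are generated in depth triplets; all
#' of a patient's segments share the patient's feature level. The test split
#' holds out `n_test_good` + `n_test_moderate` patients stratified by the
#' contralateral response label.
#'
#' @param config a [cohort_config()].
#' @return a `mer_cohort`: list with `segments` (list of `mer_segment`) and
#'   `records` (data.frame, one row per patient, with UPDRS-III scores,
#'   on/off ratios, split, and generator diagnostics `latent_class`,
#'   `latent_feature`).
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  pid <- sprintf("P%03d", seq_len(n))

  records <- with_seed(derive_seed(config$seed, "cohort"), {
    cls <- stats::rbinom(n, 1, 0.5)           # 0 good-leaning, 1 moderate
    if (length(unique(cls)) < 2) {            # force both classes present
      cls[1] <- 0L
      cls[2] <- 1L
    }
    x <- pmax(0.05, FEAT_MU + FEAT_SD * (config$effect_size * cls +
                                           stats::rnorm(n)))
    x_pop_mean <- FEAT_MU + FEAT_SD * config$effect_size / 2
    u <- stats::rnorm(n, 0, sqrt(calibrate_shared_var(config)))
    dev <- x - x_pop_mean
    ratio_right <- clip(RATIO_CENTER_CONTRA +
                          RATIO_GAIN * config$contra_coupling * dev + u +
                          stats::rnorm(n, 0, config$ratio_noise_sd), 0, 1.2)
    ratio_left <- clip(RATIO_CENTER_IPSI +
                         RATIO_GAIN * config$ipsi_coupling * dev + u +
                         stats::rnorm(n, 0, config$ratio_noise_sd), 0, 1.2)

    z_pre <- stats::rnorm(n)
    pre_right <- pmax(0, 12.4 + 5 * (sqrt(PRE_LR_CORR) * z_pre +
                                       sqrt(1 - PRE_LR_CORR) * stats::rnorm(n)))
    pre_left <- pmax(0, 12.8 + 5 * (sqrt(PRE_LR_CORR) * z_pre +
                                      sqrt(1 - PRE_LR_CORR) * stats::rnorm(n)))
    z_off <- stats::rnorm(n)
    off_right <- pmax(1, 11.2 + 4.3 * (sqrt(OFF_LR_CORR) * z_off +
                                         sqrt(1 - OFF_LR_CORR) * stats::rnorm(n)))
    off_left <- pmax(1, 11.5 + 4.4 * (sqrt(OFF_LR_CORR) * z_off +
                                        sqrt(1 - OFF_LR_CORR) * stats::rnorm(n)))

    data.frame(patient_id = pid,
               updrs3_pre_left = pre_left,
               updrs3_pre_right = pre_right,
               updrs3_off6m_left = off_left,
               updrs3_off6m_right = off_right,
               updrs3_on6m_left = ratio_left * off_left,
               updrs3_on6m_right = ratio_right * off_right,
               ratio_left = ratio_left,
               ratio_right = ratio_right,
               latent_class = ifelse(cls == 1, "moderate", "good"),
               latent_feature = x,
               stringsAsFactors = FALSE)
  })

  records$split <- assign_patient_split(
    records$patient_id,
    dichotomize(records$ratio_right, "right"),
    config$n_test_good, config$n_test_moderate,
    derive_seed(config$seed, "split"))

  counts <- with_seed(derive_seed(config$seed, "segcounts"),
                      segments_per_patient_counts(config))

  segments <- vector("list", sum(counts))
  k <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(counts[i])) {
      seg <- simulate_mer_segment(
        records$latent_feature[i], config,
        seed = derive_seed(config$seed, paste0("seg:", pid[i], ":", j)),
        patient_id = pid[i], depth_index = (j - 1L) %% 3L)
      seg$segment_id <- sprintf("%s_s%03d", pid[i], j)
      segments[[k]] <- seg
      k <- k + 1L
    }
  }

  structure(list(segments = segments, records = records,
                 config = config),
            class = "mer_cohort")
}

#' @export
print.mer_cohort <- function(x, ...) {
  cat("Synthetic MER cohort:", nrow(x$records), "patients,",
      length(x$segments), "segments (",
      round(length(x$segments) / nrow(x$records), 2), "per patient )\n")
  cat("  effect band:", x$config$effect_band,
      " effect size:", x$config$effect_size, "\n")
  cat("  split:", sum(x$records$split == "train"), "train /",
      sum(x$records$split == "test"), "test patients\n")
  invisible(x)
}
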