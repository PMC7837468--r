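# shared fixtures: all synthetic, generated at test time

# pure-tone segment
tone_segment <- function(freq_hz, fs = 2000, duration_s = 1, amp = 1,
                         id = "tone") {
  tt <- seq(0, duration_s, by = 1 / fs)[-1]
  structure(list(samples = amp * sin(2 * pi * freq_hz * tt),
                 sampling_rate_hz = fs, patient_id = "p1", side = "left",
                 depth_index = 0L, segment_id = id),
            class = "mer_segment")
}

raw_segment <- function(samples, fs = 1000, id = "seg") {
  structure(list(samples = samples, sampling_rate_hz = fs,
                 patient_id = "p1", side = "left", depth_index = 0L,
                 segment_id = id),
            class = "mer_segment")
}

# periodogram band power: independent brute-force oracle
band_power <- function(x, fs, low, high) {
  n <- length(x)
  spec <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  sum(spec[f >= low & f <= high & f <= fs / 2])
}

# cheap cohort config: waveforms only a few hundred samples long, used when
# a test only exercises records/labels/splits
cheap_cohort_config <- function(...) {
  args <- utils::modifyList(
    list(n_patients = 20, segments_per_patient = 3, duration_s = 0.05,
         sampling_rate_hz = 2000, seed = 1L),
    list(...))
  do.call(cohort_config, args)
}

# small trainable model configuration for fast tests (16x16 images)
tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(input_size = c(16L, 16L), blocks = list(4L), pools = 4L,
         epochs = 8L, learning_rate = 0.01, batch_size = 16L, seed = 1L),
    list(...))
  do.call(model_config, args)
}

# random image dataset with labels given by a linear rule on the images,
# separable by construction
separable_dataset <- function(n, hw = 16L, seed = 1L, patients = NULL) {
  set.seed(seed)
  x <- array(stats::runif(hw * hw * n), dim = c(hw, hw, n))
  cls <- rep(c(0L, 1L), length.out = n)
  # class 1 images get a bright top-left block
  for (i in which(cls == 1L)) x[1:4, 1:4, i] <- x[1:4, 1:4, i] + 2
  list(x = x,
       contra = factor(ifelse(cls == 0L, "good", "moderate"),
                       levels = c("good", "moderate")),
       ipsi = factor(ifelse(cls == 0L, "good", "moderate"),
                     levels = c("good", "moderate")),
       patient = patients %||% paste0("p", seq_len(n)),
       segment_id = sprintf("s%03d", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
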