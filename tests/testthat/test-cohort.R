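# synthetic cohort generator

test_that("segment simulation is deterministic and has the right length", {
  cfg <- cohort_config(n_patients = 4, duration_s = 0.5,
                       sampling_rate_hz = 12000, seed = 1)
  s1 <- simulate_mer_segment(1.0, cfg, seed = 99)
  s2 <- simulate_mer_segment(1.0, cfg, seed = 99)
  expect_identical(s1$samples, s2$samples)
  expect_true(all(is.finite(s1$samples)))
  expect_length(s1$samples, 6000)
  s3 <- simulate_mer_segment(1.0, cfg, seed = 100)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("a 48 kHz, 4 s segment has 192,000 samples", {
  cfg <- cohort_config(n_patients = 4, seed = 1)  # defaults: 48 kHz, 4 s
  s <- simulate_mer_segment(0.5, cfg, seed = 1)
  expect_length(s$samples, 192000L)
})

test_that("effect-band power is monotone in the feature level", {
  for (band in c("1-50", "50-500", "500-5000")) {
    cfg <- cohort_config(n_patients = 4, duration_s = 0.5,
                         sampling_rate_hz = 12000, effect_band = band,
                         seed = 1)
    lim <- band_limits(band)
    pw <- sapply(c(0, 1, 2), function(lev) {
      mean(sapply(1:20, function(k) {
        s <- simulate_mer_segment(lev, cfg, seed = 1000 * k)
        band_power(s$samples, 12000, lim[1], lim[2])
      }))
    })
    expect_true(all(diff(pw) > 0),
                info = paste("band", band, ":", paste(round(pw, 3),
                                                      collapse = " < ")))
  }
})

test_that("invalid configurations and feature levels are rejected", {
  expect_error(cohort_config(n_patients = 3), "n_patients")
  expect_error(cohort_config(effect_band = "10-100"), "effect_band")
  expect_error(cohort_config(contra_coupling = 0.2, ipsi_coupling = 0.5),
               "coupling")
  expect_error(cohort_config(duration_s = 0.3, sampling_rate_hz = 999),
               "integer sample count")
  cfg <- cheap_cohort_config()
  expect_error(simulate_mer_segment(-1, cfg, seed = 1), "band_feature_level")
})

test_that("an exact segment total is distributed to the stated mean", {
  cfg <- cheap_cohort_config(n_patients = 34, total_segments = 696)
  co <- simulate_cohort(cfg)
  expect_identical(length(co$segments), 696L)
  expect_equal(round(length(co$segments) / nrow(co$records), 2), 20.47)
})

test_that("cohorts are bit-reproducible from their configuration", {
  cfg <- cheap_cohort_config(seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(lapply(c1$segments, `[[`, "samples"),
                   lapply(c2$segments, `[[`, "samples"))
})

test_that("no patient appears in both splits and depth triplets share one outcome", {
  for (seed in 1:5) {
    co <- simulate_cohort(cheap_cohort_config(seed = seed,
                                              segments_per_patient = 7))
    by_split <- split(co$records$patient_id, co$records$split)
    expect_length(intersect(by_split$train, by_split$test), 0)
    m <- attach_labels(co$segments, co$records)
    per_pat <- tapply(as.character(m$label_contra), m$patient_id,
                      function(x) length(unique(x)))
    expect_true(all(per_pat == 1))
    # depth indices cycle 0,1,2 within each patient
    d <- m$depth_index[m$patient_id == m$patient_id[1]]
    expect_identical(d, (seq_along(d) - 1L) %% 3L)
  }
})

test_that("zero coupling decouples the feature from the ratios", {
  cfg <- cheap_cohort_config(n_patients = 200, contra_coupling = 0,
                             ipsi_coupling = 0, seed = 3)
  co <- simulate_cohort(cfg)
  r <- co$records
  expect_lt(abs(cor(r$latent_feature, r$ratio_right)), 0.2)
  expect_lt(abs(cor(r$latent_feature, r$ratio_left)), 0.2)
})

test_that("pre-operative scores are on the clinical scale and ratio-independent", {
  co <- simulate_cohort(cheap_cohort_config(n_patients = 300, seed = 11))
  r <- co$records
  expect_gt(mean(r$updrs3_pre_right), 9)
  expect_lt(mean(r$updrs3_pre_right), 16)
  expect_gt(sd(r$updrs3_pre_right), 3)
  expect_true(all(r$updrs3_pre_left >= 0))
  expect_lt(abs(cor(r$updrs3_pre_right, r$ratio_right)), 0.2)
  expect_true(all(r$ratio_left >= 0 & r$ratio_left <= 1.2))
  expect_true(all(r$ratio_right >= 0 & r$ratio_right <= 1.2))
})
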