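# outcome labels and patient-level splits

test_that("the on/off ratio is a plain quotient with validation", {
  expect_equal(onoff_ratio(6.81, 11.22), 6.81 / 11.22)  # = 0.607 (3 dp)
  expect_equal(round(onoff_ratio(6.81, 11.22), 3), 0.607)
  expect_equal(onoff_ratio(0, 7), 0)
  expect_equal(onoff_ratio(9.3, 9.3), 1)
  expect_error(onoff_ratio(5, 0), "undefined")
  expect_error(onoff_ratio(-1, 5), "non-negative")
})

test_that("response thresholds are side-specific and half-open", {
  expect_identical(as.character(dichotomize(0.69, "left")), "good")
  expect_identical(as.character(dichotomize(0.70, "left")), "moderate")
  expect_identical(as.character(dichotomize(0.59, "right")), "good")
  expect_identical(as.character(dichotomize(0.60, "right")), "moderate")
  expect_identical(as.character(dichotomize(1.15, "left")), "moderate")
  expect_error(dichotomize(-0.1, "left"), "ratio")
})

test_that("dichotomize is monotone in the ratio", {
  ratios <- sort(runif(50, 0, 1.2))
  for (side in c("left", "right")) {
    resp <- as.character(dichotomize(ratios, side))
    good_idx <- which(resp == "good")
    if (length(good_idx) > 0)
      expect_identical(good_idx, seq_len(max(good_idx)))
  }
})

test_that("labels attach per patient, triplets share them, and exclusions log", {
  co <- simulate_cohort(cheap_cohort_config(n_patients = 8,
                                            segments_per_patient = 6,
                                            seed = 2))
  m <- attach_labels(co$segments, co$records)
  expect_identical(nrow(m), length(co$segments))
  expect_identical(nrow(attr(m, "exclusions")), 0L)
  # all segments of one patient (hence each triplet) carry identical labels
  one <- m[m$patient_id == m$patient_id[1], ]
  expect_length(unique(as.character(one$label_contra)), 1L)
  expect_length(unique(as.character(one$label_ipsi)), 1L)
  expect_length(unique(one$ratio_contra), 1L)

  # a missing 6-month score excludes the patient with a logged reason
  rec <- co$records
  rec$updrs3_off6m_right[1] <- NA
  m2 <- attach_labels(co$segments, rec)
  excl <- attr(m2, "exclusions")
  expect_identical(excl$patient_id, rec$patient_id[1])
  n_seg_excluded <- sum(vapply(co$segments, function(s)
    s$patient_id == rec$patient_id[1], logical(1)))
  expect_identical(nrow(m2), length(co$segments) - n_seg_excluded)
})

test_that("the post/pre ratio variant divides by the pre-operative score", {
  co <- simulate_cohort(cheap_cohort_config(seed = 3))
  m <- attach_labels(co$segments, co$records, ratio_type = "post_pre")
  r <- co$records
  i <- match(m$patient_id[1], r$patient_id)
  expect_equal(m$ratio_contra[1],
               r$updrs3_on6m_right[i] / r$updrs3_pre_right[i])
  expect_equal(m$ratio_ipsi[1],
               r$updrs3_on6m_left[i] / r$updrs3_pre_left[i])
})

test_that("patient-level splits are leakage-free, stratified and reproducible", {
  co <- simulate_cohort(cheap_cohort_config(n_patients = 16, seed = 4))
  m <- attach_labels(co$segments, co$records)
  s1 <- patient_level_split(m, 2, 2, seed = 9)
  s2 <- patient_level_split(m, 2, 2, seed = 9)
  expect_identical(s1$split, s2$split)
  per_pat <- unique(s1[, c("patient_id", "label_contra", "split")])
  expect_length(intersect(per_pat$patient_id[per_pat$split == "train"],
                          per_pat$patient_id[per_pat$split == "test"]), 0)
  test_pat <- per_pat[per_pat$split == "test", ]
  expect_identical(nrow(test_pat), 4L)
  expect_identical(sum(test_pat$label_contra == "good"), 2L)
  expect_identical(sum(test_pat$label_contra == "moderate"), 2L)
  expect_error(patient_level_split(m, 50, 2, seed = 1), "not enough")
})

test_that("a labeled manifest round-trips through CSV", {
  co <- simulate_cohort(cheap_cohort_config(n_patients = 8, seed = 6))
  m <- attach_labels(co$segments, co$records)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(m, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(back$segment_id, m$segment_id)
  expect_identical(back$label_contra, as.character(m$label_contra))
  expect_identical(back$label_ipsi, as.character(m$label_ipsi))
  expect_identical(back$split, m$split)
  expect_equal(back$ratio_contra, m$ratio_contra)
})
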