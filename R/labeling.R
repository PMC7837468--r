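# outcome labeling and leakage-free patient-level splitting
#
# The clinical endpoint is the 6-month DBS on/off ratio of the lateralized
# UPDRS part III subtotal, off medication. The ratio is dichotomized with
# side-specific thresholds: good response below 0.70 on the left body side
# and below 0.60 on the right body side. Because only left-hemisphere MER is
# analyzed, the right body side is contralateral and the left ipsilateral.

RESPONSE_LEVELS <- c("good", "moderate")

#' DBS on/off ratio of UPDRS part III scores
#'
#' @param on_score score with stimulation on (>= 0).
#' @param off_score score with stimulation off (> 0).
#' @return `on_score / off_score`. Lower means greater stimulation benefit;
#'   values above 1 (worsening under stimulation) are permitted.
#' @export
onoff_ratio <- function(on_score, off_score) {
  if (any(!is.finite(on_score)) || any(!is.finite(off_score)))
    stop_config("scores must be finite")
  if (any(on_score < 0) || any(off_score < 0))
    stop_config("UPDRS scores must be non-negative")
  if (any(off_score == 0))
    stop_config("off-stimulation score of 0 leaves the on/off ratio undefined")
  on_score / off_score
}

#' Dichotomize an on/off ratio into a response class
#'
#' Good response is the half-open interval `[0, 0.70)` for the left body
#' side and `[0, 0.60)` for the right body side (so 0.69 left and 0.59 right
#' are good, 0.70/0.60 moderate, matching the printed two-decimal ranges
#' with no gap). Ratios above 1 are classed moderate.
#'
#' @param ratio non-negative on/off ratio (vectorized).
#' @param side `"left"` or `"right"` body side.
#' @return factor with levels `good`, `moderate`.
#' @export
dichotomize <- function(ratio, side = c("left", "right")) {
  side <- match.arg(side)
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop_config("ratio must be finite and >= 0")
  thr <- if (side == "left") 0.70 else 0.60
  factor(ifelse(ratio < thr, "good", "moderate"), levels = RESPONSE_LEVELS)
}

# stratified patient-level test-set assignment; returns "train"/"test" per
# patient. Stratification class is the contralateral response label.
assign_patient_split <- function(patient_ids, contra_labels,
                                 n_test_good, n_test_moderate, seed) {
  stopifnot(length(patient_ids) == length(contra_labels))
  good_ids <- patient_ids[contra_labels == "good"]
  mod_ids <- patient_ids[contra_labels == "moderate"]
  if (length(good_ids) < n_test_good + 1L ||
      length(mod_ids) < n_test_moderate + 1L)
    stop_config("not enough patients per response class to fill both splits ",
                "(have ", length(good_ids), " good, ", length(mod_ids),
                " moderate)")
  test_ids <- with_seed(seed, c(
    sample(good_ids, n_test_good),
    sample(mod_ids, n_test_moderate)))
  ifelse(patient_ids %in% test_ids, "test", "train")
}

#' Attach bilateral outcome labels to MER segments
#'
#' Every left-hemisphere segment inherits its patient's contralateral
#' (right-body) and ipsilateral (left-body) ratio and response label; the
#' three segments of one depth-contact triplet therefore share one outcome.
#' Patients with a missing 6-month score are excluded with a logged reason.
#'
#' @param segments list of `mer_segment` (e.g. `cohort$segments`).
#' @param records patient data.frame with `patient_id`,
#'   `updrs3_on6m_left/right`, `updrs3_off6m_left/right` (and for the
#'   `"post_pre"` variant `updrs3_pre_left/right`), optionally `split`.
#' @param ratio_type `"on_off"` (the primary endpoint: 6-month DBS-on over
#'   DBS-off) or `"post_pre"` (6-month on-stimulation over pre-operative —
#'   an alternative some summaries describe; same thresholds applied).
#' @return a `labeled_manifest` data.frame (one row per segment) with
#'   columns `segment_id`, `patient_id`, `depth_index`, `ratio_ipsi`,
#'   `ratio_contra`, `label_ipsi`, `label_contra`, `split`; excluded
#'   patients are recorded in `attr(, "exclusions")`.
#' @export
attach_labels <- function(segments, records,
                          ratio_type = c("on_off", "post_pre")) {
  ratio_type <- match.arg(ratio_type)
  seg_pid <- vapply(segments, function(s) s$patient_id, character(1))
  seg_id <- vapply(segments, function(s) s$segment_id %||% NA_character_,
                   character(1))
  depth <- vapply(segments, function(s) s$depth_index, integer(1))
  if (!all(seg_pid %in% records$patient_id))
    stop_config("segments reference patients absent from the records")

  denom_cols <- if (ratio_type == "on_off")
    c("updrs3_off6m_left", "updrs3_off6m_right")
  else c("updrs3_pre_left", "updrs3_pre_right")
  score_cols <- c("updrs3_on6m_left", "updrs3_on6m_right", denom_cols)
  missing_score <- !stats::complete.cases(records[, score_cols]) |
    records[[denom_cols[1]]] == 0 | records[[denom_cols[2]]] == 0
  exclusions <- data.frame(
    patient_id = records$patient_id[missing_score],
    reason = rep("missing or zero UPDRS III score", sum(missing_score)),
    stringsAsFactors = FALSE)
  ok <- records[!missing_score, , drop = FALSE]

  ratio_l <- onoff_ratio(ok$updrs3_on6m_left, ok[[denom_cols[1]]])
  ratio_r <- onoff_ratio(ok$updrs3_on6m_right, ok[[denom_cols[2]]])
  idx <- match(seg_pid, ok$patient_id)
  keep <- !is.na(idx)

  manifest <- data.frame(
    segment_id = seg_id[keep],
    patient_id = seg_pid[keep],
    depth_index = depth[keep],
    ratio_ipsi = ratio_l[idx[keep]],
    ratio_contra = ratio_r[idx[keep]],
    stringsAsFactors = FALSE)
  manifest$label_ipsi <- dichotomize(manifest$ratio_ipsi, "left")
  manifest$label_contra <- dichotomize(manifest$ratio_contra, "right")
  manifest$split <- if ("split" %in% names(ok))
    ok$split[idx[keep]] else NA_character_
  attr(manifest, "exclusions") <- exclusions
  class(manifest) <- c("labeled_manifest", "data.frame")
  manifest
}

#' Patient-level train/test split of labeled examples
#'
#' All of a patient's segments are assigned to one split, so no patient can
#' leak between training and testing. The test set contains exactly
#' `n_test_good` + `n_test_moderate` patients, stratified by the
#' contralateral response label (the head the test objective scores).
#'
#' @param examples a `labeled_manifest` from [attach_labels()].
#' @param n_test_good,n_test_moderate test-set patient counts per class.
#' @param seed integer seed for the random selection.
#' @return the manifest with its `split` column reassigned.
#' @export
patient_level_split <- function(examples, n_test_good = 2L,
                                n_test_moderate = 2L, seed = 1L) {
  per_pat <- unique(examples[, c("patient_id", "label_contra")])
  if (anyDuplicated(per_pat$patient_id))
    stop_config("inconsistent contralateral labels within a patient")
  split <- assign_patient_split(per_pat$patient_id, per_pat$label_contra,
                                n_test_good, n_test_moderate, seed)
  examples$split <- split[match(examples$patient_id, per_pat$patient_id)]
  examples
}
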