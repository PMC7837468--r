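# evaluation procedures: max-accuracy epoch selection, loss-ratio sweep,
# ROC/AUC, training stability, and the bilateral correlation statistics

#' Select the maximal test accuracy of a training run
#'
#' Among epochs after `min_epoch` whose training loss is below
#' `loss_epsilon` ("training cross-entropy nearly zero"), returns the
#' highest contralateral test accuracy and its epoch; ties resolve to the
#' earliest epoch. If no epoch qualifies, the loss condition is dropped with
#' a warning and the search runs over all epochs after `min_epoch`.
#'
#' @param history a training-history data.frame (from [fit_classifier()]).
#' @param loss_epsilon training-loss threshold (default 0.05).
#' @param min_epoch epochs at or before this are ignored (default 50).
#' @return list with `accuracy` and `epoch`.
#' @export
select_max_accuracy <- function(history, loss_epsilon = 0.05,
                                min_epoch = 50L) {
  if (nrow(history) == 0) stop_config("empty training history")
  if (max(history$epoch) <= min_epoch)
    stop_config("history (", max(history$epoch),
                " epochs) does not extend past min_epoch = ", min_epoch)
  late <- history[history$epoch > min_epoch, , drop = FALSE]
  qual <- late[late$train_loss < loss_epsilon, , drop = FALSE]
  if (nrow(qual) == 0) {
    warning("no epoch after ", min_epoch, " reaches train loss < ",
            loss_epsilon, "; relaxing to all epochs after ", min_epoch,
            call. = FALSE)
    qual <- late
  }
  best <- which.max(qual$acc_test_contra)  # which.max: first maximum
  list(accuracy = qual$acc_test_contra[best], epoch = qual$epoch[best])
}

#' Sweep the contralateral:ipsilateral loss-weight ratio
#'
#' Trains one model per weight pair under an identical seed policy (same
#' initialization, shuffles and dropout stream), so the sweep isolates the
#' effect of the loss weighting, and applies [select_max_accuracy()] to
#' each run.
#'
#' @param train,test datasets as in [fit_classifier()].
#' @param ratios list of `c(w_contra, w_ipsi)` pairs, e.g.
#'   `list(c(1, 1), c(5, 1))`; duplicates are rejected.
#' @param config a [model_config()]; its `loss_weights` are overridden.
#' @param loss_epsilon,min_epoch passed to [select_max_accuracy()].
#' @return a `sweep_result` data.frame with columns `w_contra`, `w_ipsi`,
#'   `max_accuracy`, `selected_epoch`.
#' @export
loss_ratio_sweep <- function(train, test, ratios, config,
                             loss_epsilon = 0.05, min_epoch = 50L) {
  if (length(ratios) == 0) stop_config("ratios must be non-empty")
  key <- vapply(ratios, paste, character(1), collapse = ":")
  if (anyDuplicated(key)) stop_config("duplicate loss ratios: ",
                                      paste(key[duplicated(key)],
                                            collapse = ", "))
  rows <- lapply(ratios, function(r) {
    cfg <- config
    cfg$loss_weights <- as.numeric(r)
    validate_model_config(cfg)
    fit <- fit_classifier(build_model(cfg), train, test)
    sel <- select_max_accuracy(fit$history, loss_epsilon, min_epoch)
    data.frame(w_contra = r[1], w_ipsi = r[2],
               max_accuracy = sel$accuracy, selected_epoch = sel$epoch)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (predicted probability of a good
#' response); AUC by the trapezoid rule, which equals the pairwise
#' concordance probability with ties counted 1/2.
#'
#' @param scores numeric scores, higher = more good-like.
#' @param labels `good`/`moderate` labels (factor or character); both
#'   classes must be present.
#' @return a `roc_curve`: list with `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) stop_config("length mismatch")
  pos <- labels == "good"
  if (!any(pos) || all(pos))
    stop_config("both classes must be present to compute a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Late-training stability of a run
#'
#' Population standard deviation of the contralateral test accuracy over
#' the final `window` epochs; smaller is more stable.
#'
#' @param history a training-history data.frame.
#' @param window number of final epochs (>= 2).
#' @return scalar SD.
#' @export
stability <- function(history, window) {
  if (window < 2) stop_config("window must be >= 2")
  if (window > nrow(history))
    stop_config("window exceeds the history length")
  x <- utils::tail(history$acc_test_contra, window)
  sqrt(mean((x - mean(x))^2))
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the usual
#' t-transform `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3)
    stop_config("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_config("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Bilateral correlation report for a cohort
#'
#' Computes the correlations the clinical analysis reports: left/right
#' pre-operative UPDRS-III scores, left/right 6-month scores in the
#' stimulation-on and -off states, the on/off ratio against the
#' pre-operative score on each side (expected null), and the left/right
#' on/off ratios.
#'
#' @param records a patient data.frame (e.g. `cohort$records`).
#' @return data.frame with columns `quantity`, `r`, `p`, `n`.
#' @export
correlation_report <- function(records) {
  ratio_l <- onoff_ratio(records$updrs3_on6m_left, records$updrs3_off6m_left)
  ratio_r <- onoff_ratio(records$updrs3_on6m_right,
                         records$updrs3_off6m_right)
  pairs <- list(
    pre_left_right = list(records$updrs3_pre_left, records$updrs3_pre_right),
    on6m_left_right = list(records$updrs3_on6m_left,
                           records$updrs3_on6m_right),
    off6m_left_right = list(records$updrs3_off6m_left,
                            records$updrs3_off6m_right),
    ratio_vs_pre_left = list(ratio_l, records$updrs3_pre_left),
    ratio_vs_pre_right = list(ratio_r, records$updrs3_pre_right),
    ratio_left_right = list(ratio_l, ratio_r))
  rows <- lapply(names(pairs), function(nm) {
    pr <- pearson_r(pairs[[nm]][[1]], pairs[[nm]][[2]])
    data.frame(quantity = nm, r = pr$r, p = pr$p, n = pr$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
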