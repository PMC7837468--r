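# evaluation: epoch selection, ROC/AUC, stability, correlations, sweep

toy_history <- function(acc, loss = rep(0.01, length(acc))) {
  data.frame(epoch = seq_along(acc), train_loss = loss,
             acc_train_contra = acc, acc_train_ipsi = acc,
             acc_test_contra = acc, acc_test_ipsi = acc)
}

test_that("max-accuracy selection honors min_epoch, loss gate and ties", {
  h <- toy_history(c(rep(0.5, 50), 0.70, 0.80, 0.75))
  sel <- select_max_accuracy(h, 0.05, 50)
  expect_equal(sel$accuracy, 0.80)
  expect_identical(sel$epoch, 52L)

  # the best accuracy before min_epoch is ignored
  h2 <- toy_history(c(rep(0.5, 49), 0.95, 0.61, 0.62, 0.60))
  sel2 <- select_max_accuracy(h2, 0.05, 50)
  expect_equal(sel2$accuracy, 0.62)

  # constant accuracy: earliest qualifying epoch wins
  h3 <- toy_history(rep(0.6, 55))
  sel3 <- select_max_accuracy(h3, 0.05, 50)
  expect_identical(sel3$epoch, 51L)

  # no epoch under the loss threshold: relaxed with a warning
  h4 <- toy_history(c(rep(0.5, 50), 0.7, 0.9), loss = rep(1, 52))
  expect_warning(sel4 <- select_max_accuracy(h4, 0.05, 50), "relaxing")
  expect_equal(sel4$accuracy, 0.9)

  expect_error(select_max_accuracy(toy_history(rep(0.5, 10)), 0.05, 50),
               "min_epoch")
})

test_that("ROC/AUC matches hand cases and the concordance oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c("good", "good", "moderate",
                                        "moderate"))
  expect_equal(r$auc, 1.0)
  # 2 concordant of 4 positive-negative pairs
  expect_equal(roc_auc(c(0.9, 0.3, 0.6, 0.7),
                       c("good", "good", "moderate", "moderate"))$auc, 0.5)
  expect_equal(roc_auc(rep(0.4, 6),
                       rep(c("good", "moderate"), 3))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c("good", "good")), "both classes")
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))

  # brute-force pairwise concordance with ties counted 1/2
  concordance <- function(scores, labels) {
    pos <- scores[labels == "good"]
    neg <- scores[labels == "moderate"]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(42)
  for (k in 1:10) {
    n <- sample(5:60, 1)
    scores <- round(runif(n), 2)  # rounded to force ties
    labels <- sample(c("good", "moderate"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, concordance(scores, labels))
  }
})

test_that("stability is the population SD of late test accuracy", {
  expect_equal(stability(toy_history(rep(0.7, 20)), 10), 0)
  expect_equal(stability(toy_history(rep(c(0.5, 1.0), 10)), 10), 0.25)
  h <- toy_history(runif(20))
  h2 <- h; h2$acc_test_contra <- h$acc_test_contra + 0.1
  expect_equal(stability(h, 8), stability(h2, 8))
  expect_error(stability(h, 1), "window")
  expect_error(stability(h, 21), "window")
})

test_that("pearson_r matches hand computations and is symmetric", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), -c(1, 2, 3))$r, -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(pearson_r(x, y)$r, pearson_r(y, x)$r)
  expect_equal(pearson_r(x, y)$p, cor.test(x, y)$p.value)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("the correlation report covers the clinical quantities", {
  co <- simulate_cohort(cheap_cohort_config(n_patients = 60, seed = 8))
  rep <- correlation_report(co$records)
  expect_setequal(rep$quantity,
                  c("pre_left_right", "on6m_left_right", "off6m_left_right",
                    "ratio_vs_pre_left", "ratio_vs_pre_right",
                    "ratio_left_right"))
  expect_true(all(is.finite(rep$r)) && all(abs(rep$r) <= 1))
  expect_gt(rep$r[rep$quantity == "pre_left_right"], 0.4)
})

test_that("the loss-ratio sweep rejects duplicates and ignores example order", {
  train <- separable_dataset(24, seed = 3)
  test <- separable_dataset(12, seed = 4, patients = paste0("q", 1:12))
  cfg <- tiny_model_config(epochs = 6L)
  expect_error(loss_ratio_sweep(train, test, list(c(1, 1), c(1, 1)), cfg),
               "duplicate")
  sw <- suppressWarnings(
    loss_ratio_sweep(train, test, list(c(1, 1), c(5, 1)), cfg,
                     min_epoch = 2L))
  expect_identical(nrow(sw), 2L)
  expect_true(all(sw$max_accuracy >= 0 & sw$max_accuracy <= 1))
  # shuffling the manifest does not change the result at fixed seed policy
  perm <- sample(24)
  train2 <- list(x = train$x[, , perm], contra = train$contra[perm],
                 ipsi = train$ipsi[perm], patient = train$patient[perm],
                 segment_id = train$segment_id[perm])
  sw2 <- suppressWarnings(
    loss_ratio_sweep(train2, test, list(c(1, 1), c(5, 1)), cfg,
                     min_epoch = 2L))
  expect_equal(sw$max_accuracy, sw2$max_accuracy)
})
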