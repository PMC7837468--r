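# shared-trunk multitask classifier

test_that("forward pass shapes follow the mode contract", {
  cfg <- tiny_model_config()
  model <- build_model(cfg)
  x <- array(runif(16 * 16 * 8), dim = c(16, 16, 8))
  p <- predict_classifier(model, x)
  expect_named(p, c("contra", "ipsi"))
  expect_identical(dim(p$contra), c(8L, 2L))
  expect_identical(dim(p$ipsi), c(8L, 2L))
  expect_equal(rowSums(p$contra), rep(1, 8))

  single <- build_model(tiny_model_config(mode = "single_task"))
  ps <- predict_classifier(single, x)
  expect_named(ps, "contra")
  expect_identical(dim(ps$contra), c(8L, 2L))
})

test_that("the parameter count matches closed-form arithmetic", {
  cfg <- tiny_model_config()  # 1 conv block, 4 channels, 16x16, pool 4
  model <- build_model(cfg)
  conv <- 4 * 9 * 1 + 4                     # 3x3x1 -> 4 kernels + biases
  flat <- (16 / 4) * (16 / 4) * 4           # 64 features
  head <- (flat * 120 + 120) + (120 * 120 + 120) +
    (120 * 16 + 16) + (16 * 2 + 2)
  expect_identical(count_parameters(model), as.integer(conv + 2 * head))
  single <- build_model(tiny_model_config(mode = "single_task"))
  expect_identical(count_parameters(single), as.integer(conv + head))
})

test_that("invalid model configurations are rejected", {
  expect_error(tiny_model_config(head_widths = c(120, 16, 3)), "end in 2")
  expect_error(tiny_model_config(loss_weights = c(0, 0)), "not both zero")
  expect_error(tiny_model_config(loss_weights = c(-1, 2)), "non-negative")
  expect_error(tiny_model_config(input_size = c(15, 15)), "downsampling")
})

test_that("multitask loss degenerates, scales, and hits hand-computed values", {
  set.seed(3)
  lc <- matrix(rnorm(8), 4, 2)
  li <- matrix(rnorm(8), 4, 2)
  yc <- factor(c("good", "moderate", "good", "moderate"),
               levels = c("good", "moderate"))
  yi <- factor(c("moderate", "moderate", "good", "good"),
               levels = c("good", "moderate"))

  # (1, 0) equals the single-task contralateral cross-entropy exactly
  single <- multitask_loss(lc, NULL, yc, NULL, 1, 0)
  p <- exp(lc) / rowSums(exp(lc))
  ce <- -mean(log(p[cbind(1:4, as.integer(yc))]))
  expect_equal(single, ce)

  # both heads put probability e^-1 on the true class, weights (5, 1) -> 6
  d <- qlogis(exp(-1))  # logit difference giving p(true) = e^-1
  ltrue <- cbind(d, 0)[rep(1, 4), ]   # class 1 ("good") is true
  y1 <- factor(rep("good", 4), levels = c("good", "moderate"))
  expect_equal(multitask_loss(ltrue, ltrue, y1, y1, 5, 1), 6)

  # near-perfect predictions drive the loss to zero
  sure <- cbind(rep(50, 4), rep(-50, 4))
  expect_lt(multitask_loss(sure, sure, y1, y1, 5, 1), 1e-12)

  # scaling both weights by c scales the loss by exactly c
  l1 <- multitask_loss(lc, li, yc, yi, 2, 3)
  l2 <- multitask_loss(lc, li, yc, yi, 2 * 7, 3 * 7)
  expect_equal(l2, 7 * l1)

  expect_error(multitask_loss(lc, li, yc, yi, -1, 1), "non-negative")
  expect_error(multitask_loss(lc, li, yc, yi, 0, 0), "zero")
})

test_that("analytic loss gradients match central finite differences", {
  set.seed(11)
  lc <- matrix(rnorm(8), 4, 2)
  li <- matrix(rnorm(8), 4, 2)
  yc <- factor(c("good", "moderate", "good", "moderate"),
               levels = c("good", "moderate"))
  yi <- factor(c("moderate", "good", "good", "moderate"),
               levels = c("good", "moderate"))
  g <- multitask_loss(lc, li, yc, yi, 5, 1, gradient = TRUE)
  eps <- 1e-6
  for (mat_name in c("contra", "ipsi")) {
    L <- if (mat_name == "contra") lc else li
    G <- g[[paste0("grad_", mat_name)]]
    for (i in seq_len(4)) for (j in 1:2) {
      Lp <- L; Lm <- L
      Lp[i, j] <- L[i, j] + eps
      Lm[i, j] <- L[i, j] - eps
      fp <- if (mat_name == "contra")
        multitask_loss(Lp, li, yc, yi, 5, 1) else
          multitask_loss(lc, Lp, yc, yi, 5, 1)
      fm <- if (mat_name == "contra")
        multitask_loss(Lm, li, yc, yi, 5, 1) else
          multitask_loss(lc, Lm, yc, yi, 5, 1)
      num <- (fp - fm) / (2 * eps)
      expect_lt(abs(num - G[i, j]) / max(abs(num), 1e-8), 1e-4)
    }
  }
})

test_that("training descends on separable data and is seed-reproducible", {
  train <- separable_dataset(32, seed = 1)
  test <- separable_dataset(16, seed = 2,
                            patients = paste0("q", 1:16))
  cfg <- tiny_model_config(epochs = 30L, learning_rate = 0.02)
  fit1 <- fit_classifier(build_model(cfg), train, test)
  expect_identical(nrow(fit1$history), 30L)
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  expect_true(all(fit1$history$acc_test_contra >= 0 &
                    fit1$history$acc_test_contra <= 1))
  fit2 <- fit_classifier(build_model(cfg), train, test)
  expect_identical(fit1$history, fit2$history)
  expect_equal(fit1$model$weights, fit2$model$weights)
})

test_that("w_ipsi = 0 multitask training equals single-task step for step", {
  train <- separable_dataset(24, seed = 5)
  test <- separable_dataset(12, seed = 6, patients = paste0("q", 1:12))
  mt <- fit_classifier(build_model(tiny_model_config(
    epochs = 10L, loss_weights = c(1, 0), mode = "multitask")), train, test)
  st <- fit_classifier(build_model(tiny_model_config(
    epochs = 10L, loss_weights = c(1, 0), mode = "single_task")), train, test)
  expect_equal(mt$history$train_loss, st$history$train_loss)
  expect_equal(mt$history$acc_test_contra, st$history$acc_test_contra)
  expect_equal(mt$model$weights$trunk_W, st$model$weights$trunk_W)
  expect_equal(mt$model$weights$heads[[1]], st$model$weights$heads[[1]])
})

test_that("patient leakage between splits aborts training", {
  train <- separable_dataset(16, seed = 7)
  test <- separable_dataset(8, seed = 8)  # same default patient ids p1..p8
  expect_error(fit_classifier(build_model(tiny_model_config()), train, test),
               "leakage")
})
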