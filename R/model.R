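# VGG-style shared-trunk multitask classifier
#
# The trunk is an ordered set of 3x3/stride-1 convolution blocks with
# max-pooling between blocks; each task head is a fully connected stack
# [120, 120, 16, 2] with dropout 0.2 on the hidden layers. The two heads
# are trained jointly on the contralateral and ipsilateral response labels
# with a weighted sum of softmax cross-entropies and plain gradient descent.
# The numerical core lives in compiled code; this file owns configuration,
# initialization, and the training/prediction interface.

#' Model configuration
#'
#' @param input_size `c(height, width)` of the scalogram images.
#' @param blocks list of integer vectors: output channels of each conv layer
#'   per block (e.g. `list(c(64, 64), c(128, 128), ...)` for the full
#'   network, `list(4)` for the desk-scale trunk).
#' @param pools max-pool window (= stride) after each block.
#' @param head_widths fully connected widths of each task head; must end in
#'   2 (the two response classes).
#' @param dropout_rate dropout on the hidden head layers.
#' @param learning_rate plain-SGD step size.
#' @param loss_weights `c(w_contra, w_ipsi)`: non-negative loss weights, not
#'   both zero. Only the ratio is semantically meaningful; no normalization
#'   is applied.
#' @param epochs,batch_size training schedule.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param mode `"multitask"` (two heads) or `"single_task"` (contralateral
#'   head only).
#' @return a validated `model_config` list.
#' @export
model_config <- function(input_size = c(64, 64),
                         blocks = list(4L),
                         pools = 4L,
                         head_widths = c(120L, 120L, 16L, 2L),
                         dropout_rate = 0.2,
                         learning_rate = 0.005,
                         loss_weights = c(1, 1),
                         epochs = 60L,
                         batch_size = 32L,
                         seed = 1L,
                         mode = c("multitask", "single_task")) {
  mode <- match.arg(mode)
  if (!is.list(blocks)) blocks <- list(blocks)
  cfg <- list(input_size = as.integer(input_size),
              blocks = lapply(blocks, as.integer),
              pools = as.integer(pools),
              head_widths = as.integer(head_widths),
              dropout_rate = dropout_rate,
              learning_rate = learning_rate,
              loss_weights = as.numeric(loss_weights),
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              seed = as.integer(seed),
              mode = mode)
  class(cfg) <- "model_config"
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  hw <- cfg$head_widths
  if (hw[length(hw)] != 2L)
    stop_config("head_widths must end in 2 (two response classes)")
  w <- cfg$loss_weights
  if (length(w) != 2 || any(w < 0) || sum(w) == 0)
    stop_config("loss_weights must be two non-negative values, not both zero")
  if (length(cfg$pools) != length(cfg$blocks))
    stop_config("one pool size per block required")
  down <- prod(cfg$pools)
  if (any(cfg$input_size %% down != 0) || any(cfg$input_size < down))
    stop_config("input_size ", paste(cfg$input_size, collapse = "x"),
                " is not divisible by the trunk's total downsampling ", down)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop_config("dropout_rate must be in [0, 1)")
  if (cfg$learning_rate <= 0) stop_config("learning_rate must be > 0")
  if (cfg$epochs < 1 || cfg$batch_size < 1)
    stop_config("epochs and batch_size must be >= 1")
  invisible(cfg)
}

#' Full-size VGG16 configuration
#'
#' The 13-convolution trunk (64-64 / 128-128 / 256-256-256 / 512-512-512 /
#' 512-512-512, pool 2 after each block) at 224x224 input, heads
#' `[120, 120, 16, 2]`, dropout 0.2, learning rate 0.001 — the published
#' architecture. Provided as a named configuration; far too large for test
#' runs.
#'
#' @param ... overrides passed to [model_config()].
#' @export
model_config_vgg16 <- function(...) {
  args <- list(...)
  defaults <- list(input_size = c(224L, 224L),
                   blocks = list(c(64L, 64L), c(128L, 128L),
                                 c(256L, 256L, 256L), c(512L, 512L, 512L),
                                 c(512L, 512L, 512L)),
                   pools = c(2L, 2L, 2L, 2L, 2L),
                   learning_rate = 0.001)
  do.call(model_config, utils::modifyList(defaults, args))
}

trunk_layer_dims <- function(cfg) {
  cin <- 1L
  dims <- list()
  for (b in cfg$blocks)
    for (cout in b) {
      dims[[length(dims) + 1L]] <- c(cin = cin, cout = cout)
      cin <- cout
    }
  dims
}

flat_feature_dim <- function(cfg) {
  hw <- cfg$input_size %/% prod(cfg$pools)
  last_block <- cfg$blocks[[length(cfg$blocks)]]
  as.integer(hw[1] * hw[2] * last_block[length(last_block)])
}

n_heads <- function(cfg) if (cfg$mode == "multitask") 2L else 1L

init_dense_stack <- function(widths, seed) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(widths) - 1)) {
      fan_in <- widths[l]
      W[[l]] <- matrix(stats::rnorm(widths[l + 1] * fan_in) *
                         sqrt(2 / fan_in), widths[l + 1], fan_in)
      b[[l]] <- numeric(widths[l + 1])
    }
    list(W = W, b = b)
  })
}

#' Build a classifier with freshly initialized weights
#'
#' Fan-in-scaled Gaussian initialization; the trunk and each head draw from
#' independent derived seeds, so a single-task model shares its trunk and
#' first-head initialization bit-for-bit with the multitask model at the
#' same seed.
#'
#' @param config a [model_config()].
#' @return a `mer_model`: list with `config` and `weights`.
#' @export
build_model <- function(config) {
  validate_model_config(config)
  dims <- trunk_layer_dims(config)
  trunk_W <- list(); trunk_b <- list()
  with_seed(derive_seed(config$seed, "trunk"), {
    for (i in seq_along(dims)) {
      fan_in <- 9L * dims[[i]]["cin"]
      trunk_W[[i]] <- matrix(stats::rnorm(dims[[i]]["cout"] * fan_in) *
                               sqrt(2 / fan_in),
                             dims[[i]]["cout"], fan_in)
      trunk_b[[i]] <- numeric(dims[[i]]["cout"])
    }
  })
  widths <- c(flat_feature_dim(config), config$head_widths)
  heads <- lapply(seq_len(n_heads(config)), function(h)
    init_dense_stack(widths, derive_seed(config$seed, paste0("head", h))))
  structure(list(config = config,
                 weights = list(trunk_W = trunk_W, trunk_b = trunk_b,
                                heads = heads)),
            class = "mer_model")
}

#' Number of trainable parameters
#'
#' @param model a `mer_model`.
#' @return integer parameter count over trunk and all heads.
#' @export
count_parameters <- function(model) {
  w <- model$weights
  n <- sum(vapply(w$trunk_W, length, numeric(1))) +
    sum(vapply(w$trunk_b, length, numeric(1)))
  for (h in w$heads)
    n <- n + sum(vapply(h$W, length, numeric(1))) +
      sum(vapply(h$b, length, numeric(1)))
  as.integer(n)
}

as_class_index <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% RESPONSE_LEVELS))
      stop_config("labels must be 'good'/'moderate'")
    ifelse(labels == "good", 0L, 1L)
  } else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop_config("integer labels must be 0/1")
    labels
  }
}

softmax_ce_rows <- function(logits, y_idx) {
  # logits: n x 2, y_idx: 0-based true class
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  true_logit <- logits[cbind(seq_len(nrow(logits)), y_idx + 1L)]
  mean(lse - true_logit)
}

#' Weighted multitask cross-entropy loss
#'
#' `L = w_contra * CE(logits_contra, y_contra) + w_ipsi * CE(logits_ipsi,
#' y_ipsi)`, each CE the softmax cross-entropy averaged over the batch. No
#' weight normalization is applied: only the ratio is meaningful, and
#' scaling both weights by `c` scales the loss (and every gradient) by `c`.
#'
#' @param logits_contra,logits_ipsi `n x 2` logit matrices; `logits_ipsi`
#'   may be `NULL` when `w_ipsi = 0` (single-task).
#' @param label_contra,label_ipsi labels as `good`/`moderate` factors or
#'   0/1 integers (0 = good).
#' @param w_contra,w_ipsi non-negative weights, not both zero.
#' @param gradient if `TRUE`, also return analytic gradients with respect to
#'   the logits.
#' @return the scalar loss, or a list `(loss, grad_contra, grad_ipsi)`.
#' @export
multitask_loss <- function(logits_contra, logits_ipsi, label_contra,
                           label_ipsi, w_contra, w_ipsi,
                           gradient = FALSE) {
  if (w_contra < 0 || w_ipsi < 0)
    stop_config("loss weights must be non-negative")
  if (w_contra + w_ipsi == 0) stop_config("loss weights must not both be zero")
  y_c <- as_class_index(label_contra)
  loss <- w_contra * softmax_ce_rows(logits_contra, y_c)
  y_i <- NULL
  if (w_ipsi > 0 || !is.null(logits_ipsi)) {
    y_i <- as_class_index(label_ipsi)
    loss <- loss + w_ipsi * softmax_ce_rows(logits_ipsi, y_i)
  }
  if (!gradient) return(loss)
  grad_of <- function(logits, y, w) {
    p <- exp(logits - apply(logits, 1, max))
    p <- p / rowSums(p)
    onehot <- matrix(0, nrow(logits), 2)
    onehot[cbind(seq_len(nrow(logits)), y + 1L)] <- 1
    w * (p - onehot) / nrow(logits)
  }
  list(loss = loss,
       grad_contra = grad_of(logits_contra, y_c, w_contra),
       grad_ipsi = if (!is.null(y_i)) grad_of(logits_ipsi, y_i, w_ipsi))
}

check_dataset <- function(d, cfg, what) {
  if (is.null(d$x) || length(dim(d$x)) != 3)
    stop_config(what, "$x must be an H x W x N array")
  if (any(dim(d$x)[1:2] != cfg$input_size))
    stop_config(what, " images are ", paste(dim(d$x)[1:2], collapse = "x"),
                " but the model expects ",
                paste(cfg$input_size, collapse = "x"))
  n <- dim(d$x)[3]
  if (n == 0) stop_config(what, " split is empty")
  if (length(d$contra) != n) stop_config(what, " labels/images mismatch")
  d
}

dataset_labels <- function(d, cfg) {
  y <- matrix(as_class_index(d$contra), nrow = 1)
  if (cfg$mode == "multitask") {
    if (is.null(d$ipsi)) stop_config("multitask training needs ipsi labels")
    y <- rbind(y, as_class_index(d$ipsi))
  }
  y
}

#' Train the classifier
#'
#' Plain mini-batch gradient descent on the weighted multitask loss for a
#' fixed number of epochs, recording per-epoch training loss and per-head
#' train/test accuracy. Fully reproducible from `config$seed`. A patient
#' must not appear in both datasets (asserted here, independently of the
#' labeling module).
#'
#' @param model a `mer_model` from [build_model()].
#' @param train,test datasets: lists with `x` (H x W x N image array),
#'   `contra` and `ipsi` labels, and `patient` ids (see [build_dataset()]).
#' @return a `mer_fit`: list with the trained `model` and `history`, a
#'   data.frame with columns `epoch`, `train_loss`, `acc_train_contra`,
#'   `acc_train_ipsi`, `acc_test_contra`, `acc_test_ipsi` (ipsi columns `NA`
#'   for single-task runs).
#' @export
canonicalize_dataset <- function(d) {
  # training must not depend on manifest row order: sort by segment id
  if (is.null(d$segment_id)) return(d)
  ord <- order(d$segment_id)
  d$x <- d$x[, , ord, drop = FALSE]
  d$contra <- d$contra[ord]
  if (!is.null(d$ipsi)) d$ipsi <- d$ipsi[ord]
  if (!is.null(d$patient)) d$patient <- d$patient[ord]
  d$segment_id <- d$segment_id[ord]
  d
}

fit_classifier <- function(model, train, test) {
  cfg <- model$config
  train <- check_dataset(canonicalize_dataset(train), cfg, "train")
  test <- check_dataset(canonicalize_dataset(test), cfg, "test")
  if (!is.null(train$patient) && !is.null(test$patient) &&
      length(common <- intersect(train$patient, test$patient)) > 0)
    stop_config("patient leakage between train and test: ",
                paste(common, collapse = ", "))

  n_tr <- dim(train$x)[3]
  shuffle <- with_seed(derive_seed(cfg$seed, "shuffle"),
                       t(replicate(cfg$epochs, sample.int(n_tr))) - 1L)
  if (cfg$epochs == 1L) shuffle <- matrix(shuffle, nrow = 1)
  storage.mode(shuffle) <- "integer"

  w <- model$weights
  hw <- if (cfg$mode == "multitask") cfg$loss_weights else cfg$loss_weights[1]
  res <- cpp_train(train$x, dataset_labels(train, cfg),
                   test$x, dataset_labels(test, cfg),
                   w$trunk_W, w$trunk_b,
                   vapply(cfg$blocks, length, integer(1)), cfg$pools,
                   w$heads, hw, cfg$dropout_rate, cfg$learning_rate,
                   cfg$epochs, cfg$batch_size,
                   as.double(derive_seed(cfg$seed, "dropout")), shuffle)

  model$weights <- list(trunk_W = res$trunk_W, trunk_b = res$trunk_b,
                        heads = res$heads)
  h <- res$history
  nh <- n_heads(cfg)
  history <- data.frame(
    epoch = seq_len(cfg$epochs),
    train_loss = h[, 1],
    acc_train_contra = h[, 2],
    acc_train_ipsi = if (nh == 2) h[, 3] else NA_real_,
    acc_test_contra = h[, 2 + nh],
    acc_test_ipsi = if (nh == 2) h[, 3 + nh] else NA_real_)
  structure(list(model = model, history = history), class = "mer_fit")
}

#' Class probabilities for new scalograms
#'
#' @param model a trained `mer_model`.
#' @param x `H x W x N` image array.
#' @return list with `contra` (and for multitask models `ipsi`): `N x 2`
#'   matrices of class probabilities, columns `good`, `moderate`.
#' @export
predict_classifier <- function(model, x) {
  cfg <- model$config
  w <- model$weights
  probs <- cpp_predict(x, w$trunk_W, w$trunk_b,
                       vapply(cfg$blocks, length, integer(1)), cfg$pools,
                       w$heads)
  probs <- lapply(probs, function(p) {
    colnames(p) <- RESPONSE_LEVELS
    p
  })
  names(probs) <- c("contra", "ipsi")[seq_along(probs)]
  probs
}

#' @export
print.mer_model <- function(x, ...) {
  cfg <- x$config
  cat("MER response classifier (", cfg$mode, ")\n", sep = "")
  cat("  input:", paste(cfg$input_size, collapse = "x"),
      " trunk:", paste(vapply(cfg$blocks, paste, character(1),
                              collapse = "-"), collapse = " | "),
      " heads:", paste(cfg$head_widths, collapse = "-"), "\n")
  cat("  parameters:", count_parameters(x), "\n")
  invisible(x)
}
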