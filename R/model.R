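# Residual 1-D convolutional classifier.
#
# Architecture (input N x T x C, convolutions along time):
#   residual block: pointwise conv (128 filters, no bias) -> BN -> GELU
#                   -> conv k=3 "same" (C filters, no bias) -> BN -> GELU
#                   -> + input -> GELU
#   head: conv k=3 "same" stride 2 (16 filters, bias) -> GELU -> flatten
#         -> dropout 0.1 -> FC(100) -> GELU -> dropout -> FC(100) -> GELU
#         -> dropout -> FC(F) -> softmax
# Trained with Adam (lr 0.01, beta1 0.9, beta2 0.999), categorical
# cross-entropy, batch size 250, 250 epochs by default.

#' Model hyperparameter configuration
#'
#' @param T_win window length in samples (20 for 100 ms at 200 Hz).
#' @param C number of input channels (4 EMG, 8 MMG).
#' @param n_classes number of output classes.
#' @param res_filters pointwise filters in the residual block.
#' @param res_kernel kernel length of the second residual convolution.
#' @param head_filters,head_stride filters and stride of the head
#'   convolution.
#' @param fc_units units of the two hidden fully-connected layers.
#' @param dropout dropout rate after flatten and each hidden FC layer.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param lr,beta1,beta2 Adam parameters.
#' @param seed seed for weight initialization, shuffling and dropout.
#' @return object of class `model_config`.
#' @export
model_config <- function(T_win = 20L, C = 8L, n_classes = 3L,
                         res_filters = 128L, res_kernel = 3L,
                         head_filters = 16L, head_stride = 2L,
                         fc_units = 100L, dropout = 0.1,
                         batch_size = 250L, epochs = 250L,
                         lr = 0.01, beta1 = 0.9, beta2 = 0.999,
                         seed = 1L) {
  cfg <- list(T_win = as.integer(T_win), C = as.integer(C),
              n_classes = as.integer(n_classes),
              res_filters = as.integer(res_filters),
              res_kernel = as.integer(res_kernel),
              head_filters = as.integer(head_filters),
              head_stride = as.integer(head_stride),
              fc_units = as.integer(fc_units), dropout = dropout,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              lr = lr, beta1 = beta1, beta2 = beta2,
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(T_win, C, n_classes, res_filters, res_kernel, head_filters,
              head_stride, fc_units, batch_size, epochs) < 1L))
      stopf("all counts must be >= 1")
    if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  })
  class(cfg) <- "model_config"
  cfg
}

flat_size <- function(cfg) {
  conv1d_geometry(cfg$T_win, cfg$res_kernel, cfg$head_stride)$t_out *
    cfg$head_filters
}

#' Build an untrained classifier
#'
#' Weights use fan-in-scaled Gaussian initialization (`sd = sqrt(2 /
#' fan_in)`) with the configured seed; batch-norm scale/shift start at
#' 1/0 and running moments at 0/1. The residual add requires the second
#' residual convolution to restore the input channel count, which is
#' asserted at construction.
#'
#' @param cfg a [model_config()].
#' @return object of class `decoder_model` (untrained).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  gi <- function(d) {
    fan_in <- prod(d[-length(d)])
    array(stats::rnorm(prod(d), sd = sqrt(2 / fan_in)), d)
  }
  params <- with_seed(derive_seed(cfg$seed, 404L), {
    fl <- flat_size(cfg)
    list(
      W1 = gi(c(1L, cfg$C, cfg$res_filters)),
      g1 = rep(1, cfg$res_filters), be1 = rep(0, cfg$res_filters),
      W2 = gi(c(cfg$res_kernel, cfg$res_filters, cfg$C)),
      g2 = rep(1, cfg$C), be2 = rep(0, cfg$C),
      W3 = gi(c(cfg$res_kernel, cfg$C, cfg$head_filters)),
      b3 = rep(0, cfg$head_filters),
      Wf1 = gi(c(fl, cfg$fc_units)), bf1 = rep(0, cfg$fc_units),
      Wf2 = gi(c(cfg$fc_units, cfg$fc_units)), bf2 = rep(0, cfg$fc_units),
      Wf3 = gi(c(cfg$fc_units, cfg$n_classes)), bf3 = rep(0, cfg$n_classes)
    )
  })
  # residual add shape check: conv2 must map back to T_win x C
  stopifnot(dim(params$W2)[3] == cfg$C,
            conv1d_geometry(cfg$T_win, cfg$res_kernel, 1L)$t_out == cfg$T_win)
  state <- list(rm1 = rep(0, cfg$res_filters), rv1 = rep(1, cfg$res_filters),
                rm2 = rep(0, cfg$C), rv2 = rep(1, cfg$C))
  structure(list(cfg = cfg, params = params, state = state,
                 loss_curve = numeric(0), classes = NULL, trained = FALSE),
            class = "decoder_model")
}

#' Number of trainable parameters
#'
#' @param model a `decoder_model`.
#' @return integer count over all weight, bias and batch-norm parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# Full forward pass; returns logits and every cache needed for backprop.
nn_forward <- function(model, X, training = FALSE) {
  p <- model$params; s <- model$state; cfg <- model$cfg
  if (length(dim(X)) != 3 || dim(X)[2] != cfg$T_win || dim(X)[3] != cfg$C)
    stopf("input must be N x %d x %d", cfg$T_win, cfg$C)
  c1 <- conv1d_forward(X, p$W1, NULL, 1L)
  b1 <- bn_forward(c1$y, p$g1, p$be1, training, s$rm1, s$rv1)
  a1 <- gelu(b1$y)
  c2 <- conv1d_forward(a1, p$W2, NULL, 1L)
  b2 <- bn_forward(c2$y, p$g2, p$be2, training, s$rm2, s$rv2)
  a2 <- gelu(b2$y)
  radd <- a2 + X
  a3 <- gelu(radd)
  c3 <- conv1d_forward(a3, p$W3, p$b3, cfg$head_stride)
  a4 <- gelu(c3$y)
  N <- dim(X)[1]
  flat <- matrix(a4, N, prod(dim(a4)[2:3]))
  d1 <- dropout_forward(flat, cfg$dropout, training)
  f1 <- dense_forward(d1$y, p$Wf1, p$bf1)
  a5 <- gelu(f1$y)
  d2 <- dropout_forward(a5, cfg$dropout, training)
  f2 <- dense_forward(d2$y, p$Wf2, p$bf2)
  a6 <- gelu(f2$y)
  d3 <- dropout_forward(a6, cfg$dropout, training)
  f3 <- dense_forward(d3$y, p$Wf3, p$bf3)
  list(logits = f3$y,
       caches = list(c1 = c1, b1 = b1, pre1 = b1$y, c2 = c2, b2 = b2,
                     pre2 = b2$y, radd = radd, c3 = c3, pre3 = c3$y,
                     d1 = d1, f1 = f1, pre4 = f1$y, d2 = d2, f2 = f2,
                     pre5 = f2$y, d3 = d3, f3 = f3, X = X,
                     dim_a4 = dim(a4)),
       new_state = list(rm1 = b1$run_mean, rv1 = b1$run_var,
                        rm2 = b2$run_mean, rv2 = b2$run_var))
}

# Backward pass from dlogits; returns parameter gradients and, optionally,
# the gradient with respect to the input tensor.
nn_backward <- function(model, fw, dlogits, need_param_grads = TRUE,
                        need_dX = FALSE) {
  p <- model$params; ca <- fw$caches
  g <- list()
  bk3 <- dense_backward(dlogits, ca$f3$cache, p$Wf3, need_param_grads)
  g$Wf3 <- bk3$dW; g$bf3 <- bk3$db
  d <- bk3$dX
  if (!is.null(ca$d3$mask)) d <- d * ca$d3$mask
  d <- d * gelu_grad(ca$pre5)
  bk2 <- dense_backward(d, ca$f2$cache, p$Wf2, need_param_grads)
  g$Wf2 <- bk2$dW; g$bf2 <- bk2$db
  d <- bk2$dX
  if (!is.null(ca$d2$mask)) d <- d * ca$d2$mask
  d <- d * gelu_grad(ca$pre4)
  bk1 <- dense_backward(d, ca$f1$cache, p$Wf1, need_param_grads)
  g$Wf1 <- bk1$dW; g$bf1 <- bk1$db
  d <- bk1$dX
  if (!is.null(ca$d1$mask)) d <- d * ca$d1$mask
  d_a4 <- array(d, ca$dim_a4)
  d_c3 <- d_a4 * gelu_grad(ca$pre3)
  bkc3 <- conv1d_backward(d_c3, ca$c3$cache, p$W3, has_bias = TRUE,
                          need_dX = TRUE, need_dW = need_param_grads)
  g$W3 <- bkc3$dW; g$b3 <- bkc3$db
  d_a3 <- bkc3$dX
  d_radd <- d_a3 * gelu_grad(ca$radd)
  # residual: gradient flows to both the conv path and the block input
  d_a2 <- d_radd * gelu_grad(ca$pre2)
  bb2 <- bn_backward(d_a2, ca$b2$cache, p$g2)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  bkc2 <- conv1d_backward(bb2$dX, ca$c2$cache, p$W2, has_bias = FALSE,
                          need_dX = TRUE, need_dW = need_param_grads)
  g$W2 <- bkc2$dW
  d_a1 <- bkc2$dX * gelu_grad(ca$pre1)
  bb1 <- bn_backward(d_a1, ca$b1$cache, p$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  bkc1 <- conv1d_backward(bb1$dX, ca$c1$cache, p$W1, has_bias = FALSE,
                          need_dX = need_dX, need_dW = need_param_grads)
  g$W1 <- bkc1$dW
  dX <- NULL
  if (need_dX) dX <- bkc1$dX + d_radd
  list(grads = g, dX = dX)
}

# conversion between the R array convention (k x Cin x Cout) and the
# flattened (k*Cin) x Cout matrices of the compiled backend
params_to_mats <- function(p) {
  cv <- function(W) matrix(W, prod(dim(W)[1:2]), dim(W)[3])
  p$W1 <- cv(p$W1); p$W2 <- cv(p$W2); p$W3 <- cv(p$W3)
  p
}

params_from_mats <- function(pm, cfg) {
  pm$W1 <- array(pm$W1, c(1L, cfg$C, cfg$res_filters))
  pm$W2 <- array(pm$W2, c(cfg$res_kernel, cfg$res_filters, cfg$C))
  pm$W3 <- array(pm$W3, c(cfg$res_kernel, cfg$C, cfg$head_filters))
  for (nm in c("g1", "be1", "g2", "be2", "b3", "bf1", "bf2", "bf3"))
    pm[[nm]] <- as.numeric(pm[[nm]])
  for (nm in c("Wf1", "Wf2", "Wf3")) pm[[nm]] <- as.matrix(pm[[nm]])
  pm
}

nn_backend <- function(backend = NULL) {
  match.arg(backend %||% getOption("mmgdecode.backend", "cpp"),
            c("cpp", "r"))
}

#' Train the classifier
#'
#' Minimizes mean categorical cross-entropy with Adam, shuffling each
#' epoch. The training data are expected to be z-scored already (moments
#' fitted on this split). Deterministic given the seed (within a backend;
#' the compiled and reference backends use different RNG streams for
#' shuffling and dropout and are not bit-identical to each other).
#'
#' @param model an untrained (or trained) `decoder_model`.
#' @param X z-scored tensor `N x T x C`.
#' @param y factor of labels (levels define the class order) or integer
#'   class indices.
#' @param epochs optional override of `cfg$epochs`.
#' @param seed optional override of `cfg$seed` for shuffling/dropout.
#' @param backend `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation); settable globally via `options(mmgdecode.backend=)`.
#' @return the trained `decoder_model`, with `loss_curve` (one mean loss
#'   per epoch) and `classes`.
#' @export
train_model <- function(model, X, y, epochs = NULL, seed = NULL,
                        backend = NULL) {
  cfg <- model$cfg
  epochs <- as.integer(epochs %||% cfg$epochs)
  seed <- as.integer(seed %||% cfg$seed)
  if (nn_backend(backend) == "cpp")
    return(train_model_cpp(model, X, y, epochs, seed))
  if (is.factor(y)) {
    model$classes <- levels(y)
    yi <- as.integer(y)
  } else {
    model$classes <- model$classes %||% as.character(seq_len(cfg$n_classes))
    yi <- as.integer(y)
  }
  n <- dim(X)[1]
  stopifnot(length(yi) == n, max(yi) <= cfg$n_classes)
  adam <- adam_init(model$params)
  losses <- numeric(epochs)
  with_seed(derive_seed(seed, 505L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        fw <- nn_forward(model, X[idx, , , drop = FALSE], training = TRUE)
        sm <- softmax_xent(fw$logits, yi[idx], "mean")
        if (!is.finite(sm$loss))
          stopf("NaN/Inf loss at epoch %d (diverged; check lr or data scaling)", ep)
        bw <- nn_backward(model, fw, sm$dlogits)
        upd <- adam_step(model$params, bw$grads, adam, cfg$lr,
                         cfg$beta1, cfg$beta2)
        model$params <- upd$params
        adam <- upd$state
        model$state <- fw$new_state
        ep_loss <- ep_loss + sm$loss * length(idx); nb <- nb + length(idx)
      }
      losses[ep] <- ep_loss / nb
    }
  })
  model$loss_curve <- c(model$loss_curve, losses)
  model$trained <- TRUE
  model
}

train_model_cpp <- function(model, X, y, epochs, seed) {
  cfg <- model$cfg
  if (is.factor(y)) {
    model$classes <- levels(y)
    yi <- as.integer(y)
  } else {
    model$classes <- model$classes %||% as.character(seq_len(cfg$n_classes))
    yi <- as.integer(y)
  }
  stopifnot(length(yi) == dim(X)[1], max(yi) <= cfg$n_classes)
  out <- nn_cpp_train(params_to_mats(model$params), model$state, X, yi,
                      epochs, cfg$batch_size, cfg$lr, cfg$beta1, cfg$beta2,
                      cfg$dropout, derive_seed(seed, 505L))
  if (!all(is.finite(unlist(out$loss_curve))))
    stopf("NaN/Inf loss during training")
  model$params <- params_from_mats(out$params, cfg)
  model$state <- lapply(out$state, as.numeric)
  model$loss_curve <- c(model$loss_curve, as.numeric(out$loss_curve))
  model$trained <- TRUE
  model
}

#' Predict class probabilities or labels
#'
#' Inference mode: dropout inactive, batch norm uses running moments.
#'
#' @param object a trained `decoder_model`.
#' @param X z-scored tensor `N x T x C` (use the train-split moments).
#' @param type `"prob"` for the `N x F` probability matrix, `"class"` for
#'   argmax labels.
#' @param backend `"cpp"` or `"r"`.
#' @param ... unused.
#' @return probability matrix or character vector of labels.
#' @export
predict.decoder_model <- function(object, X, type = c("prob", "class"),
                                  backend = NULL, ...) {
  type <- match.arg(type)
  logits <- if (nn_backend(backend) == "cpp") {
    nn_cpp_logits(params_to_mats(object$params), object$state, X)
  } else {
    nn_forward(object, X, training = FALSE)$logits
  }
  probs <- softmax_probs(logits)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' Gradient of the cross-entropy loss with respect to the input
#'
#' Inference-mode backpropagation to the input tensor; used by the
#' integrated-gradients attribution.
#'
#' @param model a trained `decoder_model`.
#' @param X tensor `N x T x C`.
#' @param y labels (factor with the model's levels, or integer indices).
#' @param backend `"cpp"` or `"r"`.
#' @return array `N x T x C` of per-sample loss gradients.
#' @export
input_gradients <- function(model, X, y, backend = NULL) {
  yi <- if (is.factor(y)) as.integer(y) else
    if (is.character(y)) match(y, model$classes) else as.integer(y)
  if (nn_backend(backend) == "cpp")
    return(nn_cpp_input_grad(params_to_mats(model$params), model$state,
                             X, yi))
  fw <- nn_forward(model, X, training = FALSE)
  sm <- softmax_xent(fw$logits, yi, "sum")
  nn_backward(model, fw, sm$dlogits, need_param_grads = FALSE,
              need_dX = TRUE)$dX
}

#' Stratified cross-validated training and evaluation
#'
#' Splits trials into `k` stratified folds, and in each fold samples fresh
#' train/test windows (defaults 500/100 per class), z-scores with
#' train-split moments, trains one model from scratch and evaluates test
#' accuracy. When several modalities are passed, the same fold plan and the
#' same window positions are used for all of them, so their test
#' predictions are aligned window-for-window (as required by the agreement
#' and McNemar analyses).
#'
#' @param envexps a single `envelope_experiment` or a named list of them
#'   (one per modality, identical trial structure).
#' @param cfg a [model_config()]; `C` is adapted per modality.
#' @param k number of folds.
#' @param n_train,n_test windows per class per split.
#' @param epochs optional override of `cfg$epochs`.
#' @param seed master seed (folds, windows, initialization, training).
#' @param permute_train if `TRUE`, training labels are randomly permuted in
#'   every fold (used for the empirical chance level).
#' @param classes label set.
#' @return object of class `cv_result`: per-modality list with `folds`
#'   (fold index, accuracy, predictions data.frame, loss curve, channel
#'   importance inputs) and `accuracy` (mean over folds); plus the shared
#'   `plan`.
#' @export
cross_validate <- function(envexps, cfg, k = 5L, n_train = 500L,
                           n_test = 100L, epochs = NULL, seed = 1L,
                           permute_train = FALSE, classes = ALL_CLASSES) {
  single <- inherits(envexps, "envelope_experiment")
  if (single) envexps <- list(model = envexps)
  trials <- envexps[[1]]$trials
  plan <- split_trials(trials, k, seed = derive_seed(seed, 606L))
  res <- lapply(envexps, function(e) list(folds = vector("list", k)))
  for (i in seq_len(k)) {
    fold_seed <- derive_seed(seed, 707L, i)
    positions <- NULL
    for (mi in seq_along(envexps)) {
      env <- envexps[[mi]]
      ds <- build_fold_dataset(env, plan$folds[[i]], n_train, n_test,
                               classes = classes, seed = fold_seed,
                               positions = positions)
      positions <- list(train = ds$train$positions, test = ds$test$positions)
      y_tr <- ds$train$y
      if (permute_train) {
        y_tr <- with_seed(derive_seed(seed, 808L, i, mi),
                          y_tr[sample.int(length(y_tr))])
      }
      mcfg <- cfg
      mcfg$C <- dim(ds$train$X)[3]
      mcfg$seed <- derive_seed(fold_seed, 909L, mi)
      model <- build_model(mcfg)
      model <- train_model(model, ds$train$X, y_tr, epochs = epochs)
      probs <- predict(model, ds$test$X, type = "prob")
      pred <- model$classes[max.col(probs, ties.method = "first")]
      acc <- mean(pred == as.character(ds$test$y))
      res[[mi]]$folds[[i]] <- list(
        fold = i,
        accuracy = acc,
        predictions = data.frame(
          window = seq_along(pred),
          true = as.character(ds$test$y),
          pred = pred,
          probs,
          check.names = FALSE,
          stringsAsFactors = FALSE
        ),
        loss_curve = model$loss_curve,
        model = model,
        test = ds$test,
        moments = ds$moments
      )
    }
  }
  for (mi in seq_along(res)) {
    res[[mi]]$accuracy <- mean(vapply(res[[mi]]$folds,
                                      function(f) f$accuracy, numeric(1)))
  }
  out <- structure(list(modalities = res, plan = plan, classes = classes,
                        seed = seed), class = "cv_result")
  if (single) out$modalities <- res  # same structure either way
  out
}

#' Confusion matrix of a cross-validation result
#'
#' @param cv a `cv_result`.
#' @param modality name or index of the modality.
#' @return `F x F` matrix (rows: truth, columns: prediction) of pooled test
#'   window counts.
#' @export
cv_confusion <- function(cv, modality = 1L) {
  preds <- do.call(rbind, lapply(cv$modalities[[modality]]$folds,
                                 function(f) f$predictions))
  table(factor(preds$true, cv$classes), factor(preds$pred, cv$classes))
}
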