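# Classifier construction, gradient correctness, backend parity, training
# behaviour and cross-validation bookkeeping.

test_that("parameter count equals the layer-by-layer hand count", {
  cfg <- model_config(T_win = 20L, C = 8L)
  m <- build_model(cfg)
  # conv: kernel*in*out (+out if bias); BN: 2*features; FC: in*out + out
  flat <- 10 * 16   # stride-2 "same" output length 10, 16 filters
  want <- 1 * 8 * 128 + 2 * 128 +        # pointwise conv + BN
    3 * 128 * 8 + 2 * 8 +                # kernel-3 conv back to C + BN
    3 * 8 * 16 + 16 +                    # head conv with bias
    flat * 100 + 100 +                   # FC1
    100 * 100 + 100 +                    # FC2
    100 * 3 + 3                          # output FC
  expect_equal(n_parameters(m), want)
})

test_that("gelu is x * Phi(x)", {
  expect_equal(gelu(0), 0)
  expect_equal(gelu(10), 10, tolerance = 1e-7)
  expect_equal(gelu(-1), -1 * stats::pnorm(-1))
  # independent oracle: Phi(-1) by quadrature of the normal density
  phi_m1 <- stats::integrate(stats::dnorm, -Inf, -1)$value
  expect_equal(gelu(-1), -phi_m1, tolerance = 1e-8)
  expect_equal(gelu(-1), -0.1586553, tolerance = 1e-6)
})

test_that("predictions are normalized probabilities with consistent argmax", {
  cfg <- model_config(T_win = 20L, C = 8L, seed = 2L)
  m <- build_model(cfg)
  m$classes <- c("DII", "DV", "NoMove")
  X <- array(stats::rnorm(40 * 20 * 8), c(40, 20, 8))
  p <- predict(m, X)
  expect_equal(unname(rowSums(p)), rep(1, 40), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
  cl <- predict(m, X, type = "class")
  expect_identical(cl, m$classes[apply(p, 1, which.max)])
  # inference is deterministic
  expect_identical(predict(m, X), p)
})

test_that("residual block reduces to GELU(input) when conv weights are zero", {
  cfg <- model_config(T_win = 8L, C = 3L, res_filters = 6L, seed = 4L)
  m <- build_model(cfg)
  m$params$W1[] <- 0
  m$params$W2[] <- 0
  fw <- mmgdecode:::nn_forward(m, array(stats::rnorm(5 * 8 * 3), c(5, 8, 3)),
                               training = FALSE)
  # batch-norm in inference with fresh state (mean 0, var 1) passes zeros
  # through, so the residual add sees the raw input
  X <- fw$caches$X
  expect_equal(fw$caches$radd, X, tolerance = 1e-6)
})

test_that("analytic gradients match finite differences (reference backend)", {
  cfg <- model_config(T_win = 6L, C = 3L, res_filters = 5L,
                      head_filters = 4L, fc_units = 7L, dropout = 0,
                      seed = 3L)
  m <- build_model(cfg)
  set.seed(1)
  X <- array(stats::rnorm(4 * 6 * 3), c(4, 6, 3))
  y <- sample(1:3, 4, TRUE)
  loss_at <- function(mm, training = TRUE) {
    fw <- mmgdecode:::nn_forward(mm, X, training)
    mmgdecode:::softmax_xent(fw$logits, y, "mean")$loss
  }
  fw <- mmgdecode:::nn_forward(m, X, training = TRUE)
  sm <- mmgdecode:::softmax_xent(fw$logits, y, "mean")
  bw <- mmgdecode:::nn_backward(m, fw, sm$dlogits, need_param_grads = TRUE,
                                need_dX = TRUE)
  eps <- 1e-6
  set.seed(2)
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (ii in sample(seq_along(p), min(4, length(p)))) {
      m2 <- m; m2$params[[nm]][ii] <- p[ii] + eps
      m3 <- m; m3$params[[nm]][ii] <- p[ii] - eps
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      expect_equal(bw$grads[[nm]][ii], num, tolerance = 1e-4)
    }
  }
  # input gradients, inference mode
  gX <- input_gradients(m, X, y, backend = "r")
  li <- function(Xp) {
    fw <- mmgdecode:::nn_forward(m, Xp, FALSE)
    mmgdecode:::softmax_xent(fw$logits, y, "sum")$loss
  }
  for (ii in sample(seq_along(X), 8)) {
    X2 <- X; X2[ii] <- X[ii] + eps
    X3 <- X; X3[ii] <- X[ii] - eps
    expect_equal(gX[ii], (li(X2) - li(X3)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("compiled backend agrees with the reference implementation", {
  cfg <- model_config(T_win = 20L, C = 8L, seed = 11L)
  m <- build_model(cfg)
  set.seed(3)
  X <- array(stats::rnorm(32 * 20 * 8), c(32, 20, 8))
  y <- sample(1:3, 32, TRUE)
  expect_equal(predict(m, X, backend = "cpp"),
               predict(m, X, backend = "r"), tolerance = 1e-4)
  g1 <- input_gradients(m, X, y, backend = "cpp")
  g2 <- input_gradients(m, X, y, backend = "r")
  expect_lt(max(abs(g1 - g2)) / max(abs(g2)), 1e-4)
})

test_that("training learns a separable problem and is seed-deterministic", {
  ds <- separable_dataset(100L, shift = 2)
  cfg <- model_config(C = 8L, seed = 21L)
  m <- train_model(build_model(cfg), ds$X, ds$y, epochs = 50)
  expect_length(m$loss_curve, 50)
  expect_true(all(is.finite(m$loss_curve)))
  expect_gte(mean(predict(m, ds$X, type = "class") == as.character(ds$y)),
             0.99)
  m2 <- train_model(build_model(cfg), ds$X, ds$y, epochs = 50)
  expect_identical(m$loss_curve, m2$loss_curve)
  expect_identical(m$params, m2$params)
})

test_that("label shuffling drives accuracy to chance", {
  ds <- separable_dataset(100L)
  accs <- vapply(1:5, function(r) {
    y_sh <- mmgdecode:::with_seed(r, sample(ds$y))
    cfg <- model_config(C = 8L, seed = 100L + r)
    m <- train_model(build_model(cfg), ds$X[1:240, , ], y_sh[1:240],
                     epochs = 15)
    mean(predict(m, ds$X[241:300, , ], type = "class") ==
           as.character(ds$y[241:300]))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.07)
})

test_that("cross-validation keeps per-fold bookkeeping and confusion totals", {
  envexp <- get_small_envexp("EMG")
  cv <- cross_validate(envexp, tiny_model_config(C = 4L), k = 2,
                       n_train = 60, n_test = 30, epochs = 5, seed = 13L)
  m <- cv$modalities[[1]]
  expect_length(m$folds, 2)
  for (f in m$folds) {
    expect_equal(nrow(f$predictions), 90)  # 30 windows x 3 classes
    expect_equal(as.vector(table(f$predictions$true)), rep(30L, 3))
    pr <- as.matrix(f$predictions[, c("DII", "DV", "NoMove")])
    expect_equal(unname(rowSums(pr)), rep(1, 90), tolerance = 1e-5)
  }
  cm <- cv_confusion(cv, 1)
  expect_equal(unname(rowSums(cm)), rep(60L, 3))
  expect_equal(m$accuracy,
               mean(vapply(m$folds, function(f) f$accuracy, numeric(1))))
})
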