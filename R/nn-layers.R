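# Internal neural-network primitives: 1-D convolution (im2col), batch
# normalization, GELU, dropout, dense layers, softmax cross-entropy and
# Adam. All tensors are N x T x C arrays (batch, time, feature maps);
# convolutions run along the time axis with "same" zero padding.

conv1d_geometry <- function(Tt, k, stride) {
  t_out <- as.integer(ceiling(Tt / stride))
  pad_total <- max((t_out - 1L) * stride + k - Tt, 0L)
  list(t_out = t_out, pad_left = pad_total %/% 2L)
}

# X: N x T x Cin, W: k x Cin x Cout, b: NULL or length Cout
conv1d_forward <- function(X, W, b = NULL, stride = 1L) {
  d <- dim(X); N <- d[1]; Tt <- d[2]; Cin <- d[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  stopifnot(dim(W)[2] == Cin)
  g <- conv1d_geometry(Tt, k, stride)
  t_out <- g$t_out
  Xcol <- matrix(0, N * t_out, k * Cin)
  src <- vector("list", k)
  for (j in seq_len(k)) {
    s <- (seq_len(t_out) - 1L) * stride + j - g$pad_left
    valid <- s >= 1L & s <= Tt
    sl <- array(0, c(N, t_out, Cin))
    if (any(valid)) sl[, valid, ] <- X[, s[valid], , drop = FALSE]
    Xcol[, (seq_len(Cin) - 1L) * k + j] <- sl
    src[[j]] <- list(s = s, valid = valid)
  }
  Ym <- Xcol %*% matrix(W, k * Cin, Cout)
  if (!is.null(b)) Ym <- Ym + matrix(b, N * t_out, Cout, byrow = TRUE)
  list(y = array(Ym, c(N, t_out, Cout)),
       cache = list(Xcol = Xcol, src = src, dimX = d, k = k,
                    t_out = t_out, Cin = Cin, Cout = Cout))
}

conv1d_backward <- function(dY, cache, W, has_bias = FALSE,
                            need_dX = TRUE, need_dW = TRUE) {
  N <- cache$dimX[1]; Cin <- cache$Cin; Cout <- cache$Cout
  k <- cache$k; t_out <- cache$t_out
  dYm <- matrix(dY, N * t_out, Cout)
  dW <- db <- dX <- NULL
  if (need_dW) {
    dW <- array(crossprod(cache$Xcol, dYm), dim(W))
    if (has_bias) db <- colSums(dYm)
  }
  if (need_dX) {
    dXcol <- dYm %*% t(matrix(W, k * Cin, Cout))
    dX <- array(0, cache$dimX)
    for (j in seq_len(k)) {
      sj <- cache$src[[j]]
      if (!any(sj$valid)) next
      part <- array(dXcol[, (seq_len(Cin) - 1L) * k + j],
                    c(N, t_out, Cin))
      idx <- sj$s[sj$valid]
      dX[, idx, ] <- dX[, idx, , drop = FALSE] +
        part[, sj$valid, , drop = FALSE]
    }
  }
  list(dW = dW, db = db, dX = dX)
}

BN_EPS <- 1e-5

# Normalizes each feature map over batch x time. Training mode uses batch
# moments (biased variance) and updates running moments with momentum 0.99;
# inference applies the running moments as a fixed affine map.
bn_forward <- function(X, gamma, beta, training, run_mean, run_var,
                       momentum = 0.99) {
  d <- dim(X)
  M <- matrix(X, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(M)
    xc <- M - matrix(mu, nrow(M), d[3], byrow = TRUE)
    v <- colMeans(xc * xc)
    new_rm <- momentum * run_mean + (1 - momentum) * mu
    new_rv <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- M - matrix(mu, nrow(M), d[3], byrow = TRUE)
    new_rm <- run_mean; new_rv <- run_var
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * matrix(inv, nrow(M), d[3], byrow = TRUE)
  Y <- xhat * matrix(gamma, nrow(M), d[3], byrow = TRUE) +
    matrix(beta, nrow(M), d[3], byrow = TRUE)
  list(y = array(Y, d),
       cache = list(xhat = xhat, inv = inv, dim = d, training = training),
       run_mean = new_rm, run_var = new_rv)
}

bn_backward <- function(dY, cache, gamma) {
  d <- cache$dim
  m <- d[1] * d[2]
  dYm <- matrix(dY, m, d[3])
  if (!cache$training) {
    dX <- dYm * matrix(gamma * cache$inv, m, d[3], byrow = TRUE)
    return(list(dX = array(dX, d), dgamma = NULL, dbeta = NULL))
  }
  xhat <- cache$xhat
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * matrix(gamma, m, d[3], byrow = TRUE)
  t1 <- matrix(colSums(dxhat), m, d[3], byrow = TRUE)
  t2 <- xhat * matrix(colSums(dxhat * xhat), m, d[3], byrow = TRUE)
  dX <- (dxhat - (t1 + t2) / m) * matrix(cache$inv, m, d[3], byrow = TRUE)
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

#' Gaussian error linear unit
#'
#' Exact form `x * pnorm(x)` (no tanh approximation).
#'
#' @param x numeric vector, matrix or array.
#' @return elementwise GELU of `x`, same shape.
#' @export
gelu <- function(x) x * stats::pnorm(x)

gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

dense_forward <- function(X, W, b) {
  list(y = X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE),
       cache = X)
}

dense_backward <- function(dY, cache, W, need_dW = TRUE) {
  list(dW = if (need_dW) crossprod(cache, dY) else NULL,
       db = if (need_dW) colSums(dY) else NULL,
       dX = dY %*% t(W))
}

# logits: N x F, y: integer class indices 1..F
softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy; reduction "mean" for training, "sum" for attribution
# (per-sample gradients unscaled).
softmax_xent <- function(logits, y, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  p <- softmax_probs(logits)
  n <- nrow(p)
  per_sample <- -log(pmax(p[cbind(seq_len(n), y)], 1e-300))
  onehot <- matrix(0, n, ncol(p))
  onehot[cbind(seq_len(n), y)] <- 1
  dlogits <- p - onehot
  if (reduction == "mean") {
    list(loss = mean(per_sample), dlogits = dlogits / n, probs = p,
         per_sample = per_sample)
  } else {
    list(loss = sum(per_sample), dlogits = dlogits, probs = p,
         per_sample = per_sample)
  }
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
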