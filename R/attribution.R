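# Integrated-gradients feature attribution.
#
# For a sample x and an all-zeros baseline x', the attribution of input
# feature i is
#   (x_i - x'_i) * (1/m) * sum_k dL(x' + a_k (x - x')) / dx_i,
# with a_k the m interpolation levels linearly spaced on [0, 1] (endpoints
# included) and L the cross-entropy loss of the sample at its true label.

#' Integrated gradients for a batch of samples
#'
#' @param model a trained `decoder_model`.
#' @param X tensor `N x T x C` (z-scored like the model's training data).
#' @param y true labels (factor/character/integer).
#' @param baseline baseline matrix `T x C`; default all zeros.
#' @param m number of interpolation levels (>= 2).
#' @return array `N x T x C` of attributions.
#' @export
integrated_gradients <- function(model, X, y, baseline = NULL, m = 6L) {
  m <- as.integer(m)
  if (m < 2L) stopf("m must be >= 2")
  d <- dim(X)
  if (length(d) != 3) stopf("X must be N x T x C")
  if (is.null(baseline)) baseline <- matrix(0, d[2], d[3])
  if (!all(dim(baseline) == d[2:3])) stopf("baseline shape mismatch")
  yi <- if (is.factor(y)) as.integer(y) else
    if (is.character(y)) match(y, model$classes) else as.integer(y)
  n <- d[1]
  alphas <- seq(0, 1, length.out = m)
  base_arr <- aperm(array(baseline, c(d[2], d[3], 1)), c(3, 1, 2))
  # interpolants, grouped per sample: row index k + m*(i-1)
  Xi <- array(0, c(n * m, d[2], d[3]))
  for (i in seq_len(n)) {
    diffi <- X[i, , , drop = FALSE] - base_arr
    for (k in seq_len(m)) {
      Xi[(i - 1L) * m + k, , ] <- base_arr[1, , ] + alphas[k] * diffi[1, , ]
    }
  }
  grads <- input_gradients(model, Xi, rep(yi, each = m))
  gmean <- colMeans(array(grads, c(m, n, d[2], d[3])), dims = 1)
  diffs <- X - aperm(array(baseline, c(d[2], d[3], n)), c(3, 1, 2))
  diffs * gmean
}

#' Per-channel importance scores from integrated gradients
#'
#' Computes per-sample attributions, L1-normalizes each sample's `T x C`
#' attribution map so samples contribute on a common scale, averages over
#' the temporal dimension and then over samples, yielding one score per
#' channel. Signed averages are the headline value; the mean of absolute
#' attributions is returned alongside.
#'
#' @param model a trained `decoder_model`.
#' @param X,y test windows and their true labels.
#' @param m interpolation levels.
#' @param normalize `"l1"` (default) or `"none"`.
#' @param chunk samples per gradient batch (memory control).
#' @return data.frame `channel`, `importance` (signed), `importance_abs`.
#' @export
channel_importance <- function(model, X, y, m = 6L,
                               normalize = c("l1", "none"),
                               chunk = 100L) {
  normalize <- match.arg(normalize)
  d <- dim(X)
  if (d[1] < 1) stopf("empty test set")
  signed <- matrix(0, d[1], d[3])
  absval <- matrix(0, d[1], d[3])
  yi <- if (is.factor(y)) as.integer(y) else
    if (is.character(y)) match(y, model$classes) else as.integer(y)
  for (start in seq(1L, d[1], by = chunk)) {
    idx <- start:min(start + chunk - 1L, d[1])
    A <- integrated_gradients(model, X[idx, , , drop = FALSE], yi[idx], m = m)
    for (jj in seq_along(idx)) {
      Ai <- A[jj, , ]
      if (normalize == "l1") {
        s <- sum(abs(Ai))
        if (s > 0) Ai <- Ai / s
      }
      signed[idx[jj], ] <- colMeans(Ai)
      absval[idx[jj], ] <- colMeans(abs(Ai))
    }
  }
  data.frame(
    channel = seq_len(d[3]),
    importance = colMeans(signed),
    importance_abs = colMeans(absval)
  )
}

#' Per-fold channel importance for a cross-validation result
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @param modality modality name or index.
#' @param channels optional channel metadata to join (data.frame with
#'   `name`, `modality`, `axis`, `side`).
#' @param m interpolation levels.
#' @return data.frame `fold`, `channel`, `name`..., `importance`,
#'   `importance_abs`.
#' @export
cv_channel_importance <- function(cv, modality = 1L, channels = NULL,
                                  m = 6L) {
  folds <- cv$modalities[[modality]]$folds
  out <- do.call(rbind, lapply(folds, function(f) {
    ci <- channel_importance(f$model, f$test$X, f$test$y, m = m)
    ci$fold <- f$fold
    ci
  }))
  if (!is.null(channels)) {
    out <- cbind(out, channels[out$channel, c("name", "axis", "side")])
  }
  out[, union(c("fold", "channel"), names(out))]
}
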