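# Evaluation statistics: permutation-based empirical chance level with
# p-value and Cohen's d, the 5x2-CV F-test, the McNemar test with Cohen's
# g, percentage agreement and Cohen's kappa.

#' Permutation null distribution of a pipeline statistic
#'
#' Repeatedly re-runs a user-supplied pipeline under label permutation.
#' `stat_fun` receives a per-permutation seed and must return the statistic
#' computed with training labels permuted under that seed (e.g.
#' [cross_validate()] with `permute_train = TRUE`).
#'
#' @param stat_fun `function(perm_seed) -> numeric(1)`.
#' @param n_perm number of permutations (>= 1).
#' @param seed master seed; per-permutation seeds are derived from it.
#' @param statistic name stored with the distribution.
#' @return object of class `null_distribution`: `values`, `n_perm`,
#'   `statistic`.
#' @export
permutation_null <- function(stat_fun, n_perm, seed = 1L,
                             statistic = "accuracy") {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  values <- vapply(seq_len(n_perm),
                   function(i) stat_fun(derive_seed(seed, 111L, i)),
                   numeric(1))
  if (!all(is.finite(values))) stopf("non-finite values in null distribution")
  structure(list(values = values, n_perm = n_perm, statistic = statistic),
            class = "null_distribution")
}

#' Permutation p-value
#'
#' Counting rule: `p = #(null > observed) / n_perm`. When no null value
#' exceeds the observed one the p-value is reported as `< 1/n_perm`
#' (`display`), with `p = 0` under the plain counting estimator; the
#' optional `"plus_one"` estimator returns `(r + 1) / (n + 1)` instead.
#'
#' @param observed observed statistic.
#' @param null a `null_distribution` (or numeric vector).
#' @param estimator `"count"` (default) or `"plus_one"`.
#' @return list `p`, `n_exceed`, `n_perm`, `display`.
#' @export
perm_pvalue <- function(observed, null, estimator = c("count", "plus_one")) {
  estimator <- match.arg(estimator)
  values <- if (inherits(null, "null_distribution")) null$values else null
  if (!length(values)) stopf("empty null distribution")
  r <- sum(values > observed)
  n <- length(values)
  p <- if (estimator == "count") r / n else (r + 1) / (n + 1)
  display <- if (r == 0L && estimator == "count")
    sprintf("< %.3g", 1 / n) else sprintf("%.4g", p)
  list(p = p, n_exceed = r, n_perm = n, display = display)
}

#' Cohen's d of an observed value against a null distribution
#'
#' `d = (observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation.
#'
#' @param observed observed statistic.
#' @param null a `null_distribution` or numeric vector.
#' @return numeric effect size.
#' @export
cohens_d_vs_null <- function(observed, null) {
  values <- if (inherits(null, "null_distribution")) null$values else null
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stopf("null distribution has zero standard deviation")
  (observed - mean(values)) / s
}

#' 5x2-CV F statistic from a matrix of accuracy differences
#'
#' `f = sum(d_ij^2) / (2 * sum(s_i^2))` where `s_i^2` is the variance of
#' the two fold differences of replication i; p-value from F(10, 5).
#'
#' @param d numeric `5 x 2` matrix of per-fold accuracy differences
#'   (model A minus model B).
#' @return list `f`, `df`, `p`, `d`.
#' @export
five_by_two_ftest <- function(d) {
  d <- as.matrix(d)
  if (!all(dim(d) == c(5L, 2L))) stopf("d must be a 5 x 2 matrix")
  s2 <- apply(d, 1, stats::var)
  if (sum(s2) == 0)
    stopf("all replication variances are zero; the 5x2 F statistic is undefined")
  f <- sum(d^2) / (2 * sum(s2))
  list(f = f, df = c(10L, 5L),
       p = stats::pf(f, 10, 5, lower.tail = FALSE), d = d)
}

#' 5x2 cross-validation F-test between two classifiers
#'
#' Runs five replications of twofold cross-validation over trials. In each
#' replication the trials are split 50/50 (stratified); each builder is
#' trained on one half and tested on the other, in both directions, and the
#' per-fold accuracy difference feeds the pseudo-F statistic referenced to
#' F(10, 5).
#'
#' @param builder_a,builder_b `function(train_trials, test_trials, seed) ->
#'   accuracy`; both are evaluated on identical trial splits.
#' @param trials trial table (columns `trial`, `label`).
#' @param seed master seed.
#' @return list `f`, `df`, `p`, `d` (5 x 2 accuracy differences),
#'   `acc_a`, `acc_b`.
#' @export
five_by_two_cv_ftest <- function(builder_a, builder_b, trials, seed = 1L) {
  d <- matrix(0, 5, 2)
  acc_a <- acc_b <- matrix(0, 5, 2)
  for (i in 1:5) {
    rep_seed <- derive_seed(seed, 222L, i)
    halves <- with_seed(rep_seed, {
      h <- integer(nrow(trials))
      for (lb in unique(trials$label)) {
        idx <- sample(which(trials$label == lb))
        h[idx] <- rep_len(1:2, length(idx))
      }
      h
    })
    for (j in 1:2) {
      tr <- trials$trial[halves != j]
      te <- trials$trial[halves == j]
      fold_seed <- derive_seed(rep_seed, j)
      acc_a[i, j] <- builder_a(tr, te, fold_seed)
      acc_b[i, j] <- builder_b(tr, te, fold_seed)
      d[i, j] <- acc_a[i, j] - acc_b[i, j]
    }
  }
  out <- five_by_two_ftest(d)
  out$acc_a <- acc_a
  out$acc_b <- acc_b
  out
}

#' McNemar test between two classifiers' predictions
#'
#' Discordant counts `b` (A correct, B wrong) and `c` (A wrong, B correct);
#' continuity-corrected statistic `(|b - c| - 1)^2 / (b + c)` referenced to
#' chi-squared with 1 df; effect size Cohen's `g = |b/(b+c) - 1/2|`.
#'
#' @param preds_a,preds_b aligned prediction vectors.
#' @param truth aligned ground-truth vector.
#' @return list `b`, `c`, `chi2`, `df`, `p`, `g`.
#' @export
mcnemar_test <- function(preds_a, preds_b, truth) {
  if (length(preds_a) != length(preds_b) ||
      length(preds_a) != length(truth))
    stopf("prediction and truth vectors must have equal length")
  ok_a <- preds_a == truth
  ok_b <- preds_b == truth
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (b + cc == 0)
    stopf("no discordant predictions; the McNemar statistic is undefined")
  chi2 <- (abs(b - cc) - 1)^2 / (b + cc)
  list(b = b, c = cc, chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       g = abs(b / (b + cc) - 0.5))
}

#' Percentage agreement between two prediction vectors
#'
#' @param preds_a,preds_b aligned prediction vectors.
#' @return percentage in `[0, 100]`.
#' @export
percentage_agreement <- function(preds_a, preds_b) {
  if (length(preds_a) != length(preds_b)) stopf("length mismatch")
  100 * mean(preds_a == preds_b)
}

#' Consensus matrix between two raters
#'
#' @param preds_a,preds_b aligned prediction vectors.
#' @param classes class levels (default: union of observed values).
#' @return `F x F` count matrix, rows indexed by A, columns by B.
#' @export
consensus_matrix <- function(preds_a, preds_b, classes = NULL) {
  if (length(preds_a) != length(preds_b)) stopf("length mismatch")
  classes <- classes %||% sort(unique(c(preds_a, preds_b)))
  unclass(table(factor(preds_a, classes), factor(preds_b, classes)))
}

#' Cohen's kappa from a consensus matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement
#' fraction and `p_e = sum_k marginal_A(k) * marginal_B(k)` the chance
#' agreement.
#'
#' @param M square count matrix (rows rater A, columns rater B).
#' @return numeric kappa in `[-1, 1]`.
#' @export
kappa_from_matrix <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stopf("consensus matrix must be square")
  n <- sum(M)
  p_o <- sum(diag(M)) / n
  p_e <- sum(rowSums(M) * colSums(M)) / n^2
  if (p_e >= 1) stopf("chance agreement is 1 (both raters constant and equal); kappa undefined")
  (p_o - p_e) / (1 - p_e)
}

#' Cohen's kappa between two prediction vectors
#'
#' @param preds_a,preds_b aligned prediction vectors.
#' @param classes class levels.
#' @return numeric kappa.
#' @export
cohens_kappa <- function(preds_a, preds_b, classes = NULL) {
  kappa_from_matrix(consensus_matrix(preds_a, preds_b, classes))
}
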