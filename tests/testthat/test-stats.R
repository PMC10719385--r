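# Agreement, comparison and permutation statistics against hand-computed
# oracles and their required symmetries.

test_that("Cohen's kappa matches the hand-computed consensus-matrix oracle", {
  M <- matrix(c(20, 10, 5, 15), 2, 2)  # rows A, cols B
  # p_o = 35/50 = 0.7; p_e = (25/50)(30/50) + (25/50)(20/50) = 0.5
  expect_equal(kappa_from_matrix(M), 0.4)
  # identical non-constant raters
  expect_equal(cohens_kappa(c(1, 2, 1, 3), c(1, 2, 1, 3)), 1)
  # matrix path and vector path agree
  a <- sample(c("DII", "DV", "NoMove"), 300, TRUE)
  b <- sample(c("DII", "DV", "NoMove"), 300, TRUE)
  expect_equal(cohens_kappa(a, b),
               kappa_from_matrix(consensus_matrix(a, b)))
  # near zero for independent uniform raters
  set.seed(4)
  a <- sample(1:3, 10000, TRUE); b <- sample(1:3, 10000, TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.03)
  # undefined when both raters are constant and equal
  expect_error(cohens_kappa(rep("DII", 5), rep("DII", 5)), "undefined")
})

test_that("percentage agreement counts matching predictions", {
  expect_equal(percentage_agreement(1:4, 1:4), 100)
  expect_equal(percentage_agreement(1:4, 5:8), 0)
  expect_equal(percentage_agreement(c(1, 1, 2, 3), c(1, 2, 2, 3)), 75)
  expect_error(percentage_agreement(1:3, 1:4), "length")
})

test_that("McNemar statistic, continuity correction and Cohen's g", {
  truth <- rep(1, 20)
  a <- c(rep(1, 10), rep(1, 10))        # A correct everywhere
  b <- c(rep(0, 10), rep(1, 10))        # B wrong on first 10
  r <- mcnemar_test(a, b, truth)
  expect_equal(r$b, 10); expect_equal(r$c, 0)
  expect_equal(r$chi2, 81 / 10)
  expect_equal(r$g, 0.5)
  expect_equal(r$p, stats::pchisq(8.1, 1, lower.tail = FALSE))
  # balanced discordance
  a <- c(rep(1, 5), rep(0, 5), rep(1, 5))
  b <- c(rep(0, 5), rep(1, 5), rep(1, 5))
  r <- mcnemar_test(a, b, rep(1, 15))
  expect_equal(r$chi2, 0.1)
  expect_equal(r$g, 0)
  # swapping raters swaps b and c
  r2 <- mcnemar_test(b, a, rep(1, 15))
  expect_equal(r2$b, r$c); expect_equal(r2$c, r$b)
  expect_equal(r2$chi2, r$chi2)
  expect_error(mcnemar_test(rep(1, 4), rep(1, 4), rep(1, 4)), "undefined")
})

test_that("5x2-CV F statistic follows the stated formula", {
  d <- matrix(c(rep(0.1, 5), rep(0, 5)), 5, 2)
  # s_i^2 of (0.1, 0) = 0.005; f = 5*0.01 / (2*5*0.005) = 1
  r <- five_by_two_ftest(d)
  expect_equal(r$f, 1.0)
  expect_equal(r$df, c(10L, 5L))
  expect_equal(r$p, stats::pf(1, 10, 5, lower.tail = FALSE))
  expect_error(five_by_two_ftest(matrix(0.2, 5, 2)), "undefined")
})

test_that("5x2-CV test on synthetic builders detects a dominant classifier", {
  trials <- data.frame(trial = 1:40,
                       label = rep(c("DII", "DV"), 20))
  # builder accuracies driven by deterministic seed-dependent noise
  mk <- function(base) function(train, test, seed)
    base + mmgdecode:::with_seed(seed + base * 1e4, stats::runif(1, 0, 0.02))
  r <- five_by_two_cv_ftest(mk(0.9), mk(0.6), trials, seed = 3L)
  expect_true(r$f > 5)
  expect_lt(r$p, 0.05)
  # identical builders -> zero variances -> explicit error
  same <- function(train, test, seed) 0.8
  expect_error(five_by_two_cv_ftest(same, same, trials, seed = 3L),
               "undefined")
  # split structure: both halves partition the trials
  got <- list()
  rec <- function(train, test, seed) {
    got[[length(got) + 1L]] <<- sort(c(train, test))
    stats::runif(1)
  }
  set.seed(1)
  r2 <- five_by_two_cv_ftest(rec, mk(0.5), trials, seed = 5L)
  expect_true(all(vapply(got, identical, logical(1), y = 1:40)))
})

test_that("permutation p-value uses the counting rule with < 1/n reporting", {
  null <- structure(list(values = seq(0.2, 0.5, length.out = 1000),
                         n_perm = 1000L, statistic = "accuracy"),
                    class = "null_distribution")
  r <- perm_pvalue(0.9, null)
  expect_equal(r$p, 0)
  expect_equal(r$display, "< 0.001")
  r <- perm_pvalue(stats::median(null$values), null)
  expect_equal(r$p, 0.5, tolerance = 0.01)
  r <- perm_pvalue(0.1, null)
  expect_equal(r$p, 1.0)
  r <- perm_pvalue(0.9, null, estimator = "plus_one")
  expect_equal(r$p, 1 / 1001)
})

test_that("Cohen's d against the null uses the sample standard deviation", {
  null <- c(0.30, 0.32, 0.34, 0.36)
  expect_equal(cohens_d_vs_null(mean(null), null), 0)
  expect_equal(cohens_d_vs_null(mean(null) + stats::sd(null), null), 1)
  expect_equal(cohens_d_vs_null(0.90, null),
               (0.90 - 0.33) / stats::sd(null))
  expect_error(cohens_d_vs_null(0.5, rep(0.3, 10)), "zero standard deviation")
})

test_that("permutation null machinery is deterministic and validates input", {
  stat_fun <- function(seed) mmgdecode:::with_seed(seed, stats::runif(1))
  n1 <- permutation_null(stat_fun, 50, seed = 9L)
  n2 <- permutation_null(stat_fun, 50, seed = 9L)
  expect_identical(n1$values, n2$values)
  expect_length(n1$values, 50)
  expect_error(permutation_null(stat_fun, 0, seed = 1L), "n_perm")
})

test_that("permutation p-values are superuniform under the null", {
  # observed values drawn from the same distribution as the null
  set.seed(11)
  ps <- replicate(200, {
    null <- stats::rnorm(199)
    perm_pvalue(stats::rnorm(1), null)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("agreement statistics are invariant to class relabelling", {
  set.seed(2)
  a <- sample(c("DII", "DV", "NoMove"), 200, TRUE)
  b <- sample(c("DII", "DV", "NoMove"), 200, TRUE)
  map <- c(DII = "x1", DV = "x2", NoMove = "x3")
  expect_equal(cohens_kappa(a, b), cohens_kappa(map[a], map[b]))
  expect_equal(percentage_agreement(a, b),
               percentage_agreement(map[a], map[b]))
  truth <- sample(c("DII", "DV", "NoMove"), 200, TRUE)
  r1 <- mcnemar_test(a, b, truth)
  r2 <- mcnemar_test(map[a], map[b], map[truth])
  expect_equal(r1$chi2, r2$chi2)
})
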