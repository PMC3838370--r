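test_that("fisher_cutpoint returns the ceiling((1-q) n_D) order statistic", {
  expect_equal(fisher_cutpoint(c(0, 0, 0, 0, 0, 0, 0, 0, 5, 10)), 5)
  # constant input: cutpoint is the constant, nothing strictly exceeds it
  expect_equal(fisher_cutpoint(rep(3.5, 12)), 3.5)
  expect_equal(sum(rep(3.5, 12) > fisher_cutpoint(rep(3.5, 12))), 0)
  # 70 distinct draws: exactly 7 strict exceedances of the m = 63 order stat
  set.seed(42)
  d <- rnorm(70)
  expect_equal(sum(d > fisher_cutpoint(d)), 7)
  expect_equal(fisher_cutpoint(d), sort(d)[63])
  expect_error(fisher_cutpoint(numeric(0)), "empty")
})

test_that("fisher_sum matches hand-computed examples", {
  v <- two_group(rep(0, 10), c(rep(0, 8), 5, 10))
  expect_equal(fisher_sum(v), 1)
  # identical groups: disease sum and control penalty cancel exactly
  same <- two_group(c(rep(0, 8), 5, 10), c(rep(0, 8), 5, 10))
  expect_equal(fisher_sum(same), 0)
})

test_that("fisher_sum is translation invariant and 1-homogeneous in scale", {
  for (s in 1:5) {
    v <- rand_two_group(s, shift = 1)
    expect_equal(fisher_sum(shift_two_group(v, 100)), fisher_sum(v))
    expect_equal(fisher_sum(scale_two_group(v, 2.5)), 2.5 * fisher_sum(v))
  }
})

test_that("final-score clamping differs from summand clamping when the
           control sum is dominated by sub-median exceedances", {
  # control values above the cutpoint but below the control median get
  # clamped to zero summand-wise, so the penalty shrinks
  ctrl <- c(rep(10, 6), 2, 2, 2, 2)
  dis <- c(rep(0, 8), 3, 4)
  v <- two_group(ctrl, dis)
  expect_gte(fisher_sum(v, clamp = "summands"),
             fisher_sum(v, clamp = "final"))
  expect_gte(fisher_sum(v, clamp = "final"), 0)
})

test_that("fisher10 equals the one-sided Fisher exact test", {
  # 7 of 70 disease and 0 of 70 control values exceed the cutpoint
  p <- fisher10_table_pvalue(7, 0, 70, 70)
  expect_equal(p, prod((70 - 0:6) / (140 - 0:6)))
  # balanced symmetric table carries no evidence
  expect_gte(fisher10_table_pvalue(3, 3, 20, 20), 0.5)
  # maximal under-representation in D
  expect_equal(fisher10_table_pvalue(0, 15, 20, 15), 1)
  # agreement with stats::fisher.test on random data fixtures
  for (s in 1:5) {
    v <- rand_two_group(s, 25, 30, shift = 0.8)
    cut <- fisher_cutpoint(v$dis)
    tab <- matrix(c(sum(v$dis > cut), sum(v$dis <= cut),
                    sum(v$ctrl > cut), sum(v$ctrl <= cut)), 2)
    expect_equal(fisher10_pvalue(v),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("outlier_sum matches hand-computed examples", {
  v <- two_group(c(-1, 1, -1, 1), c(-1, 1, -1, 1))
  expect_equal(outlier_sum(v), 0)   # threshold 2.023 never exceeded
  v2 <- two_group(1:5, c(1, 2, 3, 4, 50))
  expect_equal(outlier_sum(v2), (50 - 3) / 1.4826, tolerance = 1e-10)
})

test_that("outlier_sum is affine invariant and handles degenerate MAD", {
  for (s in 1:5) {
    v <- rand_two_group(s, shift = 2)
    expect_equal(suppressWarnings(outlier_sum(two_group(3 * v$ctrl + 7,
                                                        3 * v$dis + 7))),
                 suppressWarnings(outlier_sum(v)), tolerance = 1e-10)
  }
  flat <- two_group(rep(1, 10), c(rep(1, 9), 5))
  expect_warning(val <- outlier_sum(flat), class = "fishersum_degenerate")
  expect_equal(val, 0)
})

test_that("ort matches its definition on fixtures", {
  # all disease values below the control-derived threshold
  expect_equal(ort(two_group(c(0, 5, 10, 15), c(1, 2, 3, 4))), 0)
  # regression fixture, hand-computed: threshold q75+IQR = 0.75, outliers
  # {1,1,10}, numerator 12, pooled median absolute deviation 1
  v <- two_group(c(0, 0, 0, 1, -1, 1, -1, 0), c(0, 0, 0, 1, -1, 1, -1, 10))
  expect_equal(ort(v), 12)
  for (s in 1:5) {
    w <- rand_two_group(s, shift = 2)
    expect_equal(ort(shift_two_group(w, 42)), ort(w), tolerance = 1e-10)
  }
})

test_that("padge_score behaves as a percentile-test summary", {
  x <- rnorm(20, 0, 1)
  expect_equal(padge_score(two_group(x, x)), 0)  # identical samples
  # global shift with large n: ratio terms r_P / r_0 are ~1, so the score
  # is close to the summed Bonferroni-corrected -log10 p-values
  set.seed(99)
  ctrl <- rnorm(1000)
  dis <- ctrl + 1
  v <- two_group(ctrl, dis)
  sc <- padge_score(v)
  direct <- sum(vapply(c(80, 85, 90) / 100, function(q) {
    Cp <- ctrl[ctrl >= quantile(ctrl, q)]
    Dp <- dis[dis >= quantile(dis, q)]
    p <- min(3 * stats::t.test(Dp, Cp, alternative = "greater",
                               var.equal = TRUE)$p.value, 1)
    -log10(p)
  }, numeric(1)))
  expect_equal(sc, direct, tolerance = 0.1)
  expect_equal(padge_score(shift_two_group(v, 13)), sc)
})

test_that("excess_kurtosis is the pooled moment estimator", {
  expect_equal(excess_kurtosis(two_group(c(-1, 1, -1, 1), c(-1, 1))), -2)
  set.seed(1)
  big <- two_group(rnorm(5e4), rnorm(5e4))
  expect_lt(abs(excess_kurtosis(big)), 0.05)
  v <- rand_two_group(3)
  expect_equal(excess_kurtosis(two_group(2 * v$ctrl - 5, 2 * v$dis - 5)),
               excess_kurtosis(v), tolerance = 1e-12)
  skip_if_not_installed("e1071")
  expect_equal(excess_kurtosis(v),
               e1071::kurtosis(c(v$ctrl, v$dis), type = 1))
})

test_that("bartlett_pvalue equals stats::bartlett.test and is symmetric", {
  for (s in 1:5) {
    v <- rand_two_group(s, 12, 20)
    ref <- stats::bartlett.test(list(v$ctrl, v$dis))$p.value
    expect_equal(bartlett_pvalue(v), ref, tolerance = 1e-12)
    expect_equal(bartlett_pvalue(two_group(v$dis, v$ctrl)),
                 bartlett_pvalue(v), tolerance = 1e-12)
  }
  # equal sample variances give statistic 0, p = 1
  x <- c(-1, 0, 1)
  expect_equal(bartlett_pvalue(two_group(x, 5 + x)), 1)
  # 16-fold variance inflation at n = 50 is overwhelming
  set.seed(8)
  ctrl <- as.numeric(scale(rnorm(50)))       # sample variance exactly 1
  expect_lt(bartlett_pvalue(two_group(ctrl, 4 * as.numeric(scale(rnorm(50))))),
            1e-6)
  flat <- two_group(rep(2, 5), rep(3, 5))
  expect_warning(p <- bartlett_pvalue(flat), class = "fishersum_degenerate")
  expect_equal(p, 1)
})

test_that("one-sided t-test is the pooled-variance Student test, D > C", {
  v <- two_group(c(0, 0, 1, 1), c(1, 1, 2, 2))
  expect_equal(t_test_onesided(v), pt(sqrt(6), 6, lower.tail = FALSE))
  expect_equal(t_test_onesided(v),
               stats::t.test(v$dis, v$ctrl, alternative = "greater",
                             var.equal = TRUE)$p.value, tolerance = 1e-12)
  # identical means: symmetric null, p = 0.5
  expect_equal(t_test_onesided(two_group(c(-1, 1), c(-2, 2))), 0.5)
  # one-sided direction: disease below control gives p > 0.5
  expect_gt(t_test_onesided(rand_two_group(4, shift = -2)), 0.5)
  # complementarity without ties
  for (s in 1:5) {
    v <- rand_two_group(s, shift = 0.5)
    p_up <- t_test_onesided(v)
    p_down <- stats::t.test(v$dis, v$ctrl, alternative = "less",
                            var.equal = TRUE)$p.value
    expect_equal(p_up + p_down, 1, tolerance = 1e-12)
  }
  expect_error(t_test_onesided(two_group(c(1, 1), c(1, 1))), "variance")
})

test_that("all seven statistics are invariant under adding a constant", {
  funs <- all_stat_funs()
  for (s in 1:6) {
    v <- rand_two_group(s, 12, 14, shift = runif(1, 0, 3))
    w <- shift_two_group(v, 57.3)
    for (nm in names(funs))
      expect_equal(funs[[nm]](w), funs[[nm]](v), tolerance = 1e-8,
                   label = sprintf("%s shifted (seed %d)", nm, s))
  }
})

test_that("permutation p-value for FS is calibrated and bounded", {
  # constant data: FS is 0 under every relabeling, p = 1
  flat <- two_group(rep(1, 6), rep(1, 6))
  expect_equal(permutation_pvalue_fs(flat, n_perm = 100, seed = 1), 1)
  expect_error(permutation_pvalue_fs(flat, n_perm = 50), "n_perm")
  # p in (0, 1] by the add-one construction
  p <- permutation_pvalue_fs(rand_two_group(2, shift = 3), 200, seed = 2)
  expect_gt(p, 0)
  expect_lte(p, 1)
  # near-uniform under the no-subgroup null (KS not rejected at alpha 0.01)
  set.seed(314)
  ps <- replicate(150, {
    v <- two_group(rnorm(12), rnorm(12))
    permutation_pvalue_fs(v, n_perm = 199)
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("score_all computes every requested method and isolates failures", {
  v <- rand_two_group(10, 15, 15, shift = 1)
  res <- score_all(v)
  expect_equal(nrow(res), 8)
  expect_setequal(res$method, subgroup_methods()$method)
  expect_true(all(is.finite(res$value)))
  expect_equal(nrow(score_all(v, character(0))), 0)
  expect_error(score_all(v, c("fs", "copa")), "unknown method")
  # degenerate variable: OS warns and returns 0, others still computed
  flat <- two_group(rep(1, 10), c(rep(1, 9), 6))
  res2 <- score_all(flat, c("fs", "os", "ttest"))
  expect_false(is.na(res2$note[res2$method == "os"]))
  expect_equal(res2$value[res2$method == "os"], 0)
  expect_true(is.finite(res2$value[res2$method == "fs"]))
})

test_that("two_group rejects undersized and non-finite input", {
  expect_error(two_group(1, c(1, 2)), "at least 2")
  expect_error(two_group(c(1, NA), c(1, 2)), "finite")
  expect_error(two_group(c(1, 2), c(Inf, 2)), "finite")
})
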