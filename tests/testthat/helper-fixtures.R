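# random two-group fixtures and independent oracles shared across tests

rand_two_group <- function(seed, n_C = 15, n_D = 15, shift = 0) {
  set.seed(seed)
  two_group(rnorm(n_C), rnorm(n_D) + shift)
}

shift_two_group <- function(v, b) two_group(v$ctrl + b, v$dis + b)
scale_two_group <- function(v, a) two_group(v$ctrl * a, v$dis * a)

# brute-force AUC: count concordant / tied (positive, negative) pairs
pair_count_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos)
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# brute-force hypergeometric upper tail P(X >= n11) by term-wise summation
hyper_tail_oracle <- function(n11, n12, n_D, n_C) {
  draws <- n11 + n12
  ks <- seq(n11, min(n_D, draws))
  sum(choose(n_D, ks) * choose(n_C, draws - ks)) / choose(n_C + n_D, draws)
}

# all seven statistics plus fisher10 as (name, closure) pairs for property loops
all_stat_funs <- function() {
  list(fs = fisher_sum,
       fisher10 = fisher10_pvalue,
       os = function(v) suppressWarnings(outlier_sum(v)),
       ort = function(v) suppressWarnings(ort(v)),
       padge = padge_score,
       kurtosis = excess_kurtosis,
       bartlett = bartlett_pvalue,
       ttest = t_test_onesided)
}
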