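#' Disease-group cutpoint for FisherSum and Fisher10
#'
#' Returns the order statistic of the disease values below which a fraction
#' `1 - q_frac` of the disease group lies: the m-th smallest value with
#' m = ceiling((1 - q_frac) * n_D).  Exceedance downstream is strict
#' (`x > cut`), so at most `floor(q_frac * n_D)` disease values exceed the
#' cutpoint (fewer under ties).  With the default `q_frac = 0.1` this is the
#' "90 percent of D" cutpoint targeting subgroups of roughly 10 percent.
#'
#' @param dis numeric vector of disease-group values (length >= 2).
#' @param q_frac target exceedance fraction in (0, 1); default 0.1.
#' @return The cutpoint, a single number.
#' @examples
#' fisher_cutpoint(c(0, 0, 0, 0, 0, 0, 0, 0, 5, 10))  # 5
#' @export
fisher_cutpoint <- function(dis, q_frac = 0.1) {
  dis <- as.numeric(dis)
  if (length(dis) == 0L) stop("empty disease group", call. = FALSE)
  if (!is.numeric(q_frac) || q_frac <= 0 || q_frac >= 1)
    stop("q_frac must lie in (0, 1)", call. = FALSE)
  m <- ceiling((1 - q_frac) * length(dis))
  sort(dis, partial = m)[m]
}

## internal fast paths take bare ctrl/dis vectors; exported wrappers validate

.fs <- function(ctrl, dis, q_frac = 0.1,
                w_C = 1 / length(ctrl), w_D = 1 / length(dis),
                clamp = "summands") {
  cut <- fisher_cutpoint(dis, q_frac)
  med_C <- stats::median(ctrl)
  d_exc <- dis[dis > cut] - med_C
  c_exc <- ctrl[ctrl > cut] - med_C
  if (clamp == "summands") {
    w_D * sum(pmax(d_exc, 0)) - w_C * sum(pmax(c_exc, 0))
  } else { # clamp the final score instead of the summands
    max(w_D * sum(d_exc) - w_C * sum(c_exc), 0)
  }
}

#' FisherSum score
#'
#' Weighted sum of median-centered disease values strictly above the
#' disease-group cutpoint (see [fisher_cutpoint()]), minus a penalty sum of
#' control values above the same cutpoint.  The penalty down-weights
#' variables whose up-regulated subgroup is present in both groups
#' (a non-disease-specific pattern).  After centering at the control median,
#' each summand is clamped at zero (`clamp = "summands"`, the default);
#' `clamp = "final"` instead clamps the final score.  The score is
#' translation invariant and scales linearly under positive rescaling.
#'
#' @param v a [two_group()] object.
#' @param q_frac cutpoint exceedance fraction, default 0.1.
#' @param w_C,w_D weights for the control and disease sums; the defaults
#'   1/n_C and 1/n_D keep scores comparable across designs.
#' @param clamp `"summands"` (default) or `"final"`.
#' @return Numeric score; larger values indicate stronger evidence for a
#'   disease-specific up-regulated subgroup.
#' @examples
#' v <- two_group(rep(0, 10), c(rep(0, 8), 5, 10))
#' fisher_sum(v)  # 1
#' @export
fisher_sum <- function(v, q_frac = 0.1,
                       w_C = NULL, w_D = NULL,
                       clamp = c("summands", "final")) {
  v <- as_two_group(v)
  clamp <- match.arg(clamp)
  if (is.null(w_C)) w_C <- 1 / length(v$ctrl)
  if (is.null(w_D)) w_D <- 1 / length(v$dis)
  .fs(v$ctrl, v$dis, q_frac, w_C, w_D, clamp)
}

#' One-sided Fisher exact p-value of a 2x2 exceedance table
#'
#' Upper-tail hypergeometric probability P(X >= n11) of observing at least
#' `n11` disease exceedances when `n11 + n12` of the `n_C + n_D` samples
#' exceed the cutpoint: the one-sided Fisher's exact test for
#' over-representation of exceedances in the disease group.  Vectorized.
#'
#' @param n11,n12 exceedance counts in the disease and control group.
#' @param n_D,n_C group sizes (table column margins).
#' @return One-sided p-value(s).
#' @export
fisher10_table_pvalue <- function(n11, n12, n_D, n_C) {
  stopifnot(all(n11 >= 0), all(n12 >= 0), all(n11 <= n_D), all(n12 <= n_C))
  stats::phyper(n11 - 1, n_D, n_C, n11 + n12, lower.tail = FALSE)
}

.fisher10 <- function(ctrl, dis, q_frac = 0.1) {
  cut <- fisher_cutpoint(dis, q_frac)
  fisher10_table_pvalue(sum(dis > cut), sum(ctrl > cut),
                        length(dis), length(ctrl))
}

#' Fisher10: one-sided Fisher's exact test on cutpoint exceedances
#'
#' Builds the 2x2 table of strict exceedances of the disease-group cutpoint
#' versus group membership and returns the one-sided Fisher's exact p-value
#' for over-representation of exceedances in the disease group
#' (hypergeometric upper tail).
#'
#' @inheritParams fisher_sum
#' @return One-sided p-value; smaller values indicate stronger evidence.
#' @export
fisher10_pvalue <- function(v, q_frac = 0.1) {
  v <- as_two_group(v)
  .fisher10(v$ctrl, v$dis, q_frac)
}

.os <- function(ctrl, dis) {
  pooled <- c(ctrl, dis)
  med <- stats::median(pooled)
  s <- stats::mad(pooled)           # constant 1.4826
  if (s == 0) {
    degenerate_warning("outlier_sum: pooled MAD is 0, returning 0")
    return(0)
  }
  z <- (pooled - med) / s
  thr <- stats::quantile(z, 0.75, names = FALSE) + stats::IQR(z)
  zd <- z[(length(ctrl) + 1L):length(z)]
  sum(zd[zd > thr])
}

#' Outlier sum (OS) statistic
#'
#' Robustly standardizes the pooled values (median-centered, divided by the
#' MAD with constant 1.4826) and sums the standardized disease values that
#' strictly exceed the threshold q75 + IQR of the pooled standardized
#' values.  Returns 0 (with a warning of class `"fishersum_degenerate"`)
#' when the pooled MAD is zero, and 0 when no disease value exceeds the
#' threshold.
#'
#' @param v a [two_group()] object.
#' @return Numeric score; higher values indicate stronger evidence.
#' @export
outlier_sum <- function(v) {
  v <- as_two_group(v)
  .os(v$ctrl, v$dis)
}

.ort <- function(ctrl, dis) {
  thr <- stats::quantile(ctrl, 0.75, names = FALSE) + stats::IQR(ctrl)
  out <- dis[dis > thr]
  if (length(out) == 0L) return(0)
  med_C <- stats::median(ctrl)
  med_D <- stats::median(dis)
  den <- stats::median(c(abs(dis - med_D), abs(ctrl - med_C)))
  if (den == 0) {
    degenerate_warning("ort: zero median absolute deviation, returning 0")
    return(0)
  }
  sum(out - med_C) / den
}

#' Outlier-robust t (ORT) statistic
#'
#' Variant of the outlier sum in which the outlier threshold
#' q75(ctrl) + IQR(ctrl) and the centering median are derived from the
#' control group only, avoiding the variance overestimation OS suffers when
#' a subgroup is present.  The exceedance sum is scaled by the median of
#' the pooled absolute deviations of each observation from its own group
#' median (Wu's statistic).  Returns 0 for an empty outlier set and 0 with
#' a degenerate-variable warning for a zero denominator.
#'
#' @param v a [two_group()] object.
#' @return Numeric score; higher values indicate stronger evidence.
#' @export
ort <- function(v) {
  v <- as_two_group(v)
  .ort(v$ctrl, v$dis)
}

.padge <- function(ctrl, dis, percentiles = c(80, 85, 90), eps = 0.1) {
  r0 <- mean(dis) - mean(ctrl)
  denom <- max(r0, eps)
  k <- length(percentiles)
  score <- 0
  for (P in percentiles) {
    Cp <- ctrl[ctrl >= stats::quantile(ctrl, P / 100, names = FALSE)]
    Dp <- dis[dis >= stats::quantile(dis, P / 100, names = FALSE)]
    if (length(Cp) < 2L || length(Dp) < 2L) next
    vC <- stats::var(Cp); vD <- stats::var(Dp)
    if (vC == 0 && vD == 0) next          # degenerate subset
    rP <- mean(Dp) - mean(Cp)
    if (rP <= 0) next
    p <- .t_onesided(Cp, Dp)
    p_adj <- min(k * p, 1)
    score <- score + (-log10(p_adj)) * (rP / denom)
  }
  score
}

#' PADGE-like percentile score
#'
#' Percentile analysis for differential gene expression: one-sided pooled
#' t-tests are applied to the upper-percentile subsets of each group
#' (values at or above the 80/85/90 percent within-group quantiles by
#' default), Bonferroni-corrected over the percentile series and combined
#' into the summary score sum_P (-log10 p_P) * (r_P / max(r_0, eps)) where
#' r_P is the subset mean difference and r_0 the overall mean difference.
#' Terms with non-positive subset mean difference or degenerate subsets
#' contribute zero; `eps = 0.1` floors the overall-ratio denominator.
#'
#' @param v a [two_group()] object; each group should have at least 10
#'   observations for the default percentiles.
#' @param percentiles percentile series (percent), default `c(80, 85, 90)`.
#' @param eps floor for the overall mean-difference denominator.
#' @return Numeric score; higher values indicate stronger evidence.
#' @export
padge_score <- function(v, percentiles = c(80, 85, 90), eps = 0.1) {
  v <- as_two_group(v)
  .padge(v$ctrl, v$dis, percentiles, eps)
}

.kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) stop("excess_kurtosis: zero variance", call. = FALSE)
  mean(x^4) / m2^2 - 3
}

#' Excess kurtosis of the pooled observations
#'
#' Plain moment estimator b2 - 3 = m4/m2^2 - 3 over the pooled control and
#' disease values.  Small up-regulated subgroups inflate the fourth moment,
#' so positive excess kurtosis indicates heavy-tailed variables compatible
#' with a subgroup (the one-step "PAK" reading of PACK without its
#' clustering preselection).
#'
#' @param v a [two_group()] object with at least 4 pooled observations.
#' @return Numeric score; higher values indicate stronger evidence.
#' @export
excess_kurtosis <- function(v) {
  v <- as_two_group(v)
  x <- c(v$ctrl, v$dis)
  if (length(x) < 4L) stop("excess_kurtosis needs >= 4 observations", call. = FALSE)
  .kurtosis(x)
}

.bartlett <- function(ctrl, dis) {
  n1 <- length(ctrl); n2 <- length(dis)
  v1 <- stats::var(ctrl); v2 <- stats::var(dis)
  if (v1 == 0 && v2 == 0) {
    degenerate_warning("bartlett_pvalue: both variances 0, returning p = 1")
    return(1)
  }
  if (v1 == 0 || v2 == 0) return(0)   # one group constant: maximal evidence
  N <- n1 + n2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (N - 2)
  stat <- ((N - 2) * log(sp2) - (n1 - 1) * log(v1) - (n2 - 1) * log(v2)) /
    (1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (N - 2)) / 3)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Bartlett's test for equal variances between the two groups
#'
#' Standard two-group Bartlett chi-square statistic (1 df) with its
#' upper-tail p-value.  Under normality it detects the variance inflation a
#' dysregulated subgroup induces in the disease group, in either direction.
#' Identical to `stats::bartlett.test()` on two groups.
#'
#' @param v a [two_group()] object.
#' @return Upper-tail p-value; smaller values indicate stronger evidence.
#' @export
bartlett_pvalue <- function(v) {
  v <- as_two_group(v)
  .bartlett(v$ctrl, v$dis)
}

.t_onesided <- function(ctrl, dis) {
  n1 <- length(ctrl); n2 <- length(dis)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(ctrl) + (n2 - 1) * stats::var(dis)) / df
  if (sp2 == 0) stop("t_test_onesided: zero pooled variance", call. = FALSE)
  t <- (mean(dis) - mean(ctrl)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  stats::pt(t, df, lower.tail = FALSE)
}

#' One-sided two-sample Student t-test (up-regulation in the disease group)
#'
#' Pooled-variance t statistic with n_C + n_D - 2 degrees of freedom and
#' one-sided p-value for the alternative mean(D) > mean(C).  Identical to
#' `stats::t.test(..., var.equal = TRUE, alternative = "greater")`.
#'
#' @param v a [two_group()] object.
#' @return One-sided p-value; smaller values indicate stronger evidence.
#' @export
t_test_onesided <- function(v) {
  v <- as_two_group(v)
  .t_onesided(v$ctrl, v$dis)
}

#' Permutation p-value for the FisherSum score
#'
#' Estimates P(FS_perm >= FS_obs) by permuting the group labels with fixed
#' group sizes, using the add-one estimator
#' (1 + #\{FS_perm >= FS_obs\}) / (n_perm + 1), which is always in (0, 1].
#'
#' @param v a [two_group()] object.
#' @param n_perm number of label permutations (>= 100).
#' @param seed optional integer seed for the permutation stream.
#' @inheritParams fisher_sum
#' @return Permutation p-value in (0, 1].
#' @export
permutation_pvalue_fs <- function(v, n_perm = 1000, seed = NULL,
                                  q_frac = 0.1) {
  v <- as_two_group(v)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nC <- length(v$ctrl)
  pooled <- c(v$ctrl, v$dis)
  n <- length(pooled)
  obs <- .fs(v$ctrl, v$dis, q_frac)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, nC)
    if (.fs(pooled[idx], pooled[-idx], q_frac) >= obs) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' The per-variable subgroup-detection methods
#'
#' Registry of the implemented univariate methods.  `orientation` records
#' whether larger values (`"higher_is_evidence"`, scores) or smaller values
#' (`"lower_is_evidence"`, p-values) indicate a disease-specific subgroup;
#' the evaluation harness uses it to put all methods on a common
#' evidence scale for ranking and AUC.
#'
#' @return A data frame with columns `method`, `label` and `orientation`.
#' @export
subgroup_methods <- function() {
  data.frame(
    method = c("fs", "fisher10", "os", "ort", "padge",
               "kurtosis", "bartlett", "ttest"),
    label = c("FisherSum", "Fisher10", "OS", "ORT", "PADGE",
              "Kurtosis", "Bartlett", "t-test"),
    orientation = c("higher_is_evidence", "lower_is_evidence",
                    "higher_is_evidence", "higher_is_evidence",
                    "higher_is_evidence", "higher_is_evidence",
                    "lower_is_evidence", "lower_is_evidence"),
    stringsAsFactors = FALSE
  )
}

method_fun <- function(method) {
  switch(method,
    fs = function(c, d) .fs(c, d),
    fisher10 = .fisher10,
    os = .os,
    ort = .ort,
    padge = .padge,
    kurtosis = function(c, d) .kurtosis(c(c, d)),
    bartlett = .bartlett,
    ttest = .t_onesided,
    stop(sprintf("unknown method '%s'", method), call. = FALSE)
  )
}

#' Apply a set of subgroup-detection methods to one variable
#'
#' Computes each requested method on the same control/disease split.  A
#' method failure or degenerate-variable warning is recorded per method and
#' is not fatal to the others.
#'
#' @param v a [two_group()] object.
#' @param methods character vector of method ids, a subset of
#'   `subgroup_methods()$method`; defaults to all eight.
#' @return A data frame with one row per requested method and columns
#'   `method`, `value`, `orientation`, `note` (warning or error message,
#'   `NA` when clean).
#' @export
score_all <- function(v, methods = subgroup_methods()$method) {
  v <- as_two_group(v)
  reg <- subgroup_methods()
  bad <- setdiff(methods, reg$method)
  if (length(bad))
    stop("unknown method id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(methods) == 0L)
    return(data.frame(method = character(0), value = numeric(0),
                      orientation = character(0), note = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(methods, function(m) {
    f <- method_fun(m)
    note <- NA_character_
    val <- withCallingHandlers(
      tryCatch(f(v$ctrl, v$dis), error = function(e) {
        note <<- conditionMessage(e)
        NA_real_
      }),
      warning = function(w) {
        note <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    )
    data.frame(method = m, value = val,
               orientation = reg$orientation[match(m, reg$method)],
               note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
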