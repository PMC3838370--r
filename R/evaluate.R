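#' Mann-Whitney AUC of a score vector against a binary truth
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic
#' (#concordant + 0.5 #tied) / (n1 n0) over all (positive, negative)
#' pairs, via midranks.  Scores must already be on the evidence scale
#' (larger = more evidence); flip p-values first (see
#' `evidence_scores`, done automatically by [benchmark_auc()]).
#'
#' @param scores numeric vector, larger = more evidence.
#' @param truth binary vector (0 = null variable, 1 = disease-specific
#'   subgroup variable), same length.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(2, 1, 3, 4), c(0, 1, 0, 1))  # 0.5
#' @export
auc <- function(scores, truth) {
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length", call. = FALSE)
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L)))
    stop("truth must be binary 0/1", call. = FALSE)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)               # midranks handle ties as 0.5
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Standard staircase ROC: thresholds swept from +Inf downward over the
#' unique score values, tied scores advancing TPR and FPR simultaneously
#' (diagonal segments).  The trapezoidal area under the returned polyline
#' equals [auc()] exactly.
#'
#' @inheritParams auc
#' @return A data frame with columns `fpr` and `tpr`, starting at (0, 0)
#'   and ending at (1, 1).
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t1 <- truth[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE)   # last index of each tie block
  tpr <- cumsum(t1)[keep] / n1
  fpr <- cumsum(1 - t1)[keep] / n0
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

# simulate one benchmark matrix and return per-method AUC (evidence scale)
auc_one_matrix <- function(spec, n, counts, methods, q_b, seed = NULL) {
  sim <- simulate_subgroup_matrix(spec, n = n, counts = counts, seed = seed)
  scan <- suppressWarnings(
    subgroup_scan(sim$x, sim$group, methods = methods,
                  spec = spec, q_b = q_b))
  ev <- evidence_scores(scan)
  vapply(methods, function(m) auc(ev[, m], sim$is_h1), numeric(1))
}

null_counts <- function(n_null, n_h1, q_b) {
  n_h0b <- round(q_b * n_null)
  c(n_null - n_h0b, n_h0b, n_h1)
}

#' Benchmark AUC of methods at one scenario setting
#'
#' Simulates `reps` independent benchmark matrices (default design: 1000
#' variables, 500 composite-null and 500 disease-specific, n = 70 per
#' group) and returns each method's AUC for separating the
#' disease-specific variables from the null variables, averaged over
#' replicates.
#'
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param z deviation parameter of the scenario.
#' @param methods method ids (see [subgroup_methods()]), plus `"lr"` for
#'   the likelihood-ratio oracle.
#' @param n per-group sample size.
#' @param p subgroup proportion.
#' @param q_b proportion of both-groups-contaminated variables among the
#'   nulls; `q_b = 0.5` is the composite-null benchmark, `q_b = 0` the
#'   simple null design.
#' @param n_null,n_h1 numbers of null and disease-specific variables.
#' @param reps number of replicate matrices averaged.
#' @param seed integer seed; replicate r uses `seed + r - 1`.
#' @return Named numeric vector of AUC values, one per method.
#' @examples
#' benchmark_auc("I", z = 3, methods = c("fs", "ttest"), n = 20,
#'               n_null = 40, n_h1 = 40, seed = 1)
#' @export
benchmark_auc <- function(scenario, z, methods = c("fs", "ttest"),
                          n = 70, p = 0.1, q_b = 0.5,
                          n_null = 500, n_h1 = 500,
                          reps = 1, seed = NULL) {
  spec <- scenario_spec(scenario, z, p)
  counts <- null_counts(n_null, n_h1, q_b)
  a <- vapply(seq_len(reps), function(r) {
    s <- if (is.null(seed)) NULL else seed + r - 1L
    auc_one_matrix(spec, n, counts, methods, q_b, seed = s)
  }, numeric(length(methods)))
  if (length(methods) == 1L) a <- matrix(a, nrow = 1L,
                                         dimnames = list(methods, NULL))
  rowMeans(a)
}

#' AUC-versus-deviation curves over a parameter grid
#'
#' Runs [benchmark_auc()] for every deviation value in `z_grid` (one fresh
#' matrix per grid point and replicate) and collects the AUC curves of all
#' requested methods.
#'
#' @inheritParams benchmark_auc
#' @param z_grid strictly increasing deviation values.
#' @param seed integer seed; grid point i, replicate r uses
#'   `seed + (i-1) * reps + r - 1` so points are independent.
#' @return An object of class `"auc_grid"`: a data frame with columns `z`,
#'   one AUC column per method, and the design in attributes.
#' @export
auc_grid <- function(scenario, z_grid, methods = c("fs", "ttest"),
                     n = 70, p = 0.1, q_b = 0.5,
                     n_null = 500, n_h1 = 500, reps = 1, seed = NULL) {
  if (is.unsorted(z_grid, strictly = TRUE))
    stop("z_grid must be strictly increasing", call. = FALSE)
  rows <- lapply(seq_along(z_grid), function(i) {
    s <- if (is.null(seed)) NULL else seed + (i - 1L) * reps
    benchmark_auc(scenario, z_grid[i], methods, n, p, q_b,
                  n_null, n_h1, reps, seed = s)
  })
  out <- data.frame(z = z_grid, do.call(rbind, rows), check.names = FALSE)
  attr(out, "design") <- list(scenario = scenario, n = n, p = p, q_b = q_b,
                              n_null = n_null, n_h1 = n_h1, reps = reps)
  class(out) <- c("auc_grid", "data.frame")
  out
}

#' @export
plot.auc_grid <- function(x, target = 0.95, ...) {
  methods <- setdiff(colnames(x), "z")
  d <- attr(x, "design")
  graphics::matplot(x$z, as.matrix(x[methods]), type = "l", lty = 1,
                    xlab = sprintf("deviation z (scenario %s)", d$scenario),
                    ylab = "AUC", ylim = c(0.4, 1), ...)
  graphics::abline(h = target, lty = 3)
  graphics::legend("bottomright", legend = methods, lty = 1,
                   col = seq_along(methods), bty = "n")
  invisible(x)
}

#' Smallest deviation at which a method's AUC reaches a target
#'
#' @param curve an [auc_grid()] result (or data frame with a `z` column).
#' @param method method column to inspect.
#' @param target AUC target, default 0.95.
#' @param interpolate if `TRUE`, linearly interpolate the crossing between
#'   the bracketing grid points instead of returning the grid minimum.
#' @return The smallest grid `z` with AUC >= target (or the interpolated
#'   crossing), or `Inf` if the curve never reaches the target.
#' @export
threshold_z <- function(curve, method, target = 0.95, interpolate = FALSE) {
  stopifnot(method %in% colnames(curve), nrow(curve) > 0)
  a <- curve[[method]]
  i <- which(a >= target)
  if (!length(i)) return(Inf)
  i <- i[1]
  if (!interpolate || i == 1L) return(curve$z[i])
  z0 <- curve$z[i - 1L]; z1 <- curve$z[i]
  a0 <- a[i - 1L]; a1 <- a[i]
  z0 + (target - a0) / (a1 - a0) * (z1 - z0)
}

# default deviation grids per scenario for the summary table
default_z_grid <- function(scenario) {
  switch(scenario,
    I = seq(0.2, 6, by = 0.2),
    II = seq(0.33, 9.9, by = 0.33),
    III = sort(unique(c(seq(1.1, 6, by = 0.1), 2.93, 5.33)))
  )
}

#' Method-comparison summary table (AUC benchmark)
#'
#' For each scenario: finds the smallest grid deviation z* at which the
#' likelihood-ratio oracle's AUC reaches `target`, then reports (a) every
#' method's AUC at z* and (b) every method's own smallest z reaching
#' `target` (`Inf` when never reached on the grid).  This is the standard
#' two-block comparison of the benchmark at n = 70, p = 0.1, q_b = 0.5.
#'
#' @param n,p,q_b,n_null,n_h1,reps,seed as in [benchmark_auc()].
#' @param scenarios scenarios to include.
#' @param methods method ids; the LR oracle is always added.
#' @param target AUC level defining both blocks, default 0.95.
#' @param z_grids optional named list of deviation grids per scenario;
#'   defaults to step 0.2 on (0, 6\] for I, step 0.33 on (0, 9.9\] for II,
#'   step 0.1 on (1, 6\] for III.
#' @return An object of class `"table4_report"`: list with `auc_at_lr`
#'   (methods x scenarios AUC at z*), `z_at_target` (methods x scenarios),
#'   `z_lr` (the LR crossing per scenario) and `curves` (the
#'   [auc_grid()] objects).
#' @export
table4_report <- function(n = 70, p = 0.1, q_b = 0.5,
                          scenarios = c("I", "II", "III"),
                          methods = subgroup_methods()$method,
                          target = 0.95, n_null = 500, n_h1 = 500,
                          reps = 1, seed = NULL, z_grids = NULL) {
  all_m <- unique(c("lr", methods))
  auc_at_lr <- z_at <- matrix(NA_real_, length(all_m), length(scenarios),
                              dimnames = list(all_m, scenarios))
  z_lr <- stats::setNames(numeric(length(scenarios)), scenarios)
  curves <- list()
  for (sc in scenarios) {
    grid <- if (!is.null(z_grids)) z_grids[[sc]] else default_z_grid(sc)
    s <- if (is.null(seed)) NULL else seed + 1000L * match(sc, scenarios)
    cur <- auc_grid(sc, grid, methods = all_m, n = n, p = p, q_b = q_b,
                    n_null = n_null, n_h1 = n_h1, reps = reps, seed = s)
    curves[[sc]] <- cur
    zl <- threshold_z(cur, "lr", target)
    z_lr[sc] <- zl
    row_at <- if (is.finite(zl)) which(cur$z == zl)[1] else nrow(cur)
    auc_at_lr[, sc] <- unlist(cur[row_at, all_m])
    z_at[, sc] <- vapply(all_m, function(m) threshold_z(cur, m, target),
                         numeric(1))
  }
  structure(list(auc_at_lr = auc_at_lr, z_at_target = z_at,
                 z_lr = z_lr, curves = curves, target = target,
                 design = list(n = n, p = p, q_b = q_b,
                               n_null = n_null, n_h1 = n_h1, reps = reps)),
            class = "table4_report")
}

#' @export
print.table4_report <- function(x, digits = 2, ...) {
  d <- x$design
  cat(sprintf(
    "Method comparison, n = %d per group, p = %g, q_b = %g, %d+%d variables\n",
    d$n, d$p, d$q_b, d$n_null, d$n_h1))
  cat(sprintf("\nAUC at the z where the LR oracle reaches %.2f (z* = %s):\n",
              x$target,
              paste(format(x$z_lr, digits = 3), collapse = ", ")))
  print(round(x$auc_at_lr, digits))
  cat(sprintf("\nSmallest z with AUC >= %.2f per method:\n", x$target))
  print(round(x$z_at_target, digits))
  invisible(x)
}
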