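#' Scan an expression matrix for subgroup-bearing variables
#'
#' Applies a set of univariate subgroup-detection methods independently to
#' every row (variable) of a two-group expression matrix.  This is the main
#' entry point for data analysis; for simulation benchmarking see
#' [benchmark_auc()] and [auc_grid()].
#'
#' The optional method `"lr"` (likelihood-ratio oracle) requires the true
#' generative `spec` and is only meaningful on simulated data.
#'
#' @param x numeric matrix, variables in rows, samples in columns.  All
#'   values must be finite.
#' @param group factor or character vector of per-column labels, `"C"`
#'   (control) or `"D"` (disease).
#' @param methods character vector of method ids from
#'   `subgroup_methods()$method`, plus optionally `"lr"`.
#' @param spec a [scenario_spec()]; required iff `"lr"` is requested.
#' @param q_b null-mixture proportion for the LR oracle.
#' @param q_frac FisherSum/Fisher10 cutpoint fraction.
#' @return An object of class `"subgroup_scan"`: a list with
#'   \item{scores}{numeric matrix, variables x methods (raw statistic or
#'     p-value per the method's orientation);}
#'   \item{orientation}{named character vector per method;}
#'   \item{notes}{list of per-method warning messages keyed by variable;}
#'   \item{group}{the column labels.}
#' @examples
#' sim <- simulate_subgroup_matrix(scenario_spec("I", 3), n = 20,
#'                                 counts = c(5, 5, 10), seed = 1)
#' scan <- subgroup_scan(sim$x, sim$group, methods = c("fs", "ttest"))
#' head(summary(scan))
#' @export
subgroup_scan <- function(x, group,
                          methods = subgroup_methods()$method,
                          spec = NULL, q_b = 0.5, q_frac = 0.1) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("x must be a numeric matrix (variables x samples)", call. = FALSE)
  group <- as.character(group)
  if (length(group) != ncol(x))
    stop("length(group) must equal ncol(x)", call. = FALSE)
  if (!all(group %in% c("C", "D")))
    stop("group labels must be 'C' or 'D'", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x)))
    stop("x must contain only finite values", call. = FALSE)
  reg <- subgroup_methods()
  bad <- setdiff(methods, c(reg$method, "lr"))
  if (length(bad))
    stop("unknown method id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if ("lr" %in% methods && is.null(spec))
    stop("method 'lr' needs the true scenario_spec", call. = FALSE)

  ic <- which(group == "C")
  id <- which(group == "D")
  if (length(ic) < 2L || length(id) < 2L)
    stop("need at least 2 samples per group", call. = FALSE)

  nv <- nrow(x)
  scores <- matrix(NA_real_, nv, length(methods),
                   dimnames = list(rownames(x), methods))
  notes <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) {
    f <- if (m == "lr") {
      function(ctrl, dis)
        log_likelihood_ratio(two_group(ctrl, dis), spec, q_b)
    } else if (m == "fs") {
      function(ctrl, dis) .fs(ctrl, dis, q_frac)
    } else if (m == "fisher10") {
      function(ctrl, dis) .fisher10(ctrl, dis, q_frac)
    } else method_fun(m)
    msgs <- character(0)
    vals <- withCallingHandlers(
      vapply(seq_len(nv), function(i) {
        tryCatch(f(x[i, ic], x[i, id]), error = function(e) {
          msgs <<- c(msgs, sprintf("%s: %s", i, conditionMessage(e)))
          NA_real_
        })
      }, numeric(1)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    scores[, m] <- vals
    if (length(msgs)) notes[[m]] <- msgs
  }
  orientation <- stats::setNames(
    c(reg$orientation, "higher_is_evidence")[match(methods,
                                                   c(reg$method, "lr"))],
    methods)
  structure(list(scores = scores, orientation = orientation,
                 notes = notes, group = group),
            class = "subgroup_scan")
}

# evidence scale: monotone transform so that larger = more evidence
evidence_scores <- function(scan) {
  s <- scan$scores
  flip <- scan$orientation == "lower_is_evidence"
  s[, flip] <- -s[, flip, drop = FALSE]
  s
}

#' @export
print.subgroup_scan <- function(x, ...) {
  cat(sprintf("subgroup_scan: %d variables, %d samples (%d C / %d D)\n",
              nrow(x$scores), length(x$group),
              sum(x$group == "C"), sum(x$group == "D")))
  cat("methods:", paste(colnames(x$scores), collapse = ", "), "\n")
  nwarn <- sum(lengths(x$notes))
  if (nwarn) cat(sprintf("%d per-variable warnings (see $notes)\n", nwarn))
  invisible(x)
}

#' Ranked candidate table of a subgroup scan
#'
#' @param object a [subgroup_scan()] result.
#' @param rank_by method id used to order the table; defaults to the first
#'   scanned method (variables ranked by decreasing evidence, i.e.
#'   decreasing score or increasing p-value).
#' @param ... unused.
#' @return A data frame of per-variable scores, ordered by decreasing
#'   evidence of the `rank_by` method, with a `rank` column.
#' @export
summary.subgroup_scan <- function(object, rank_by = colnames(object$scores)[1],
                                  ...) {
  stopifnot(rank_by %in% colnames(object$scores))
  ev <- evidence_scores(object)[, rank_by]
  ord <- order(ev, decreasing = TRUE)
  out <- data.frame(variable = rownames(object$scores)[ord],
                    rank = seq_along(ord),
                    object$scores[ord, , drop = FALSE],
                    row.names = NULL, check.names = FALSE)
  out
}

#' @export
as.data.frame.subgroup_scan <- function(x, ...) {
  data.frame(variable = rownames(x$scores), x$scores,
             row.names = NULL, check.names = FALSE)
}

#' Pairwise score scatter of a subgroup scan
#'
#' Plots one method's per-variable evidence against another's (p-value
#' methods shown as -log10 p), the diagnostic view used to contrast a
#' subgroup score with a global-shift test.
#'
#' @param x a [subgroup_scan()] result.
#' @param methods two method ids to plot (default: first two scanned).
#' @param ... passed to [graphics::plot()].
#' @export
plot.subgroup_scan <- function(x, methods = colnames(x$scores)[1:2], ...) {
  stopifnot(length(methods) == 2L, all(methods %in% colnames(x$scores)))
  val <- function(m) {
    v <- x$scores[, m]
    if (x$orientation[m] == "lower_is_evidence") -log10(pmax(v, 1e-300)) else v
  }
  lab <- function(m)
    if (x$orientation[m] == "lower_is_evidence")
      sprintf("-log10 p (%s)", m) else m
  graphics::plot(val(methods[1]), val(methods[2]),
                 xlab = lab(methods[1]), ylab = lab(methods[2]), ...)
  invisible(x)
}
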