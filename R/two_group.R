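#' Observations of one variable split into control and disease group
#'
#' Container for a single variable's expression values (log-intensities)
#' in a two-group comparison.  All per-variable statistics in this package
#' take such an object.  Values must be finite; variance-based tests need
#' at least two observations per group.
#'
#' @param ctrl numeric vector of control-group values (length >= 2).
#' @param dis numeric vector of disease-group values (length >= 2).
#' @return An object of class `"two_group"`: a list with components
#'   `ctrl` and `dis`.
#' @examples
#' v <- two_group(rnorm(70), rnorm(70))
#' fisher_sum(v)
#' @export
two_group <- function(ctrl, dis) {
  ctrl <- as.numeric(ctrl)
  dis <- as.numeric(dis)
  if (length(ctrl) < 2L || length(dis) < 2L)
    stop("two_group needs at least 2 observations per group", call. = FALSE)
  if (anyNA(ctrl) || anyNA(dis) || !all(is.finite(ctrl)) || !all(is.finite(dis)))
    stop("two_group values must be finite (no NA/NaN/Inf)", call. = FALSE)
  structure(list(ctrl = ctrl, dis = dis), class = "two_group")
}

#' @export
print.two_group <- function(x, ...) {
  cat(sprintf("two_group: n_C = %d, n_D = %d\n", length(x$ctrl), length(x$dis)))
  invisible(x)
}

as_two_group <- function(v) {
  if (inherits(v, "two_group")) return(v)
  if (is.list(v) && all(c("ctrl", "dis") %in% names(v)))
    return(two_group(v$ctrl, v$dis))
  stop("expected a two_group object", call. = FALSE)
}

# warning subclass used for degenerate variables (MAD = 0, zero denominators)
degenerate_warning <- function(msg) {
  warning(warningCondition(msg, class = "fishersum_degenerate"))
}
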