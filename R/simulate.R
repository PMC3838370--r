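# random draws from the subgroup distribution of a scenario
rsubgroup <- function(spec, m) {
  switch(spec$scenario,
    I = stats::rnorm(m, mean = spec$z),
    II = stats::rnorm(m) + stats::runif(m, 0, spec$z),
    III = stats::rnorm(m, sd = spec$z)
  )
}

#' Simulate a benchmark expression matrix with planted subgroups
#'
#' Generates independent variables over a balanced two-group design
#' (n controls "C", n diseased "D") under three distributional patterns:
#' \describe{
#'   \item{H0a}{no subgroups at all: every observation ~ N(0,1);}
#'   \item{H0b}{non-disease-specific subgroup: k = round(p n) planted
#'     subgroup members in *both* groups;}
#'   \item{H1}{disease-specific subgroup: k planted members in D only.}
#' }
#' Planted members are drawn from the scenario's subgroup distribution
#' ([subgroup_density()]); all remaining observations are iid N(0,1).
#' Rows are ordered H0a, H0b, H1 so the default design (250/250/500) yields
#' the truth vector of 500 nulls followed by 500 alternatives.  Planted
#' positions are the last k columns of each group; all statistics here are
#' permutation invariant within groups, so the fixed placement is
#' harmless and keeps the masks simple.
#'
#' @param spec a [scenario_spec()].
#' @param n per-group sample size (n_C = n_D = n); default 70.
#' @param counts named or unnamed integer vector `(n_H0a, n_H0b, n_H1)`;
#'   default `c(250, 250, 500)`, i.e. 1000 variables with a composite null
#'   of q_b = 0.5.
#' @param seed optional integer seed; fixed seed gives bit-identical output.
#' @return An object of class `"subgroup_sim"`: a list with
#'   \item{x}{numeric matrix, variables x samples;}
#'   \item{group}{factor of column labels, `"C"` then `"D"`;}
#'   \item{truth}{character vector per row, `"H0a"`/`"H0b"`/`"H1"`;}
#'   \item{is_h1}{binary truth vector (1 = disease-specific subgroup);}
#'   \item{mask}{list per row of planted column indices;}
#'   \item{spec, n, counts}{the design.}
#' @examples
#' sim <- simulate_subgroup_matrix(scenario_spec("I", 2), n = 20,
#'                                 counts = c(5, 5, 10), seed = 1)
#' dim(sim$x)
#' @export
simulate_subgroup_matrix <- function(spec, n = 70,
                                     counts = c(250, 250, 500),
                                     seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(counts < 0) || sum(counts) < 1L)
    stop("counts must be three nonnegative integers summing to >= 1",
         call. = FALSE)
  if (n < 2) stop("need n >= 2 per group", call. = FALSE)
  k <- round(spec$p * n)
  if (k < 1 && (counts[2] > 0 || counts[3] > 0))
    stop("round(p * n) must be >= 1 when subgroup-bearing rows are requested",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  nv <- sum(counts)
  x <- matrix(stats::rnorm(nv * 2 * n), nrow = nv, ncol = 2 * n)
  truth <- rep(c("H0a", "H0b", "H1"), counts)

  cols_C <- seq.int(n - k + 1, n)              # last k control columns
  cols_D <- seq.int(2 * n - k + 1, 2 * n)      # last k disease columns
  h0b <- which(truth == "H0b")
  h1 <- which(truth == "H1")
  if (length(h0b)) {
    x[h0b, cols_C] <- rsubgroup(spec, length(h0b) * k)
    x[h0b, cols_D] <- rsubgroup(spec, length(h0b) * k)
  }
  if (length(h1))
    x[h1, cols_D] <- rsubgroup(spec, length(h1) * k)

  mask <- vector("list", nv)
  mask[h0b] <- list(c(cols_C, cols_D))
  mask[h1] <- list(cols_D)
  mask[truth == "H0a"] <- list(integer(0))

  rownames(x) <- sprintf("var%04d", seq_len(nv))
  group <- factor(rep(c("C", "D"), each = n), levels = c("C", "D"))
  colnames(x) <- paste0(rep(c("C", "D"), each = n), seq_len(n))

  structure(list(x = x, group = group, truth = truth,
                 is_h1 = as.integer(truth == "H1"), mask = mask,
                 spec = spec, n = n, counts = counts),
            class = "subgroup_sim")
}

#' @export
print.subgroup_sim <- function(x, ...) {
  cat(sprintf(
    "subgroup_sim: %d variables x %d samples (n = %d per group)\n",
    nrow(x$x), ncol(x$x), x$n))
  cat(sprintf("  patterns: %d H0a, %d H0b, %d H1; ",
              x$counts[1], x$counts[2], x$counts[3]))
  print(x$spec)
  invisible(x)
}
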