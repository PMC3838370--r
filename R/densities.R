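#' Scenario specification for the subgroup distribution
#'
#' The subgroup members of a contaminated variable deviate from the
#' standard-normal background according to one of three scenarios:
#' \describe{
#'   \item{I}{location shift, subgroup ~ N(delta, 1), `z = delta > 0`;}
#'   \item{II}{simultaneous mean and variance increase, subgroup ~
#'     N(0,1) + U\[0, b\], `z = b > 0`;}
#'   \item{III}{pure variance inflation, subgroup ~ N(0, sigma^2),
#'     `z = sigma > 1`.}
#' }
#' `p` is the subgroup proportion within a group.
#'
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param z deviation parameter (delta, b, or sigma by scenario).
#' @param p subgroup proportion in (0, 1].
#' @return An object of class `"scenario_spec"`.
#' @examples
#' scenario_spec("I", z = 2, p = 0.1)
#' @export
scenario_spec <- function(scenario = c("I", "II", "III"), z, p = 0.1) {
  scenario <- match.arg(scenario)
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("z must be a single finite number", call. = FALSE)
  if (scenario %in% c("I", "II") && z <= 0)
    stop(sprintf("scenario %s requires z > 0", scenario), call. = FALSE)
  if (scenario == "III" && z <= 1)
    stop("scenario III requires sigma > 1", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("p must lie in (0, 1]", call. = FALSE)
  structure(list(scenario = scenario, z = z, p = p), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  par_name <- switch(x$scenario, I = "delta", II = "b", III = "sigma")
  cat(sprintf("scenario %s: %s = %g, subgroup proportion p = %g\n",
              x$scenario, par_name, x$z, x$p))
  invisible(x)
}

#' Background density: standard normal
#'
#' Density of the uncontaminated observations (and of the whole control
#' group for disease-specific variables).
#'
#' @param x numeric vector of evaluation points.
#' @param log return the log density.
#' @return phi(x), the standard normal density.
#' @export
f0_density <- function(x, log = FALSE) stats::dnorm(x, log = log)

# log of Phi(x) - Phi(x - b), computed from normal tail log-probabilities
# with log-space subtraction so extreme x do not underflow to log(0)
log_uniform_normal_conv <- function(x, b) {
  upper <- x >= b / 2
  la <- lb <- numeric(length(x))
  # difference of upper tails for large x, of lower tails for small x
  la[upper] <- stats::pnorm(x[upper] - b, lower.tail = FALSE, log.p = TRUE)
  lb[upper] <- stats::pnorm(x[upper], lower.tail = FALSE, log.p = TRUE)
  la[!upper] <- stats::pnorm(x[!upper], log.p = TRUE)
  lb[!upper] <- stats::pnorm(x[!upper] - b, log.p = TRUE)
  la + log1p(-exp(lb - la)) - log(b)
}

#' Density of the subgroup distribution
#'
#' Scenario I: N(delta, 1).  Scenario II: exact closed-form convolution of
#' N(0,1) with U\[0, b\], density (Phi(x) - Phi(x - b)) / b.  Scenario III:
#' N(0, sigma^2).
#'
#' @param spec a [scenario_spec()].
#' @param x numeric vector of evaluation points.
#' @param log return the log density.
#' @return Density values at `x`.
#' @export
subgroup_density <- function(spec, x, log = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  ld <- switch(spec$scenario,
    I = stats::dnorm(x - spec$z, log = TRUE),
    II = log_uniform_normal_conv(x, spec$z),
    III = stats::dnorm(x / spec$z, log = TRUE) - log(spec$z)
  )
  if (log) ld else exp(ld)
}

#' Density of a contaminated (subgroup-bearing) group
#'
#' Mixture density f1(x) = (1 - p) f0(x) + p d_s(x) of the background and
#' the scenario's subgroup distribution; this is the disease-group density
#' of a disease-specific variable and the density of both groups for a
#' non-disease-specific variable.
#'
#' @inheritParams subgroup_density
#' @return Density values at `x`.
#' @export
f1_density <- function(spec, x, log = FALSE) {
  lf0 <- stats::dnorm(x, log = TRUE)
  ld <- subgroup_density(spec, x, log = TRUE)
  # pairwise log-sum-exp of log(1-p)+lf0 and log(p)+ld
  a <- log1p(-spec$p) + lf0
  b <- log(spec$p) + ld
  hi <- pmax(a, b)
  lf1 <- hi + log1p(exp(pmin(a, b) - hi))
  if (log) lf1 else exp(lf1)
}

logsumexp2 <- function(a, b) {
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  ifelse(is.infinite(hi) & hi < 0, -Inf, hi + log1p(exp(lo - hi)))
}

#' Log likelihood ratio against the composite null (performance oracle)
#'
#' For a variable with known generative parameters, the likelihood ratio of
#' the disease-specific subgroup pattern (control ~ f0, disease ~ f1)
#' against the composite null that mixes "no subgroup anywhere" (all
#' observations ~ f0, weight 1 - q_b) and "subgroups in both groups" (all
#' observations ~ f1, weight q_b):
#' log LR = log L1 - log\[(1 - q_b) L0a + q_b L0b\], combined in log space.
#' By the Neyman-Pearson lemma its AUC upper-bounds every method in the
#' simulation benchmark; it is not applicable to real data, where the true
#' subgroup distribution is unknown.
#'
#' @param v a [two_group()] object.
#' @param spec a [scenario_spec()] holding the true scenario, deviation and
#'   subgroup proportion.
#' @param q_b proportion of the both-groups-contaminated pattern among the
#'   null variables, in \[0, 1\]; default 0.5.
#' @return log LR, a single finite number.
#' @export
log_likelihood_ratio <- function(v, spec, q_b = 0.5) {
  v <- as_two_group(v)
  stopifnot(inherits(spec, "scenario_spec"),
            is.numeric(q_b), length(q_b) == 1L, q_b >= 0, q_b <= 1)
  lf0_c <- sum(stats::dnorm(v$ctrl, log = TRUE))
  lf0_d <- sum(stats::dnorm(v$dis, log = TRUE))
  lf1_c <- sum(f1_density(spec, v$ctrl, log = TRUE))
  lf1_d <- sum(f1_density(spec, v$dis, log = TRUE))
  logL1 <- lf0_c + lf1_d
  logL0a <- lf0_c + lf0_d
  logL0b <- lf1_c + lf1_d
  logL0 <- if (q_b == 0) logL0a
           else if (q_b == 1) logL0b
           else logsumexp2(log1p(-q_b) + logL0a, log(q_b) + logL0b)
  logL1 - logL0
}
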