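# Expected burden of private mutations: the fraction of a newly sequenced
# individual's heterozygous sites that are singletons in the combined sample
# with the n individuals sequenced before it.

#' Expected burden of private mutations, constant population size
#'
#' Under constant population size the expected proportion of the (n+1)-st
#' individual's heterozygous sites that are novel (singletons in the combined
#' sample of `n + 1` diploids) has the closed form
#' `E[alpha] = E[s]/E[h] = 2/(2n + 1)`: the expected folded singleton count
#' `theta * (1 + 1/(2n+1))` is shared equally among the `n + 1` exchangeable
#' individuals, giving `E[s] = 2*theta/(2n+1)` private singletons against
#' `E[h] = theta` heterozygous sites.
#'
#' @param n Number of previously sequenced diploid individuals (`>= 1`,
#'   vectorized).
#' @return Expected proportion(s) in `(0, 1]` (dimensionless; multiply by 100
#'   for the conventional percentage).
#' @examples
#' 100 * expected_alpha_constant(c(100, 492, 1000, 4299, 10000))
#' @export
expected_alpha_constant <- function(n) {
  if (!is.numeric(n) || any(n < 1)) stop("n must be >= 1")
  2 / (2 * n + 1)
}

#' Expected burden of private mutations, general demographic model
#'
#' For an arbitrary piecewise history the expected burden is
#' `E[alpha] = (1/(n+1)) * (E[T_{2n+2,1}] + E[T_{2n+2,2n+1}]) / E[T_{2,1}]`:
#' folded singletons of the `2n + 2`-chromosome sample arise on branches
#' subtending 1 or `2n + 1` tips, each individual owns `1/(n+1)` of them by
#' exchangeability, and heterozygosity of one individual is proportional to
#' the two-tip tree length `E[T_{2,1}]` (which the model rescales, so it is
#' computed, not fixed at 2).
#'
#' @param model A [demographic_model()].
#' @param n Number of previously sequenced diploid individuals (`>= 1`).
#' @return Expected proportion in `(0, 1]`.
#' @export
expected_alpha_general <- function(model, n) {
  stopifnot(inherits(model, "demographic_model"))
  n <- as.integer(n)
  if (length(n) != 1L || n < 1L) stop("n must be a single integer >= 1")
  p <- 2L * n + 2L
  top <- expected_branch_lengths(model, p, qs = c(1L, p - 1L))
  bot <- expected_branch_lengths(model, 2L, qs = 1L)
  (1 / (n + 1)) * sum(top$value) / bot$value
}

#' Expected burden across a range of prior sample sizes
#'
#' Evaluates [expected_alpha_general()] at each `n` and returns a tidy table,
#' e.g. for the classical grid `n = 100, 492, 1000, 4299, 10000`.
#'
#' @inheritParams expected_alpha_general
#' @param ns Ascending vector of prior sample sizes.
#' @return `data.frame` with columns `model`, `n`, `alpha` (proportion) and
#'   `alpha_percent`; `alpha` is strictly decreasing in `n`.
#' @export
burden_curve <- function(model, ns) {
  stopifnot(inherits(model, "demographic_model"), length(ns) >= 1)
  if (is.unsorted(ns, strictly = TRUE)) stop("ns must be strictly ascending")
  alpha <- vapply(ns, function(n) expected_alpha_general(model, n), numeric(1))
  data.frame(model = if (nzchar(model$label)) model$label else "model",
             n = as.integer(ns), alpha = alpha, alpha_percent = 100 * alpha)
}
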