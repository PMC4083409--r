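# Probabilistic subsampling ("projection") of folded site-frequency data to a
# common chromosome count. Each SNV with j minor alleles among n successfully
# genotyped chromosomes contributes, to every minor-count class x of an
# m-chromosome subsample, the hypergeometric probability of drawing x copies
# of either allele labelling, folded onto the minor class.

# log C(a, b) with the convention C(a, b) = 0 for b < 0 or b > a
.lch <- function(a, b) {
  out <- rep(-Inf, length(b))
  ok <- b >= 0 & b <= a
  out[ok] <- lchoose(a, b[ok])
  out
}

#' Project a folded allele count onto a smaller subsample
#'
#' For a SNV with `j` minor alleles out of `n` successfully genotyped
#' chromosomes, returns the probability that a uniform random subsample of
#' `m` chromosomes contains `x` minor alleles, for `x = 0..floor(m/2)`:
#' \deqn{P(x) = \frac{1}{1+\delta(x, m-x)}
#'   \frac{{j \choose x}{n-j \choose m-x} + {j \choose m-x}{n-j \choose x}}
#'        {{n \choose m}}}
#' with \eqn{\delta(a,b) = 1} iff \eqn{a = b} and \eqn{{a \choose b} = 0} for
#' \eqn{b > a}. The two terms fold the subsample's count of the original
#' minor allele (`x` or `m - x` copies) onto the subsample's minor class; the
#' \eqn{\delta} factor stops the self-complementary class `x = m/2` from
#' being counted twice. The vector sums to exactly 1.
#'
#' @param j Minor allele count in the full data (`0 <= j <= n/2`).
#' @param n Successfully genotyped chromosomes (`>= 2`).
#' @param m Target subsample size in chromosomes (`2 <= m <= n`).
#' @return Numeric probability vector named by minor count `0..floor(m/2)`.
#' @examples
#' project_folded(2, 4, 2)  # 1/3 monomorphic, 2/3 singleton
#' @export
project_folded <- function(j, n, m) {
  stopifnot(length(j) == 1, length(n) == 1, length(m) == 1)
  if (m > n) stop("target size m must not exceed the called count n")
  if (m < 1 || n < 2) stop("need m >= 1 and n >= 2")
  if (j < 0 || j > n / 2) stop("j must be a minor count: 0 <= j <= n/2")
  x <- 0:(m %/% 2)
  if (n <= 50) {
    # all binomials are exact integers in double precision here, so the
    # ratio is correctly rounded — matches exhaustive enumeration bit for bit
    ch <- function(a, b) ifelse(b >= 0 & b <= a, choose(a, b), 0)
    num <- ch(j, x) * ch(n - j, m - x) + ch(j, m - x) * ch(n - j, x)
    p <- num / choose(n, m) / (1 + (x == m - x))
  } else {
    lnm <- lchoose(n, m)
    term1 <- exp(.lch(j, x) + .lch(n - j, m - x) - lnm)
    term2 <- exp(.lch(j, m - x) + .lch(n - j, x) - lnm)
    p <- (term1 + term2) / (1 + (x == m - x))
  }
  names(p) <- x
  p
}

#' Project a folded SFS to a smaller sample size
#'
#' Pushes each minor-count class of a folded spectrum at `n` chromosomes
#' through [project_folded()] and sums, giving the expected folded spectrum
#' of a random `m`-chromosome subsample. For a normalized input the result
#' is renormalized over segregating classes (`x >= 1`), i.e. conditioned on
#' the site still segregating in the subsample.
#'
#' @param sfs A [folded_sfs()] at `n >= m` chromosomes.
#' @param m Target chromosome count.
#' @return A [folded_sfs()] at `m` chromosomes with the same `normalized`
#'   flag as the input.
#' @export
project_sfs <- function(sfs, m) {
  stopifnot(inherits(sfs, "folded_sfs"))
  m <- as.integer(m)
  if (m > sfs$m) stop("target size m must not exceed the source size")
  mass <- numeric(m %/% 2 + 1L)
  for (j in which(sfs$mass > 0) - 1L) {
    mass <- mass + sfs$mass[j + 1L] * project_folded(j, sfs$m, m)
  }
  if (sfs$normalized) {
    mass[1] <- 0
    mass <- mass / sum(mass)
  }
  folded_sfs(mass, m, normalized = sfs$normalized)
}

#' Project a set of SNV counts to a common folded spectrum
#'
#' Applies [project_folded()] independently to each SNV (the projection
#' treats sites as unlinked) and sums the probability vectors into a folded
#' SFS at `m` chromosomes. SNVs with fewer than `max(m, min_called)`
#' successful genotype calls are dropped first — the quality filter used when
#' heterogeneous call counts are reduced to one sample size. Mass that
#' becomes monomorphic in the subsample is kept in the `x = 0` class of the
#' result, so total mass equals the number of SNVs retained.
#'
#' @param snvs `data.frame` with columns `j` (minor allele count) and
#'   `n_called` (successful genotype count in chromosomes) — one row per SNV.
#' @param m Target chromosome count (`>= 2`).
#' @param min_called Minimum successful call count to retain a SNV
#'   (default `m`; values below `m` are raised to `m` since projection
#'   requires `n >= m`).
#' @return A [folded_sfs()] (unnormalized) with attributes `n_snvs_used` and
#'   `n_snvs_dropped`.
#' @export
project_dataset <- function(snvs, m, min_called = m) {
  stopifnot(is.data.frame(snvs), all(c("j", "n_called") %in% names(snvs)))
  m <- as.integer(m)
  if (m < 2) stop("m must be at least 2")
  thr <- max(m, min_called)
  keep <- snvs$n_called >= thr
  if (!any(keep)) stop("no SNVs left after the min_called filter")
  kept <- snvs[keep, , drop = FALSE]
  mass <- numeric(m %/% 2 + 1L)
  # aggregate identical (j, n_called) pairs: one projection per unique pair
  key <- paste(kept$j, kept$n_called)
  for (grp in split(seq_len(nrow(kept)), key)) {
    w <- length(grp)
    mass <- mass + w * project_folded(kept$j[grp[1]], kept$n_called[grp[1]], m)
  }
  out <- folded_sfs(mass, m, normalized = FALSE)
  attr(out, "n_snvs_used") <- sum(keep)
  attr(out, "n_snvs_dropped") <- sum(!keep)
  out
}
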