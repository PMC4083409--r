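# Empirical per-individual burden of private mutations from a diploid
# genotype panel: for each individual, the proportion of its heterozygous
# sites whose minor allele count among all called chromosomes at that site is
# exactly 1 (i.e. the heterozygote's own copy is the only one in the sample).
# Missing genotypes are discarded site-by-site, so per-site sample sizes vary.

# per-SNV minor allele count among called chromosomes, given dosage matrix
.minor_counts <- function(gm) {
  called <- rowSums(!is.na(gm))            # called individuals per SNV
  dose <- rowSums(gm, na.rm = TRUE)        # copies of the designated allele
  pmin(dose, 2 * called - dose)            # fold onto the observed minor
}

#' Per-individual burden of private mutations
#'
#' `individual_alpha()` computes, for one individual, the proportion of its
#' heterozygous sites that are singletons: sites where the minor allele count
#' over all called chromosomes equals 1. SNVs at which the individual itself
#' is missing are skipped; at other SNVs, missing calls in the rest of the
#' panel simply reduce the called-chromosome count. `panel_alpha()` returns
#' the vector over all individuals, with `NA` for individuals that have no
#' usable heterozygous site (their burden is undefined).
#'
#' @param gm Genotype matrix: SNVs x individuals, minor-allele dosage
#'   0/1/2 or `NA`.
#' @param i Individual (column) index.
#' @return `individual_alpha()`: a proportion in `[0, 1]`, or `NA` if the
#'   individual has no heterozygous site. `panel_alpha()`: numeric vector of
#'   length `ncol(gm)`.
#' @export
individual_alpha <- function(gm, i) {
  panel_alpha(gm)[i]
}

#' @rdname individual_alpha
#' @export
panel_alpha <- function(gm) {
  stopifnot(is.matrix(gm))
  mc <- .minor_counts(gm)
  het <- !is.na(gm) & gm == 1L
  n_het <- colSums(het)
  n_priv <- colSums(het & mc == 1L)
  ifelse(n_het > 0L, n_priv / n_het, NA_real_)
}

# Summarize a vector of per-individual alphas into a burden_result
.burden_summary <- function(alpha, n_snvs, label = "") {
  used <- alpha[!is.na(alpha)]
  structure(list(alpha = alpha,
                 mean = mean(used),
                 sd = stats::sd(used),
                 n_individuals = length(alpha),
                 n_excluded = sum(is.na(alpha)),
                 n_snvs = n_snvs,
                 boot_mean = NA_real_, boot_se = NA_real_, n_boot = 0L,
                 label = label),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf(
    "Burden of private mutations%s: mean %.3f%% (SD %.3f%%) over %d individuals",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    100 * x$mean, 100 * x$sd, x$n_individuals - x$n_excluded))
  if (x$n_excluded > 0) cat(sprintf(" (%d excluded, no het sites)",
                                    x$n_excluded))
  cat(sprintf("; %d SNVs", x$n_snvs))
  if (x$n_boot > 0) cat(sprintf("; bootstrap SE %.3f%% (%d resamples)",
                                100 * x$boot_se, x$n_boot))
  cat("\n")
  invisible(x)
}

#' Burden estimate for a full panel
#'
#' Computes per-individual burdens over the whole panel and summarizes them:
#' mean across individuals, standard deviation with the `n - 1` denominator
#' (individuals without a heterozygous site are excluded and counted), and
#' optionally a bootstrap standard error from [bootstrap_se()].
#'
#' @inheritParams individual_alpha
#' @param n_boot Number of SNV bootstrap resamples (0 = skip).
#' @param seed RNG seed for the bootstrap.
#' @param label Label carried into the result.
#' @return An object of class `"burden_result"`.
#' @export
burden_estimate <- function(gm, n_boot = 0L, seed = 1L, label = "") {
  res <- .burden_summary(panel_alpha(gm), nrow(gm), label)
  if (n_boot > 0L) {
    bs <- bootstrap_se(gm, n_boot = n_boot, seed = seed)
    res$boot_mean <- bs$boot_mean
    res$boot_se <- bs$boot_se
    res$n_boot <- bs$n_boot
  }
  res
}

#' Burden at a smaller sample size by downsampling individuals
#'
#' Draws `m_individuals` of the panel's individuals at random, recomputes
#' singleton status within the subset (a variant private to the subset may
#' not be private to the full panel and vice versa), and averages the
#' per-individual burdens. Repeated over `reps` subsets; the pooled
#' per-individual values are summarized as in [burden_estimate()]. The
#' result estimates the burden at `n = m_individuals - 1` prior individuals.
#'
#' @inheritParams individual_alpha
#' @param m_individuals Subset size (`2 <= m_individuals <= ncol(gm)`).
#' @param reps Number of random subsets to average over (default 10; use 1
#'   for a single-draw estimate).
#' @param seed RNG seed.
#' @param label Label carried into the result.
#' @return A `"burden_result"`; `n_individuals` is `m_individuals`, and the
#'   `alpha` field pools the per-individual values across subsets.
#' @export
downsample_alpha <- function(gm, m_individuals, reps = 10L, seed = 1L,
                             label = "") {
  stopifnot(is.matrix(gm))
  m_individuals <- as.integer(m_individuals)
  if (m_individuals < 2) stop("m_individuals must be at least 2")
  if (m_individuals > ncol(gm)) {
    stop("m_individuals exceeds the panel size ", ncol(gm))
  }
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  if (m_individuals == ncol(gm)) reps <- 1L   # every draw is the full panel
  alphas <- lapply(seq_len(reps), function(r) {
    idx <- if (m_individuals == ncol(gm)) seq_len(ncol(gm)) else
      sample.int(ncol(gm), m_individuals)
    panel_alpha(gm[, idx, drop = FALSE])
  })
  res <- .burden_summary(unlist(alphas), nrow(gm), label)
  res$n_individuals <- m_individuals
  res$n_excluded <- as.integer(res$n_excluded / reps)
  res
}

#' Bootstrap standard error of the mean burden
#'
#' Resamples SNVs (sites) with replacement `n_boot` times; for each resample
#' the mean per-individual burden is recomputed, and the standard deviation
#' of these bootstrap means (with the `n_boot - 1` denominator) estimates the
#' standard error of the panel mean due to the finite number of sites.
#'
#' @inheritParams individual_alpha
#' @param n_boot Number of bootstrap resamples (`>= 2`, conventionally 1000).
#' @param seed RNG seed.
#' @return List with `boot_mean`, `boot_se`, `n_boot`.
#' @export
bootstrap_se <- function(gm, n_boot = 1000L, seed = 1L) {
  stopifnot(is.matrix(gm))
  n_boot <- as.integer(n_boot)
  if (n_boot < 2) stop("n_boot must be at least 2")
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  n_snv <- nrow(gm)
  means <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n_snv, n_snv, replace = TRUE)
    a <- panel_alpha(gm[idx, , drop = FALSE])
    mean(a, na.rm = TRUE)
  }, numeric(1))
  list(boot_mean = mean(means), boot_se = stats::sd(means), n_boot = n_boot)
}

#' Fold difference between two burden estimates
#'
#' Ratio of mean burdens (first over second), e.g. to compare functional
#' categories under different strengths of purifying selection. When both
#' results carry bootstrap standard errors, a delta-method standard error of
#' the ratio is attached: `SE(r) = r * sqrt((se1/m1)^2 + (se2/m2)^2)`.
#'
#' @param r1,r2 `"burden_result"` objects (numerator, denominator).
#' @return List with `ratio` and `se` (`NA` if either input lacks a
#'   bootstrap SE).
#' @export
category_ratio <- function(r1, r2) {
  stopifnot(inherits(r1, "burden_result"), inherits(r2, "burden_result"))
  if (!(r1$mean > 0) || !(r2$mean > 0)) {
    stop("both mean burdens must be positive")
  }
  ratio <- r1$mean / r2$mean
  se <- if (r1$n_boot > 0 && r2$n_boot > 0) {
    ratio * sqrt((r1$boot_se / r1$mean)^2 + (r2$boot_se / r2$mean)^2)
  } else NA_real_
  list(ratio = ratio, se = se)
}
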