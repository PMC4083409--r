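# Simulation of diploid genotype panels with the statistical structure the
# burden estimator assumes: per-SNV minor allele counts drawn from a folded
# SFS, minor alleles placed uniformly at random among chromosomes (each
# chromosome carries at most one copy — biallelic SNV semantics), chromosomes
# paired into individuals, and missingness applied to whole genotypes (both
# chromosomes of an individual together). Also houses the Monte-Carlo
# coalescent simulator used as an independent check on the exact expectation
# engine.

#' Specify a synthetic genotype panel
#'
#' Bundles everything needed to simulate a panel: the number of diploid
#' individuals, the number of segregating SNVs, the source folded SFS the
#' minor counts are drawn from (either a [folded_sfs()] at `2*n_individuals`
#' chromosomes or a [demographic_model()] from which it is computed), a
#' per-genotype missingness rate, and a seed. Fixing the SNV count rather
#' than a mutation rate keeps the scale-free burden statistic free of any
#' unneeded `theta`.
#'
#' @param n_individuals Diploid individuals (`>= 2`).
#' @param n_snvs Segregating SNVs (`>= 1`).
#' @param sfs A [folded_sfs()] at `m = 2*n_individuals`, or a
#'   [demographic_model()] (the expected folded SFS is computed from it).
#' @param missing_rate Probability a genotype (both chromosomes of one
#'   individual at one SNV) is missing, in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @param label Free-text label, e.g. `"NR-like"`.
#' @return An object of class `"panel_spec"`.
#' @export
panel_spec <- function(n_individuals, n_snvs, sfs, missing_rate = 0,
                       seed = 1L, label = "") {
  n_individuals <- as.integer(n_individuals)
  n_snvs <- as.integer(n_snvs)
  stopifnot(n_individuals >= 2, n_snvs >= 1,
            missing_rate >= 0, missing_rate < 1)
  if (inherits(sfs, "demographic_model")) {
    sfs <- expected_folded_sfs(sfs, 2L * n_individuals, normalized = TRUE)
  }
  stopifnot(inherits(sfs, "folded_sfs"))
  if (sfs$m != 2L * n_individuals) {
    stop("source SFS must be at m = 2 * n_individuals = ",
         2L * n_individuals, " chromosomes, got m = ", sfs$m)
  }
  if (sum(sfs$mass[-1]) <= 0) stop("source SFS has no segregating mass")
  structure(list(n_individuals = n_individuals, n_snvs = n_snvs, sfs = sfs,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 label = label),
            class = "panel_spec")
}

#' Simulate a diploid genotype panel from a folded SFS
#'
#' Each SNV independently draws a minor allele count `x >= 1` from the source
#' SFS (normalized over segregating classes) and places the `x` minor alleles
#' uniformly without replacement among the `2 * n_individuals` chromosomes;
#' consecutive chromosome pairs form individuals (placement is exchangeable,
#' so this equals random pairing). Genotypes are coded as minor-allele dosage
#' 0/1/2. If the spec has a positive `missing_rate`, [apply_missingness()] is
#' applied afterwards. Output is reproducible from the spec's seed.
#'
#' @param spec A [panel_spec()].
#' @return A genotype matrix (class `"genotype_matrix"`): integer matrix,
#'   rows = SNVs, columns = individuals, entries 0/1/2 or `NA` for missing.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  n_chr <- 2L * spec$n_individuals
  prob <- spec$sfs$mass
  prob[1] <- 0                      # condition on segregating
  xs <- 0:(length(prob) - 1L)
  old <- .save_rng(spec$seed)
  on.exit(.restore_rng(old))
  counts <- sample(xs, spec$n_snvs, replace = TRUE, prob = prob)
  gm <- matrix(0L, nrow = spec$n_snvs, ncol = spec$n_individuals)
  for (s in seq_len(spec$n_snvs)) {
    carriers <- sample.int(n_chr, counts[s])
    ind <- (carriers + 1L) %/% 2L    # chromosome -> individual
    tab <- tabulate(ind, spec$n_individuals)
    gm[s, ] <- tab
  }
  rownames(gm) <- paste0("snv", seq_len(spec$n_snvs))
  colnames(gm) <- paste0("ind", seq_len(spec$n_individuals))
  class(gm) <- c("genotype_matrix", class(gm))
  if (spec$missing_rate > 0) {
    gm <- apply_missingness(gm, spec$missing_rate,
                            seed = spec$seed + 1000003L)
  }
  gm
}

#' Skew a folded SFS to a target singleton proportion
#'
#' Emulates the spectrum of a functional category under purifying selection
#' without an explicit selection model: the singleton class is set to the
#' requested proportion of segregating mass and the remaining classes are
#' rescaled proportionally. More constrained categories (missense, nonsense,
#' splice) show higher singleton proportions than neutral ones, and panels
#' drawn from such spectra carry a higher burden of private mutations.
#'
#' @param sfs A normalized [folded_sfs()].
#' @param singleton_prop Target proportion of segregating sites that are
#'   singletons, in `(0, 1)`.
#' @return A normalized [folded_sfs()] with the requested singleton share.
#' @export
skew_sfs <- function(sfs, singleton_prop) {
  stopifnot(inherits(sfs, "folded_sfs"), sfs$normalized,
            singleton_prop > 0, singleton_prop < 1)
  mass <- sfs$mass
  rest <- sum(mass[-c(1L, 2L)])
  if (rest <= 0) stop("SFS has no non-singleton mass to rescale")
  mass[2L] <- singleton_prop
  mass[-c(1L, 2L)] <- mass[-c(1L, 2L)] * (1 - singleton_prop) / rest
  folded_sfs(mass, sfs$m, normalized = TRUE)
}

#' Apply paired missingness to a genotype panel
#'
#' Missing genotype calls are assigned per (individual, SNV) cell: the two
#' chromosomes of an individual at a site are either both observed or both
#' missing, matching how genotype-calling failures behave. Each cell is
#' masked independently with probability `rate`. Minor allele counts among
#' the remaining called chromosomes are whatever survives the masking.
#'
#' @param gm A genotype matrix (SNVs x individuals, 0/1/2/`NA`).
#' @param rate Per-genotype missingness probability in `[0, 1)`: a single
#'   rate for the whole panel, or one rate per SNV (length `nrow(gm)`) to
#'   match empirical per-site call counts.
#' @param seed Integer RNG seed.
#' @return The masked genotype matrix.
#' @export
apply_missingness <- function(gm, rate, seed = 1L) {
  stopifnot(is.matrix(gm), is.numeric(rate),
            length(rate) == 1L || length(rate) == nrow(gm),
            all(rate >= 0), all(rate < 1))
  if (all(rate == 0)) return(gm)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  # comparison recycles a per-SNV rate vector down each individual's column
  mask <- matrix(stats::runif(length(gm)), nrow = nrow(gm)) < rate
  gm[mask] <- NA_integer_
  gm
}

#' Monte-Carlo expected branch lengths
#'
#' Simulates coalescent trees under a demographic model (standard
#' exponential coalescence times mapped through the inverse cumulative
#' intensity, random exchangeable topologies) and averages, per tree, the
#' total length of branches subtending each number of tips `q`. Serves as an
#' independent stochastic check on [expected_branch_lengths()].
#'
#' @param model A [demographic_model()].
#' @param p Number of tips (`2 <= p <= 50`).
#' @param reps Number of simulated trees (`>= 1000`).
#' @param seed Integer RNG seed.
#' @return List with `p`, `q = 1:(p-1)`, `value` (Monte-Carlo means, units of
#'   `2*N0` generations), `se` (Monte-Carlo standard errors), `reps`.
#' @export
simulate_coalescent_trees <- function(model, p, reps = 10000L, seed = 1L) {
  stopifnot(inherits(model, "demographic_model"))
  p <- as.integer(p); reps <- as.integer(reps)
  if (p < 2 || p > 50) stop("p must be in 2..50")
  if (reps < 1000) stop("reps must be at least 1000")
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  tab <- .epoch_table(model)
  unit <- 2 * tab$n0[1]
  rates <- choose(p:2, 2)
  # standard-time coalescence instants, all reps at once
  ustd <- matrix(stats::rexp(reps * (p - 1L), rate = rep(rates, each = reps)),
                 nrow = reps)
  ustd <- t(apply(ustd, 1L, cumsum))
  if (p == 2L) ustd <- matrix(ustd, nrow = reps)
  rt <- matrix(.inverse_intensity(model, ustd), nrow = reps) / unit
  totals <- matrix(0, reps, p - 1L)
  sums <- numeric(p - 1L)
  for (r in seq_len(reps)) {
    tau <- diff(c(0, rt[r, ]))
    blocks <- rep(1L, p)
    acc <- sums; acc[] <- 0
    for (lev in seq_len(p - 1L)) {
      tb <- tabulate(blocks, p - 1L)
      acc <- acc + tb * tau[lev]
      pair <- sample.int(length(blocks), 2L)
      blocks <- c(blocks[-pair], blocks[pair[1L]] + blocks[pair[2L]])
    }
    totals[r, ] <- acc
  }
  list(p = p, q = seq_len(p - 1L), value = colMeans(totals),
       se = apply(totals, 2L, stats::sd) / sqrt(reps), reps = reps)
}

# Seed bookkeeping: run a block under a local RNG state without disturbing
# the caller's stream.
.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
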