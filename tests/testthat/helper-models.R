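# Shared fixtures and independent oracles.

model_constant <- function(n = 1e4) {
  demographic_model(list(epoch(Inf, n)), label = "constant")
}

# instant 10-fold expansion 0.1 coalescent (2*N0) units ago
model_expansion <- function(n0 = 1e4) {
  demographic_model(list(epoch(0.1 * 2 * n0, n0), epoch(Inf, n0 / 10)),
                    label = "expansion10x")
}

model_two_epoch <- function() {
  demographic_model(list(epoch(1000, 1000), epoch(Inf, 10000)),
                    label = "two_epoch")
}

# Exhaustive enumeration oracle for folded projection: average, over all
# C(n, m) subsamples of the n chromosomes (j carrying the minor allele),
# the indicator of each possible subsample minor count. Exact integer
# arithmetic throughout (all counts are small integers).
enumerate_projection <- function(j, n, m) {
  subs <- utils::combn(n, m)
  counts <- integer(m %/% 2 + 1L)
  for (k in seq_len(ncol(subs))) {
    x <- sum(subs[, k] <= j)          # chromosomes 1..j carry the minor allele
    x <- min(x, m - x)                # fold onto the subsample's minor class
    counts[x + 1L] <- counts[x + 1L] + 1L
  }
  counts / ncol(subs)
}

# Deterministic hand-built genotype matrix (SNVs x individuals)
gm_from_rows <- function(...) {
  gm <- do.call(rbind, lapply(list(...), as.integer))
  rownames(gm) <- paste0("snv", seq_len(nrow(gm)))
  colnames(gm) <- paste0("ind", seq_len(ncol(gm)))
  gm
}
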