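# Plain-text formats and the two end-to-end pipelines: spectra at a common
# subsample size, and burden-versus-sample-size tables combining theoretical
# expectations with empirical panel estimates.

#' Read and write folded SFS tables
#'
#' TSV with columns `minor_count` and `mass`, preceded by a comment header
#' `# m=<chromosomes>` (and `# normalized=<TRUE|FALSE>`).
#'
#' @param sfs A [folded_sfs()].
#' @param path File path.
#' @return `write_sfs_tsv()` returns `path` invisibly; `read_sfs_tsv()`
#'   returns a [folded_sfs()].
#' @export
write_sfs_tsv <- function(sfs, path) {
  stopifnot(inherits(sfs, "folded_sfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# m=%d", sfs$m),
               sprintf("# normalized=%s", sfs$normalized)), con)
  utils::write.table(
    data.frame(minor_count = seq_along(sfs$mass) - 1L, mass = sfs$mass),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sfs_tsv
#' @export
read_sfs_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  m <- as.integer(sub("^# m=", "", hdr[1]))
  norm <- identical(sub("^# normalized=", "", hdr[2]), "TRUE")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  mass <- numeric(m %/% 2 + 1L)
  mass[df$minor_count + 1L] <- df$mass
  folded_sfs(mass, m, normalized = norm)
}

#' Read and write genotype panels as TSV
#'
#' Tab-separated matrix with SNVs as rows and individuals as columns; cells
#' are minor-allele dosages 0/1/2 with `NA` for missing genotypes. Row and
#' column names are preserved.
#'
#' @param gm Genotype matrix (SNVs x individuals).
#' @param path File path.
#' @return `write_genotype_tsv()` returns `path` invisibly;
#'   `read_genotype_tsv()` returns a genotype matrix.
#' @export
write_genotype_tsv <- function(gm, path) {
  stopifnot(is.matrix(gm))
  utils::write.table(as.data.frame(unclass(gm)), path, sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  gm <- as.matrix(df)
  storage.mode(gm) <- "integer"
  class(gm) <- c("genotype_matrix", class(gm))
  gm
}

#' Read genotypes from a VCF file
#'
#' Converts the GT field of a VCF into a minor-allele dosage matrix
#' (SNVs x individuals, 0/1/2/`NA`). Only biallelic sites are kept. The
#' dosage counts the site's minor allele as observed in this file (ties
#' resolved towards ALT). Requires the `vcfR` package.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return A genotype matrix as from [read_genotype_tsv()].
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- vcfR::is.biallelic(v)
  gt <- gt[biallelic, , drop = FALSE]
  alt_dose <- matrix(NA_integer_, nrow(gt), ncol(gt),
                     dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  alt_dose[clean == "0/0"] <- 0L
  alt_dose[clean == "0/1" | clean == "1/0"] <- 1L
  alt_dose[clean == "1/1"] <- 2L
  # fold each site onto its observed minor allele (ties -> ALT)
  called <- rowSums(!is.na(alt_dose))
  ac <- rowSums(alt_dose, na.rm = TRUE)
  flip <- ac > called                      # ALT is the major allele
  alt_dose[flip, ] <- 2L - alt_dose[flip, , drop = FALSE]
  class(alt_dose) <- c("genotype_matrix", class(alt_dose))
  alt_dose
}

#' Write a genotype panel as VCF
#'
#' Minimal VCF 4.2 writer for synthetic panels: one biallelic SNV per row
#' with GT-only genotype columns (`./.` for missing). Dosage 0/1/2 maps to
#' `0/0`, `0/1`, `1/1` with the minor allele as ALT.
#'
#' @inheritParams write_genotype_tsv
#' @export
write_genotype_vcf <- function(gm, path) {
  stopifnot(is.matrix(gm))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gm)), collapse = "\t")),
             con)
  code <- c("0/0", "0/1", "1/1")
  for (s in seq_len(nrow(gm))) {
    g <- gm[s, ]
    cells <- ifelse(is.na(g), "./.", code[g + 1L])
    writeLines(paste(c("1", s, rownames(gm)[s], "A", "T", ".", "PASS", ".",
                       "GT", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Spectra of models and panels at a common subsample size
#'
#' Builds the comparison table behind a spectra figure: for each demographic
#' model, the exact expected folded SFS at `m` chromosomes; for each genotype
#' panel, the observed counts projected to `m` chromosomes by probabilistic
#' subsampling ([project_dataset()]), dropping SNVs with fewer than
#' `min_called` successful calls and renormalizing over segregating classes
#' (`x >= 1`).
#'
#' @param models Named list of [demographic_model()] objects (may be empty).
#' @param panels Named list of genotype matrices (may be empty).
#' @param m Common chromosome count (default 900).
#' @param min_called Call-count filter for panels (default `m`).
#' @param n_classes Number of minor-count classes to tabulate (default 10).
#' @return `data.frame` with columns `source`, `minor_count`, `proportion`;
#'   attribute `dropped` records per-panel filtered SNV counts.
#' @export
run_figure1_pipeline <- function(models = list(), panels = list(), m = 900,
                                 min_called = m, n_classes = 10) {
  if (length(models) + length(panels) == 0) {
    stop("provide at least one model or panel")
  }
  rows <- list()
  dropped <- integer(0)
  for (nm in names(models)) {
    sfs <- expected_folded_sfs(models[[nm]], m, normalized = TRUE)
    rows[[nm]] <- data.frame(source = nm,
                             minor_count = seq_len(n_classes),
                             proportion = sfs$mass[1 + seq_len(n_classes)])
  }
  for (nm in names(panels)) {
    gm <- panels[[nm]]
    called <- 2L * rowSums(!is.na(gm))
    snvs <- data.frame(j = .minor_counts(gm), n_called = called)
    proj <- project_dataset(snvs, m, min_called = min_called)
    seg <- proj$mass
    seg[1] <- 0
    seg <- seg / sum(seg)
    rows[[nm]] <- data.frame(source = nm,
                             minor_count = seq_len(n_classes),
                             proportion = seg[1 + seq_len(n_classes)])
    dropped[nm] <- attr(proj, "n_snvs_dropped")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Burden of private mutations across sample sizes
#'
#' Builds the burden-versus-sample-size table: one row per (source, n). For
#' demographic models the exact expectation [expected_alpha_general()] is
#' used; for genotype panels the empirical estimator with individual
#' downsampling to `n + 1` individuals and an SNV bootstrap SE. Panel rows
#' with `n + 1` exceeding the panel size are reported as `NA`.
#'
#' @inheritParams run_figure1_pipeline
#' @param ns Prior sample sizes, e.g. `c(100, 492, 1000, 4299, 10000)`.
#' @param n_boot Bootstrap resamples for panel SEs (default 1000).
#' @param reps Downsampling repetitions per panel row (default 10).
#' @param seed Integer seed for downsampling and bootstrap.
#' @return `data.frame` with columns `source`, `type`, `n`, `alpha_percent`,
#'   `sd_percent`, `boot_se_percent`, `n_used`.
#' @export
run_figure2_pipeline <- function(models = list(), panels = list(), ns,
                                 n_boot = 1000, reps = 10, seed = 1L) {
  if (length(ns) == 0) stop("ns must be non-empty")
  if (length(models) + length(panels) == 0) {
    stop("provide at least one model or panel")
  }
  ns <- as.integer(ns)
  rows <- list()
  for (nm in names(models)) {
    alpha <- vapply(ns, function(n) expected_alpha_general(models[[nm]], n),
                    numeric(1))
    rows[[nm]] <- data.frame(source = nm, type = "model", n = ns,
                             alpha_percent = 100 * alpha, sd_percent = NA_real_,
                             boot_se_percent = NA_real_, n_used = NA_integer_)
  }
  for (nm in names(panels)) {
    gm <- panels[[nm]]
    res <- lapply(ns, function(n) {
      if (n + 1L > ncol(gm)) return(NULL)
      full <- (n + 1L == ncol(gm))
      est <- downsample_alpha(gm, n + 1L, reps = if (full) 1L else reps,
                              seed = seed, label = nm)
      # bootstrap SE at this sample size (full panel, or one representative
      # subset when downsampled)
      sub <- if (full) gm else .downsample_subset(gm, n + 1L, seed)
      bs <- bootstrap_se(sub, n_boot = n_boot, seed = seed)
      c(est$mean, est$sd, bs$boot_se)
    })
    vals <- do.call(rbind, lapply(res, function(x) {
      if (is.null(x)) rep(NA_real_, 3) else x
    }))
    rows[[nm]] <- data.frame(source = nm, type = "panel", n = ns,
                             alpha_percent = 100 * vals[, 1],
                             sd_percent = 100 * vals[, 2],
                             boot_se_percent = 100 * vals[, 3],
                             n_used = ifelse(ns + 1L <= ncol(gm), ns + 1L,
                                             NA_integer_))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.downsample_subset <- function(gm, m_individuals, seed) {
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  gm[, sample.int(ncol(gm), m_individuals), drop = FALSE]
}

#' Format a burden table the conventional way
#'
#' Renders `alpha_percent` (and a parenthesized bootstrap SE where present)
#' at three decimal places, as burden tables are conventionally printed.
#' Full-precision values stay in the input columns.
#'
#' @param tab Output of [run_figure2_pipeline()].
#' @return Character matrix of formatted entries (sources x n).
#' @export
format_burden_table <- function(tab) {
  srcs <- unique(tab$source)
  ns <- sort(unique(tab$n))
  out <- matrix("NA", length(srcs), length(ns),
                dimnames = list(srcs, paste0("n=", ns)))
  for (r in seq_len(nrow(tab))) {
    v <- tab$alpha_percent[r]
    if (is.na(v)) next
    cell <- sprintf("%.3f%%", v)
    if (!is.na(tab$boot_se_percent[r])) {
      cell <- sprintf("%.3f%% (%.3f%%)", v, tab$boot_se_percent[r])
    }
    out[tab$source[r], paste0("n=", tab$n[r])] <- cell
  }
  out
}
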