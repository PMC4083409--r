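test_that("an all-singleton spectrum makes every variant private", {
  sfs <- folded_sfs(c(0, 1, rep(0, 9)), 20, normalized = TRUE)
  gm <- simulate_panel(panel_spec(10, 100, sfs, seed = 5))
  expect_identical(dim(gm), c(100L, 10L))
  expect_true(all(rowSums(gm) == 1L))           # one carrier chromosome
  expect_true(all(gm %in% c(0L, 1L)))           # never homozygous
  a <- panel_alpha(gm)
  expect_true(all(is.na(a) | a == 1))
})

test_that("simulated panels are reproducible and conserve allele counts", {
  cst <- model_constant()
  spec <- panel_spec(50, 300, expected_folded_sfs(cst, 100), seed = 123)
  gm1 <- simulate_panel(spec)
  gm2 <- simulate_panel(spec)
  expect_identical(gm1, gm2)
  gm3 <- simulate_panel(panel_spec(50, 300, expected_folded_sfs(cst, 100),
                                   seed = 124))
  expect_false(identical(gm1, gm3))
  # counts are folded minor counts: between 1 and m/2
  counts <- rowSums(gm1)
  expect_true(all(counts >= 1 & counts <= 50))
})

test_that("fixed-count spectra reproduce their count exactly", {
  mass <- rep(0, 11); mass[4] <- 1                 # all SNVs at x = 3
  sfs <- folded_sfs(mass, 20, normalized = TRUE)
  gm <- simulate_panel(panel_spec(10, 200, sfs, seed = 9))
  expect_true(all(rowSums(gm) == 3L))
})

test_that("simulated SFS matches the source spectrum (goodness of fit)", {
  cst <- model_constant()
  m <- 40
  sfs <- expected_folded_sfs(cst, m)
  rejections <- 0L
  for (s in 1:20) {
    gm <- simulate_panel(panel_spec(m / 2, 1500, sfs, seed = 800 + s))
    counts <- rowSums(gm)
    obs <- tabulate(counts, m %/% 2)
    exp_p <- sfs$mass[-1]
    # pool sparse high-count classes to keep expected cells reasonable
    cut <- min(max(which(1500 * exp_p > 5)), length(exp_p) - 1L)
    obs2 <- c(obs[1:cut], sum(obs[-(1:cut)]))
    p2 <- c(exp_p[1:cut], sum(exp_p[-(1:cut)]))
    pv <- suppressWarnings(stats::chisq.test(obs2, p = p2)$p.value)
    if (pv < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("missingness is paired, unbiased in rate, and inert downstream", {
  cst <- model_constant()
  gm <- simulate_panel(panel_spec(100, 1000, expected_folded_sfs(cst, 200),
                                  seed = 31))
  expect_identical(apply_missingness(gm, 0), gm)
  gm_miss <- apply_missingness(gm, 0.05, seed = 77)
  frac <- mean(is.na(gm_miss))
  se <- sqrt(0.05 * 0.95 / length(gm))
  expect_lt(abs(frac - 0.05) / se, 3)
  # genotype-level masking means a whole individual-site call drops out:
  # called chromosome counts are always even
  called <- 2 * rowSums(!is.na(gm_miss))
  expect_true(all(called %% 2 == 0))
  # per-SNV rates reproduce heterogeneous call counts
  rates <- rep(c(0, 0.5), length.out = nrow(gm))
  gm_var <- apply_missingness(gm, rates, seed = 78)
  miss_by_snv <- rowMeans(is.na(gm_var))
  expect_true(all(miss_by_snv[rates == 0] == 0))
  expect_gt(mean(miss_by_snv[rates == 0.5]), 0.4)
  # missing cells do not contribute het or singleton counts
  one <- gm_from_rows(c(1, 0, 0), c(1, 1, 0))
  expect_identical(unname(panel_alpha(one)[1]), 0.5)  # snv1 singleton for ind1
  one[1, 1] <- NA                        # mask ind1's only singleton site
  a <- panel_alpha(one)
  expect_identical(unname(a[1]), 0)      # only snv2 left, shared het
  expect_identical(unname(a[2]), 0)      # snv2 minor count is 2 among called
})

test_that("Monte-Carlo trees reproduce the constant-size law", {
  cst <- model_constant()
  mc2 <- simulate_coalescent_trees(cst, 2, reps = 20000L, seed = 1)
  expect_lt(abs(mc2$value - 2) / mc2$se, 3)
  mc6 <- simulate_coalescent_trees(cst, 6, reps = 20000L, seed = 2)
  z <- abs(mc6$value - 2 / (1:5)) / mc6$se
  expect_true(all(z < 3))
})

test_that("population expansion shifts simulated trees towards singletons", {
  mcg <- simulate_coalescent_trees(model_expansion(), 6, reps = 20000L,
                                   seed = 3)
  mcc <- simulate_coalescent_trees(model_constant(), 6, reps = 20000L,
                                   seed = 4)
  expect_gt(mcg$value[1] / sum(mcg$value),
            mcc$value[1] / sum(mcc$value))
})

test_that("panel specs validate their inputs", {
  cst <- model_constant()
  sfs <- expected_folded_sfs(cst, 20)
  expect_error(panel_spec(5, 10, sfs), "m = 2 \\* n_individuals")
  expect_error(panel_spec(10, 10, sfs, missing_rate = 1), "missing_rate")
  mono <- folded_sfs(c(1, rep(0, 10)), 20)
  expect_error(panel_spec(10, 10, mono), "segregating")
})
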