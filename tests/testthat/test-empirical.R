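test_that("per-individual burden matches a hand count", {
  # site A: only ind1 het (singleton); site B: ind1 and ind2 het (count 2)
  gm <- gm_from_rows(c(1, 0, 0), c(1, 1, 0))
  a <- panel_alpha(gm)
  expect_equal(unname(a), c(1 / 2, 0, NA))
  expect_equal(individual_alpha(gm, 1), 1 / 2, ignore_attr = TRUE)
  # hom-minor carriers are not singletons and not het
  gm2 <- gm_from_rows(c(2, 0, 0), c(1, 0, 0))
  expect_equal(unname(panel_alpha(gm2)), c(1, NA, NA))
})

test_that("individuals without heterozygous sites are excluded", {
  gm <- gm_from_rows(c(1, 0, 0), c(1, 2, 0))
  res <- burden_estimate(gm)
  expect_identical(res$n_excluded, 2L)   # ind2 is hom-minor only, ind3 all-ref
  # ind1 is het at both sites; only snv1 (count 1) is a singleton --
  # snv2 has 3 minor copies among the 6 called chromosomes
  expect_equal(res$mean, 1 / 2)
  expect_equal(unname(res$alpha), c(1 / 2, NA, NA))
})

test_that("bootstrap SE is zero for identical SNV columns", {
  gm <- gm_from_rows(c(1, 0, 0, 0))[rep(1, 8), ]
  rownames(gm) <- paste0("snv", 1:8)
  bs <- bootstrap_se(gm, n_boot = 200, seed = 4)
  expect_identical(bs$boot_se, 0)
  expect_equal(bs$boot_mean, mean(panel_alpha(gm), na.rm = TRUE))
})

test_that("bootstrap SE scales as one over the square root of SNV count", {
  cst <- model_constant()
  sfs <- expected_folded_sfs(cst, 60)
  ratio <- sapply(1:8, function(s) {
    g1 <- simulate_panel(panel_spec(30, 400, sfs, seed = 50 + s))
    g2 <- simulate_panel(panel_spec(30, 800, sfs, seed = 150 + s))
    bootstrap_se(g1, 200, seed = s)$boot_se /
      bootstrap_se(g2, 200, seed = s)$boot_se
  })
  expect_equal(mean(ratio), sqrt(2), tolerance = 0.15)
})

test_that("bootstrap SE tracks the between-panel spread of the mean", {
  cst <- model_constant()
  sfs <- expected_folded_sfs(cst, 60)
  means <- numeric(30); ses <- numeric(30)
  for (s in 1:30) {
    gm <- simulate_panel(panel_spec(30, 500, sfs, seed = 9000 + s))
    means[s] <- mean(panel_alpha(gm), na.rm = TRUE)
    ses[s] <- bootstrap_se(gm, 200, seed = s)$boot_se
  }
  expect_lt(max(mean(ses) / sd(means), sd(means) / mean(ses)), 1.5)
})

test_that("downsampling to the full panel equals the direct estimate", {
  cst <- model_constant()
  gm <- simulate_panel(panel_spec(40, 500, expected_folded_sfs(cst, 80),
                                  seed = 21))
  full <- burden_estimate(gm)
  down <- downsample_alpha(gm, 40, reps = 3, seed = 2)
  expect_equal(down$mean, full$mean)
  expect_equal(down$sd, full$sd)
  expect_error(downsample_alpha(gm, 41), "exceeds")
  expect_error(downsample_alpha(gm, 1), "at least 2")
})

test_that("burden decreases on average as the subset grows", {
  cst <- model_constant()
  gm <- simulate_panel(panel_spec(60, 800, expected_folded_sfs(cst, 120),
                                  seed = 33))
  m_small <- downsample_alpha(gm, 10, reps = 20, seed = 3)
  m_large <- downsample_alpha(gm, 50, reps = 20, seed = 3)
  expect_gt(m_small$mean, m_large$mean)
})

test_that("downsampled and directly simulated panels agree in distribution", {
  cst <- model_constant()
  m_sub <- 15
  reject <- 0L
  for (s in 1:20) {
    big <- simulate_panel(panel_spec(60, 600,
                                     expected_folded_sfs(cst, 120),
                                     seed = 4000 + s))
    down <- downsample_alpha(big, m_sub, reps = 1, seed = s)
    direct <- simulate_panel(panel_spec(m_sub, 600,
                                        expected_folded_sfs(cst, 2 * m_sub),
                                        seed = 5000 + s))
    a1 <- down$alpha[!is.na(down$alpha)]
    a2 <- panel_alpha(direct); a2 <- a2[!is.na(a2)]
    pv <- suppressWarnings(stats::ks.test(a1, a2)$p.value)
    if (pv < 0.01) reject <- reject + 1L
  }
  expect_lte(reject, 1L)
})

test_that("removing an individual changes only singleton status", {
  gm <- gm_from_rows(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 1, 1, 1))
  het_before <- colSums(gm == 1L, na.rm = TRUE)
  sub <- gm[, -2, drop = FALSE]
  het_after <- colSums(sub == 1L, na.rm = TRUE)
  expect_identical(unname(het_before[-2]), unname(het_after))
  # dropping ind2 makes snv1 a singleton for ind1: alpha rises from 1/2 to 1
  expect_equal(unname(panel_alpha(gm)[1]), 1 / 2)
  expect_equal(unname(panel_alpha(sub)[1]), 1)
})

test_that("category ratios compare mean burdens with a delta-method SE", {
  gm <- gm_from_rows(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  r1 <- burden_estimate(gm, n_boot = 100, seed = 1)
  expect_equal(category_ratio(r1, r1)$ratio, 1)
  gm2 <- gm[c(1, 2), , drop = FALSE]
  r2 <- burden_estimate(gm2, n_boot = 100, seed = 2)
  cr <- category_ratio(r2, r1)
  expect_equal(cr$ratio, r2$mean / r1$mean)
  expect_true(is.finite(cr$se) && cr$se > 0)
  r_noboot <- burden_estimate(gm)
  expect_true(is.na(category_ratio(r_noboot, r_noboot)$se))
})

test_that("estimator is consistent with the closed form at small n", {
  cst <- model_constant()
  n <- 10
  sfs <- expected_folded_sfs(cst, 2 * (n + 1))
  ms <- sapply(1:50, function(s) {
    gm <- simulate_panel(panel_spec(n + 1, 800, sfs, seed = 600 + s))
    mean(panel_alpha(gm), na.rm = TRUE)
  })
  se <- sd(ms) / sqrt(length(ms))
  expect_lt(abs(mean(ms) - 2 / (2 * n + 1)) / se, 3)
})
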