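test_that("constant-size branch lengths obey the 2/q law", {
  cst <- model_constant()
  expect_equal(expected_branch_lengths(cst, 2)$value, 2.0)
  expect_equal(expected_branch_lengths(cst, 4)$value, c(2, 1, 2 / 3))
  for (p in c(10, 57, 200)) {
    bl <- expected_branch_lengths(cst, p)
    expect_lt(max(abs(bl$value * bl$q / 2 - 1)), 1e-8)
  }
})

test_that("branch-length engine stays finite and positive at p = 20002", {
  bl <- expected_branch_lengths(model_constant(), 20002L,
                                qs = c(1L, 20001L))
  expect_true(all(is.finite(bl$value)))
  expect_true(all(bl$value > 0))
  expect_equal(bl$value[1], 2, tolerance = 1e-10)
  expect_equal(bl$value[2], 2 / 20001, tolerance = 1e-8)
})

test_that("non-constant branch lengths match a Monte-Carlo oracle", {
  exp10 <- model_expansion()
  bl <- expected_branch_lengths(exp10, 6)
  mc <- simulate_coalescent_trees(exp10, 6, reps = 20000L, seed = 42L)
  z <- abs(bl$value - mc$value) / mc$se
  expect_true(all(z < 4))
})

test_that("expected folded SFS matches closed forms at small m", {
  cst <- model_constant()
  s4 <- expected_folded_sfs(cst, 4)
  expect_equal(s4$mass, c(0, 8 / 11, 3 / 11))
  s2 <- expected_folded_sfs(cst, 2)
  expect_equal(s2$mass, c(0, 1))
  # unnormalized: raw branch lengths, folded
  u5 <- expected_folded_sfs(cst, 5, normalized = FALSE)
  expect_equal(u5$mass, c(0, 2 + 2 / 4, 1 + 2 / 3))
})

test_that("recent growth inflates the singleton share of the folded SFS", {
  pm <- preset_models()
  g <- expected_folded_sfs(pm$growth_toy, 900)
  cst <- expected_folded_sfs(pm$constant, 900)
  expect_gt(g$mass[2], cst$mass[2])
})

test_that("normalized SFS and burden are invariant to joint rescaling", {
  base <- demographic_model(list(epoch(120, 5e5, 0.035),
                                 epoch(880, 7500),
                                 epoch(Inf, 1e4)))
  c_scale <- 3.7
  scaled <- demographic_model(list(
    epoch(120 * c_scale, 5e5 * c_scale, 0.035 / c_scale),
    epoch(880 * c_scale, 7500 * c_scale),
    epoch(Inf, 1e4 * c_scale)))
  s1 <- expected_folded_sfs(base, 40)
  s2 <- expected_folded_sfs(scaled, 40)
  expect_equal(s1$mass, s2$mass, tolerance = 1e-9)
  expect_equal(expected_alpha_general(base, 12),
               expected_alpha_general(scaled, 12), tolerance = 1e-9)
})

test_that("singleton and heterozygosity expectations follow theta", {
  expect_equal(expected_singletons_folded(1, 0), 2)
  expect_equal(expected_singletons_folded(1, 100), 1 + 1 / 201)
  expect_equal(expected_singletons_folded(5, 1e9), 5, tolerance = 1e-8)
  expect_equal(expected_heterozygosity(1), 1)
  expect_equal(expected_heterozygosity(0.001 * 1e6), 1000)
  expect_error(expected_singletons_folded(-1, 10))
})

test_that("heterozygosity expectation matches genotype simulation", {
  # constant model, m chromosomes: expected het sites per individual given
  # S segregating sites is S * E[T_{m,.} het share]; for one individual the
  # probability a count-x site is heterozygous is 2x(m-x)/(m(m-1)) -- check
  # the simulated panel against that direct expectation
  cst <- model_constant()
  m <- 40
  sfs <- expected_folded_sfs(cst, m)
  n_snv <- 2000
  x <- seq_len(m %/% 2)
  p_het <- sum(sfs$mass[x + 1] * 2 * x * (m - x) / (m * (m - 1)))
  gm <- simulate_panel(panel_spec(m / 2, n_snv, sfs, seed = 11))
  het_per_ind <- colSums(gm == 1L)
  se <- sd(het_per_ind) / sqrt(length(het_per_ind))
  expect_lt(abs(mean(het_per_ind) - n_snv * p_het) / se, 3)
})

test_that("invalid sample sizes and subsets are rejected", {
  cst <- model_constant()
  expect_error(expected_branch_lengths(cst, 1), "at least 2")
  expect_error(expected_branch_lengths(cst, 10, qs = 10), "subset")
  expect_error(expected_folded_sfs(cst, 1), "at least 2")
})
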