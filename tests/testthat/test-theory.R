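# Closed-form model quantities and their oracles.

test_that("trait specificity matches hand arithmetic and stays in [0,1]", {
  expect_identical(trait_specificity(c(1, 0, 0)), 1)
  expect_equal(trait_specificity(rep(2, 18)), 1 / 18)
  expect_equal(trait_specificity(c(4, 1, 1)), 4 / 6)
  expect_error(trait_specificity(c(0, 0)), "all-zero")
  # property: in [0,1], equals 1 iff only the focal entry is nonzero
  set.seed(1)
  for (i in 1:50) {
    x <- rexp(5) * rbinom(5, 1, 0.7)
    if (sum(x) == 0) next
    psi <- trait_specificity(x, focal = 2)
    expect_gte(psi, 0)
    expect_lte(psi, 1)
    expect_identical(psi == 1, x[2] > 0 && all(x[-2] == 0))
  }
  m <- matrix(c(4, 1, 1, 2, 2, 0), nrow = 2, byrow = TRUE)
  expect_equal(trait_specificity(m), c(4 / 6, 0.5))
})

test_that("squared-effect estimator is unbiased under the Normal noise model", {
  expect_equal(unbiased_importance(0.5, 0.3), 0.16)
  expect_identical(unbiased_importance(0.3, 0.3), 0)
  set.seed(42)
  gamma <- 0.2
  se <- 0.1
  draws <- rnorm(1e5, gamma, se)
  est <- unbiased_importance(draws, se)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - gamma^2), 3 * mc_se)
  # variance of the estimator: 4 gamma^2 se^2 + 2 se^4
  expect_lt(abs(var(est) - (4 * gamma^2 * se^2 + 2 * se^4)) /
              (4 * gamma^2 * se^2 + 2 * se^4), 0.05)
})

test_that("burden strength composes with the balance frequency to mu*L*psi", {
  expect_identical(expected_burden_strength(0.5, 0), 0)
  expect_equal(expected_burden_strength(2, 0.1), 2 * expected_burden_strength(1, 0.1))
  # with p_lof = c mu L / s_het and s_het = sum(gamma^2), the composition is
  # proportional to mu L psi for rare p_lof
  set.seed(3)
  ratios <- replicate(200, {
    g_sq <- rexp(7) * 1e-3
    mu_l <- runif(1, 1e-6, 1e-5)
    s_het <- sum(g_sq)
    p_lof <- expected_plof_product(1, mu_l, s_het) / 1  # per-unit L folded into mu_l
    strength <- expected_burden_strength(g_sq[1], p_lof)
    psi <- trait_specificity(g_sq)
    strength / (mu_l * psi * (1 - p_lof))
  })
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-9)
})

test_that("balance heterozygosity formula agrees with the DTWF solve", {
  expect_equal(expected_plof_product(1e-8, 200, 0.01),
               2 * expected_plof_product(1e-8, 100, 0.01))
  s <- c(0.001, 0.01, 0.1)
  vals <- expected_plof_product(1e-8, 100, s)
  expect_true(all(diff(vals) < 0))
  expect_identical(expected_plof_product(1e-3, 1000, 1e-4), 0.25)  # clipped
  # per-site stationary oracle
  d <- stationary_distribution(population_params(2000, 1e-6), 0.01)
  het <- distribution_moments(d)$het
  expect_lt(abs(expected_plof_product(1e-6, 1, 0.01) - het) / het, 0.2)
})

test_that("realized heritability is the frequency-weighted squared effect", {
  expect_equal(realized_heritability(0.1, 0.5), 0.05)
  expect_identical(realized_heritability(3, 0), 0)
  expect_identical(realized_heritability(3, 1), 0)
  p <- runif(20)
  expect_equal(realized_heritability(0.3, p), realized_heritability(0.3, 1 - p))
})

test_that("z^2 - 1 proxy is centered under the null", {
  expect_identical(heritability_proxy(1), 0)
  expect_identical(heritability_proxy(0.5), -0.5)
  set.seed(9)
  z_sq <- rchisq(1e5, df = 1)
  prox <- heritability_proxy(z_sq)
  expect_lt(abs(mean(prox)), 3 * sd(prox) / sqrt(length(prox)))
})

test_that("Bonferroni threshold reproduces the burden-study cutoff", {
  expect_equal(signif(bonferroni_threshold(0.05, 18524), 2), 2.7e-6)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.1, 10), 0.01)
})

test_that("flattening curve rises in the weak regime and plateaus at 2 mu psi", {
  grid <- small_grid()
  mu <- grid$params$mut_rate
  two_n <- 2 * grid$params$n_diploids
  psi <- 0.4
  alpha2 <- 10^seq(log10(0.2 * psi / two_n), log10(0.3 * psi), length.out = 40)
  fc <- flattening_curve(alpha2, psi, grid)
  weak <- fc[2 * grid$params$n_diploids * fc$s_het_implied < 1, ]
  expect_gt(nrow(weak), 3)
  expect_true(all(diff(weak$expected_h2) >= -1e-15))
  strong <- fc[2 * grid$params$n_diploids * fc$s_het_implied > 20, ]
  expect_gt(nrow(strong), 3)
  # plateau level; single points carry the grid's nearest-value quantization
  expect_lt(abs(mean(strong$expected_h2) - 2 * mu * psi) / (2 * mu * psi), 0.2)
  # doubling psi doubles the plateau (compared on the shared strong points)
  fc2 <- flattening_curve(alpha2, 2 * psi, grid)
  strong2 <- fc2[2 * grid$params$n_diploids * fc2$s_het_implied > 20, ]
  common <- intersect(strong$alpha_sq, strong2$alpha_sq)
  expect_gt(length(common), 3)
  ratio <- mean(strong2$expected_h2[strong2$alpha_sq %in% common]) /
    mean(strong$expected_h2[strong$alpha_sq %in% common])
  expect_lt(abs(ratio - 2), 2 * 0.05)
  # pointwise monotone in psi
  expect_true(all(fc2$expected_h2 >= fc$expected_h2 - 1e-18))
})

test_that("summary records enforce p-value / z-score consistency", {
  rec <- summary_records(c("g1", "g2"), c(0.5, -0.2), c(0.1, 0.1))
  expect_equal(rec$z_sq, c(25, 4))
  expect_error(summary_records("g1", 0.5, 0), "standard errors")
  good_p <- pchisq(25, 1, lower.tail = FALSE)
  expect_silent(summary_records("g1", 0.5, 0.1, p_value = good_p))
  expect_error(summary_records("g1", 0.5, 0.1, p_value = good_p * 10),
               "inconsistent")
})
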