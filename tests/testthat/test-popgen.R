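# Wright-Fisher core: transition matrix structure, stationary solves
# against independent oracles, grid construction, and sampling.

test_that("neutral transition row is the plain binomial and rows are stochastic", {
  params <- population_params(2, 0)
  tm <- build_transition_matrix(params, s_het = 0)
  # current count 2 of 4 copies, frequency 0.5
  expect_equal(as.numeric(tm[3, ]), dbinom(0:4, 4, 0.5), tolerance = 1e-12)
  for (s in c(0, 0.3, 1)) {
    tm <- build_transition_matrix(population_params(30, 1e-3), s)
    expect_true(all(abs(Matrix::rowSums(tm) - 1) < 1e-9))
  }
})

test_that("full heterozygote disadvantage leaves frequency 1/2 unmoved", {
  # at p = 0.5 the two homozygote classes balance exactly
  p_next <- burdengwas:::dtwf_pnext(50, 100, mut_rate = 0, s_het = 1)
  expect_equal(p_next, 0.5, tolerance = 1e-12)
})

test_that("s_het outside [0,1] and oversized populations are rejected", {
  params <- population_params(10, 1e-3)
  expect_error(build_transition_matrix(params, -0.1), "s_het")
  expect_error(build_transition_matrix(params, 1.5), "s_het")
  expect_error(build_transition_matrix(population_params(1e6, 1e-3), 0.1),
               "cap")
})

test_that("stationary distribution matches the forward-simulation oracle", {
  params <- population_params(50, 1e-3)
  for (s in c(0, 0.02)) {
    stat <- stationary_distribution(params, s)
    expect_prob_vector(stat$mass)
    expect_identical(stat$mass[length(stat$mass)], 0)  # no fixed class
    sim <- forward_simulate(params, s, n_generations = 2e5, seed = 7,
                            burn_in = 5e3)
    tv <- total_variation(stat$mass, sim$counts_distribution)
    expect_lt(tv, 0.03)
  }
})

test_that("stationary mean matches deterministic mutation-selection balance", {
  params <- population_params(2000, 1e-6)
  d <- stationary_distribution(params, 0.01)
  m <- distribution_moments(d)
  expect_lt(abs(m$mean_freq - 1e-4) / 1e-4, 0.2)
  expect_lt(abs(m$het - 1e-4) / 1e-4, 0.2)
})

test_that("adaptive truncation agrees with the full-state solve", {
  params <- population_params(500, 1e-5)
  full <- burdengwas:::solve_stationary_states(params, 0.02, k = 1000,
                                               truncation = 1e-12,
                                               genic = FALSE)
  trunc <- stationary_distribution(params, 0.02)$mass
  expect_lt(total_variation(c(full, 0), trunc), 1e-6)
})

test_that("unconditioned chain is absorbed at fixation", {
  d <- stationary_distribution(population_params(20, 1e-3), 0.01,
                               condition_no_fix = FALSE)
  expect_identical(d$mass[length(d$mass)], 1)
})

test_that("selection grid spacing, endpoints, and lookup rules hold", {
  params <- population_params(50, 1e-3)
  grid <- build_selection_grid(params, n_points = 50, lo = 1e-7, hi = 0.05,
                               eager = FALSE)
  v <- grid$s_het_values
  expect_length(v, 50)
  expect_identical(v[1], 1e-7)
  expect_identical(v[50], 0.05)
  ratios <- v[-1] / v[-50]
  expect_lt(diff(range(ratios)) / ratios[1], 1e-9)

  tiny <- build_selection_grid(params, n_points = 2, lo = 1e-4, hi = 1e-2,
                               eager = FALSE)
  expect_identical(tiny$s_het_values, c(1e-4, 1e-2))
  expect_error(build_selection_grid(params, lo = 0, hi = 0.05), "lo")

  # identity, clamping, and the lower-index midpoint tie rule
  expect_identical(nearest_grid_index(grid, v[17]), 17L)
  expect_identical(nearest_grid_index(grid, 1), 50L)
  expect_identical(nearest_grid_index(grid, 1e-12), 1L)
  mid <- sqrt(v[5] * v[6])   # exact log midpoint
  expect_identical(nearest_grid_index(grid, mid), 5L)
})

test_that("moments of point masses and the balance identity are exact", {
  params <- population_params(10, 1e-3)
  at <- function(count) {
    mass <- numeric(21)
    mass[count + 1] <- 1
    burdengwas:::new_freq_dist(params, 0, mass, TRUE)
  }
  expect_equal(distribution_moments(at(0)), list(mean_freq = 0, het = 0))
  expect_equal(distribution_moments(at(10)),
               list(mean_freq = 0.5, het = 0.25))
})

test_that("frequency sampling is deterministic and consistent with moments", {
  d <- stationary_distribution(population_params(200, 1e-4), 0.005)
  expect_identical(sample_frequencies(d, 0), numeric(0))
  expect_identical(sample_frequencies(d, 50, seed = 3),
                   sample_frequencies(d, 50, seed = 3))
  f <- sample_frequencies(d, 1e5, seed = 4)
  m <- distribution_moments(d)
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - m$mean_freq), 3 * se + 1e-12)
  f_seg <- sample_frequencies(d, 1000, seed = 5, segregating_only = TRUE)
  expect_true(all(f_seg > 0))
})

test_that("forward simulation respects absorbing and martingale structure", {
  # no mutation from the empty state: stays at zero forever
  sim <- forward_simulate(population_params(20, 0), 0.1,
                          n_generations = 500, seed = 1)
  expect_identical(sim$counts_distribution[1], 1)
  # neutral chain without mutation: mean frequency change ~ 0
  params <- population_params(50, 0)
  drifts <- vapply(1:60, function(s) {
    sim <- forward_simulate(params, 0, n_generations = 5, seed = s,
                            start_count = 50, condition_no_fix = FALSE)
    sum(sim$counts_distribution * (0:100)) / 100 - 0.5
  }, numeric(1))
  expect_lt(abs(mean(drifts)), 0.05)
})

test_that("E[p(1-p)] decreases along the selection grid", {
  grid <- small_grid()
  idx <- c(1L, 8L, 15L, 22L, 30L)
  het <- vapply(idx, function(k) {
    distribution_moments(grid_distribution(grid, k))$het
  }, numeric(1))
  expect_true(all(diff(het) < 0))
})

test_that("distributions round-trip through the TSV serialization", {
  d <- stationary_distribution(population_params(100, 1e-4), 0.01)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distribution(d, path)
  d2 <- read_distribution(path)
  expect_equal(d2$params$n_diploids, d$params$n_diploids)
  expect_equal(d2$s_het, d$s_het)
  expect_lt(total_variation(d$mass, d2$mass), 1e-12)
})
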