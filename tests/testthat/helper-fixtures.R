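# Shared fixtures. Grids are cached for the whole test run because the
# full-state stationary solves are the expensive step.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Small diffusion-rescaled grid for unit tests: N = 400 diploids with
# 2N*mu and the 2N*s_het range matched to the production configuration
# (N = 20,000, mu = 1.25e-8, s_het in 1e-7..0.05; scale factor 50).
small_grid <- function() {
  cached("small_grid", function() {
    params <- population_params(400, 1.25e-8 * 50)
    build_selection_grid(params, n_points = 30, lo = 1e-7 * 50, hi = 1,
                         eager = FALSE)
  })
}

# Paper-scale grid (N = 20,000) with lazily solved truncated points; only
# the strong-selection end is ever touched by the tests that use it.
production_grid <- function() {
  cached("production_grid", function() {
    build_selection_grid(population_params(20000, 1.25e-8),
                         n_points = 50, lo = 1e-7, hi = 0.05, eager = FALSE)
  })
}

# Diffusion-rescaled study grid used by the acceptance checks: N = 2000
# diploids with 2N*mu and the 2N*s_het range preserved from the production
# configuration (scale factor 10). Built eagerly once (~1.5 min).
scaled_grid <- function() {
  cached("scaled_grid", function() {
    build_selection_grid(population_params(2000, 1.25e-7),
                         n_points = 50, lo = 1e-6, hi = 0.5, eager = TRUE)
  })
}

# Small synthetic study shared across pipeline tests.
small_study <- function() {
  cached("small_study", function() {
    config <- synthetic_config(n_genes = 2000, n_traits = 8,
                               n_chromosomes = 6, seed = 101)
    make_synthetic_study(config, small_grid(), burden_traits = 1:3)
  })
}

expect_prob_vector <- function(mass, tol = 1e-9) {
  expect_true(all(mass >= 0))
  expect_lt(abs(sum(mass) - 1), tol)
}
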