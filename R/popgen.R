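# Equilibrium discrete-time Wright-Fisher (DTWF) allele-frequency
# distributions under heterozygote selection with recurrent one-way mutation,
# conditioned on non-fixation, plus sampling utilities and a forward
# simulation used as an independent oracle in tests.

#' Population parameters for the Wright-Fisher model
#'
#' @param n_diploids Number of diploid individuals `N`; the chain tracks
#'   derived-allele counts over the `2N` haploid copies.
#' @param mut_rate Per-site, per-generation probability that an ancestral
#'   copy mutates to the derived allele. One-way mutation only: the ancestral
#'   allele is taken as known and back mutation is ignored.
#' @return An object of class `population_params`.
#' @examples
#' population_params(2000, 1.25e-7)
#' @export
population_params <- function(n_diploids, mut_rate) {
  check_number(n_diploids, "n_diploids", lower = 2)
  if (n_diploids != round(n_diploids)) stopf("n_diploids must be an integer")
  check_number(mut_rate, "mut_rate", lower = 0, upper = 0.25)
  if (mut_rate >= 0.25) stopf("mut_rate must be < 0.25")
  structure(
    list(n_diploids = as.integer(n_diploids), mut_rate = mut_rate),
    class = "population_params"
  )
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("Wright-Fisher population: N = %d diploids, mu = %g per site per generation\n",
              x$n_diploids, x$mut_rate))
  invisible(x)
}

# Expected post-selection + post-mutation derived-allele probability for each
# current count. Fitnesses: both homozygotes 1, heterozygote 1 - s_het
# (genic = TRUE instead gives the derived homozygote fitness 1 - 2 s_het,
# the classical additive scheme; for rare alleles the two are approximately
# equivalent). Update order: selection, then mutation, then binomial sampling.
dtwf_pnext <- function(counts, two_n, mut_rate, s_het, genic = FALSE) {
  p <- counts / two_n
  w_der_hom <- if (genic) 1 - 2 * s_het else 1
  num <- p^2 * w_der_hom + p * (1 - p) * (1 - s_het)
  den <- p^2 * w_der_hom + 2 * p * (1 - p) * (1 - s_het) + (1 - p)^2
  p_sel <- ifelse(den > 0, num / den, 0)
  p_sel + (1 - p_sel) * mut_rate
}

# Maximum state-space dimension guard for the dense enumeration of rows.
.max_two_n <- 2^17

#' Wright-Fisher transition matrix
#'
#' Row-stochastic transition matrix over derived-allele counts `0..2N`.
#' Row `i` is the binomial sampling distribution of the next generation's
#' count given current count `i`, after viability selection against
#' heterozygotes and one-way ancestral-to-derived mutation. Binomial tails
#' below `truncation` are dropped and each row renormalized, which keeps the
#' matrix sparse.
#'
#' @param params A [population_params()] object.
#' @param s_het Selection coefficient against heterozygous carriers, in
#'   `[0, 1]`.
#' @param truncation Row entries below this value are zeroed, then the row is
#'   renormalized.
#' @param genic If `TRUE`, the derived homozygote has fitness `1 - 2 s_het`
#'   instead of 1.
#' @return A sparse `Matrix::dgCMatrix` of dimension `(2N+1) x (2N+1)`.
#' @examples
#' tm <- build_transition_matrix(population_params(2, 0.01), s_het = 0)
#' Matrix::rowSums(tm)
#' @export
build_transition_matrix <- function(params, s_het, truncation = 1e-12,
                                    genic = FALSE) {
  stopifnot(inherits(params, "population_params"))
  check_number(s_het, "s_het", lower = 0, upper = 1)
  two_n <- 2L * params$n_diploids
  if (two_n + 1L > .max_two_n) {
    stopf("transition matrix dimension %d exceeds cap %d", two_n + 1L, .max_two_n)
  }
  rows <- dtwf_rows(0:two_n, two_n, params$mut_rate, s_het, truncation,
                    genic = genic, col_cap = two_n)
  Matrix::sparseMatrix(i = rows$i, j = rows$j + 1L, x = rows$x,
                       dims = c(two_n + 1L, two_n + 1L))
}

# Shared row construction: for each state in `states` (a derived count),
# evaluate the binomial pmf over the quantile-bounded support, truncate, and
# renormalize. Columns above col_cap are clipped off (used by the truncated
# solver; the clipped mass is negligible by construction or redirected by the
# caller). Returns triplet vectors with j as a count (0-based).
dtwf_rows <- function(states, two_n, mut_rate, s_het, truncation, genic,
                      col_cap) {
  pnext <- dtwf_pnext(states, two_n, mut_rate, s_het, genic = genic)
  n_states <- length(states)
  ii <- vector("list", n_states)
  jj <- vector("list", n_states)
  xx <- vector("list", n_states)
  for (r in seq_len(n_states)) {
    pr <- pnext[r]
    lo <- min(stats::qbinom(1e-14, two_n, pr), col_cap)
    hi <- min(stats::qbinom(1e-14, two_n, pr, lower.tail = FALSE), col_cap)
    k <- lo:hi
    v <- stats::dbinom(k, two_n, pr)
    keep <- v >= truncation
    if (!any(keep)) {           # keep at least the modal entry
      keep <- v == max(v)
    }
    k <- k[keep]
    v <- v[keep]
    v <- v / sum(v)
    ii[[r]] <- rep.int(r, length(k))
    jj[[r]] <- k
    xx[[r]] <- v
  }
  list(i = unlist(ii), j = unlist(jj), x = unlist(xx))
}

#' Equilibrium allele-frequency distribution
#'
#' Stationary distribution of the discrete-time Wright-Fisher chain under
#' heterozygote selection and recurrent one-way mutation. With
#' `condition_no_fix = TRUE` (the default, and the model used throughout the
#' package) the derived allele is not allowed to fix: a fixation event
#' returns the site to the all-ancestral state, because once the derived
#' allele has fixed the site is no longer a variant for the known ancestral
#' allele. The resulting chain on counts `0..2N-1` is solved exactly by a
#' sparse LU factorization of its stationary equations.
#'
#' Under strong selection the stationary mass is confined to low counts, and
#' the solver works on an adaptively truncated state space: it starts from a
#' few hundred states and doubles until the upper-tail mass is below
#' `tail_tol`, falling back to the full state space when selection is weak.
#' This makes production-scale populations (N = 20,000 diploids) tractable
#' for selected variants.
#'
#' @inheritParams build_transition_matrix
#' @param condition_no_fix Condition on non-fixation (see Details). With
#'   `FALSE` the chain has an absorbing fixed class and its stationary
#'   distribution is the point mass at count `2N`, which is returned exactly.
#' @param tail_tol Mass allowed in the top states of a truncated solve before
#'   the state space is expanded.
#' @return An object of class `freq_dist` with fields `params`, `s_het`,
#'   `mass` (probabilities over counts `0..2N`), and `conditioned`.
#' @examples
#' d <- stationary_distribution(population_params(200, 1e-4), s_het = 0.01)
#' sum(d$mass)
#' @export
stationary_distribution <- function(params, s_het, condition_no_fix = TRUE,
                                    truncation = 1e-12, genic = FALSE,
                                    tail_tol = 1e-9) {
  stopifnot(inherits(params, "population_params"))
  check_number(s_het, "s_het", lower = 0, upper = 1)
  two_n <- 2L * params$n_diploids
  if (!condition_no_fix) {
    # One-way mutation makes the fixed class absorbing; all other states are
    # transient when mut_rate > 0, so the stationary law is degenerate.
    mass <- c(rep(0, two_n), 1)
    return(new_freq_dist(params, s_het, mass, conditioned = FALSE))
  }
  if (params$mut_rate == 0) {
    stopf("stationary_distribution requires mut_rate > 0 (the chain is absorbed at count 0 otherwise)",
          class = "burdengwas_convergence_error")
  }
  n_states <- two_n           # counts 0 .. 2N-1
  k_try <- min(n_states, 512L)
  repeat {
    v <- solve_stationary_states(params, s_het, k_try, truncation, genic)
    tail_mass <- sum(v[max(1L, length(v) - 10L):length(v)])
    if (k_try >= n_states || tail_mass < tail_tol) break
    k_try <- min(n_states, k_try * 4L)
  }
  if (k_try < n_states && tail_mass >= tail_tol) {
    stopf("stationary solve did not confine mass below tail tolerance (residual %g)",
          tail_mass, class = "burdengwas_convergence_error")
  }
  mass <- c(v, rep(0, two_n + 1L - length(v)))
  new_freq_dist(params, s_het, mass, conditioned = TRUE)
}

# Solve the stationary equations of the no-fixation chain restricted to
# counts 0..(k-1). When k spans the full polymorphic range, transitions into
# the fixed class 2N are redirected to count 0; otherwise the clipped upper
# tail is negligible and rows are simply renormalized.
solve_stationary_states <- function(params, s_het, k, truncation, genic) {
  two_n <- 2L * params$n_diploids
  full <- k >= two_n
  col_cap <- if (full) two_n else k - 1L
  rows <- dtwf_rows(0:(k - 1L), two_n, params$mut_rate, s_het, truncation,
                    genic, col_cap = col_cap)
  if (full) {
    # redirect fixation mass to the all-ancestral state
    fixed <- rows$j == two_n
    rows$j[fixed] <- 0L
  }
  q <- Matrix::sparseMatrix(i = rows$i, j = rows$j + 1L, x = rows$x,
                            dims = c(k, k))
  rs <- Matrix::rowSums(q)
  q <- Matrix::Diagonal(x = 1 / rs) %*% q
  a <- Matrix::t(q) - Matrix::Diagonal(k)
  # stationary equations a %*% v = 0; fix v[1] = 1 and drop its (redundant)
  # balance equation, leaving a nonsingular sparse system
  x <- tryCatch(
    as.numeric(Matrix::solve(a[-1L, -1L, drop = FALSE], -a[-1L, 1L])),
    error = function(e) {
      # extreme selection can defeat the sparse LU's pivoting; fall back to
      # a dense partial-pivoting solve when the system is small enough
      tryCatch({
        if (k > 2000L) stop(e)
        as.numeric(solve(as.matrix(a[-1L, -1L, drop = FALSE]),
                         as.numeric(-a[-1L, 1L])))
      }, error = function(e2) stationary_power_iteration(q) )
    }
  )
  v <- c(1, x)
  v[v < 0] <- 0
  v / sum(v)
}

# Last-resort solver for pathological corners (e.g. lethal heterozygote
# selection makes mid-frequency states unreachable and the linear systems
# singular): plain power iteration on the conditioned chain. Returns the
# vector without the fixed-component convention of the LU path.
stationary_power_iteration <- function(q, tol = 1e-13, max_iter = 1e5) {
  k <- nrow(q)
  v <- rep(1 / k, k)
  for (i in seq_len(max_iter)) {
    v_new <- as.numeric(v %*% q)
    v_new <- v_new / sum(v_new)
    delta <- sum(abs(v_new - v))
    v <- v_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    stopf("power-iteration fallback did not converge (residual %g)", delta,
          class = "burdengwas_convergence_error")
  }
  # match the LU path's convention: components relative to state 0
  if (v[1] <= 0) {
    stopf("stationary mass at the all-ancestral state vanished",
          class = "burdengwas_convergence_error")
  }
  v[-1] / v[1]
}

new_freq_dist <- function(params, s_het, mass, conditioned) {
  structure(
    list(params = params, s_het = s_het, mass = mass,
         conditioned = conditioned),
    class = "freq_dist"
  )
}

#' @export
print.freq_dist <- function(x, ...) {
  m <- distribution_moments(x)
  cat(sprintf("DTWF equilibrium frequency distribution (N = %d, mu = %g, s_het = %g%s)\n",
              x$params$n_diploids, x$params$mut_rate, x$s_het,
              if (x$conditioned) ", no fixation" else ""))
  cat(sprintf("  mean frequency %.4g, E[p(1-p)] %.4g, P(segregating) %.4g\n",
              m$mean_freq, m$het, 1 - x$mass[1]))
  invisible(x)
}

#' Moments of a frequency distribution
#'
#' @param dist A `freq_dist` object.
#' @return A list with `mean_freq` (mean derived-allele frequency) and `het`
#'   (the heterozygosity factor `E[p(1-p)]`, which under strong selection is
#'   approximately `mu / s_het`).
#' @export
distribution_moments <- function(dist) {
  stopifnot(inherits(dist, "freq_dist"))
  two_n <- 2L * dist$params$n_diploids
  p <- (seq_along(dist$mass) - 1) / two_n
  list(mean_freq = sum(dist$mass * p), het = sum(dist$mass * p * (1 - p)))
}

#' Grid of equilibrium distributions across selection coefficients
#'
#' Builds `n_points` selection coefficients log-uniformly spaced between `lo`
#' and `hi` (inclusive) and the equilibrium distribution at each. With
#' `eager = FALSE` the distributions are solved lazily on first access via
#' [nearest_distribution()], which pays off when only part of the grid is
#' needed (for example, the pleiotropy simulator only ever visits the
#' strong-selection end).
#'
#' @inheritParams stationary_distribution
#' @param n_points Number of grid values.
#' @param lo,hi Grid endpoints (selection coefficients), `0 < lo < hi`.
#' @param eager Solve all distributions now (`TRUE`) or on demand.
#' @return An object of class `selection_grid`.
#' @export
build_selection_grid <- function(params, n_points = 50, lo = 1e-7, hi = 0.05,
                                 eager = TRUE, truncation = 1e-12,
                                 genic = FALSE) {
  stopifnot(inherits(params, "population_params"))
  if (!is.numeric(lo) || lo <= 0) stopf("lo must be > 0")
  if (hi <= lo) stopf("need lo < hi")
  if (n_points < 2) stopf("n_points must be >= 2")
  s_values <- 10^seq(log10(lo), log10(hi), length.out = n_points)
  s_values[1] <- lo
  s_values[n_points] <- hi
  cache <- new.env(parent = emptyenv())
  grid <- structure(
    list(params = params, s_het_values = s_values, truncation = truncation,
         genic = genic, cache = cache),
    class = "selection_grid"
  )
  if (eager) for (k in seq_len(n_points)) grid_distribution(grid, k)
  grid
}

#' @export
print.selection_grid <- function(x, ...) {
  cat(sprintf("Selection grid: %d log-spaced s_het values in [%g, %g], N = %d, mu = %g (%d solved)\n",
              length(x$s_het_values), min(x$s_het_values), max(x$s_het_values),
              x$params$n_diploids, x$params$mut_rate,
              length(ls(x$cache))))
  invisible(x)
}

#' Distribution at a given grid index, solving it if necessary
#'
#' @param grid A `selection_grid`.
#' @param index Grid index in `1..n_points`.
#' @return A `freq_dist`.
#' @export
grid_distribution <- function(grid, index) {
  stopifnot(inherits(grid, "selection_grid"))
  index <- as.integer(index)
  if (index < 1L || index > length(grid$s_het_values)) {
    stopf("grid index %d out of range", index)
  }
  key <- as.character(index)
  if (is.null(grid$cache[[key]])) {
    grid$cache[[key]] <- stationary_distribution(
      grid$params, grid$s_het_values[index],
      condition_no_fix = TRUE, truncation = grid$truncation,
      genic = grid$genic
    )
  }
  grid$cache[[key]]
}

#' Index of the grid value nearest to a selection coefficient
#'
#' Nearest in log10 distance; values beyond the grid clamp to the endpoint,
#' and an exact log-midpoint tie resolves to the lower index. Vectorized.
#'
#' @param grid A `selection_grid`.
#' @param s_het Positive selection coefficient(s).
#' @return Integer index (vector) into the grid.
#' @export
nearest_grid_index <- function(grid, s_het) {
  stopifnot(inherits(grid, "selection_grid"))
  if (length(grid$s_het_values) == 0L) stopf("empty selection grid")
  if (any(s_het <= 0)) stopf("s_het must be > 0 for grid lookup")
  lg <- log10(grid$s_het_values)
  mids <- (lg[-1] + lg[-length(lg)]) / 2
  x <- log10(pmin(pmax(s_het, grid$s_het_values[1]),
                  grid$s_het_values[length(lg)]))
  # left-open intervals put an exact midpoint with the lower grid value
  findInterval(x, mids, left.open = TRUE) + 1L
}

#' Grid distribution nearest to a selection coefficient
#'
#' @inheritParams nearest_grid_index
#' @return The `freq_dist` at the nearest grid value (see
#'   [nearest_grid_index()] for the tie and clamp rules).
#' @export
nearest_distribution <- function(grid, s_het) {
  check_number(s_het, "s_het", lower = 0, allow_boundary = FALSE)
  grid_distribution(grid, nearest_grid_index(grid, s_het))
}

#' Sample allele frequencies from an equilibrium distribution
#'
#' @param dist A `freq_dist`.
#' @param n Number of independent draws.
#' @param seed Optional integer seed; same seed, same draws.
#' @param segregating_only Condition the draws on the site being polymorphic
#'   (count at least 1). Used when the sampled objects are variants rather
#'   than arbitrary positions.
#' @return Numeric vector of `n` frequencies (count / 2N).
#' @export
sample_frequencies <- function(dist, n, seed = NULL,
                               segregating_only = FALSE) {
  stopifnot(inherits(dist, "freq_dist"))
  if (n < 0) stopf("n must be >= 0")
  if (n == 0) return(numeric(0))
  mass <- dist$mass
  if (segregating_only) {
    mass[1] <- 0
    if (sum(mass) <= 0) stopf("distribution has no segregating mass")
    mass <- mass / sum(mass)
  }
  two_n <- 2L * dist$params$n_diploids
  with_seed(seed, {
    cm <- cumsum(mass)
    findInterval(stats::runif(n), cm) / two_n
  })
}

#' Forward simulation of the Wright-Fisher chain
#'
#' Simulates the same selection, mutation, and binomial-resampling update as
#' [build_transition_matrix()] generation by generation, recording visited
#' counts after a burn-in. With `condition_no_fix = TRUE` a fixation event
#' returns the chain to the all-ancestral state, exactly mirroring the model
#' solved by [stationary_distribution()]; this is the independent sampling
#' oracle used to validate the solver.
#'
#' @inheritParams stationary_distribution
#' @param n_generations Generations recorded after burn-in.
#' @param seed Integer seed (the simulation is deterministic given it).
#' @param burn_in Generations discarded before recording.
#' @param start_count Starting derived-allele count.
#' @return Object of class `wf_forward_sim`: a list with `counts_distribution`
#'   (empirical probabilities over counts `0..2N`), plus the simulation
#'   settings.
#' @export
forward_simulate <- function(params, s_het, n_generations, seed,
                             burn_in = 0L, start_count = 0L,
                             condition_no_fix = TRUE, genic = FALSE) {
  stopifnot(inherits(params, "population_params"))
  check_number(s_het, "s_het", lower = 0, upper = 1)
  if (n_generations < 1) stopf("n_generations must be >= 1")
  two_n <- 2L * params$n_diploids
  pnext <- dtwf_pnext(0:two_n, two_n, params$mut_rate, s_het, genic = genic)
  emp <- with_seed(seed, {
    x <- as.integer(start_count)
    tab <- numeric(two_n + 1L)
    total <- burn_in + n_generations
    for (g in seq_len(total)) {
      x <- stats::rbinom(1L, two_n, pnext[x + 1L])
      if (condition_no_fix && x == two_n) x <- 0L
      if (g > burn_in) tab[x + 1L] <- tab[x + 1L] + 1
    }
    tab / n_generations
  })
  structure(
    list(counts_distribution = emp, params = params, s_het = s_het,
         n_generations = n_generations, burn_in = burn_in,
         conditioned = condition_no_fix),
    class = "wf_forward_sim"
  )
}

#' Total variation distance between two probability vectors
#'
#' @param p,q Probability vectors of equal length.
#' @return Half the L1 distance.
#' @export
total_variation <- function(p, q) {
  if (length(p) != length(q)) stopf("length mismatch")
  0.5 * sum(abs(p - q))
}

#' Write / read a frequency distribution as a tab-separated table
#'
#' The table has columns `count`, `frequency`, `mass`, preceded by a `#`
#' header line recording the population parameters and selection coefficient.
#'
#' @param dist A `freq_dist`.
#' @param path Output file path.
#' @return `write_distribution` returns `path` invisibly;
#'   `read_distribution` returns the `freq_dist`.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "freq_dist"))
  two_n <- 2L * dist$params$n_diploids
  header <- sprintf("# n_diploids=%d mut_rate=%.17g s_het=%.17g conditioned=%d",
                    dist$params$n_diploids, dist$params$mut_rate,
                    dist$s_het, as.integer(dist$conditioned))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("count\tfrequency\tmass", con)
  keep <- dist$mass > 0
  counts <- which(keep) - 1L
  writeLines(sprintf("%d\t%.17g\t%.17g", counts, counts / two_n,
                     dist$mass[keep]), con)
  invisible(path)
}

#' @rdname write_distribution
#' @param path Path to a file written by `write_distribution`.
#' @export
read_distribution <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- regmatches(header, gregexpr("[a-z_]+=[-0-9.e+]+", header))[[1]]
  vals <- stats::setNames(
    as.numeric(sub(".*=", "", kv)),
    sub("=.*", "", kv)
  )
  tab <- utils::read.delim(path, skip = 1L)
  params <- population_params(vals[["n_diploids"]], vals[["mut_rate"]])
  mass <- numeric(2L * params$n_diploids + 1L)
  mass[tab$count + 1L] <- tab$mass
  new_freq_dist(params, vals[["s_het"]], mass / sum(mass),
                conditioned = vals[["conditioned"]] == 1)
}
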