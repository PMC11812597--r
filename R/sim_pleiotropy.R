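# Multi-trait pleiotropy simulator: correlated log-normal squared effects
# across traits, selection proportional to the total squared effect,
# equilibrium frequency assignment, noisy association statistics, hit
# calling, and significance-quartile summaries.

#' Configuration for the GWAS-hit pleiotropy simulation
#'
#' Defaults match the study conditions: 18 traits, 10 million not
#' necessarily segregating positions, specificity parameters
#' `sim_f = 0.33` and `sim_p = 0.5`, an effective sample-size/noise scale
#' `n_eff = 1e7`, and a genome-wide hit threshold of `1e-5`.
#'
#' The squared-effect vector of position `j` is drawn as
#' `alpha2_j = C * exp(3 * sim_f * Z_j)` with
#' `Z_j ~ MVN(0, sim_p * I + (1 - sim_p) * 11')`, exponentiation
#' element-wise. The printed form of the leading constant `C` is ambiguous
#' in the source material; `prefactor = "exp10"` reads it as `10^(-7 sim_f)`
#' (the default - the only reading that produces signal-driven hits and the
#' observed MAF/specificity/pleiotropy gradients), while
#' `prefactor = "linear"` reads it as `1e-7 * sim_f`.
#'
#' @param n_traits Number of traits (at least 2).
#' @param n_positions Number of simulated positions.
#' @param sim_f Scale parameter of the log-normal effects, `> 0`.
#' @param sim_p Off-diagonal mixing parameter in `[0, 1]`; `1` gives
#'   independent traits, `0` perfectly correlated log-effects.
#' @param n_eff Effective sample-size scale of the association noise.
#' @param hit_threshold Genome-wide significance threshold on p-values.
#' @param prefactor `"exp10"` or `"linear"` (see Details).
#' @param block_size Positions processed per block, bounding memory at
#'   roughly `8 * block_size * n_traits * 5` bytes.
#' @return A `pleiotropy_sim_config` list.
#' @export
pleiotropy_sim_config <- function(n_traits = 18, n_positions = 1e7,
                                  sim_f = 0.33, sim_p = 0.5, n_eff = 1e7,
                                  hit_threshold = 1e-5,
                                  prefactor = c("exp10", "linear"),
                                  block_size = 5e5) {
  check_number(n_traits, "n_traits", lower = 2)
  check_number(n_positions, "n_positions", lower = 1)
  check_number(sim_f, "sim_f", lower = 0, allow_boundary = FALSE)
  check_number(sim_p, "sim_p", lower = 0, upper = 1)
  check_number(n_eff, "n_eff", lower = 1)
  check_number(hit_threshold, "hit_threshold", lower = 0, upper = 1,
               allow_boundary = FALSE)
  prefactor <- match.arg(prefactor)
  structure(
    list(n_traits = as.integer(n_traits), n_positions = n_positions,
         sim_f = sim_f, sim_p = sim_p, n_eff = n_eff,
         hit_threshold = hit_threshold, prefactor = prefactor,
         block_size = block_size),
    class = "pleiotropy_sim_config"
  )
}

prefactor_value <- function(config) {
  switch(config$prefactor,
         exp10 = 10^(-7 * config$sim_f),
         linear = 1e-7 * config$sim_f)
}

#' Draw the matrix of squared effect sizes
#'
#' One row per position, one column per trait; see
#' [pleiotropy_sim_config()] for the generative model. Intended for
#' moderate position counts (tests, diagnostics); the full-scale simulation
#' in [run_pleiotropy_sim()] generates blocks internally and never
#' materializes the complete matrix.
#'
#' @param config A [pleiotropy_sim_config()].
#' @param seed Optional integer seed.
#' @param n_positions Override of `config$n_positions`.
#' @return Numeric matrix of strictly positive squared effects.
#' @export
draw_effect_matrix <- function(config, seed = NULL,
                               n_positions = config$n_positions) {
  stopifnot(inherits(config, "pleiotropy_sim_config"))
  with_seed(seed, draw_effect_block(config, n_positions))
}

draw_effect_block <- function(config, n) {
  n <- as.integer(n)
  k <- config$n_traits
  # MVN(0, p I + (1-p) 11') == sqrt(p) * iid + sqrt(1-p) * shared
  z <- sqrt(config$sim_p) * matrix(stats::rnorm(n * k), n, k) +
    sqrt(1 - config$sim_p) * stats::rnorm(n)
  prefactor_value(config) * exp(3 * config$sim_f * z)
}

#' Assign equilibrium allele frequencies from selection strengths
#'
#' Each position's selection strength (the L1 norm of its squared-effect
#' vector) is matched to the grid value with the nearest `s_het` on the
#' log scale, one frequency is sampled from that equilibrium distribution,
#' and frequencies are folded to the minor-allele convention
#' `min(f, 1 - f)`. Positions may be monomorphic (MAF 0).
#'
#' @param selection_strengths Positive selection strengths, one per position.
#' @param grid A [build_selection_grid()].
#' @param seed Optional integer seed.
#' @param segregating_only Condition each draw on the site being
#'   polymorphic. Off by default: the pleiotropy simulator works with "not
#'   necessarily segregating" positions. Turn on when the positions
#'   represent variants in an assayed panel, which segregate by definition.
#' @return Numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @export
assign_frequencies <- function(selection_strengths, grid, seed = NULL,
                               segregating_only = FALSE) {
  stopifnot(inherits(grid, "selection_grid"))
  if (any(selection_strengths <= 0)) stopf("selection strengths must be > 0")
  idx <- nearest_grid_index(grid, selection_strengths)
  two_n <- 2L * grid$params$n_diploids
  with_seed(seed, {
    u <- stats::runif(length(idx))
    f <- numeric(length(idx))
    for (k in unique(idx)) {
      sel <- idx == k
      mass <- grid_distribution(grid, k)$mass
      if (segregating_only) {
        mass[1] <- 0
        mass <- mass / sum(mass)
      }
      f[sel] <- findInterval(u[sel], cumsum(mass)) / two_n
    }
    pmin(f, 1 - f)
  })
}

#' Simulate noisy association statistics
#'
#' Observed effects are Normal about the true (squared-effect) means with
#' variance `1 / (2 n_eff MAF (1 - MAF))`; the squared z-score is
#' `2 n_eff MAF (1 - MAF) * observed^2`, chi-square with 1 df under the
#' null, and p-values are its upper tail. Monomorphic positions (MAF 0)
#' have undefined noise variance: they are flagged with `z_sq = 0`,
#' `p = 1` and a warning, and can never be hits.
#'
#' @param effects Positions-by-traits matrix of true means.
#' @param mafs Minor allele frequencies in `[0, 0.5]`, one per position.
#' @param n_eff Effective sample-size scale.
#' @param seed Optional integer seed.
#' @return List of three positions-by-traits matrices: `observed`, `z_sq`,
#'   `p_value`.
#' @export
simulate_association <- function(effects, mafs, n_eff, seed = NULL) {
  effects <- as.matrix(effects)
  if (length(mafs) != nrow(effects)) stopf("mafs must have one entry per row of effects")
  if (any(mafs < 0 | mafs > 0.5)) stopf("MAFs must be in [0, 0.5]")
  mono <- mafs == 0
  if (any(mono)) {
    warnf("%d monomorphic position(s): association undefined, set to null", sum(mono))
  }
  info <- 2 * n_eff * mafs * (1 - mafs)      # inverse noise variance
  sd_noise <- ifelse(mono, 0, 1 / sqrt(info))
  obs <- with_seed(seed, {
    effects + matrix(stats::rnorm(length(effects)), nrow(effects)) * sd_noise
  })
  z_sq <- info * obs^2
  z_sq[mono, ] <- 0
  list(observed = obs, z_sq = z_sq, p_value = zsq_to_p(z_sq))
}

#' Significance-quartile summaries of simulated GWAS hits
#'
#' Per trait, hits are cells with `p < hit_threshold`. Each trait's hits are
#' ordered by p-value (ties broken by position index, a stable order) and
#' split into four quartiles, quartile 1 the most significant. Per quartile
#' the summary reports the mean MAF relative to that trait's all-hits mean,
#' the mean variant trait specificity, and the mean number of traits in
#' which the variant is a hit. Traits with fewer than 4 hits are excluded
#' and recorded in the `excluded_traits` attribute.
#'
#' @param p_values Positions-by-traits matrix of p-values.
#' @param mafs Minor allele frequencies per position.
#' @param specificities Positions-by-traits matrix of variant trait
#'   specificities (`psi` of each position with the column trait focal).
#' @param hit_threshold Hit-calling threshold.
#' @return A `data.table` with columns `trait`, `quartile`, `n_hits`,
#'   `mean_rel_maf`, `mean_psi`, `mean_traits_hit`.
#' @export
call_and_bin_hits <- function(p_values, mafs, specificities, hit_threshold) {
  p_values <- as.matrix(p_values)
  specificities <- as.matrix(specificities)
  if (!all(dim(p_values) == dim(specificities))) stopf("shape mismatch")
  if (length(mafs) != nrow(p_values)) stopf("mafs must match rows of p_values")
  hits <- p_values < hit_threshold
  n_traits_hit <- rowSums(hits)
  res <- vector("list", ncol(p_values))
  excluded <- integer(0)
  for (tt in seq_len(ncol(p_values))) {
    hi <- which(hits[, tt])
    if (length(hi) < 4L) {
      excluded <- c(excluded, tt)
      next
    }
    ord <- hi[order(p_values[hi, tt], hi)]
    q <- quartile_of(length(ord))
    res[[tt]] <- data.table::data.table(
      trait = tt,
      quartile = 1:4,
      n_hits = as.integer(tabulate(q, 4L)),
      mean_rel_maf = as.numeric(tapply(mafs[ord], q, mean)) / mean(mafs[hi]),
      mean_psi = as.numeric(tapply(specificities[ord, tt], q, mean)),
      mean_traits_hit = as.numeric(tapply(n_traits_hit[ord], q, mean))
    )
  }
  out <- data.table::rbindlist(res)
  data.table::setattr(out, "excluded_traits", excluded)
  out[]
}

# Quartile labels for n ordered items with sizes differing by at most 1,
# larger quartiles first (the most significant end).
quartile_of <- function(n) {
  sizes <- rep(n %/% 4L, 4L) + (seq_len(4L) <= n %% 4L)
  rep(1:4, times = sizes)
}

#' Run the pleiotropy simulation end to end
#'
#' Generates squared-effect vectors in blocks, assigns equilibrium minor
#' allele frequencies by selection strength, simulates association
#' statistics, and retains every position that is a hit for at least one
#' trait. Memory stays bounded by the block size; the default
#' 10-million-position run never materializes the full effect matrix.
#'
#' @param config A [pleiotropy_sim_config()].
#' @param grid A [build_selection_grid()] spanning the relevant selection
#'   strengths (strengths beyond it clamp to the endpoints).
#' @param seed Integer seed; the run is deterministic given it.
#' @return A list with `hits` (a `data.table`: `position`, `maf`,
#'   `selection`, and per-trait p-values/specificities in matrix columns
#'   `p_value`, `psi`, `hit`), `summary` (the [call_and_bin_hits()] table),
#'   `n_hit_cells`, and `n_segregating`.
#' @export
run_pleiotropy_sim <- function(config, grid, seed = NULL) {
  stopifnot(inherits(config, "pleiotropy_sim_config"),
            inherits(grid, "selection_grid"))
  n_total <- config$n_positions
  block <- min(config$block_size, n_total)
  acc <- list()
  n_seg <- 0
  done <- 0
  b <- 0L
  with_seed(seed, {
    while (done < n_total) {
      b <- b + 1L
      n <- as.integer(min(block, n_total - done))
      a2 <- draw_effect_block(config, n)
      strength <- rowSums(a2)
      maf <- assign_frequencies(strength, grid)
      n_seg <- n_seg + sum(maf > 0)
      assoc <- suppressWarnings(
        simulate_association(a2, maf, config$n_eff)
      )
      hit <- assoc$p_value < config$hit_threshold
      keep <- which(rowSums(hit) > 0L)
      if (length(keep)) {
        acc[[b]] <- list(
          position = done + keep,
          maf = maf[keep],
          selection = strength[keep],
          p_value = assoc$p_value[keep, , drop = FALSE],
          psi = a2[keep, , drop = FALSE] / strength[keep],
          hit = hit[keep, , drop = FALSE]
        )
      }
      done <- done + n
      rm(a2, strength, maf, assoc, hit)
      gc(verbose = FALSE)
    }
  })
  if (length(acc) == 0L || all(vapply(acc, is.null, logical(1)))) {
    return(list(hits = NULL, summary = NULL, n_hit_cells = 0L,
                n_segregating = n_seg))
  }
  acc <- Filter(Negate(is.null), acc)
  hits <- list(
    position = unlist(lapply(acc, `[[`, "position")),
    maf = unlist(lapply(acc, `[[`, "maf")),
    selection = unlist(lapply(acc, `[[`, "selection")),
    p_value = do.call(rbind, lapply(acc, `[[`, "p_value")),
    psi = do.call(rbind, lapply(acc, `[[`, "psi")),
    hit = do.call(rbind, lapply(acc, `[[`, "hit"))
  )
  summary <- call_and_bin_hits(hits$p_value, hits$maf, hits$psi,
                               config$hit_threshold)
  list(hits = hits, summary = summary,
       n_hit_cells = sum(hits$hit), n_segregating = n_seg)
}

#' Average quartile summaries across traits
#'
#' @param summary Output table of [call_and_bin_hits()].
#' @return A `data.table` with one row per quartile: across-trait means of
#'   the relative MAF, specificity, and traits-hit columns, plus total hit
#'   counts and the number of contributing traits.
#' @export
aggregate_hit_quartiles <- function(summary) {
  if (is.null(summary) || nrow(summary) == 0L) stopf("empty quartile summary")
  summary[, .(
    n_traits = .N,
    n_hits = sum(n_hits),
    mean_rel_maf = mean(mean_rel_maf),
    mean_psi = mean(mean_psi),
    mean_traits_hit = mean(mean_traits_hit)
  ), by = quartile][order(quartile)]
}
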