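# Closed-form quantities from the stabilizing-selection model of association
# strength: trait importance and specificity, unbiased squared-effect
# estimation from noisy summary statistics, expected burden association
# strength, realized heritability, and the heritability flattening curve.
# All "proportional to" results carry an explicit constant defaulting to 1.

#' Trait specificity of a variant or gene
#'
#' The focal trait's squared effect divided by the summed squared effects
#' across all fitness-relevant traits: `psi = x_focal / sum(x)`. Accepts a
#' single vector of squared effects or a positions-by-traits matrix (one
#' specificity per row).
#'
#' @param squared_effects Non-negative squared effects (`alpha_t^2` for a
#'   variant, `gamma_t^2` for a gene): numeric vector, or matrix with one
#'   trait per column.
#' @param focal Column/position index of the trait under study.
#' @return Specificity in `[0, 1]` (vector input) or a vector of
#'   specificities (matrix input).
#' @examples
#' trait_specificity(c(4, 1, 1))     # 2/3
#' @export
trait_specificity <- function(squared_effects, focal = 1L) {
  if (is.matrix(squared_effects)) {
    if (focal < 1L || focal > ncol(squared_effects)) stopf("focal index out of range")
    if (any(squared_effects < 0)) stopf("squared effects must be >= 0")
    tot <- rowSums(squared_effects)
    if (any(tot == 0)) stopf("specificity undefined for all-zero effect vectors")
    return(squared_effects[, focal] / tot)
  }
  if (focal < 1L || focal > length(squared_effects)) stopf("focal index out of range")
  if (any(squared_effects < 0)) stopf("squared effects must be >= 0")
  tot <- sum(squared_effects)
  if (tot == 0) stopf("specificity undefined for all-zero effect vectors")
  squared_effects[focal] / tot
}

#' Unbiased estimate of a squared effect from a noisy estimate
#'
#' For an effect estimate `b` that is approximately Normal about the true
#' effect with standard error `se`, `b^2` overestimates the squared effect by
#' `se^2`; `b^2 - se^2` removes that bias. The result may be negative:
#' unbiasedness, not positivity, is the contract.
#'
#' @param estimate Effect estimate(s) (`gamma-hat` or `alpha-hat`).
#' @param se Standard error(s), positive.
#' @return `estimate^2 - se^2`, vectorized.
#' @export
unbiased_importance <- function(estimate, se) {
  if (any(se <= 0)) stopf("standard errors must be > 0")
  estimate^2 - se^2
}

#' Expected burden-test association strength
#'
#' The expected squared z-score of a gene's LoF burden test is proportional
#' to `gamma1_sq * p_lof * (1 - p_lof)`, the product of the gene's focal
#' trait importance and the binomial variance of its aggregate LoF frequency.
#'
#' @param gamma1_sq Focal-trait importance (squared LoF effect on the study
#'   trait).
#' @param p_lof Aggregate LoF allele frequency in `[0, 1]`.
#' @param const Proportionality constant (study-wide scale), default 1.
#' @return Relative expected squared z-score, vectorized.
#' @export
expected_burden_strength <- function(gamma1_sq, p_lof, const = 1) {
  if (any(gamma1_sq < 0)) stopf("gamma1_sq must be >= 0")
  if (any(p_lof < 0 | p_lof > 1)) stopf("p_lof must be in [0, 1]")
  const * gamma1_sq * p_lof * (1 - p_lof)
}

#' Expected LoF heterozygosity at mutation-selection balance
#'
#' Under sufficiently strong selection the aggregate LoF frequency satisfies
#' `p_lof (1 - p_lof) ~ mu * L / s_het`, where `mu` is the per-site mutation
#' rate and `L` the number of sites at which an LoF can arise. Clipped to
#' `[0, 0.25]`, the binomial-variance maximum.
#'
#' @param mu Per-site per-generation mutation rate.
#' @param L Number of LoF-mutable sites (mutational target size).
#' @param s_het Selection coefficient against heterozygous LoF carriers.
#' @param scale_c Proportionality constant, default 1.
#' @return Expected `p_lof (1 - p_lof)`, vectorized.
#' @export
expected_plof_product <- function(mu, L, s_het, scale_c = 1) {
  if (any(mu <= 0) || any(L <= 0) || any(s_het <= 0) || any(scale_c <= 0)) {
    stopf("all arguments must be positive")
  }
  pmin(scale_c * mu * L / s_het, 0.25)
}

#' Realized heritability of a variant
#'
#' A variant's actual contribution to trait heritability: `2 alpha1^2 p(1-p)`
#' for focal squared effect `alpha1^2` and allele frequency `p`. In a
#' well-powered GWAS, variants are ranked by this quantity.
#'
#' @param alpha1_sq Focal-trait squared effect.
#' @param p Allele frequency in `[0, 1]`.
#' @return `2 * alpha1_sq * p * (1 - p)`, vectorized.
#' @export
realized_heritability <- function(alpha1_sq, p) {
  if (any(p < 0 | p > 1)) stopf("p must be in [0, 1]")
  2 * alpha1_sq * p * (1 - p)
}

#' Heritability proxy from a squared z-score
#'
#' Under the Normal summary-statistic model, `E[z^2] = 1 + n h2_j`-type
#' relations make `z^2 - 1` proportional to the heritability tagged by the
#' test; its null expectation is exactly 0 and negative values are allowed.
#'
#' @param z_sq Squared z-score(s), non-negative.
#' @return `z_sq - 1`, vectorized.
#' @export
heritability_proxy <- function(z_sq) {
  if (any(z_sq < 0)) stopf("z_sq must be >= 0")
  z_sq - 1
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha Family-wise error rate in `(0, 1)`.
#' @param n_tests Number of tests, at least 1.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 18524)   # ~2.7e-6
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  check_number(alpha, "alpha", lower = 0, upper = 1, allow_boundary = FALSE)
  check_number(n_tests, "n_tests", lower = 1)
  alpha / n_tests
}

#' Expected heritability contribution as a function of total effect size
#'
#' The flattening curve: for a variant with total effect `alpha^2` on a trait
#' and trait specificity `psi`, the stabilizing-selection model implies a
#' selection strength `s_het = alpha^2 / psi` (total squared effects summed
#' across traits), so the expected contribution to heritability is
#' `2 * alpha^2 * E[p(1-p)]` evaluated under the equilibrium frequency
#' distribution at that selection strength. The curve first rises linearly
#' with `alpha^2` while selection is effectively neutral, then flattens to a
#' plateau of about `2 * mu * psi` per site once `E[p(1-p)] ~ mu / s_het`.
#'
#' @param alpha2_grid Ascending positive total squared effects at which to
#'   evaluate the curve.
#' @param psi Trait specificity in `(0, 1]`, shared by all evaluated variants.
#' @param grid A [build_selection_grid()] whose population parameters define
#'   the equilibrium distributions.
#' @return A `data.frame` with columns `alpha_sq`, `s_het_implied`,
#'   `s_het_used` (grid value after clamping), and `expected_h2`.
#' @export
flattening_curve <- function(alpha2_grid, psi, grid) {
  check_number(psi, "psi", lower = 0, upper = 1, allow_boundary = TRUE)
  if (psi <= 0) stopf("psi must be in (0, 1]")
  if (any(alpha2_grid <= 0)) stopf("alpha2_grid must be positive")
  if (is.unsorted(alpha2_grid, strictly = FALSE)) stopf("alpha2_grid must be ascending")
  stopifnot(inherits(grid, "selection_grid"))
  s_implied <- alpha2_grid / psi
  s_range <- range(grid$s_het_values)
  if (any(s_implied < s_range[1] | s_implied > s_range[2])) {
    warnf("implied s_het outside the grid range [%g, %g]; clamping to the nearest endpoint",
          s_range[1], s_range[2])
  }
  idx <- nearest_grid_index(grid, s_implied)
  het <- vapply(idx, function(k) distribution_moments(grid_distribution(grid, k))$het,
                numeric(1))
  data.frame(
    alpha_sq = alpha2_grid,
    s_het_implied = s_implied,
    s_het_used = grid$s_het_values[idx],
    expected_h2 = 2 * alpha2_grid * het
  )
}

#' Build a validated table of association summary records
#'
#' Checks the internal consistency of gene- or variant-level summary
#' statistics: positive standard errors, finite squared z-scores, and (when
#' p-values are supplied) agreement between the p-value and the two-sided
#' 1-df chi-square tail of `(estimate/se)^2`.
#'
#' @param id Gene or variant identifiers.
#' @param estimate Effect estimates.
#' @param se Standard errors, positive.
#' @param p_value Optional p-values in `(0, 1]`; computed from the z-scores
#'   when missing.
#' @param tol Allowed absolute discrepancy between supplied and recomputed
#'   p-values.
#' @return A `data.frame` with columns `id`, `estimate`, `se`, `z_sq`,
#'   `p_value`.
#' @export
summary_records <- function(id, estimate, se, p_value = NULL, tol = 1e-6) {
  if (any(se <= 0)) stopf("standard errors must be > 0")
  z_sq <- (estimate / se)^2
  if (any(!is.finite(z_sq))) stopf("non-finite z-scores")
  p_from_z <- zsq_to_p(z_sq)
  if (is.null(p_value)) {
    p_value <- p_from_z
  } else {
    if (any(p_value <= 0 | p_value > 1)) stopf("p-values must be in (0, 1]")
    bad <- abs(p_value - p_from_z) > tol
    if (any(bad)) {
      stopf("%d record(s) have p-values inconsistent with (estimate/se)^2 beyond tol %g",
            sum(bad), tol)
    }
  }
  data.frame(id = as.character(id), estimate = estimate, se = se,
             z_sq = z_sq, p_value = p_value, stringsAsFactors = FALSE)
}
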