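# Quantile binning, per-bin means with empirical standard errors,
# inverse-variance-weighted cross-trait combination, and enrichment
# renormalization.

#' Equal-count quantile bin assignments
#'
#' Splits values into `n_bins` rank-based bins of equal count; when the
#' count does not divide evenly, the lowest bins receive one extra item
#' each. Ties stay adjacent (stable sort on value, then input order).
#'
#' @param values Finite numeric vector.
#' @param n_bins Number of bins, at least 1 and at most `length(values)`.
#' @return Integer vector of bin indices (1 = smallest values), aligned
#'   with the input order.
#' @export
quantile_bins <- function(values, n_bins) {
  if (any(!is.finite(values))) stopf("values must be finite")
  check_number(n_bins, "n_bins", lower = 1)
  n <- length(values)
  if (n < n_bins) stopf("fewer values (%d) than bins (%d)", n, n_bins)
  n_bins <- as.integer(n_bins)
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  ord <- order(values, seq_along(values))      # stable
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

#' Per-bin means with empirical standard errors
#'
#' @param values Numeric vector.
#' @param assignments Bin indices from [quantile_bins()].
#' @return A `data.table` with `bin`, `mean`, `se` (sd / sqrt(n); reported
#'   as 0 with `degenerate = TRUE` for single-item bins), `n`, and the bin
#'   boundary values `min_value`, `max_value`.
#' @export
bin_mean_se <- function(values, assignments) {
  if (length(values) != length(assignments)) stopf("length mismatch")
  dt <- data.table::data.table(v = values, bin = assignments)
  out <- dt[, .(
    mean = mean(v),
    se = if (.N > 1L) stats::sd(v) / sqrt(.N) else 0,
    n = .N,
    min_value = min(v),
    max_value = max(v),
    degenerate = .N == 1L
  ), by = bin]
  data.table::setorder(out, bin)
  out[]
}

#' Inverse-variance-weighted combination
#'
#' Weights `1/se^2`; the combined estimate is the weighted mean and its
#' standard error the square root of the reciprocal total weight. Infinite
#' standard errors contribute zero weight; zero standard errors are an
#' input error.
#'
#' @param estimates Numeric vector.
#' @param standard_errors Positive (possibly infinite) standard errors.
#' @return List with `estimate` and `se`.
#' @export
ivw_combine <- function(estimates, standard_errors) {
  if (length(estimates) != length(standard_errors)) stopf("length mismatch")
  if (any(standard_errors <= 0)) stopf("standard errors must be > 0")
  w <- 1 / standard_errors^2
  if (sum(w) == 0) stopf("all weights are zero")
  list(estimate = sum(w * estimates) / sum(w), se = sqrt(1 / sum(w)))
}

#' Renormalize values to a reference scale
#'
#' `mode = "mean"` divides by the mean so the result averages to one;
#' `mode = "sum"` divides by the sum so the result sums to one.
#'
#' @param values Numeric vector with nonzero mean.
#' @param mode `"mean"` or `"sum"`.
#' @return Rescaled vector.
#' @export
enrichment_normalize <- function(values, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  denom <- switch(mode, mean = mean(values), sum = sum(values))
  if (denom == 0) stopf("cannot renormalize: %s is zero", mode)
  values / denom
}

#' Per-bin heritability enrichment from squared z-scores
#'
#' Implements the relative `z^2 - 1` proxy pipeline: per trait, each gene's
#' `z^2 - 1` is divided by the trait's global mean of `z^2 - 1`; per bin
#' the relative values are averaged with an empirical standard error; the
#' per-trait bin estimates are combined across traits by inverse-variance
#' weighting; and the combined estimates are renormalized (to average one
#' by default). Traits whose global mean of `z^2 - 1` is not positive carry
#' no heritability signal on this scale and are excluded with a warning.
#'
#' @param z_sq_matrix Genes-by-traits matrix of squared z-scores.
#' @param assignments Bin index per gene ([quantile_bins()]).
#' @param normalize Final renormalization mode, `"mean"` or `"sum"`.
#' @return A `data.table` with `bin`, `enrichment`, `se`, `n_genes`,
#'   `n_traits`.
#' @export
relative_proxy_enrichment <- function(z_sq_matrix, assignments,
                                      normalize = c("mean", "sum")) {
  normalize <- match.arg(normalize)
  z_sq_matrix <- as.matrix(z_sq_matrix)
  if (nrow(z_sq_matrix) != length(assignments)) stopf("assignments must match rows")
  proxy <- z_sq_matrix - 1
  global <- colMeans(proxy)
  usable <- global > 0
  if (!any(usable)) stopf("no trait has a positive global mean of z^2 - 1")
  if (any(!usable)) {
    warnf("excluding %d trait(s) with nonpositive global mean z^2 - 1", sum(!usable))
  }
  bins <- sort(unique(assignments))
  per_trait <- lapply(which(usable), function(tt) {
    rel <- proxy[, tt] / global[tt]
    bin_mean_se(rel, assignments)
  })
  comb <- lapply(bins, function(b) {
    est <- vapply(per_trait, function(x) x$mean[x$bin == b], numeric(1))
    se <- vapply(per_trait, function(x) x$se[x$bin == b], numeric(1))
    se[se == 0] <- Inf           # degenerate bins carry no weight
    if (all(!is.finite(se))) {
      return(list(estimate = mean(est), se = NA_real_))
    }
    ivw_combine(est, se)
  })
  out <- data.table::data.table(
    bin = bins,
    enrichment = vapply(comb, `[[`, numeric(1), "estimate"),
    se = vapply(comb, `[[`, numeric(1), "se"),
    n_genes = as.integer(tabulate(assignments)[bins]),
    n_traits = sum(usable)
  )
  scale_factor <- switch(normalize,
                         mean = mean(out$enrichment),
                         sum = sum(out$enrichment))
  if (scale_factor == 0) stopf("cannot renormalize: zero %s enrichment", normalize)
  out[, `:=`(enrichment = enrichment / scale_factor, se = se / abs(scale_factor))]
  out[]
}
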