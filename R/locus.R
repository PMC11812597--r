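# GWAS locus definition and the locus-level / LD-block-level comparison of
# GWAS and LoF burden discoveries, operating purely on summary tables.
# Coordinates are 1-based inclusive throughout (BED input is converted on
# read by read_bed()).

#' Group LD-clumped GWAS hits into non-overlapping loci
#'
#' Processes hits in ascending p-value order. The most significant
#' unassigned hit seeds a locus, which transitively absorbs every
#' unassigned hit within `window` of any current member, until no further
#' hit is that close; the procedure repeats until all hits are assigned.
#' Two hits in different loci on the same chromosome are therefore always
#' more than `window` apart, and the result does not depend on the input
#' row order (p-value ties break by chromosome, then position).
#'
#' @param hits `data.frame` with columns `variant`, `chrom`, `pos`
#'   (1-based), `pval`; extra columns are carried along.
#' @param window Maximum distance (bp) at which a hit joins a locus.
#' @return A `data.table` of loci: `locus`, `chrom`, `start`, `end`,
#'   `n_hits`, `min_pval`, `lead_variant`, and `members` (list column of
#'   variant ids ordered by position), ranked by `min_pval`.
#' @export
group_loci <- function(hits, window = 1e6) {
  hits <- validate_hits(hits)
  if (anyDuplicated(hits$variant)) stopf("duplicate variant ids in hits")
  ord <- order(hits$pval, hits$chrom, hits$pos)
  assigned <- integer(nrow(hits))          # locus id per hit, 0 = unassigned
  locus_id <- 0L
  for (i in ord) {
    if (assigned[i] != 0L) next
    locus_id <- locus_id + 1L
    same_chr <- which(hits$chrom == hits$chrom[i] & assigned == 0L)
    pos <- hits$pos[same_chr]
    o <- order(pos)
    same_chr <- same_chr[o]
    pos <- pos[o]
    seed_at <- match(i, same_chr)
    # transitive closure on a line: extend over consecutive unassigned hits
    # while the gap to the next one is within the window
    lo <- seed_at
    while (lo > 1L && pos[lo] - pos[lo - 1L] <= window) lo <- lo - 1L
    hi <- seed_at
    while (hi < length(pos) && pos[hi + 1L] - pos[hi] <= window) hi <- hi + 1L
    assigned[same_chr[lo:hi]] <- locus_id
  }
  dt <- data.table::as.data.table(hits)
  dt[, .locus_raw := assigned]
  loci <- dt[, .(
    chrom = chrom[1],
    start = min(pos),
    end = max(pos),
    n_hits = .N,
    min_pval = min(pval),
    lead_variant = variant[which.min(pval)],
    members = list(variant[order(pos)])
  ), by = .locus_raw]
  data.table::setorder(loci, min_pval, chrom, start)
  loci[, locus := sprintf("locus_%04d", seq_len(.N))]
  loci[, .locus_raw := NULL]
  data.table::setcolorder(loci, c("locus", "chrom", "start", "end", "n_hits",
                                  "min_pval", "lead_variant", "members"))
  loci[]
}

validate_hits <- function(hits) {
  need <- c("variant", "chrom", "pos", "pval")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stopf("hits table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(hits$pval <= 0 | hits$pval > 1)) stopf("hit p-values must be in (0, 1]")
  if (any(hits$pos < 1)) stopf("positions must be >= 1")
  hits
}

validate_genes <- function(genes) {
  need <- c("gene", "chrom", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stopf("gene table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(genes$start > genes$end)) stopf("gene start > end")
  genes <- data.table::as.data.table(genes)
  if (!"midpoint" %in% names(genes)) {
    genes[, midpoint := floor((start + end) / 2)]
  }
  genes
}

#' Assign overlapping genes to loci
#'
#' A gene is assigned to a locus iff its interval intersects the locus span
#' (inclusive coordinates; sharing a single base counts).
#'
#' @param loci Output of [group_loci()].
#' @param genes `data.frame` with columns `gene`, `chrom`, `start`, `end`.
#' @return The loci table with an added list column `genes` (gene ids) and
#'   `n_genes`.
#' @export
assign_genes <- function(loci, genes) {
  genes <- validate_genes(genes)
  loci <- data.table::copy(data.table::as.data.table(loci))
  loci[, genes := lapply(seq_len(.N), function(k) {
    g <- genes[chrom == loci$chrom[k] & start <= loci$end[k] &
                 end >= loci$start[k]]
    g$gene
  })]
  loci[, n_genes := vapply(genes, length, integer(1))]
  loci[]
}

#' Power-matched selection of top GWAS loci and their genes
#'
#' Ranks loci by minimum GWAS p-value and walks down the ranking. From each
#' locus it selects every overlapping gene that is significant in the LoF
#' burden test; if none is, it selects the single overlapping gene with the
#' smallest burden p-value (a locus overlapping no genes contributes
#' nothing but still consumes a rank slot). Selection stops once the number
#' of selected genes reaches the number of burden-significant genes
#' genome-wide; the final locus is included in full, so the count may
#' overshoot (set `strict_stop = TRUE` to truncate the final locus's
#' contribution at the target instead).
#'
#' @param loci Gene-assigned loci ([assign_genes()]).
#' @param burden Burden summary table with columns `gene` and `pval`,
#'   covering the gene universe.
#' @param burden_threshold Burden genome-wide significance threshold.
#' @param strict_stop Truncate at exactly the target count.
#' @return List: `selected_genes`, `top_loci` (locus ids in rank order),
#'   `target` (number of burden-significant genes), `n_selected`.
#' @export
select_top_locus_genes <- function(loci, burden, burden_threshold,
                                   strict_stop = FALSE) {
  loci <- data.table::as.data.table(loci)
  if (!"genes" %in% names(loci)) stopf("loci must be gene-assigned; run assign_genes()")
  sig_genes <- unique(burden$gene[burden$pval < burden_threshold])
  target <- length(sig_genes)
  if (target == 0L) {
    warnf("no burden-significant genes at threshold %g; empty selection", burden_threshold)
    return(list(selected_genes = character(0), top_loci = character(0),
                target = 0L, n_selected = 0L))
  }
  burden_p <- stats::setNames(burden$pval, burden$gene)
  ord <- order(loci$min_pval, loci$chrom, loci$start)
  selected <- character(0)
  top <- character(0)
  for (k in ord) {
    top <- c(top, loci$locus[k])
    gs <- loci$genes[[k]]
    if (length(gs)) {
      known <- gs[gs %in% names(burden_p)]
      pick <- known[burden_p[known] < burden_threshold]
      if (length(pick) == 0L && length(known)) {
        pick <- known[which.min(burden_p[known])]
      }
      new <- setdiff(pick, selected)
      if (strict_stop && length(selected) + length(new) > target) {
        new <- new[seq_len(target - length(selected))]
      }
      selected <- c(selected, new)
    }
    if (length(selected) >= target) break
  }
  list(selected_genes = selected, top_loci = top, target = target,
       n_selected = length(selected))
}

#' Fraction of burden-significant genes contained in top GWAS loci
#'
#' @param significant_genes Character vector of burden-significant gene ids.
#' @param top_loci Gene-assigned loci table restricted to the top loci (or
#'   the full table plus a vector of top locus ids via `locus_ids`).
#' @param locus_ids Optional subset of locus ids to treat as the top loci.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(significant_genes, top_loci, locus_ids = NULL) {
  if (length(significant_genes) == 0L) stopf("no significant burden genes: fraction undefined")
  top_loci <- data.table::as.data.table(top_loci)
  if (!is.null(locus_ids)) top_loci <- top_loci[locus %in% locus_ids]
  contained <- unique(unlist(top_loci$genes))
  mean(significant_genes %in% contained)
}

#' Locus-level concordance between GWAS and burden minima
#'
#' For every locus overlapping at least one gene, pairs the locus's minimum
#' GWAS p-value with the minimum burden p-value across its genes, and
#' reports the Spearman correlation of the two on the -log10 scale.
#'
#' @param loci Gene-assigned loci.
#' @param burden Burden table (`gene`, `pval`).
#' @return List: `pairs` (a `data.table` with `locus`, `min_gwas_p`,
#'   `min_burden_p`), `rho` (`NA` if fewer than 3 loci have genes),
#'   `defined`.
#' @export
locus_concordance <- function(loci, burden) {
  loci <- data.table::as.data.table(loci)
  if (!"genes" %in% names(loci)) stopf("loci must be gene-assigned; run assign_genes()")
  burden_p <- stats::setNames(burden$pval, burden$gene)
  keep <- vapply(loci$genes, function(g) any(g %in% names(burden_p)), logical(1))
  sub <- loci[keep]
  pairs <- data.table::data.table(
    locus = sub$locus,
    min_gwas_p = sub$min_pval,
    min_burden_p = vapply(sub$genes, function(g) {
      min(burden_p[g[g %in% names(burden_p)]])
    }, numeric(1))
  )
  if (nrow(pairs) < 3L) {
    return(list(pairs = pairs, rho = NA_real_, defined = FALSE))
  }
  rho <- stats::cor(-log10(pairs$min_gwas_p), -log10(pairs$min_burden_p),
                    method = "spearman")
  list(pairs = pairs, rho = rho, defined = is.finite(rho))
}

#' LD-block-level comparison of GWAS and burden minima
#'
#' Per block: the minimum GWAS p-value over variants inside the block and
#' the minimum burden p-value over genes overlapping any part of it. Blocks
#' with no variants or no overlapping genes are excluded. Whenever
#' consecutive retained blocks share the identical minimum-burden gene (one
#' significant gene spanning them), the whole run of blocks is dropped.
#'
#' @param blocks Block intervals (`chrom`, `start`, `end`, 1-based
#'   inclusive, non-overlapping within chromosome), e.g. from [read_bed()].
#' @param gwas_variants Variant table with `chrom`, `pos`, `pval`.
#' @param burden Burden table (`gene`, `pval`).
#' @param genes Gene table (`gene`, `chrom`, `start`, `end`).
#' @return A `data.table` with `chrom`, `start`, `end`, `min_gwas_p`,
#'   `min_burden_p`, `min_burden_gene`; dropped duplicate runs are recorded
#'   in the `n_dropped_duplicates` attribute.
#' @export
ld_block_compare <- function(blocks, gwas_variants, burden, genes) {
  blocks <- data.table::as.data.table(blocks)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(blocks))) stopf("blocks need chrom/start/end")
  data.table::setorder(blocks, chrom, start)
  overl <- blocks[, any(start[-1] <= end[-.N]), by = chrom]$V1
  if (any(overl)) stopf("overlapping blocks within a chromosome")
  genes <- validate_genes(genes)
  burden_p <- stats::setNames(burden$pval, burden$gene)
  rows <- vector("list", nrow(blocks))
  for (k in seq_len(nrow(blocks))) {
    v <- gwas_variants[gwas_variants$chrom == blocks$chrom[k] &
                         gwas_variants$pos >= blocks$start[k] &
                         gwas_variants$pos <= blocks$end[k], ]
    if (nrow(v) == 0L) next
    g <- genes[chrom == blocks$chrom[k] & start <= blocks$end[k] &
                 end >= blocks$start[k]]
    g <- g[gene %in% names(burden_p)]
    if (nrow(g) == 0L) next
    bp <- burden_p[g$gene]
    rows[[k]] <- data.table::data.table(
      chrom = blocks$chrom[k], start = blocks$start[k], end = blocks$end[k],
      min_gwas_p = min(v$pval),
      min_burden_p = min(bp),
      min_burden_gene = g$gene[which.min(bp)]
    )
  }
  out <- data.table::rbindlist(Filter(Negate(is.null), rows))
  if (nrow(out) == 0L) {
    data.table::setattr(out, "n_dropped_duplicates", 0L)
    return(out)
  }
  data.table::setorder(out, chrom, start)
  # runs of consecutive blocks sharing the same minimum-burden gene
  run_id <- cumsum(c(TRUE, out$min_burden_gene[-1] != out$min_burden_gene[-nrow(out)] |
                       out$chrom[-1] != out$chrom[-nrow(out)]))
  run_len <- stats::ave(run_id, run_id, FUN = length)
  dropped <- sum(run_len > 1)
  out <- out[run_len == 1]
  data.table::setattr(out, "n_dropped_duplicates", as.integer(dropped))
  out[]
}

#' Count GWAS hits assigned to their nearest gene
#'
#' Each hit is assigned to the gene with the nearest midpoint on its
#' chromosome (equidistant ties go to the gene with the smaller start
#' coordinate). Hits on chromosomes without genes stay unassigned, with a
#' warning.
#'
#' @param hits Hit table (`chrom`, `pos`).
#' @param genes Gene table (`gene`, `chrom`, `start`, `end`, optional
#'   `midpoint`).
#' @return A `data.table` with one row per gene: `gene`, `n_hits` (zeros
#'   included); the number of unassignable hits is in the
#'   `n_unassigned` attribute.
#' @export
nearest_gene_hit_counts <- function(hits, genes) {
  genes <- validate_genes(genes)
  counts <- stats::setNames(integer(nrow(genes)), genes$gene)
  unassigned <- 0L
  for (cc in unique(hits$chrom)) {
    h <- hits[hits$chrom == cc, ]
    g <- genes[chrom == cc]
    if (nrow(g) == 0L) {
      unassigned <- unassigned + nrow(h)
      next
    }
    # order candidate genes by (midpoint, start) so ties at equal midpoint
    # distance resolve to the smaller start coordinate; genes sharing a
    # midpoint collapse to the smaller-start gene for assignment
    data.table::setorder(g, midpoint, start)
    g <- g[!duplicated(midpoint)]
    mids <- g$midpoint
    left <- findInterval(h$pos, mids)            # last midpoint <= pos
    left[left == 0L] <- 1L
    right <- pmin(left + 1L, nrow(g))
    d_left <- abs(h$pos - mids[left])
    d_right <- abs(h$pos - mids[right])
    pick_left <- d_left < d_right |
      (d_left == d_right & (g$start[left] <= g$start[right]))
    chosen <- ifelse(pick_left, g$gene[left], g$gene[right])
    tab <- table(chosen)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  if (unassigned > 0L) {
    warnf("%d hit(s) on chromosomes without genes were left unassigned", unassigned)
  }
  out <- data.table::data.table(gene = names(counts), n_hits = as.integer(counts))
  data.table::setattr(out, "n_unassigned", unassigned)
  out[]
}

#' Correlation between per-gene hit counts and trait importance
#'
#' Reports both Pearson and Spearman correlations, optionally restricted to
#' genes with at least one hit.
#'
#' @param counts Per-gene hit counts ([nearest_gene_hit_counts()] order).
#' @param importance Per-gene importance estimates, aligned with `counts`.
#' @param hits_only Restrict to genes with `counts > 0`.
#' @return Named numeric vector `c(pearson = , spearman = )`.
#' @export
hit_count_importance_cor <- function(counts, importance, hits_only = FALSE) {
  if (length(counts) != length(importance)) stopf("length mismatch")
  if (hits_only) {
    keep <- counts > 0
    counts <- counts[keep]
    importance <- importance[keep]
  }
  c(pearson = stats::cor(counts, importance),
    spearman = stats::cor(counts, importance, method = "spearman"))
}
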