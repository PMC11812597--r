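# Synthetic study generator: gene annotations, LoF burden summary
# statistics, GWAS summary statistics with a clumped hit list, and LD
# blocks, all with full ground truth. The generator emulates the schemas
# and the statistical structure the analysis assumes (per-gene selection
# coefficients coupled to summed trait effects, specificity-structured
# multi-trait effects, mutation-selection-balance LoF frequencies, and
# sampling noise on effect estimates); it makes no attempt at realistic LD
# or gene structure.

#' Configuration of the synthetic study
#'
#' Defaults mirror the real studies being emulated: 18,524 protein-coding
#' genes, 27 genetically uncorrelated traits, and burden/GWAS sample sizes
#' of about 360,000 individuals. Gene squared effects per trait use the
#' same correlated log-normal structure as the pleiotropy simulator
#' (`sim_f`, `sim_p`), scaled by `gene_effect_scale` and a per-gene overall
#' magnitude with log-sd `gene_magnitude_sdlog`, so that per-gene selection
#' coefficients `s_het = sum_t gamma_t^2` span roughly `1e-4` to `1`.
#' The LoF mutational target `mu*L` is log-normal (`mu_l_meanlog`,
#' `mu_l_sdlog`), a proxy for coding-sequence length, and the aggregate LoF
#' frequency is `p_lof = lof_scale_c * mu*L / s_het`, clipped to the burden
#' mask's 1% bound.
#'
#' @param n_genes Number of genes.
#' @param n_traits Number of traits; trait 1 is the focal study trait.
#' @param n_chromosomes Number of chromosomes genes are spread over.
#' @param chrom_length Chromosome length in bp.
#' @param burden_n,gwas_n Sample sizes (individuals) of the burden study
#'   and the GWAS.
#' @param sim_f,sim_p Effect-structure parameters shared with
#'   [pleiotropy_sim_config()].
#' @param gene_effect_scale Per-trait squared-effect scale.
#' @param gene_magnitude_sdlog Log-sd of the per-gene overall magnitude.
#' @param mu_l_meanlog,mu_l_sdlog Log-normal parameters of `mu*L`.
#' @param lof_scale_c Proportionality constant of the balance frequency.
#' @param variants_per_gene Mean number of candidate regulatory variants
#'   per gene (Poisson, plus one).
#' @param variant_window Variants are placed within this distance of the
#'   gene midpoint.
#' @param reg_magnitude_meanlog,reg_magnitude_sdlog Log-normal parameters
#'   of the regulatory magnitude `b` linking variant effects to gene
#'   effects (`alpha_t = b * gamma_t`).
#' @param gwas_threshold Genome-wide significance threshold for the
#'   emitted hit list.
#' @param hit_spacing Minimum spacing (bp) enforced among emitted hits of a
#'   chromosome, standing in for LD-clump independence.
#' @param seed Mandatory integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 18524, n_traits = 27,
                             n_chromosomes = 22, chrom_length = 1.25e8,
                             burden_n = 360000, gwas_n = 1e6,
                             sim_f = 0.33, sim_p = 0.5,
                             gene_effect_scale = 2e-4,
                             gene_magnitude_sdlog = 1.5,
                             mu_l_meanlog = log(5e-5), mu_l_sdlog = 1.2,
                             lof_scale_c = 1,
                             variants_per_gene = 15, variant_window = 3e5,
                             reg_magnitude_meanlog = log(0.25),
                             reg_magnitude_sdlog = 0.7,
                             gwas_threshold = 5e-8, hit_spacing = 1e4,
                             seed) {
  if (missing(seed) || is.null(seed)) stopf("synthetic_config requires a seed")
  check_number(n_genes, "n_genes", lower = 1)
  check_number(n_traits, "n_traits", lower = 2)
  check_number(n_chromosomes, "n_chromosomes", lower = 1)
  check_number(chrom_length, "chrom_length", lower = 1e5)
  structure(
    list(n_genes = as.integer(n_genes), n_traits = as.integer(n_traits),
         n_chromosomes = as.integer(n_chromosomes),
         chrom_length = chrom_length, burden_n = burden_n, gwas_n = gwas_n,
         sim_f = sim_f, sim_p = sim_p,
         gene_effect_scale = gene_effect_scale,
         gene_magnitude_sdlog = gene_magnitude_sdlog,
         mu_l_meanlog = mu_l_meanlog, mu_l_sdlog = mu_l_sdlog,
         lof_scale_c = lof_scale_c,
         variants_per_gene = variants_per_gene,
         variant_window = variant_window,
         reg_magnitude_meanlog = reg_magnitude_meanlog,
         reg_magnitude_sdlog = reg_magnitude_sdlog,
         gwas_threshold = gwas_threshold, hit_spacing = hit_spacing,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate gene annotations with ground-truth effects
#'
#' Places non-overlapping gene intervals across chromosomes, draws per-gene
#' per-trait squared effects with the correlated log-normal structure,
#' sets `s_het` to their sum (clipped to `s_range`), draws `mu*L`
#' log-normally, and computes balance LoF frequencies
#' `p_lof = c * mu*L / s_het` clipped to `(0, 0.01]`.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional override of `config$seed`.
#' @param s_range Selection coefficients are clipped to this range (set it
#'   to the frequency-grid range when the truth feeds a grid lookup).
#' @return List with `genes` (a `data.table`: `gene`, `chrom`, `start`,
#'   `end`, `midpoint`, `mu_l`, `s_het`) and `truth` (adds the per-trait
#'   squared-effect matrix `gamma_sq`, `psi_focal`, `p_lof`).
#' @export
generate_genes <- function(config, seed = NULL, s_range = c(1e-7, 1)) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- seed %||% config$seed
  n <- config$n_genes
  per_chrom <- ceiling(n / config$n_chromosomes)
  with_seed(child_seed(seed, "genes"), {
    # intervals: lay genes on an even lattice with log-normal lengths
    chrom <- rep(seq_len(config$n_chromosomes), each = per_chrom)[seq_len(n)]
    slot <- (seq_len(n) - 1L) %% per_chrom
    pitch <- floor(config$chrom_length / (per_chrom + 1L))
    len <- pmin(round(stats::rlnorm(n, log(3e4), 0.6)), pitch - 2L)
    start <- 1L + slot * pitch + round(stats::runif(n, 0, pmax(pitch - len - 1, 1)))
    if (any(len >= pitch)) stopf("gene density too high for chromosome length")
    end <- start + len - 1L
    effect_cfg <- pleiotropy_sim_config(
      n_traits = config$n_traits, n_positions = n,
      sim_f = config$sim_f, sim_p = config$sim_p
    )
    magnitude <- stats::rlnorm(n, 0, config$gene_magnitude_sdlog)
    gamma_sq <- draw_effect_block(effect_cfg, n) *
      (config$gene_effect_scale / prefactor_value(effect_cfg)) * magnitude
    s_het <- pmin(pmax(rowSums(gamma_sq), s_range[1]), s_range[2])
    mu_l <- stats::rlnorm(n, config$mu_l_meanlog, config$mu_l_sdlog)
    p_lof <- pmin(config$lof_scale_c * mu_l / s_het, 0.01)
    genes <- data.table::data.table(
      gene = sprintf("G%05d", seq_len(n)),
      chrom = paste0("chr", chrom),
      start = as.integer(start), end = as.integer(end),
      midpoint = as.integer(floor((start + end) / 2)),
      mu_l = mu_l, s_het = s_het
    )
    truth <- list(genes = genes, gamma_sq = gamma_sq,
                  psi_focal = gamma_sq[, 1] / rowSums(gamma_sq),
                  p_lof = p_lof, config = config)
    list(genes = genes, truth = truth)
  })
}

#' Generate per-trait LoF burden summary statistics
#'
#' For gene g and trait t: standard error
#' `se = 1 / sqrt(2 n p_lof (1 - p_lof))` (standardized-phenotype
#' convention), estimate `~ Normal(gamma_t, se^2)`, two-sided p-value from
#' the 1-df chi-square of `(estimate/se)^2`.
#'
#' @param truth Ground truth from [generate_genes()].
#' @param n_samples Burden sample size (individuals).
#' @param seed Optional integer seed (defaults to a child of the config
#'   seed).
#' @param traits Trait indices to generate (default all).
#' @return A list of `data.table`s, one per trait, with columns `gene`,
#'   `beta`, `se`, `pval`, `p_lof`.
#' @export
generate_burden_stats <- function(truth, n_samples = NULL, seed = NULL,
                                  traits = NULL) {
  config <- truth$config
  n_samples <- n_samples %||% config$burden_n
  seed <- seed %||% child_seed(config$seed, "burden")
  traits <- traits %||% seq_len(config$n_traits)
  skip <- truth$p_lof <= 0
  if (any(skip)) warnf("skipping %d gene(s) with p_lof = 0", sum(skip))
  keep <- !skip
  se <- 1 / sqrt(2 * n_samples * truth$p_lof[keep] * (1 - truth$p_lof[keep]))
  gene_ids <- truth$genes$gene[keep]
  with_seed(seed, {
    lapply(traits, function(tt) {
      gamma_t <- sqrt(truth$gamma_sq[keep, tt])
      beta <- stats::rnorm(length(se), gamma_t, se)
      data.table::data.table(
        gene = gene_ids, beta = beta, se = se,
        pval = zsq_to_p((beta / se)^2),
        p_lof = truth$p_lof[keep]
      )
    })
  })
}

#' Generate GWAS variant summary statistics and a clumped hit list
#'
#' Variants are placed near gene midpoints; each carries effects
#' proportional to its gene's (`alpha_t = b * gamma_t` for a log-normal
#' regulatory magnitude `b`), experiences selection `sum_t alpha_t^2`, and
#' receives an equilibrium frequency from the nearest grid distribution.
#' Observed statistics come from [simulate_association()] with
#' `n_eff = gwas_n`. The focal-trait hit list keeps variants with
#' `p < gwas_threshold`, greedily enforcing a minimum spacing (best p
#' first) as a stand-in for LD-clump independence.
#'
#' @param truth Ground truth from [generate_genes()].
#' @param grid A [build_selection_grid()] for frequency assignment.
#' @param seed Optional integer seed.
#' @param traits Trait indices for which summary tables are returned.
#' @return List with `variants` (a `data.table`: `variant`, `chrom`, `pos`,
#'   `gene`, `maf`, `selection`, and focal-trait `beta`, `se`, `pval`),
#'   `hits` (per requested trait, the clumped hit tables), and
#'   `alpha_sq` (the true squared-effect matrix).
#' @export
generate_gwas_stats <- function(truth, grid, seed = NULL, traits = 1L) {
  stopifnot(inherits(grid, "selection_grid"))
  config <- truth$config
  seed <- seed %||% child_seed(config$seed, "gwas")
  genes <- truth$genes
  with_seed(seed, {
    n_var_per <- stats::rpois(nrow(genes), config$variants_per_gene) + 1L
    gene_idx <- rep(seq_len(nrow(genes)), n_var_per)
    n_var <- length(gene_idx)
    offset <- round(stats::runif(n_var, -config$variant_window,
                                 config$variant_window))
    pos <- pmax(1, genes$midpoint[gene_idx] + offset)
    b_sq <- stats::rlnorm(n_var, config$reg_magnitude_meanlog,
                          config$reg_magnitude_sdlog)^2
    alpha_sq <- truth$gamma_sq[gene_idx, , drop = FALSE] * b_sq
    selection <- rowSums(alpha_sq)
    # variants in an association panel segregate by definition
    maf <- assign_frequencies(selection, grid, segregating_only = TRUE)
    assoc <- suppressWarnings(simulate_association(
      sqrt(alpha_sq), maf, n_eff = config$gwas_n
    ))
    se <- ifelse(maf > 0, 1 / sqrt(2 * config$gwas_n * maf * (1 - maf)), NA)
    variants <- data.table::data.table(
      variant = sprintf("V%06d", seq_len(n_var)),
      chrom = genes$chrom[gene_idx],
      pos = as.integer(pos),
      gene = genes$gene[gene_idx],
      maf = maf, selection = selection,
      beta = assoc$observed[, 1], se = se,
      pval = assoc$p_value[, 1]
    )
    hits <- lapply(traits, function(tt) {
      clump_hits(variants, assoc$p_value[, tt], config$gwas_threshold,
                 config$hit_spacing)
    })
    names(hits) <- paste0("trait", traits)
    list(variants = variants, hits = hits, alpha_sq = alpha_sq)
  })
}

# Greedy spacing filter: keep significant variants in ascending p order,
# discarding any within `spacing` of an already-kept hit on the same
# chromosome.
clump_hits <- function(variants, pval, threshold, spacing) {
  sig <- which(pval < threshold & variants$maf > 0)
  sig <- sig[order(pval[sig])]
  kept <- integer(0)
  for (i in sig) {
    close_by <- any(variants$chrom[kept] == variants$chrom[i] &
                      abs(variants$pos[kept] - variants$pos[i]) < spacing)
    if (!close_by) kept <- c(kept, i)
  }
  out <- data.table::data.table(
    variant = variants$variant[kept],
    chrom = variants$chrom[kept],
    pos = variants$pos[kept],
    pval = pval[kept],
    maf = variants$maf[kept]
  )
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Generate an LD-block partition of the synthetic genome
#'
#' Tiles each chromosome with contiguous, non-overlapping blocks whose
#' sizes are drawn around `mean_size`.
#'
#' @param chrom_lengths Named vector of chromosome lengths (names are
#'   chromosome ids).
#' @param mean_size Target mean block size in bp.
#' @param seed Optional integer seed.
#' @return A `data.table` with `chrom`, `start`, `end` (1-based inclusive)
#'   covering each chromosome exactly.
#' @export
generate_ld_blocks <- function(chrom_lengths, mean_size, seed = NULL) {
  if (mean_size <= 0) stopf("mean_size must be > 0")
  with_seed(seed, {
    out <- lapply(names(chrom_lengths), function(cc) {
      len <- chrom_lengths[[cc]]
      edges <- 0
      while (utils::tail(edges, 1) < len) {
        step <- max(round(stats::rnorm(1, mean_size, mean_size / 4)),
                    round(mean_size / 10))
        edges <- c(edges, min(utils::tail(edges, 1) + step, len))
      }
      data.table::data.table(
        chrom = cc,
        start = as.integer(utils::head(edges, -1) + 1),
        end = as.integer(edges[-1])
      )
    })
    data.table::rbindlist(out)
  })
}

#' Generate the complete synthetic study
#'
#' Convenience wrapper chaining [generate_genes()],
#' [generate_burden_stats()], [generate_gwas_stats()], and
#' [generate_ld_blocks()], optionally writing every table to `dir` as
#' tab-separated files.
#'
#' @param config A [synthetic_config()].
#' @param grid A [build_selection_grid()].
#' @param dir Optional output directory for TSV/BED files.
#' @param burden_traits,gwas_traits Trait indices to emit.
#' @param block_mean_size Mean LD-block size.
#' @return List: `genes`, `truth`, `burden` (list per trait), `gwas`
#'   (variants, hits, alpha_sq), `blocks`.
#' @export
make_synthetic_study <- function(config, grid, dir = NULL,
                                 burden_traits = seq_len(config$n_traits),
                                 gwas_traits = 1L,
                                 block_mean_size = 2e6) {
  gg <- generate_genes(config, s_range = range(grid$s_het_values))
  burden <- generate_burden_stats(gg$truth, traits = burden_traits)
  names(burden) <- paste0("trait", burden_traits)
  gwas <- generate_gwas_stats(gg$truth, grid, traits = gwas_traits)
  chrom_lengths <- stats::setNames(
    rep(config$chrom_length, config$n_chromosomes),
    paste0("chr", seq_len(config$n_chromosomes))
  )
  blocks <- generate_ld_blocks(chrom_lengths, block_mean_size,
                               seed = child_seed(config$seed, "blocks"))
  out <- list(genes = gg$genes, truth = gg$truth, burden = burden,
              gwas = gwas, blocks = blocks)
  if (!is.null(dir)) write_synthetic_study(out, dir)
  out
}

write_synthetic_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(study$genes, file.path(dir, "genes.tsv"), sep = "\t")
  truth_tab <- data.table::data.table(
    gene = study$genes$gene,
    s_het = study$genes$s_het,
    mu_l = study$genes$mu_l,
    p_lof = study$truth$p_lof,
    gamma1_sq = study$truth$gamma_sq[, 1],
    psi_focal = study$truth$psi_focal
  )
  data.table::fwrite(truth_tab, file.path(dir, "truth.tsv"), sep = "\t")
  for (nm in names(study$burden)) {
    data.table::fwrite(study$burden[[nm]],
                       file.path(dir, sprintf("burden.%s.tsv", nm)), sep = "\t")
  }
  data.table::fwrite(study$gwas$variants, file.path(dir, "gwas.trait1.tsv"),
                     sep = "\t")
  for (nm in names(study$gwas$hits)) {
    data.table::fwrite(study$gwas$hits[[nm]],
                       file.path(dir, sprintf("hits.%s.tsv", nm)), sep = "\t")
  }
  write_bed(study$blocks, file.path(dir, "blocks.bed"))
  cfg <- study$truth$config
  writeLines(
    paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","),
                             character(1)), sep = ": "),
    file.path(dir, "config.txt")
  )
  invisible(dir)
}
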