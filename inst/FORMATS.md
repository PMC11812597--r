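# Table formats

All tables are tab-separated with a header row; p-values may use scientific
notation. Coordinates are 1-based inclusive everywhere except BED files,
which follow the standard 0-based half-open convention and are converted on
read.

## gwas — variant-level GWAS summary statistics

| column | type | notes |
| --- | --- | --- |
| variant | string | unique variant id |
| chrom | string | chromosome id |
| pos | int | 1-based position |
| beta | float | effect estimate (standardized phenotype) |
| se | float | standard error, > 0 |
| pval | float | in (0, 1] |
| maf | float | optional, minor allele frequency in [0, 0.5] |

## hits — LD-clumped GWAS hit list

`variant`, `chrom`, `pos`, `pval` as above; optional `maf`. Hits are assumed
clumped upstream (pairwise approximately independent).

## burden — gene-level LoF burden summary statistics

| column | type | notes |
| --- | --- | --- |
| gene | string | gene id |
| beta | float | burden effect estimate |
| se | float | standard error, > 0 |
| pval | float | in (0, 1] |
| p_lof | float | optional, aggregate LoF frequency in [0, 1] |

## genes — gene annotation

`gene`, `chrom`, `start`, `end` (1-based inclusive); optional `midpoint`
(defaults to `floor((start+end)/2)`), `mu_l` (LoF mutational target,
mu times L), `s_het`.

## truth — synthetic-study ground truth

`gene`, `s_het`, `mu_l`, `p_lof`; optional `gamma1_sq` (true focal-trait
importance) and `psi_focal` (true specificity).

## blocks — LD blocks (BED)

Three columns, no header: chromosome, 0-based start, half-open end. Blocks
must not overlap within a chromosome.

## Frequency-distribution TSV

Written by `write_distribution()`: a `#` header line recording
`n_diploids`, `mut_rate`, `s_het` and the conditioning flag, then columns
`count`, `frequency`, `mass` (zero-mass counts omitted).
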