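# Readers and writers for the summary-statistic tables and BED intervals,
# with schema validation. All tables are tab-separated with a header; BED
# input is 0-based half-open and converted to the package-internal 1-based
# inclusive convention on read.

table_schemas <- list(
  gwas   = list(required = c(variant = "character", chrom = "character",
                             pos = "integer", beta = "numeric",
                             se = "numeric", pval = "numeric"),
                optional = c(maf = "numeric")),
  hits   = list(required = c(variant = "character", chrom = "character",
                             pos = "integer", pval = "numeric"),
                optional = c(maf = "numeric")),
  burden = list(required = c(gene = "character", beta = "numeric",
                             se = "numeric", pval = "numeric"),
                optional = c(p_lof = "numeric")),
  genes  = list(required = c(gene = "character", chrom = "character",
                             start = "integer", end = "integer"),
                optional = c(midpoint = "integer", mu_l = "numeric",
                             s_het = "numeric")),
  truth  = list(required = c(gene = "character", s_het = "numeric",
                             mu_l = "numeric", p_lof = "numeric"),
                optional = c(gamma1_sq = "numeric", psi_focal = "numeric"))
)

#' Read and validate a summary-statistics table
#'
#' Reads a tab-separated table of a known kind, checks that the required
#' columns are present, coerces column types, and rejects rows violating
#' the schema invariants (non-finite numbers where finite ones are
#' required; p-values outside `(0, 1]`; `se <= 0`; `start > end`), logging
#' each rejection with its file line number to standard error.
#'
#' @param path File path.
#' @param kind One of `"gwas"`, `"hits"`, `"burden"`, `"genes"`, `"truth"`.
#' @return A validated `data.table`; the number of rejected rows is in the
#'   `n_rejected` attribute.
#' @export
read_sumstats <- function(path, kind = names(table_schemas)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  schema <- table_schemas[[kind]]
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  miss <- setdiff(names(schema$required), names(tab))
  if (length(miss)) {
    stopf("%s table %s is missing required column(s): %s",
          kind, path, paste(miss, collapse = ", "),
          class = "burdengwas_schema_error")
  }
  types <- c(schema$required,
             schema$optional[names(schema$optional) %in% names(tab)])
  bad <- rep(FALSE, nrow(tab))
  for (col in names(types)) {
    if (types[[col]] == "character") next
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    invalid <- !is.finite(vals)
    if (types[[col]] == "integer") invalid <- invalid | vals != floor(vals)
    if (col == "pval") invalid <- invalid | vals <= 0 | vals > 1
    if (col == "se") invalid <- invalid | vals <= 0
    if (col %in% c("maf", "p_lof")) invalid <- invalid | vals < 0 | vals > 1
    data.table::set(tab, j = col,
                    value = if (types[[col]] == "integer") as.integer(vals) else vals)
    bad <- bad | invalid
  }
  if ("start" %in% names(tab) && "end" %in% names(tab)) {
    bad <- bad | tab$start > tab$end
  }
  if (any(bad)) {
    # +1 for the header line
    lines <- which(bad) + 1L
    for (ln in utils::head(lines, 20L)) {
      message(sprintf("%s:%d: rejected row (schema violation)", path, ln))
    }
    message(sprintf("%s: rejected %d of %d rows", path, sum(bad), nrow(tab)))
    tab <- tab[!bad]
  }
  data.table::setattr(tab, "n_rejected", sum(bad))
  tab[]
}

#' Write a summary table as TSV
#'
#' @param tab A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(tab, path) {
  tab <- data.table::as.data.table(tab)
  list_cols <- names(tab)[vapply(tab, is.list, logical(1))]
  if (length(list_cols)) {
    tab <- data.table::copy(tab)
    for (col in list_cols) {
      data.table::set(tab, j = col,
                      value = vapply(tab[[col]], paste, character(1), collapse = ","))
    }
  }
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Read LD blocks from a BED file
#'
#' Expects at least 3 columns (chrom, start, end), 0-based half-open, no
#' header. Intervals are converted to the internal 1-based inclusive
#' convention; overlapping intervals within a chromosome are an input
#' error and rows with `start >= end` are rejected with their line number.
#'
#' @param path BED file path.
#' @return A `data.table` with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- tryCatch(
    suppressWarnings(data.table::fread(path, sep = "\t", header = FALSE,
                                       colClasses = list(character = 1))),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0)))
  }
  if (ncol(raw) < 3L) stopf("BED file must have at least 3 columns")
  out <- data.table::data.table(
    chrom = as.character(raw[[1]]),
    start0 = suppressWarnings(as.numeric(raw[[2]])),
    end0 = suppressWarnings(as.numeric(raw[[3]]))
  )
  bad <- !is.finite(out$start0) | !is.finite(out$end0) | out$start0 >= out$end0
  if (any(bad)) {
    for (ln in which(bad)) message(sprintf("%s:%d: rejected BED row", path, ln))
    out <- out[!bad]
  }
  out <- out[, .(chrom, start = as.integer(start0 + 1), end = as.integer(end0))]
  data.table::setorder(out, chrom, start)
  overl <- out[, if (.N > 1L) any(start[-1] <= end[-.N]) else FALSE, by = chrom]$V1
  if (any(overl)) stopf("overlapping BED intervals within a chromosome")
  out[]
}

#' Write blocks as BED (0-based half-open)
#'
#' @param blocks Table with `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(blocks, path) {
  data.table::fwrite(
    data.table::data.table(blocks$chrom, blocks$start - 1L, blocks$end),
    path, sep = "\t", col.names = FALSE
  )
  invisible(path)
}
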