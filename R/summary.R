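# Per-sample circulome summary tables and length distributions.

#' Percentage of eccDNAs with a coding sequence
#'
#' `100 * n_with_gene / n_ecc`, rounded half-up at two decimals — the
#' convention used by the published per-sample summary tables this module
#' reproduces.
#'
#' @param n_with_gene Number of eccDNAs carrying at least one predicted gene.
#' @param n_ecc Total number of (non-redundant) eccDNAs.
#' @return Percentage with two decimals.
#' @export
pct_cds <- function(n_with_gene, n_ecc) {
  round_half_up(100 * n_with_gene / n_ecc, 2)
}

#' Summarize one sample's circulome
#'
#' Computes the per-sample summary row: number of non-redundant eccDNAs,
#' mean and range of lengths, counts with predicted genes and tRNAs, the
#' percentage with coding sequence, and the per-eccDNA gene-count range and
#' mean (over eccDNAs that carry at least one gene).
#'
#' @param records Record data frame for one sample (see [read_ecc_fasta()]),
#'   with `has_cds`/`has_trna` flags set by annotation.
#' @param gene_counts Optional named vector mapping eccDNA id to its number
#'   of predicted genes; ids absent from the map count as zero genes.
#' @return A one-row data frame of class `circulome_summary`.
#' @export
summarize_circulome <- function(records, gene_counts = NULL) {
  sample <- unique(records$sample)
  if (length(sample) != 1) stop2("records must come from exactly one sample")
  if (nrow(records) == 0) stop2("no records for sample '", sample, "'")
  if (!is.null(gene_counts)) {
    g <- gene_counts[records$id]
    g[is.na(g)] <- 0
    records$has_cds <- records$has_cds | g > 0
  } else {
    g <- rep(0, nrow(records))
  }
  gpos <- g[g > 0]
  out <- data.frame(
    sample = sample,
    n_ecc = nrow(records),
    mean_length = mean(records$length),
    min_length = min(records$length),
    max_length = max(records$length),
    n_with_gene = sum(records$has_cds),
    n_with_trna = sum(records$has_trna),
    pct_with_cds = pct_cds(sum(records$has_cds), nrow(records)),
    genes_per_ecc_min = if (length(gpos)) min(gpos) else NA_integer_,
    genes_per_ecc_max = if (length(gpos)) max(gpos) else NA_integer_,
    genes_per_ecc_mean = if (length(gpos)) mean(gpos) else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("circulome_summary", class(out))
  out
}

#' Cohort aggregate of per-sample summaries
#'
#' Cross-sample means of the eccDNA count and the with-gene count, rounded
#' half-up to the nearest integer.
#'
#' @param summaries A data frame with columns `n_ecc` and `n_with_gene`
#'   (one row per sample), e.g. rbind-ed [summarize_circulome()] rows.
#' @return A list with `n_samples`, `mean_n_ecc`, `mean_n_with_gene`.
#' @export
aggregate_summaries <- function(summaries) {
  if (nrow(summaries) < 1) stop2("need at least one sample summary")
  list(
    n_samples = nrow(summaries),
    mean_n_ecc = round_half_up(mean(summaries$n_ecc)),
    mean_n_with_gene = round_half_up(mean(summaries$n_with_gene))
  )
}

#' Binned eccDNA length distribution
#'
#' Half-open bins `[k*w, (k+1)*w)`; bin counts always sum to the number of
#' records.
#'
#' @param records Record data frame (or anything with a `length` column).
#' @param bin_width Bin width in bp (default 1000).
#' @return Data frame with `bin_start`, `bin_end`, `count`.
#' @export
length_histogram <- function(records, bin_width = 1000) {
  if (bin_width <= 0) stop2("bin_width must be > 0")
  len <- records$length
  bin <- floor(len / bin_width)
  all_bins <- 0:max(bin)
  cnt <- tabulate(bin + 1L, nbins = length(all_bins))
  data.frame(bin_start = all_bins * bin_width,
             bin_end = (all_bins + 1) * bin_width,
             count = cnt)
}

#' Write the per-sample summary table in publication column order
#'
#' Mean length is printed to zero decimals and the length range as
#' `min-max`, matching the conventional layout of circulome summary tables.
#'
#' @param summaries rbind-ed [summarize_circulome()] rows.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  out <- data.frame(
    sample = summaries$sample,
    n_eccdna = summaries$n_ecc,
    mean_length = round_half_up(summaries$mean_length),
    length_range = paste0(summaries$min_length, "-", summaries$max_length),
    n_eccdna_with_gene = summaries$n_with_gene,
    n_eccdna_with_trna = summaries$n_with_trna,
    pct_eccdna_with_cds = summaries$pct_with_cds,
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}
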