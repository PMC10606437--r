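# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals (commercial rounding).
# Printed summary tables use this convention; base round() would round
# half-to-even. A tiny epsilon guards against 0.5 boundaries landing just
# below .5 through floating-point representation of x*10^digits.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Write a data frame as a plain TSV
#'
#' All tabular outputs of the pipeline use this writer: tab-separated,
#' header line, no quoting, no row names.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain TSV with a header line
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# Validate a 0-based half-open interval data.frame (chrom/start/end columns).
check_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop2(sprintf("%d invalid %s(s): need 0 <= start < end (first bad row: %d)",
                  length(bad), what, bad[1]))
  }
  invisible(df)
}

# Interval overlap (>= 1 bp) between one interval and vectors of intervals,
# all 0-based half-open on the same chromosome coordinate system.
overlaps_any <- function(chrom, start, end, f_chrom, f_start, f_end) {
  f_chrom == chrom & f_start < end & f_end > start
}
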