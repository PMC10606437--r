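# Overlap of mapped eccDNAs and their coding sequences with
# herbicide-resistance QTL intervals.

#' Classify QTL intervals by overlapping eccDNA content
#'
#' Uses the any-overlap (>= 1 bp) rule throughout. Per QTL, counts the
#' distinct HR and HS eccDNA ids whose mapped intervals overlap it, and
#' classifies its coding-sequence content as `HR-only`, `HS-only`, `both`
#' or `none` from the phenotypes of overlapping CDS intervals. Overlapping
#' QTLs are allowed; an eccDNA may count toward several.
#'
#' @param ecc_intervals Mapped eccDNA intervals (with `sample` column).
#' @param cds_intervals Mapped intervals of eccDNA coding sequences (same
#'   shape; may be a subset of `ecc_intervals`).
#' @param qtls QTL feature data frame (see [read_features()], name column
#'   = QTL id).
#' @param group_map Named vector mapping sample to `"HR"`/`"HS"`.
#' @param count_mode `"unique"` (default): the summary totals count each
#'   eccDNA id once even if it overlaps several QTLs; `"per_qtl"`: totals
#'   are sums of the per-QTL counts.
#' @return Object of class `qtl_report`: data frame with `qtl_id`,
#'   `n_hr_ecc`, `n_hs_ecc`, `cds_class`; attribute `summary` holds
#'   `n_qtl_with_cds`, `n_hs_only`, `n_hr_only`, `total_hr_ecc`,
#'   `total_hs_ecc`.
#' @export
overlap_qtl <- function(ecc_intervals, cds_intervals, qtls, group_map,
                        count_mode = c("unique", "per_qtl")) {
  count_mode <- match.arg(count_mode)
  grp <- function(df) unname(group_map[df$sample])
  ecc_grp <- grp(ecc_intervals)
  cds_grp <- if (nrow(cds_intervals)) grp(cds_intervals) else character(0)

  hit_ids <- function(iv, q) unique(iv$ecc_id[
    overlaps_any(qtls$chrom[q], qtls$start[q], qtls$end[q],
                 iv$chrom, iv$start, iv$end)])

  rows <- lapply(seq_len(nrow(qtls)), function(q) {
    hr_ids <- hit_ids(ecc_intervals[which(ecc_grp == "HR"), , drop = FALSE], q)
    hs_ids <- hit_ids(ecc_intervals[which(ecc_grp == "HS"), , drop = FALSE], q)
    cds_hr <- length(hit_ids(cds_intervals[which(cds_grp == "HR"), , drop = FALSE], q)) > 0
    cds_hs <- length(hit_ids(cds_intervals[which(cds_grp == "HS"), , drop = FALSE], q)) > 0
    cls <- if (cds_hr && cds_hs) "both" else if (cds_hr) "HR-only"
           else if (cds_hs) "HS-only" else "none"
    list(qtl_id = qtls$id[q], n_hr = length(hr_ids), n_hs = length(hs_ids),
         hr_ids = hr_ids, hs_ids = hs_ids, cds_class = cls)
  })

  out <- data.frame(
    qtl_id = vapply(rows, `[[`, "", "qtl_id"),
    n_hr_ecc = vapply(rows, `[[`, 0L, "n_hr"),
    n_hs_ecc = vapply(rows, `[[`, 0L, "n_hs"),
    cds_class = vapply(rows, `[[`, "", "cds_class"),
    stringsAsFactors = FALSE
  )
  total_hr <- if (count_mode == "unique") {
    length(unique(unlist(lapply(rows, `[[`, "hr_ids"))))
  } else sum(out$n_hr_ecc)
  total_hs <- if (count_mode == "unique") {
    length(unique(unlist(lapply(rows, `[[`, "hs_ids"))))
  } else sum(out$n_hs_ecc)
  attr(out, "summary") <- list(
    n_qtl_with_cds = sum(out$cds_class != "none"),
    n_hs_only = sum(out$cds_class == "HS-only"),
    n_hr_only = sum(out$cds_class == "HR-only"),
    total_hr_ecc = total_hr, total_hs_ecc = total_hs)
  class(out) <- c("qtl_report", class(out))
  out
}

#' @export
print.qtl_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("QTL overlap report: %d QTL regions\n", nrow(x)))
  cat(sprintf("  eccDNAs mapped to QTLs: HR %d, HS %d\n",
              s$total_hr_ecc, s$total_hs_ecc))
  cat(sprintf("  QTLs with CDS content: %d (HS-only %d, HR-only %d)\n",
              s$n_qtl_with_cds, s$n_hs_only, s$n_hr_only))
  print.data.frame(x, ...)
  invisible(x)
}

#' Windows inside QTLs mapped exclusively by HR samples
#'
#' Returns the windows overlapping a QTL in which at least `min_samples`
#' HR samples contribute >= 1 eccDNA and no HS eccDNA maps at all.
#' Relaxing `min_samples` can only grow the result set.
#'
#' @param windows Window count table from [count_windows()] (per-sample
#'   columns present).
#' @param qtls QTL feature data frame.
#' @param group_map Named vector mapping sample to `"HR"`/`"HS"`.
#' @param min_samples Minimum number of contributing HR samples (default 3).
#' @return Subset of `windows` rows with an added `n_hr_samples` column.
#' @export
hr_exclusive_windows <- function(windows, qtls, group_map, min_samples = 3) {
  samples <- attr(windows, "samples") %||%
    intersect(names(group_map), names(windows))
  hr <- samples[group_map[samples] == "HR"]
  hs <- samples[group_map[samples] == "HS"]
  in_qtl <- vapply(seq_len(nrow(windows)), function(i) {
    any(overlaps_any(windows$chrom[i], windows$start[i], windows$end[i],
                     qtls$chrom, qtls$start, qtls$end))
  }, TRUE)
  hr_n <- rowSums(windows[, hr, drop = FALSE] > 0)
  hs_tot <- if (length(hs)) rowSums(windows[, hs, drop = FALSE]) else 0
  keep <- in_qtl & hr_n >= min_samples & hs_tot == 0
  out <- windows[keep, , drop = FALSE]
  out$n_hr_samples <- hr_n[keep]
  rownames(out) <- NULL
  out
}
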