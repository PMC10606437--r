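# Genome-window density mapping and hotspot calling.
#
# The genome is tiled with non-overlapping windows of width W (default
# 500 kb); a short terminal window is kept so the grid tiles each
# chromosome exactly. A mapped interval increments EVERY window it overlaps
# by >= 1 bp (BEDtools-intersect semantics); midpoint assignment is
# available behind a flag.

#' Non-overlapping window grid over a genome
#'
#' @param genome_index Named vector of chromosome lengths (bp).
#' @param W Window width in bp (default 500000).
#' @return Data frame with `chrom`, `start`, `end`, `window` (0-based index
#'   within chromosome).
#' @export
window_grid <- function(genome_index, W = 5e5) {
  if (W <= 0) stop2("window width must be > 0")
  do.call(rbind, lapply(names(genome_index), function(ch) {
    len <- genome_index[[ch]]
    starts <- seq(0, len - 1, by = W)
    data.frame(chrom = ch, start = starts, end = pmin(starts + W, len),
               window = seq_along(starts) - 1L, stringsAsFactors = FALSE)
  }))
}

#' Count mapped eccDNAs in genome windows
#'
#' Each interval increments every window it overlaps (any overlap, >= 1 bp);
#' with `midpoint = TRUE` it instead increments only the window containing
#' its midpoint. Intervals on chromosomes absent from `genome_index` are
#' collected into an `unplaced` attribute with a warning.
#'
#' @param intervals Mapped intervals (see [read_alignments()]), with a
#'   `sample` column.
#' @param genome_index Named vector of chromosome lengths.
#' @param W Window width in bp.
#' @param group_map Optional named vector mapping sample to `"HR"`/`"HS"`;
#'   when given, `hr_total` and `hs_total` columns are added.
#' @param midpoint Midpoint assignment instead of any-overlap counting.
#' @return Data frame of windows with one count column per sample (ordered
#'   by chrom then start). Attributes: `samples`, `unplaced` (count of
#'   intervals on unknown chromosomes).
#' @export
count_windows <- function(intervals, genome_index, W = 5e5,
                          group_map = NULL, midpoint = FALSE) {
  grid <- window_grid(genome_index, W)
  samples <- sort(unique(intervals$sample))
  counts <- matrix(0L, nrow = nrow(grid), ncol = length(samples),
                   dimnames = list(NULL, samples))
  # row offset of each chromosome's first window in the grid
  offset <- c(0L, cumsum(tapply(grid$chrom, factor(grid$chrom, levels = unique(grid$chrom)), length)))
  names(offset) <- c(unique(grid$chrom), "_end")
  nwin <- tapply(grid$window, factor(grid$chrom, levels = unique(grid$chrom)), max)

  known <- intervals$chrom %in% names(genome_index)
  n_unplaced <- sum(!known)
  if (n_unplaced > 0) {
    warning(sprintf("%d interval(s) on chromosomes absent from the genome index (unplaced)",
                    n_unplaced))
  }
  iv <- intervals[known, , drop = FALSE]
  for (r in seq_len(nrow(iv))) {
    ch <- iv$chrom[r]
    if (midpoint) {
      w0 <- w1 <- floor(((iv$start[r] + iv$end[r]) / 2) / W)
    } else {
      w0 <- floor(iv$start[r] / W)
      w1 <- floor((iv$end[r] - 1) / W)
    }
    w0 <- max(0L, min(w0, nwin[[ch]]))
    w1 <- max(0L, min(w1, nwin[[ch]]))
    rows <- offset[[ch]] + (w0:w1) + 1L
    j <- match(iv$sample[r], samples)
    counts[rows, j] <- counts[rows, j] + 1L
  }
  out <- cbind(grid, as.data.frame(counts, check.names = FALSE))
  if (!is.null(group_map)) out <- phenotype_totals(out, group_map)
  attr(out, "samples") <- samples
  attr(out, "unplaced") <- n_unplaced
  out
}

#' Per-phenotype window totals
#'
#' Adds `hr_total`, `hs_total` and `grand` (= hr + hs) columns by summing
#' per-sample counts within each phenotype group.
#'
#' @param windows Window count table from [count_windows()] (or any data
#'   frame with per-sample count columns).
#' @param group_map Named vector mapping each sample to `"HR"` or `"HS"`.
#' @return `windows` with `hr_total`, `hs_total`, `grand` columns.
#' @export
phenotype_totals <- function(windows, group_map) {
  samples <- attr(windows, "samples") %||%
    setdiff(names(windows), c("chrom", "start", "end", "window",
                              "hr_total", "hs_total", "grand"))
  missing <- setdiff(samples, names(group_map))
  if (length(missing)) stop2("sample(s) missing from group map: ",
                             paste(missing, collapse = ", "))
  hr <- samples[group_map[samples] == "HR"]
  hs <- samples[group_map[samples] == "HS"]
  windows$hr_total <- if (length(hr)) rowSums(windows[, hr, drop = FALSE]) else 0L
  windows$hs_total <- if (length(hs)) rowSums(windows[, hs, drop = FALSE]) else 0L
  windows$grand <- windows$hr_total + windows$hs_total
  windows
}

#' Call hotspot windows
#'
#' Formalizes "windows with a mapping count far above background" as a
#' z-score rule: score = (count - mean) / SD over all windows genome-wide;
#' a window passes when score >= k (default 3). A top-quantile mode is
#' available. With zero genome-wide SD no hotspot is called (warning).
#'
#' @param windows Window table with the count column `value` present.
#' @param k Z-score threshold (mode `"sd"`).
#' @param mode `"sd"` (mean + k * SD) or `"quantile"`.
#' @param q Quantile for mode `"quantile"` (default 0.99).
#' @param value Name of the count column to score (default `"grand"`).
#' @return Data frame `chrom`, `start`, `end`, `count`, `score`, `passed`,
#'   ordered by (chrom, start).
#' @export
call_hotspots <- function(windows, k = 3, mode = c("sd", "quantile"),
                          q = 0.99, value = "grand") {
  mode <- match.arg(mode)
  if (nrow(windows) < 2) stop2("need at least two windows")
  x <- windows[[value]]
  if (is.null(x)) stop2("no count column '", value, "' in window table")
  if (mode == "sd") {
    s <- stats::sd(x)
    if (s == 0) {
      warning("zero variance across windows; no hotspots called")
      score <- rep(0, length(x)); passed <- rep(FALSE, length(x))
    } else {
      score <- (x - mean(x)) / s
      passed <- score >= k
    }
  } else {
    cut <- stats::quantile(x, q)
    score <- x - cut
    passed <- x > cut
  }
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, count = x, score = score,
                    passed = passed, stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Mapping-rate statistics
#'
#' Fraction of eccDNAs with at least one alignment, split into
#' chromosome-anchored and unanchored placements.
#'
#' @param ecc_ids All eccDNA ids in the inventory.
#' @param intervals Mapped intervals.
#' @param anchored Chromosome names counted as anchored (others are
#'   unanchored scaffolds).
#' @return List with `n_total`, `mapped_frac`, `anchored_frac`,
#'   `unanchored_frac` (fractions of the total inventory).
#' @export
mapping_stats <- function(ecc_ids, intervals, anchored) {
  ecc_ids <- unique(ecc_ids)
  mapped <- unique(intervals$ecc_id)
  anchored_ids <- unique(intervals$ecc_id[intervals$chrom %in% anchored])
  unanchored_ids <- setdiff(mapped, anchored_ids)
  list(n_total = length(ecc_ids),
       mapped_frac = length(intersect(mapped, ecc_ids)) / length(ecc_ids),
       anchored_frac = length(intersect(anchored_ids, ecc_ids)) / length(ecc_ids),
       unanchored_frac = length(intersect(unanchored_ids, ecc_ids)) / length(ecc_ids))
}

#' Export circos-style track files
#'
#' One TSV per track (`chrom`, `start`, `end`, `value`): eccDNA window
#' counts per phenotype, gene counts and TE counts on the same window grid
#' (features are counted with the same any-overlap rule as eccDNAs).
#'
#' @param windows Window table from [count_windows()] with phenotype totals.
#' @param genes,tes Feature data frames (see [read_features()]).
#' @param genome_index Named vector of chromosome lengths.
#' @param dir Output directory.
#' @param W Window width (must match `windows`).
#' @return Named character vector of the files written.
#' @export
export_tracks <- function(windows, genes, tes, genome_index, dir, W = 5e5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  track <- function(df, value, file) {
    out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                      value = value, stringsAsFactors = FALSE)
    write_tsv(out, file.path(dir, file))
    file.path(dir, file)
  }
  count_feature <- function(feats) {
    if (nrow(feats) == 0) return(rep(0L, nrow(windows)))
    fi <- data.frame(ecc_id = feats$id, sample = "all", chrom = feats$chrom,
                     start = feats$start, end = feats$end, stringsAsFactors = FALSE)
    cw <- count_windows(fi, genome_index, W)
    cw[["all"]]
  }
  files <- c(
    eccdna_hr = track(windows, windows$hr_total, "track_eccdna_hr.tsv"),
    eccdna_hs = track(windows, windows$hs_total, "track_eccdna_hs.tsv"),
    genes = track(windows, count_feature(genes), "track_genes.tsv"),
    tes = track(windows, count_feature(tes), "track_tes.tsv")
  )
  files
}
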