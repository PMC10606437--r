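# Flanking-density profiles and the label-permutation enrichment test.
#
# Question under test: do eccDNA-associated regions sit in gene- (or TE-)
# denser neighbourhoods than eccDNA-free regions? For each unit (an
# annotated gene, or a genome window) we count genes and TEs in its
# +/- 200 kb flanks, mark whether the unit itself overlaps a mapped eccDNA,
# and compare group means by permuting the presence labels.

#' Build flanking-density profiles
#'
#' The flank of a unit `[start, end)` is `[start - flank, end + flank)`
#' minus the unit itself, clipped to `[0, chromosome length)`. Flank counts
#' use the any-overlap rule; when units are genes, the unit's own gene is
#' excluded from its flank count. `ecc_present` is `TRUE` when the unit
#' interval overlaps at least one mapped eccDNA.
#'
#' @param units Unit intervals: a feature data frame (`unit_mode = "gene"`)
#'   or ignored in favour of the window grid (`unit_mode = "window"`).
#' @param genes,tes Feature data frames (see [read_features()]).
#' @param ecc_intervals Mapped eccDNA intervals.
#' @param flank Flank width each side, bp (default 200000).
#' @param unit_mode `"gene"` or `"window"`.
#' @param genome_index Named chromosome lengths; required for clipping and
#'   for `unit_mode = "window"`.
#' @param W Window width for `unit_mode = "window"`.
#' @return Data frame with `unit_id`, `chrom`, `start`, `end`,
#'   `flank_gene_count`, `flank_te_count`, `ecc_present`.
#' @export
build_flank_profiles <- function(units, genes, tes, ecc_intervals,
                                 flank = 2e5, unit_mode = c("gene", "window"),
                                 genome_index = NULL, W = 5e5) {
  unit_mode <- match.arg(unit_mode)
  if (flank <= 0) stop2("flank must be > 0")
  if (unit_mode == "window") {
    if (is.null(genome_index)) stop2("genome_index required for window units")
    g <- window_grid(genome_index, W)
    units <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                        id = sprintf("%s_w%d", g$chrom, g$window),
                        stringsAsFactors = FALSE)
  }
  if (is.null(units) || nrow(units) == 0) stop2("empty unit list")

  count_flank <- function(i, feats, exclude_id = NULL) {
    ch <- units$chrom[i]
    clen <- if (!is.null(genome_index) && ch %in% names(genome_index))
      genome_index[[ch]] else Inf
    ls <- max(0, units$start[i] - flank); le <- units$start[i]   # left flank
    rs <- units$end[i]; re <- min(clen, units$end[i] + flank)    # right flank
    hit <- feats$chrom == ch &
      ((feats$start < le & feats$end > ls) | (feats$start < re & feats$end > rs))
    if (!is.null(exclude_id)) hit <- hit & feats$id != exclude_id
    sum(hit)
  }

  n <- nrow(units)
  fg <- ft <- integer(n)
  present <- logical(n)
  for (i in seq_len(n)) {
    excl <- if (unit_mode == "gene") units$id[i] else NULL
    fg[i] <- count_flank(i, genes, exclude_id = excl)
    ft[i] <- count_flank(i, tes)
    present[i] <- any(overlaps_any(units$chrom[i], units$start[i], units$end[i],
                                   ecc_intervals$chrom, ecc_intervals$start,
                                   ecc_intervals$end))
  }
  data.frame(unit_id = units$id, chrom = units$chrom,
             start = units$start, end = units$end,
             flank_gene_count = fg, flank_te_count = ft,
             ecc_present = present, stringsAsFactors = FALSE)
}

#' Label-permutation test for a difference of group means
#'
#' Statistic: mean(feature | eccDNA present) - mean(feature | absent).
#' The null is built by shuffling the presence labels with group sizes held
#' fixed. When the number of distinct labelings `C(n, n_present)` is at
#' most `exact_limit`, the null is enumerated exhaustively and the p-value
#' is the exact fraction of labelings at least as extreme as the observed
#' one (the observed labeling is itself enumerated, so p > 0). Otherwise
#' `n_perm` random shuffles are drawn and the add-one p-value
#' `(1 + n_extreme) / (1 + n_perm)` is reported.
#'
#' @param profiles Profile table from [build_flank_profiles()].
#' @param feature `"gene"` or `"te"` — which flank count to test.
#' @param n_perm Number of random permutations when sampling (default 10000).
#' @param sidedness `"two"` (by absolute value) or `"greater"`.
#' @param seed RNG seed; required when sampling is used.
#' @param exact_limit Enumerate exhaustively when `C(n, n_present)` is at
#'   most this (default 20000).
#' @return An object of class `ecc_permtest`: list with `feature`,
#'   `obs_diff`, `n_perm`, `p_value`, `sidedness`, `method`
#'   (`"exact"`/`"sampled"`), `seed`, `null_mean`, `null_sd`, group sizes.
#' @export
permutation_test <- function(profiles, feature = c("gene", "te"),
                             n_perm = 10000, sidedness = c("two", "greater"),
                             seed = NULL, exact_limit = 20000) {
  feature <- match.arg(feature)
  sidedness <- match.arg(sidedness)
  x <- switch(feature, gene = profiles$flank_gene_count,
              te = profiles$flank_te_count)
  g <- profiles$ecc_present
  n <- length(x); n1 <- sum(g); n0 <- n - n1
  if (n1 == 0) stop2("group 'eccDNA-present' is empty")
  if (n0 == 0) stop2("group 'eccDNA-absent' is empty")
  obs <- mean(x[g]) - mean(x[!g])
  tot <- sum(x)
  stat_from_s1 <- function(s1) s1 / n1 - (tot - s1) / n0
  eps <- 1e-9
  extreme <- function(st) {
    if (sidedness == "greater") st >= obs - eps else abs(st) >= abs(obs) - eps
  }
  if (choose(n, n1) <= exact_limit) {
    labelings <- utils::combn(n, n1)
    s1 <- colSums(matrix(x[labelings], nrow = n1))
    st <- stat_from_s1(s1)
    p <- mean(extreme(st))
    method <- "exact"; n_used <- ncol(labelings)
  } else {
    if (is.null(seed)) stop2("a seed is required for sampled permutations")
    set.seed(seed)
    st <- vapply(seq_len(n_perm), function(i) {
      stat_from_s1(sum(x[sample.int(n, n1)]))
    }, 0)
    p <- (1 + sum(extreme(st))) / (1 + n_perm)
    method <- "sampled"; n_used <- n_perm
  }
  structure(list(feature = feature, obs_diff = obs, n_perm = n_used,
                 p_value = p, sidedness = sidedness, method = method,
                 seed = seed, null_mean = mean(st), null_sd = stats::sd(st),
                 n_present = n1, n_absent = n0),
            class = "ecc_permtest")
}

#' @export
print.ecc_permtest <- function(x, ...) {
  cat(sprintf("Permutation test (%s flank counts), %s null\n",
              x$feature, x$method))
  cat(sprintf("  present n = %d, absent n = %d\n", x$n_present, x$n_absent))
  cat(sprintf("  observed mean difference = %.4f\n", x$obs_diff))
  cat(sprintf("  p = %.4g (%s-sided, %d %s)\n", x$p_value, x$sidedness,
              x$n_perm, if (x$method == "exact") "labelings" else "permutations"))
  invisible(x)
}

#' Tabulate permutation results
#'
#' @param results List of `ecc_permtest` objects.
#' @return Data frame with one row per test (feature, obs_diff, n_perm, p,
#'   sidedness, method, seed).
#' @export
permtest_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(feature = r$feature, obs_diff = r$obs_diff, n_perm = r$n_perm,
               p_value = r$p_value, sidedness = r$sidedness, method = r$method,
               seed = r$seed %||% NA_integer_, stringsAsFactors = FALSE)
  }))
}
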