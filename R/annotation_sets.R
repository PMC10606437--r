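# Set algebra over per-sample PFAM domain catalogs.
#
# A catalog is the set of protein-domain accessions seen on a sample's
# eccDNA genes, with per-accession eccDNA counts. The comparisons of
# interest are shared cores (all samples, all-HR, all-HS), group-specific
# cores, per-sample unique accessions and pairwise sharing.

#' Build per-sample domain catalogs
#'
#' @param domains Domain record data frame (see [read_domains()]).
#' @return Named list (one element per sample) of named integer vectors:
#'   accession -> number of distinct eccDNAs annotated with it.
#' @export
domain_catalogs <- function(domains) {
  if (nrow(domains) == 0) stop2("no domain records")
  split_df <- split(domains, domains$sample)
  lapply(split_df, function(d) {
    # one eccDNA counts once per accession even with several annotated genes
    u <- unique(d[c("ecc_id", "pfam")])
    tab <- table(u$pfam)
    stats::setNames(as.integer(tab), names(tab))
  })
}

#' Partition domain accessions into shared cores and specific sets
#'
#' Computes the HR core (accessions in every HR sample), the HS core, the
#' all-sample core (their intersection), the group-specific cores (HR core
#' minus HS core and vice versa), per-sample unique accessions, and
#' pairwise shared sets within each group. By the partition identity,
#' `|hr_core| = |core_all| + |hr_core_specific|` (and symmetrically for HS).
#'
#' @param catalogs Named list from [domain_catalogs()].
#' @param group_map Named vector mapping sample to `"HR"`/`"HS"`.
#' @param unique_scope `"all"`: a unique accession occurs in exactly one
#'   sample across both groups (default); `"group"`: unique within its own
#'   group only.
#' @param pairwise_exclusive When `TRUE`, pairwise shared sets exclude
#'   accessions present in any other sample of the same group.
#' @return Object of class `domain_partition`: list with `core_all`,
#'   `hr_core`, `hs_core`, `hr_core_specific`, `hs_core_specific`,
#'   `per_sample_unique` (named list), `pairwise_shared` (named list,
#'   names `"A|B"`).
#' @export
partition_domains <- function(catalogs, group_map,
                              unique_scope = c("all", "group"),
                              pairwise_exclusive = FALSE) {
  unique_scope <- match.arg(unique_scope)
  if (any(vapply(catalogs, length, 0L) == 0)) stop2("empty domain catalog")
  samples <- names(catalogs)
  missing <- setdiff(samples, names(group_map))
  if (length(missing)) stop2("sample(s) missing from group map: ",
                             paste(missing, collapse = ", "))
  sets <- lapply(catalogs, names)
  hr_samples <- samples[group_map[samples] == "HR"]
  hs_samples <- samples[group_map[samples] == "HS"]
  if (!length(hr_samples) || !length(hs_samples)) {
    stop2("need at least one sample per phenotype group")
  }
  hr_core <- Reduce(intersect, sets[hr_samples])
  hs_core <- Reduce(intersect, sets[hs_samples])
  core_all <- intersect(hr_core, hs_core)

  per_sample_unique <- lapply(samples, function(s) {
    others <- if (unique_scope == "all") setdiff(samples, s)
              else setdiff(samples[group_map[samples] == group_map[[s]]], s)
    setdiff(sets[[s]], unique(unlist(sets[others])))
  })
  names(per_sample_unique) <- samples

  pairwise_shared <- list()
  for (grp in list(hr_samples, hs_samples)) {
    if (length(grp) < 2) next
    prs <- utils::combn(sort(grp), 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      sh <- intersect(sets[[a]], sets[[b]])
      if (pairwise_exclusive) {
        rest <- setdiff(grp, c(a, b))
        sh <- setdiff(sh, unique(unlist(sets[rest])))
      }
      pairwise_shared[[paste(a, b, sep = "|")]] <- sort(sh)
    }
  }

  structure(list(core_all = sort(core_all),
                 hr_core = sort(hr_core), hs_core = sort(hs_core),
                 hr_core_specific = sort(setdiff(hr_core, hs_core)),
                 hs_core_specific = sort(setdiff(hs_core, hr_core)),
                 per_sample_unique = per_sample_unique,
                 pairwise_shared = pairwise_shared),
            class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("Protein-domain set partition\n")
  cat(sprintf("  shared by all samples: %d\n", length(x$core_all)))
  cat(sprintf("  HR core: %d (HR-specific: %d)\n",
              length(x$hr_core), length(x$hr_core_specific)))
  cat(sprintf("  HS core: %d (HS-specific: %d)\n",
              length(x$hs_core), length(x$hs_core_specific)))
  uq <- vapply(x$per_sample_unique, length, 0L)
  cat("  unique per sample: ",
      paste(sprintf("%s=%d", names(uq), uq), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Rank accessions by total eccDNA count
#'
#' @param catalogs Named list from [domain_catalogs()].
#' @param subset Optional accession set to restrict to.
#' @param samples Optional samples to sum over (default all).
#' @param top_n Keep the top n rows (default all).
#' @return Data frame `pfam`, `n_ecc`, sorted by decreasing count, ties
#'   broken by accession string.
#' @export
rank_abundance <- function(catalogs, subset = NULL, samples = NULL, top_n = Inf) {
  if (!is.null(samples)) catalogs <- catalogs[samples]
  all_acc <- sort(unique(unlist(lapply(catalogs, names))))
  if (!is.null(subset)) {
    unknown <- setdiff(subset, all_acc)
    if (length(unknown)) stop2("subset accession(s) absent from catalogs: ",
                               paste(unknown, collapse = ", "))
    all_acc <- sort(intersect(all_acc, subset))
  }
  total <- vapply(all_acc, function(a) {
    sum(vapply(catalogs, function(ct) if (a %in% names(ct)) ct[[a]] else 0L, 0L))
  }, 0L)
  out <- data.frame(pfam = all_acc, n_ecc = total, stringsAsFactors = FALSE)
  out <- out[order(-out$n_ecc, out$pfam), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Presence matrix for a watchlist of domain groups
#'
#' A watchlist names functional groups of interest (e.g. cytochrome P450s,
#' ABC transporters, glutathione transferases) as sets of accessions. The
#' result flags, per sample, whether any accession of the group is present,
#' and derives the list of samples each group is confined to.
#'
#' @param catalogs Named list from [domain_catalogs()].
#' @param watchlist Named list: group name -> character vector of PFAM
#'   accessions. Groups whose accessions occur in no catalog produce a
#'   warning and an all-`FALSE` column.
#' @return Logical matrix samples x watchlist entries, with attribute
#'   `exclusive`: named list of the samples each entry is present in.
#' @export
detox_flags <- function(catalogs, watchlist) {
  samples <- names(catalogs)
  universe <- unique(unlist(lapply(catalogs, names)))
  m <- matrix(FALSE, nrow = length(samples), ncol = length(watchlist),
              dimnames = list(samples, names(watchlist)))
  for (w in names(watchlist)) {
    acc <- watchlist[[w]]
    if (!any(acc %in% universe)) {
      warning("watchlist entry '", w, "' matches no accession in any catalog")
      next
    }
    m[, w] <- vapply(catalogs, function(ct) any(acc %in% names(ct)), TRUE)
  }
  exclusive <- lapply(names(watchlist), function(w) samples[m[, w]])
  names(exclusive) <- names(watchlist)
  attr(m, "exclusive") <- exclusive
  m
}

#' Hypergeometric term enrichment with BH correction
#'
#' A deliberately plain enrichment utility: for each term, the upper-tail
#' hypergeometric p-value of its overlap with the target set against the
#' background, Benjamini-Hochberg adjusted. (No length-bias correction is
#' attempted; this is a self-contained simplification of GO-style
#' enrichment, not a reimplementation of bias-aware methods.)
#'
#' @param target Character vector of target ids (must be a subset of
#'   `background`); non-empty.
#' @param background Character vector of background ids.
#' @param term_map Named list: term -> character vector of member ids.
#' @param fdr FDR threshold for the `enriched` flag (default 0.05).
#' @return Data frame `term`, `n_target`, `n_background`, `p_value`,
#'   `q_value`, `enriched`, sorted by p.
#' @export
term_enrichment <- function(target, background, term_map, fdr = 0.05) {
  target <- unique(target); background <- unique(background)
  if (length(target) == 0) stop2("empty target set")
  if (length(term_map) == 0) stop2("empty term map")
  if (length(setdiff(target, background))) {
    stop2("target must be a subset of background")
  }
  N <- length(background); n <- length(target)
  rows <- lapply(names(term_map), function(tm) {
    members <- intersect(term_map[[tm]], background)
    K <- length(members)
    k <- length(intersect(members, target))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_target = k, n_background = K, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$q_value < fdr
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
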