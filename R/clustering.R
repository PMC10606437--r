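# Greedy identity clustering of circular DNA sequences.
#
# Mirrors the CD-hit style of redundancy collapse: sequences are sorted by
# decreasing length and each either joins the first existing cluster whose
# representative it matches at >= threshold identity, or founds a new
# cluster. Identity is taken from the best local alignment and divided by
# the length of the shorter sequence (the CD-hit convention). Because the
# molecules are circles, a rotated copy can score poorly against the linear
# representative; the doubling trick (aligning against the representative
# concatenated to itself) recovers rotation-invariant identity.

default_dna_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = 2, gap_ext = 1)
}

dna_submat <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
}

#' Identity between two DNA sequences from the best local alignment
#'
#' Identity = identical aligned positions / length of the shorter sequence.
#' With `circular = TRUE` the shorter sequence is additionally aligned
#' against the longer one concatenated to itself and the better identity is
#' kept, so a pure rotation of a circle scores 1. Scoring: match +1,
#' mismatch -1; a gap of length L costs `gap_open + L * gap_ext`.
#'
#' @param a,b DNA sequences (character strings).
#' @param circular Use the doubling trick for rotation-aware identity.
#' @param scoring Alignment scoring parameters, see [default_dna_scoring()].
#' @return Identity in `[0, 1]`.
#' @export
seq_identity <- function(a, b, circular = TRUE, scoring = default_dna_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop2("empty sequence")
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  mat <- dna_submat(scoring)
  idy <- function(subject) {
    aln <- Biostrings::pairwiseAlignment(
      a, subject, type = "local", substitutionMatrix = mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
    Biostrings::nmatch(aln) / nchar(a)
  }
  id <- idy(b)
  if (circular && id < 1) id <- max(id, idy(paste0(b, b)))
  min(id, 1)
}

# All k-mers of a sequence (character vector, possibly empty for short s).
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

#' Greedy redundancy collapse of eccDNA sequences
#'
#' @param records Record data frame (columns `id`, `sequence`, `length`;
#'   see [read_ecc_fasta()]).
#' @param threshold Identity threshold in `(0, 1]` (default 0.9).
#' @param circular Rotation-aware identity via the doubling trick.
#' @param prefilter Require at least one shared k-mer (k = 11) with the
#'   representative before computing the alignment. Pairs whose shorter
#'   sequence is too short to carry a k-mer are always aligned.
#' @param k Prefilter k-mer size.
#' @param best_hit Assign each sequence to the best-matching qualifying
#'   representative instead of the first (CD-hit default is first).
#' @param scoring Alignment scoring, see [seq_identity()].
#' @return An object of class `ecc_clusters`: a list of clusters, each with
#'   `representative` (id) and `members` (data frame of `id`,
#'   `identity_to_rep`). Input order does not matter: records are ordered
#'   internally by decreasing length, ties by id.
#' @export
cluster_greedy <- function(records, threshold = 0.9, circular = TRUE,
                           prefilter = TRUE, k = 11, best_hit = FALSE,
                           scoring = default_dna_scoring()) {
  if (nrow(records) == 0) stop2("no records to cluster")
  if (!(threshold > 0 && threshold <= 1)) stop2("threshold must be in (0, 1]")
  ord <- order(-records$length, records$id)
  records <- records[ord, , drop = FALSE]

  rep_idx <- integer(0)         # row index of each cluster representative
  rep_kmers <- list()           # k-mers of representative (doubled if circular)
  members <- list()             # per-cluster member ids + identities

  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    skm <- seq_kmers(s, k)
    assigned <- 0L
    best_id <- -1
    for (ci in seq_along(rep_idx)) {
      if (prefilter && length(skm) && !any(skm %in% rep_kmers[[ci]])) next
      id <- seq_identity(s, records$sequence[rep_idx[ci]],
                         circular = circular, scoring = scoring)
      if (id >= threshold) {
        if (!best_hit) { assigned <- ci; best_id <- id; break }
        if (id > best_id) { assigned <- ci; best_id <- id }
      }
    }
    if (assigned > 0L) {
      members[[assigned]] <- rbind(
        members[[assigned]],
        data.frame(id = records$id[i], identity_to_rep = best_id,
                   stringsAsFactors = FALSE))
    } else {
      ci <- length(rep_idx) + 1L
      rep_idx[ci] <- i
      rseq <- if (circular) paste0(s, s) else s
      rep_kmers[[ci]] <- seq_kmers(rseq, k)
      members[[ci]] <- data.frame(id = records$id[i], identity_to_rep = 1,
                                  stringsAsFactors = FALSE)
    }
  }

  clusters <- lapply(seq_along(rep_idx), function(ci) {
    list(representative = records$id[rep_idx[ci]], members = members[[ci]])
  })
  structure(clusters, class = "ecc_clusters",
            threshold = threshold, circular = circular)
}

#' @export
print.ecc_clusters <- function(x, ...) {
  sizes <- vapply(x, function(cl) nrow(cl$members), 0L)
  cat(sprintf("eccDNA clustering: %d clusters from %d sequences (threshold %.2f)\n",
              length(x), sum(sizes), attr(x, "threshold")))
  cat(sprintf("  singletons: %d, largest cluster: %d members\n",
              sum(sizes == 1L), if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Non-redundant representative records of a clustering
#'
#' @param clusters An `ecc_clusters` object.
#' @param records The record data frame the clustering was computed from.
#' @return One record per cluster, ordered by representative id.
#' @export
representatives <- function(clusters, records) {
  ids <- vapply(clusters, function(cl) cl$representative, "")
  out <- records[match(sort(ids), records$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster membership table
#'
#' @param clusters An `ecc_clusters` object.
#' @return Data frame with `cluster_id`, `representative`, `member_id`,
#'   `identity`.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters), function(ci) {
    cl <- clusters[[ci]]
    data.frame(cluster_id = ci, representative = cl$representative,
               member_id = cl$members$id, identity = cl$members$identity_to_rep,
               stringsAsFactors = FALSE)
  }))
}
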