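# Protein homology screening of predicted eccDNA genes against known
# herbicide-resistance candidates: best local alignment under BLOSUM62 with
# affine gaps, plus Karlin-Altschul bit scores and E-values.

AA_ALPHABET_STRICT <- c("A","R","N","D","C","Q","E","G","H","I","L","K",
                        "M","F","P","S","T","W","Y","V","X")

# BLOSUM62 with every X pairing scored 0 (unknown residues are neutral).
blosum62_x0 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET_STRICT, AA_ALPHABET_STRICT]
  m["X", ] <- 0L; m[, "X"] <- 0L
  m
}

#' Best local protein alignment
#'
#' Smith-Waterman-style best local alignment under BLOSUM62 with affine
#' gaps (a gap of length L costs `gap_open + L * gap_ext`; defaults 11/1,
#' the standard gapped-BLOSUM62 setting). Identity uses the BLAST
#' convention: identical columns / alignment columns (gaps included) * 100.
#' `X` is allowed and scored 0 against everything.
#'
#' @param query,subject Protein sequences (character strings, 20-letter
#'   alphabet plus X).
#' @param gap_open,gap_ext Affine gap parameters.
#' @return List with `score` (raw S), `pct_identity`, `aln_length`
#'   (alignment columns), `n_identical`.
#' @export
align_local <- function(query, subject, gap_open = 11, gap_ext = 1) {
  for (s in c(query, subject)) {
    if (!nzchar(s)) stop2("empty protein sequence")
    bad <- setdiff(strsplit(toupper(s), "")[[1]], AA_ALPHABET_STRICT)
    if (length(bad)) stop2("invalid residue(s): ", paste(bad, collapse = ""))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(query)), Biostrings::AAString(toupper(subject)),
    type = "local", substitutionMatrix = blosum62_x0(),
    gapOpening = gap_open, gapExtension = gap_ext)
  # alignment columns incl. gaps = width of the gapped pattern string
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  nid <- Biostrings::nmatch(aln)
  list(score = Biostrings::score(aln),
       pct_identity = 100 * nid / cols,
       aln_length = cols,
       n_identical = nid)
}

#' Karlin-Altschul bit score and E-value
#'
#' `bit = (lambda * S - ln K) / ln 2`; `E = m * n * 2^(-bit)`. The default
#' lambda and K are the published constants for gapped BLOSUM62 (11/1)
#' searches.
#'
#' @param S Raw alignment score.
#' @param m Query length (residues).
#' @param n Database length (total residues searched).
#' @param lambda,K Karlin-Altschul parameters.
#' @return List with `bit_score` and `e_value`.
#' @export
karlin_altschul <- function(S, m, n, lambda = 0.267, K = 0.041) {
  if (m <= 0 || n <= 0) stop2("m and n must be positive")
  bit <- (lambda * S - log(K)) / log(2)
  list(bit_score = bit, e_value = m * n * 2^(-bit))
}

#' Screen eccDNA proteins against candidate genes
#'
#' Aligns every (query, candidate) pair, converts scores to bit scores and
#' E-values with the database length n = total residues in the candidate
#' set, and reports the hits passing the E-value cutoff, sorted by E
#' ascending. When a group map is supplied, each candidate is annotated
#' with the phenotype exclusivity of its hits (`HR`, `HS` or `both`).
#'
#' @param ecc_proteins Named character vector of predicted eccDNA protein
#'   sequences; names are query ids of the form `"<sample>_<n>"` (or supply
#'   `samples`).
#' @param candidates Named character vector of candidate protein sequences.
#' @param max_e E-value cutoff (default 1e-10).
#' @param group_map Optional named vector mapping sample to `"HR"`/`"HS"`.
#' @param samples Optional named vector mapping query id to sample.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Object of class `homology_hits`: data frame with `query_id`,
#'   `subject_id`, `pct_identity`, `e_value`, `bit_score`, `aln_length`,
#'   `sample`, `group`; attribute `exclusivity` (named by candidate).
#' @export
screen_candidates <- function(ecc_proteins, candidates, max_e = 1e-10,
                              group_map = NULL, samples = NULL,
                              lambda = 0.267, K = 0.041) {
  if (!length(ecc_proteins) || !length(candidates)) {
    stop2("both protein sets must be non-empty")
  }
  n_db <- sum(nchar(candidates))
  if (is.null(samples)) {
    samples <- stats::setNames(ecc_sample_from_id(names(ecc_proteins)),
                               names(ecc_proteins))
  }
  rows <- list()
  for (q in names(ecc_proteins)) {
    for (s in names(candidates)) {
      al <- align_local(ecc_proteins[[q]], candidates[[s]])
      ka <- karlin_altschul(al$score, nchar(ecc_proteins[[q]]), n_db,
                            lambda = lambda, K = K)
      if (ka$e_value <= max_e) {
        smp <- unname(samples[[q]])
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = q, subject_id = s,
          pct_identity = al$pct_identity, e_value = ka$e_value,
          bit_score = ka$bit_score, aln_length = al$aln_length,
          sample = smp,
          group = if (!is.null(group_map)) unname(group_map[[smp]]) else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0), subject_id = character(0),
               pct_identity = numeric(0), e_value = numeric(0),
               bit_score = numeric(0), aln_length = integer(0),
               sample = character(0), group = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$e_value), , drop = FALSE]
  rownames(out) <- NULL
  excl <- lapply(split(out$group, out$subject_id), function(g) {
    g <- unique(g[!is.na(g)])
    if (length(g) == 2) "both" else if (length(g) == 1) g else NA_character_
  })
  attr(out, "exclusivity") <- excl
  class(out) <- c("homology_hits", class(out))
  out
}

#' @export
print.homology_hits <- function(x, ...) {
  cat(sprintf("Candidate-gene homology hits: %d pair(s) passing E cutoff\n", nrow(x)))
  if (nrow(x)) print.data.frame(format(x, digits = 4), ...)
  excl <- attr(x, "exclusivity")
  if (length(excl)) {
    cat("  phenotype exclusivity: ",
        paste(sprintf("%s=%s", names(excl), unlist(excl)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
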