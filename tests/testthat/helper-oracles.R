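# Shared fixtures and independent oracles for the test suite.
# The aligner here is a deliberately plain Gotoh dynamic program, written
# independently of the package's alignment route so it can serve as an
# oracle; the window and flank counters are brute-force double loops.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rotate_str <- function(s, k) {
  n <- nchar(s); k <- k %% n
  if (k == 0) return(s)
  paste0(substring(s, k + 1, n), substring(s, 1, k))
}

mutate_str <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# Best local alignment score under affine gaps where a gap of length L
# costs open + L * ext. `submat` is a lookup matrix over the residue
# alphabet. Returns the raw score (0 if no positive-scoring alignment).
sw_score <- function(a, b, submat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a advances)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (b advances)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- s + max(0, M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext), X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext), Y[i + 1, j] - ext)
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  best
}

dna_mat_oracle <- function(match = 1, mismatch = -1) {
  b <- c("A", "C", "G", "T")
  m <- matrix(mismatch, 4, 4, dimnames = list(b, b))
  diag(m) <- match
  m
}

# Brute-force per-window interval counts: loop every (window, interval)
# pair and test for >= 1 bp overlap.
brute_window_counts <- function(intervals, grid) {
  cnt <- integer(nrow(grid))
  for (w in seq_len(nrow(grid))) {
    for (r in seq_len(nrow(intervals))) {
      if (intervals$chrom[r] == grid$chrom[w] &&
          intervals$start[r] < grid$end[w] &&
          intervals$end[r] > grid$start[w]) {
        cnt[w] <- cnt[w] + 1L
      }
    }
  }
  cnt
}

# Brute-force flank profiles for gene units.
brute_flank_profiles <- function(units, genes, tes, ecc, flank, genome_index) {
  n <- nrow(units)
  fg <- ft <- integer(n); present <- logical(n)
  in_flank <- function(fs, fe, fch, uch, s0, e0) {
    fch == uch && ((fs < s0 && fe > max(0, s0 - flank)) ||
                   (fs < min(genome_index[[uch]], e0 + flank) && fe > e0))
  }
  for (i in seq_len(n)) {
    uch <- units$chrom[i]; s0 <- units$start[i]; e0 <- units$end[i]
    for (r in seq_len(nrow(genes))) {
      if (genes$id[r] != units$id[i] &&
          in_flank(genes$start[r], genes$end[r], genes$chrom[r], uch, s0, e0)) {
        fg[i] <- fg[i] + 1L
      }
    }
    for (r in seq_len(nrow(tes))) {
      if (in_flank(tes$start[r], tes$end[r], tes$chrom[r], uch, s0, e0)) {
        ft[i] <- ft[i] + 1L
      }
    }
    for (r in seq_len(nrow(ecc))) {
      if (ecc$chrom[r] == uch && ecc$start[r] < e0 && ecc$end[r] > s0) {
        present[i] <- TRUE
      }
    }
  }
  data.frame(unit_id = units$id, flank_gene_count = fg, flank_te_count = ft,
             ecc_present = present, stringsAsFactors = FALSE)
}

# Record data frame from bare sequences.
records_from_seqs <- function(seqs, sample = "S1", prefix = "e") {
  data.frame(id = sprintf("%s%03d", prefix, seq_along(seqs)),
             sample = sample, length = nchar(seqs),
             has_cds = FALSE, has_trna = FALSE, sequence = seqs,
             stringsAsFactors = FALSE)
}

# Tiny fast simulation config for integration-style tests.
small_sim_config <- function(seed = 1, ...) {
  sim_config(genome_length = 2e6, unanchored_length = 2e5,
             circles_per_sample = 40, length_mean = 400,
             length_range = c(31, 3000), length_sdlog = 1,
             n_genes = 120, n_tes = 200, n_qtl = 8,
             hotspots = data.frame(chrom = "chr1", window = 1L,
                                   multiplier = 10),
             seed = seed, ...)
}
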