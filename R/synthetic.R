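# Synthetic eccDNA-excision generator with known ground truth.
#
# Emulates the structure of a multi-population circulome experiment: a toy
# genome with gene and TE annotation, seven samples (4 herbicide-resistant,
# 3 herbicide-sensitive) of circular excision events, genome-wide origins
# with planted high-density windows, an excision rate that can couple to
# local gene density, mutated/rotated duplicate circles to exercise
# redundancy collapse, and per-sample protein-domain catalogs with a
# planted shared-core / HR-specific / HS-specific structure. Every emitted
# file is derived deterministically from a single seed.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: a 5 Mb two-chromosome
#' genome plus an unanchored scaffold, 4 HR and 3 HS samples, 500 circles
#' per sample with a truncated log-normal length law (mean 6900 bp on
#' [31, 29081]), a few planted high-density 500-kb windows, an optional
#' log-odds coupling of excision to local gene count, and domain
#' vocabularies of 69 shared / 11 HR-specific / 22 HS-specific accessions.
#'
#' @param genome_length Total anchored genome length, split evenly across
#'   `n_chrom` chromosomes.
#' @param n_chrom Number of anchored chromosomes.
#' @param unanchored_length Length of the unanchored scaffold.
#' @param n_hr,n_hs Number of herbicide-resistant / -sensitive samples.
#' @param circles_per_sample Circles excised per sample (before duplicates).
#' @param length_mean Target mean circle length (bp).
#' @param length_range Truncation bounds (bp), inclusive.
#' @param length_sdlog Log-scale SD of the length law.
#' @param hotspots Data frame `chrom`, `window` (0-based index on the
#'   `window_size` grid), `multiplier` (>= 1) of planted hotspot windows.
#' @param gene_density_beta Excision log-rate slope on the number of genes
#'   within +/- `flank` of the origin midpoint (0 = no coupling).
#' @param n_genes,n_tes Number of gene / TE annotations.
#' @param n_gene_islands,island_sd,island_frac Spatial clustering of genes:
#'   `island_frac` of genes are drawn around `n_gene_islands` Gaussian
#'   centers with SD `island_sd`; the rest are uniform.
#' @param gene_length,te_length Feature lengths (bp).
#' @param n_qtl Number of QTL intervals.
#' @param qtl_length QTL length range (bp).
#' @param domain_core,domain_hr_only,domain_hs_only,domain_unique_per_sample
#'   Sizes of the planted domain vocabulary strata.
#' @param dup_frac Fraction of circles re-emitted as a mutated, rotated
#'   near-duplicate (to exercise clustering).
#' @param dup_sub_rate Per-base substitution rate of duplicates.
#' @param frac_unanchored Fraction of circles excised from the unanchored
#'   scaffold.
#' @param frac_with_cds Fraction of circles carrying predicted genes.
#' @param window_size Window width of the hotspot grid (bp).
#' @param flank Flank width used by the gene-density coupling (bp).
#' @param subbin Discretization width for origin sampling (bp).
#' @param seed Global seed; all per-sample substreams are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 5e6, n_chrom = 2, unanchored_length = 4e5,
                       n_hr = 4, n_hs = 3, circles_per_sample = 500,
                       length_mean = 6900, length_range = c(31, 29081),
                       length_sdlog = 1.1,
                       hotspots = data.frame(chrom = c("chr1", "chr2"),
                                             window = c(2L, 4L),
                                             multiplier = c(5, 4)),
                       gene_density_beta = 0.05,
                       n_genes = 400, n_tes = 800,
                       n_gene_islands = 6, island_sd = 1e5, island_frac = 0.5,
                       gene_length = 3000, te_length = 500,
                       n_qtl = 15, qtl_length = c(2e5, 6e5),
                       domain_core = 69, domain_hr_only = 11,
                       domain_hs_only = 22, domain_unique_per_sample = 20,
                       dup_frac = 0.1, dup_sub_rate = 0.03,
                       frac_unanchored = 0.085, frac_with_cds = 0.22,
                       window_size = 5e5, flank = 2e5, subbin = 1e4,
                       seed = 1) {
  cfg <- list(genome_length = genome_length, n_chrom = n_chrom,
              unanchored_length = unanchored_length, n_hr = n_hr, n_hs = n_hs,
              circles_per_sample = circles_per_sample,
              length_mean = length_mean, length_range = length_range,
              length_sdlog = length_sdlog, hotspots = hotspots,
              gene_density_beta = gene_density_beta,
              n_genes = n_genes, n_tes = n_tes,
              n_gene_islands = n_gene_islands, island_sd = island_sd,
              island_frac = island_frac, gene_length = gene_length,
              te_length = te_length, n_qtl = n_qtl, qtl_length = qtl_length,
              domain_core = domain_core, domain_hr_only = domain_hr_only,
              domain_hs_only = domain_hs_only,
              domain_unique_per_sample = domain_unique_per_sample,
              dup_frac = dup_frac, dup_sub_rate = dup_sub_rate,
              frac_unanchored = frac_unanchored, frac_with_cds = frac_with_cds,
              window_size = window_size, flank = flank, subbin = subbin,
              seed = seed)
  sizes <- c(genome_length, n_chrom, n_hr, n_hs, circles_per_sample,
             n_genes, n_tes, n_qtl)
  if (any(sizes <= 0)) stop2("all size parameters must be positive")
  if (nrow(hotspots) && any(hotspots$multiplier < 1)) {
    stop2("hotspot intensity multipliers must be >= 1")
  }
  # length-law feasibility (bounds must bracket the target mean)
  solve_length_law(length_mean, length_range, length_sdlog)
  class(cfg) <- "sim_config"
  cfg
}

# Solve the log-normal location parameter so the truncated mean matches the
# target. The truncated mean is monotone increasing in meanlog and spans
# (a, b), so the target is feasible iff a < mean < b.
solve_length_law <- function(target_mean, range, sdlog) {
  a <- range[1]; b <- range[2]
  if (!(a > 0 && b > a)) stop2("invalid length range")
  if (!(target_mean > a && target_mean < b)) {
    stop2(sprintf(
      "infeasible truncated length law: mean %g outside bounds (%g, %g)",
      target_mean, a, b))
  }
  trunc_mean <- function(mu) {
    la <- (log(a) - mu) / sdlog; lb <- (log(b) - mu) / sdlog
    exp(mu + sdlog^2 / 2) *
      (stats::pnorm(lb - sdlog) - stats::pnorm(la - sdlog)) /
      (stats::pnorm(lb) - stats::pnorm(la))
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - target_mean,
                       lower = log(a) - 1, upper = log(b) + 1,
                       extendInt = "upX", tol = 1e-8)$root
  list(meanlog = mu, sdlog = sdlog, min = a, max = b)
}

#' Draw circle lengths from the truncated log-normal length law
#'
#' Rejection sampling from the log-normal with the location parameter
#' solved numerically so that the truncated mean equals `mean`.
#'
#' @param n Number of lengths.
#' @param mean Target mean (bp).
#' @param range Inclusive truncation bounds (bp).
#' @param sdlog Log-scale SD.
#' @return Integer vector of lengths, all inside `range`.
#' @export
r_circle_lengths <- function(n, mean = 6900, range = c(31, 29081), sdlog = 1.1) {
  law <- solve_length_law(mean, range, sdlog)
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * (n - length(out)) + 10, law$meanlog, law$sdlog)
    x <- x[x >= law$min & x <= law$max]
    out <- c(out, x)
  }
  pmin(pmax(round(out[seq_len(n)]), range[1]), range[2])
}

sim_sample_names <- function(cfg) {
  c(sprintf("HR%d", seq_len(cfg$n_hr)), sprintf("HS%d", seq_len(cfg$n_hs)))
}

sim_group_map <- function(cfg) {
  s <- sim_sample_names(cfg)
  stats::setNames(ifelse(startsWith(s, "HR"), "HR", "HS"), s)
}

rand_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate the toy genome
#'
#' @param cfg A [sim_config()].
#' @return List with `seqs` (named character), `lengths` (named numeric)
#'   and `anchored` (chromosome names; the unanchored scaffold is excluded).
#' @export
sim_genome <- function(cfg) {
  set.seed(cfg$seed + 1L)
  clen <- floor(cfg$genome_length / cfg$n_chrom)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  lens <- stats::setNames(rep(clen, cfg$n_chrom), chroms)
  lens <- c(lens, scaffold_1 = cfg$unanchored_length)
  seqs <- vapply(lens, rand_dna_string, "")
  list(seqs = seqs, lengths = lens, anchored = chroms)
}

#' Simulate gene, TE and QTL annotations
#'
#' Genes are spatially clustered (a mixture of uniform placement and
#' Gaussian "gene islands") so that local gene density varies along the
#' genome — the structure the gene-density coupling and the enrichment
#' test act on. TEs are uniform. QTLs are random intervals.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [sim_genome()].
#' @return List of feature data frames `genes`, `tes`, `qtls`.
#' @export
sim_features <- function(cfg, genome) {
  set.seed(cfg$seed + 2L)
  chroms <- genome$anchored
  place <- function(n, len_lo, len_hi, kind, prefix, islands = FALSE,
                    disjoint = FALSE) {
    ch <- sample(chroms, n, replace = TRUE)
    clen <- genome$lengths[ch]
    len <- round(stats::runif(n, len_lo, len_hi))
    centers <- NULL
    if (islands) {
      centers <- lapply(chroms, function(c0)
        stats::runif(cfg$n_gene_islands, 0, genome$lengths[[c0]]))
      names(centers) <- chroms
    }
    isl <- if (islands) stats::runif(n) < cfg$island_frac else rep(FALSE, n)
    draw_pos <- function(i) {
      if (isl[i]) stats::rnorm(1, sample(centers[[ch[i]]], 1), cfg$island_sd)
      else stats::runif(1, 0, clen[i])
    }
    start <- numeric(n)
    placed <- vector("list", length(chroms)); names(placed) <- chroms
    for (i in seq_len(n)) {
      for (try in 1:50) {
        s0 <- pmin(pmax(round(draw_pos(i)), 0), clen[i] - len[i])
        if (!disjoint) break
        prev <- placed[[ch[i]]]
        if (is.null(prev) ||
            !any(prev$start < s0 + len[i] & prev$end > s0)) break
      }
      start[i] <- s0
      if (disjoint) {
        placed[[ch[i]]] <- rbind(placed[[ch[i]]],
                                 data.frame(start = s0, end = s0 + len[i]))
      }
    }
    data.frame(chrom = ch, start = start, end = start + len, kind = kind,
               id = sprintf("%s%04d", prefix, seq_len(n)),
               stringsAsFactors = FALSE)
  }
  # gene models are kept disjoint (real annotations rarely overlap; and a
  # single excision marking several stacked gene units would induce
  # between-unit dependence the enrichment test does not model)
  genes <- place(cfg$n_genes, cfg$gene_length * 0.5, cfg$gene_length * 1.5,
                 "gene", "g", islands = TRUE, disjoint = TRUE)
  tes <- place(cfg$n_tes, cfg$te_length * 0.5, cfg$te_length * 1.5, "TE", "te")
  qtls <- place(cfg$n_qtl, cfg$qtl_length[1], cfg$qtl_length[2], "QTL", "qtl-")
  list(genes = genes, tes = tes, qtls = qtls)
}

#' Origin-sampling weights over the anchored genome
#'
#' Discretizes the anchored chromosomes into sub-bins and assigns each the
#' excision weight: hotspot multiplier of the containing window times
#' `exp(beta * number of genes within +/- flank of the bin midpoint)`.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [sim_genome()].
#' @param genes Gene feature data frame (see [sim_features()]).
#' @return Data frame `chrom`, `start`, `end`, `weight`.
#' @export
sim_origin_weights <- function(cfg, genome, genes) {
  grids <- lapply(genome$anchored, function(ch) {
    clen <- genome$lengths[[ch]]
    starts <- seq(0, clen - 1, by = cfg$subbin)
    mids <- pmin(starts + cfg$subbin / 2, clen)
    mult <- rep(1, length(starts))
    hs <- cfg$hotspots
    if (nrow(hs)) {
      nwin <- ceiling(clen / cfg$window_size)
      for (j in which(hs$chrom == ch)) {
        if (hs$window[j] < 0 || hs$window[j] >= nwin) {
          stop2("hotspot window index out of range for ", ch)
        }
        mult[floor(starts / cfg$window_size) == hs$window[j]] <- hs$multiplier[j]
      }
    }
    gsub <- genes[genes$chrom == ch, , drop = FALSE]
    gcount <- vapply(mids, function(m) {
      sum(gsub$start < m + cfg$flank & gsub$end > m - cfg$flank)
    }, 0)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + cfg$subbin, clen),
               weight = mult * exp(cfg$gene_density_beta * gcount),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, grids)
}

mutate_dna <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

rotate_dna <- function(s, k) {
  n <- nchar(s)
  k <- ((k - 1) %% n) + 1
  if (k == n) return(s)
  paste0(substring(s, k + 1, n), substring(s, 1, k))
}

#' Simulate one sample's circle inventory
#'
#' Draws origins from the weighted grid (or the unanchored scaffold),
#' lengths from the truncated log-normal law, copies each circle's
#' sequence from the genome at its origin, flags coding circles, and
#' appends mutated/rotated near-duplicate copies.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [sim_genome()].
#' @param weights Origin grid from [sim_origin_weights()].
#' @param sample Sample name.
#' @param seed Substream seed for this sample.
#' @return Circle data frame (id, origin interval, length, flags,
#'   `parent_id` for duplicates, sequence).
#' @export
sim_sample_circles <- function(cfg, genome, weights, sample, seed) {
  set.seed(seed)
  n <- cfg$circles_per_sample
  len <- r_circle_lengths(n, cfg$length_mean, cfg$length_range, cfg$length_sdlog)
  on_scaffold <- stats::runif(n) < cfg$frac_unanchored
  bin <- sample.int(nrow(weights), n, replace = TRUE, prob = weights$weight)
  chrom <- ifelse(on_scaffold, "scaffold_1", weights$chrom[bin])
  mid <- ifelse(on_scaffold,
                stats::runif(n, 0, genome$lengths[["scaffold_1"]]),
                stats::runif(n, weights$start[bin], weights$end[bin]))
  clen <- genome$lengths[chrom]
  start <- pmin(pmax(round(mid - len / 2), 0), clen - len)
  end <- start + len
  has_cds <- stats::runif(n) < cfg$frac_with_cds
  if (cfg$frac_with_cds > 0 && !any(has_cds)) has_cds[1] <- TRUE
  n_genes <- ifelse(has_cds, pmin(1L + stats::rpois(n, 1), 15L), 0L)
  seqs <- vapply(seq_len(n), function(i) {
    substring(genome$seqs[[chrom[i]]], start[i] + 1, end[i])
  }, "")
  circles <- data.frame(
    id = sprintf("%s_%05d", sample, seq_len(n)), sample = sample,
    chrom = chrom, start = start, end = end, length = len,
    has_cds = has_cds, n_genes = n_genes, has_trna = FALSE,
    parent_id = NA_character_, sequence = seqs,
    stringsAsFactors = FALSE)

  n_dup <- round(cfg$dup_frac * n)
  if (n_dup > 0) {
    di <- sample.int(n, n_dup)
    dups <- circles[di, , drop = FALSE]
    dups$parent_id <- dups$id
    dups$id <- sprintf("%s_%05d", sample, n + seq_len(n_dup))
    dups$sequence <- vapply(dups$sequence, function(s) {
      mutate_dna(rotate_dna(s, sample.int(nchar(s), 1)), cfg$dup_sub_rate)
    }, "", USE.NAMES = FALSE)
    circles <- rbind(circles, dups)
  }
  rownames(circles) <- NULL
  circles
}

# Planted domain vocabulary strata. Accession blocks are disjoint by
# construction so recovered set algebra is exact.
sim_vocab <- function(cfg) {
  pf <- function(base, n) sprintf("PF%05d", base + seq_len(n))
  samples <- sim_sample_names(cfg)
  uniq <- lapply(seq_along(samples), function(i)
    pf(30000 + i * 200, cfg$domain_unique_per_sample))
  names(uniq) <- samples
  list(core = pf(0, cfg$domain_core),
       hr_only = pf(10000, cfg$domain_hr_only),
       hs_only = pf(20000, cfg$domain_hs_only),
       unique = uniq)
}

# Domain records for one sample: every accession of the sample's vocabulary
# is annotated to >= 1 coding eccDNA; the first core accession is planted
# as the dominant (most-abundant) domain.
sim_sample_domains <- function(cfg, vocab, sample, group, cds_ids, seed) {
  set.seed(seed)
  acc <- c(vocab$core,
           if (group == "HR") vocab$hr_only else vocab$hs_only,
           vocab$unique[[sample]])
  if (!length(cds_ids)) stop2("no coding eccDNAs to annotate in ", sample)
  rows <- lapply(seq_along(acc), function(j) {
    n_target <- if (j == 1L) 25L else 1L + stats::rpois(1, 0.6)
    ids <- unique(sample(cds_ids, min(n_target, length(cds_ids)),
                         replace = FALSE))
    data.frame(sample = sample, ecc_id = ids,
               gene_id = sprintf("%s.g%d", ids, j), pfam = acc[j],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a full multi-sample eccDNA experiment
#'
#' Generates the toy genome, annotations, per-sample circle inventories
#' (with near-duplicate copies), genome mappings, domain catalogs, QTL
#' intervals and the ground truth. With `dir` set, writes every file the
#' pipeline readers consume: one FASTA per sample, `alignments.paf`,
#' `genes.gff3`, `tes.bed`, `qtl.bed`, `domains.tsv`, `config.yaml`, and a
#' `truth/` directory of TSVs. The same seed yields byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @return Invisibly (visibly when `dir` is `NULL`), a list with `config`,
#'   `genome`, `genes`, `tes`, `qtls`, `circles`, `intervals`, `domains`,
#'   `group_map`, `truth` (hotspot windows, vocabulary, per-circle origin
#'   truth) and, when written, `files`.
#' @export
simulate_eccdna <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- sim_genome(cfg)
  feats <- sim_features(cfg, genome)
  weights <- sim_origin_weights(cfg, genome, feats$genes)
  vocab <- sim_vocab(cfg)
  group_map <- sim_group_map(cfg)
  samples <- sim_sample_names(cfg)

  # Per-sample substreams keyed by sample NAME, so adding samples to the
  # config never perturbs the circles of existing ones.
  sub_seed <- function(name, stream) {
    h <- Reduce(function(a, c) (a * 31 + c) %% 2147483647L,
                utf8ToInt(name), accumulate = FALSE)
    as.integer((h * 127 + (cfg$seed %% 1e6) * 1009 + stream * 17) %% 2147483647)
  }

  circles <- list(); domains <- list()
  for (i in seq_along(samples)) {
    s <- samples[i]
    circles[[s]] <- sim_sample_circles(cfg, genome, weights, s, sub_seed(s, 1L))
    cds_ids <- circles[[s]]$id[circles[[s]]$has_cds &
                               is.na(circles[[s]]$parent_id)]
    domains[[s]] <- sim_sample_domains(cfg, vocab, s, group_map[[s]],
                                       cds_ids, sub_seed(s, 2L))
  }
  circles <- do.call(rbind, circles); rownames(circles) <- NULL
  domains <- do.call(rbind, domains); rownames(domains) <- NULL

  intervals <- data.frame(ecc_id = circles$id, sample = circles$sample,
                          chrom = circles$chrom, start = circles$start,
                          end = circles$end, strand = "+",
                          stringsAsFactors = FALSE)
  truth <- list(
    origins = circles[c("id", "sample", "chrom", "start", "end", "parent_id")],
    hotspots = cfg$hotspots,
    vocab = vocab)
  out <- list(config = cfg, genome = genome, genes = feats$genes,
              tes = feats$tes, qtls = feats$qtls, circles = circles,
              intervals = intervals, domains = domains,
              group_map = group_map, truth = truth)
  if (is.null(dir)) return(out)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  files <- character(0)
  for (s in samples) {
    f <- file.path(dir, paste0(s, ".fasta"))
    write_ecc_fasta(circles[circles$sample == s, , drop = FALSE], f)
    files[paste0("fasta_", s)] <- f
  }
  paf <- data.frame(
    qname = circles$id, qlen = circles$length, qstart = 0,
    qend = circles$length, strand = "+", tname = circles$chrom,
    tlen = unname(genome$lengths[circles$chrom]), tstart = circles$start,
    tend = circles$end, nmatch = circles$length, alen = circles$length,
    mapq = 60, tp = "tp:A:P", stringsAsFactors = FALSE)
  files["paf"] <- file.path(dir, "alignments.paf")
  utils::write.table(paf, files["paf"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gff <- c("##gff-version 3",
           sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                   feats$genes$chrom, feats$genes$start + 1L,
                   feats$genes$end, feats$genes$id))
  files["genes"] <- file.path(dir, "genes.gff3")
  writeLines(gff, files["genes"])
  files["tes"] <- file.path(dir, "tes.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", feats$tes$chrom, feats$tes$start,
                     feats$tes$end, feats$tes$id), files["tes"])
  files["qtl"] <- file.path(dir, "qtl.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s", feats$qtls$chrom, feats$qtls$start,
                     feats$qtls$end, feats$qtls$id), files["qtl"])
  files["domains"] <- file.path(dir, "domains.tsv")
  write_tsv(domains, files["domains"])
  files["genome_index"] <- file.path(dir, "genome_index.tsv")
  write_tsv(data.frame(chrom = names(genome$lengths),
                       length = unname(genome$lengths),
                       anchored = names(genome$lengths) %in% genome$anchored),
            files["genome_index"])
  files["config"] <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), files["config"])
  files["truth_origins"] <- file.path(dir, "truth", "origins.tsv")
  write_tsv(truth$origins, files["truth_origins"])
  files["truth_hotspots"] <- file.path(dir, "truth", "hotspots.tsv")
  write_tsv(cfg$hotspots, files["truth_hotspots"])
  vocab_df <- data.frame(
    pfam = c(vocab$core, vocab$hr_only, vocab$hs_only, unlist(vocab$unique)),
    stratum = c(rep("core", length(vocab$core)),
                rep("hr_only", length(vocab$hr_only)),
                rep("hs_only", length(vocab$hs_only)),
                rep(names(vocab$unique), vapply(vocab$unique, length, 0L))),
    stringsAsFactors = FALSE)
  files["truth_vocab"] <- file.path(dir, "truth", "vocab.tsv")
  write_tsv(vocab_df, files["truth_vocab"])
  files["truth_groups"] <- file.path(dir, "truth", "groups.tsv")
  write_tsv(data.frame(sample = names(group_map), group = unname(group_map)),
            files["truth_groups"])
  out$files <- files
  invisible(out)
}
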