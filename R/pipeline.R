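# End-to-end pipeline: cluster -> summarize -> windows -> permutation ->
# domain sets -> QTL -> (optional) homology, driven by one config.

#' Build or read a run configuration
#'
#' A run config lists the input files and every numeric parameter of the
#' pipeline; each parameter defaults to the value the analysis is defined
#' with (identity threshold 0.9, 500-kb windows, 200-kb flanks, 10000
#' permutations, hotspot z >= 3, FDR 0.05).
#'
#' @param fasta Named list/vector: sample -> FASTA path.
#' @param alignments Path to eccDNA-to-genome alignments.
#' @param alignment_format `"paf"` or `"bed"`.
#' @param genes,tes,qtl Annotation file paths (GFF3/BED).
#' @param domains Domain TSV path.
#' @param genome_index Named vector of chromosome lengths, or path to a TSV
#'   with columns `chrom`, `length` and optional `anchored`.
#' @param group_map Named vector sample -> `"HR"`/`"HS"`.
#' @param proteins,candidates Optional protein FASTA paths for the homology
#'   screen.
#' @param threshold,window_size,flank,n_perm,hotspot_k,fdr,max_e Pipeline
#'   parameters.
#' @param cluster_scope `"per_sample"` (default) or `"pooled"`.
#' @param seed Seed for the permutation stage (required when sampling).
#' @return A `run_config` list.
#' @export
run_config <- function(fasta, alignments, genes, tes, qtl, domains,
                       genome_index, group_map,
                       alignment_format = "paf",
                       proteins = NULL, candidates = NULL,
                       threshold = 0.9, window_size = 5e5, flank = 2e5,
                       n_perm = 10000, hotspot_k = 3, fdr = 0.05,
                       max_e = 1e-10, cluster_scope = "per_sample",
                       seed = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$group_map <- unlist(y$group_map)
  if (!is.null(y$genome_index) && is.list(y$genome_index)) {
    y$genome_index <- unlist(y$genome_index)
  }
  do.call(run_config, y)
}

read_genome_index <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    df <- read_tsv(x)
    gi <- stats::setNames(df$length, df$chrom)
    attr(gi, "anchored") <- if ("anchored" %in% names(df))
      df$chrom[as.logical(df$anchored)] else df$chrom
    gi
  } else {
    gi <- x
    if (is.null(attr(gi, "anchored"))) attr(gi, "anchored") <- names(gi)
    gi
  }
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.null(v)) "NULL" else v), f)
  unname(tools::md5sum(f))
}

#' Run the full circulome pipeline
#'
#' Validates every referenced input path up front, then executes the
#' stages in order (cluster, summarize, windows + hotspots + tracks,
#' permutation tests per phenotype group, domain set partition, QTL
#' overlap, optional homology screen), writing one TSV per result plus a
#' machine-readable JSON manifest (package version, config hash, seed,
#' MD5 of every output). Reruns with an identical config and seed produce
#' identical outputs.
#'
#' @param cfg A [run_config()] (or path to its YAML).
#' @param out_dir Output directory (created).
#' @return Invisibly, a list of in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  paths <- c(unlist(cfg$fasta), cfg$alignments, cfg$genes, cfg$tes,
             cfg$qtl, cfg$domains, cfg$proteins, cfg$candidates,
             if (is.character(cfg$genome_index)) cfg$genome_index)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop2("missing input file(s): ",
                             paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop2(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  res <- list()
  gi <- read_genome_index(cfg$genome_index)
  anchored <- attr(gi, "anchored")
  gi_anchored <- gi[anchored]

  records <- stage("read", {
    do.call(rbind, lapply(names(cfg$fasta), function(s)
      read_ecc_fasta(cfg$fasta[[s]], sample = s)))
  })
  domains <- stage("read", read_domains(cfg$domains))
  genes <- stage("read", read_features(cfg$genes, kind = "gene"))
  tes <- stage("read", read_features(cfg$tes, kind = "TE"))
  qtls <- stage("read", read_features(cfg$qtl, kind = "QTL"))
  intervals <- stage("read", read_alignments(cfg$alignments,
                                             format = cfg$alignment_format))

  res$clusters <- stage("cluster", {
    if (cfg$cluster_scope == "per_sample") {
      cl <- lapply(split(records, records$sample), cluster_greedy,
                   threshold = cfg$threshold)
      names(cl) <- names(split(records, records$sample))
      cl
    } else {
      list(pooled = cluster_greedy(records, threshold = cfg$threshold))
    }
  })
  res$representatives <- stage("cluster", {
    do.call(rbind, lapply(names(res$clusters), function(s) {
      representatives(res$clusters[[s]],
                      if (s == "pooled") records
                      else records[records$sample == s, , drop = FALSE])
    }))
  })
  write_tsv(do.call(rbind, lapply(names(res$clusters), function(s)
    cbind(sample = s, cluster_table(res$clusters[[s]])))),
    file.path(out_dir, "clusters.tsv"))

  res$summary <- stage("summarize", {
    gene_counts <- vapply(split(domains$gene_id, domains$ecc_id),
                          function(g) length(unique(g)), 0L)
    reps <- res$representatives
    do.call(rbind, lapply(split(reps, reps$sample), summarize_circulome,
                          gene_counts = gene_counts))
  })
  write_summary_table(res$summary, file.path(out_dir, "summary.tsv"))

  rep_ids <- res$representatives$id
  rep_iv <- intervals[intervals$ecc_id %in% rep_ids, , drop = FALSE]
  res$windows <- stage("windows", {
    suppressWarnings(count_windows(rep_iv, gi_anchored, cfg$window_size,
                                   group_map = cfg$group_map))
  })
  write_tsv(res$windows, file.path(out_dir, "window_counts.tsv"))
  res$hotspots <- stage("windows", call_hotspots(res$windows, k = cfg$hotspot_k))
  write_tsv(res$hotspots, file.path(out_dir, "hotspots.tsv"))
  res$mapping <- stage("windows", mapping_stats(records$id, intervals, anchored))
  stage("windows", export_tracks(res$windows, genes, tes, gi_anchored,
                                 file.path(out_dir, "tracks"),
                                 W = cfg$window_size))

  res$permtests <- stage("permutation", {
    out <- list()
    for (g in c("HR", "HS")) {
      giv <- rep_iv[cfg$group_map[rep_iv$sample] == g, , drop = FALSE]
      prof <- build_flank_profiles(genes, genes, tes, giv,
                                   flank = cfg$flank, unit_mode = "gene",
                                   genome_index = gi_anchored)
      for (f in c("gene", "te")) {
        out[[paste(g, f, sep = "_")]] <- permutation_test(
          prof, feature = f, n_perm = cfg$n_perm, seed = cfg$seed)
      }
    }
    out
  })
  write_tsv(cbind(test = names(res$permtests),
                  permtest_table(res$permtests)),
            file.path(out_dir, "permutation_tests.tsv"))

  res$partition <- stage("domains", {
    partition_domains(domain_catalogs(domains), cfg$group_map)
  })
  pt <- res$partition
  write_tsv(data.frame(
    set = c(rep("core_all", length(pt$core_all)),
            rep("hr_core_specific", length(pt$hr_core_specific)),
            rep("hs_core_specific", length(pt$hs_core_specific))),
    pfam = c(pt$core_all, pt$hr_core_specific, pt$hs_core_specific)),
    file.path(out_dir, "domain_partition.tsv"))
  res$abundance <- stage("domains", rank_abundance(domain_catalogs(domains)))
  write_tsv(res$abundance, file.path(out_dir, "domain_abundance.tsv"))

  res$qtl <- stage("qtl", {
    cds_ids <- unique(domains$ecc_id)
    cds_iv <- rep_iv[rep_iv$ecc_id %in% cds_ids, , drop = FALSE]
    overlap_qtl(rep_iv, cds_iv, qtls, cfg$group_map)
  })
  write_tsv(as.data.frame(res$qtl), file.path(out_dir, "qtl_report.tsv"))

  if (!is.null(cfg$proteins) && !is.null(cfg$candidates)) {
    res$homology <- stage("homology", {
      screen_candidates(read_protein_fasta(cfg$proteins),
                        read_protein_fasta(cfg$candidates),
                        max_e = cfg$max_e, group_map = cfg$group_map)
    })
    write_tsv(as.data.frame(res$homology), file.path(out_dir, "homology.tsv"))
  }

  outputs <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "circulome",
    version = as.character(utils::packageVersion("circulome")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
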