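# Readers and writers for the external formats the pipeline touches.
#
# Coordinate convention: every interval held in memory is 0-based half-open
# (BED-style). GFF3 (1-based closed) is converted at the boundary; PAF and
# BED are native. These readers are the only place +/-1 arithmetic occurs.

#' Read per-sample eccDNA sequences from FASTA
#'
#' Parses one FASTA file of circular DNA sequences belonging to a single
#' sample and returns one record per sequence. Sequences are uppercased and
#' lengths computed; the coding/tRNA flags default to `FALSE` until an
#' annotation source sets them.
#'
#' @param path Path to a FASTA file.
#' @param sample Sample label; defaults to the file name without extension.
#' @return A data frame of eccDNA records with columns `id`, `sample`,
#'   `length`, `has_cds`, `has_trna`, `sequence`.
#' @export
read_ecc_fasta <- function(path, sample = NULL) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  sample <- sample %||% sub("\\.(fa|fasta|fna)$", "", basename(path))
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop2("duplicate FASTA id within sample '", sample, "': ", dup[1])
  if (any(Biostrings::width(seqs) == 0)) {
    stop2("empty sequence for id '", ids[Biostrings::width(seqs) == 0][1], "'")
  }
  data.frame(
    id = ids,
    sample = sample,
    length = Biostrings::width(seqs),
    has_cds = FALSE,
    has_trna = FALSE,
    sequence = toupper(as.character(seqs)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write eccDNA records to FASTA
#'
#' @param records A record data frame as returned by [read_ecc_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecc_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Derive the sample label from an eccDNA id of the form "<sample>_<number>".
ecc_sample_from_id <- function(ids) sub("_[^_]*$", "", ids)

#' Read a protein FASTA as a named character vector
#'
#' @param path Path to a protein FASTA file.
#' @return Named character vector of uppercased sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop2("duplicate FASTA id: ", dup[1])
  stats::setNames(toupper(as.character(seqs)), ids)
}

#' Read eccDNA-to-genome alignments (PAF or BED)
#'
#' Returns one mapped interval per retained alignment line, 0-based
#' half-open on the target/genome. For PAF, target start/end are copied
#' as-is (PAF is already 0-based half-open) and, when the `tp:A` tag is
#' present, only primary alignments (`tp:A:P`) are kept unless
#' `primary_only = FALSE`. Lines with `start >= end` are skipped with a
#' warning giving the number skipped.
#'
#' @param path Path to a PAF or BED file.
#' @param format `"paf"` or `"bed"`. BED input must be BED4+ with the name
#'   column carrying the eccDNA id.
#' @param primary_only Keep only primary PAF alignments when the `tp:A`
#'   tag is present (default `TRUE`).
#' @param sample Optional sample label vector or single value; by default
#'   the sample is derived from the eccDNA id prefix (`"<sample>_<n>"`).
#' @return A data frame with columns `ecc_id`, `sample`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_alignments <- function(path, format = c("paf", "bed"),
                            primary_only = TRUE, sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("alignment file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "paf") {
    ok <- vapply(fields, length, 0L) >= 9L
    if (any(!ok)) stop2("PAF lines with fewer than 9 columns: line ", which(!ok)[1])
    ecc_id <- vapply(fields, `[[`, "", 1L)
    chrom  <- vapply(fields, `[[`, "", 6L)
    start  <- as.numeric(vapply(fields, `[[`, "", 8L))
    end    <- as.numeric(vapply(fields, `[[`, "", 9L))
    strand <- vapply(fields, `[[`, "", 5L)
    if (primary_only) {
      tp <- vapply(fields, function(f) {
        hit <- grep("^tp:A:", f, value = TRUE)
        if (length(hit)) sub("^tp:A:", "", hit[1]) else NA_character_
      }, "")
      keep <- is.na(tp) | tp == "P"
      ecc_id <- ecc_id[keep]; chrom <- chrom[keep]
      start <- start[keep]; end <- end[keep]; strand <- strand[keep]
    }
  } else {
    ok <- vapply(fields, length, 0L) >= 4L
    if (any(!ok)) stop2("BED alignment lines need >= 4 columns (name = eccDNA id): line ",
                        which(!ok)[1])
    chrom  <- vapply(fields, `[[`, "", 1L)
    start  <- as.numeric(vapply(fields, `[[`, "", 2L))
    end    <- as.numeric(vapply(fields, `[[`, "", 3L))
    ecc_id <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*", "")
  }
  bad <- !(start >= 0 & start < end)
  if (any(bad)) {
    warning(sprintf("skipped %d alignment line(s) with start >= end", sum(bad)))
    ecc_id <- ecc_id[!bad]; chrom <- chrom[!bad]
    start <- start[!bad]; end <- end[!bad]; strand <- strand[!bad]
  }
  strand[!strand %in% c("+", "-")] <- "unknown"
  if (is.null(sample)) sample <- ecc_sample_from_id(ecc_id)
  data.frame(ecc_id = ecc_id, sample = sample, chrom = chrom,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read genome annotation features (genes, TEs, QTLs)
#'
#' GFF3 input keeps only lines of type `gene` (for `kind = "gene"`) and
#' converts 1-based closed coordinates to the internal 0-based half-open
#' convention; BED input is taken natively. Invalid intervals
#' (`start >= end` after conversion) are skipped with a warning.
#'
#' @param path Path to a GFF3 or BED file.
#' @param kind Feature kind stored on every row: `"gene"`, `"TE"` or `"QTL"`.
#' @param format `"gff3"` or `"bed"`; guessed from the file extension by
#'   default.
#' @return A data frame with columns `chrom`, `start`, `end`, `kind`, `id`.
#' @export
read_features <- function(path, kind = c("gene", "TE", "QTL"), format = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop2("feature file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gff3") {
    ok <- vapply(fields, length, 0L) >= 9L
    fields <- fields[ok]
    type <- vapply(fields, `[[`, "", 3L)
    fields <- fields[type == "gene"]
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.numeric(vapply(fields, `[[`, "", 4L)) - 1  # 1-based closed -> 0-based half-open
    end   <- as.numeric(vapply(fields, `[[`, "", 5L))
    attr9 <- vapply(fields, `[[`, "", 9L)
    id <- sub("^.*ID=([^;]+).*$", "\\1", attr9)
  } else {
    ok <- vapply(fields, length, 0L) >= 3L
    fields <- fields[ok]
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.numeric(vapply(fields, `[[`, "", 2L))
    end   <- as.numeric(vapply(fields, `[[`, "", 3L))
    id <- vapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) >= 4L && nzchar(f[[4L]])) f[[4L]] else sprintf("%s_%d", kind, i)
    }, "")
  }
  bad <- !(start >= 0 & start < end)
  if (any(bad)) {
    warning(sprintf("skipped %d %s feature line(s) with invalid interval", sum(bad), kind))
  }
  data.frame(chrom = chrom[!bad], start = start[!bad], end = end[!bad],
             kind = kind, id = id[!bad], stringsAsFactors = FALSE, row.names = NULL)
}

#' Read per-eccDNA protein-domain annotations
#'
#' Expects a TSV with a header and columns `sample`, `ecc_id`, `gene_id`,
#' `pfam`. Accessions must match the PFAM pattern `PFxxxxx`.
#'
#' @param path Path to the domain TSV.
#' @return A data frame of domain records.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) stop2("domain file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "ecc_id", "gene_id", "pfam")
  if (!all(need %in% names(df))) {
    stop2("domain TSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !grepl("^PF[0-9]{5}$", df$pfam)
  if (any(bad)) stop2("malformed PFAM accession: '", df$pfam[bad][1], "'")
  df[need]
}
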