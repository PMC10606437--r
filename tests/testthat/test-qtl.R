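# QTL-interval overlap classification.

mk_iv <- function(id, sample, chrom, start, end) {
  data.frame(ecc_id = id, sample = sample, chrom = chrom, start = start,
             end = end, strand = rep("+", length(id)),
             stringsAsFactors = FALSE)
}

test_that("planted 15-QTL toy recovers the (12 with CDS, 4 HS-only, 1 HR-only) summary", {
  # 15 QTLs side by side; CDS planted in the first 12: QTLs 1-4 HS-only,
  # QTL 5 HR-only, QTLs 6-12 both; 13-15 empty.
  qtls <- data.frame(chrom = "chr1", start = (0:14) * 1e6,
                     end = (0:14) * 1e6 + 5e5, kind = "QTL",
                     id = sprintf("qtl-%02d", 1:15), stringsAsFactors = FALSE)
  gm <- c(HR1 = "HR", HS1 = "HS")
  at <- function(q) (q - 1) * 1e6 + 1000   # inside QTL q
  cds <- rbind(
    mk_iv(sprintf("HS1_%02d", 1:4), "HS1", "chr1", at(1:4), at(1:4) + 200),
    mk_iv("HR1_05", "HR1", "chr1", at(5), at(5) + 200),
    mk_iv(sprintf("HR1_%02d", 6:12), "HR1", "chr1", at(6:12), at(6:12) + 200),
    mk_iv(sprintf("HS1_%02d", 6:12), "HS1", "chr1", at(6:12), at(6:12) + 200))
  rep_cds <- overlap_qtl(cds, cds, qtls, gm)
  s <- attr(rep_cds, "summary")
  expect_equal(s$n_qtl_with_cds, 12L)
  expect_equal(s$n_hs_only, 4L)
  expect_equal(s$n_hr_only, 1L)
  expect_equal(rep_cds$cds_class[13:15], rep("none", 3))
  # classification is exhaustive and exclusive
  expect_true(all(rep_cds$cds_class %in% c("HR-only", "HS-only", "both", "none")))
})

test_that("no eccDNAs means every QTL classifies as none", {
  qtls <- data.frame(chrom = "chr1", start = 0, end = 1e5, kind = "QTL",
                     id = "qtl-1", stringsAsFactors = FALSE)
  none <- mk_iv(character(0), character(0), character(0), numeric(0), numeric(0))
  r <- overlap_qtl(none, none, qtls, c(S = "HR"))
  expect_equal(r$cds_class, "none")
  expect_equal(attr(r, "summary")$total_hr_ecc, 0L)
})

test_that("per-QTL counts equal the brute-force double loop; dedup mode differs from per-QTL sums", {
  set.seed(51)
  gi <- c(chr1 = 3e6)
  qtls <- data.frame(chrom = "chr1", start = seq(0, 2.7e6, by = 3e5),
                     end = seq(0, 2.7e6, by = 3e5) + 2.5e5, kind = "QTL",
                     id = sprintf("q%02d", 1:10), stringsAsFactors = FALSE)
  n <- 100
  samples <- sample(c("HR1", "HR2", "HS1"), n, TRUE)
  start <- floor(runif(n, 0, 2.9e6))
  iv <- mk_iv(sprintf("%s_%03d", samples, 1:n), samples, "chr1", start,
              start + sample(200:400000, n, TRUE))
  gm <- c(HR1 = "HR", HR2 = "HR", HS1 = "HS")
  r <- overlap_qtl(iv, iv, qtls, gm)
  for (q in seq_len(nrow(qtls))) {
    hit <- iv$start < qtls$end[q] & iv$end > qtls$start[q]
    expect_equal(r$n_hr_ecc[q], length(unique(iv$ecc_id[hit & gm[iv$sample] == "HR"])))
    expect_equal(r$n_hs_ecc[q], length(unique(iv$ecc_id[hit & gm[iv$sample] == "HS"])))
  }
  r2 <- overlap_qtl(iv, iv, qtls, gm, count_mode = "per_qtl")
  expect_equal(attr(r2, "summary")$total_hr_ecc, sum(r$n_hr_ecc))
  expect_lte(attr(r, "summary")$total_hr_ecc, attr(r2, "summary")$total_hr_ecc)
})

test_that("HR-exclusive windows: planted recovery, HS exclusion, monotone relaxation", {
  gm <- c(HR1 = "HR", HR2 = "HR", HR3 = "HR", HS1 = "HS")
  w <- data.frame(chrom = "chr1", start = (0:3) * 5e5, end = (1:4) * 5e5,
                  window = 0:3,
                  HR1 = c(2L, 1L, 0L, 1L), HR2 = c(1L, 1L, 0L, 0L),
                  HR3 = c(3L, 0L, 0L, 1L), HS1 = c(0L, 0L, 0L, 2L))
  attr(w, "samples") <- c("HR1", "HR2", "HR3", "HS1")
  qtls <- data.frame(chrom = "chr1", start = 0, end = 2e6, kind = "QTL",
                     id = "q1", stringsAsFactors = FALSE)
  r3 <- hr_exclusive_windows(w, qtls, gm, min_samples = 3)
  expect_equal(r3$start, 0)          # window 0: three HR samples, zero HS
  # window 3 has HR content but any HS count excludes it
  r1 <- hr_exclusive_windows(w, qtls, gm, min_samples = 1)
  expect_false(any(r1$start == 15e5))
  # relaxing min_samples only grows the result set
  expect_true(all(r3$start %in% r1$start))
  expect_gte(nrow(r1), nrow(r3))
})
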