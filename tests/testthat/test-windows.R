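# Genome-window counting, phenotype totals, hotspot calls, tracks.

gi2 <- c(chr1 = 2e6, chr2 = 1.5e6)

iv_row <- function(id, sample, chrom, start, end) {
  data.frame(ecc_id = id, sample = sample, chrom = chrom, start = start,
             end = end, strand = rep("+", length(id)),
             stringsAsFactors = FALSE)
}

test_that("an interval spanning a window boundary increments both windows", {
  iv <- iv_row("e1", "S1", "chr1", 499900, 500100)
  w <- count_windows(iv, gi2, 5e5)
  expect_equal(w$S1[w$chrom == "chr1" & w$window %in% c(0, 1)], c(1L, 1L))
  expect_equal(sum(w$S1), 2L)
  # midpoint mode assigns to a single window
  wm <- count_windows(iv, gi2, 5e5, midpoint = TRUE)
  expect_equal(sum(wm$S1), 1L)
})

test_that("no intervals gives an all-zero grid that tiles the genome exactly", {
  w <- count_windows(iv_row(character(0), character(0), character(0),
                            numeric(0), numeric(0))[0, ], gi2, 5e5)
  expect_equal(nrow(w), 4L + 3L)
  expect_true(all(w$end - w$start <= 5e5))
  for (ch in names(gi2)) {
    ww <- w[w$chrom == ch, ]
    expect_equal(ww$start[1], 0)
    expect_equal(ww$end[nrow(ww)], unname(gi2[ch]))
    expect_true(all(ww$start[-1] == ww$end[-nrow(ww)]))
  }
})

test_that("window counts match the brute-force double loop on random intervals", {
  set.seed(9)
  n <- 200
  ch <- sample(names(gi2), n, TRUE)
  start <- floor(runif(n, 0, gi2[ch] - 30000))
  len <- sample(31:29081, n, TRUE)
  iv <- iv_row(sprintf("S1_%03d", 1:n), "S1", ch, start,
               pmin(start + len, gi2[ch]))
  w <- count_windows(iv, gi2, 5e5)
  grid <- window_grid(gi2, 5e5)
  expect_equal(w$S1, brute_window_counts(iv, grid))
  # conservation: any-overlap counting is >= one count per interval
  expect_gte(sum(w$S1), n)
})

test_that("unknown chromosomes go to the unplaced bucket with a warning", {
  iv <- rbind(iv_row("e1", "S1", "chr1", 0, 100),
              iv_row("e2", "S1", "scaffold_9", 0, 100))
  expect_warning(w <- count_windows(iv, gi2, 5e5), "unplaced")
  expect_equal(attr(w, "unplaced"), 1L)
  expect_equal(sum(w$S1), 1L)
})

test_that("phenotype totals sum per-sample counts and grand = hr + hs", {
  w <- data.frame(chrom = "chr1", start = 0, end = 5e5, window = 0L,
                  A = 70L, B = 63L, C = 60L, D = 44L)
  attr(w, "samples") <- c("A", "B", "C", "D")
  gm <- c(A = "HR", B = "HR", C = "HS", D = "HS")
  t1 <- phenotype_totals(w, gm)
  expect_equal(t1$hr_total, 133)
  expect_equal(t1$hs_total, 104)
  expect_equal(t1$grand, 237)
  expect_error(phenotype_totals(w, gm[-1]), "missing from the group map|missing from group map")
  # all-zero window
  w0 <- w; w0[c("A", "B", "C", "D")] <- 0L; attr(w0, "samples") <- c("A","B","C","D")
  t0 <- phenotype_totals(w0, gm)
  expect_equal(unlist(t0[c("hr_total", "hs_total", "grand")]),
               c(hr_total = 0, hs_total = 0, grand = 0))
})

test_that("hotspot calling: uniform counts yield none, k = 0 means above-mean", {
  w <- data.frame(chrom = "chr1", start = (0:9) * 5e5, end = (1:10) * 5e5,
                  window = 0:9, grand = rep(5L, 10))
  expect_warning(h <- call_hotspots(w, k = 3), "zero variance")
  expect_false(any(h$passed))
  w$grand <- c(rep(2L, 9), 40L)
  h0 <- call_hotspots(w, k = 0)
  expect_identical(h0$passed, w$grand > mean(w$grand))
})

test_that("a planted 50x hotspot is called at k = 3", {
  cfg <- small_sim_config(seed = 31)
  cfg$hotspots <- data.frame(chrom = "chr1", window = 4L, multiplier = 50)
  cfg$window_size <- 1e5          # 20 anchored windows
  cfg$frac_unanchored <- 0
  sim <- simulate_eccdna(cfg)
  gi <- sim$genome$lengths[sim$genome$anchored]
  w <- count_windows(sim$intervals, gi, 1e5, group_map = sim$group_map)
  h <- call_hotspots(w, k = 3)
  called <- h[h$passed, ]
  expect_true(any(called$chrom == "chr1" & called$start == 4e5))
})

test_that("mapping-rate statistics recover a planted unanchored fraction", {
  cfg <- small_sim_config(seed = 17)
  cfg$circles_per_sample <- 300
  cfg$dup_frac <- 0
  sim <- simulate_eccdna(cfg)   # frac_unanchored = 0.085
  ms <- mapping_stats(sim$circles$id, sim$intervals, sim$genome$anchored)
  expect_equal(ms$mapped_frac, 1)
  n <- nrow(sim$circles)
  se <- sqrt(0.085 * (1 - 0.085) / n)
  expect_lt(abs(ms$unanchored_frac - 0.085), 4 * se)
  expect_equal(ms$anchored_frac + ms$unanchored_frac, ms$mapped_frac)
})

test_that("exported tracks are consistent with count_windows on the features", {
  sim <- simulate_eccdna(small_sim_config(seed = 19))
  gi <- sim$genome$lengths[sim$genome$anchored]
  w <- suppressWarnings(count_windows(sim$intervals, gi, 5e5,
                                      group_map = sim$group_map))
  d <- withr::local_tempdir()
  files <- export_tracks(w, sim$genes, sim$tes, gi, d)
  expect_true(all(file.exists(files)))
  gt <- read_tsv(files[["genes"]])
  giv <- data.frame(ecc_id = sim$genes$id, sample = "all",
                    chrom = sim$genes$chrom, start = sim$genes$start,
                    end = sim$genes$end)
  expect_equal(gt$value, count_windows(giv, gi, 5e5)$all)
  # empty annotation gives an all-zero track
  f0 <- export_tracks(w, sim$genes[0, ], sim$tes[0, ], gi, d)
  expect_true(all(read_tsv(f0[["tes"]])$value == 0))
})
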