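# Flank profiles and the label-permutation test.

feat <- function(chrom, start, end, id, kind = "gene") {
  data.frame(chrom = chrom, start = start, end = end, kind = kind, id = id,
             stringsAsFactors = FALSE)
}

toy_profiles <- function(x, present) {
  data.frame(unit_id = sprintf("u%d", seq_along(x)), chrom = "chr1",
             start = 0, end = 1, flank_gene_count = x, flank_te_count = x,
             ecc_present = present, stringsAsFactors = FALSE)
}

test_that("flank counting: containment, self-exclusion and edge clipping", {
  gi <- c(chr1 = 3e6)
  genes <- rbind(feat("chr1", 1e6, 1001000, "gA"),
                 feat("chr1", 1151000, 1154000, "gB"),   # 150 kb away
                 feat("chr1", 2.5e6, 2503000, "gC"))     # far away
  tes <- feat("chr1", 1.05e6, 1050500, "t1", kind = "TE")
  ecc <- data.frame(ecc_id = "e1", sample = "S1", chrom = "chr1",
                    start = 1000500, end = 1000900, strand = "+")
  prof <- build_flank_profiles(genes, genes, tes, ecc, flank = 2e5,
                               unit_mode = "gene", genome_index = gi)
  a <- prof[prof$unit_id == "gA", ]
  expect_equal(a$flank_gene_count, 1L)  # gB in flank, gA itself excluded
  expect_equal(a$flank_te_count, 1L)
  expect_true(a$ecc_present)
  expect_false(prof$ecc_present[prof$unit_id == "gB"])

  # unit at the chromosome start: left flank clipped, counts still defined
  g0 <- rbind(feat("chr1", 0, 1000, "g0"), genes)
  prof0 <- build_flank_profiles(g0, g0, tes, ecc, flank = 2e5,
                                unit_mode = "gene", genome_index = gi)
  expect_equal(prof0$flank_gene_count[prof0$unit_id == "g0"], 0L)
})

test_that("flank profiles equal the brute-force overlap scan on random features", {
  set.seed(23)
  gi <- c(chr1 = 2e6, chr2 = 2e6)
  n <- 50
  mk <- function(n, len, prefix, kind) {
    ch <- sample(names(gi), n, TRUE)
    s <- floor(runif(n, 0, gi[ch] - len))
    feat(ch, s, s + len, sprintf("%s%03d", prefix, 1:n), kind)
  }
  genes <- mk(n, 2000, "g", "gene")
  tes <- mk(n, 400, "t", "TE")
  ecc <- {
    ch <- sample(names(gi), 60, TRUE)
    s <- floor(runif(60, 0, gi[ch] - 5000))
    data.frame(ecc_id = sprintf("e%03d", 1:60), sample = "S1", chrom = ch,
               start = s, end = s + sample(100:5000, 60, TRUE), strand = "+")
  }
  prof <- build_flank_profiles(genes, genes, tes, ecc, flank = 2e5,
                               unit_mode = "gene", genome_index = gi)
  oracle <- brute_flank_profiles(genes, genes, tes, ecc, 2e5, gi)
  expect_equal(prof$flank_gene_count, oracle$flank_gene_count)
  expect_equal(prof$flank_te_count, oracle$flank_te_count)
  expect_equal(prof$ecc_present, oracle$ecc_present)
})

test_that("identical group values give zero difference and p = 1", {
  prof <- toy_profiles(c(3, 3, 3, 3, 3, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  r <- permutation_test(prof, "gene")
  expect_equal(r$obs_diff, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$method, "exact")
})

test_that("3-vs-3 toy: exact one-sided p is 1/20 and sampling agrees within 3 SE", {
  prof <- toy_profiles(c(2, 2, 2, 0, 0, 0), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ex <- permutation_test(prof, "gene", sidedness = "greater")
  expect_equal(ex$method, "exact")
  expect_equal(ex$obs_diff, 2)
  expect_equal(ex$p_value, 1 / 20)
  sam <- permutation_test(prof, "gene", sidedness = "greater",
                          n_perm = 10000, seed = 4, exact_limit = 1)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(sam$p_value - 0.05), 3 * se)
})

test_that("one empty group is a hard error naming the group", {
  prof <- toy_profiles(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_error(permutation_test(prof, "gene"), "absent")
  prof$ecc_present <- FALSE
  expect_error(permutation_test(prof, "gene"), "present")
})

test_that("sampling without a seed is an error; exact enumeration needs none", {
  x <- rnorm(30)
  prof <- toy_profiles(x, rep(c(TRUE, FALSE), 15))
  expect_error(permutation_test(prof, "gene", exact_limit = 10), "seed")
  expect_silent(permutation_test(prof, "gene", exact_limit = 10,
                                 n_perm = 100, seed = 1))
})

test_that("one-sided p is non-increasing in the observed difference (fixed null)", {
  # same values, two labelings of equal group sizes -> identical null set
  x <- c(5, 4, 3, 2, 1, 0)
  small <- toy_profiles(x, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  large <- toy_profiles(x, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  p_small <- permutation_test(small, "gene", sidedness = "greater")
  p_large <- permutation_test(large, "gene", sidedness = "greater")
  expect_gt(p_large$obs_diff, p_small$obs_diff)
  expect_lte(p_large$p_value, p_small$p_value)
})

test_that("sampled p converges to the exact p on a small instance", {
  set.seed(12)
  x <- rpois(12, 3)
  g <- rep(c(TRUE, FALSE), each = 6)
  prof <- toy_profiles(x, g)
  ex <- permutation_test(prof, "gene")           # C(12,6) = 924 -> exact
  expect_equal(ex$method, "exact")
  sam <- permutation_test(prof, "gene", n_perm = 10000, seed = 2,
                          exact_limit = 1)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 10000)
  expect_lt(abs(sam$p_value - ex$p_value), 3 * se + 2e-4)
})
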