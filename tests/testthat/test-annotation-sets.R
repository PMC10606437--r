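# Set algebra over per-sample PFAM catalogs and term enrichment.

catalog_from <- function(...) {
  # build catalogs from named accession character vectors
  lapply(list(...), function(acc) setNames(rep(1L, length(acc)), acc))
}

test_that("identical catalogs share everything; specific and unique sets are empty", {
  acc <- sprintf("PF%05d", 1:10)
  cats <- catalog_from(A = acc, B = acc, C = acc, D = acc)
  gm <- c(A = "HR", B = "HR", C = "HS", D = "HS")
  p <- partition_domains(cats, gm)
  expect_setequal(p$core_all, acc)
  expect_length(p$hr_core_specific, 0L)
  expect_length(p$hs_core_specific, 0L)
  expect_true(all(lengths(p$per_sample_unique) == 0L))
})

test_that("partition identities hold on random catalogs (property)", {
  set.seed(41)
  universe <- sprintf("PF%05d", 1:300)
  for (rep_i in 1:40) {
    cats <- lapply(1:5, function(i) {
      acc <- sample(universe, sample(20:120, 1))
      setNames(sample(1:5, length(acc), TRUE), acc)
    })
    names(cats) <- c("A", "B", "C", "D", "E")
    gm <- c(A = "HR", B = "HR", C = "HR", D = "HS", E = "HS")
    p <- partition_domains(cats, gm)
    # hr_core = core_all (disjoint-)union hr_core_specific
    expect_length(intersect(p$core_all, p$hr_core_specific), 0L)
    expect_setequal(p$hr_core, union(p$core_all, p$hr_core_specific))
    expect_equal(length(p$hr_core),
                 length(p$core_all) + length(p$hr_core_specific))
    expect_equal(length(p$hs_core),
                 length(p$core_all) + length(p$hs_core_specific))
    # unique accessions occur in exactly one sample
    for (s in names(cats)) {
      others <- unlist(lapply(cats[setdiff(names(cats), s)], names))
      expect_length(intersect(p$per_sample_unique[[s]], others), 0L)
    }
    # invariant to sample order and to counts
    p2 <- partition_domains(rev(cats), gm)
    expect_setequal(p2$core_all, p$core_all)
    cats10 <- lapply(cats, function(ct) ct * 10L)
    expect_setequal(partition_domains(cats10, gm)$core_all, p$core_all)
  }
})

test_that("planted 69/11/22 vocabulary is recovered with its size identities", {
  sim <- simulate_eccdna(small_sim_config(seed = 43))
  p <- partition_domains(domain_catalogs(sim$domains), sim$group_map)
  expect_length(p$core_all, 69L)
  expect_length(p$hr_core_specific, 11L)
  expect_length(p$hs_core_specific, 22L)
  expect_length(p$hr_core, 80L)   # 69 + 11
  expect_length(p$hs_core, 91L)   # 69 + 22
})

test_that("abundance ranking sums counts over samples with deterministic ties", {
  cats <- list(A = c(PF00001 = 3L, PF00002 = 5L), B = c(PF00001 = 3L))
  r <- rank_abundance(cats)
  expect_equal(r$pfam, c("PF00001", "PF00002"))  # 6 > 5
  expect_equal(r$n_ecc, c(6L, 5L))
  tie <- rank_abundance(list(A = c(PF00009 = 2L, PF00003 = 2L)))
  expect_equal(tie$pfam, c("PF00003", "PF00009"))
  # the generator's planted dominant domain comes out at rank 1
  sim <- simulate_eccdna(small_sim_config(seed = 44))
  top <- rank_abundance(domain_catalogs(sim$domains), top_n = 1)
  expect_equal(top$pfam, sim$truth$vocab$core[1])
})

test_that("watchlist flags mark exactly the samples carrying the group", {
  cats <- catalog_from(A = c("PF00001", "PF99001"), B = "PF00001",
                       C = "PF99001", D = "PF00002")
  wl <- list(p450 = "PF99001", gst = c("PF00001", "PF00002"),
             ghost = "PF55555")
  expect_warning(m <- detox_flags(cats, wl), "ghost")
  expect_equal(unname(m[, "p450"]), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(m[, "gst"]), c(TRUE, TRUE, FALSE, TRUE))
  expect_true(all(!m[, "ghost"]))
  expect_equal(attr(m, "exclusive")$p450, c("A", "C"))
  # entry present in every sample -> confined-to list is all samples
  expect_equal(attr(m, "exclusive")$gst, c("A", "B", "D"))
})

test_that("hypergeometric enrichment has closed-form p-values and BH control", {
  bg <- sprintf("id%03d", 1:50)
  target <- bg[1:5]
  tm <- list(all_term = bg, rare = bg[1:5])
  r <- term_enrichment(target, bg, tm, fdr = 0.05)
  expect_equal(r$p_value[r$term == "all_term"], 1)
  expect_equal(r$p_value[r$term == "rare"], 1 / choose(50, 5))
  # BH by hand on p = .01/.02/.04 with m = 3 at fdr .05: all pass
  q <- stats::p.adjust(c(0.01, 0.02, 0.04), "BH")
  expect_true(all(q < 0.05))
  expect_error(term_enrichment(character(0), bg, tm), "empty target")
  expect_error(term_enrichment("nope", bg, tm), "subset")
})
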