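toy_library <- function() {
  oligo_library(
    oligo_id = c("o1", "o2", "o3", "o4", "o5"),
    sequence = c("AAAAAAAACCCCCCCC", "CCCCCCCCGGGGGGGG",
                 "GGGGGGGGAAAAAAAA", "ACGUACGUACGUACGU",
                 "AAAAAAAACCCCCCCG"), # o5 is 1 mismatch from o1
    validate = FALSE
  )
}

test_that("read matching follows best-stratum unique assignment", {
  lib <- toy_library()
  reads <- read_pool(
    c("AAAAAAAACCCCCCCC",  # exact o1
      "CCCCCCCCGGGGGGGA",  # 1 mm from o2
      "GGGGGGGGAAAAAAUU",  # 2 mm from o3 -> unassigned
      "AAAAAAAACCCCCCCA"), # 1 mm from both o1 and o5 -> multimapper
    role = "bound", randomized_length = 16
  )
  res <- match_reads(reads, lib, max_mismatch = 1)
  expect_equal(unname(res$counts[c("o1", "o2", "o3")]), c(1, 1, 0))
  expect_equal(res$n_unassigned, 1)
  expect_equal(res$n_multimapped, 1)
})

test_that("matching equals the brute-force Hamming oracle", {
  lib <- make_ns_library(group_sizes = c(control = 30, shared = 20),
                         seed = 13)
  windows <- setNames(substr(lib$sequence, 1, 30), lib$oligo_id)
  set.seed(14)
  ## reads: sampled windows with 0-2 random substitutions
  idx <- sample(nrow(lib), 120, replace = TRUE)
  reads <- vapply(idx, function(i) {
    s <- windows[[i]]
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      at <- sample(30, nmut)
      for (p in at) {
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "U"),
                                          substr(s, p, p)), 1)
      }
    }
    s
  }, character(1))
  pool <- read_pool(reads, role = "bound", randomized_length = 30)
  for (mm in 0:1) {
    res <- match_reads(pool, lib, max_mismatch = mm)
    oracle_counts <- setNames(numeric(nrow(lib)), lib$oligo_id)
    o_multi <- 0; o_un <- 0
    for (j in seq_along(pool$seq)) {
      a <- oracle_assign(pool$seq[j], windows, mm)
      if (a == "multimapped") o_multi <- o_multi + pool$count[j]
      else if (a == "unassigned") o_un <- o_un + pool$count[j]
      else oracle_counts[a] <- oracle_counts[a] + pool$count[j]
    }
    expect_equal(res$counts, oracle_counts)
    expect_equal(res$n_multimapped, o_multi)
    expect_equal(res$n_unassigned, o_un)
  }
})

test_that("count filter and enrichment frequencies follow the contract", {
  ci <- c(a = 50, b = 25, c = 25, d = 10, e = 100)
  cb <- c(a = 50, b = 25, c = 25, d = 100, e = 10)
  oe <- oligo_enrichment(ci, cb, min_count = 25)
  expect_identical(oe$passed_filter, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(oe$R[oe$passed_filter] == 1))
  expect_true(all(is.na(oe$R[!oe$passed_filter])))
  ## retained frequencies sum to 1 per pool
  expect_equal(sum(oe$freq_input, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_equal(sum(oe$freq_bound, na.rm = TRUE), 1, tolerance = 1e-12)
  ## hand frequencies: input (30,30,60) / bound (60,30,30)
  oe2 <- oligo_enrichment(c(x = 30, y = 30, z = 60),
                          c(x = 60, y = 30, z = 30), min_count = 25)
  expect_equal(oe2$R, c(2, 1, 0.5))
  expect_error(oligo_enrichment(c(a = 1), c(a = 1), min_count = 25),
               "no oligo")
})

test_that("group comparisons run all pairs with BH correction", {
  ids <- sprintf("g%02d", 1:30)
  oe <- oligo_enrichment(setNames(rep(100, 30), ids),
                         setNames(c(rep(400, 10), rep(100, 10),
                                    rep(25, 10)), ids),
                         min_count = 25)
  grouping <- setNames(rep(c("high", "mid", "low"), each = 10), ids)
  ## jitter within groups so KS sees continuous samples
  oe$log2R <- oe$log2R + rep(seq(-0.1, 0.1, length.out = 10), 3)
  cmp <- compare_groups(oe, grouping)
  expect_identical(nrow(cmp), 3L)
  expect_true(all(cmp$D >= 0 & cmp$D <= 1))
  expect_true(all(cmp$p_adj >= cmp$p))
  expect_true(all(cmp$p_adj <= 1))
  ## disjoint supports -> D = 1
  expect_identical(cmp$D[cmp$group1 == "high" & cmp$group2 == "low"], 1)
  ## identical samples -> D = 0
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
})

test_that("wt/mut deltas classify at the 0.5 log2 threshold", {
  lib <- oligo_library(
    oligo_id = c(paste0("w", 1:3), paste0("w", 1:3, "_mut")),
    sequence = c(rep("GGUAGG", 3), rep("GGCCGG", 3)),
    variant = rep(c("wt", "mut"), each = 3),
    partner_id = c(paste0("w", 1:3, "_mut"), paste0("w", 1:3)),
    validate = FALSE
  )
  ids <- c(paste0("w", 1:3), paste0("w", 1:3, "_mut"))
  ci <- setNames(rep(1000, 6), ids)
  ## deltas: +0.6, -0.6, +0.2
  cb <- setNames(c(1000 * 2^0.6, 1000 * 2^-0.6, 1000 * 2^0.2,
                   1000, 1000, 1000), ids)
  oe <- oligo_enrichment(ci, round(cb), min_count = 25)
  res <- wt_mut_delta(oe, lib)
  expect_identical(res$pairs$class[match(paste0("w", 1:3),
                                         res$pairs$wt_id)],
                   c("wt_better", "mut_better", "similar"))
  expect_identical(res$n_excluded, 0L)
})

test_that("all-zero paired deltas give Wilcoxon p = 1 with warning", {
  expect_warning(
    res <- wilcoxon_test(rep(1, 5), rep(1, 5), paired = TRUE,
                         alternative = "greater"),
    "zero"
  )
  expect_identical(res$p, 1)
})

test_that("paired one-sided Wilcoxon matches the sign-flip oracle", {
  set.seed(31)
  for (i in 1:3) {
    d <- round(rnorm(8, mean = 0.5), 3)
    d <- d[d != 0]
    p_pkg <- wilcoxon_test(d, alternative = "greater")$p
    expect_equal(p_pkg, oracle_signflip_p(d), tolerance = 1e-12)
  }
  ## all positive deltas, n = 6: p = 1/2^6
  expect_equal(wilcoxon_test(c(1, 2, 3, 4, 5, 6),
                             alternative = "greater")$p,
               1 / 2^6)
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  set.seed(41)
  for (i in 1:3) {
    p <- runif(10)
    expect_equal(bh_adjust(p), oracle_bh(p))
    ## permutation invariance
    perm <- sample(10)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  }
})

test_that("enrichment by motif count is monotone for a planted library", {
  ids <- sprintf("m%02d", 1:24)
  uag <- rep(0:3, each = 6)
  seqs <- vapply(uag, function(u) {
    paste0(strrep("UAGCC", u), strrep("CCACC", 4 - u), "CCCC")
  }, character(1))
  lib <- oligo_library(ids, seqs, validate = FALSE)
  expect_identical(lib$uag_count, as.integer(uag))
  ci <- setNames(rep(1000, 24), ids)
  cb <- setNames(round(1000 * 2^uag + rep(0:5, 4)), ids)
  oe <- oligo_enrichment(ci, cb, min_count = 25)
  summ <- enrichment_by_motif_count(oe, lib)
  expect_identical(summ$uag_count, 0:3)
  expect_true(all(diff(summ$median_log2R) > 0))
  ## absent class yields an absent row
  oe2 <- oe[lib$uag_count != 2, ]
  summ2 <- enrichment_by_motif_count(oe2, lib)
  expect_identical(summ2$uag_count, c(0L, 1L, 3L))
})

test_that("simulated nsRBNS reproduces the planted group ordering", {
  lib <- make_ns_library(seed = 61)
  sim <- simulate_library_selection(lib, n_input = 40000,
                                    n_bound = 40000, seed = 62)
  oe <- oligo_enrichment(match_reads(sim$input, lib)$counts,
                         match_reads(sim$bound, lib)$counts)
  grp <- setNames(ifelse(lib$variant == "mut", "mut", lib$group),
                  lib$oligo_id)
  ok <- oe$passed_filter
  med <- tapply(oe$log2R[ok], grp[oe$oligo_id[ok]], median)
  expect_gt(med[["shared"]], med[["msi1_only"]])
  expect_gt(med[["shared"]], med[["unk_only"]])
  expect_gt(med[["msi1_only"]], med[["control"]])
  expect_gt(med[["unk_only"]], med[["control"]])
  ## background groups are equivalent
  expect_lt(abs(med[["control"]] - med[["stop_codon"]]), 0.4)
  expect_lt(abs(med[["control"]] - med[["mut"]]), 0.4)
})
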