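test_that("kmer counting matches the naive double-loop oracle exactly", {
  for (seed in 1:3) {
    pool <- make_random_pool(length = 12, n = 80, seed = seed)
    for (k in c(2, 4)) {
      fast <- count_kmers(pool, k)
      slow <- oracle_count_kmers(pool$seq, pool$count, k)
      expect_identical(fast[names(slow)], slow)
      expect_identical(sum(fast), sum(slow))
      ## total = reads x positions
      expect_equal(sum(fast),
                   pool_size(pool) * (pool$randomized_length - k + 1))
    }
  }
})

test_that("R values reproduce the hand-counted example", {
  ip <- read_pool(c("UAGUAG", "CCCCCC"), role = "input")
  bp <- read_pool("UAGUAG", role = "bound")
  kt <- compute_kmer_table(ip, bp, k = 3, pseudocount = 0)
  ## input 3mers: UAG,AGU,GUA,UAG + CCC x4 -> f(UAG) = 2/8
  ## bound 3mers: UAG,AGU,GUA,UAG       -> f(UAG) = 2/4
  expect_equal(kt$R[kt$kmer == "UAG"], 2)
  expect_equal(kt$R[kt$kmer == "AGU"], 2)
  expect_equal(kt$R[kt$kmer == "CCC"], 0)
  expect_false(kt$defined[kt$kmer == "CCC"])
  expect_identical(kt$log2R[kt$kmer == "CCC"], -Inf)
  ## frequency normalization invariants
  expect_equal(sum(kt$freq_input), 1, tolerance = 1e-9)
  expect_equal(sum(kt$freq_bound), 1, tolerance = 1e-9)
  expect_identical(nrow(kt), 64L)
})

test_that("identical pools give R = 1 everywhere present", {
  pool <- make_random_pool(length = 10, n = 300, seed = 5)
  kt <- compute_kmer_table(pool, pool, k = 3)
  present <- kt$count_input > 0
  expect_true(all(kt$R[present] == 1))
  expect_true(all(kt$log2R[present] == 0))
})

test_that("bound-pool occurrences monotonically increase R", {
  ip <- make_random_pool(length = 10, n = 200, seed = 9)
  bp <- make_random_pool(length = 10, n = 200, seed = 10)
  target <- substr(bp$seq[1], 1, 4)
  r_at_copies <- vapply(c(1L, 4L, 16L), function(mult) {
    boosted <- bp
    boosted$count[1] <- mult
    compute_kmer_table(ip, boosted, k = 4, pseudocount = 1e-6)$R[
      all_kmers(4) == target
    ]
  }, numeric(1))
  expect_true(all(diff(r_at_copies) > 0))
})

test_that("replicate merging averages R and recomputes frequencies", {
  ip <- make_random_pool(length = 10, n = 400, seed = 21)
  reps <- lapply(1:3, function(i) {
    bp <- simulate_selection(ip, uag_core_model(), n_bound = 400,
                             seed = 30 + i,
                             replicate_id = paste0("rep", i))
    compute_kmer_table(ip, bp, k = 3, pseudocount = 1e-6)
  })
  merged <- merge_replicates(reps)
  ## independent element-wise recomputation
  expect_equal(merged$R,
               (reps[[1]]$R + reps[[2]]$R + reps[[3]]$R) / 3)
  expect_equal(merged$count_bound,
               reps[[1]]$count_bound + reps[[2]]$count_bound +
                 reps[[3]]$count_bound)
  expect_equal(sum(merged$freq_bound), 1, tolerance = 1e-9)
  expect_identical(attr(merged, "replicates_merged"),
                   c("rep1", "rep2", "rep3"))
  ## single table returned unchanged
  expect_identical(merge_replicates(reps[1]), reps[[1]])
  ## two-replicate mean: R {2, 4} -> 3
  t1 <- reps[[1]]; t2 <- reps[[1]]
  t1$R[] <- 2; t2$R[] <- 4
  expect_true(all(merge_replicates(list(t1, t2))$R == 3))
})

test_that("replicate log2R correlate strongly at moderate depth", {
  ip <- make_random_pool(length = 20, n = 100000, seed = 100)
  tabs <- lapply(1:2, function(i) {
    bp <- simulate_selection(ip, aurich_additive_model(),
                             n_bound = 100000, seed = 200 + i)
    compute_kmer_table(ip, bp, k = 6, pseudocount = 1e-6)
  })
  r <- cor(tabs[[1]]$log2R, tabs[[2]]$log2R)
  expect_gt(r, 0.9)
})

test_that("top-k overlap matches a set-operation oracle", {
  ip <- make_random_pool(length = 10, n = 500, seed = 41)
  tabs <- lapply(1:3, function(i) {
    bp <- simulate_selection(ip, uag_core_model(), n_bound = 500,
                             seed = 50 + i)
    compute_kmer_table(ip, bp, k = 3, pseudocount = 1e-6)
  })
  names(tabs) <- c("A", "B", "C")
  ov <- top_k_overlap(tabs, n_top = 25)
  sets <- lapply(tabs, function(t) t$kmer[order(-t$R, t$kmer)][1:25])
  for (a in names(tabs)) for (b in names(tabs)) {
    expect_identical(ov$pairwise[a, b],
                     length(intersect(sets[[a]], sets[[b]])))
  }
  expect_identical(ov$all_shared,
                   length(intersect(intersect(sets$A, sets$B), sets$C)))
  ## identity and disjoint corner cases
  same <- top_k_overlap(list(x = tabs$A, y = tabs$A), n_top = 10)
  expect_identical(unname(same$pairwise[1, 2]), 10L)
  expect_identical(same$all_shared, 10L)
  expect_error(top_k_overlap(tabs, n_top = 65), "n_top")
})

test_that("single-mutant profile equals direct lookups on a toy table", {
  kt <- data.frame(kmer = all_kmers(3), R = 1)
  attr(kt, "k") <- 3L
  ## hand-set: top UAG, graded single mutants
  set_r <- function(km, val) kt$R[kt$kmer == km] <<- val
  set_r("UAG", 10)
  set_r("AAG", 7); set_r("CAG", 6); set_r("GAG", 2)
  set_r("UCG", 3); set_r("UGG", 2); set_r("UUG", 8)
  set_r("UAA", 9); set_r("UAC", 1); set_r("UAU", 4)
  prof <- single_mutant_profile(kt)
  expect_identical(prof$top_kmer, "UAG")
  expect_equal(prof$matrix["pos1", "A"], 7)
  expect_equal(prof$matrix["pos2", "U"], 8)
  expect_equal(prof$matrix["pos3", "A"], 9)
  expect_equal(prof$matrix["pos1", "U"], 10) # wild-type cell
  ## r_drop = R(top) - best alternative per position
  expect_equal(unname(prof$r_drop), c(10 - 7, 10 - 8, 10 - 9))
  expect_true(all(prof$r_drop >= 0))
  ## flat table: zero drop everywhere, lexicographic top
  flat <- data.frame(kmer = all_kmers(3), R = 1)
  attr(flat, "k") <- 3L
  pf <- single_mutant_profile(flat)
  expect_identical(pf$top_kmer, "AAA")
  expect_true(all(pf$r_drop == 0))
})

test_that("UAG-core simulation concentrates R drop inside the UAG", {
  ip <- make_random_pool(length = 20, n = 100000, seed = 61)
  bp <- simulate_selection(ip, uag_context_model(), n_bound = 100000,
                           seed = 62)
  kt <- compute_kmer_table(ip, bp, k = 6, pseudocount = 1e-6)
  prof <- single_mutant_profile(kt)
  at <- regexpr("UAG", prof$top_kmer)[1]
  expect_gte(at, 1) # the top 6mer carries the UAG core
  core <- at:(at + 2)
  expect_gt(min(prof$r_drop[core]),
            max(prof$r_drop[setdiff(1:6, core)]))
})

test_that("logo alignment and normalization follow the stated rules", {
  kt <- data.frame(kmer = all_kmers(3), R = 1)
  attr(kt, "k") <- 3L
  kt$R[kt$kmer == "UAG"] <- 5
  lg1 <- build_logo(kt, n_top = 1)
  expect_identical(dim(lg1$ppm), c(4L, 3L))
  expect_true(all(lg1$ppm %in% c(0, 1)))
  expect_identical(rownames(lg1$ppm)[apply(lg1$ppm, 2, which.max)],
                   c("U", "A", "G"))
  ## offset scoring: AGUAGU aligns to UAGUAG at offset -1 with 5 matches
  kt6 <- data.frame(kmer = all_kmers(6), R = 1)
  attr(kt6, "k") <- 6L
  kt6$R[kt6$kmer == "UAGUAG"] <- 10
  kt6$R[kt6$kmer == "AGUAGU"] <- 9
  lg <- build_logo(kt6, n_top = 2)
  expect_identical(lg$kmers, c("UAGUAG", "AGUAGU"))
  expect_identical(lg$offsets, c(0, -1))
  expect_equal(unname(colSums(lg$ppm)), rep(1, ncol(lg$ppm)),
               tolerance = 1e-9)
  ## column sums are 1 for any input
  lg15 <- build_logo(kt6, n_top = 15)
  expect_equal(unname(colSums(lg15$ppm)), rep(1, ncol(lg15$ppm)),
               tolerance = 1e-9)
})

test_that("k larger than the read length errors", {
  pool <- make_random_pool(length = 6, n = 10, seed = 1)
  expect_error(count_kmers(pool, 7), "exceeds")
})
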