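library(GenomicRanges)

## printed toy genome: one 200-nt chromosome with TAGs at known spots
toy_bundle <- function() {
  base <- strrep("ACCA", 50) # no TAG anywhere
  g <- base
  substr(g, 61, 63) <- "TAG"  # forward TAG
  substr(g, 121, 123) <- "CTA" # reverse-strand TAG
  tx <- data.frame(
    transcript_id = c("t1", "t2"), chrom = "chr1",
    strand = c("+", "-"), tx_start = c(11, 101),
    tx_end = c(90, 180), cds_start = c(21, 121),
    cds_end = c(70, 160), stringsAsFactors = FALSE
  )
  exons <- data.frame(
    transcript_id = c("t1", "t1", "t2"),
    start = c(11, 51, 101), end = c(40, 90, 180)
  )
  genome_bundle(setNames(g, "chr1"), tx, exons,
                c(t1 = 10, t2 = 4.9))
}

test_that("peaks re-center on the nearest motif with correct strand", {
  b <- toy_bundle()
  peaks <- GRanges("chr1", IRanges(c(48, 110), c(54, 116)),
                   strand = c("+", "-"),
                   transcript_id = c("t1", "t2"),
                   region = c("CDS", "CDS"))
  out <- center_and_collapse(peaks, b)
  expect_identical(attr(out, "n_dropped"), 0L)
  expect_true(all(width(out) == 33))
  ## forward peak centered on the TAG at 61..63 (center 62)
  expect_identical(start(out)[1], 62L - 16L)
  ## minus-strand peak centered on the CTA at 121..123 (center 122)
  expect_identical(start(out)[2], 122L - 16L)
  ## central 3 nt spell TAG on the annotated strand
  for (i in 1:2) {
    s <- rbnskit:::strand_seq(
      b, "chr1", start(out)[i], end(out)[i],
      as.character(strand(out)[i])
    )
    expect_identical(substr(s, 16, 18), "TAG")
  }
})

test_that("peaks without a motif in the window are dropped and tallied", {
  b <- toy_bundle()
  peaks <- GRanges("chr1", IRanges(c(48, 190), c(54, 196)),
                   strand = c("+", "+"),
                   transcript_id = c("t1", "t1"),
                   region = c("CDS", "CDS"))
  out <- center_and_collapse(peaks, b)
  expect_length(out, 1L)
  expect_identical(attr(out, "n_dropped"), 1L)
  ## unknown strand is rejected
  bad <- GRanges("chr1", IRanges(48, 54), strand = "*",
                 transcript_id = "t1", region = "CDS")
  expect_error(center_and_collapse(bad, b), "strand")
})

test_that("interval union matches the sweep-line oracle", {
  b <- toy_bundle()
  starts <- c(10, 15, 40, 42, 44, 90)
  ends <- c(20, 30, 43, 50, 45, 95)
  peaks <- GRanges("chr1", IRanges(starts, ends), strand = "+",
                   transcript_id = "t1", region = "CDS")
  merged <- merge_peaks(peaks, b, recenter = FALSE)
  oracle <- oracle_merge(starts, ends)
  expect_identical(cbind(start(merged), end(merged)),
                   matrix(as.integer(oracle), ncol = 2,
                          dimnames = NULL))
  ## disjoint peaks unchanged; opposite strands never merge
  p2 <- GRanges("chr1", IRanges(c(10, 50), c(20, 60)),
                strand = c("+", "-"),
                transcript_id = c("t1", "t2"),
                region = c("CDS", "CDS"))
  expect_length(merge_peaks(p2, b, recenter = FALSE), 2L)
  p3 <- GRanges("chr1", IRanges(c(10, 15), c(20, 25)),
                strand = c("+", "-"),
                transcript_id = c("t1", "t2"),
                region = c("CDS", "CDS"))
  expect_length(merge_peaks(p3, b, recenter = FALSE), 2L)
})

test_that("expression filter is strict at the TPM boundary", {
  b <- toy_bundle() # t1 = 10 TPM, t2 = 4.9 TPM
  peaks <- GRanges("chr1", IRanges(c(20, 30, 110), c(26, 36, 116)),
                   strand = c("+", "+", "-"),
                   transcript_id = c("t1", "t99", "t2"),
                   region = c("CDS", "CDS", "CDS"))
  out <- filter_expressed(peaks, b, tpm_min = 5)
  expect_identical(S4Vectors::mcols(out)$transcript_id, "t1")
  expect_identical(attr(out, "n_missing_expression"), 1L)
  ## TPM exactly at the threshold is excluded, just above retained
  b$expression[["t2"]] <- 5
  expect_length(filter_expressed(peaks[c(1, 3)], b), 1L)
  b$expression[["t2"]] <- 5.1
  expect_length(filter_expressed(peaks[c(1, 3)], b), 2L)
})

test_that("overlap summary counts transcripts and distinct sites", {
  mk <- function(tx, starts) {
    GRanges("chr1", IRanges(starts, width = 33), strand = "+",
            transcript_id = tx, region = "CDS")
  }
  a <- mk(c("t1", "t2", "t3", "t4"), c(100, 200, 300, 400))
  bpk <- mk(c("t1", "t2", "t3", "t9"), c(110, 400, 600, 800))
  ov <- overlap_summary(a, bpk)
  expect_identical(ov$transcript$n_both, 3L)
  expect_equal(ov$transcript$frac_shared_A, 3 / 4)
  ## t1 sites overlap (100 vs 110); t2 and t3 sites are distinct
  expect_equal(ov$motif$frac_distinct_sites, 2 / 3)
  ## identity: full overlap, no distinct sites
  self <- overlap_summary(a, a)
  expect_equal(self$transcript$frac_shared_A, 1)
  expect_equal(self$motif$frac_distinct_sites, 0)
  ## disjoint transcript sets
  none <- overlap_summary(a, mk("t7", 100))
  expect_identical(none$transcript$n_both, 0L)
})

test_that("control regions match region type and splice-site distance", {
  b <- toy_bundle()
  ## UTR3 of t1 (+): 71..90; CDS peak of t1 at distance from splice
  ## sites 40/41 and 50/51
  peaks <- GRanges("chr1", IRanges(c(75, 30), width = 7),
                   strand = "+",
                   transcript_id = c("t1", "t1"),
                   region = c("UTR3", "CDS"))
  ctl <- make_control_regions(peaks, b, seed = 3)
  expect_length(ctl, 2L)
  expect_identical(S4Vectors::mcols(ctl)$region,
                   S4Vectors::mcols(peaks)$region)
  ## controls stay within the same region of the same transcript
  utr3_ctl <- ctl[S4Vectors::mcols(ctl)$region == "UTR3"]
  expect_true(start(utr3_ctl) >= 71 && end(utr3_ctl) <= 90)
  ## CDS control preserves the distance to the nearest splice site
  cds_peak_center <- 30 + 3
  cds_ctl <- ctl[S4Vectors::mcols(ctl)$region == "CDS"]
  ss <- rbnskit:::splice_sites(b, "t1")
  d_peak <- min(abs(cds_peak_center - ss))
  d_ctl <- min(abs((start(cds_ctl) + 3) - ss))
  expect_identical(d_ctl, d_peak)
  ## controls never overlap real peaks
  expect_length(findOverlaps(ctl, peaks), 0L)
  ## seeded determinism
  ctl2 <- make_control_regions(peaks, b, seed = 3)
  expect_identical(start(ctl), start(ctl2))
})

test_that("toy genome peaks satisfy the planted invariants end to end", {
  tg <- make_toy_genome(n_transcripts = 6, seed = 17)
  for (nm in c("A", "B")) {
    centered <- center_and_collapse(tg$peaks[[nm]], tg$bundle)
    expect_identical(attr(centered, "n_dropped"), 0L)
    expect_true(all(width(centered) == 33))
    for (i in seq_along(centered)) {
      s <- rbnskit:::strand_seq(
        tg$bundle, "chr1", start(centered)[i], end(centered)[i],
        as.character(strand(centered)[i])
      )
      expect_identical(substr(s, 16, 18), "TAG")
    }
  }
  ## identical seed reproduces the genome exactly
  tg2 <- make_toy_genome(n_transcripts = 6, seed = 17)
  expect_identical(tg$bundle$genome, tg2$bundle$genome)
  expect_identical(start(tg$peaks$A), start(tg2$peaks$A))
})

test_that("BED round trip preserves coordinates and names", {
  skip_if_not_installed("rtracklayer")
  peaks <- GRanges("chr1", IRanges(c(62, 150), width = 33),
                   strand = c("+", "-"),
                   transcript_id = c("t1", "t2"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(peaks, bed)
  back <- read_peaks_bed(bed)
  expect_identical(start(back), start(peaks))
  expect_identical(end(back), end(peaks))
  expect_identical(S4Vectors::mcols(back)$transcript_id,
                   c("t1", "t2"))
  ## on-disk BED is 0-based half-open
  raw <- read.delim(bed, header = FALSE)
  expect_identical(raw$V2, start(peaks) - 1L)
  expect_identical(raw$V3, end(peaks))
})
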