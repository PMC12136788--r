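## iCLIP peak processing: motif centering, merging, expression filtering,
## cross-protein overlap summaries and matched control regions.
##
## Coordinates are 0-based half-open internally (GRanges' 1-based closed
## convention is converted at the BED boundary by rtracklayer).

#' Bundle a toy or real genome with annotation and expression
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences (DNA alphabet, `TAG` motifs on the forward strand).
#' @param transcripts data frame with one row per transcript:
#'   `transcript_id`, `chrom`, `strand`, and 1-based closed genomic
#'   coordinates `tx_start`, `tx_end`, `cds_start`, `cds_end`.
#' @param exons data frame with `transcript_id`, `start`, `end` (1-based
#'   closed) giving exon structure; internal exon boundaries are the
#'   splice sites.
#' @param expression named numeric vector of transcript TPM.
#' @return list of class `genome_bundle`.
#' @export
genome_bundle <- function(genome, transcripts, exons, expression) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  stopifnot(!is.null(names(genome)),
            all(transcripts$chrom %in% names(genome)))
  bad <- transcripts$tx_end > nchar(genome[transcripts$chrom])
  if (any(bad)) {
    stop("transcripts beyond chromosome bounds: ",
         paste(transcripts$transcript_id[bad], collapse = ", "))
  }
  structure(
    list(genome = genome, transcripts = transcripts, exons = exons,
         expression = expression),
    class = "genome_bundle"
  )
}

## forward-strand genomic sequence of a window (1-based closed)
genomic_seq <- function(bundle, chrom, start, end) {
  substr(bundle$genome[[chrom]], start, end)
}

strand_seq <- function(bundle, chrom, start, end, strand) {
  s <- genomic_seq(bundle, chrom, start, end)
  if (strand == "-") {
    s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))
    )
  }
  s
}

#' Center peaks on a motif and collapse to fixed width
#'
#' Each peak is expanded to `expand_to` bases around its center, the
#' expanded window's strand-local sequence is searched for `motif`, peaks
#' without any occurrence are dropped (tallied), and the rest are
#' re-centered on the occurrence nearest the original peak center (ties:
#' 5'-most on the transcript strand) and collapsed to `final_width`.
#' After centering, the central `nchar(motif)` bases of a width-33 peak
#' spell the motif on the annotated strand.
#'
#' @param peaks `GRanges` with strand and a `transcript_id` metadata
#'   column.
#' @param bundle a [genome_bundle()].
#' @param expand_to expansion width (default 100).
#' @param final_width collapsed width (default 33).
#' @param motif DNA motif (default `"TAG"`).
#' @return `GRanges` of centered peaks; attribute `n_dropped` counts
#'   peaks without the motif. Windows extending past a chromosome end are
#'   clipped before the search.
#' @export
center_and_collapse <- function(peaks, bundle, expand_to = 100L,
                                final_width = 33L, motif = "TAG") {
  stopifnot(inherits(peaks, "GRanges"))
  if (any(GenomicRanges::strand(peaks) == "*")) {
    stop("strand must be known for every peak")
  }
  chrom_len <- nchar(bundle$genome)
  keep <- logical(length(peaks))
  new_start <- integer(length(peaks))
  mlen <- nchar(motif)
  half <- (final_width - 1L) %/% 2L
  for (i in seq_along(peaks)) {
    chrom <- as.character(GenomicRanges::seqnames(peaks)[i])
    strand <- as.character(GenomicRanges::strand(peaks)[i])
    center <- (GenomicRanges::start(peaks)[i] +
                 GenomicRanges::end(peaks)[i]) %/% 2L
    ws <- max(1L, center - expand_to %/% 2L)
    we <- min(chrom_len[[chrom]], ws + expand_to - 1L)
    seq_local <- strand_seq(bundle, chrom, ws, we, strand)
    occ <- locate_overlapping(seq_local, motif)[[1]]
    if (!length(occ)) next
    ## genomic coordinate of each occurrence's central base
    if (strand == "+") {
      motif_center <- ws + (occ - 1L) + (mlen - 1L) %/% 2L
    } else {
      motif_center <- we - (occ - 1L) - (mlen - 1L) %/% 2L
    }
    d <- abs(motif_center - center)
    ## ties: 5'-most on the transcript strand = smallest local coord
    pick <- occ[order(d, occ)][1]
    mc <- motif_center[order(d, occ)][1]
    keep[i] <- TRUE
    new_start[i] <- mc - half
  }
  out <- peaks[keep]
  if (length(out)) {
    GenomicRanges::ranges(out) <- IRanges::IRanges(
      start = new_start[keep], width = final_width
    )
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Merge overlapping peaks and re-center
#'
#' Overlapping same-strand intervals are unioned, annotated with the
#' `transcript_id` of their first constituent, then re-centered on the
#' motif via [center_and_collapse()] (expanded back out to `expand_to`
#' and collapsed again).
#'
#' @inheritParams center_and_collapse
#' @param recenter re-run motif centering after the union (default
#'   `TRUE`).
#' @return `GRanges` of merged peaks.
#' @export
merge_peaks <- function(peaks, bundle, expand_to = 100L,
                        final_width = 33L, motif = "TAG",
                        recenter = TRUE) {
  merged <- GenomicRanges::reduce(peaks, ignore.strand = FALSE)
  hits <- GenomicRanges::findOverlaps(merged, peaks, select = "first")
  S4Vectors::mcols(merged)$transcript_id <-
    S4Vectors::mcols(peaks)$transcript_id[hits]
  S4Vectors::mcols(merged)$region <-
    S4Vectors::mcols(peaks)$region[hits]
  if (recenter) {
    merged <- center_and_collapse(merged, bundle, expand_to = expand_to,
                                  final_width = final_width,
                                  motif = motif)
  }
  merged
}

#' Filter peaks to well-expressed transcripts
#'
#' Retains peaks whose transcript has expression strictly greater than
#' `tpm_min`; peaks on transcripts missing from the expression table are
#' excluded and tallied.
#'
#' @param peaks `GRanges` with a `transcript_id` column.
#' @param bundle a [genome_bundle()] with an `expression` table.
#' @param tpm_min TPM threshold (default 5; strictly greater-than).
#' @return filtered `GRanges`; attribute `n_missing_expression`.
#' @export
filter_expressed <- function(peaks, bundle, tpm_min = 5) {
  tx <- S4Vectors::mcols(peaks)$transcript_id
  tpm <- bundle$expression[tx]
  missing <- is.na(tpm)
  out <- peaks[!missing & tpm > tpm_min]
  attr(out, "n_missing_expression") <- sum(missing)
  out
}

#' Transcript- and motif-level overlap of two peak sets
#'
#' Transcript level: numbers of transcripts bound by each protein and by
#' both. Motif level: among shared transcripts, the fraction where the
#' two proteins' centered peaks occupy distinct (non-overlapping) sites
#' versus overlapping ones.
#'
#' @param peaksA,peaksB centered/collapsed `GRanges` with
#'   `transcript_id`.
#' @return list with `transcript` (`n_A`, `n_B`, `n_both`,
#'   `frac_shared_A`, `frac_shared_B`) and `motif`
#'   (`n_shared_transcripts`, `frac_overlapping_sites`,
#'   `frac_distinct_sites`).
#' @export
overlap_summary <- function(peaksA, peaksB) {
  txA <- unique(S4Vectors::mcols(peaksA)$transcript_id)
  txB <- unique(S4Vectors::mcols(peaksB)$transcript_id)
  both <- intersect(txA, txB)
  overlapping <- vapply(both, function(tx) {
    a <- peaksA[S4Vectors::mcols(peaksA)$transcript_id == tx]
    b <- peaksB[S4Vectors::mcols(peaksB)$transcript_id == tx]
    length(GenomicRanges::findOverlaps(a, b)) > 0
  }, logical(1))
  list(
    transcript = list(
      n_A = length(txA), n_B = length(txB), n_both = length(both),
      frac_shared_A = length(both) / max(1L, length(txA)),
      frac_shared_B = length(both) / max(1L, length(txB))
    ),
    motif = list(
      n_shared_transcripts = length(both),
      frac_overlapping_sites =
        if (length(both)) mean(overlapping) else NA_real_,
      frac_distinct_sites =
        if (length(both)) mean(!overlapping) else NA_real_
    )
  )
}

## region interval (1-based closed, genomic) of a transcript
region_interval <- function(txrow, region) {
  if (region == "CDS") {
    c(txrow$cds_start, txrow$cds_end)
  } else if (region == "UTR3") {
    if (txrow$strand == "+") {
      c(txrow$cds_end + 1L, txrow$tx_end)
    } else {
      c(txrow$tx_start, txrow$cds_start - 1L)
    }
  } else if (region == "UTR5") {
    if (txrow$strand == "+") {
      c(txrow$tx_start, txrow$cds_start - 1L)
    } else {
      c(txrow$cds_end + 1L, txrow$tx_end)
    }
  } else {
    c(txrow$tx_start, txrow$tx_end)
  }
}

## internal splice-site coordinates of a transcript (boundaries between
## adjacent exons)
splice_sites <- function(bundle, transcript_id) {
  ex <- bundle$exons[bundle$exons$transcript_id == transcript_id, ,
                     drop = FALSE]
  if (nrow(ex) < 2L) return(integer(0))
  ex <- ex[order(ex$start), , drop = FALSE]
  sort(c(ex$end[-nrow(ex)], ex$start[-1]))
}

#' Matched control regions for a peak set
#'
#' One control interval per peak, matched by region type: for UTR peaks
#' the control is sampled uniformly within the same region of the same
#' transcript; for CDS peaks the control is chosen among CDS positions
#' preserving the peak's distance to the nearest splice site. Controls
#' never overlap real peaks; sampling is seeded and reproducible.
#'
#' @param peaks `GRanges` with `transcript_id` and `region` metadata.
#' @param bundle a [genome_bundle()].
#' @param seed RNG seed.
#' @param max_tries rejection-sampling attempts per peak (default 100).
#' @return `GRanges` of controls (metadata column `peak_index` links each
#'   control to its source peak); attribute `unmatched` lists indices of
#'   peaks for which no eligible control was found.
#' @export
make_control_regions <- function(peaks, bundle, seed, max_tries = 100L) {
  stopifnot(inherits(peaks, "GRanges"))
  tx_tab <- bundle$transcripts
  with_seed(seed, {
    ctl_start <- integer(0)
    ctl_chrom <- character(0)
    ctl_strand <- character(0)
    ctl_tx <- character(0)
    ctl_region <- character(0)
    ctl_src <- integer(0)
    unmatched <- integer(0)
    for (i in seq_along(peaks)) {
      tx_id <- S4Vectors::mcols(peaks)$transcript_id[i]
      region <- S4Vectors::mcols(peaks)$region[i]
      txrow <- tx_tab[tx_tab$transcript_id == tx_id, , drop = FALSE]
      if (nrow(txrow) != 1L) {
        unmatched <- c(unmatched, i)
        next
      }
      width <- GenomicRanges::width(peaks)[i]
      pk_start <- GenomicRanges::start(peaks)[i]
      pk_center <- pk_start + (width - 1L) %/% 2L
      iv <- region_interval(as.list(txrow), region)
      lo <- iv[1]
      hi <- iv[2] - width + 1L
      if (hi < lo) {
        unmatched <- c(unmatched, i)
        next
      }
      if (region == "CDS") {
        ss <- splice_sites(bundle, tx_id)
        ss <- ss[ss >= iv[1] & ss <= iv[2]]
        if (length(ss)) {
          d <- min(abs(pk_center - ss))
          cand_centers <- unique(as.vector(outer(ss, c(-d, d), `+`)))
          cand <- cand_centers - (width - 1L) %/% 2L
          cand <- cand[cand >= lo & cand <= hi]
        } else {
          cand <- lo:hi
        }
      } else {
        cand <- lo:hi
      }
      ## reject candidates overlapping any real peak
      found <- NA_integer_
      cand <- if (length(cand)) sample(cand, min(length(cand),
                                                 max_tries)) else cand
      for (s in cand) {
        trial <- GenomicRanges::GRanges(
          txrow$chrom, IRanges::IRanges(s, width = width),
          strand = txrow$strand
        )
        if (length(GenomicRanges::findOverlaps(trial, peaks)) == 0L) {
          found <- s
          break
        }
      }
      if (is.na(found)) {
        unmatched <- c(unmatched, i)
        next
      }
      ctl_start <- c(ctl_start, found)
      ctl_chrom <- c(ctl_chrom, txrow$chrom)
      ctl_strand <- c(ctl_strand, txrow$strand)
      ctl_tx <- c(ctl_tx, tx_id)
      ctl_region <- c(ctl_region, region)
      ctl_src <- c(ctl_src, i)
    }
    out <- GenomicRanges::GRanges(
      ctl_chrom,
      IRanges::IRanges(ctl_start,
                       width = GenomicRanges::width(peaks)[ctl_src]),
      strand = ctl_strand,
      transcript_id = ctl_tx, region = ctl_region, peak_index = ctl_src
    )
    attr(out, "unmatched") <- unmatched
    out
  })
}

#' Read a BED6 peak file into a GRanges
#'
#' BED is 0-based half-open on disk; rtracklayer converts to the 1-based
#' closed GRanges convention. The BED name column is taken as
#' `transcript_id`.
#'
#' @param path BED file.
#' @return `GRanges` with `transcript_id` and `score`.
#' @export
read_peaks_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_peaks_bed requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::mcols(gr)$transcript_id <- S4Vectors::mcols(gr)$name
  gr
}

#' Write peaks to BED6
#' @param peaks `GRanges` with `transcript_id` (written as the BED name).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("write_peaks_bed requires the rtracklayer package")
  }
  gr <- peaks
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(peaks)$transcript_id,
    score = if (!is.null(S4Vectors::mcols(peaks)$score)) {
      S4Vectors::mcols(peaks)$score
    } else 0
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
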