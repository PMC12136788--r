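## posRBNS analytics: positional enrichment of kmers around a locked
## central motif with the extra-motif read exclusion filter, bipartite
## spacing tables, and locked-prefix kmer tables.

## Offset convention (N_k spacer notation):
##   offset -1 = nucleotide immediately 5' of the locked motif's first
##   base; offset +1 = immediately 3' of its last base. Query kmers are
##   located by their 5' end for downstream offsets and by their 3' end
##   for upstream offsets, so spacer_len = |offset| - 1 on both sides.

## 0-based query start index for a (offset, query length) combination
offset_query_start <- function(offset, locked_start, locked_len, qlen) {
  if (offset >= 1L) {
    locked_start + locked_len + (offset - 1L)
  } else {
    locked_start + offset - (qlen - 1L) # 3' end at locked_start + offset
  }
}

valid_offsets <- function(read_len, locked_start, locked_len, qlen) {
  up <- if (locked_start >= 1L) seq(-locked_start, -1L) else integer(0)
  down_n <- max(0L, read_len - locked_start - locked_len - qlen + 1L)
  offs <- c(up, seq_len(down_n))
  keep <- vapply(offs, function(o) {
    s <- offset_query_start(o, locked_start, locked_len, qlen)
    s >= 0L && s + qlen <= read_len
  }, logical(1))
  sort(offs[keep])
}

## Per-read locked-motif occurrence bookkeeping shared by the positional
## routines. Returns list(pos = long df of (idx, occ_start0), central_ok).
motif_occurrences <- function(pool, locked_motif, locked_start) {
  occ <- locate_overlapping(pool$seq, locked_motif)
  idx <- rep.int(seq_along(occ), lengths(occ))
  pos0 <- unlist(occ, use.names = FALSE) - 1L # 0-based
  central_ok <- substr(pool$seq, locked_start + 1L,
                       locked_start + nchar(locked_motif)) == locked_motif
  list(idx = idx, pos0 = if (is.null(pos0)) integer(0) else pos0,
       central_ok = central_ok)
}

positional_side <- function(pool, occ, locked_motif, locked_start,
                            query_kmer, offsets, exclusion = TRUE) {
  lm_len <- nchar(locked_motif)
  qlen <- nchar(query_kmer)
  counts <- pool$count
  res <- lapply(offsets, function(o) {
    qs <- offset_query_start(o, locked_start, lm_len, qlen)
    if (exclusion) {
      ## an occurrence is allowed if central, or fully inside the counted
      ## query window (i.e. created by the counted query kmer itself)
      bad <- occ$pos0 != locked_start &
        !(occ$pos0 >= qs & occ$pos0 + lm_len <= qs + qlen)
      excluded <- unique(occ$idx[bad])
      keep <- rep(TRUE, length(pool$seq))
      if (length(excluded)) keep[excluded] <- FALSE
    } else {
      keep <- rep(TRUE, length(pool$seq))
    }
    hit <- keep &
      substr(pool$seq, qs + 1L, qs + qlen) == query_kmer
    c(n_used = sum(counts[keep]), n_hit = sum(counts[hit]))
  })
  do.call(rbind, res)
}

#' Positional enrichment around a locked central motif
#'
#' For each offset, counts reads (in both pools) whose `query_kmer`
#' occurs at that offset, excluding from numerator and denominator any
#' read containing an occurrence of the locked motif other than (a) the
#' central one and (b) an occurrence created by the counted query kmer
#' itself (i.e. lying fully within the counted query window). Both pools
#' are filtered symmetrically; `log2R = log2(freq_bound / freq_input)`
#' with the configured pseudocount (default 0, undefined values flagged).
#'
#' @param input_pool,bound_pool [read_pool()]s whose reads carry
#'   `locked_motif` at `locked_start`. Reads violating this are dropped
#'   with a tally; if more than 10\% of either pool violates it, an error
#'   is raised (pool/config mismatch).
#' @param locked_motif locked motif string (default `"UAG"`).
#' @param locked_start 0-based index of the motif's first base (default 8,
#'   i.e. an 8/3/9 split of a 20-nt read).
#' @param query_kmer kmer whose positional enrichment is profiled.
#' @param pseudocount nonnegative frequency pseudocount (default 0).
#' @param exclusion apply the extra-motif read exclusion filter
#'   (default `TRUE`).
#' @return data frame of class `positional_profile` with columns
#'   `offset`, `spacer_len`, `freq_input`, `freq_bound`, `log2R`,
#'   `defined`, `n_reads_used_input`, `n_reads_used_bound`,
#'   `n_hit_input`, `n_hit_bound`; metadata in attributes (including
#'   `denominator = "filtered"` recording the symmetric-filter policy).
#' @export
positional_enrichment <- function(input_pool, bound_pool,
                                  locked_motif = "UAG", locked_start = 8L,
                                  query_kmer, pseudocount = 0,
                                  exclusion = TRUE) {
  stopifnot(nchar(query_kmer) >= 1L, pseudocount >= 0)
  L <- input_pool$randomized_length
  stopifnot(bound_pool$randomized_length == L)
  pools <- list(input = input_pool, bound = bound_pool)
  occs <- lapply(pools, motif_occurrences, locked_motif = locked_motif,
                 locked_start = locked_start)
  for (nm in names(pools)) {
    frac_bad <- sum(pools[[nm]]$count[!occs[[nm]]$central_ok]) /
      pool_size(pools[[nm]])
    if (frac_bad > 0.10) {
      stop("locked motif absent at locked_start in ",
           round(100 * frac_bad, 1), "% of ", nm,
           " reads: pool/config mismatch")
    }
    if (frac_bad > 0) {
      keep <- occs[[nm]]$central_ok
      pools[[nm]]$seq <- pools[[nm]]$seq[keep]
      pools[[nm]]$count <- pools[[nm]]$count[keep]
      occs[[nm]] <- motif_occurrences(pools[[nm]], locked_motif,
                                      locked_start)
    }
  }
  offsets <- valid_offsets(L, locked_start, nchar(locked_motif),
                           nchar(query_kmer))
  ci <- positional_side(pools$input, occs$input, locked_motif,
                        locked_start, query_kmer, offsets, exclusion)
  cb <- positional_side(pools$bound, occs$bound, locked_motif,
                        locked_start, query_kmer, offsets, exclusion)
  fi <- ci[, "n_hit"] / ci[, "n_used"]
  fb <- cb[, "n_hit"] / cb[, "n_used"]
  log2R <- log2((fb + pseudocount) / (fi + pseudocount))
  out <- data.frame(
    offset = offsets,
    spacer_len = abs(offsets) - 1L,
    freq_input = fi,
    freq_bound = fb,
    log2R = log2R,
    defined = is.finite(log2R),
    n_reads_used_input = ci[, "n_used"],
    n_reads_used_bound = cb[, "n_used"],
    n_hit_input = ci[, "n_hit"],
    n_hit_bound = cb[, "n_hit"],
    row.names = NULL
  )
  attr(out, "locked_motif") <- locked_motif
  attr(out, "locked_start") <- as.integer(locked_start)
  attr(out, "query_kmer") <- query_kmer
  attr(out, "pseudocount") <- pseudocount
  attr(out, "exclusion") <- exclusion
  attr(out, "denominator") <- "filtered"
  class(out) <- c("positional_profile", "data.frame")
  out
}

#' Count bipartite pattern occurrences in one sequence
#'
#' Overlapping occurrences of `left . N^spacer . right` are counted.
#' @param x character vector of sequences.
#' @param left_motif,right_motif motif strings.
#' @param spacer nonnegative spacer length.
#' @return integer vector of per-sequence occurrence counts.
#' @export
count_bipartite <- function(x, left_motif, right_motif, spacer) {
  stopifnot(spacer >= 0)
  pat <- paste0(left_motif, strrep(".", spacer), right_motif)
  count_overlapping(x, pat)
}

#' Bipartite motif spacing enrichment
#'
#' For each spacer length `s` in `0..max_spacer`, reads containing
#' `left_motif N^s right_motif` are counted in both pools (read-level,
#' weighted by read count), frequencies are normalized for library size,
#' and the enrichment is `log2` of the bound/input frequency ratio.
#'
#' @param input_pool,bound_pool [read_pool()]s.
#' @param left_motif,right_motif motifs of length >= 3.
#' @param max_spacer maximum spacer length (>= 0).
#' @param pseudocount nonnegative frequency pseudocount (default 0).
#' @return data frame of class `bipartite_table` with columns
#'   `left_motif`, `spacer_len`, `right_motif`, `freq_input`,
#'   `freq_bound`, `log2_enrichment`, `defined`.
#' @export
bipartite_enrichment <- function(input_pool, bound_pool, left_motif,
                                 right_motif, max_spacer,
                                 pseudocount = 0) {
  stopifnot(nchar(left_motif) >= 3L, nchar(right_motif) >= 3L,
            max_spacer >= 0L, pseudocount >= 0)
  spacers <- 0:max_spacer
  one_pool <- function(pool) {
    total <- pool_size(pool)
    vapply(spacers, function(s) {
      pat <- paste0(left_motif, strrep(".", s), right_motif)
      hit <- grepl(pat, pool$seq, perl = TRUE)
      sum(pool$count[hit]) / total
    }, numeric(1))
  }
  fi <- one_pool(input_pool)
  fb <- one_pool(bound_pool)
  log2e <- log2((fb + pseudocount) / (fi + pseudocount))
  out <- data.frame(
    left_motif = left_motif,
    spacer_len = spacers,
    right_motif = right_motif,
    freq_input = fi,
    freq_bound = fb,
    log2_enrichment = log2e,
    defined = is.finite(log2e),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bipartite_table", "data.frame")
  out
}

#' Enrichment table of kmers anchored at the locked motif
#'
#' Enumerates every kmer of the form `prefix N^(length - |prefix|)`
#' anchored at the locked position (e.g. the 4^7 = 16384 10mers starting
#' with a locked UAG), computes `R` from anchored-window counts in both
#' pools, and assigns ranks by descending R with lexicographic
#' tie-breaking.
#'
#' @param input_pool,bound_pool [read_pool()]s anchored so that `prefix`
#'   occurrences start at `locked_start`; reads whose anchored window does
#'   not begin with `prefix` are dropped with a tally.
#' @param prefix locked prefix (default `"UAG"`).
#' @param length total kmer length (default 10).
#' @param locked_start 0-based anchor index (default 8).
#' @param pseudocount nonnegative frequency pseudocount (default 0).
#' @return data frame of class `locked_kmer_table` with columns `kmer`,
#'   `count_input`, `count_bound`, `freq_input`, `freq_bound`, `R`,
#'   `log2R`, `defined`, `rank`; attributes `prefix`, `length`,
#'   `locked_start`, `dropped_input`, `dropped_bound`.
#' @export
locked_prefix_table <- function(input_pool, bound_pool, prefix = "UAG",
                                length = 10L, locked_start = 8L,
                                pseudocount = 0) {
  L <- input_pool$randomized_length
  stopifnot(bound_pool$randomized_length == L)
  if (locked_start + length > L) {
    stop("length exceeds read span downstream of the locked position")
  }
  np <- nchar(prefix)
  stopifnot(length > np)
  suffixes <- all_kmers(length - np)
  universe <- paste0(prefix, suffixes)
  one_pool <- function(pool) {
    win <- substr(pool$seq, locked_start + 1L, locked_start + length)
    anchored <- startsWith(win, prefix)
    counts <- setNames(numeric(base::length(universe)), universe)
    if (any(anchored)) {
      agg <- rowsum(as.numeric(pool$count[anchored]), win[anchored])
      counts[rownames(agg)] <- agg[, 1]
    }
    list(counts = counts, dropped = sum(pool$count[!anchored]))
  }
  pi <- one_pool(input_pool)
  pb <- one_pool(bound_pool)
  fi <- pi$counts / sum(pi$counts)
  fb <- pb$counts / sum(pb$counts)
  R <- (fb + pseudocount) / (fi + pseudocount)
  out <- data.frame(
    kmer = universe,
    count_input = as.numeric(pi$counts),
    count_bound = as.numeric(pb$counts),
    freq_input = as.numeric(fi),
    freq_bound = as.numeric(fb),
    R = as.numeric(R),
    log2R = log2(as.numeric(R)),
    stringsAsFactors = FALSE
  )
  out$defined <- is.finite(out$log2R)
  out$rank <- rank_kmers(out)
  attr(out, "prefix") <- prefix
  attr(out, "length") <- as.integer(length)
  attr(out, "locked_start") <- as.integer(locked_start)
  attr(out, "dropped_input") <- pi$dropped
  attr(out, "dropped_bound") <- pb$dropped
  class(out) <- c("locked_kmer_table", "data.frame")
  out
}
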