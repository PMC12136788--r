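## Classic RBNS analytics: kmer R values, replicate merging, top-k
## overlap, single-mutant R-drop profiles and top-kmer logos.

#' Count overlapping kmer occurrences in a pool
#'
#' Every overlapping occurrence is counted, weighted by the read count.
#'
#' @param pool a [read_pool()].
#' @param k kmer length, `k <= randomized_length`.
#' @return named numeric vector over all `4^k` kmers (lexicographic).
#' @export
count_kmers <- function(pool, k) {
  stopifnot(inherits(pool, "read_pool"))
  L <- pool$randomized_length
  if (k > L) stop("k (", k, ") exceeds read length (", L, ")")
  kmers <- all_kmers(k)
  counts <- setNames(numeric(length(kmers)), kmers)
  if (length(pool$seq) == 0L) return(counts)
  w <- as.numeric(pool$count)
  for (i in seq_len(L - k + 1L)) {
    sub <- substr(pool$seq, i, i + k - 1L)
    agg <- rowsum(w, sub)
    counts[rownames(agg)] <- counts[rownames(agg)] + agg[, 1]
  }
  counts
}

#' Compute a kmer enrichment table (R values)
#'
#' The enrichment of a kmer is `R = (freq_bound + pc) / (freq_input + pc)`
#' where frequencies are overlapping-occurrence frequencies normalized
#' within each pool and `pc` is a pseudocount (default 0). With `pc = 0`,
#' kmers absent from the bound pool get `R = 0` (`log2R = -Inf`) and are
#' flagged `defined = FALSE`; kmers absent from both pools get `R = NaN`.
#'
#' @param input_pool,bound_pool [read_pool()]s of the same read length.
#' @param k kmer length.
#' @param pseudocount nonnegative frequency pseudocount.
#' @return data frame of class `kmer_table` with one row per kmer
#'   (`kmer`, `count_input`, `count_bound`, `freq_input`, `freq_bound`,
#'   `R`, `log2R`, `defined`) and attributes `k`, `pseudocount`,
#'   `protein_label`, `concentration_nM`, `replicates_merged`,
#'   `total_input`, `total_bound`.
#' @export
compute_kmer_table <- function(input_pool, bound_pool, k,
                               pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  if (pool_size(input_pool) == 0L || pool_size(bound_pool) == 0L) {
    stop("both pools must be non-empty")
  }
  ci <- count_kmers(input_pool, k)
  cb <- count_kmers(bound_pool, k)
  fi <- ci / sum(ci)
  fb <- cb / sum(cb)
  R <- (fb + pseudocount) / (fi + pseudocount)
  tab <- data.frame(
    kmer = names(ci),
    count_input = as.numeric(ci),
    count_bound = as.numeric(cb),
    freq_input = as.numeric(fi),
    freq_bound = as.numeric(fb),
    R = as.numeric(R),
    log2R = log2(as.numeric(R)),
    stringsAsFactors = FALSE
  )
  tab$defined <- is.finite(tab$log2R)
  attr(tab, "k") <- as.integer(k)
  attr(tab, "pseudocount") <- pseudocount
  attr(tab, "protein_label") <- bound_pool$protein_label
  attr(tab, "concentration_nM") <- bound_pool$concentration_nM
  attr(tab, "replicates_merged") <- bound_pool$replicate_id
  attr(tab, "total_input") <- sum(ci)
  attr(tab, "total_bound") <- sum(cb)
  class(tab) <- c("kmer_table", "data.frame")
  tab
}

#' Merge replicate kmer tables
#'
#' `R` is the arithmetic mean of the replicate R values; frequencies are
#' recomputed as count-weighted means (equivalently, from summed counts).
#' Merge provenance is recorded in the `replicates_merged` attribute.
#'
#' @param tables list of `kmer_table`s with identical `k` and pseudocount.
#' @return merged `kmer_table`.
#' @export
merge_replicates <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  ks <- vapply(tables, attr, integer(1), which = "k")
  if (length(unique(ks)) != 1L) stop("mismatched k across replicates")
  if (length(tables) == 1L) return(tables[[1]])
  base <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(t$kmer, base$kmer)) stop("mismatched kmer universe")
  }
  ci <- Reduce(`+`, lapply(tables, `[[`, "count_input"))
  cb <- Reduce(`+`, lapply(tables, `[[`, "count_bound"))
  Rmat <- vapply(tables, `[[`, numeric(nrow(base)), "R")
  out <- base
  out$count_input <- ci
  out$count_bound <- cb
  out$freq_input <- ci / sum(ci)
  out$freq_bound <- cb / sum(cb)
  out$R <- rowMeans(Rmat)
  out$log2R <- log2(out$R)
  out$defined <- is.finite(out$log2R)
  attr(out, "total_input") <- sum(ci)
  attr(out, "total_bound") <- sum(cb)
  attr(out, "replicates_merged") <-
    unlist(lapply(tables, attr, "replicates_merged"))
  out
}

## deterministic ranking used everywhere: descending R, ties lexicographic
rank_kmers <- function(table) {
  ord <- order(-table$R, table$kmer)
  out <- integer(nrow(table))
  out[ord] <- seq_len(nrow(table))
  out
}

top_kmers <- function(table, n_top) {
  table$kmer[order(-table$R, table$kmer)][seq_len(n_top)]
}

#' Top-kmer overlap across conditions
#'
#' For each pair of tables, the number of shared kmers among the top
#' `n_top` by R (ties broken by descending R then lexicographic kmer
#' order), plus the size of the intersection across all tables.
#'
#' @param tables named list of `kmer_table`s over one kmer universe.
#' @param n_top number of top kmers to compare (`<= 4^k`).
#' @return list with `top` (list of top-kmer vectors), `pairwise`
#'   (symmetric count matrix) and `all_shared` (intersection size).
#' @export
top_k_overlap <- function(tables, n_top) {
  stopifnot(length(tables) >= 1L)
  if (n_top > nrow(tables[[1]])) stop("n_top exceeds table size")
  if (is.null(names(tables))) {
    names(tables) <- paste0("table", seq_along(tables))
  }
  tops <- lapply(tables, top_kmers, n_top = n_top)
  m <- length(tops)
  pairwise <- matrix(NA_integer_, m, m,
                     dimnames = list(names(tops), names(tops)))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      pairwise[i, j] <- length(intersect(tops[[i]], tops[[j]]))
    }
  }
  list(
    top = tops,
    pairwise = pairwise,
    all_shared = length(Reduce(intersect, tops))
  )
}

#' Single-mutant enrichment profile of the top kmer
#'
#' Fills a position-by-base matrix with the R value of every single-base
#' substitution of the top kmer (the argmax-R kmer; ties broken
#' lexicographically), and summarizes positional importance as the R drop:
#' the change in enrichment from the top kmer upon the least damaging
#' single-nucleotide mutation at each position,
#' `r_drop[p] = R(top) - max_base R(mutant at p)`.
#'
#' @param table a complete `kmer_table` (all `4^k` rows).
#' @return list of class `single_mutant_profile` with `top_kmer`,
#'   `top_R`, `matrix` (k x 4, bases ACGU; the wild-type base cell holds
#'   `R(top)`) and `r_drop` (length-k vector).
#' @export
single_mutant_profile <- function(table) {
  k <- attr(table, "k")
  if (nrow(table) != 4^k) stop("table must contain all 4^k kmers")
  Rmap <- setNames(table$R, table$kmer)
  top <- top_kmers(table, 1L)
  chars <- strsplit(top, "", fixed = TRUE)[[1]]
  mat <- matrix(NA_real_, nrow = k, ncol = 4,
                dimnames = list(paste0("pos", seq_len(k)), RNA_BASES))
  for (p in seq_len(k)) {
    for (b in RNA_BASES) {
      mut <- chars
      mut[p] <- b
      mat[p, b] <- Rmap[[paste(mut, collapse = "")]]
    }
  }
  r_drop <- vapply(seq_len(k), function(p) {
    alt <- setdiff(RNA_BASES, chars[p])
    Rmap[[top]] - max(mat[p, alt])
  }, numeric(1))
  structure(
    list(top_kmer = top, top_R = unname(Rmap[[top]]), matrix = mat,
         r_drop = r_drop),
    class = "single_mutant_profile"
  )
}

## Best alignment offset of `query` against `ref`.
## A placement puts query's first base at ref coordinate `s` (0-based,
## s in -(k-1)..(k-1)); the reported offset is -s so that a query matching
## ref shifted one base rightwards scores offset -1. Ties: highest
## identity, then smallest |offset|, then the negative offset.
align_offset <- function(ref, query) {
  k1 <- nchar(ref)
  k2 <- nchar(query)
  rc <- strsplit(ref, "", fixed = TRUE)[[1]]
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  best <- NULL
  for (s in seq(-(k2 - 1L), k1 - 1L)) {
    idx_r <- seq_len(k1)
    idx_q <- idx_r - s
    ok <- idx_q >= 1L & idx_q <= k2
    score <- sum(rc[idx_r[ok]] == qc[idx_q[ok]])
    off <- -s
    cand <- c(score = score, offset = off)
    if (is.null(best) ||
        score > best["score"] ||
        (score == best["score"] && abs(off) < abs(best["offset"])) ||
        (score == best["score"] && abs(off) == abs(best["offset"]) &&
         off < best["offset"])) {
      best <- cand
    }
  }
  best
}

#' Build a motif logo from the top kmers
#'
#' Aligns each of the top `n_top` kmers (by R, ties lexicographic) to the
#' top kmer at the integer offset maximizing positionwise identity (ties:
#' smallest absolute offset, then the negative one), then computes
#' per-column base probabilities with equal weight per kmer over the kmers
#' covering each column.
#'
#' @param table a `kmer_table`.
#' @param n_top number of top kmers to include (default 15).
#' @return list of class `motif_logo` with `ppm` (4 x n_columns base
#'   probability matrix, columns sum to 1), `kmers` and `offsets`
#'   (alignment offset per kmer; 0 for the top kmer).
#' @export
build_logo <- function(table, n_top = 15L) {
  stopifnot(n_top >= 1L)
  kmers <- top_kmers(table, min(n_top, nrow(table)))
  ref <- kmers[1]
  offs <- vapply(kmers, function(km) align_offset(ref, km)["offset"],
                 numeric(1))
  ## query base i (1-based) sits at ref coordinate i - 1 - offset (0-based)
  starts <- -offs
  k_len <- nchar(kmers)
  span <- range(c(starts, starts + k_len - 1L))
  ncols <- span[2] - span[1] + 1L
  counts <- matrix(0, nrow = 4, ncol = ncols,
                   dimnames = list(RNA_BASES, NULL))
  for (i in seq_along(kmers)) {
    chars <- strsplit(kmers[i], "", fixed = TRUE)[[1]]
    cols <- starts[i] + seq_along(chars) - 1L - span[1] + 1L
    for (j in seq_along(chars)) {
      counts[chars[j], cols[j]] <- counts[chars[j], cols[j]] + 1
    }
  }
  covered <- colSums(counts) > 0
  counts <- counts[, covered, drop = FALSE]
  ppm <- sweep(counts, 2, colSums(counts), "/")
  colnames(ppm) <- seq(span[1], span[2])[covered]
  structure(
    list(ppm = ppm, kmers = kmers, offsets = unname(offs)),
    class = "motif_logo"
  )
}

#' Write a kmer table to TSV
#' @param table a `kmer_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  out <- as.data.frame(table)
  out$rank <- rank_kmers(table)
  write.table(out[order(out$rank), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
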