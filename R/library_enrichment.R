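## nsRBNS: match reads to a designed oligo library, per-oligo enrichments
## with count filtering, and the group-level comparisons (KS + BH,
## wild-type vs motif-mutant deltas, motif-count stratification).

## Hamming distances from one read to a character matrix of oligo windows
hamming_to_windows <- function(read, win_mat) {
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  rowSums(win_mat != matrix(rc, nrow = nrow(win_mat),
                            ncol = length(rc), byrow = TRUE))
}

#' Match reads to a designed oligo library
#'
#' A read is assigned to an oligo if it matches that oligo's read window
#' (the `window_length` bases from `window_offset`) with at most
#' `max_mismatch` substitutions and no other oligo matches at the same
#' best distance. Reads matching two or more oligos at the best stratum
#' are discarded as multimappers; reads beyond `max_mismatch` everywhere
#' are unassigned. Both are tallied.
#'
#' @param reads a [read_pool()] trimmed to the library's read window
#'   length.
#' @param library an [oligo_library()].
#' @param max_mismatch maximum substitutions (default 1; no indels).
#' @param window_offset 0-based start of the read window within each
#'   oligo (default 0, i.e. the first `L` bases).
#' @return list with `counts` (named per-oligo read counts),
#'   `n_multimapped` and `n_unassigned`.
#' @export
match_reads <- function(reads, library, max_mismatch = 1L,
                        window_offset = 0L) {
  stopifnot(inherits(reads, "read_pool"),
            inherits(library, "oligo_library"))
  if (nrow(library) == 0L) stop("empty oligo library")
  L <- reads$randomized_length
  windows <- substr(library$sequence, window_offset + 1L,
                    window_offset + L)
  if (any(nchar(windows) != L)) {
    stop("library oligos shorter than the read window")
  }
  counts <- setNames(numeric(nrow(library)), library$oligo_id)
  n_multi <- 0
  n_unassigned <- 0
  ## exact stratum first via hash lookup; an exact hit is ambiguous only
  ## when two oligos share an identical window
  dup_win <- windows %in% windows[duplicated(windows)]
  exact <- match(reads$seq, windows)
  ambiguous_exact <- !is.na(exact) & dup_win[exact]
  unresolved <- which(is.na(exact) | ambiguous_exact)
  resolved <- which(!is.na(exact) & !ambiguous_exact)
  if (length(resolved)) {
    agg <- rowsum(as.numeric(reads$count[resolved]), exact[resolved])
    counts[as.integer(rownames(agg))] <-
      counts[as.integer(rownames(agg))] + agg[, 1]
  }
  if (length(unresolved)) {
    win_mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
    for (i in unresolved) {
      d <- hamming_to_windows(reads$seq[i], win_mat)
      dmin <- min(d)
      if (dmin > max_mismatch) {
        n_unassigned <- n_unassigned + reads$count[i]
      } else if (sum(d == dmin) > 1L) {
        n_multi <- n_multi + reads$count[i]
      } else {
        j <- which.min(d)
        counts[j] <- counts[j] + reads$count[i]
      }
    }
  }
  list(counts = counts, n_multimapped = n_multi,
       n_unassigned = n_unassigned)
}

#' Per-oligo enrichment with count filtering
#'
#' Oligos with fewer than `min_count` reads in either pool are excluded
#' from the frequency denominators and flagged; for retained oligos the
#' enrichment is the frequency of the oligo in the bound pool over its
#' frequency in the input pool.
#'
#' @param counts_input,counts_bound named per-oligo count vectors over
#'   the same library (as from [match_reads()]`$counts`).
#' @param min_count minimum count required in both pools (default 25).
#' @return data frame of class `oligo_enrichment` with `oligo_id`,
#'   `count_input`, `count_bound`, `passed_filter`, `freq_input`,
#'   `freq_bound`, `R`, `log2R` (`NA` for filtered oligos); attribute
#'   `min_count_policy = "both pools"`.
#' @export
oligo_enrichment <- function(counts_input, counts_bound,
                             min_count = 25L) {
  stopifnot(identical(names(counts_input), names(counts_bound)))
  passed <- counts_input >= min_count & counts_bound >= min_count
  if (!any(passed)) stop("no oligo passes the count filter")
  fi <- fb <- rep(NA_real_, length(counts_input))
  fi[passed] <- counts_input[passed] / sum(counts_input[passed])
  fb[passed] <- counts_bound[passed] / sum(counts_bound[passed])
  out <- data.frame(
    oligo_id = names(counts_input),
    count_input = as.numeric(counts_input),
    count_bound = as.numeric(counts_bound),
    passed_filter = passed,
    freq_input = fi,
    freq_bound = fb,
    R = fb / fi,
    log2R = log2(fb / fi),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "min_count") <- as.integer(min_count)
  attr(out, "min_count_policy") <- "both pools"
  class(out) <- c("oligo_enrichment", "data.frame")
  out
}

#' Pairwise group comparisons of oligo enrichments
#'
#' All pairwise two-sided two-sample Kolmogorov-Smirnov tests on per-oligo
#' `log2R` between groups, corrected across the family of comparisons via
#' the Benjamini-Hochberg procedure. Groups with fewer than two retained
#' oligos are skipped with a warning.
#'
#' @param enrichments an [oligo_enrichment()].
#' @param grouping named character vector mapping `oligo_id` to group.
#' @return data frame of class `group_comparison` with `group1`,
#'   `group2`, `n1`, `n2`, `D`, `p`, `p_adj`.
#' @export
compare_groups <- function(enrichments, grouping) {
  ok <- enrichments$passed_filter & is.finite(enrichments$log2R)
  vals <- enrichments$log2R[ok]
  grp <- grouping[enrichments$oligo_id[ok]]
  keep_groups <- names(which(table(grp) >= 2L))
  skipped <- setdiff(unique(stats::na.omit(grp)), keep_groups)
  if (length(skipped)) {
    warning("groups skipped (<2 retained oligos): ",
            paste(skipped, collapse = ", "))
  }
  keep_groups <- sort(keep_groups)
  if (length(keep_groups) < 2L) stop("need at least two testable groups")
  pairs <- combn(keep_groups, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    x <- vals[grp == pr[1] & !is.na(grp)]
    y <- vals[grp == pr[2] & !is.na(grp)]
    kt <- suppressWarnings(ks.test(x, y, alternative = "two.sided"))
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(x), n2 = length(y),
               D = unname(kt$statistic), p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Wild-type versus motif-mutant enrichment deltas
#'
#' For each wt/mut partner pair where both oligos passed the count
#' filter, computes `delta = log2R(wt) - log2R(mut)` and classifies:
#' `delta > 0.5` bound better in wt, `delta < -0.5` bound better in mut,
#' otherwise similar. A paired one-sided Wilcoxon signed-rank test
#' (alternative: wt greater) is run on the paired log2 enrichments.
#'
#' @param enrichments an [oligo_enrichment()].
#' @param library the [oligo_library()] providing wt/mut pairing.
#' @param threshold class threshold on `|delta|` (default 0.5 log2
#'   units).
#' @return list with `pairs` (data frame: `wt_id`, `mut_id`,
#'   `log2R_wt`, `log2R_mut`, `delta`, `class`), `p` (Wilcoxon p value),
#'   `n_excluded` (unpaired or filtered oligo pairs).
#' @export
wt_mut_delta <- function(enrichments, library, threshold = 0.5) {
  muts <- library[library$variant == "mut", , drop = FALSE]
  lr <- setNames(enrichments$log2R, enrichments$oligo_id)
  pf <- setNames(enrichments$passed_filter, enrichments$oligo_id)
  wt_id <- muts$partner_id
  mut_id <- muts$oligo_id
  usable <- wt_id %in% names(lr) & mut_id %in% names(lr)
  usable[usable] <- pf[wt_id[usable]] & pf[mut_id[usable]]
  n_excluded <- sum(!usable)
  wt_id <- wt_id[usable]
  mut_id <- mut_id[usable]
  if (!length(wt_id)) stop("no usable wt/mut pairs")
  delta <- lr[wt_id] - lr[mut_id]
  cls <- ifelse(delta > threshold, "wt_better",
                ifelse(delta < -threshold, "mut_better", "similar"))
  p <- wilcoxon_test(lr[wt_id], lr[mut_id], paired = TRUE,
                     alternative = "greater")$p
  list(
    pairs = data.frame(
      wt_id = wt_id, mut_id = mut_id,
      log2R_wt = unname(lr[wt_id]), log2R_mut = unname(lr[mut_id]),
      delta = unname(delta), class = unname(cls),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    p = p,
    n_excluded = n_excluded
  )
}

#' Enrichment summarized by per-oligo motif count
#'
#' Median `log2R` of retained oligos keyed by their `uag_count`; motif
#' count classes with no retained oligo are absent (not zero) rows.
#'
#' @param enrichments an [oligo_enrichment()].
#' @param library the [oligo_library()] providing `uag_count`.
#' @return data frame with `uag_count`, `median_log2R`, `n`.
#' @export
enrichment_by_motif_count <- function(enrichments, library) {
  ok <- enrichments$passed_filter & is.finite(enrichments$log2R)
  uag <- setNames(library$uag_count, library$oligo_id)
  df <- data.frame(
    uag_count = uag[enrichments$oligo_id[ok]],
    log2R = enrichments$log2R[ok]
  )
  df <- df[!is.na(df$uag_count), , drop = FALSE]
  agg <- aggregate(log2R ~ uag_count, data = df,
                   FUN = function(v) c(median = median(v), n = length(v)))
  out <- data.frame(
    uag_count = agg$uag_count,
    median_log2R = agg$log2R[, "median"],
    n = as.integer(agg$log2R[, "n"])
  )
  out[order(out$uag_count), , drop = FALSE]
}
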