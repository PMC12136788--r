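## Competition posRBNS analytics: per-fold enrichment tables normalized
## to the no-competitor condition, and rank-depletion reporting.

#' Assemble a competition series
#'
#' Bundles per-condition enrichment tables from a competition experiment
#' in which an untagged competitor protein is titrated against the tagged
#' (assayed) protein at increasing fold excess. The condition with
#' `competitor_fold = 0` is the baseline.
#'
#' @param tables list of `locked_kmer_table`s (or any data frames with
#'   `kmer` and `R` columns over one shared universe), one per condition.
#' @param folds numeric vector of competitor fold excesses (must include
#'   0), parallel to `tables`.
#' @param tagged_protein,competitor labels.
#' @return object of class `competition_series`.
#' @export
competition_series <- function(tables, folds, tagged_protein = "",
                               competitor = "") {
  stopifnot(length(tables) == length(folds))
  if (!any(folds == 0)) stop("missing baseline condition (fold 0)")
  base_kmers <- tables[[1]]$kmer
  for (t in tables) {
    if (!identical(t$kmer, base_kmers)) {
      stop("conditions do not share one kmer universe")
    }
  }
  ord <- order(folds)
  structure(
    list(tables = tables[ord], folds = folds[ord],
         tagged_protein = tagged_protein, competitor = competitor),
    class = "competition_series"
  )
}

#' Normalize a competition series to the 0-competitor baseline
#'
#' Per item, `normalized = log2(R_cond) - log2(R_baseline)`; the baseline
#' condition is exactly all-zero.
#'
#' @param series a [competition_series()].
#' @return the series with an added `normalized` matrix (kmers x folds)
#'   and `ranks` matrix (per-condition ranks, descending R with
#'   lexicographic tie-breaking).
#' @export
normalize_to_baseline <- function(series) {
  stopifnot(inherits(series, "competition_series"))
  base_i <- which(series$folds == 0)[1]
  Rb <- series$tables[[base_i]]$R
  norm <- vapply(series$tables, function(t) log2(t$R) - log2(Rb),
                 numeric(length(Rb)))
  norm[, base_i] <- 0
  ranks <- vapply(series$tables, rank_kmers,
                  integer(length(Rb)))
  dimnames(norm) <- dimnames(ranks) <-
    list(series$tables[[1]]$kmer, paste0("fold_", series$folds))
  series$normalized <- norm
  series$ranks <- ranks
  series
}

#' Rank depletion of the baseline top kmers under competition
#'
#' Reports the baseline (0-competitor) top `n_top` items with their rank
#' trajectory across competitor folds. Positive `drank` means depleted
#' (the rank number increased); items leaving the baseline top `n_top`
#' are flagged.
#'
#' @param series a [competition_series()] (normalized on the fly if
#'   needed).
#' @param n_top number of baseline top items to follow (default 10).
#' @return data frame with one row per (kmer, fold): `kmer`,
#'   `baseline_rank`, `fold`, `R`, `rank`, `drank`, `normalized`,
#'   `left_top`.
#' @export
rank_depletion <- function(series, n_top = 10L) {
  stopifnot(inherits(series, "competition_series"))
  if (is.null(series$normalized)) series <- normalize_to_baseline(series)
  base_i <- which(series$folds == 0)[1]
  if (n_top > nrow(series$tables[[1]])) stop("n_top exceeds table size")
  base_rank <- series$ranks[, base_i]
  top_idx <- order(base_rank)[seq_len(n_top)]
  rows <- list()
  for (j in seq_along(series$folds)) {
    rows[[j]] <- data.frame(
      kmer = rownames(series$ranks)[top_idx],
      baseline_rank = base_rank[top_idx],
      fold = series$folds[j],
      R = series$tables[[j]]$R[top_idx],
      rank = series$ranks[top_idx, j],
      drank = series$ranks[top_idx, j] - base_rank[top_idx],
      normalized = series$normalized[top_idx, j],
      left_top = series$ranks[top_idx, j] > n_top,
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
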