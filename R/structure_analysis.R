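## Base-pair probabilities and structure-derived summaries: positional
## BPP by motif, sliding-window group fold changes, and
## structured/unstructured kmer classification.

BUILTIN_ENERGIES <- c(AU = -2, GC = -3, GU = -1) # arbitrary units
BUILTIN_MIN_HAIRPIN <- 3L

encode_rna <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  code <- match(chars, RNA_BASES) - 1L
  if (anyNA(code)) stop("invalid alphabet in sequence: ", sequence)
  code
}

#' Per-nucleotide base-pair probability of an RNA sequence
#'
#' `p_paired[i]` is the probability that base `i` is paired, summed over
#' all pairing partners under a partition function over nested secondary
#' structures. The builtin engine uses a simplified McCaskill recursion
#' with pair energies GC = -3, AU = -2, GU = -1 (arbitrary units,
#' temperature factor 1), minimum hairpin loop of 3 unpaired bases, and
#' no dangles; it is exact for that model. The external engine delegates
#' to an installed `RNAfold` binary (`-p`) and parses its dot-plot
#' pair-probability output, giving fidelity to the full nearest-neighbor
#' model.
#'
#' Note that with wobble pairing enabled the model is not symmetric
#' under reverse complementation (a GU pair maps to an unpairable AC);
#' set `energies["GU"] = Inf` to disable wobble pairs.
#'
#' @param sequence one RNA string (T converted to U); length >= 4 for the
#'   builtin engine.
#' @param engine `"builtin"` or `"external"`.
#' @param energies builtin pair energies, named `AU`, `GC`, `GU`
#'   (arbitrary units; `Inf` disables a pair type).
#' @return object of class `bpp_profile`: list with `sequence` and
#'   `p_paired` (numeric in `[0,1]`, one value per nucleotide).
#' @export
compute_bpp <- function(sequence, engine = c("builtin", "external"),
                        energies = BUILTIN_ENERGIES) {
  engine <- match.arg(engine)
  sequence <- to_rna(sequence)
  p <- switch(engine,
    builtin = {
      if (nchar(sequence) < 4L) {
        stop("builtin engine requires length >= 4")
      }
      code <- encode_rna(sequence)
      .bpp_partition(code,
                     exp(-energies[["AU"]]),
                     exp(-energies[["GC"]]),
                     exp(-energies[["GU"]]),
                     BUILTIN_MIN_HAIRPIN)
    },
    external = bpp_external(sequence)
  )
  structure(list(sequence = sequence, p_paired = as.numeric(p)),
            class = "bpp_profile")
}

## shell out to RNAfold -p and parse the "ubox" entries of the dot plot
bpp_external <- function(sequence) {
  rnafold <- Sys.which("RNAfold")
  if (!nzchar(rnafold)) {
    stop("external BPP engine requires an 'RNAfold' binary on the PATH ",
         "(ViennaRNA)")
  }
  wd <- tempfile("rnafold")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  fa <- file.path(wd, "in.fa")
  writeLines(c(">q", sequence), fa)
  ## RNAfold writes q_dp.ps into the current directory
  old <- setwd(wd)
  on.exit(setwd(old), add = TRUE)
  system2(rnafold, c("-p", "--noPS", "-i", shQuote(fa)),
          stdout = FALSE, stderr = FALSE)
  dp <- file.path(wd, "q_dp.ps")
  if (!file.exists(dp)) stop("RNAfold did not produce a dot plot")
  lines <- grep("ubox$", readLines(dp), value = TRUE)
  lines <- lines[grepl("^[0-9]", lines)]
  n <- nchar(sequence)
  p <- numeric(n)
  if (length(lines)) {
    parts <- do.call(rbind, strsplit(lines, "\\s+"))
    i <- as.integer(parts[, 1])
    j <- as.integer(parts[, 2])
    pij <- as.numeric(parts[, 3])^2 # ps stores sqrt(p)
    for (k in seq_along(i)) {
      p[i[k]] <- p[i[k]] + pij[k]
      p[j[k]] <- p[j[k]] + pij[k]
    }
  }
  pmin(p, 1)
}

#' Mean base-pair probability of a query kmer by offset
#'
#' Folds reads of a locked-motif pool (optionally a seeded subsample)
#' and, for every positional offset, averages over reads carrying the
#' query kmer at that offset the mean `p_paired` across the kmer's
#' nucleotides.
#'
#' @param pool a [read_pool()] with locked geometry.
#' @param locked_motif,locked_start locked motif and its 0-based start.
#' @param query_kmer kmer whose positional accessibility is profiled.
#' @param engine BPP engine, see [compute_bpp()].
#' @param max_reads subsample size cap (default 2000); subsampling is
#'   seeded and reproducible.
#' @param seed subsample seed (default 1).
#' @return data frame with `offset`, `mean_bpp`, `n` (reads averaged).
#' @export
positional_bpp_by_motif <- function(pool, locked_motif = "UAG",
                                    locked_start = 8L, query_kmer,
                                    engine = "builtin",
                                    max_reads = 2000L, seed = 1L) {
  stopifnot(inherits(pool, "read_pool"))
  seqs <- rep(pool$seq, pool$count)
  if (length(seqs) > max_reads) {
    seqs <- with_seed(seed, sample(seqs, max_reads))
  }
  bpp <- lapply(unique(seqs), compute_bpp, engine = engine)
  names(bpp) <- unique(seqs)
  qlen <- nchar(query_kmer)
  offsets <- valid_offsets(pool$randomized_length, locked_start,
                           nchar(locked_motif), qlen)
  rows <- lapply(offsets, function(o) {
    qs <- offset_query_start(o, locked_start, nchar(locked_motif), qlen)
    hit <- substr(seqs, qs + 1L, qs + qlen) == query_kmer
    if (!any(hit)) {
      return(data.frame(offset = o, mean_bpp = NA_real_, n = 0L))
    }
    vals <- vapply(seqs[hit], function(s) {
      mean(bpp[[s]]$p_paired[(qs + 1L):(qs + qlen)])
    }, numeric(1))
    data.frame(offset = o, mean_bpp = mean(vals), n = length(vals))
  })
  do.call(rbind, rows)
}

## per-oligo BPP profiles for a library, with optional precomputed list
library_bpp <- function(library, engine = "builtin", bpp = NULL) {
  if (is.null(bpp)) {
    bpp <- lapply(library$sequence, function(s) {
      compute_bpp(s, engine = engine)$p_paired
    })
    names(bpp) <- library$oligo_id
  }
  stopifnot(all(library$oligo_id %in% names(bpp)))
  bpp[library$oligo_id]
}

#' Sliding-window BPP fold change of oligo groups versus a reference
#'
#' Computes centered sliding-window means of per-nucleotide BPP for every
#' oligo, averages them per group and position, and reports the log2
#' fold change of each group's mean versus the reference group, with a
#' delta-method standard error of the log2 group mean.
#'
#' @param library an [oligo_library()] of equal-length oligos.
#' @param window window size in nt (default 10).
#' @param reference_group reference group name (default `"control"`).
#' @param engine BPP engine (ignored when `bpp` given).
#' @param bpp optional precomputed list of per-oligo `p_paired` vectors
#'   named by `oligo_id`.
#' @return data frame with `group`, `position` (window center, 1-based),
#'   `mean_bpp`, `ref_mean_bpp`, `log2_fc`, `sem_log2`, `n`.
#' @export
sliding_window_bpp_fc <- function(library, window = 10L,
                                  reference_group = "control",
                                  engine = "builtin", bpp = NULL) {
  stopifnot(inherits(library, "oligo_library"))
  lens <- unique(nchar(library$sequence))
  if (length(lens) != 1L) stop("oligos must share one length")
  if (!any(library$group == reference_group)) {
    stop("reference group '", reference_group, "' is empty")
  }
  bpp <- library_bpp(library, engine, bpp)
  win_means <- function(p) {
    cs <- cumsum(c(0, p))
    (cs[(window + 1L):(lens + 1L)] - cs[1:(lens - window + 1L)]) / window
  }
  wm <- do.call(rbind, lapply(bpp, win_means))
  positions <- seq_len(lens - window + 1L) + floor(window / 2)
  groups <- unique(library$group)
  ref_rows <- library$group == reference_group
  ref_mean <- colMeans(wm[ref_rows, , drop = FALSE])
  rows <- lapply(groups, function(g) {
    sel <- library$group == g
    m <- colMeans(wm[sel, , drop = FALSE])
    n <- sum(sel)
    sdv <- apply(wm[sel, , drop = FALSE], 2, sd)
    sem_log2 <- (sdv / sqrt(n)) / (m * log(2))
    data.frame(group = g, position = positions, mean_bpp = m,
               ref_mean_bpp = ref_mean, log2_fc = log2(m / ref_mean),
               sem_log2 = sem_log2, n = n, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify kmer occurrences as more or less structured
#'
#' Every kmer occurrence in the library gets the mean BPP of its
#' nucleotides; the reference is the median of those means per kmer
#' identity across the whole library (kmer identities have different
#' intrinsic BPP distributions, e.g. GC-rich kmers pair more). An
#' occurrence is `more_structured` iff its mean BPP is strictly greater
#' than its kmer's median (ties and single-occurrence kmers classify as
#' `less_structured`).
#'
#' @param library an [oligo_library()].
#' @param k kmer length (default 3).
#' @param engine BPP engine (ignored when `bpp` given).
#' @param bpp optional precomputed per-oligo `p_paired` list.
#' @return data frame of class `structure_class_table` with
#'   `oligo_id`, `position` (1-based), `kmer`, `mean_bpp`, `class`;
#'   attribute `median_bpp` (named per-kmer medians).
#' @export
classify_kmer_structure <- function(library, k = 3L, engine = "builtin",
                                    bpp = NULL) {
  stopifnot(inherits(library, "oligo_library"))
  bpp <- library_bpp(library, engine, bpp)
  occ <- lapply(seq_len(nrow(library)), function(i) {
    s <- library$sequence[i]
    L <- nchar(s)
    pos <- seq_len(L - k + 1L)
    p <- bpp[[library$oligo_id[i]]]
    cs <- cumsum(c(0, p))
    data.frame(
      oligo_id = library$oligo_id[i],
      position = pos,
      kmer = substring(s, pos, pos + k - 1L),
      mean_bpp = (cs[pos + k] - cs[pos]) / k,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, occ)
  med <- tapply(tab$mean_bpp, tab$kmer, median)
  tab$class <- ifelse(tab$mean_bpp > med[tab$kmer],
                      "more_structured", "less_structured")
  attr(tab, "median_bpp") <- med
  attr(tab, "k") <- as.integer(k)
  class(tab) <- c("structure_class_table", "data.frame")
  tab
}
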