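## Seeded generators that emulate every assayed input at desk scale:
## random and locked-motif pools, equilibrium-selected bound pools with
## an optional untagged competitor, designed natural-sequence libraries
## with motif mutants, fluorescence polarization curves, and a toy
## genome with planted peaks.
##
## All randomness flows through a single seeded generator per call; the
## caller's RNG state is untouched.

random_rna <- function(n, length) {
  chars <- sample(RNA_BASES, n * length, replace = TRUE)
  apply(matrix(chars, nrow = n), 1, paste, collapse = "")
}

#' Generate a uniform random pool
#'
#' @param length read length in nt (default 20).
#' @param n number of reads.
#' @param seed RNG seed.
#' @param role,protein_label,concentration_nM,replicate_id pool metadata
#'   (see [read_pool()]).
#' @return a [read_pool()] of `n` uniform random reads.
#' @export
make_random_pool <- function(length = 20L, n, seed, role = "input",
                             protein_label = "",
                             concentration_nM = NA_real_,
                             replicate_id = "rep1") {
  seqs <- with_seed(seed, random_rna(n, length))
  read_pool(seqs, role = role, protein_label = protein_label,
            concentration_nM = concentration_nM,
            replicate_id = replicate_id, randomized_length = length)
}

#' Generate a locked-motif pool
#'
#' Every read carries `locked_motif` at a fixed central position with
#' uniformly randomized flanks (default geometry: 8 nt, the 3-nt motif,
#' 9 nt — a 20-nt read with the motif starting at 0-based index 8).
#'
#' @param locked_motif central motif (default `"UAG"`).
#' @param flanks lengths of the 5' and 3' randomized flanks
#'   (default `c(8, 9)`).
#' @inheritParams make_random_pool
#' @return a [read_pool()]; the locked start (0-based) equals
#'   `flanks[1]`.
#' @export
make_locked_pool <- function(locked_motif = "UAG", flanks = c(8L, 9L),
                             n, seed, role = "input",
                             protein_label = "",
                             concentration_nM = NA_real_,
                             replicate_id = "rep1") {
  seqs <- with_seed(seed, {
    up <- random_rna(n, flanks[1])
    down <- random_rna(n, flanks[2])
    paste0(up, locked_motif, down)
  })
  read_pool(seqs, role = role, protein_label = protein_label,
            concentration_nM = concentration_nM,
            replicate_id = replicate_id,
            randomized_length = flanks[1] + nchar(locked_motif) +
              flanks[2])
}

#' Define a protein specificity model for the equilibrium simulator
#'
#' Maps kmers to dissociation constants; any window not listed binds at
#' the (weakest) background Kd. Occupancy at concentration `c` follows
#' the single-site isotherm `theta = c / (c + Kd)`.
#'
#' @param kmer_kd named numeric vector of per-kmer Kd (nM); all names
#'   must share one length.
#' @param background_kd background Kd (nM), must be `>=` every motif Kd.
#' @param protein_conc_nM protein concentration driving selection.
#' @param binding_rule `"best_site"` (read occupancy from its
#'   minimum-Kd window) or `"sum_occupancy"`
#'   (`1 - prod(1 - theta_w)` over windows, emulating multi-site
#'   avidity).
#' @return list of class `specificity_model`.
#' @export
specificity_model <- function(kmer_kd, background_kd,
                              protein_conc_nM,
                              binding_rule = c("best_site",
                                               "sum_occupancy")) {
  binding_rule <- match.arg(binding_rule)
  stopifnot(all(kmer_kd > 0), background_kd > 0, protein_conc_nM > 0)
  if (length(kmer_kd)) {
    stopifnot(!is.null(names(kmer_kd)),
              length(unique(nchar(names(kmer_kd)))) == 1L)
    if (background_kd < max(kmer_kd)) {
      stop("background_kd must be >= every motif Kd")
    }
  }
  structure(
    list(kmer_kd = kmer_kd, background_kd = background_kd,
         protein_conc_nM = protein_conc_nM,
         binding_rule = binding_rule),
    class = "specificity_model"
  )
}

## per-read window Kd matrix lookup: returns n x n_windows matrix
window_kds <- function(seqs, model) {
  kl <- nchar(names(model$kmer_kd)[1])
  L <- nchar(seqs[1])
  nw <- L - kl + 1L
  kd <- matrix(model$background_kd, nrow = length(seqs), ncol = nw)
  for (w in seq_len(nw)) {
    win <- substr(seqs, w, w + kl - 1L)
    hit <- model$kmer_kd[win]
    kd[!is.na(hit), w] <- hit[!is.na(hit)]
  }
  kd
}

## per-read selection weight; with a competitor, the tagged-bound weight
## at the tagged protein's best site is
## (cA/KdA) / (1 + cA/KdA + cB/KdB)
read_weights <- function(seqs, model, competitor = NULL,
                         competitor_conc = 0) {
  cA <- model$protein_conc_nM
  if (length(model$kmer_kd) == 0L) {
    kdA <- matrix(model$background_kd, nrow = length(seqs), ncol = 1L)
  } else {
    kdA <- window_kds(seqs, model)
  }
  if (model$binding_rule == "sum_occupancy" && is.null(competitor)) {
    theta <- cA / (cA + kdA)
    return(1 - apply(1 - theta, 1, prod))
  }
  best <- max.col(-kdA, ties.method = "first")
  kdA_best <- kdA[cbind(seq_along(seqs), best)]
  if (is.null(competitor) || competitor_conc == 0) {
    return((cA / kdA_best) / (1 + cA / kdA_best))
  }
  kdB <- if (length(competitor$kmer_kd) == 0L) {
    matrix(competitor$background_kd, nrow = length(seqs), ncol = 1L)
  } else {
    window_kds(seqs, competitor)
  }
  ## competitor Kd evaluated at the tagged protein's best site (or its
  ## own best site if window universes differ in length)
  kdB_best <- if (ncol(kdB) == ncol(kdA)) {
    kdB[cbind(seq_along(seqs), best)]
  } else {
    apply(kdB, 1, min)
  }
  (cA / kdA_best) /
    (1 + cA / kdA_best + competitor_conc / kdB_best)
}

sample_bound <- function(input_pool, weights, n_bound, seed,
                         protein_label, concentration_nM,
                         replicate_id) {
  w <- weights * input_pool$count
  if (all(w == 0)) stop("all selection weights are zero")
  idx <- with_seed(seed, {
    sample.int(length(w), size = n_bound, replace = TRUE, prob = w)
  })
  tab <- tabulate(idx, nbins = length(w))
  keep <- tab > 0L
  read_pool(input_pool$seq[keep], counts = tab[keep], role = "bound",
            protein_label = protein_label,
            concentration_nM = concentration_nM,
            replicate_id = replicate_id,
            randomized_length = input_pool$randomized_length)
}

#' Simulate an equilibrium selection (pulldown)
#'
#' Each read's selection weight is its equilibrium occupancy under the
#' specificity model (times its input count); the bound pool is sampled
#' with replacement proportionally to weight.
#'
#' @param input_pool a [read_pool()].
#' @param model a [specificity_model()].
#' @param n_bound number of bound reads to sample.
#' @param seed RNG seed.
#' @param protein_label,replicate_id metadata for the bound pool.
#' @return a bound [read_pool()].
#' @export
simulate_selection <- function(input_pool, model, n_bound, seed,
                               protein_label = "protein",
                               replicate_id = "rep1") {
  w <- read_weights(input_pool$seq, model)
  sample_bound(input_pool, w, n_bound, seed, protein_label,
               model$protein_conc_nM, replicate_id)
}

#' Simulate a competition selection series
#'
#' For each competitor fold excess, the tagged protein's per-read weight
#' is the competitive occupancy at the read's best (tagged) site; one
#' bound pool is sampled per fold. The fold-0 pool follows the same seed
#' path as [simulate_selection()] and is distributed identically to it.
#'
#' @param input_pool a [read_pool()].
#' @param tagged,competitor [specificity_model()]s; the competitor's
#'   concentration is `fold * competitor$protein_conc_nM`.
#' @param folds competitor fold excesses (must include 0).
#' @param n_bound reads per bound pool.
#' @param seed RNG seed (fold `i` uses `seed + i - 1` over the sorted
#'   folds, so fold 0 uses `seed`).
#' @return named list of bound [read_pool()]s, one per fold (sorted).
#' @export
simulate_competition <- function(input_pool, tagged, competitor, folds,
                                 n_bound, seed) {
  if (!any(folds == 0)) stop("folds must include the 0 baseline")
  folds <- sort(folds)
  pools <- lapply(seq_along(folds), function(i) {
    f <- folds[i]
    w <- read_weights(input_pool$seq, tagged, competitor,
                      competitor_conc = f * competitor$protein_conc_nM)
    sample_bound(input_pool, w, n_bound, seed + i - 1L,
                 protein_label = "tagged",
                 concentration_nM = tagged$protein_conc_nM,
                 replicate_id = paste0("fold", f))
  })
  names(pools) <- paste0("fold_", folds)
  pools
}

## default per-group ground-truth Kd (nM) for the designed library:
## shared regions bind tightest, single-protein regions intermediate,
## control / stop-codon / motif-mutant oligos at background
NS_GROUP_KD <- c(shared = 5, msi1_only = 20, unk_only = 20,
                 control = 500, stop_codon = 500, other = 500)
NS_MUT_KD <- 500

mutate_uag_to_ccg <- function(seqs) {
  while (any(grepl("UAG", seqs, fixed = TRUE))) {
    seqs <- gsub("UAG", "CCG", seqs, fixed = TRUE)
  }
  seqs
}

plant <- function(backbone, element, at) {
  paste0(substr(backbone, 1, at - 1L), element,
         substr(backbone, at + nchar(element), nchar(backbone)))
}

#' Generate a designed natural-sequence-style oligo library
#'
#' Builds 120-nt oligos in five binding-pattern groups with planted
#' motif elements — `shared`: `CCC`-`UAG`-N2-`UAG`-`AUA`; `msi1_only`:
#' bipartite `UAG`-N2-`UAG`; `unk_only`: `CCC`-`UAG`-`AUA`;
#' `control` and `stop_codon`: a lone `UAG` in a neutral context — plus a
#' motif-mutant partner for every wt oligo in which every `UAG` is
#' replaced by `CCG`. Ground-truth per-oligo dissociation constants
#' (shared 5 nM < single-protein 20 nM < control = stop codon = mutant
#' 500 nM) are attached for end-to-end recovery checks.
#'
#' @param group_sizes named integer vector of wt oligos per group
#'   (default 25 control, 15 stop_codon, 20 msi1_only, 20 unk_only,
#'   20 shared).
#' @param oligo_length oligo length in nt (default 120).
#' @param seed RNG seed.
#' @return an [oligo_library()] (wt records followed by their `_mut`
#'   partners) with attribute `kd_nM` (named per-oligo ground truth).
#' @export
make_ns_library <- function(group_sizes = c(control = 25L,
                                            stop_codon = 15L,
                                            msi1_only = 20L,
                                            unk_only = 20L,
                                            shared = 20L),
                            oligo_length = 120L, seed = 1L) {
  stopifnot(all(group_sizes > 0), !is.null(names(group_sizes)))
  with_seed(seed, {
    ids <- character(0); seqs <- character(0); groups <- character(0)
    regions <- character(0)
    for (g in names(group_sizes)) {
      for (i in seq_len(group_sizes[[g]])) {
        ## backbone free of UAG so that motif content is controlled
        backbone <- mutate_uag_to_ccg(
          paste(sample(RNA_BASES, oligo_length, replace = TRUE),
                collapse = "")
        )
        at <- sample(20:(oligo_length - 30), 1)
        element <- switch(g,
          shared = {
            nn <- paste(sample(c("A", "U"), 2, replace = TRUE),
                        collapse = "")
            paste0("CCCUAG", nn, "UAGAUA")
          },
          msi1_only = {
            nn <- paste(sample(c("A", "U"), 2, replace = TRUE),
                        collapse = "")
            paste0("UAG", nn, "UAG")
          },
          unk_only = "CCCUAGAUA",
          "UAG"
        )
        seqs <- c(seqs, plant(backbone, element, at))
        ids <- c(ids, sprintf("%s_%03d", g, i))
        groups <- c(groups, g)
        regions <- c(regions,
                     if (g == "stop_codon") "CDS"
                     else sample(c("CDS", "UTR3"), 1))
      }
    }
    mut_seqs <- mutate_uag_to_ccg(seqs)
    lib <- oligo_library(
      oligo_id = c(ids, paste0(ids, "_mut")),
      sequence = c(seqs, mut_seqs),
      group = c(groups, groups),
      variant = rep(c("wt", "mut"), each = length(ids)),
      partner_id = c(paste0(ids, "_mut"), ids),
      region = c(regions, regions)
    )
    kd <- c(NS_GROUP_KD[groups], rep(NS_MUT_KD, length(ids)))
    attr(lib, "kd_nM") <- setNames(as.numeric(kd), lib$oligo_id)
    lib
  })
}

#' Simulate an nsRBNS experiment against a designed library
#'
#' Input reads sample oligos uniformly; bound reads sample oligos with
#' probability proportional to their equilibrium occupancy
#' `theta = c / (c + Kd)` under the supplied ground-truth Kd. Reads are
#' the first `read_length` bases of each oligo.
#'
#' @param library an [oligo_library()] (e.g. from [make_ns_library()]).
#' @param kd_nM named per-oligo Kd vector (defaults to the library's
#'   `kd_nM` attribute).
#' @param protein_conc_nM assayed protein concentration (default
#'   100 nM).
#' @param n_input,n_bound read counts per pool.
#' @param read_length read window length; `NULL` (default) sequences the
#'   full-length oligo, which keeps every wt/mut pair distinguishable.
#' @param seed RNG seed.
#' @return list with `input` and `bound` [read_pool()]s.
#' @export
simulate_library_selection <- function(library, kd_nM = NULL,
                                       protein_conc_nM = 100,
                                       n_input = 50000L,
                                       n_bound = 50000L,
                                       read_length = NULL, seed = 1L) {
  stopifnot(inherits(library, "oligo_library"))
  if (is.null(kd_nM)) kd_nM <- attr(library, "kd_nM")
  stopifnot(!is.null(kd_nM), all(library$oligo_id %in% names(kd_nM)))
  if (is.null(read_length)) read_length <- min(nchar(library$sequence))
  windows <- substr(library$sequence, 1L, read_length)
  theta <- protein_conc_nM / (protein_conc_nM + kd_nM[library$oligo_id])
  with_seed(seed, {
    n_in <- as.vector(stats::rmultinom(1, n_input,
                                       rep(1, nrow(library))))
    n_bd <- as.vector(stats::rmultinom(1, n_bound, theta))
    list(
      input = read_pool(windows[n_in > 0], counts = n_in[n_in > 0],
                        role = "input",
                        randomized_length = read_length),
      bound = read_pool(windows[n_bd > 0], counts = n_bd[n_bd > 0],
                        role = "bound", protein_label = "protein",
                        concentration_nM = protein_conc_nM,
                        randomized_length = read_length)
    )
  })
}

#' Generate a synthetic fluorescence polarization curve
#'
#' Points lie on the single-site isotherm
#' `fp_min + (fp_max - fp_min) * c / (Kd + c)` plus Gaussian noise.
#'
#' @param Kd_nM true dissociation constant.
#' @param fp_min,fp_max signal floor and plateau (defaults 20 and 180
#'   mP).
#' @param concentrations_nM titration points (default a half-log series
#'   from 0.1 to 3000 nM).
#' @param noise_sd Gaussian noise SD in signal units (default 0).
#' @param replicates replicate curves (default 3).
#' @param seed RNG seed.
#' @return a [binding_curve()].
#' @export
make_fp_curve <- function(Kd_nM, fp_min = 20, fp_max = 180,
                          concentrations_nM = 10^seq(-1, 3.5, by = 0.5),
                          noise_sd = 0, replicates = 3L, seed = 1L) {
  conc <- rep(concentrations_nM, times = replicates)
  repl <- rep(seq_len(replicates), each = length(concentrations_nM))
  mu <- fp_min + (fp_max - fp_min) * conc / (Kd_nM + conc)
  fp <- if (noise_sd > 0) {
    with_seed(seed, mu + rnorm(length(mu), sd = noise_sd))
  } else {
    mu
  }
  binding_curve(conc, fp, replicate = repl)
}

#' Generate a toy genome bundle with planted peaks
#'
#' One chromosome carrying `n_transcripts` two-exon transcripts
#' (alternating strands) with 5' UTR, CDS split across the exons, and
#' 3' UTR. Two proteins' peak sets are planted in CDS and 3' UTR with a
#' strand-local `TAG` written at every peak center; some transcripts are
#' shared between the proteins, and expression spans the >5 TPM filter
#' boundary.
#'
#' @param n_transcripts number of transcripts (default 6).
#' @param seed RNG seed.
#' @return list with `bundle` (a [genome_bundle()]) and `peaks` (list of
#'   two `GRanges`, `A` and `B`).
#' @export
make_toy_genome <- function(n_transcripts = 6L, seed = 1L) {
  with_seed(seed, {
    tx_len <- 900L
    gap <- 100L
    chrom_len <- n_transcripts * (tx_len + gap) + gap
    genome_chars <- sample(c("A", "C", "G", "T"), chrom_len,
                           replace = TRUE)
    tx <- data.frame(
      transcript_id = sprintf("tx%02d", seq_len(n_transcripts)),
      chrom = "chr1",
      strand = rep(c("+", "-"), length.out = n_transcripts),
      tx_start = gap + (seq_len(n_transcripts) - 1L) * (tx_len + gap) +
        1L,
      stringsAsFactors = FALSE
    )
    tx$tx_end <- tx$tx_start + tx_len - 1L
    ## exon1: first 400 nt; intron 100; exon2: last 400 nt
    exons <- do.call(rbind, lapply(seq_len(n_transcripts), function(i) {
      data.frame(
        transcript_id = tx$transcript_id[i],
        start = c(tx$tx_start[i], tx$tx_start[i] + 500L),
        end = c(tx$tx_start[i] + 399L, tx$tx_end[i])
      )
    }))
    tx$cds_start <- tx$tx_start + 100L
    tx$cds_end <- tx$tx_start + 649L # spans the splice junction
    expression <- setNames(
      round(runif(n_transcripts, 0, 60), 1), tx$transcript_id
    )
    expression[1] <- 4.0 # below the >5 TPM filter
    plant_tag <- function(center, strand) {
      el <- if (strand == "+") c("T", "A", "G") else c("C", "T", "A")
      genome_chars[(center - 1L):(center + 1L)] <<- el
    }
    mk_peaks <- function(which_tx, regions, score_base) {
      centers <- integer(0); txs <- character(0)
      strands <- character(0); regs <- character(0)
      for (j in seq_along(which_tx)) {
        i <- which_tx[j]
        iv <- region_interval(as.list(tx[i, ]), regions[j])
        center <- sample(seq(iv[1] + 20L, iv[2] - 20L), 1)
        plant_tag(center, tx$strand[i])
        centers <- c(centers, center)
        txs <- c(txs, tx$transcript_id[i])
        strands <- c(strands, tx$strand[i])
        regs <- c(regs, regions[j])
      }
      GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(centers - 10L, centers + 10L),
        strand = strands, transcript_id = txs, region = regs,
        score = score_base + seq_along(centers)
      )
    }
    idxA <- seq_len(min(4L, n_transcripts))
    idxB <- seq(from = min(3L, n_transcripts),
                to = n_transcripts)
    peaksA <- mk_peaks(idxA,
                       rep(c("UTR3", "CDS"), length.out = length(idxA)),
                       10)
    peaksB <- mk_peaks(idxB,
                       rep(c("CDS", "UTR3"), length.out = length(idxB)),
                       20)
    genome <- setNames(paste(genome_chars, collapse = ""), "chr1")
    bundle <- genome_bundle(genome, tx, exons, expression)
    list(bundle = bundle, peaks = list(A = peaksA, B = peaksB))
  })
}
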