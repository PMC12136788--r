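## I/O: read pools from FASTQ, designed oligo libraries from FASTA + TSV
## metadata, run configuration as flat JSON.

#' Construct a read pool
#'
#' A `read_pool` is a weighted multiset of constant-length RNA sequences
#' from one side of a selection experiment (the free `input` pool or the
#' protein-`bound` pool). Sequences are stored as RNA (`ACGU`); duplicate
#' sequences are aggregated into integer counts.
#'
#' @param sequences character vector of RNA/DNA sequences (T is converted
#'   to U). All retained sequences must share one length.
#' @param counts nonnegative integer count per sequence (default 1 each).
#' @param role `"input"` or `"bound"`.
#' @param protein_label protein (or domain) name, free text.
#' @param concentration_nM protein concentration in nM (`NA` for input).
#' @param replicate_id replicate label.
#' @param randomized_length expected sequence length; reads of any other
#'   length, or containing characters outside `ACGU`, are dropped and
#'   tallied in `dropped`.
#' @return object of class `read_pool` with elements `seq`, `count`,
#'   `role`, `protein_label`, `concentration_nM`, `replicate_id`,
#'   `randomized_length` and a `dropped` tally
#'   (`wrong_length` / `bad_alphabet`).
#' @export
read_pool <- function(sequences, counts = NULL, role = c("input", "bound"),
                      protein_label = "", concentration_nM = NA_real_,
                      replicate_id = "rep1", randomized_length = NULL) {
  role <- match.arg(role)
  sequences <- to_rna(as.character(sequences))
  if (is.null(counts)) counts <- rep(1L, length(sequences))
  stopifnot(length(counts) == length(sequences), all(counts >= 0))
  counts <- as.integer(counts)
  if (is.null(randomized_length)) {
    if (length(sequences) == 0L) stop("empty pool and no randomized_length")
    randomized_length <- nchar(sequences[1])
  }
  ok_len <- nchar(sequences) == randomized_length
  ok_alpha <- !grepl("[^ACGU]", sequences)
  dropped <- list(
    wrong_length = sum(counts[!ok_len]),
    bad_alphabet = sum(counts[ok_len & !ok_alpha])
  )
  keep <- ok_len & ok_alpha
  sequences <- sequences[keep]
  counts <- counts[keep]
  if (length(sequences)) {
    agg <- rowsum(counts, sequences)
    sequences <- rownames(agg)
    counts <- as.integer(agg[, 1])
    nz <- counts > 0L
    sequences <- sequences[nz]
    counts <- counts[nz]
  }
  structure(
    list(
      seq = sequences, count = counts, role = role,
      protein_label = protein_label,
      concentration_nM = concentration_nM,
      replicate_id = replicate_id,
      randomized_length = as.integer(randomized_length),
      dropped = dropped
    ),
    class = "read_pool"
  )
}

#' Total retained read count of a pool
#' @param pool a `read_pool`.
#' @return integer total of per-sequence counts.
#' @export
pool_size <- function(pool) {
  stopifnot(inherits(pool, "read_pool"))
  sum(pool$count)
}

#' @export
print.read_pool <- function(x, ...) {
  cat(sprintf(
    "read_pool: %d unique / %d total %d-nt reads [%s, %s%s]\n",
    length(x$seq), pool_size(x), x$randomized_length, x$role,
    if (nzchar(x$protein_label)) x$protein_label else "unlabelled",
    if (is.finite(x$concentration_nM)) {
      sprintf(", %g nM", x$concentration_nM)
    } else ""
  ))
  drop_n <- sum(unlist(x$dropped))
  if (drop_n > 0) cat(sprintf("  dropped at import: %d\n", drop_n))
  invisible(x)
}

#' Read a sequencing pool from FASTQ
#'
#' Reads a (optionally gzipped) FASTQ file, applies a fixed-coordinate trim,
#' converts T to U, drops reads of the wrong length or with non-`ACGU(T)`
#' characters (for example `N` calls), and aggregates identical reads into
#' counts. Quality scores are ignored.
#'
#' @param path FASTQ file path.
#' @param trim list with `start` (1-based first retained base, default 1)
#'   and `length` (retained insert length). `length = NULL` keeps the read
#'   from `start` to its end. Trim coordinates are experiment-specific and
#'   therefore user-supplied.
#' @inheritParams read_pool
#' @return a [read_pool()]. A message is logged if more than half the reads
#'   were dropped.
#' @export
read_fastq_pool <- function(path, trim = list(start = 1L, length = NULL),
                            role = c("input", "bound"), protein_label = "",
                            concentration_nM = NA_real_,
                            replicate_id = "rep1",
                            randomized_length = NULL) {
  role <- match.arg(role)
  reads <- Biostrings::readBStringSet(path, format = "fastq")
  if (length(reads) == 0L) stop("empty FASTQ file: ", path)
  seqs <- as.character(reads)
  start <- if (is.null(trim$start)) 1L else as.integer(trim$start)
  if (!is.null(trim$length)) {
    seqs <- substr(seqs, start, start + as.integer(trim$length) - 1L)
  } else if (start > 1L) {
    seqs <- substr(seqs, start, nchar(seqs))
  }
  pool <- read_pool(
    seqs, role = role, protein_label = protein_label,
    concentration_nM = concentration_nM, replicate_id = replicate_id,
    randomized_length = randomized_length
  )
  n_drop <- sum(unlist(pool$dropped))
  if (n_drop > length(reads) / 2) {
    message(sprintf(
      "read_fastq_pool: %d of %d reads dropped (>50%%) from %s",
      n_drop, length(reads), path
    ))
  }
  pool
}

#' Write a read pool to FASTQ
#'
#' Expands counts into individual records (constant dummy quality `I`) so
#' that re-reading with [read_fastq_pool()] reproduces the identical pool.
#'
#' @param pool a `read_pool`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_fastq_pool <- function(pool, path) {
  stopifnot(inherits(pool, "read_pool"))
  seqs <- rep(pool$seq, pool$count)
  qual <- strrep("I", pool$randomized_length)
  lines <- as.vector(rbind(
    paste0("@read", seq_along(seqs)), seqs, "+", qual
  ))
  writeLines(lines, path)
  invisible(path)
}

OLIGO_GROUPS <- c("control", "stop_codon", "msi1_only", "unk_only",
                  "shared", "other")

#' Construct a designed oligo library
#'
#' An `oligo_library` is a data frame of designed sequences (typically
#' 120 nt naturally derived oligos) with group labels, wild-type/mutant
#' pairing and per-oligo `UAG` counts, as used for natural-sequence
#' selection experiments.
#'
#' @param oligo_id unique oligo identifiers.
#' @param sequence RNA/DNA sequences (converted to RNA).
#' @param group one of `r paste(OLIGO_GROUPS, collapse = ", ")`.
#' @param variant `"wt"` or `"mut"`.
#' @param partner_id for `mut` records, the `oligo_id` of the paired `wt`
#'   oligo (and vice versa where known); `NA` otherwise.
#' @param region transcript region of origin: `"CDS"`, `"UTR3"` or
#'   `"other"`.
#' @param validate if `TRUE` (default), invariant violations (duplicate
#'   ids, unresolved partners, residual UAG in mutants) raise errors that
#'   name the offending records.
#' @return data frame of class `oligo_library` with a computed `uag_count`
#'   column (overlapping occurrences of `UAG`).
#' @export
oligo_library <- function(oligo_id, sequence, group = "other",
                          variant = "wt", partner_id = NA_character_,
                          region = "other", validate = TRUE) {
  sequence <- to_rna(as.character(sequence))
  n <- length(oligo_id)
  lib <- data.frame(
    oligo_id = as.character(oligo_id),
    sequence = sequence,
    group = rep_len(as.character(group), n),
    variant = rep_len(as.character(variant), n),
    partner_id = rep_len(as.character(partner_id), n),
    region = rep_len(as.character(region), n),
    uag_count = count_overlapping(sequence, "UAG"),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("oligo_library", "data.frame")
  if (validate) validate_oligo_library(lib)
  lib
}

validate_oligo_library <- function(lib) {
  if (anyDuplicated(lib$oligo_id)) {
    stop("duplicate oligo_ids: ",
         paste(unique(lib$oligo_id[duplicated(lib$oligo_id)]),
               collapse = ", "))
  }
  bad_group <- setdiff(unique(lib$group), OLIGO_GROUPS)
  if (length(bad_group)) stop("unknown groups: ",
                              paste(bad_group, collapse = ", "))
  bad_var <- setdiff(unique(lib$variant), c("wt", "mut"))
  if (length(bad_var)) stop("unknown variants: ",
                            paste(bad_var, collapse = ", "))
  muts <- lib[lib$variant == "mut", , drop = FALSE]
  unresolved <- muts$oligo_id[
    is.na(muts$partner_id) | !(muts$partner_id %in% lib$oligo_id)
  ]
  if (length(unresolved)) {
    stop("mut records with unresolved wt partner: ",
         paste(unresolved, collapse = ", "))
  }
  residual <- muts$oligo_id[muts$uag_count > 0]
  if (length(residual)) {
    stop("mut records still containing UAG: ",
         paste(residual, collapse = ", "))
  }
  invisible(lib)
}

#' Read an oligo library from FASTA plus a metadata table
#'
#' @param fasta_path FASTA of oligo sequences; record ids must match the
#'   metadata `oligo_id` column exactly (both directions).
#' @param metadata_path TSV with header, columns `oligo_id` and optionally
#'   `group`, `variant`, `partner_id`, `region`.
#' @param validate passed to [oligo_library()].
#' @return an `oligo_library`.
#' @export
read_library_fasta <- function(fasta_path, metadata_path, validate = TRUE) {
  seqs <- Biostrings::readBStringSet(fasta_path, format = "fasta")
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!"oligo_id" %in% names(meta)) {
    stop("metadata table lacks an oligo_id column")
  }
  missing_meta <- setdiff(ids, meta$oligo_id)
  missing_seq <- setdiff(meta$oligo_id, ids)
  if (length(missing_meta) || length(missing_seq)) {
    stop(
      "FASTA/metadata id mismatch; missing from metadata: [",
      paste(missing_meta, collapse = ", "), "]; missing from FASTA: [",
      paste(missing_seq, collapse = ", "), "]"
    )
  }
  meta <- meta[match(ids, meta$oligo_id), , drop = FALSE]
  get_col <- function(col, default) {
    if (col %in% names(meta)) meta[[col]] else default
  }
  oligo_library(
    oligo_id = ids,
    sequence = as.character(seqs),
    group = get_col("group", "other"),
    variant = get_col("variant", "wt"),
    partner_id = get_col("partner_id", NA_character_),
    region = get_col("region", "other"),
    validate = validate
  )
}

#' Write an oligo library to FASTA + TSV metadata
#' @param library an `oligo_library`.
#' @param fasta_path,metadata_path output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_library_fasta <- function(library, fasta_path, metadata_path) {
  stopifnot(inherits(library, "oligo_library"))
  writeLines(as.vector(rbind(paste0(">", library$oligo_id),
                             library$sequence)), fasta_path)
  meta <- library[, c("oligo_id", "group", "variant", "partner_id",
                      "region")]
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fasta_path)
}

RUN_CONFIG_KEYS <- c(
  "kmer_size", "pseudocount", "locked_motif", "locked_start",
  "min_count", "n_top", "seed", "input_fastq", "bound_fastq",
  "library_fasta", "library_metadata", "out_dir"
)

#' Read and validate a flat JSON run configuration
#'
#' Known keys: `r paste(RUN_CONFIG_KEYS, collapse = ", ")`. Unknown keys
#' are rejected; numeric parameters are validated
#' (`kmer_size`, `min_count`, `n_top` positive; `pseudocount` nonnegative;
#' `locked_start` nonnegative).
#'
#' @param path JSON file path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown run config keys: ", paste(unknown, collapse = ", "))
  }
  check_pos <- function(key, strict = TRUE) {
    if (!is.null(cfg[[key]])) {
      v <- cfg[[key]]
      if (!is.numeric(v) || length(v) != 1L ||
          (strict && v <= 0) || (!strict && v < 0)) {
        stop("run config key '", key, "' must be a ",
             if (strict) "positive" else "nonnegative", " number")
      }
    }
  }
  for (k in c("kmer_size", "min_count", "n_top")) check_pos(k)
  for (k in c("pseudocount", "locked_start", "seed")) check_pos(k, FALSE)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to JSON
#' @param config named list (validated against the known key set).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown run config keys: ", paste(unknown, collapse = ", "))
  }
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
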