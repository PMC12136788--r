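## Independent brute-force oracles used to pin the fast implementations.
## These deliberately share no code with the package internals.

## naive double-loop kmer counter (overlapping, weighted)
oracle_count_kmers <- function(seqs, counts, k) {
  out <- new.env()
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    for (p in 1:(nchar(s) - k + 1)) {
      km <- substr(s, p, p + k - 1)
      out[[km]] <- (if (is.null(out[[km]])) 0 else out[[km]]) + counts[i]
    }
  }
  res <- unlist(as.list(out))
  res[order(names(res))]
}

## per-read positional exclusion filter: read usable at query start qs0
## (0-based) iff every locked-motif occurrence is central or fully inside
## the query window
oracle_read_usable <- function(seq, locked, locked_start0, qs0, qlen) {
  lm_len <- nchar(locked)
  occ <- c()
  for (p in 1:(nchar(seq) - lm_len + 1)) {
    if (substr(seq, p, p + lm_len - 1) == locked) occ <- c(occ, p - 1)
  }
  all(occ == locked_start0 |
        (occ >= qs0 & occ + lm_len <= qs0 + qlen))
}

## brute-force Hamming assignment of one read to oligo windows
oracle_assign <- function(read, windows, max_mismatch) {
  d <- vapply(windows, function(w) {
    sum(strsplit(read, "")[[1]] != strsplit(w, "")[[1]])
  }, numeric(1))
  dmin <- min(d)
  if (dmin > max_mismatch) return("unassigned")
  if (sum(d == dmin) > 1) return("multimapped")
  names(windows)[which.min(d)]
}

## sweep-line interval union on (start, end) 1-based closed intervals
oracle_merge <- function(starts, ends) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  out <- list(c(starts[1], ends[1]))
  for (i in seq_along(starts)[-1]) {
    last <- out[[length(out)]]
    if (starts[i] <= last[2] + 1) { # overlap or adjacency (closed)
      out[[length(out)]] <- c(last[1], max(last[2], ends[i]))
    } else {
      out[[length(out) + 1]] <- c(starts[i], ends[i])
    }
  }
  do.call(rbind, out)
}

## exact one-sided (greater) sign-flip p value for paired deltas:
## P(W >= W_obs) over all 2^n equally likely sign assignments of the
## rank magnitudes (no ties, no zeros assumed)
oracle_signflip_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(w_all >= w_obs)
}

## Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

## exhaustive nested-structure enumeration for the builtin energy model
oracle_enum_bpp <- function(seq, minloop = 3,
                            energies = c(AU = -2, GC = -3, GU = -1)) {
  chars <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(chars)
  pw <- function(a, b) {
    p <- paste0(sort(c(chars[a], chars[b])), collapse = "")
    if (p == "AU") exp(-energies[["AU"]])
    else if (p == "CG") exp(-energies[["GC"]])
    else if (p == "GU") exp(-energies[["GU"]])
    else 0
  }
  structs <- function(i, j) {
    if (j - i + 1 <= 0) return(list(list(w = 1, pairs = NULL)))
    out <- list()
    for (s in structs(i + 1, j)) out[[length(out) + 1]] <- s
    if (i + minloop + 1 <= j) {
      for (k in seq(i + minloop + 1, j)) {
        w <- pw(i, k)
        if (w > 0) {
          for (s1 in structs(i + 1, k - 1)) {
            for (s2 in structs(k + 1, j)) {
              out[[length(out) + 1]] <- list(
                w = w * s1$w * s2$w,
                pairs = rbind(c(i, k), s1$pairs, s2$pairs)
              )
            }
          }
        }
      }
    }
    out
  }
  ptot <- numeric(n)
  Z <- 0
  for (s in structs(1, n)) {
    Z <- Z + s$w
    if (!is.null(s$pairs)) {
      for (r in seq_len(nrow(s$pairs))) {
        ptot[s$pairs[r, 1]] <- ptot[s$pairs[r, 1]] + s$w
        ptot[s$pairs[r, 2]] <- ptot[s$pairs[r, 2]] + s$w
      }
    }
  }
  ptot / Z
}

## small fixed specificity model used across simulation tests: a UAG-core
## binder with graded, non-mutually-extending 6mer preferences (no
## planted kmer contains a second UAG, so reads rarely carry compound
## sites that would blur the planted affinity ordering)
uag_core_model <- function(conc = 50, rule = "best_site") {
  kd <- c(UAGUAA = 2, UAGAUA = 4, UAGAAU = 8, UAGUUA = 16,
          UAGAAA = 32, UAGUUU = 64)
  specificity_model(kd, background_kd = 100, protein_conc_nM = conc,
                    binding_rule = rule)
}

## UAG binder embedded in a graded 3mer context (GC-rich contexts bind
## weakly): every 6mer gets a distinct enrichment, and mutating the UAG
## core of the top 6mer costs far more than mutating its flanks
uag_context_model <- function(conc = 10) {
  kmers <- all_kmers(3)
  gc <- vapply(strsplit(kmers, ""), function(ch) {
    sum(ch %in% c("G", "C"))
  }, numeric(1))
  jit <- 1 + 0.5 * ((seq_along(kmers) * 7) %% 13 - 6) / 6
  kd <- setNames((10 + 12 * gc) * jit, kmers)
  kd[["UAG"]] <- 2
  specificity_model(kd, background_kd = max(kd) + 1,
                    protein_conc_nM = conc)
}

## A/U-rich additive binder (sum-occupancy at low occupancy), giving a
## smooth full-spectrum enrichment landscape across all 6mers -- the
## regime where replicate R values are strongly correlated
aurich_additive_model <- function(conc = 0.2) {
  kmers <- all_kmers(3)
  gc <- vapply(strsplit(kmers, ""), function(ch) {
    sum(ch %in% c("G", "C"))
  }, numeric(1))
  jit <- ((seq_along(kmers) * 37) %% 64) / 63
  kd <- setNames((4 + 30 * gc) * (0.5 + jit), kmers)
  kd[["UAG"]] <- 1.5
  specificity_model(kd, background_kd = max(kd) + 1,
                    protein_conc_nM = conc,
                    binding_rule = "sum_occupancy")
}

## UAG-anchored binder with twelve graded extended motifs, so that the
## top anchored kmers of a locked-pool experiment are all true binders
uag_anchor_model <- function(conc = 50) {
  ext <- c("UAA", "UAG", "AUA", "AAU", "UUA", "AAA", "UAU", "AUU",
           "UUU", "AGU", "GUA", "UGA")
  kd <- setNames(seq(2, 13), paste0("UAG", ext))
  specificity_model(kd, background_kd = 100, protein_conc_nM = conc)
}

## competitor with orthogonal specificity (C-rich), same affinity scale
## for its own sites but negligible nonspecific binding -- its presence
## should leave the tagged protein's relative enrichments untouched
ccc_model <- function(conc = 50) {
  ext <- c("AAA", "ACA", "AUA", "CAC", "CCC", "CUC", "GAG", "GCG",
           "GUG", "UAU", "UCU", "UUU")
  kd <- setNames(seq(2, 13), paste0("CCC", ext))
  specificity_model(kd, background_kd = 5000, protein_conc_nM = conc)
}
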