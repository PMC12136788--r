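---
title: "Models and methods behind rbnskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rbnskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbnskit)
```

This vignette is the package's own account of the models it implements:
what each statistic assumes, which tunable parameters matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## 1. Enrichment analytics for selection sequencing

### The R value

RNA bind-n-seq and its variants compare a protein-bound sequencing pool
with the input pool it was selected from. For a kmer $w$ the enrichment
is

$$R(w) = \frac{f_\text{bound}(w) + pc}{f_\text{input}(w) + pc},$$

where $f$ is the frequency of $w$ among **all overlapping kmer
occurrences** in a pool (weighted by read counts) and $pc$ is a
pseudocount. Counting every overlapping occurrence is standard practice
for these assays; it makes frequencies sum to one over the $4^k$ kmer
universe, which `compute_kmer_table()` asserts.

**Pseudocount.** The default is $pc = 0$: a kmer absent from the bound
pool honestly reports $R = 0$ with `log2R = -Inf` and is flagged
undefined rather than silently shrunk. For correlation analyses across
replicates or proteins — where $-\infty$ values would be destructive — a
small $pc$ (we use $10^{-6}$ in the examples) is appropriate; it leaves
well-measured kmers essentially untouched.

**Tie-breaking.** Every ranking in the package orders by descending R
and then lexicographic kmer, so outputs are bit-stable across runs and
platforms. Replicate merging averages replicate R values arithmetically
and recomputes frequencies from summed counts; provenance is kept in the
table's attributes.

**R drop.** For the top kmer, the per-position importance is
$R(\text{top}) - \max_b R(\text{mutant}_b)$ — the cost of the *least*
damaging substitution. Both this summary and the full
$k \times 4$ single-mutant matrix are returned, since either view can be
wanted downstream.

**Logos.** The logo of the top $n$ kmers (default 15) aligns each kmer
to the top one at the integer offset maximizing positionwise identity
(ties: smallest absolute offset, then the negative one) and weights the
kmers equally — the alignment is automatic rather than curated, so a
deterministic tie rule is essential.

### Positional enrichment and the exclusion filter

In a locked-motif pool every read carries the core motif centrally
(default geometry: 8 nt flank, `UAG`, 9 nt flank in a 20-nt read; the
exact flank split of such pools is a synthesis choice, so it is
configurable). The positional profile of a query kmer counts, per
offset, reads carrying the query there — after **excluding any read
that contains an occurrence of the locked motif other than (a) the
central one and (b) an occurrence lying fully inside the counted query
window**. Without this filter, secondary-motif enrichments are
contaminated by reads that are really bipartite-core binders.

Offset convention: offset $-1$ is the nucleotide immediately 5' of the
locked motif, $+1$ immediately 3' of it; query kmers are located by
their 5' end downstream and 3' end upstream, so the spacer length is
$|o| - 1$ on both sides, matching the $N_k$ spacer notation used for
bipartite motifs.

An open design question was whether the denominator should use the
filtered or the full input pool; we filter **both pools symmetrically**
(recorded in the profile's `denominator` attribute), because an
asymmetric denominator would make the identity null (bound = input)
deviate from zero.

### Bipartite and locked-prefix tables

Bipartite enrichment counts reads containing
$\text{LEFT}\,N^s\,\text{RIGHT}$ per spacer $s$, normalizes for library
size and reports the log2 bound/input ratio. The locked-prefix table
enumerates the complete anchored universe (e.g. all $4^7 = 16384$
`UAGN7` 10mers) so ranks are a permutation by construction.

### Competition series

Competition experiments are normalized per item as
$\log_2 R_\text{fold} - \log_2 R_0$; the 0-competitor condition is the
baseline and is exactly zero. Rank depletion follows the baseline top
items (default 10) across folds; the sign convention is positive =
depleted (the rank number increased). Ranks are computed after replicate
merging. We do not assert the empirically observed enrichment *increase*
at low competitor fold as an invariant: it is a signal-to-noise effect
whose parameter regime (background binding of both proteins) is not
pinned down, though the simulator exposes the background-Kd parameter
needed to explore it.

## 2. nsRBNS

Reads are matched to the designed library by Hamming distance
(substitutions only, matching the mismatch semantics of the aligner
filters such experiments use): a read is assigned to the unique oligo at
the best distance within `max_mismatch` (default 1); ties at the best
stratum are discarded as multimappers. Oligos with fewer than 25 reads
in **either** pool are excluded — the count filter's pool scope is not
dictated by the assay definition, so it is applied to both pools (the
conservative choice) and recorded in the result's attributes.

Group comparisons are two-sided two-sample KS tests across all group
pairs with BH correction over the family; wild-type/mutant pairs are
classified at $|\Delta| > 0.5$ log2 units and tested with a paired
one-sided Wilcoxon (wt greater). All-zero paired differences yield
$p = 1$ with a warning rather than an error, so degenerate synthetic
inputs fail soft.

## 3. Secondary structure

### The builtin partition function

`compute_bpp()` implements a McCaskill-style inside/outside recursion
over nested structures in which a structure's Boltzmann weight is the
product of its pair weights, with pair energies GC $=-3$, AU $=-2$,
GU $=-1$ (arbitrary units, temperature factor 1), a minimum hairpin
loop of 3 unpaired bases, no dangles and no loop terms. This model was
chosen for *verifiability*: for sequences up to 14 nt the package's
tests compare it against exhaustive enumeration of every nested
structure and require agreement to $10^{-9}$. The external engine
(`engine = "external"`) shells out to an installed `RNAfold -p` and
parses the dot-plot pair probabilities; it is the fidelity path for
real analyses. Conclusions that depend on structure are therefore
validated as qualitative trends (which regions are more accessible),
not as absolute BPP values.

One property worth noting: with wobble pairing enabled the model is
**not** symmetric under reverse complementation, because a GU pair maps
to an unpairable AC. The symmetry holds exactly — and is tested — with
GU disabled (`energies["GU"] = Inf`).

### Structure stratification

Kmer occurrences are assigned a mean BPP over their nucleotides and
classified against the **median of their kmer identity across the whole
library**. The per-identity reference matters because kmer identities
have very different intrinsic BPP distributions (GC-rich kmers pair
more); a single global median would label composition, not context.
Ties at the median classify as less structured (the rule is a strict
greater-than), which also covers single-occurrence kmers.

The linear model regresses per-oligo log2 enrichment on the
$2 \times 4^3 = 128$ structure-stratified 3mer counts,
pruning zero-variance columns, and performs bidirectional stepwise
selection by AIC (Gaussian log-likelihood, the usual $2(p+1)$ penalty)
starting from the full model; candidate ties are resolved by R's
deterministic term ordering. Plain AIC is a liberal criterion: with
decoy features it retains any feature whose partial F exceeds roughly
2 (about a 16% rate for pure noise), so selected models are expected to
carry a tail of weak features — consistent with the dozens of features
such models retain on real libraries — while planted true features are
recovered reliably. Sparser models require a stricter penalty than AIC
by definition, not a different search.

## 4. Peak processing

Peaks are expanded to 100 nt around their center, searched for the core
motif (`TAG` in genome space) on the annotated strand, re-centered on
the occurrence nearest the original center (ties: 5'-most on the
transcript strand) and collapsed to 33 nt, so the central trinucleotide
spells the motif on the strand. Merging takes the strand-aware interval
union and re-centers through the same contract. Coordinates are BED
0-based half-open on disk and GRanges 1-based closed in memory;
rtracklayer does the conversion.

Control regions are matched by transcript region: UTR controls are
sampled uniformly within the same region of the same transcript; CDS
controls preserve the peak's distance to the nearest splice site
(candidates at mirrored distances around each internal exon boundary).
Controls never overlap real peaks, and sampling is seeded. A peak with
no eligible control is reported unmatched rather than silently matched
badly. Expression filtering is strictly greater than 5 TPM.

## 5. The synthetic-data generator

The generator defines the study conditions for every test and for the
acceptance script; its defaults are fixed once and not tuned.

**Selection model.** Each read's selection weight is the equilibrium
occupancy $\theta = c/(c + K_d)$ at its best (minimum-$K_d$) window
under a kmer $\to K_d$ map with a weakest background $K_d$; bound pools
are sampled with replacement proportionally to weight. The alternative
`sum_occupancy` rule, $1 - \prod_w (1-\theta_w)$, emulates multi-site
avidity. Best-site is the default for analytic tractability: the weight
of any read is then a closed-form function of a single window, which
the tests exploit. Competition weights follow
$(c_A/K_A)/(1 + c_A/K_A + c_B/K_B)$ at the tagged protein's best site,
so the fold-0 condition reduces exactly to plain selection (same seed
path).

**Study conditions.** The locked pool uses the 8/`UAG`/9 geometry over
20 nt. Competition folds are $\{0, 0.1, 1, 10\}$. The designed library
plants, per binding-pattern group: `CCC-UAG-N2-UAG-AUA` (shared),
`UAG-N2-UAG` (MSI-type single), `CCC-UAG-AUA` (UNK-type single), and a
lone `UAG` for controls and stop-codon oligos; mutants replace every
`UAG` with `CCG`. Ground-truth dissociation constants are 5 nM
(shared), 20 nM (single-protein), 500 nM (control, stop codon and
mutant — the background), assayed at 100 nM protein: clear but
unsaturated selection. Fluorescence polarization defaults use a
half-log titration from 0.1 nM to ~3 µM with a 20–180 mP dynamic
range, 3 replicates. The toy genome plants two-exon transcripts on
alternating strands with a strand-local `TAG` written at every peak
center and expression values spanning the 5 TPM filter boundary.

**Problem sizes.** The headline recovery checks run at $10^5$ reads
(kmer recovery, replicate correlation), $2\times 10^5$ reads per
competition pool, and $6\times 10^4$ reads per nsRBNS pool — sizes at
which the Monte-Carlo noise of every asserted quantity is comfortably
inside its tolerance while the whole suite stays interactive.

**What passing tests do and do not show.** The generator draws
uniformly random flanks, uses a single-site equilibrium model with
exact integer counts, and has no sequencing-error model (an optional
uniform substitution rate is the only corruption available), no
amplification bias, no crosslinking bias, and no cellular context.
Recovery of planted parameters therefore validates the *analytics* —
counting, filtering, normalization, ranking, fitting — not the
biological fidelity of any particular enrichment landscape. In
particular, the replicate-correlation condition uses an additive
(sum-occupancy) A/U-rich binder because a full spectrum of enrichment
values across all kmers is precisely the regime where replicate
correlation is informative; a sparse binder leaves most kmers at noise
level, where no pipeline could (or should) correlate.

## 6. Numerical choices and degenerate inputs

- Reads containing `N` are dropped and tallied, never randomly
  resolved: enrichment denominators must be unambiguous.
- Sequences are held as RNA (`U`) internally; DNA input (and `TAG` in
  genome space) is converted at the boundary.
- Kd fitting starts from the data range and the median concentration,
  runs Levenberg–Marquardt with a positivity bound on Kd, and reports a
  profile-likelihood CI when the profile converges (`NA` otherwise).
  Flat curves are rejected; fits with $\hat{K_d}$ above the largest
  assayed concentration carry a non-saturation warning flag.
- All generator randomness flows through one seeded path per call and
  the caller's RNG state is restored afterwards, so the package never
  perturbs global reproducibility.
- Subsampling for BPP profiling is seeded and capped (default 2000
  reads) because the partition function is cubic in sequence length.

## 7. Known limitations

- The builtin energy model is deliberately minimal; absolute BPP values
  are not comparable to full nearest-neighbor models. Use the external
  engine where fidelity matters.
- `match_reads()` handles substitutions only — indel-containing reads
  are unassigned by construction.
- The peak module consumes called peaks; it does not call crosslink
  sites from raw reads, and liftOver/ortholog mapping are expected to
  happen upstream.
- Competitor Kd fitting from depletion curves is out of scope; the
  competition module reports normalized depletion and rank
  trajectories only.
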