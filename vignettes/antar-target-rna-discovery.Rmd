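---
title: "Discovering ANTAR-target dual stem-loop RNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering ANTAR-target dual stem-loop RNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antarscan)
```

## The biological problem

ANTAR-domain proteins (named for the AmiR and NasR transcription
antitermination regulators) bind a conserved cis-regulatory RNA element: two
short hairpins, each capped by a hexanucleotide loop carrying an adenine at
loop position 1 (A1) and a guanine at position 4 (G4), joined by a linker of
roughly 2–25 nt. These dual stem-loop elements sit near the starts of the
genes they regulate — upstream in the 5'UTR, overlapping the ribosome-binding
site (RBS) or start codon, or just inside the coding sequence — and binding
by an activated ANTAR protein switches the downstream gene on or off.

`antarscan` implements a desk-scale pipeline for discovering and
characterizing such elements in bacterial genomes, with an emphasis on
high-GC genomes where GC-rich stems arise frequently by chance and naive
structure searches drown in false positives. Every stage is exercised
end-to-end on simulated genomes carrying planted motifs with known ground
truth.

## The motif model and bit score

The family is modeled probabilistically from a seed alignment (Stockholm
format with a `#=GC SS_cons` line describing exactly two hairpins with 6-nt
loops and at least 3 paired columns per stem):

* **Loop tables** — per-column nucleotide frequencies with a pseudocount
  (default 1.0, distributed according to the background), expressed as
  log2 odds against the background.
* **Stem tables** — frequencies of the six canonical pair types (AU, UA, GC,
  CG, GU, UG; wobble pairs are canonical) pooled across the paired columns
  of each stem, against the background pair-type probability conditional on
  canonical pairing. Pooling avoids sparse per-position tables when seed
  stems vary in length; rows whose characters do not form a canonical pair at
  a paired column are ignored.
* **Linker term** — the log2 odds of the observed linker-length distribution
  against a uniform distribution over 2–25 nt.

A candidate's **bit score** is the sum of these terms. It plays the role a
covariance-model bit score plays in profile-based RNA homology search, but
its scale is this package's own; no attempt is made to reproduce another
tool's score values. `max_score` is the score of the best admissible
candidate (stems extended to `max_stem_bp` when a pair type has positive
log-odds) and bounds every score.

The **background matters**: in a genome at 65% GC, GC stems are cheap. The
recommended (and pipeline-default) background is the scanned genome's own
mononucleotide frequencies, which deflates GC-stem scores accordingly; a
uniform background is available by flag.

### Hard curation rules

Beyond the probabilistic score, candidates must satisfy the family's
categorical constraints: hexanucleotide loops; contiguous stems of at least
3 canonical pairs; linker length 2–25 nt; and the conserved A1/G4 loop
positions with **at most one point variation across the four constrained
positions per motif** (`max_conserved_violations = 1`). Whether the single
tolerated variation applies per loop or per motif is genuinely ambiguous in
the family description; the stricter per-motif reading is the default and
the per-loop reading is reachable via `motif_constraints()`.

## Scanning and thresholding

`find_hairpins()` enumerates every (position, stem length) hairpin with a
6-nt loop — all sub-stems down to 3 bp are emitted so that the *scorer*, not
the enumerator, decides stem extent. `pair_hairpins()` assembles all ordered
hairpin pairs with an admissible linker; candidates then pass curation, the
bit-score threshold, and overlap deduplication (among spans overlapping by
more than 50% of the shorter span, the best score wins; ties go to the
leftmost start, then the + strand). Both strands are scanned and motifs may
not span an N. Genomes are stored as DNA; motif logic operates on an RNA
view.

The **threshold is calibrated, not borrowed**: the default `min_bits` is the
0.999 quantile of candidate scores observed on a composition-preserving
shuffled null (below). Calibration scores the same gated candidate stream
the scanner thresholds — structural enumeration followed by curation — so the
quantile refers to exactly the statistic it later gates. A fixed `min_bits`
can be supplied instead.

When ORF annotations are available, the scanner retains only hits lying
between 500 nt upstream and 100 nt downstream of the nearest same-strand ORF
start; without annotations all hits are emitted and the positional filter
defers to the context classifier.

## Negative controls

`shuffle_mono()` permutes sequences uniformly (exact base-count
preservation). `shuffle_di()` performs a dinucleotide-preserving shuffle via
the Eulerian-trail construction on the nucleotide multigraph: a random
last-edge arborescence toward the terminal residue, remaining out-edges
uniformly permuted, then a walk from the first residue. Every shuffle
preserves the full dinucleotide count vector and both terminal residues
exactly, and on small enumerable cases the sampler is uniform over the
reachable set within Monte-Carlo error — both properties are asserted in the
test suite.

The package's standard negative-control design shuffles each of the 30 seed
sequences 500 times (15,000 nulls) with the dinucleotide-preserving mode,
calibrates the threshold at the 0.999 null quantile, and then measures the
per-sequence false-positive rate on a fresh 5,000-sequence null.

## Genomic context classification

Each hit is joined to the nearest same-strand ORF whose start lies within
the retained window and labeled with precedence
**sequester > inside-ORF > intergenic**:

* `SEQUESTER_RBS_OR_AUG` — the flank-inclusive span (the dual stem loop plus
  10 nt on each side) overlaps the start codon or the detected RBS window.
* `INSIDE_ORF` — the motif 5' end lies after the ORF start, within 100 nt.
* `INTERGENIC` — the flank-inclusive 3' end lies 15–500 nt upstream of the
  ORF start.

Hits 1–14 nt upstream that touch neither the RBS nor the start codon fall in
the gap the three category thresholds leave open; they are reported as
`UNASSIGNED` rather than silently stretching a threshold. The flank-inclusive
upstream measure is the default; a motif-only measure is available by flag.
Same-strand ORFs only: cis-regulation implies the regulated gene is
downstream on the same strand.

The **RBS detector** scans windows of length 6, then 5, then 4 at spacers
0–15 nt upstream of the start codon and keeps AG-rich windows (at most one
non-purine, at least four purines). Among windows of the same length,
purine-perfect windows win, then the smallest spacer — without the
purine-perfect preference, any perfect 6-mer followed by a pyrimidine would
be shadowed by its own one-base-shifted window at a smaller spacer.

`find_alt_orfs()` rescues `UNASSIGNED` hits using open reading frames with
ATG/GTG/TTG starts, an in-frame stop, at least 60 nt of length and a
detected RBS at spacer 0–15; rescued calls are flagged with their altORF.
`find_terminator()` is a deliberately simple surrogate for dedicated
rho-independent terminator callers: a hairpin (stem ≥ 4 bp, ≥ 60% G/C
pairs, loop 3–8 nt) within the hit's 3' region plus 40 nt downstream,
followed within 2 nt by at least four U's in the next 8 nt. Terminator
prediction in high-GC genomes is unreliable for any method; the flag is
descriptive, not a confidence call.

## Clustering and conservation statistics

Hits are clustered by **single-linkage** on the graph whose edges connect
pairs with global alignment identity (match 1, mismatch 0, linear gap −1)
at or above the cutoff; components of size ≥ 2 are clusters and singletons
are discarded. The identity cutoff is swept from 30% to 60%. Cluster counts
rise as the cutoff rises *when every member retains at least one close
partner at the top cutoff* — a 2-member cluster can dissolve into discarded
singletons, so the monotone trend is a property of family-structured inputs
(as in the package's synthetic families), not a theorem.

**Folding** uses a weighted base-pair-maximization dynamic program (GC/CG
= 3, AU/UA = 2, GU/UG = 1; minimum loop 3 nt; no pseudoknots) with a
deterministic traceback (pairing preferred over leaving a base unpaired;
among partners, maximal span then leftmost opener). Energies are the
negative of the maximal pair weight, in surrogate units — deliberately not
kcal/mol, and any thermodynamic MFE printed elsewhere is not a target on
this scale. The DP is verified against exhaustive structure enumeration on
short sequences.

**SCI** (structure conservation index) folds the column-majority consensus
with every pair weight scaled by the fraction of rows able to form a
canonical pair at that column pair, and divides by the mean folding energy
of the individual rows. Identical rows give SCI = 1 exactly; rows with no
common pairing drive it toward 0.

**z-scores** standardize a sequence's folding energy against
composition-matched shuffles; negative z means more stable than composition
explains. The reference set for this statistic is defined by *length and
base composition*, so the default null is the mononucleotide shuffle. The
dinucleotide-preserving mode is available, but under a base-pair-maximization
energy it retains most of the pairing capacity of GC-alternating stems
(dinucleotide counts nearly determine pairing potential there), compressing
z toward 0 for high-GC motifs — a documented limitation of the surrogate
energy, not of the motifs. A homopolymer has constant shuffles and z = 0 by
convention.

**Covariation** is summarized as mutual information (bits) over the joint
nucleotide frequencies of paired columns, gaps excluded pairwise. This is a
descriptive statistic; it makes no statistical significance claim the way
dedicated covariation tests do. The advisory `functional_candidate` flag
(SCI ≥ 0.4 and mean z ≤ −0.5, both configurable) marks clusters worth manual
inspection and nothing more.

Cluster alignments use a center-star projection onto the member with the
highest mean identity (insertions relative to the reference are dropped) —
sufficient for column statistics on near-equal-length family members, and
not a general-purpose MSA.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` generates an i.i.d. background genome at a configurable
GC fraction (default 0.65, the high-GC regime of actinobacterial genomes),
lays out non-overlapping same-strand ORFs (ATG…stop with an AGGAGG RBS at a
4–10 nt spacer), and plants motifs to realize an intended context-label mix
(default 39% intergenic / 37% sequester / 24% inside-ORF, the
typical category split for this family). Every placement is verified against the real classifier at
generation time, so the emitted truth labels are consistent by construction.
All randomness derives from one integer seed and regeneration is
byte-identical.

Planted motifs are drawn from an anatomy (default: canonical A1/G4 loops,
GC-rich 6-bp stems, an inert 8-nt poly-A linker) with configurable loop and
stem mutation rates. **Stem mutations are compensatory by default** —
a mutated pair is replaced by a different canonical pair, preserving
structure — because that is how structured RNA families actually diverge
(stems keep pairing while sequence identity decays; this is the premise of
covariance-based search, and the package's own covariation statistic exists
to measure it). Pair-breaking one-sided mutations are available
(`compensatory = FALSE`) as a stress mode for the curation filter and the MI
statistic.

What the simulator does *not* emulate: realistic gene content, codon usage,
operon structure, repeats, or phylogenetic correlation between genomes.
Passing recovery tests on simulated genomes therefore demonstrates that the
scanner finds what its model defines under controlled composition and
geometry — not that the model captures everything real genomes contain.

## Problem sizes and numerical choices

The packaged validation runs at these sizes, chosen to exercise every code
path at desk scale: a 30-row seed family; a 200 kb genome at GC 0.65 with
25 planted motifs and 30 ORFs; a 15,000-sequence calibration null (30 × 500,
the standard negative-control design) and a fresh 5,000-sequence
false-positive null; 1,000 folding-oracle cases (length ≤ 12); 10,000
context-classifier geometries; identity sweeps over 0.30–0.60 in steps of
0.03.

Numerical conventions: internal coordinates are 0-based half-open with
1-based inclusive TSV/GFF3 output and 0-based BED export; quantiles use the
inverse empirical CDF (type 1), so quantile 1.0 is the maximum observed null
score; pseudocounts default to 1.0 (Laplace, background-distributed);
per-replicate RNG streams are derived from the master seed by a stable hash
of (seed, source id, replicate), so results are independent of evaluation
order; SCI drops all-gap columns with a notice; sd = 0 in the z-score
returns 0.

## Known limitations

* The surrogate energy ranks pairing quantity, not thermodynamic stability;
  folding z-scores of short GC-saturated motifs have little headroom against
  any composition-matched null (see above).
* Stems are contiguous: bulges and internal loops inside stems are not
  modeled, and pseudoknots are out of scope.
* The bit score is not comparable across profiles built from different seeds
  or backgrounds; recalibrate whenever either changes.
* The terminator surrogate imitates no published predictor's confidence
  model.
* Iterative model refinement (scan → select representatives → rebuild
  profile) is supported mechanically, but representative selection is an
  analyst's judgment the package does not automate.
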