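---
title: "Methods behind mitokit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mitokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitokit)
```

# Scope

`mitokit` implements the downstream comparative analysis that follows the
assembly of a plant mitochondrial genome — the workflow applied to the
decaploid *Camellia hainanica* mitogenome and its relatives: organelle read
baiting, repeat landscapes, codon-usage bias, C-to-U RNA-editing effects,
LWL/MLWL Ka/Ks with nucleotide diversity, and mitochondrion–plastid
homologous-fragment (MTPT) detection. Assembly itself (read correction,
graph untangling), tRNA covariance-model annotation, multiple alignment and
tree building are out of scope; the package starts from an assembled
genome, gene models and read sets.

Because the real accession and its comparator genomes require downloads,
the package carries a synthetic-data generator that emits every input with
machine-readable ground truth, plus small plain-text reference tabulations
of the published worked examples (the RNA-editing transition census, the
SSR class counts, and the homologous-fragment table for the
*C. hainanica* mitogenome, GenBank PV110147). All quantitative claims in
this vignette are computed by the test suite or `scripts/acceptance.R`.

# The shared aligner

Every alignment-driven stage runs on one engine (`build_index()`,
`local_align()`, `pileup()`): an exact k-mer index over the target set with
a repeat-shielding occurrence cap (default 200), diagonal chaining of
seeds, and gapped local extension of each seed cluster restricted to the
seed-bounded window (match +1, mismatch −2, gap open −5, extend −2). Two
fast paths matter in practice:

* a contiguous seed run on the cluster's dominant diagonal is emitted as an
  exact hit without dynamic programming when it explains ≥ 90% of the
  cluster span — this is what makes error-free long-read recruitment and
  whole-genome self-comparison tractable;
* clusters whose window would be too large for full dynamic programming
  (> 2.5 × 10⁷ cells) fall back to a gapless X-drop extension along the
  dominant diagonal.

Hit significance uses Karlin–Altschul statistics,
$E = K m n e^{-\lambda S}$ with $\lambda = 1.28$, $K = 0.46$ for the +1/−2
scheme. The thresholds the analyses quote (E ≤ 10⁻⁵) therefore refer to
this statistic, not to BLAST's; the constants are stated here because only
the threshold, not the statistic, is conventionally reported.

A practical consequence of seeding at small word sizes: random seed pairs
form chance clusters at a density that grows quadratically with genome
length. `local_align()` therefore exposes `min_seeds` and
`min_diag_seeds`; any true local similarity places consecutive exact words
on one diagonal, so requiring a handful of same-diagonal seeds prunes
chance clusters without losing real hits. Dispersed-repeat scanning uses
`min_diag_seeds = 4` at word size 7.

# Read baiting

Seeds are reads with at least one core-gene alignment *strictly longer*
than 50 bp; candidates hitting two or more distinct core genes are all
seeds, otherwise the top 20% by summed gene coverage are taken (the
published procedure ranks candidates qualitatively by "more genes, more
complete coverage"; the 2-gene/20% rule is this package's concrete
reading). Recruitment then iterates: any unrecruited read overlapping the
recruited set by *more than* 1 kb is added, to a fixed point (cap 20
iterations). "Overlap" is operationalised as a local alignment of the
stated length at identity ≥ 0.85 — the identity floor is ours, added to
prevent low-complexity chaining, and matters only for noisy reads.

# Repeat landscape

**SSRs** follow MISA semantics with class minima 1-10 2-5 3-4 4-3 5-3 6-3:
maximal exact tandem runs, complete copies only, interruptions split runs,
motifs that are repetitions of a shorter unit are reported at the shorter
unit, no canonical-strand collapsing, no compound merging. The scanner is
property-tested against a brute-force regex oracle.

**Tandem repeats** are found by k-mer recurrence voting (distances between
consecutive occurrences of the same 7-mer propose candidate periods),
followed by a maximal-scoring-segment scan of period-offset agreement
(+2 match / −7 mismatch) and column-wise scoring of each locus against its
tiled phase-majority consensus. Score floor 50, period cap 2000, report
floors copy ≥ 1.9 and percent-match ≥ 80 (the smallest values conventional
reports print). Indels inside loci are not modelled — the locus/consensus
comparison is column-wise — and TRF's stochastic (80, 10) parameters are
mapped onto this deterministic scoring; both simplifications are
deliberate. Overlapping calls at different periods are resolved by score,
then smaller period: for a perfect repeat the true period always scores
highest, which is why planted perfect repeats are recovered at exact
period and integer copy number.

**Dispersed repeats** (≥ 30 bp, word size 7, E ≤ 10⁻⁵) come from genome
self-comparison with self and near-diagonal hits removed, hits overlapping
SSR/tandem loci removed, and symmetric duplicates collapsed. Detection is
strand-symmetric (tested by reverse-complementing the genome).

All repeat scans run on the linear sequence; origin-crossing repeats on
circular molecules are not chased.

# Codon usage

RSCU for codon $c$ with amino-acid family count $N_{aa}$ and family size
$f$: $\mathrm{RSCU}(c) = (n_c / N_{aa}) \cdot f$. "Unique CDS" means
exact-sequence de-duplication before counting. Stop codons form their own
three-codon family, as organelle codon-bias reports include Ter among the
amino acids. Families with zero usage yield `NA`, not zero. Invariants
tested: family sums equal family sizes, scale invariance, totals equal
summed CDS length over three.

# RNA editing

Sites are called from RNA reads aligned to the CDS set: positions where
the reference base is C and the T fraction reaches `min_fraction`
(default 0.1) at depth ≥ `min_depth` (default 5). The published pipeline
ran a variant caller without stating thresholds; these defaults are this
package's choice and calling is threshold-monotone, so stricter settings
only remove sites. Effects are annotated from the codon context
(start-gain for ACG→ATG at codon 1, stop-gain for CAG→TAG / CGA→TGA) and
classified by hydropathy: hydrophilic {R K D E N Q H S T Y C G},
hydrophobic {A V L I P F M W}, stop its own class. The partition is
reverse-engineered from the published transition census (which fixes,
e.g., C and G hydrophilic, W hydrophobic) and extended to the residues the
census never shows (K D E N) by Kyte–Doolittle sign; the classifier
reproduces all 30 published transition rows, and the census totals
(539 sites; 12.99 / 48.24 / 0.74 / 7.61 / 30.43 percent across the five
observed categories) are recomputed exactly by `editing_summary()`.

# Ka/Ks and nucleotide diversity

Homolog pairs are aligned codon-wise: proteins by global alignment
(identity scoring, affine gaps −8/−1, C-backed), back-threaded to
nucleotides; codon columns with gaps, ambiguity or stops are dropped.

LWL classifies each codon position as 0-, 2- or 4-fold degenerate (a
change to a stop codon counts as nonsynonymous), averages site counts over
the two sequences, counts transitions/transversions per class — averaging
over all minimal substitution pathways for multi-difference codons, with
site classes taken from the two *observed* codons and pathways through
stop codons excluded (all pathways are used if every one hits a stop) —
applies Kimura-2P per class, and composes

$$K_s = \frac{L_2 A_2 + L_4 (A_4 + B_4)}{L_2/3 + L_4}, \qquad
  K_a = \frac{L_0 (A_0 + B_0) + L_2 B_2}{L_0 + 2 L_2/3}.$$

MLWL (the default, as in the published analysis) refines the 2-fold
class: sites whose synonymous change is a transversion (Arg AGA/AGG
position 1, Ile ATA position 3, Arg CGA position 1) contribute their
transversion distance to $K_s$ and transition distance to $K_a$, and the
fixed 1/3 : 2/3 split is replaced by the observed transition proportion
$r = R/(R+1)$. With no transversional 2-fold sites and $R = 0.5$, MLWL
equals LWL exactly (tested). When no substitutions are observed $r$
defaults to 1/3; a saturated Kimura-2P log argument raises a flagged
result rather than a number. $K_a/K_s$ is reported only when $K_s > 0$.

π is the dnasp-style average pairwise difference per site with pairwise
gap/N deletion, tested against hand enumeration and `ape::dist.dna`.
Shared-CDS selection keeps genes present in ≥ ⌈0.7 · n⌉ species.

# MTPT detection

Plastid–mitochondrion fragments are local alignments with E ≤ 10⁻⁵ and
identity ≥ 70% ("identity" = matches / aligned length, the BLAST
"Identical" column convention), both orientations, sorted by length
descending. Overlapping hits are merged only for coverage fractions; the
fragment list keeps distinct hits, because published tables list
IR-mediated near-duplicates separately. Gene assignment lists any
annotation overlapping a fragment by ≥ 1 bp (partial overlaps count).
Transfer-direction inference is narrative in the literature and is not
computed here.

# The synthetic-data generator

The generator defines the study conditions for all recovery tests:

* **Genome**: background drawn i.i.d. per base at the target GC (default
  0.45, matching the Camellia range), then scrubbed — windows containing
  repeats at the detection thresholds are resampled, and the bases
  flanking every planted repeat are set to break periodicity, so the
  detectors see the planted landscape and nothing else. Default scale is
  a 22 kb genome with 4 genes; tests and the acceptance script state their
  sizes explicitly, chosen so every stage is exercised at long-read scale.
* **Plans**: default SSR plans cover all six unit lengths but keep tracts
  below the tandem score floor, and tandem plans use periods ≥ 7, so the
  two detectors' truths stay disjoint. A perfect tandem locus must satisfy
  $(copies - 1) \times period \ge 25$ — below that, a score-50 detector
  cannot report it, so such plans are a planning error rather than a
  silent miss.
* **Reads**: error-free by default (an optional uniform substitution rate
  exists), sampled uniformly from the circular genome with wrap-around,
  plus labelled contaminants from independent random nuclear/plastid
  decoys. Quality modelling and realistic nanopore error profiles are
  non-goals; recovery results on these reads demonstrate the logic of the
  pipeline, not its robustness to real noise.
* **Edits**: planted at interior CDS positions; the generator forces the
  reference base to C. Sites within ~150 bp of a CDS end sit in the
  coverage taper of uniformly sampled 150 bp reads and may fall below the
  depth floor — edit plans for recovery tests therefore use interior
  codons.
* **Homologs**: synonymous changes are planted at 4-fold third positions
  and nonsynonymous changes at 0-fold sites, with per-site substitution
  probabilities obtained by inverting the Kimura-2P distance under uniform
  alternative-base choice, so the estimator's expected values equal the
  plan; realized counts are recorded. Planted Ks 0.2 / Ka 0.02 on a 10 kb
  CDS is recovered within 20% relative error.
* **Transfers**: fragments with identity ≥ 0.7 are degraded by i.i.d.
  per-base substitution (binomial-testable); fragments below 0.7 —
  planted to be *rejected* — are degraded with a maximum 10 bp clean run,
  modelling uniformly diverged sequence. Without this, a 300 bp tract at
  60% mean identity occasionally contains a ~40 bp window above 70% local
  identity that any local aligner legitimately reports. Identities below
  0.5 are refused as undetectable by design.

Determinism: identical configuration (including seed) gives byte-identical
FASTA/FASTQ output; generators restore the caller's RNG state.

# Numerical and degenerate-input conventions

External coordinates are 1-based inclusive; wrap-around exons are encoded
as `start > end` on circular molecules and refused on linear ones. ORFs
require an ATG start (editing-created ACG starts are the editing module's
concern) and include the stop codon in the ≥ 102 bp length floor. Ties in
alignment are broken by score, then leftmost target start, then leftmost
query start. Zero-SSR summaries report `NA` percentages, empty fragment
lists report zeros with an explicit empty flag, and all-N sequences refuse
composition analysis.

# Known limitations

The aligner trades Smith–Waterman optimality for seed-bounded windows; a
similarity with no intact seed word (identity well below ~0.75 at word
size 11) is invisible, which is also why sub-70% transfers are reliably
rejected. Tandem detection does not model indels within loci, so drifting
repeat arrays are reported as split or lower-match loci. The editing
caller assumes sense-strand RNA reads and reports CDS coordinates. Ka/Ks
is the LWL family only — no maximum-likelihood estimators — and the
pipeline computes statistics per input pair; the published study's
species-level census decisions (which gene copies count as the "40 PCGs")
are left to the user.
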