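---
title: "nrnbkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nrnbkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The biological problem

NrnB proteins are standalone DHH–DHHA1 nanoribonucleases: bacterial
enzymes built from exactly two domains — a DHH phosphoesterase domain
(named for its conserved Asp-His-His motif) and the associated DHHA1
domain (carrying the conserved GGGH motif) — that degrade very short RNAs
from the 3′ end. The family divides into three clades with distinct
sequence architectures: clade A carries a lysine at the diagnostic
active-site position (residue 285 in *B. subtilis* NrnB numbering) and a
long (> 100 aa), positively charged C-terminal extension; clade B carries
an asparagine at that position and a short (< 50 aa) tail; clade C is
variable at the signature position with a short tail. `nrnbkit`
operationalizes the classification of such sequences and the biochemical
polarity logic used to distinguish 3′→5′ from 5′→3′ exonucleases.

# Domain segmentation model

The package does not predict domain boundaries from structure. Instead,
boundaries are anchored on the two literal signature motifs and extended
by fixed offsets (`segmentation_offsets()`):

* DHH region end = DHH motif end + `k1` (default 10 aa),
* DHHA1 region start = GGGH motif start − `k2` (default 10 aa),
* DHHA1 region end = GGGH motif end + `k3` (default 30 aa, clamped at the
  sequence end).

The linker is everything strictly between the DHH region end and the
DHHA1 region start; the C-terminal tail is everything after the DHHA1
region. All coordinates are 1-based with closed intervals. This
parameterization is an explicit stand-in for boundaries one would read
off structural models; the synthetic generator emits sequences built with
the same offsets, so generated linker/tail lengths equal measured ones by
construction. Motif matching is exact-string: the family signatures are
the literal strings `DHH` and `GGGH`, and degenerate patterns are out of
scope. When a motif occurs more than once inside its search window, the
most N-terminal hit is primary — a deterministic tie-break. Default
search windows (`[0, 0.7]` of the length for DHH, `[0.2, 1]` for GGGH)
suppress spurious matches in the wrong half of the protein.

The standalone filter accepts a sequence iff both primary motifs are
present in N→C order and the total length lies in
`[min_length, max_standalone_length]` = [250, 700] aa by default. The cap
proxies "carries no additional domains": multi-domain relatives
(GdpP-like proteins with PAS/GGDEF extensions) are much longer than any
two-domain architecture.

# Redundancy clustering

`greedy_cluster()` emulates CD-HIT's greedy incremental algorithm:
records sorted by length descending (ties by id), each joining the first
cluster whose representative it matches at or above the identity
threshold, else founding a new cluster. Choices that follow the tool the
workflow names:

* identity denominator = length of the shorter sequence;
* inclusive threshold (identity exactly at the cutoff joins), matching a
  `-c`-style ≥ comparison;
* defaults 0.70 (prokaryote-style reduction) and 0.90 (eukaryote-style).

Identity itself is computed from the package's optimal global alignment,
not from a heuristic banded alignment. The k-mer prefilter is an
admissible bound (matched residues form runs; each interruption destroys
at most k−1 shared words), so enabling it never changes the result — a
tested invariant.

# Alignment

The pipeline carries its own aligner so that no external tool is
required: pairwise global Needleman–Wunsch/Gotoh with affine gaps (a gap
of length L costs `open + (L-1)·extend`, defaults 10/1, BLOSUM62), and a
progressive multiple aligner that merges profiles in the post-order of a
UPGMA guide tree built on fractional shared-k-mer distances
(`1 − |shared| / min(count)`, k = 3). The profile–profile column score is
the frequency-weighted mean substitution score; gap mass contributes
zero. Numerical determinism choices: trace-back ties resolve
diagonal > up > left; UPGMA ties resolve by lexicographic cluster label;
terminal gaps are scored like internal gaps (a documented
simplification). An externally produced alignment can be imported
(`read_alignment_fasta()`) for parity runs with MUSCLE/ClustalO-class
tools.

Columns whose gap fraction is *strictly greater* than 95% are removed
before tree building. The strict reading means a 100-row column with
exactly 95 gaps is retained; provenance of retained columns is kept in
`source_column_map`, and the filter is idempotent.

# Tree inference and clade extraction

Distances come from the filtered alignment with pairwise deletion
(mismatches over columns where both rows are non-gap), optionally
Poisson-corrected (`d = −ln(1 − p)`; saturated pairs are clamped at
`p = 1 − 10⁻³`, i.e. d ≈ 6.9, to keep the matrix finite). Trees are built
with neighbor joining (the canonical `ape::nj` implementation) with
negative branch lengths clamped to zero. This distance/NJ route is a
deliberate, documented substitution for maximum-likelihood inference with
model selection, which needs external tools; on strong-signal data the
two agree at topology level, and that is the level this package tests.

Midpoint rooting is implemented in-package: the root is placed halfway
along the longest leaf-to-leaf path; if the midpoint falls exactly on a
node the tree is rooted there without inserting a zero-length edge; ties
between equally long paths break by lexicographic leaf-pair order; a tree
with all-zero branch lengths roots at the first internal node with a
warning. Bootstrap support resamples alignment columns with replacement,
rebuilds the NJ tree per replicate and reports the recovery fraction of
each original bipartition (default 1000 replicates; seeded). Inside
bootstrap replicates a resampled pair with no comparable columns is
assigned the model's distance ceiling instead of erroring, so seeded runs
are total; in direct use `distance_matrix()` errors and names the pair.
When the support-labelled tree is re-rooted, node labels travel with the
internal vertices (the standard, slightly lossy convention for labels
that really describe bipartitions).

The notion of a "major clade" — read off trees by eye in comparative
studies — is formalized here: depth-first from the root, a node is
reported when its subtree has at least `clade_min_size` leaves (default
5) and the mean pairwise leaf path length within the subtree is at most
`clade_tightness` (default α = 0.5) times the whole-tree mean.
Descendants of reported nodes are skipped, so reported sets are disjoint.
A star tree has no substructure and yields no clades under the default α.

# Conservation profiles and the clade classifier

Per-column Shannon entropy uses log base 2 and excludes gaps from the
frequencies (gap fraction is recorded separately; `X` is treated as
unknown and excluded from the 20-letter simplex). Information content is
`log2(20) − entropy`, and logo letter heights are frequency × information
content. The choice of base and gap handling is the package's own; both
are stated in every output.

Classification works on single sequences without a tree. Feature vector:
linker length, tail length, the residue in the alignment column anchored
to reference position 285, the tail's K+R fraction and (K+R)−(D+E) net
charge. Scores are unweighted indicator sums:

* `score_A = [sig = K] + [tail > 100 aa] + [K+R fraction ≥ 0.15]`
* `score_B = [sig = N] + [tail < 50 aa]`
* `score_C = [sig ∉ {K, N, gap}] + [tail < 50 aa]`

The call is the argmax clade iff it beats the runner-up by `min_margin`
(default 1), else `unclassified`. Transparency over tuning: every fired
rule is reported as evidence. A gap at the signature column is missing
evidence and deliberately does not count for clade C's "other residue"
rule. The "positively charged patch" — in reality a structural,
surface-electrostatics observation — is proxied by the tail K+R fraction
with a 0.15 default cutoff. Linker binarization (long iff strictly
> 200 aa) is exposed as an annotation (`linker_class`) but is *not* a
classifier rule, because the mapping between linker classes and specific
clades is only shown graphically in the source analyses and was never
stated as a rule.

# Assay logic

The degradation-ladder model is product-identity only: processive
single-residue removal from the acting end, with a cleavage step
forbidden when it would sever a blocked (phosphorothioate) linkage. With
a block at linkage *i* (joining residues *i* and *i*+1), 3′→5′ processing
stalls at the 5′ prefix of length *i*+1 — the worked 20-mer with a block
at linkage 10 stalls at the 11-mer — while 5′→3′ processing releases the
labeled 5′ mononucleotide first and stalls at the suffix starting at
residue *i*. No rate modeling is attempted (none is available to model),
and slow read-through past a block is not simulated. Polarity inference
is the inverse mapping: proper 5′ prefix → 3′→5′; proper 3′ suffix →
5′→3′; identical → no processing; both (repeated termini) → ambiguous;
neither → inconsistent.

Depletion traces are normalized to the first time point (which must be
positive), making the output invariant to detector gain. The phosphate
standard curve is ordinary least squares of absorbance on concentration;
inversion flags extrapolation beyond the calibrated range. The c-di-AMP
stoichiometry helper returns the upper bound on phosphatase-released
phosphate: 0 per molecule for intact c-di-AMP, 1 for linearized pApA, 2
for complete processing to AMP. Measured releases (for example the ~10 µM
scale seen for positive-control enzymes at 20 µM substrate) are
experimental quantities that the package only bounds, never predicts.

# The synthetic generator: what it emulates, and what it does not

`generate_dataset()` builds one archetype per clade on a fixed
architecture — 140 aa N-terminal region, DHH at 141–143, 10 aa of DHH
filler, a clade-specific linker, a shared 10-aa active-site block whose
last residue is the clade signature, GGGH, 30 aa of DHHA1 filler, and a
clade-specific tail. The clade-A archetype's linker is fixed at 122 aa so
that its signature residue sits at position 285, mirroring the reference
numbering; that archetype is emitted unevolved as `NrnB_ref`. Families of
20 leaves (default) evolve along Yule subtrees; per-site substitutions
are Poisson events (uniform replacement over the other 19 residues), with
motif and signature positions mutating at 1% of the base rate.

Parameter choices and why:

* substitution rate 0.05 /site/branch-unit — the module's stated default;
* family depth 10 — calibrated so that expected within-family divergence
  (~0.45–0.50) sits safely below the 0.70 clustering threshold, keeping
  enough representatives per family for clade extraction. A first guess
  of depth 5, based on a crude 2×depth path approximation, left median
  within-family identity above 0.70 in the actual Yule geometry and was
  corrected to realize the intended "three well-separated families"
  regime before any acceptance expectation was frozen;
* root branches of 5 joining the families — between-family sequence
  content is independent anyway, so these only shape the true tree;
* clade linker ranges (A 120–180, B 60–120, C 40–90) are inventions: all
  below the 200 aa binarization boundary, which the generator therefore
  does not exercise by default (crafted fixtures in the tests do);
* tail ranges (A 105–160; B/C 10–45) place every clade on the correct
  side of the 100/50 aa rules, and tail K+R enrichment 0.30 (A) vs 0.05
  (B/C) keeps clade A above the 0.15 positive-fraction cutoff even after
  substitutional decay.

What a green test on this generator establishes: that the pipeline's
machinery — scanning, clustering, alignment, tree building, clade
extraction, classification — recovers planted structure under a
substitutions-only model. What it does not establish: performance on real
families with indels, domain rearrangements, compositional bias,
long-branch attraction, or databases at real scale; none of those are
simulated. Because protected positions still mutate at a small positive
rate, a few leaves per dataset may lose a motif and (correctly) fail the
standalone filter — the generator guarantees a ≥ 95% pass rate in
practice, not 100%.

Truth labels ride in FASTA descriptions and a sidecar TSV; the analysis
pipeline never reads them — they exist only for tests and scoring.

# Known limitations

* NJ on Poisson-corrected distances, not maximum likelihood; no model
  selection, no rate heterogeneity.
* The progressive aligner has no iterative refinement; alignments of
  low-identity regions are approximate (import an external alignment for
  publication-grade work).
* Exact-string motif scanning misses divergent signatures by design.
* The classifier is a transparent rule score, not a trained model; its
  thresholds encode reported clade descriptions, not fitted boundaries.
* Newick parsing delegates to `ape` after a bracket-balance pre-check;
  only imbalance errors carry a character offset.
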