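---
title: "Methods: ancestral karyotypes, rearrangements, and discordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestral karyotypes, rearrangements, and discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(karyevol)
```

This vignette documents the models behind `karyevol`, the parameters that
matter, the numerical choices made where conventions diverge, and the
limits of what the package's simulation-based validation demonstrates.

## 1. The reconstruction model

The package treats a genome as ordered lists of gene families; base-pair
coordinates never enter. Synteny between two chromosomes is summarized by
collinear blocks: maximal chains of same-family gene pairs whose
positions increase strictly in both genomes (or increase in one and
decrease in the other; orientation −1), with at most `max_gap`
intervening genes between consecutive anchors on either side and at least
`min_anchors` anchors. Chains are extracted greedily by repeated longest
chain dynamic programming with anchor removal, so duplicated regions of a
polyploid genome contribute one block per copy. The thresholds
(`min_anchors = 5`, `max_gap = 25`) are the package's declared defaults —
block-detection tools generally leave these to the user, and results are
insensitive to them on chromosome-scale data; both are exposed
everywhere.

For chromosomes $i, j$ the collinearity ratio is
$x_{ij} = 2\,CN_{ij} / (N_i + N_j)$, with $CN_{ij}$ the anchor-pair count
over all retained blocks and $N$ the chromosomes' gene counts. Counting
anchor *pairs* (not genes) makes $x = 1$ exactly for identical
chromosomes. Ratios are Z-transformed row-wise,
$Zx_{ij} = (x_{ij} - \mu_i)/\sigma_i$, with $\mu_i, \sigma_i$ the mean
and sample (n−1) standard deviation of row $i$'s off-diagonal entries;
the diagonal (a chromosome against itself) is excluded from both the
matrix and the moments, since self-identity carries no grouping
information. Row-wise standardization makes $Zx$ asymmetric; it is
symmetrized by the arithmetic mean before clustering. A row with zero
spread is an error by design: such a chromosome cannot be placed.

Chromosomes are clustered by average-linkage hierarchical clustering on
the distance $\max(S) - S$, $S = (Zx + Zx^\top)/2$. The number of
clusters is either fixed or chosen to maximize mean silhouette width over
$k \in [2, 15]$. Average linkage plus silhouette selection is a
deterministic, documented choice; the recovery tests (below) are the
criterion by which it is justified, and any user can substitute a fixed
$k$.

Each cluster's reference is its member with the highest mean collinearity
ratio to the other members (ties: larger gene count, then lexicographic
id). Augmentation then walks every other cluster member: for two
adjacent anchors inside one block, if the donor carries 1–5 genes between
them, the families not yet present are inserted immediately before the
right anchor, in donor order, reversed for orientation −1 blocks (the
natural reading of a reversed segment; flagged because conventions could
differ). Donors are processed in decreasing collinearity to the
reference so the most reliable donor wins collisions; families already
present are skipped, keeping each ancestral chromosome a duplicate-free
total order. Anchor pairs whose reference positions have been crossed by
earlier insertions are skipped and counted rather than fatal.

Projection paints a target genome by assigning every anchored gene the
ancestral chromosome and index of its anchor (highest-scoring block wins;
ties to the lower ancestral index). Unanchored genes flanked within 10
genes on both sides by anchors of one ancestral chromosome inherit it
with a linearly interpolated fractional index — this keeps paintings
nearly gapless without ever reordering anchors. Segments are maximal
same-origin runs (unassigned genes are transparent); runs shorter than
`min_seg` are dropped and their neighbours merged. `min_seg = 10` is the
default for fractionated real-scale data; clean, loss-free simulations
are segmented with `min_seg = 2` since there is no noise to smooth.
Copies of one ancestral chromosome are grouped greedily — largest unused
segment seeds a copy; segments joining it must overlap its covered
intervals by < 20% of their own span — then ranked by completeness
(distinct families covered / ancestral family count) and labelled A, B,
C…, ties broken by target chromosome id. Completeness ranking is the only
biologically anchored part of copy labelling; the grouping rule is this
package's answer to a genuinely underdetermined problem (interleaved
segments admit several defensible groupings) and its threshold is a flag.

## 2. Fusion classification and shared-fusion testing

Fusion calls read the segment string of each derived chromosome:
X–Y–X is a nested fusion (NCF) when the X pieces jointly cover ≥ τ of X
and Y covers ≥ τ of Y; X–Y is end-end joining (EEJ) when both cover ≥ τ
and all four extremities map within `end_eps` genes of ancestral termini;
two chromosomes holding complementary pieces of X and Y (pairwise overlap
≤ `end_eps`, joint coverage ≥ τ) are one reciprocal translocation (RTA).
Defaults τ = 0.8, `end_eps` = 10 replace what is otherwise a visual
dot-plot judgement; both are flags. A junction is the inter-gene position
between the last assigned gene of one segment and the first of the next.
Junctions closer to a terminus than one block (≈ `min_anchors` genes) are
below the method's resolution — an arm shorter than a detectable block
cannot anchor — so simulations probing junction recovery draw breakpoints
with a 10-gene margin from the ends.

Two species share a fusion (inherited) rather than repeating it
(parallel) when a collinear block between them runs continuously through
the junction in both genomes — anchors strictly on both sides of each
junction within one block — and the two junctions sit within `window`
(default 10) anchored genes of each other inside that block. The test is
evaluated in both directions and symmetrized; a fusion compared with
itself is shared by definition.

## 3. Polyploidy inference

Syntenic depth tiles one genome into non-overlapping 20-gene windows and
counts distinct blocks of the other genome covering each window midpoint;
the modal count over covered windows, read in both directions, is the
depth ratio (2:1 after one unshared WGD, 2:2 for independent WGDs, and so
on). Ks values are summarized per block by the exact median and fitted on
the log scale with 1–4 component Gaussian mixtures (EM from seeded
k-means starts, component count by minimum BIC, modes reported as
$e^{\mu}$). Fitting log-Ks rather than raw Ks reflects the right skew of
synonymous-divergence distributions. The collinear gene-tree test roots
each tree on a randomly chosen copy of one species (the rooting species
alternates deterministically with tree index so neither dominates) and
scores the tree as supporting independent polyploidy iff the other
species' retained copies are monophyletic; trees lacking the required
copies are skipped and reported.

## 4. Discordance decomposition

Per-node gene-tree support is the fraction of (pruned) gene trees whose
unrooted splits contain the node's bipartition restricted to shared taxa,
with per-node denominators counting only informative trees. The
coalescent parameter is $\theta = 2m/d$ from a branch's mutation-unit
length $m$ and coalescent-unit length $d$ (derivation: $d = t/2N$,
$m = \mu t$, so $2m/d = 4N\mu$); the constant is exposed since only the
inputs, not the constant, are conventionally fixed. The reticulation
index samples, per node, up to 200 taxon triplets spanning the node's
three subtrees, counts the two minor (discordant) rooted-triplet
topologies in observed trees, and tests their asymmetry. Without a null
set the test is goodness-of-fit against exact equality; with ILS-only
trees simulated on the same species tree it is a 2×2 contingency
chi-square of observed versus simulated minor counts — the contingency
form absorbs the sampling noise of the null simulation, which a fixed
expectation would turn into false positives. P-values are BH-corrected
within each node and the index is the rejected fraction; because the
field's aggregation convention is ambiguous, the mean raw asymmetry
$|m_1 - m_2|/(m_1 + m_2)$ is emitted alongside. Estimation error is
isolated by simulating alignments on the fixed species tree (so all
discordance is reconstruction noise), rebuilding trees by neighbor
joining on Jukes–Cantor distances, and scoring bipartition recovery;
neighbor joining on model-corrected distances replaces maximum-likelihood
rebuilding as a desk-scale tree estimator that preserves the construct
(finite-data estimation error). Saturated replicates (mismatch fraction
≥ 3/4) are skipped and tallied, never truncated. The lmg decomposition
averages each predictor's R² increment over all predictor orderings via
the subset-weight identity; shares sum to the full-model R² to machine
precision, and the implementation is validated in the tests against an
independently coded all-orderings enumerator.

## 5. The simulator and what validation does (not) show

The simulator evolves a single-copy ancestor (default 7 chromosomes — the
canonical ancestral eudicot karyotype size — with 100–200 genes each)
along a species tree. Polyploidy duplicates or triplicates every
chromosome; the progenitor copy of each gene is always kept and each
extra copy is retained independently with probability `retention`
(vector-valued for biased subgenome fractionation). Fusions implement
EEJ (tail-to-head by default; other end combinations reverse the joined
segment, since end polarity is not biologically constrained), RTA and
NCF; fissions and inversions complete the repertoire. Coordinates are
0-based half-open throughout, which makes splits and joins unambiguous.
Every event is recorded fully concretely — including realized
fractionation outcomes — so replaying the log reproduces each tip genome
byte-for-byte; this replay identity is a tested invariant. Event ages
are user-specified scalars rather than clock draws because Ks emission
needs controllable separation between events. Ks values are lognormal
around `age × ks_per_age` with coefficient of variation `cv`.

Gene trees are sampled under the multispecies coalescent (rate
$\binom{k}{2}$ per branch in coalescent units); introgression reroutes
each recipient lineage with probability γ to the donor's path from the
tips — a strong-recent-gene-flow approximation that produces the
asymmetric minor triplets the reticulation index detects, without
modelling the timing of the flow. Sequences evolve site-independently
under GTR (normalized to one expected substitution per unit branch
length, optional 4-category discrete gamma rates); the simulator is
checked against the matrix exponential of its own generator and against
stationarity limits.

The standard six-genome test scenario (`moderate_scenario()`) gives every
lineage one polyploidization (four WGD, two WGT), 0–2 fusions covering
all three kinds, and a few inversions, at retention 0.7. Tests and the
acceptance checks run at 60–200 genes per chromosome and 500–2000 gene
trees; these sizes were chosen so each property is measured well inside
its stochastic tolerance while the whole suite stays interactive.

What passing these tests shows: the implementation is internally
consistent, matches closed forms and independent oracles, and recovers
the generator's ground truth under realistic amounts of fractionation
and rearrangement. What it does not show: robustness to features the
generator omits — tandem duplications and segmental (non-whole-genome)
duplication, gene family expansion, annotation error and missing genes,
translocation of small segments, rate variation across lineages in Ks,
and gene-tree estimation error correlated with tree content. Real
analyses should treat the declared thresholds as starting points and
inspect dot plots (`plot_dotplot()`) and ideograms (`plot_ideogram()`)
alongside the automated calls.

## 6. Known limitations

* Fractionation in the simulator never removes the progenitor copy, so a
  family can never be lost outright; real fractionation can delete all
  copies, which lowers attainable reconstruction recall.
* The reconstruction assigns each chromosome to exactly one ancestral
  cluster; a fused chromosome is clustered with whichever component
  dominates its collinearity profile, and its minority component is
  recovered only through augmentation and painting.
* The shared-fusion test requires junctions resolvable by anchored
  blocks on both sides; heavy post-fusion rearrangement around a
  junction pushes the test toward "independent".
* The reticulation index localizes gene flow to nodes, not to specific
  donor–recipient edges, and its two published aggregation conventions
  (rejection fraction vs raw asymmetry frequency) can differ; both are
  reported.
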