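# karyevol

Tools for reconstructing ancestral karyotypes from gene-order data and for
dissecting the processes — polyploidy, chromosome fusion, incomplete
lineage sorting, hybridization — that reshape plant genomes. The package
targets the kind of analysis done on early-diverging eudicots, where a
small set of ancestral chromosomes (classically seven) persists, shuffled
and multiplied, inside extant genomes; everything is equally usable on any
clade with chromosome-level gene orders.

## What it does

**Ancestral karyotype reconstruction.** Collinear blocks (chains of
same-family gene pairs monotonic in both genomes) are detected between all
chromosome pairs of a set of genomes. For chromosomes *i*, *j* the
collinearity ratio

&nbsp;&nbsp;&nbsp;&nbsp;*x*<sub>ij</sub> = 2·CN<sub>ij</sub> / (N<sub>i</sub> + N<sub>j</sub>)

(CN = collinear gene pairs, N = chromosome gene counts) is Z-transformed
row-wise, *Zx*<sub>ij</sub> = (*x*<sub>ij</sub> − μ<sub>i</sub>)/σ<sub>i</sub>,
and the chromosomes are clustered (average linkage; silhouette-selected
*k*) into ancestral groups. Each group's most complete chromosome becomes
the reference and is augmented with the short (≤ 5 gene) runs its
relatives retain between adjacent anchors, yielding one ordered family
list per ancestral chromosome. Projecting these onto a genome paints every
chromosome as a mosaic of ancestral segments, with multiple copies ranked
by completeness and labelled A, B, C, …

**Rearrangement classification.** From segment patterns the package calls
fusion types — end-end joining (EEJ, X then Y), reciprocal arm
translocation (RTA, complementary X/Y pieces on two chromosomes), nested
chromosome fusion (NCF, X–Y–X) — plus rare fissions, and decides whether
two species share a fusion or acquired it in parallel by asking whether
collinear blocks run continuously through both junctions.

**Polyploidy inference.** Syntenic depth ratios (modal block coverage per
20-gene window; 2:1 after one unshared WGD), per-block median Ks with
log-scale Gaussian-mixture peak fitting (EM, BIC-selected component
count), and a collinear gene-tree test: root each tree on one species'
copy and ask whether the other species' copies are monophyletic —
the signature of independent polyploidizations.

**Discordance decomposition.** Per species-tree node: gene-tree
bipartition support; θ = 2m/d from mutation-unit and coalescent-unit
branch lengths (high θ = high expected ILS); a reticulation index from
chi-squared tests of minor-triplet asymmetry against ILS-only coalescent
simulations; estimation-error support from GTR sequence simulation plus
neighbor-joining rebuilding; and an lmg decomposition attributing
gene-tree variation to the three causes.

**Simulator.** All of the above is testable without external data: a
genome-evolution simulator applies WGD/WGT with fractionation, the three
fusion types, fissions and inversions along a species tree (with an exact
replayable event log), samples gene trees under the multispecies
coalescent (optionally with introgression), evolves sequences under GTR,
and emits Ks values clustered around event ages.

## Worked example

```r
library(karyevol)

# six genomes from a 7-chromosome ancestor: every lineage polyploid,
# fused and inverted, duplicate retention 0.7
ds <- moderate_scenario(retention = 0.7, genes_per_chrom = 100, seed = 1)

cm <- z_normalize(collinearity_matrix(ds$tips))
cl <- cluster_chromosomes(cm, k = "auto")
cl$k
#> [1] 7            # the ancestral chromosome number, recovered

aek <- build_aek(ds$tips, k = cl$k)
nrow(aek)
#> [1] 700          # all 700 ancestral families recovered

pg <- paint_genome(aek, ds$tips$S1)
head(pg$copies, 4)
#>   aek_chrom copy completeness n_segments n_genes
#> 1         1    A         1.00          1     100
#> 2         1    B         0.68          1      68
#> 3         2    A         1.00          1     100
#> 4         2    B         0.70          1      70

classify_fusion(pg$segments, table(aek$aek_chrom))
#> fusion_calls: 1 call(s)
#>   EEJ on c4_c7x2 [7A, 6B]
```

The copy table reads as a subgenome inventory: after the simulated WGD,
each ancestral chromosome is present as a complete copy (A) and a
fractionated copy (B, ~70% of families). The fusion call identifies the
end-end joining the scenario applied on the S1 branch, naming the two
ancestral chromosome copies that were joined.

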