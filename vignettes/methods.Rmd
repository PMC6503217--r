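---
title: "Methods: genomic clusters, the divergence continuum, and symbiotic-plasmid transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic clusters, the divergence continuum, and symbiotic-plasmid transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Rhizobia — nitrogen-fixing symbionts of legumes — carry multipartite genomes:
a chromosome plus several large plasmids, one of which (the symbiotic
plasmid, pSym) carries the nodulation (*nodABC*) and nitrogen-fixation
(*nifHDK*) genes and is known to move horizontally between strains. Whether
whole-genome identity clusters (ANI clusters) in such genera correspond to
species, or are merely points on a continuum of divergence, is an open
question. This package implements the comparative-genomics workflow used to
ask that question: pairwise average nucleotide identity (ANI) and genome
coverage against core-genome genetic distance; threshold-based genomic
cluster calling; consensus pangenome structure; plasmid families from Rep
replication proteins; and synonymous-rate contrasts between chromosome and
pSym that expose recent plasmid acquisition.

Because the original result rests on a large public genome collection that
cannot be redistributed, every stage here is validated instead against a
genome-evolution simulator whose ground truth (tree, divergence, family
content, transfer events) is known exactly. The statements the package can
make are therefore of the form "on data with the assumed structure, the
method recovers the truth"; they are not re-estimates of the original
collection's numbers.

# The simulator and what it emulates

`sim_config()` / `evolve_collection()` generate a clonal collection:

* **Species tree.** Either a user tree or a Yule (pure-birth) tree
  (`simulate_tree()`; rate `birth_rate`, default 1). Trees are ultrametric, so
  "contemporaneous lineage" is well defined for transfer events.
* **Replicons.** One chromosome (default 1 Mb) carrying `n_core_genes`
  (default 120) core families, the first `n_marker_genes` (default 58, the
  ribosomal-protein analog set) tagged `ribosomal`; plasmids per
  `plasmid_plan` (default one 200 kb conserved plasmid and one 250 kb pSym
  carrying tagged nodABC/nifHDK analogs). Every plasmid carries RepC and RepB
  genes drawn from an independent random ancestral sequence per plasmid, so
  Rep lineages identify plasmid families. Genes are stop-free random codon
  sequences (gamma-distributed lengths, mean 300 codons, minimum 60);
  intergenic spacers fill each replicon to its planned length and evolve
  neutrally like everything else.
* **Substitution.** JC69 at every site: on a branch of length *t* each site
  changes with probability 3/4(1 − e^(−4·r·t/3)) (`subs_rate` r, default
  0.05/unit), the changed base uniform over the other three. Inside genes,
  mutations that would create an internal stop codon are reverted (<1% of
  proposals), keeping simulated proteins translatable; the effect on
  realized nucleotide divergence is far below the tolerances used anywhere.
  JC69 was chosen because one model then drives both the ANI continuum
  (identity after distance d is exactly 1/4 + 3/4·e^(−4d/3)) and the Ks
  analysis, with closed forms available for validation.
* **Gene content.** A finite accessory pool (default 200 families). Presence
  of each family along each lineage is a two-state Markov process with gain
  rate 0.2 and loss rate 1.0 per unit branch length (equilibrium occupancy
  1/6), started at equilibrium; gained copies are inserted from the pool's
  ancestral sequence, biased 3:1 toward plasmids. Core, plasmid backbone,
  nod/nif and Rep genes are exempt from loss. The finite pool keeps family
  truth well defined for recovery tests.
* **pSym transfer.** At rate `psym_transfer_rate` per lineage per unit length
  (or at planted times via `forced_transfers` /
  `simulate_transfer_pair()`), the recipient's entire pSym replicon —
  sequence, genes, and any accessory families riding on it — is replaced by
  a copy of a uniformly chosen contemporaneous donor's pSym. Immediately
  after the event the two copies are byte-identical, then diverge; a
  genealogy of pSym copies is kept so the true pSym divergence of every
  genome pair is exact.

What the simulator deliberately does **not** model: recombination within
genes, rearrangements and indels (other than whole-gene gain/loss), selection
(so protein divergence tracks nucleotide divergence — see the Ks section),
codon-usage bias, and draft-assembly fragmentation. Passing tests therefore
show correctness of the algorithms under neutral, structurally clean
divergence; they do not certify behaviour on, say, highly recombinogenic real
data.

# ANI engine

`compute_ani()` follows the fragment convention of JSpecies-style ANIb: the
query is cut into consecutive 1020 bp windows (fragments never cross replicon
boundaries; a trailing fragment ≥ 100 bp is kept), each window is placed at
its best location in the target by exact 15-mer seeding (most-voted diagonal,
both strands, at least 2 seeds required) and aligned by a banded local
alignment (band 32, match +1 / mismatch −1 / gap −2). A fragment is retained
when its identity (matches over aligned columns) is ≥ 30% across ≥ 70% of its
length. ANI is the plain mean identity of retained fragments; the
length-weighted mean is also reported ("anim-like") and correlates with the
plain mean at Spearman ρ > 0.99 on simulations, mirroring the known
ANIb/ANIm agreement. Coverage (Gcov) is the retained fragment length over the
query length; the directed values and their pair mean are all reported (the
mean is the symmetric value used downstream — the symmetrisation convention
is ours, as is the query-based Gcov denominator).

Numerical behaviour worth knowing: the k-mer seed bound, not the 30% identity
gate, is what excludes random sequence (a random 1 Mb pair yields Gcov ≈ 0);
sensitivity is ample for ANI ≥ 80%, the range the analysis uses. On simulated
JC69 pairs of 1 Mb at d ∈ {0.005, …, 0.08} the symmetric ANI sits within
0.1 percentage points of the closed form, against a 0.5-point acceptance
band.

`register_matches()` reuses the same seeding to report all local alignments
longer than 300 bp between two replicons (both strands, 0-based half-open
coordinates), and `replicon_conservation()` turns them into merged-interval
coverage — the plasmid-conservation measure.

# Homology, clustering, and the consensus core

`align_proteins()` is an exact Smith–Waterman with BLOSUM62 and affine gaps
(open 11, extend 1; a gap of length L costs 11 + L). It is implemented in
C++ for the all-vs-all throughput BDBH needs and is cross-checked in the
tests against both a full-matrix R implementation and
`Biostrings::pairwiseAlignment`. Identity is counted over aligned columns
(gaps included, BLAST-style); coverage is the aligned span over each
sequence's length, or over the larger length for the 60/60 marker rule — the
two coverage readings the thresholds distinguish.

For collection-scale all-vs-all work the batch aligner skips the dynamic
program for pairs in which both proteins are at least 100 residues long yet
share no 6-residue word — the usual word-seeding shortcut. Pairs clearly above
the 50% identity gate share such words with overwhelming probability, so the
gated results are unchanged (a test asserts exact agreement with the
unfiltered computation); like any word-based search, sensitivity right at the
gate is seed-limited.

`bdbh()` keeps a hit when identity ≥ 50%, coverage ≥ 50% (of each sequence),
and raw score ≥ 50. The raw-score floor stands in for the customary e-value
cutoff: on shuffled-sequence nulls at typical bacterial protein lengths
(100–500 aa), local BLOSUM62 scores above 50 occur with probability well
below 1e-6, which is all the e-value gate is asked to do here. Best hits are
by score, ties broken by identity then lexicographic target id; an edge
requires reciprocity.

`mcl_cluster()` is the standard Markov Cluster iteration on a
column-stochastic sparse matrix: expansion (squaring), inflation (elementwise
power 1.5 — the GET_HOMOLOGS-style default; the original text does not state
one), pruning at 1e-5, convergence at a maximum entry change of 1e-9. Self
loops are set to each node's maximum incident weight; with the weak unit
loops sometimes used instead, a two-node clique with a heavy edge oscillates
between the odd and even powers of the walk and splits, which is why the
max-weight convention is used. Clusters are connected components of the
converged non-zero structure, which makes the output invariant to node
order.

`consensus_core()` implements the strict intersection reading: a family is
consensus-core only when a BDBH component and an MCL cluster contain the
*identical* gene set and that set has exactly one member per genome. A family
lost in one genome, or split differently by the two methods, is excluded.

# Pangenome curves and profiles

`pangenome_curves()` permutes genome order (20 permutations by default),
accumulates core(n) (families in all of the first n) and pan(n) (families in
any), and fits the medians: pan to Heaps' law K·nᵞ and core to
A·e^(−n/τ) + C, both by Levenberg–Marquardt least squares started from the
log-log regression (the fit falls back to the log-log estimates if the
nonlinear step fails). γ > 0 reads as an open pangenome; on simulations γ is
positive exactly when the gain rate is.

`map_symbiotic()` first collapses the reference protein set by MCL at the
50/50 gates (one representative per cluster — the "non-redundant symbiotic
families" step), then maps each representative to a gene family by reciprocal
best hit; the family's genome presence becomes the reference's profile row.
`order_profiles()` orders genomes by UPGMA (average-linkage `hclust`) on
pairwise Bray–Curtis dissimilarity Σ|x−y|/Σ(x+y), with columns pre-sorted by
label so ties break deterministically.

# Marker phylogenetics

`extract_markers()` collects the tagged marker genes (families by simulator
truth when available, otherwise BDBH at 60% identity / 60% coverage of the
larger protein) and keeps only families present exactly once in every genome.
Simulated markers are gap-free and equal-length, so alignment is trivial;
real data must arrive pre-aligned (progressive alignment is out of scope and
the function says so rather than aligning badly). `trim_columns()` implements
complete deletion (every column containing a gap or unknown is removed) plus
a gap-fraction alternative.

`pairwise_distance()` offers the Poisson correction d = −ln(1 − p) and the
Kimura protein correction d = −ln(1 − p − p²/5) on the fraction of differing
sites p, flagging saturated pairs. A full ML JTT distance is deliberately not
implemented: the continuum analysis needs a monotone distance, not a specific
model, and on simulations the Poisson distance is monotone in the true
divergence throughout the range used.

`nj_tree()` is standard Saitou–Nei neighbor joining with the Studier–Keppler
Q-criterion, deterministic tie-breaking by the lexicographically smallest
label pair, and negative branch lengths clamped to zero with the deficit
moved to the sister edge so path lengths are preserved; on additive matrices
it reproduces the generating tree exactly (RF 0, branch lengths to 1e-9).
ML tree search is intentionally replaced by NJ on corrected distances: the
downstream claims re-validated here depend on topology and monotone
distances, and NJ is deterministic, fast and exactly testable.
`rf_distance()` counts non-trivial bipartitions present in exactly one
(unrooted, possibly multifurcating) tree.

`filter_markers()` is the stand-in for the published recombination/topology
marker screen, whose internals (density-based tree outlier tests, support
thresholds) are not specified in the source text: each marker gets an NJ
tree; the majority-rule consensus of all marker trees is the reference;
markers whose RF distance to the consensus exceeds the 0.75 quantile of all
marker RF values are dropped. On clean simulations most markers are retained
(noisy short markers may be sacrificed — the filter is conservative by
construction); a single planted cross-clade marker transfer is dropped in
≥ 90% of seeds. The quantile rule is explicitly a congruence screen, not a
claim of equivalence to the original software.

# Continuum diagnostics and cluster calls

`spearman_cor()` reports the tie-corrected rank correlation with a
t-approximation p-value (n − 2 df), or the exact permutation p-value for
n ≤ 10 (full enumeration, two-sided on |ρ|). p-values are reported, never
used to gate anything — the analysis is estimation-oriented.

`call_clusters()` joins every genome pair with ANI strictly greater than 96
and coverage strictly greater than 90 (strict inequalities, following the
"ANI > 96%" notation) and takes connected components — single linkage, the
permissive reading; whether the original clusters were components or cliques
is not stated, so the linkage is exposed as a parameter. Raising a threshold
can only refine the partition; this monotonicity is property-tested.

`continuum_profile()` replaces local regression with a fixed-width
sliding-window mean (window 0.005 substitutions/site, centres every half
window): same qualitative use — trend plus asymptote — without a smoothing
dependency in the core. Saturation is flagged where the local slope falls
below 10% of its initial magnitude.

# Synonymous rates and transfer detection

`ks_ng86()` implements Nei–Gojobori (1986): synonymous site fractions per
codon position (changes to stop codons count as nonsynonymous), pathway
averaging for codons differing at several positions (pathways through stop
codons are excluded; if none avoid stops, all are used), and the
Jukes–Cantor correction Ks = −(3/4)ln(1 − 4pS/3), with pS ≥ 3/4 flagged
saturated and excluded from medians. The method choice is ours — the source
text names only a "Ka/Ks calculator" and the third codon position — and NG86
honours "third position" through its site counting rather than a naive
third-position p-distance. The implementation is table-driven (precomputed
61×61 pathway-averaged differences) and was frozen against an independent
NG86 implementation to 10 decimals.

For validation, `simulate_syn_cds_pairs()` builds genes exclusively from the
five amino acids whose codon families are fourfold-degenerate at the third
position and nowhere else synonymous (Ala, Gly, Pro, Thr, Val). Every codon
then contributes exactly one synonymous site, third positions evolve under
plain JC69, and the generating Ks is exact — the estimator recovers it within
~2% at Ks ∈ {0.05, 0.2, 0.5} (500-codon genes, 100 pairs).

`compartment_contrast()` pairs homologs by BDBH over the two proteomes,
keeps pairs lying in the same compartment (both chromosomal or both pSym;
straddling pairs are excluded and logged), computes Ks per pair via the
back-mapped codon alignment, and summarises each compartment by the median of
unsaturated values (medians for robustness to saturated or outlying pairs). A
recent transfer is flagged when median Ks(pSym)/median Ks(chromosome) < 0.2
while median Ks(chromosome) > 0.1 — the two thresholds operationalise the
qualitative published contrast ("pSym Ks near zero, chromosomal Ks large"),
and the chromosomal guard keeps very recent splits, where both compartments
are near zero, unflagged. Both thresholds are parameters. The reverse pattern
(pSym ≫ chromosome, dissimilar evolutionary lines) is reported alongside.

One neutral-simulation caveat: without selection, protein identity decays
with nucleotide divergence, so homolog pairing at the 50% identity gate
thins out beyond chromosomal divergence ≈ 0.35 substitutions/site. Transfer
detection is therefore validated at chromosomal Ks = 0.3 (ratio 0.1 at the
planted transfers) — the same contrast as the published Ks > 0.5 cases, at a
divergence where neutral proteins still pair. On real (purifying-selected)
proteins the pairing range is much wider.

# Validation conditions and problem sizes

The acceptance suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) runs at these sizes, chosen to exercise each method
at realistic signal levels:

* ANI closed form: 1 Mb genome pairs at d ∈ {0.005, 0.01, 0.02, 0.04, 0.08};
  tolerance 0.5 percentage points.
* Continuum: a 16-genome ultrametric ladder spanning d = 0.005–0.08
  (250 kb chromosomes + 40 kb pSym, 58 markers); Spearman ρ ≤ −0.9 required,
  ρ ≈ −0.997 observed.
* Cluster recovery: three planted clades of three genomes (within-clade
  ANI ≈ 98, between ≈ 90; 80 kb chromosomes), 20 seeds; 3 clusters and
  ARI = 1 required in all seeds.
* BDBH/MCL/NJ/RF: exact-oracle comparisons (brute-force reciprocal bests,
  hand-derivable graphs, additive matrices, exhaustive bipartition
  enumeration at n ≤ 8).
* Ks: 100 fourfold-degenerate 500-codon pairs per level, median within 5%.
* Transfer detection: 20 planted transfers at relative age 0.1 of a 0.3-split
  plus 20 no-transfer controls; sensitivity ≥ 0.9, specificity ≥ 0.95.
* Pangenome: 8 genomes, 60-family pool, gain 0.4 / loss 1; ARI = 1 family
  recovery, monotone curves, γ > 0 iff gain > 0.
* Marker filter: 21 markers of 300 codons over 8 genomes, one cross-clade
  transfer planted between the most distant pair; dropped in ≥ 90% of seeds.

The `analysis/` scripts run the same workflow at the default (larger)
simulator conditions and write all stage tables under `results/`.

# Known limitations

* Neutral evolution only; see the Ks caveat above.
* ANI sensitivity is seed-limited below ~75% identity — irrelevant for the
  96%-threshold analysis, but the engine is not a general homology searcher.
* `filter_markers()` is a congruence screen, not a recombination test; it
  will sacrifice noisy-but-clean short markers.
* Real-data marker extraction expects annotations (role tags) or pre-aligned
  markers; gene calling and multiple alignment are out of scope.
* The pipeline's YAML configuration covers every threshold named above; the
  defaults reproduce the documented conditions.
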