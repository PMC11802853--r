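---
title: "immunoclone: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{immunoclone: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what each
statistic assumes, which tunable parameters matter and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## 1. Chain assignment per droplet

Droplet VDJ libraries routinely contain more than one contig per chain
class (ambient contigs, secondary rearrangements, assembly artefacts). The
`select_chains()` rule is: per droplet and chain class, keep the contig
with the most UMIs — molecule counts are the best available evidence for
which rearrangement the cell actually expresses. Kappa and lambda light
chains compete in a single "light" slot because a B cell expresses one
light-chain isotype; the same argmax covers TRA/TRB for T cells.

Two conventions are ours rather than forced by the data model:

* **Tie-breaking.** UMI ties break by higher read count, then by the
  lexicographically smallest contig identifier. Any fixed rule would do;
  this one makes the output invariant to input row order, which the tests
  enforce.
* **Cross-lineage droplets.** A droplet carrying both BCR and TCR loci is
  an annotation conflict (most plausibly a doublet); we flag it
  `receptor_class = "ambiguous"` and assign no chains rather than guess a
  lineage.

SHM is quantified from the aligner's V-segment percent identity as
`round((1 - v_identity/100) * v_sequence_length)` — an integer mutation
count comparable across V genes of different lengths. R's `round()`
(half-to-even) resolves exact .5 ties; at realistic identities this is
immaterial.

## 2. Clone calling

B-cell clones combine two criteria, unioned: (a) connectivity in a
point-mutation network whose edges join equal-length CDR3 DNA sequences at
Hamming distance exactly 1, and (b) identical CDR3 DNA with identical IGHV
and IGHJ families. Criterion (a) captures clones diversified by SHM;
criterion (b) captures convergent annotations of the same rearrangement.

One consequence of computing the network on CDR3 DNA (full-length V(D)J
sequence is typically unavailable from contig tables): two cells with
identical CDR3 already share a network node, so criterion (b) is logically
subsumed by (a) in this implementation. Both are still evaluated — the
contract is stated as a union and stays correct if the network is ever
rebuilt on full-length sequences, where (b) regains independent force.

The clone partition is the transitive closure of the pairwise relation,
computed by union-find; edges are found with a positional-wildcard hash
(O(nL) instead of all-pairs). The tests verify equivalence against an
independent O(n^2) scan plus igraph connected components on 50 random
instances.

T-cell clones: identical TRB CDR3 DNA + TRBV + TRBJ; when both cells carry
a TRA chain its CDR3 must also match, otherwise the cells are separated.
Cells lacking TRA can bridge two TRA-discordant cells through transitive
closure — a stated property of the closure semantics, not an accident.
Nucleotide (not amino-acid) CDR3 is used for both receptor classes, mirrors
of each other by design.

Clone identifiers order by size (descending) then smallest member cell id,
and are prefixed with the patient identifier when present, so per-patient
calls concatenate without collisions. Clones never span patients.

## 3. Depth-normalised clonality

Raw "fraction of cells in expanded clones" is confounded by sequencing
depth: deeper samples reveal more co-clonal pairs. Both estimators
therefore subsample to a fixed depth, **recount clone sizes inside the
subsample**, and average over replicates:

* **Intra-subset** (`depth = 5`, `reps = 1000`): percentage of the 5
  sampled cells of one subset whose clone has >= 2 sampled members.
* **Inter-subset** (`depth = 50`, `reps = 1000`): 50 cells drawn across
  all subsets of a lineage (B, CD4 or CD8, matching how the metric is
  reported per lineage); per subset, the percentage of its sampled cells
  in clones with >= 3 sampled members counted across subsets. Replicates
  that sample no cell of a subset contribute no observation for it.

The thresholds are "2 or more" and "3 or more" — where the source
wording was ambiguous between ">2" and ">=2", the operational (Methods)
reading >= was implemented. The small depths are deliberate: they keep the
metric computable for rare subsets while still registering expansion.

Subsets smaller than the depth return `status = "insufficient_cells"`
rather than sampling with replacement, which would inflate clonality in
tiny subsets. Estimates carry a Monte-Carlo standard error (`se`), and
fixed `reps` + `seed` gives bit-identical results.

Two subtleties the acceptance tests made explicit:

* *Duplication invariance* is an asymptotic property. Literally duplicating
  every cell doubles clone sizes; in a 20-cell toy the without-replacement
  finite-population correction shifts the estimate by several points. On
  populations of hundreds of cells — the regime the statistic is designed
  for — the correction is an order of magnitude below Monte-Carlo noise,
  and that is where the invariance is asserted.
* The Monte-Carlo estimator is validated against exact enumeration of all
  C(n, depth) subsamples on populations of <= 15 cells.

## 4. Clonal transitions and recirculation

The overlap matrix counts **cells** (not clones or pairs): for each
unordered subset pair (i, j), clones with members in both contribute their
cell counts in i plus in j. A clone spanning three subsets contributes to
each pair independently and unweighted — down-weighting was considered and
rejected as an unstated complication. Normalisation is per sample over all
pairs jointly (sums to 1); all-zero samples are excluded and reported, so
downstream group comparisons only see samples with observed transitions.

Clones with cells in both blood and tumour are *recirculating*; otherwise
blood-only or tumour-only. Migration linkage counts, per recirculating
clone, every (blood phenotype, tumour phenotype) combination present in
the clone, normalises per patient, and averages across patients with at
least one recirculating clone.

Known-TCR screening is exact-string on the beta CDR3 amino-acid sequence
(plus TRBV when the reference provides it). No fuzzy matching: reference
databases list exact receptor sequences, and fuzzy thresholds would invent
a specificity model the data does not support.

## 5. Receptor–ligand interaction scoring

"Expressing" means raw count > 0. This makes the expressing fraction — and
hence the strength product — invariant to per-cell count rescaling and to
subset abundance, which is the design goal: the score reflects
cell-intrinsic expression states, not composition. The >= 3 cells floor
per patient keeps fractions from degenerating (a 1-cell subset expresses
every gene at 0% or 100%). Self-pairs (A -> A) are included by default and
can be switched off; whether autocrine edges belong in the network is a
genuinely open question, so it is a flag rather than a fixed choice.

Link counts tally nonzero strengths by sender (outgoing) and receiver
(incoming); their totals are equal by construction and the tests assert
it. Group comparison per (sender, receiver) edge feeds the per-patient
vectors of pair strengths to the MANOVA below; the sign convention is
first-group-level mean minus second, so relabelling groups flips every
direction.

The bundled ligand–receptor table is a small curated immune-specific CSV
(37 pairs: chemokine, cytokine, checkpoint, costimulation). It is a
usable default and a test fixture, not a comprehensive reference; users
with a full interaction database should pass their own table.

## 6. Module scoring, pAPC threshold and gating

`module_score()` follows the binned-control recipe: library-size
normalise to 10,000, log1p, rank genes by dataset-mean expression into
`n_bins = 24` equal-frequency bins, and for each set gene draw
`n_ctrl = 100` control genes from its bin (the conventional defaults of
the procedure this mirrors). The score is the set mean minus the mean over
the drawn control multiset. Controls are sampled without replacement
unless a bin is smaller than `n_ctrl`. Under gene-label permutation the
expected score is 0 — asserted over 20 seeds — and a fixture whose bins
contain identical expression profiles gives a fully hand-computable
oracle.

The pAPC threshold is learned by logistic regression of class on score
using known positives (DCs) and negatives (CD8 T cells); the threshold is
the score at predicted probability 0.5 (`-intercept/slope`). Perfectly
separable inputs get the midpoint of the separating gap (the glm would
diverge); indistinguishable distributions get the pooled median with a
warning. Cells strictly above the threshold are pAPCs; the pool
composition per patient is the fraction of pAPCs contributed by each cell
type.

`gate_cells()` is a declarative rule engine: ordered rules of ANDed
predicates over per-cell features, cluster means, or cluster fractions;
first match by priority wins; unmatched cells get the fallback. The B-cell
rulebook (plasma, plasmablast, naive, memory thresholds) ships as an
editable YAML config rather than hard-coded logic, because those
thresholds are dataset-calibrated, not universal.

## 7. Gene correlation modules

Per sample, cells are downsampled without replacement to 2,000 UMIs
(cells below the target are kept), genes with < 5 UMIs are excluded,
expression is log(1 + UMI)-transformed and gene–gene Pearson correlations
computed. Correlations are averaged across samples via Fisher
z-transformation (clamped at |r| = 0.9999999) and transformed back; genes
must pass the filter in every sample to enter the average. Modules are
complete-linkage hierarchical clusters of (1 - correlation) distances cut
into `n_modules`. The dendrogram is validated against a naive O(n^3)
agglomerative oracle. Note that the "averaging equals single-sample"
identity only holds when the per-sample inputs are literally equal, i.e.
when downsampling is a no-op; active downsampling draws independently per
sample.

## 8. SVM label transfer

Reference-based annotation should be driven by expression geometry, not by
class abundance. Each of `reps = 25` rounds trains a one-vs-rest **linear**
SVM on a class-balanced subsample (`cells_per_class = 50`; classes smaller
than that are sampled with replacement so rare populations are never
silently dropped) and predicts all query cells; the final label is the
majority vote and the probability is its vote fraction. The embedding is
any shared per-cell numeric space (e.g. batch-corrected components);
producing it is out of scope. A linear kernel is the standard choice on
such embeddings and keeps desk-scale runtime.

No SVM library is assumed: training is Pegasos subgradient descent with
the intercept as an augmented regularised feature and final-epoch iterate
averaging (30 epochs, lambda = 0.01), standardising on reference
statistics. On 6-sigma-separated Gaussian classes the tests require >= 95%
recovery.

One honest caveat the tests encode: when query classes are tight clusters,
all cells of a class receive the *same* prediction, so under permuted
reference labels the accuracy's sampling unit is the cluster, not the
cell. The chance-level check therefore estimates the estimator's SE over
independent permutation draws instead of using the (far too small)
cell-level binomial SE.

## 9. Group comparisons

`manova_compare()` uses Pillai's trace with its F approximation — the most
robust of the classical MANOVA statistics to covariance heterogeneity.
Zero-variance features are dropped and reported; a single remaining
feature reduces to univariate ANOVA; a singular within-group covariance
(more features than residual degrees of freedom) triggers a feature-wise
fallback with a warning, reporting the smallest Benjamini–Hochberg-adjusted
p. P-values are uncorrected across edges/subsets by default with BH
available, since the appropriate correction depends on the analysis
family. The trace is validated against a by-hand tr(H(H+E)^-1)
computation.

## 10. The synthetic world

`sim_config()` defaults describe the cohort the analyses assume: patients
with paired blood and tumour samples of 250 cells each; nine subsets
across B, CD4, CD8 and non-lymphoid lineages with a T-dominated
composition; clone sizes from a discrete power law (alpha = 2.5, support
1–500) — the canonical heavy-tailed model for lymphocyte clone sizes;
recirculation probability 0.2 for multi-cell clones; cross-subset
probability 0.2; SHM rate 2 mutations per V segment (Poisson, scaled to
the 45-nt junction as 2 x 45/300); an 8-category isotype distribution
dominated by IGHM/IGHG1/IGHA1 as in unsorted B cells; expressing-fraction
matrix over an 81-gene immune panel with a 0.05 baseline and biologically
motivated elevations (FOXP3/CCR4/CCR8 in Tregs, the MHC-II programme in
DCs/macrophages/B cells, cytotoxicity in CD8 effectors); sequencing depth
2,000 UMIs per cell; decoy secondary contigs with probability 0.1 at
strictly lower UMI count, to exercise chain selection. One master seed
fans out to per-stage seeds through a deterministic hash
(`derive_seed()`), so stages regenerate independently and runs are
byte-identical.

The generator is a stated world, not a calibration target. It emulates:
clone-structured VDJ tables with UMI evidence and V-identity, per-subset
expressing fractions with exactly the configured nonzero probability
(counts are shifted negative binomial given expression), compartment
sharing, and ground-truth labels for every latent variable. It does *not*
emulate: transcriptome-wide expression, batch effects, doublets, ambient
RNA, isotype–phenotype coupling, or SHM lineage structure within clones
beyond independent per-cell mutations. A green test therefore establishes
algorithmic correctness against the stated statistical structure — not
robustness to the full messiness of real droplet data.

## 11. Numerical choices and degenerate inputs

* Sampling is always without replacement inside subsamples; `reps` and
  `seed` fixed gives bit-identical output (asserted).
* Chain-selection and ranking ties break deterministically
  (reads -> contig id; lexicographic for interaction ranks).
* Probability-vector validation uses a 1e-9 tolerance on sums.
* Fisher z clamps |r| at 0.9999999 to keep atanh finite; zero-variance
  correlation entries (NaN) contribute 0.
* Empty inputs return typed empty tables (clone callers, rankers) rather
  than erroring, except where the contract demands an error (unknown
  subsets, missing columns, multi-patient clone calls, unknown receptors,
  invalid configs — which report *all* violations at once).
* The pipeline writes provenance headers (tool version, config hash,
  seed) on every TSV and a manifest of md5 sums; reruns are byte-identical
  (asserted end-to-end on the bundled 2,000-cell fixture).

## 12. Known limitations

* The mutation network is CDR3-based; clones whose SHM differences lie
  entirely outside the junction are linked only through criterion (b),
  i.e. exact junction identity.
* Interaction scoring has no significance model of its own (no
  permutation null); inference is deferred to the MANOVA across patients.
* The SVM is linear; strongly non-linear class boundaries in the
  embedding would need a different kernel, at odds with desk-scale
  runtime.
* Intra/inter clonality at very small depths have granular support
  (multiples of 100/depth per replicate); comparisons should use the
  reported Monte-Carlo SE.
* The myeloid gene-module step ships the machinery, not curated gene
  lists; lateral-programme exclusion (cell cycle, HLA, histones) is the
  caller's responsibility.
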