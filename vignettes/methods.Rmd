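---
title: "Methods: screening, grouping and profiling protein channel families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, grouping and profiling protein channel families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloscreen)
```

phyloscreen implements a comparative-genomics workflow for
membrane-protein families such as the slow (SLAC/SLAH) and quick
(ALMT/QUAC) plant anion channels: fingerprint motifs are turned into
profile HMMs and used to screen proteomes; candidates are curated by
pairwise identity; the family is grouped by UPGMA and interpreted
against a species tree by reconciliation; and per-residue features
(hydropathicity, kinase-target propensity) are projected onto the family
alignment to find clade-level structure — transmembrane topology and
group-specifically conserved phosphorylation sites. This vignette
explains each model, its assumptions, the tunable parameters, and what
the synthetic validation does and does not establish.

## Profile HMMs and the screening rule

A motif seed alignment is compiled into a profile HMM in the Plan7
spirit. Columns with gap fraction below 0.5 become match states; the
rest feed inserts. Match emissions are pseudocounted
background-proportionally, `(count + w·bg) / (n_eff + w)` with weight
`w = 1` and a uniform background of 1/20 by default; transitions are
estimated from the seed rows' match/insert/delete paths with add-one
pseudocounts over the allowed moves (M→M/I/D, I→M/I, D→M/D; insert
states emit from the background). Scoring is **local in the sequence,
global in the model**: flanking residues cost nothing in log2-odds, and
a path must traverse all K positions (through deletes if necessary).
This is the natural mode for finding short internal motifs in
full-length proteins; multi-hit scoring and composition bias filters are
deliberately out of scope.

Viterbi gives the best single match and its span; the forward score sums
over all paths and is used as a sanity bound (forward ≥ Viterbi always).
Both are checked against exhaustive path enumeration on small models in
the test suite.

Significance is calibrated empirically: the Viterbi scores of
`n_random = 1000` i.i.d. background sequences of length 400 follow an
extreme-value (Gumbel) law to good approximation, and maximum-likelihood
estimates of its location and inverse scale convert a bit score into
`E = N · P(S ≥ s)` for a database of N sequences. The screening rule —
a protein is kept when **at least one** motif hits with E-value at or
below the cut-off (default `1e-3`), and the whole protein is retained —
mirrors the fingerprint logic of database screens for these families.
The raw-score reading of such a threshold ("score above 0.001") would
keep essentially everything, so the cut-off is interpreted as an
E-value criterion; both the quantity and the direction are configurable.

## Curation by pairwise identity

All n(n−1)/2 candidate pairs are scored as percent identity of their
global alignment (Needleman–Wunsch under BLOSUM62, gap open 10, gap
extend 0.5; identity = identical pairs / alignment columns). Pairs above
97% are treated as the same sequence and collapse to the first-seen
representative — the alternative (keeping the later one) is equally
defensible, but a deterministic convention makes runs reproducible.
Pairs below 20% contribute no edge. The surviving edges fragment the
candidates into connected components, and the component with the highest
mean-over-references best-member identity is selected. The aggregate
(mean over references of the best member identity) is one of several
reasonable readings of "highest similarity to the reference channels";
it rewards groups that cover all references rather than matching one.

Completeness screening aligns each candidate to the analysis region of
its best-matching reference (global in the region, local in the
candidate) and flags it when more than 10% of the region aligns to gaps
— the signature of internal deletions from mispredicted splice sites.
N- or C-terminal extensions beyond the region do not count against a
candidate.

## Grouping, support, and conservation structure

UPGMA is run on `100 − identity` distances with size-weighted average
linkage, merge height d/2, and lowest-index tie-breaking, so the output
is a deterministic ultrametric tree; the implementation is cross-checked
against average-linkage `hclust` in the tests. Column bootstrap
resampling re-runs the builder and annotates each reference clade with
the fraction of replicates containing it. Robust alignment regions are
selected with a transparent two-rule surrogate (modal-residue fraction
≥ 0.5, gap fraction ≤ 0.5, runs of ≥ 5 columns) rather than a
reimplementation of the GBlocks heuristics, whose exact semantics are
not part of this package's claims. Conservation-zone segmentation
smooths the per-column modal-residue fraction with a centered moving
average (default width 11) and splits the region at a threshold into
alternating high/low zones; window and threshold are descriptive
parameters with no single right value, and are exposed as configuration.

Within- and between-group identity summaries report mean, SD, min and
max over all member pairs; the SD is the population SD (dividing by the
number of pairs), a convention chosen once and used consistently — with
dozens of pairs the distinction from the sample SD is negligible.

## Reconciliation

The LCA map sends each gene-tree node to the species node spanning its
descendant species. A node is a duplication when it maps to the same
species node as one of its children; losses on an edge are the skipped
species-tree levels, plus one for the unused side at a duplication.
These counts coincide with the minimum over all valid embeddings, which
the tests verify by exhaustive enumeration on small trees. Unrooted gene
trees are rooted by evaluating every edge and minimizing duplications +
losses; all co-optimal rootings are reported rather than picking one
arbitrarily. Species trees must be binary; polytomous gene trees are
rejected rather than resolved (threshold-based rearrangement of weakly
supported edges is a different algorithm and out of scope).

## Feature tracks and the phosphosite screen

Kyte–Doolittle hydropathicity uses the published residue constants with
a centered window (default 19 residues, the transmembrane-scan
convention); positions without a full window are undefined. Tracks are
projected onto the master alignment (values travel with their residues;
gaps are undefined) and averaged per clade. A column enters the average
only when fewer than 25% of the group's sequences are gapped there —
the mask threshold matters little in practice over a wide range, but
25% is the fixed default. Transmembrane segments are maximal unmasked
runs with mean hydropathicity ≥ 1.0 over ≥ 10 columns.

Kinase-target propensity is a pluggable scorer contract: any function
returning [0,1] scores at S/T/Y positions. Two implementations ship: a
file adapter for externally computed tables, and a transparent surrogate
— a logistic transform of a ±4-residue position-weight sum (weights
reward R at −3/−2, L at +1, E at +2; intercept −4). The surrogate is
**not** a retrained clone of any external predictor; it exists so the
screening logic can be exercised and validated end to end with known
truth. Scores are projected like any track, and a column is reported
for a group when (i) more than 90% of members carry the residue class
(S and T interchangeable, since homologous sites swap between them
across channels; Y separate), (ii) some member scores above 0.6, and
(iii) the group mean exceeds 0.2. The mean is taken over the members
carrying the class; counting absent members as zero is available as an
option since either reading is defensible.

## The synthetic generator: what it emulates

`simulate_family()` produces three-tier families with full ground
truth. A Yule species tree (unit birth rate, conditioned on the species
count) is copied three times; each copy is rescaled so its mean
leaf-to-leaf path length matches the tier's divergence target, and the
copies are joined by two ancient duplications. Root sequences follow
the preset architecture — SLAC-like: a cytosolic N-terminus, ten
21-residue hydrophobic transmembrane segments separated by 15-residue
loops, a C-terminus; ALMT-like: six transmembrane segments, then a
C-terminal half with a WEP anchor triplet and two further hydrophobic
segments. Sites substitute along branches with probability
`1 − exp(−rate · t)`, with replacements drawn from the region
composition: a hydrophobic pool for TM segments (rate multiplier 0.45),
a hydrophilic pool for linkers (multiplier 1), and a near-frozen anchor
(0.02). Planted phosphosites carry the surrogate scorer's consensus
context, held invariant in carrier groups and stripped of S/T/Y in
non-carriers.

The tier divergences (0.46 / 0.70 / 0.92 mean path) were calibrated once
so that realized within-group identities land near 78%, 69% and 58% —
the regime reported for the SLAC1, SLAH2/3 and SLAH1/4 groups — with the
most conserved tier staying inside a 73–83% band across seeds. The
group-joining stems are placed adaptively: the group1/group2 ancestor
joins 0.45 path units above the deepest within-group coalescence and the
third group 0.15 units above that, which guarantees that groups separate
before any within-group structure regardless of the sampled tree shape.
The price is that realized between-group identities (roughly 40% for the
closest pair, low 30s for the distant ones) sit a few points below the
upper end of the published 35–52% band; matching the closest published
between-group value (~52%) exactly would leave the group split at the
mercy of tree-shape noise, and clean recoverability of the planted
groups was prioritized.

Version 1 is indel-free, so the true alignment is the identity column
map. Consequences worth keeping in mind: the gap-mask logic is exercised
by constructed alignments in the tests, not by the simulator; and none
of the alignment-quality failure modes of real data (misaligned
low-complexity regions, fragmentary gene models) are represented.
Passing the synthetic acceptance checks therefore demonstrates that the
algorithms are implemented correctly, not that the pipeline is robust to
alignment error. Decoys are uniform-composition random proteins — an
easy negative set; real screens face homologous non-family proteins,
which only the identity-based curation stage addresses.

## Problem sizes and determinism

The shipped presets use 10 species × 3 groups (30 members) plus 5
decoys, sequences of ~450–470 residues, E-value calibration with 1000
random sequences of length 400, and three replicate bundles for the
stochastic recovery summaries — sizes at which a full analysis runs in
about a minute. Every stochastic step (species tree, gene family,
sequence evolution, calibration, bootstrap) is seeded explicitly;
identical configurations reproduce byte-identical outputs, which the
tests assert. Floating-point conventions: emission/transition
distributions are validated to 1e-9; scorer oracle equivalence is
asserted to 1e-10 in log2 units; UPGMA tie-breaks and duplicate-collapse
order are deterministic by construction.

## Known limitations

* No indel realism, codon models or empirical substitution matrices in
  the generator; no multi-hit HMM scoring; no GBlocks-exact block
  selection; no maximum-likelihood or Bayesian tree inference (externally
  built trees can be supplied as Newick for reconciliation).
* The reconciler requires binary species trees and binary gene trees;
  co-optimal polytomy resolutions are future work.
* The surrogate phosphosite scorer is a validation instrument; biological
  conclusions about real sites require an external predictor through the
  adapter.
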