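---
title: "Methods: detecting and classifying archaeal histone paralogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and classifying archaeal histone paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the models behind each pipeline stage, the
parameters a user may want to change, the design choices made where the
design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## Scientific setting

Archaeal histones of the HMf-like family are single histone-fold proteins
of roughly 67 residues. In several archaeal orders, two paralogs with
systematically different physicochemical properties coexist in nearly
every genome. Two observations support an ancient origin for such pairs:
(i) alignment columns whose residue compositions differ near-categorically
between the two groups (diagnostic residues), and (ii) reciprocal
monophyly on a gene tree — all members of one group descend from a common
ancestor to the exclusion of the other group, placing the duplication
before the species radiation. This package operationalizes both
observations, together with the supporting stages (detection in
proteomes, presence/absence parsimony on a species tree, and synteny).

## Detection by profile scan

A `ScoringProfile` is built from a seed alignment of known histones:
columns with more than 50% gaps are dropped, and for retained column $c$
and residue $a$

$$\mathrm{logodds}[c,a] \;=\; \log_2
 \frac{(n_{c,a} + \alpha)\,/\,(n_c + 20\alpha)}{b_a},$$

with Laplace pseudocount $\alpha = 1$ by default and background $b$
either uniform or the residue frequencies of the scanned proteome (the
default, because hyperthermophile proteomes are strongly
composition-biased; a lysine-rich decoy looks histone-like against a
uniform background but not against its own proteome). The profile is slid
ungapped along each protein; the score is the best window sum. An
ungapped scan replaces a profile-HMM because the target family is short
and nearly indel-free, which makes the fully specified deterministic scan
adequate; the inner loop is compiled (Rcpp). Proteins shorter than the
profile are slid inside it with uncovered columns contributing zero.

Significance is empirical: each protein is shuffled within itself
`n_shuffles` times (preserving length and composition, the dominant
confounder), the best-window scores of all shuffles are pooled into a
null distribution, and the calling threshold is its
$(1-\mathrm{fpr})$-quantile, default `fpr_target = 0.001`. On simulated
data the score separation is large (true histones score above 50 bits,
the null threshold near 11), so recall is insensitive to the exact
quantile. A `denylist` argument reproduces manual exclusions when users
need them.

In the orchestrated pipeline, only candidates whose best profile window
spans at least `min_fold_coverage = 0.5` of the protein enter the A/B
classification. This delimits the single-fold (HMf-like) histones the
classification is defined for: longer proteins carrying a histone-like
window — fold doublets, multi-domain proteins, or the occasional
statistical false positive among thousands of scanned proteins — are
reported separately instead of being forced into a group, mirroring how
single-fold and doublet histone-fold proteins are conventionally
distinguished by length.

## Featurization and classification

Each candidate is summarized by ten features: the fractions of the nine
AAstat residue classes (Tiny, Small, Aliphatic, Aromatic, NonPolar,
Polar, Charged, Basic, Acidic), computed over counted residues with `X`
excluded, plus the isoelectric point. The pI is the root of the
Henderson–Hasselbalch net charge

$$q(\mathrm{pH}) = \sum_{\mathrm{basic}} \frac{1}{1+10^{\mathrm{pH}-pK_a}}
 \;-\; \sum_{\mathrm{acidic}} \frac{1}{1+10^{pK_a-\mathrm{pH}}},$$

including both termini, found by bisection on $[0,14]$ to
$|q| < 10^{-4}$. The pKa table is fixed (N-terminus 8.6, C-terminus 3.6,
C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1 — EMBOSS-style
values); published tables differ by a few tenths of a pH unit, and any
fixed table preserves the between-group contrast that matters here.
Because the charge function is monotone in pH with at least one acidic
and one basic group (the termini), the root always exists and bisection
cannot fail.

Featurization is alignment-free by design: composition and pI are what
the AAstat summary actually measures, and they are insensitive to
alignment choices. Alignments are used only downstream (diagnostics and
trees). Features are z-scored and projected onto principal components
(`stats::prcomp`); zero-variance features are dropped with a message.
PC1's sign is oriented so the B-reference anchor scores higher than the
A-reference. Assignment uses the midpoint $m$ of the two reference scores
and their separation $d$: a histone is labeled with a group when it lies
on that group's side of $m$ by at least $\varepsilon \cdot d$
(`eps = 0.05`), and `unassigned` otherwise. The dead zone has no analog
in eyeball classifications; it exists so that borderline synthetic cases
are flagged rather than silently forced, and `margin` records the
distance in separation units. Standardization and this exact feature set
are frozen choices; the source analyses do not pin them down, and
freezing is what makes results reproducible.

When no external alignment is supplied, an internal center-star
construction is used: the sequence minimizing the summed pairwise
distance (100 − percent similarity) is the center, all others are
globally aligned to it (BLOSUM62, gap open 10 / extend 1, a length-$k$
gap costing $10 + k$), and the pairwise alignments are merged under
"once a gap, always a gap". For near-indel-free histones this is
essentially exact; externally computed (e.g. MAFFT) alignments can always
be imported with `read_alignment()`.

## Diagnostic columns

Per column and group, residue frequencies exclude gaps and `X`. The
diagnostic score is the total-variation distance
$D = \tfrac12\sum_a |f_A(a) - f_B(a)| \in [0,1]$: $D = 1$ iff the two
compositions are disjoint (the "always Y versus always K" case), and it
is symmetric and invariant under residue relabeling. The calling
threshold `tau_d = 0.9` is a frozen choice — published analyses read
logos by eye; a threshold of 0.9 accepts columns that are categorical up
to ~5% leakage per group. Information content per group is
$\log_2 20 - H$ bits with no small-sample correction: with dozens of
sequences per group the correction is negligible, and the uncorrected
form stays analytic for testing. Positions are reported in the numbering
of a chosen reference row (conventionally HMfB), assigning position $k$
to its $k$-th non-gap character.

Pairwise identity divides matches by columns where at least one row has a
residue: a gap aligned to a residue is a mismatch, gap–gap columns are
excluded. For two full-length 67-residue histones this reduces to
matches/67.

## Gene trees and reciprocal monophyly

Distances are p-distances over columns where both rows carry residues,
Poisson-corrected ($d = -\ln(1-p)$, $p$ capped at 0.95 with a message).
Trees come from classic Saitou–Nei neighbor joining with the
Studier–Keppler criterion, made fully deterministic: ties in $Q$ are
broken by the lexicographically smallest pair of minimal descendant taxon
ids, and negative branch lengths are clamped to zero with the deficit
moved to the sister edge, preserving their sum. Maximum-likelihood
inference is deliberately out of scope — the monophyly logic is
tree-source-agnostic, and externally inferred trees can be supplied as
newick. There is no bootstrap; determinism replaces replicate trees here.

`is_separable()` asks whether any single edge bipartitions the leaves
into a given set and its complement; `reciprocal_monophyly()` applies it
to the A-labeled set (equivalently the B-set) after excluding unassigned
leaves. On failure it reports the smallest symmetric difference between
the A-set and any edge bipartition — a greedy single-edge repair that
names the offending leaves (candidate transfers, contaminations or
misclassifications) without inventing a transfer statistic.

## Presence/absence parsimony

Fitch mode computes the minimal number of binary state changes by
dynamic programming over both root states (rooting by outgroup knowledge
is not modeled; ties prefer presence), and places events on edges by a
top-down resolution that keeps the parent state on ties — a deterministic
representative of the optimal set. Dollo mode fixes a single gain at the
MRCA of the present species and counts the minimal set of loss edges
(maximal all-absent subtrees) below it; the reported count excludes the
fixed gain, so "present in every species" is zero events in both modes.

## Orthology and synteny

Similarity is the fraction of positive-scoring aligned pairs over the
full alignment length (gap columns included in the denominator), the
"positives" convention, times 100. The "within 20% length" filter is
interpreted symmetrically as min/max ≥ 0.8. Reciprocal best hits require
mutual best similarity with ties broken by id order. Neighborhoods are
the `k = 5` nearest genes by start coordinate on each side of a focal
gene on its contig — gene ranks, not base pairs, because intergenic
distances vary; conservation is the per-side fraction of shared ortholog
families, averaged over sides. The global-alignment dynamic programming
(Needleman–Wunsch with affine gaps, Gotoh recursion) is compiled; its
scores are pinned to `Biostrings::pairwiseAlignment` in the test suite.
Full BLAST heuristics (seeding, E-values) are out of scope: at
proteome-pair scale exact global alignment is affordable and simpler to
specify.

## The simulator

`simulate_dataset()` emulates the evolutionary structure the analysis
assumes, not any particular genome set:

* a pure-birth species tree rescaled so every root-to-tip path equals
  `tree_depth` expected substitutions/site (default 0.09, which yields
  ~85% mean within-group identity at the default 30 species — the level
  of divergence at which the classification problem is interesting but
  solvable);
* one ancestral 67-residue histone drawn from a lysine/glutamate-rich
  background composition, duplicated at the root into groups A and B;
* `n_diagnostic_sites = 8` positions fixed per group, drawn once from
  contrasting pools (acidic/aromatic/aliphatic for A, basic/polar for B)
  so that the groups acquire the distinct physicochemical character —
  different charge and pI — that real paralog groups display and that
  composition-based classification relies on;
* Poisson background substitution (uniform among the 19 alternatives;
  an empirical exchange matrix would add realism the distance- and
  identity-based pipeline does not test), Bernoulli loss and extra
  duplication per copy per branch (defaults 0.02), optional terminal
  HGT;
* conserved group-specific gene neighborhoods (`neighborhood_size = 5`
  families per side, each family evolving along the species tree like an
  unconstrained protein of 150–350 residues) and `n_decoys = 10`
  composition-matched decoys of 80–500 residues per species;
* ground truth for every emitted histone, diagnostic site, event and
  ortholog family.

The `"terminal"` duplication mode is the negative control: a single
ancestral gene duplicates independently on each terminal branch, and
each species draws its own diagnostic residues from the two pools. The
copies therefore have group-like chemistry without shared descent — the
gene tree pairs the two copies of each species, and reciprocal monophyly
must fail. (Coordinating the same residues across species would instead
add a constant to every between-group distance, which is metrically
indistinguishable from an ancient duplication — precisely the confound
the control must avoid.)

All randomness flows through the configured seed; identical
configurations produce identical bundles.

What the simulator does **not** emulate: insertions and deletions (real
histone alignments contain occasional indels; the center-star merge and
identity denominators handle them, but simulated tests do not exercise
deep-indel regimes), rate heterogeneity across sites and lineages,
empirical substitution biases, genome rearrangements, partial or
truncated gene models, and the internal structure of fold-doublet
proteins. Passing tests therefore certify the pipeline's logic and
calibration under the assumed generative structure, not performance on
any particular real genome set.

## Problem sizes and determinism

Default analyses run at 30 species (~960 proteins), with detection
calibrated on 10–20 shuffles per protein and null-scale checks at 5,000
decoys; tree oracles use up to 12 taxa (neighbor joining) and 8 leaves
(parsimony enumeration). These sizes make every stage's behavior
measurable in seconds while leaving the asymptotics to the compiled
kernels. Every stochastic stage takes an explicit seed, and the
orchestrator derives per-stage seeds from one master seed, so a report is
reproducible end to end.

## Known limitations

* Classification accuracy degrades as the number of diagnostic sites
  approaches zero or divergence grows; histones near the PC1 midpoint
  are labeled only beyond the `eps` margin, and a mislabeled boundary
  case will break reciprocal monophyly on the gene tree — the report's
  offender list points at such leaves.
* The profile scan has no indel states; a histone fold interrupted by a
  long insertion would score as two partial windows.
* Dollo mode assumes the type arose once; for genuinely polyphyletic
  types (e.g. repeated horizontal acquisition) Fitch counts are the
  meaningful ones.
* The empirical-null calibration controls the false-positive rate per
  proteome scan, not family-wise error across many proteomes.
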