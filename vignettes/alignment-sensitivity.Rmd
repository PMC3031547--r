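---
title: "Alignment sensitivity analysis for divergent protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment sensitivity analysis for divergent protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alnsens)
```

## The problem

Insect odorant binding proteins (OBPs) are small secreted proteins that
share a skeleton of six conserved cysteines and almost nothing else: across
a family the mean pairwise amino-acid identity is around 20%. At that
divergence a multiple sequence alignment is not a fact but an estimate, and
different estimation strategies disagree substantially — in total length, in
which residues they call homologous, and consequently in every inference
computed downstream: tree topology, branch support, and codon-level tests of
positive selection. `alnsens` packages that *sensitivity analysis* as a
reproducible pipeline: simulate (or ingest) a divergent family, align it
several ways, quantify how much the alignments disagree, infer a tree from
each, score each tree against a reference, and run the selection-test
battery on each alignment — making explicit how much of the biological
conclusion is an artifact of the aligner.

Because the package must be testable without any sequence download, it
includes a codon-level family simulator with complete known truth: the tree
that generated the data, the exact homology map (true alignment), and the
per-site selective regime.

## The simulator

`familySimConfig()` describes an OBP-like family; `simulateFamily()` draws
one. The moving parts, with defaults and the reasoning behind them:

* **Family composition** — 11 "conserved ortholog" lineages plus a 7-gene
  lineage-specific expansion (18 sequences in all, the size of a typical
  single-species OBP repertoire). The expansion clade sits on a stem of 1.0
  expected substitutions per codon and all branches inside it are shrunk by
  a radiation factor (default 0.35): an old duplication followed by a
  recent, rapid radiation. This shape makes the clade genuinely recoverable
  from the sequences — distance trees on the true alignment recover its
  monophyly essentially always — which mirrors how consistently real
  lineage-specific expansions are recovered despite overall saturation.
* **Sequence layout** — 150 codons: a signal-peptide region of 19 codons
  whose first position is a frozen methionine, and six cysteine anchor
  columns (default positions 30, 58, 62, 100, 112, 121) spaced like the
  C1–C6 motif of real OBPs. Anchors and the initial M never substitute and
  are never deleted. The signal region is otherwise ordinary sequence — no
  hydrophobicity modeling — because the only claim tested about it is that
  alignable blocks survive there.
* **Codon process** — a Goldman–Yang-style 61-state model, uniform codon
  frequencies on the simulation side, transition/transversion ratio
  `kappa = 2`, and a site-class mixture of dN/dS regimes, default 60% of
  sites at ω = 0.08, 30% at ω = 0.6, 10% at ω = 2.5: purifying-dominated
  with a small positively selected fraction, so that selection tests have
  something real to find without being trivial. Class matrices are jointly
  scaled so branch lengths are expected substitutions per codon at the
  mixture mean.
* **Identity calibration** — the tree depth is not a free parameter; the
  generator scales the whole tree so the realized mean pairwise amino-acid
  identity hits `targetIdentity` (default 0.20). The multiplier is found by
  bisection on the *analytic* expected identity — the match probability of
  the codon process expanded in the eigenbasis and evaluated along the
  tree's path lengths, with the seven frozen columns credited — followed by
  at most two pilot simulations that absorb what the analytic curve does not
  model (columns created by insertions are younger than the root and pull
  realized identity up). Realized identity lands within ±0.02 of target in
  typical seeds; the test suite checks the ±0.05 band over many seeds.
* **Indels** — whole-codon events (so the nucleotide and amino-acid
  alignments stay consistent; real OBP indels need not respect frames) at
  0.01 events per substitution, insertion/deletion 50:50, geometric lengths
  with mean 2 codons, never touching frozen columns. The rate deserves a
  note: at ~20% identity the underlying codon divergence is enormous
  (mean pairwise paths of 20+ substitutions per codon, because most
  substitutions at low ω are synonymous), so an indel rate that looks small
  per substitution is large per site. At 0.05 events per substitution
  essentially every unfrozen column is hit somewhere on the tree and pairs
  of sequences end up sharing little beyond the anchors; 0.01 produces true
  alignments of roughly 250–450 columns for 150-codon sequences, matching
  the length spread real aligners produce on real OBPs. There is no
  empirical OBP indel rate to anchor this; it is a declared free parameter.
* **C-minus lineages** — with probability 0.10 a lineage loses one cysteine
  pair. The lost pair is fixed to anchors 2 and 5; real C-minus OBPs lose
  *a* pair but the literature does not pin down which, and the analysis only
  needs a consistent choice.
* **Seeding** — one master seed; every stochastic operation draws from a
  named child stream derived from it, so the tree, the codon evolution, the
  bootstrap and the optimizer restarts are independently reproducible.

What the simulator does **not** emulate: amino-acid exchangeability
structure (it uses uniform codon frequencies, so its saturation floor is
lower than real proteins'), hydrophobicity of signal peptides, frame-breaking
indels, sequencing artifacts, and assembly errors. Tests passing on this
generator show the *machinery* is correct and the *protocol* behaves as
described at realistic divergence; they do not certify aligner accuracy on
real OBPs.

```{r sim-example}
fam <- simulateFamily(familySimConfig(seed = 7))
fam
percentIdentity(fam@alignmentAa)
```

## Aligners

External MSA programs are deliberately out of scope; the package ships a
progressive aligner with six presets spanning strict/loose affine gap costs
(a gap run of length *k* costs `gapOpen + k * gapExtend`), BLOSUM62/BLOSUM45
scores, and two guide strategies (pairwise-distance NJ, or 3-mer identity
with UPGMA). The point of the battery is not to imitate any particular
program but to produce the *disagreement* among reasonable methods that the
sensitivity analysis studies; externally computed alignments can be dropped
into the same pipeline through `readAlignment()`. Profile–profile merging
uses sum-of-pairs scoring with no iterative refinement, ties in the
traceback broken deterministically (aligned column, then gap in the first
profile, then gap in the second), and input order canonicalized by id before
guide-tree construction so results are reproducible.

## Alignment metrics

Per-alignment statistics follow the conventions a reader would expect from
a method-comparison table, with every convention stated:

* `coreLength()` — anchor columns are columns where at least half the
  non-gap cells are cysteine; the core is the inclusive column span from the
  first to the last such column (columns, not residues). C-minus rows do not
  break detection because they are a minority by construction.
* `percentIdentity()` — mean over row pairs of matches over shared non-gap
  columns; a pair with no shared column contributes 0. Gap handling in
  published identity figures is rarely stated; this convention is declared
  rather than inferred.
* `parsimonyInformativeCount()` — columns with two states each in two rows;
  gaps are not a state.
* `columnCongruence()` / `uncertaintyProfile()` — alignment agreement in
  homology-pair currency: a reference column's score is the fraction of its
  co-aligned (row, residue-ordinal) pairs that some column of the other
  alignment also co-aligns; near-empty columns score 1 by convention. The
  battery mean per column is the heat-map analog of alignment-uncertainty
  plots.
* `saturationTest()` — substitution saturation assessed by a fully specified
  entropy index: the mean per-column Shannon entropy of non-gap cells (log
  base = alphabet size, so the index sits in [0, 1], columns with at least
  four non-gap cells). The critical value is the 5th percentile of the same
  index over alignments whose columns are filled i.i.d. from the empirical
  residue frequencies — the full-saturation null. Data are *saturated* when
  the observed index fails to fall below that critical value; the p-value is
  the fraction of null replicates at or below the observed index, so small
  p means structure remains. Named saturation tests in the literature have
  unpublished internals; no fidelity to them is claimed, only a
  deterministic, testable criterion with the same role.

## Phylogenetics

Tree inference follows the standard two-phase protocol at desk scale:
Poisson-corrected protein distances → BioNJ → maximum likelihood under
LG+I+Γ with 4 discrete-gamma categories (category means of equal-probability
bins) and alignment-derived (+F) frequencies. The per-column likelihood is
`pInv · I[column constant] · π(state) + (1 − pInv) · mean over categories`,
gaps and X as missing data; this exact convention is what the test suite's
exhaustive-state oracle checks, which is why the pruning core is implemented
in the package (in C++) rather than delegated. Topology search is NNI hill
climbing from a BioNJ start plus seeded random starts — spectral-scale
rearrangements (SPR) are out of scope — with branch lengths re-optimized by
cycled Brent searches (local bracket around the current value, relative
tolerance 1%, monotone accept-if-better). Branch support is a nonparametric
bootstrap (column resampling → distance BioNJ → bipartition frequencies);
the approximate likelihood-ratio supports some programs report add
machinery orthogonal to the question here, which only needs a consistent
per-edge support to average. Midpoint rooting is used for display, as is
conventional when no outgroup exists.

Tree concordance is the Robinson–Foulds symmetric difference over
non-trivial bipartitions, refused (not silently pruned) on mismatched leaf
sets unless pruning is requested. `rankAlignments()` orders methods by RF to
the reference, breaking ties by log-likelihood then mean support — the
composite rule is declared here since comparison tables in the literature
bold "best" values without stating one. The "reference" is the simulator's
true tree by default, or any user-supplied tree standing in for a jointly
estimated alignment+tree anchor.

## Selection models

The codon stage is authored in full: F3×4 frequencies, the GY94-style rate
matrix (`codonQ()`), and mixture likelihoods by pruning for M0, M1a, M2a,
M7, M8, the two-ratio branch model, and branch-site model A. Conventions
and numerical choices:

* The input topology is fixed (ML tree from the protein stage, or truth);
  its branch lengths supply the *proportions*, and every model re-optimizes
  a single rate-scale factor together with κ. Per-branch re-optimization
  under the codon process is deliberately not done — fixed-proportion
  rescaling is standard practice and keeps the simulation studies tractable.
* Mixture proportions are profiled out by EM at every objective evaluation;
  the remaining 3–6 parameters are optimized by bounded quasi-Newton
  (`nlminb`) on transformed scales (log κ, log scale, logit ω₀,
  log(ω₂ − 1), log beta shapes; κ ∈ [0.1, 20], ω ∈ [10⁻⁴, 50]). Restarts
  are drawn from a seeded Latin hypercube; M2a and M8 always include a
  start at the nested-null boundary (ω₂ → 1), which enforces the nesting
  dominance lnL(M2a) ≥ lnL(M1a) and lnL(M8) ≥ lnL(M7) by construction
  rather than by fiat. A fit is flagged `converged` when the best two
  restarts agree within 0.01 log units; best-of-restarts is returned either
  way (replicated-run protocols in the literature do not state an agreement
  rule, so one is declared here).
* M7/M8 discretize the beta into 10 equal-probability categories at the
  category medians.
* LRTs report the χ² p-value at the nominal df (2 for the site-model pairs)
  *and* the conservative df = 1 p-value, the guard commonly used against
  mixture-boundary violations; significance stars in report tables use the
  conventional 3.84/6.63 thresholds.
* Site identification is naive empirical Bayes at the MLEs by default;
  `"beb-lite"` additionally averages posteriors over a coarse
  likelihood-weighted grid of the mixture parameters (5 points per mixture
  parameter, proportions re-profiled per grid point) as a lightweight nod to
  full Bayes empirical Bayes, which is not reimplemented; results label
  which method produced them. Sites are flagged at posterior ≥ 0.95 and
  numbered 1-based over codon (amino-acid) columns.
* Stop codons in input are an error, never silently dropped; all-gap codon
  sites are dropped with a warning.
* Cross-alignment comparison of flagged sites maps each flagged column to
  its (sequence, residue-ordinal) tokens — an alignment-independent currency
  — and reports Jaccard overlap between alignments, so "the tests are not
  picking up the same signal under different aligners" becomes a number.
* A significant two-ratio branch test with foreground ω̂ < 1 is reported as
  relaxed/purifying selection on the foreground, never as positive
  selection.

## Pipeline and problem sizes

`runPipeline()` chains the stages and writes the two report tables
(per-alignment metric battery ranked by RF; per-alignment selection suite
with site overlap), the per-column uncertainty profile, the per-method
trees, and a log that records the seed. The test suite and the acceptance
script run everything at deliberately chosen desk scales: simulation
calibration studies use 13 taxa × 300 codons with 200 null and 50
power replicates; the sensitivity battery uses 20 seeded 18-taxon families
under 3 presets with distance-based trees; exhaustive-state likelihood
oracles run on ≤5 taxa × ≤10 columns where enumeration is exact. These
sizes are the package's validation design: large enough for the statistical
assertions (type-I error ≤ 8% at the nominal 5% threshold, power > 80% at
ω₂ = 3 with 15% of sites), small enough that the whole suite reruns in one
sitting.

## Known limitations

* The simulator's uniform codon frequencies understate the identity floor
  of real proteins; the calibration compensates by depth, so simulated
  families are *more* saturated than real ones at the same identity —
  conservative for the sensitivity question, but worth remembering.
* The aligner presets are a spread of plausible progressive methods, not
  emulations of specific programs; conclusions about any named program
  require ingesting its alignments.
* Branch lengths are not re-optimized per codon model; likelihood values
  are therefore not comparable to runs that do re-optimize them, though
  LRTs between models fitted the same way remain internally consistent.
* Full Bayes empirical Bayes site identification is approximated, not
  reproduced.
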