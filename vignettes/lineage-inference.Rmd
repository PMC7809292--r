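---
title: "Methods: Y-chromosome lineage inference from low-coverage samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-chromosome lineage inference from low-coverage samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylineage)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the design choices made where the design was
genuinely open, and what the test suite does and does not demonstrate.

## The inference problem

The non-recombining portion of the Y chromosome evolves as a single
genealogy: every SNP arises once on one branch and is inherited by all
descendants. A reference *haplotree* (the structure curated by the
ISOGG/FamilyTreeDNA databases) names clades — haplogroups — by their
defining derived alleles. Placing a sample means finding the deepest branch
whose defining variants the sample's reads support; with ancient samples at
0.17–7× coverage most sites are unobserved, so the logic must descend on
partial evidence, use confident ancestral calls to exclude branches, and
treat absence of data as silence rather than contradiction.

Three further questions follow placement. Samples that share derived
alleles absent from the reference tree define *novel* clades; the sharing
pattern across a cohort, interpreted under the single-origin
(perfect-phylogeny) assumption, yields their nested structure. Counting
SNPs along branches inside a callable region turns the tree into a clock.
And the uniparental markers (Y, mtDNA) exclude pedigree relationships
between individuals.

## Allele calling under ancient-DNA damage

Each observed site carries per-base read counts and mean base qualities
(the read-count table semantics; VCF with per-sample allelic depths is
accepted equivalently). `call_state()` reduces a site to one of four
states. The policy parameters:

* `min_depth = 1` read. Genomes at 0.17× would lose nearly everything at
  `min_depth = 2`; single-read calls are the operating regime of this kind
  of analysis, and the damage gate (below) covers the dangerous subset.
* `min_quality = 20` (mean base quality per allele; alleles below it are
  invisible). Qualities are assumed already damage-rescaled upstream.
* `min_major_fraction = 0.7`, constrained > 0.5 so at most one allele can
  qualify. Sites where both alleles are present without a qualifying
  majority are `conflict` — kept distinct from `missing` so
  contamination-like signals surface in QC instead of vanishing.
* `damage_mode = "strict"` demands `min_depth_damage = 2` reads before a
  *derived* call at a C→T or G→A variant: a single T over a reference C is
  exactly what post-mortem cytosine deamination produces. The gate applies
  only to the deamination-prone variant classes and only to derived calls;
  it converts probable artefacts into missingness rather than guessing.

Calling is monotone in evidence: added derived-supporting reads can never
demote a derived call (property-tested).

## Placement: the descent rule

From the root, a child branch is *supported* iff `n_derived >= 1` and
`n_derived > n_ancestral` over its defining variants. Descent stops at a
node with no supported child. If several children are supported the walk
follows the largest derived fraction `n_derived / n_observed`; an exact tie
stops the walk and reports the tied children as ambiguous — ambiguity is
surfaced, never resolved by guessing, because in practice such cases are
resolved by inspection. Siblings of the chosen child with at least one
ancestral call are reported as positively excluded. Conflict calls count as
observed but support neither side.

Consequences worth stating: an all-missing sample places at the root with
`fraction_path_observed = 0`; deleting observations can only shorten (never
deepen) the path, also property-tested; and a clade with no defining
variants can never be entered, which is why the synthetic reference-tree
builder collapses variant-less internal nodes by default — real reference
trees list only SNP-defined haplogroups.

## Novel-clade discovery

For every site with a derived call in some sample and no entry in the
tree's site index, the cohort splits into carriers, confident noncarriers,
and unknowns. The clustering model is a perfect phylogeny over binary
characters: member sets of clades must be pairwise nested or disjoint.

The algorithm seeds one proto-clade per distinct carrier set, then merges
proto-clades to a fixpoint whenever the union of their member sets contains
no confident noncarrier of any supporting variant, i.e. whenever nothing in
the data forces two clades. This is a parsimony choice with a deliberate
asymmetry: *unknowns never veto membership*. A sample at 2× coverage that
misses several of a clade's defining sites must still be attachable to the
clade; only a confident ancestral call separates. The flip side is a real
identifiability limit: a true subclade none of whose variants has a
confident ancestral call among the remaining members of its parent is
indistinguishable from the parent, and the merge collapses it. The
recovery properties in the test suite therefore hold under an
identifiability condition — noncarrier evidence retained, every member
witnessed as carrier at ≥ 1 site per clade — and that is exactly what
passing tests show; they do not show recovery from arbitrary missingness,
which no method can provide.

Member sets that still overlap improperly after merging are homoplasy
signals (recurrent mutation, error); offending clades are dropped greedily,
fewest members first, and reported with reason `"incompatible"`. The
four-gamete check is available as an independent diagnostic.
`min_support = 1` by default: a clade may rest on a single sample's private
SNPs. Verified clades attach below the shared terminal of their members;
members on different backbone branches are an error (or skipped in
pipeline mode), not a guess.

Correctness is checked against two independent oracles: on complete
homoplasy-free matrices the truth is the set of distinct nonzero column
patterns; on small instances (≤ 6 samples, ≤ 8 variants) an exhaustive
search over all set partitions of the variants confirms the result is a
coarsest feasible laminar hierarchy.

## SNP-count dating

Branch lengths are counts of defining variants inside a callable-region
mask. Mask intervals are BED (0-based, half-open); variant positions are
1-based; the membership test converts explicitly (`start < pos <= end`)
because a silent off-by-one here is the classic failure mode. The mask is a
first-class input — published age estimates hinge on which SNPs are
admitted, so it is never hard-coded.

Two clock modes:

* `anchor_path`: given an anchor node of known age `A`, the rate is
  `A / D` years/SNP where `D` is the anchor's SNP distance to the present;
  `age(node) = rate × d(node)`. By construction the anchor's age is
  reproduced exactly.
* `fixed_interval`: ages are bracketed by `[k μ_min, k μ_max]` with the
  interval defaulting to 100–150 years/SNP, the canonical germline
  SNP-accumulation interval; the midpoint is reported as the point age.

Distances `d(node)` average over all descendant tips (the rho-statistic
convention, default) or follow one designated tip (`single_path`), which
exists to reproduce single-lineage arithmetic such as the worked example in
the README: counts 17/9/9 below a 4100-year anchor give 117.1 years/SNP
and a split age of 4100 × 18/35 ≈ 2109 years. Either recipe for the
youngest node — 9 total SNPs × 100, or the 6 in-mask SNPs × 150 — gives
900 years, and both are exposed because the choice between them is not
decidable from the published description. Ages are clamped non-increasing
from root to tips after estimation; the clamp only acts when averaging
noise inverts a short branch. Estimator bias was checked by simulation
(μ = 120, three node depths, 100 replicates): recovered ages are within
two standard errors of truth.

## Sex assignment and kinship exclusion

`Ry = nY/(nX + nY)` over X/Y read counts. Males carry one X and one Y, so
Ry concentrates near 0.5; female Y-mapped reads are mismapping noise near
zero. Thresholds `t_male = 0.075`, `t_female = 0.016` follow the
established read-ratio method; anything between is `ambiguous`, never
forced. Average per-chromosome coverages may substitute for read counts:
the ratio is scale-invariant, and the residual X-vs-Y length re-weighting
is an accepted, documented approximation.

Kinship verdicts are pure exclusion logic on terminal haplogroup labels:
mtDNA transmits mother→child, so differing mtDNA excludes mother–child and
full siblings; the Y transmits father→son, so differing Y excludes
father–son, paternal grandfather–grandson and any shared paternal lineage
(inapplicable unless both individuals carry a Y label). Matching labels
never prove a relationship. Comparison is string equality on the terminal
clade after alias normalisation — no "compatible ancestor" reasoning, so
upstream placement must have normalised depth. The full truth table over
{Y same/different/absent} × {mt same/different} is asserted against hand
enumeration in the tests.

## The generative model

`simulate_cohort()` produces every pipeline input with ground truth:

* *Genealogy*: binary splits at uniform times below `root_age` (default
  5000 years), tips in the present. An explicit dated genealogy can be
  supplied instead.
* *Mutations*: per-branch Poisson with mean `branch_years /
  snp_interval_mu` (default 120 years/SNP, the midpoint regime of the
  100–150 interval), positions uniform without collision inside the mask,
  derived alleles favouring transitions 2:1. The default mask is a 100 kb
  toy region so end-to-end runs take seconds; scale is a knob, not a
  constant.
* *Observations*: per-site depth Poisson at the sample's mean (defaults
  span 0.17–30× in the analysis scripts, mirroring the published coverage
  spread), 0.1% per-read error, 10% per-read deamination at C→T/G→A sites,
  5% extra site dropout. Damage is modelled per read at eligible sites
  only — a deliberate simplification of positional damage profiles that is
  sufficient to exercise the strict calling gate, and nothing else in the
  package depends on damage localisation.
* *Reference tree*: the genealogy's internal backbone with chosen clades
  withheld (their variants become novel) and variant-less nodes collapsed.
* *Sex counts*: XY splits reads binomially between X and Y; XX sends reads
  to Y only at a mismap floor (0.5%).

Everything is bit-identical under a fixed seed. What the simulation does
*not* emulate: fragment-end damage gradients, contamination mixtures,
mapping bias, indels, recurrent mutation, and population-level coalescent
structure (the genealogy is fixed, not drawn from a demographic model).
Tests passing on these simulations therefore validate the inference logic
and its contracts, not robustness to every artefact of real ancient DNA.

## Problem sizes and numerical choices

The test suite simulates cohorts of 6–12 tips with ~100 kb masks, 100+
placement replicates, 100 dating replicates and exhaustive clade oracles up
to 6 samples × 8 variants; the whole suite runs in under two minutes on a
single core — sizes chosen so the properties are sharp but cheap.
Deterministic tie-breaks are used throughout (lexicographic orderings in
clade processing, explicit stop-on-tie in placement) so that identical
inputs give byte-identical reports, which the pipeline tests assert
directly. Degenerate inputs have defined behaviour rather than errors
wherever the input can legitimately arise from thin data: empty
observation sets place at the root, empty partitions leave the tree
unchanged, zero-SNP anchors refuse to calibrate with an explicit message.

## Known limitations

Placement is rule-based, not probabilistic: no likelihoods, no
contamination deconvolution, no per-branch posterior. Clade discovery
inherits the identifiability limit described above and resolves it by
parsimony. Dating carries no uncertainty beyond the μ-interval envelope
and assumes a strict clock. Kinship exclusion cannot distinguish
relationships that uniparental markers cannot see (e.g. father–son versus
grandfather–grandson along an unbroken male line).
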