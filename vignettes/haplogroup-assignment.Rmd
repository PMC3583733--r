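---
title: "Assigning Y-chromosome haplogroups from whole-genome SNP calls"
author: "ylineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning Y-chromosome haplogroups from whole-genome SNP calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ylineage)
```

## The problem

The non-recombining portion of the Y chromosome is inherited strictly
paternally, so the hierarchy of all human Y lineages — haplogroups — can be
written as a single rooted tree in which every branch is defined by one or
more binary markers (Y-SNPs). Whole-genome sequencing yields, per sample, a
list of positions where the sample differs from the reference genome. Given
that call list, a marker catalogue (which allele of each Y-SNP is ancestral
and which derived, with positions on hg18 and hg19), and a haplogroup tree,
`ylineage` determines the sample's (sub-)haplogroup and emits the auxiliary
reports used to check, correct and extend the tree in use.

Two properties of real data drive the design:

* **The reference Y is a composite.** The reference sequence mixes several
  sub-haplogroups (notably within haplogroups G and R), while any sample
  belongs to exactly one lineage. Consequently a sample is expected to
  differ from the reference at some backbone sites *whatever* its lineage —
  which is what makes calling quality estimable from the calls themselves.
* **Call sets are imperfect.** Low coverage drops true variants and adds
  false positives; published marker lists disagree on strand and on which
  allele is ancestral; trees contain occasional errors. Every stage
  therefore works with proportions and reports ambiguities instead of
  trusting single markers.

## Marker states

Each non-indel marker with a position on the active build receives a state:

* `1` (mutant/derived), `0` (ancestral), or `-1` (other),
* with provenance `called` when the profile has a call at the position, and
  `reference` otherwise — an uncalled site is assumed to equal the
  reference base.

Markers whose conversion is not a single-base substitution (e.g. `4G->3G`)
are excluded: indel calling in whole-genome data is not reliable enough,
and consequently sub-haplogroups defined only by indels are never assigned.
Two markers are excluded by default on empirical grounds: `V218` (recurrent
mutation inside haplogroup I, although diagnostic for A2) and `MEH2`
(ambiguous behaviour within haplogroup Q). The exclusion list is a plain
configuration item.

Because marker lists mix strands, an observed allele matching neither
listed allele is retried as its complement (*strand rescue*, flag-
controlled, default on, every rescue noted in the output). Only after both
comparisons fail is a state `-1` recorded. The quality test below
deliberately does *not* use strand rescue: a consistent caller reports the
listed strand, and rescue would make every base "consistent" since the four
bases fall into two complement pairs.

## The call-quality test

The published tool gates its search on a "sufficient"/"insufficient"
verdict whose exact criteria were distributed as supplementary material
that is not available here. This package therefore fixes the *interface*
and the *qualitative contract* and makes the constants explicit and
configurable:

* panel: by default all markers defining nodes of depth ≤ 2 of the loaded
  tree (the well-known backbone markers of the major haplogroups);
* score: the fraction of panel markers having an **explicit call** whose
  observed allele equals the marker's ancestral or mutant allele;
* verdict: `sufficient` iff score ≥ 0.5.

Only explicit calls count, because composite-reference sites guarantee
that calls are always expected: a truncated call set scores low no matter
how plausible its imputed reference states are, and a call-rich profile
whose observations match neither allele also scores low — a higher call
count does not imply better quality. The score, panel size and threshold
are all reported so users can recalibrate on their own data.

## Node truth and the four searches

For a node with defining markers (a paragroup such as `Z2b*` uses its
parent's markers), let the *usable* states be those in {0, 1} — "other"
states never enter the denominator. Then:

* **sufficient regime** — all usable states count (calls and
  reference-derived alike); the node is *true* iff the mutant fraction is
  strictly greater than 0.85;
* **insufficient regime** — mutant states with provenance `reference` are
  removed from numerator *and* denominator (the reference cannot be
  trusted to stand in for missing calls); the node is *true* iff the
  remaining mutant fraction strictly exceeds 0.05.

Both thresholds are strict ("more than"): a node at exactly 85.0% or 5.0%
is false. A node with no usable state is *indeterminate*.

The search then combines four sub-algorithms:

1. **Vertical** — the set of true leaves. Cheap but false-positive-prone,
   since a single spurious call can switch a one-marker leaf.
2. **Horizontal** — a descent from the root over *internal* nodes: every
   true internal child is entered recursively; a true internal node none
   of whose internal children is true contributes itself; indeterminate
   internal nodes are passed through but are never returnable. If no
   internal child of the root is true the result is empty ("the descent
   stopped at the root"). Restricting the descent to internal nodes is a
   deliberate reading: it is what makes the leaf level the vertical
   algorithm's exclusive responsibility, and it is the only reading under
   which a worked example can simultaneously have true leaves below a
   horizontal result node.
3. **Combinatorial** — vertical leaves retained only when some horizontal
   node is among their ancestors; this removes most vertical false
   positives.
4. **Most specific** — drops every candidate that is an ancestor of
   another candidate; a paragroup leaf additionally yields to candidates
   inside its named siblings' subtrees (`Z2b*` yields to `Z2b3a`).
   Incomparable candidates are all returned — a deliberate refusal to
   guess between conflicting lineages, common under the insufficient
   regime.

When the horizontal set is empty the final result falls back to the most
specific vertical leaves with a warning, which reproduces the observed
behaviour on low-coverage samples: an empty answer would discard the only
usable signal. Final haplogroups are named in both nomenclatures, e.g.
`R1b1b2a2*` and `R-P312*` (main-haplogroup letter plus first defining
marker, asterisk preserved).

## Reports

Four byte-stable files per run: the analysis summary (quality score and
category, all four sub-algorithm results, final names in both
nomenclatures, warnings); the per-marker status table with provenance and
exclusion reasons; the markers found in derived state whose name *and*
synonyms are absent from the tree in use (candidates for tree extension;
synonym closure is respected, so a marker referenced in the tree under a
synonym is not reported); and the called SNPs at positions unknown to the
marker catalogue — novel SNPs with yet-unknown phylogenetic position.
These two lists partition every call: known-marker or novel, never both.

## Format converters

`convertVcf()` and `convertCga()` reduce VCF and Complete Genomics var
files to the three-column profile (1-based position, reference allele,
observed allele), keeping only single-base substitutions on the Y
(`Y`/`chrY`/`24`). Every input record lands in exactly one of three
buckets — kept, non-Y, non-SNP — so the stats always reconcile. Decisions
where the formats leave room:

* heterozygous genotypes on the haploid Y are artifacts: skipped, counted
  in the non-SNP bucket, warned about (keeping them would inject false
  positives);
* homozygous-reference and missing genotypes are likewise not variant
  calls for the sample and are skipped;
* multi-allelic records use the ALT the genotype actually carries;
* Complete Genomics coordinates are 0-based half-open, so a one-base SNP
  at `begin = b` is emitted at `position = b + 1` (= `end`); VCF is
  already 1-based;
* duplicate positions (e.g. merged call sets) keep the first occurrence
  with a warning — deterministic for a given input order.

## The synthetic generator

`makeFixture()` builds the validation world: a balanced tree (`nLevels`
levels, `branching` children per node, names following the alphanumeric
convention `A`, `A1`, `A1a`, ...), `markersPerBranch` markers per branch
with random ancestral/derived alleles at positions drawn without
replacement from `1..10·nMarkers` (the slack leaves room to plant novel
SNPs), and a composite reference that carries the derived allele exactly
on the branches ancestral to the chosen `referenceLineages`. Defaults —
5 levels, branching 2, 2 markers per branch, and three reference lineages
spread over both top-level clades — were chosen once as a realistic desk-
scale analogue of the study conditions: a tree deep enough for all four
searches to matter, a composite reference touching several sub-lineages
(as the real reference does), and backbone coverage such that any
zero-error sample produces enough expected calls to pass the quality gate.

`simulateProfile()` derives the true call set (sites where the leaf's
allele differs from the composite reference), drops each true call with
probability `fnRate`, and adds spurious calls with probability `fpRate`
per non-differing site. All randomness is Mersenne-Twister under one
explicit seed per call, restored afterwards; identical seeds give
identical fixtures on any platform.

What the generator does *not* emulate: read-level sequencing error,
coverage heterogeneity along the chromosome, polytomies and recurrent
mutations of real trees, linked error between co-located markers, and
build differences (synthetic hg18/hg19 positions coincide). Passing tests
on these fixtures therefore demonstrate the correctness of the state
logic, the searches and the error-handling contracts — not calibration of
the quality constants against any particular sequencing platform.

`oracleAssign()` is the independent cross-check: it ignores the tree
search entirely and exhaustively scores every leaf by the derived fraction
of its path markers, returning the arg-max set (ties included). At zero
error it must and does agree with the full pipeline on every leaf.

## Numerical and degenerate-input choices

* Thresholds are strict inequalities; the quality threshold is `>=` (a
  score exactly at threshold is sufficient).
* Set-valued results are emitted sorted by name; children keep file
  order; re-runs are byte-identical.
* Zero usable states → `indeterminate`, excluded from vertical results,
  passed through horizontally, always named in the warnings.
* Markers with no position on the active build are skipped and listed in
  the warnings; co-located markers each get their own state from the same
  call.
* Empty inputs (empty profile, empty converter output, empty candidate
  sets) flow through every stage without special-casing and yield empty,
  header-only reports.

## Validation sizes

The shipped checks run the four searches against brute-force
re-implementations on 200 random trees (≤ 6 levels, ≤ ~100 nodes, random
true/false/indeterminate statuses), recover all 32 leaves of a 5-level
fixture from zero-error profiles under the sufficient regime, and verify
the threshold boundary cases with 20- and 1000-marker nodes. These sizes
exercise every code path while keeping the whole suite well under a
minute.

## Known limitations

* Indel-defined sub-haplogroups cannot be assigned (by design).
* The quality constants are package defaults, not the original unpublished
  calibration; verdicts near the threshold deserve manual review.
* Recurrent mutations are handled only via the exclusion list; the package
  reports ambiguities but never edits the tree.
* Single-sample scope: cross-sample aggregation of the curation lists is
  out of scope.

## A worked run

```{r example}
fx <- fictiveFixture()
res <- assignHaplogroup(fx$profile, fx$tree, fx$markers, fx$reference)
res
```
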