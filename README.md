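# ylineage

Y-chromosome haplogroup assignment from whole-genome SNP calling profiles.

## What it does, and for whom

Population geneticists, genetic genealogists and forensic scientists place
male samples on the Y-chromosome phylogeny. Genotyping the defining Y-SNPs
one by one does not scale to trees with hundreds of lineages;
whole-genome sequencing already contains every informative site.
`ylineage` takes

* a **SNP calling profile** — the sample's Y-chromosome differences from
  the reference (tab-separated `position / ref / obs`, or VCF / Complete
  Genomics var files via the built-in converters),
* a **marker conversion table** — for every known Y-SNP its synonyms,
  hg18/hg19 positions and mutation conversion (e.g. `M173: A->C`, ancestral
  `A`, derived `C`),
* a **haplogroup tree** (tab-separated parent/child rows with defining
  markers), and
* the **reference Y sequence** (FASTA),

and returns the sample's (sub-)haplogroup in both nomenclatures (e.g.
`R1b1b2a2*` / `R-P312*`), together with curation reports: per-marker
allelic states, derived markers missing from the tree in use, and called
SNPs with yet-unknown phylogenetic position (novel-SNP candidates).

## The method

Every eligible marker *m* gets a state
*s(m)* ∈ {0 (ancestral), 1 (derived), −1 (other)} — from the explicit call
at its position when present, from the reference base otherwise. A
call-quality test exploits the composite nature of the reference Y (a
mosaic of several sub-haplogroups, so explicit calls at backbone sites are
always expected): with panel *P* (markers of tree depth ≤ 2 by default),

score = |{m ∈ P : m explicitly called, obs ∈ {anc, mut}}| / |P|,

with verdict *sufficient* iff score ≥ 0.5. For each node *h* with marker
set *M(h)*, the mutant fraction is

p(h) = |{m ∈ M(h) : s(m) = 1}| / |{m ∈ M(h) : s(m) ∈ {0,1}}|,

and *h* is **true** iff p(h) > 0.85 (sufficient regime) or, after removing
reference-derived 1-states from numerator and denominator, p(h) > 0.05
(insufficient regime). Four searches combine into the answer: **vertical**
(true leaves), **horizontal** (root-to-leaf descent over true internal
nodes), **combinatorial** (vertical leaves below a horizontal node) and
**most specific** (deepest remaining candidates; paragroups yield to their
named siblings). Incompatible survivors are all reported, never guessed
between.

A seeded synthetic-fixture generator (`makeFixture()`, `simulateProfile()`)
and a brute-force oracle (`oracleAssign()`) provide ground-truth validation
throughout the test suite.

## Worked example

The package ships a small fictive input bundle (tree with haplogroups
`X`, `Y`, `Z`; an individual belonging to `Z2b3a`):

```r
library(ylineage)
fx <- fictiveFixture()
res <- assignHaplogroup(fx$profile, fx$tree, fx$markers, fx$reference)
res
#> AssignmentResult
#> Call-quality: sufficient (score 0.500 = 3/6 consistent panel calls; threshold 0.5)
#>   vertical:       X1a, Z2b*, Z2b3a
#>   horizontal:     Z2b
#>   combinatorial:  Z2b*, Z2b3a
#>   specific:       Z2b3a
#>   final:          Z2b3a (Z-M8)
#>   warning: markers without a position on hg19 skipped: NOP1
```

Reading the output: three leaves look true in isolation (`X1a` is a false
positive from a single spurious call), the internal descent supports only
the `Z2b` branch, intersecting the two keeps `Z2b*` and `Z2b3a`, and the
most specific of those is the final answer `Z2b3a`, also reported by its
defining marker as `Z-M8`. The curation side:

```r
states <- buildStatusTable(fx$markers, fx$profile, fx$reference)
findConvNotTree(states, fx$markers, fx$tree)
#>   marker synonyms
#> 1   L999     S999
findYuppSnps(fx$profile, fx$markers)
#>   position ref_allele obs_allele
#> 1     1201          A          G
```

`L999` is derived but absent from the loaded tree (a candidate for tree
extension); position 1201 is a called SNP unknown to the marker catalogue.

Command-line wrappers live in `inst/scripts/`: `ylineage.R run|simulate`
and `snp-profile-convert.R` (VCF/CGA to profile TSV).

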