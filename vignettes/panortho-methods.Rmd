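---
title: "Methods and models behind panortho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind panortho}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panortho)
```

panortho analyses gene-based pangenomes: collections of many annotated
genomes of one clade, represented as orthologous groups (orthogroups) rather
than sequence graphs. This vignette explains the models and procedures the
package implements, the parameters that matter, what the synthetic-data
generators emulate, and the numerical choices behind the implementation.
Nothing here reports an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

An analysis starts from three tabular objects:

* a **genome table** (`genome_table()`), assigning every genome to one of
  four taxon groups — distant wild relatives (`WILD`), the ancestral
  *S. pimpinellifolium* type (`SP`), early-domesticated cherry-sized types
  (`SLC`), and large-fruited cultivated types (`SLL`);
* an **orthogroup table** (`read_orthogroups()`), the OrthoFinder
  `Orthogroups.tsv` dialect merged with the unassigned-genes file, in which
  every unassigned gene becomes a singleton orthogroup. A gene that appears
  in more than one orthogroup is an error, not a warning: the upstream
  inference guarantees disjointness, and a violation means the inputs were
  mixed up. Orthogroup inference itself is out of scope — the table is
  consumed, never computed;
* **gene coordinates** (`read_gene_coordinates()`), GFF3 `gene` features
  reduced to a 0-based `rank` per sequence region (ascending start,
  ties broken by gene id so ranks are a deterministic, permutation-invariant
  function of the coordinates). All adjacency and collinearity arithmetic
  uses ranks, never base pairs; strand is recorded but ignored.

## Pan-gene set classification

With presence defined as at least one gene copy, an orthogroup present in
`k` of `N` genomes is classified as

* **core** — `k = N`;
* **private** — `k <= private_max_genomes` (default 1);
* **softcore** — `round(softcore_fraction * N) <= k < N` (default fraction
  0.99);
* **dispensable** — everything else.

The verbal thresholds "present in more than 99% / less than 1% of genomes"
are degenerate for moderate `N`: at `N = 61` no integer count other than 61
exceeds 99%, yet a nonempty softcore class is reported alongside the core.
We therefore use the rounded-count rule above, which reproduces the
published semantics (softcore = 60 of 61, private = 1 genome) while keeping
both thresholds user-adjustable. Classification is always a total,
exclusive partition; `pan_class_summary()` reports counts, gene totals and
percentage shares at one decimal place. A related reporting note: where a
source reports two incompatible core counts under one rule, the package
follows the count implied by the `k = N` rule.

## Rarefaction and openness

`rarefaction_curves()` draws random genome orderings and accumulates
`pan(n)` (orthogroups seen in the first `n` genomes) and `core(n)`
(orthogroups in all of the first `n`). For up to 7 genomes, requesting at
least `N!` permutations switches to exact enumeration of all distinct
orderings, which is what the oracle tests exercise. Sampling is with
replacement of orderings otherwise; 100 permutations is the default.

`fit_openness()` fits three descriptive models to the mean curves:

* Heaps' law `P(n) = kappa * n^gamma` by least squares on the log-log
  scale;
* the new-orthogroup discovery decay `deltaP(n) ~ n^(-alpha)`; following
  the classic rule, `alpha > 1` means the discovery rate decays faster than
  `1/n` and the pangenome is closed/restricted. The source material asserts
  closedness without naming a model, so this criterion is a design choice
  of the package;
* an exponential core decay `core(n) = c_inf + a * exp(-n/tau)` (via
  `stats::nls`), whose asymptote `c_inf` estimates the core size at
  infinite sampling. If the exponential fit fails to converge the final
  observed core size is reported instead.

A constant pan curve is handled explicitly (`gamma = 0`, `alpha = Inf`,
closed).

## Presence/absence variation across taxon groups

An orthogroup is specific to a taxon group when it is present in at least
`min_group_genomes` genomes of that group (default 1 — the source does not
state whether all genomes of the focal group were required, so the weakest
reading is the default and the knob is exposed) and absent from every
genome outside it. Core orthogroups are excluded from the tested universe
first, exactly as the published procedure prescribes; `include_core = TRUE`
restores them for exploratory use. The same exclusivity logic applied to
annotation terms (`specific_pfam_ids()`) finds protein families confined to
one taxon group. No copy-number thresholds are applied anywhere: presence
is presence.

## Term enrichment

`fisher_enrichment()` is a foreground/background over-representation test.
For each term the p-value is the hypergeometric upper tail
`P(X >= k_fg)` with population `n_bg`, successes `k_bg` and draws `n_fg` —
the one-sided Fisher exact test. Three deliberate choices:

* **adjustment** is Benjamini-Hochberg across all tested terms; the source
  says only "adjusted P-value", and BH is the default of the GO tooling it
  names, so one consistent procedure is used for Pfam and GO alike;
* **unannotated genes stay in the denominators** (the background is "the
  total gene count encompassed by the database"), with
  `drop_unannotated = TRUE` available;
* an **enriched call requires `k_fg >= 2`** foreground genes besides
  `p_adjusted < alpha`, suppressing single-gene artifacts (the source is
  silent; the threshold is exposed).

GO terms are tested exactly as annotated — no ontology propagation — which
is documented as a known limitation.

## Duplication origin: collinearity and tandem arrays

Anchors for collinearity are cross-genome gene pairs sharing an orthogroup
(`orthogroup_anchors()`); this replaces raw BLAST hit tables, and a
user-supplied anchor table with the same columns is accepted. Blocks are
extracted greedily per region pair: the longest chain of anchors with
strictly monotone ranks on both sides (same or inverted orientation) and
per-step gaps of at most `max_rank_gap` (default 25, the common MCScanX
default; the published tool invocation includes a `u = 1` flag with no
documented meaning, which we record but cannot honour) is taken, its
anchors removed, and the search repeated while chains reach `min_block`
anchors (default 15, matching the published `s = 15`). The published
BLAST e-value cutoff is inapplicable to orthogroup anchors and is a no-op
configuration field.

A gene is labelled **WGD** when it lies in the focal-side interval of two
collinear blocks whose outgroup-side intervals overlap — two focal regions
anchored to one region of an outgroup genome that lacks the recent
polyploidy — and it shares an orthogroup with a gene of the sister region.
Whether the published analysis required focal-focal or only focal-outgroup
blocks is unstated; the two-blocks-to-one-outgroup-region rule is this
package's documented interpretation. **TD** labels come from maximal runs
of co-orthogroup genes at consecutive ranks (`max_gap = 0` by default: the
rule is literal adjacency; gaps are configurable). TD takes precedence
over WGD when both apply, mirroring classifiers that rank tandem
separately; everything else is **other**. Labels are always exclusive and
complete.

## Ka/Ks: Nei-Gojobori with Jukes-Cantor correction

The published pipeline names only a calculator tool; the package implements
the fully specified NG86 method so that every number is checkable against
an enumeration oracle:

* **sites**: per codon, the 9 single-base mutations are classified
  synonymous/nonsynonymous; mutations creating a stop are excluded from
  numerator and denominator. `S + N = 3L` holds identically.
* **differences**: codons differing at `d` positions are averaged over all
  `d!` mutational orderings, skipping paths through stop codons (standard
  NG86 practice); `sd + nd = d` whenever a valid path exists. Codon pairs
  with no stop-free path are excluded with a warning.
* **correction**: `K = -3/4 * log(1 - 4p/3)`, undefined (flagged `NA`, not
  an error) for `p >= 3/4`.
* **significance**: a two-sided Fisher exact test on the 2x2 table of
  sites versus differences, fractional counts rounded to the nearest
  integer (the rounding is our choice and is documented here).

Between-set comparisons are a genuine gap: the published text reports a
"Fisher P-value" for comparisons of set *means*, which matches no standard
mean-comparison procedure. `aggregate_by_set()` substitutes a two-sided
Mann-Whitney test with BH adjustment and this substitution is recorded
prominently rather than guessed around.

## The codon-model engine

`codon_selection` is an in-house Goldman-Yang engine over the 61 sense
codons of the universal code. The generator has off-diagonal rates
`pi_j * kappa^[transition] * omega^[nonsynonymous]` for single-nucleotide
changes, is scaled to one expected substitution per unit branch length, and
is reversible; transition matrices come from the symmetrized
eigendecomposition, which is exact and fast enough that likelihoods are
deterministic to machine precision. Codon frequencies are F3x4 (per-position
nucleotide frequencies multiplied per codon, stop mass removed,
renormalized) or user-supplied. Likelihoods use Felsenstein pruning over
compressed site patterns.

The branch-model hypotheses follow the published three-hypothesis design:
`H0` (one omega), `H1` (foreground omega + shared background omega), `H2`
(free omega per branch). Decision rule for a **rapidly evolving**
orthogroup: BH-adjusted p of the `H1` vs `H0` LRT below 0.01 (chi-square,
df 1), `H2` vs `H1` *not* significant (df = number of branches minus 2;
the published df is unstated, so the parameter-count difference is used),
and the foreground omega estimate above the background. The branch-site
test uses the standard four-site-class mixture (background omega0 < 1 and
omega1 = 1; foreground class omega2 fixed at 1 under the null, free in
[1, 50] and initialized at 1.5 under the alternative, matching the
published null/alternative settings); **positively selected** means the
BH-adjusted branch-site LRT p is below 0.01, referred to the conservative
chi-square(1) rather than the 50:50 boundary mixture. The two test
families are FDR-corrected separately.

Numerical choices: kappa is fixed at 2.5 (the published setting) unless
the user overrides it; omegas are optimized on the log scale by bounded
quasi-Newton search (`L-BFGS-B`) with multi-starts at 0.2, 1 and 2 (`H0`,
being one-dimensional, uses golden-section search); branch lengths are
taken from the input tree, with an optional single scale factor estimated
under `H0` and then fixed for all other hypotheses, which keeps the
optimizer dimension small at the cost of not re-estimating per-branch
lengths per hypothesis (a documented difference from per-gene ML branch
lengths). `fit_branch_models()` warm-starts `H1` and `H2` from the
preceding optimum so the nesting `loglik(H2) >= loglik(H1) >= loglik(H0)`
holds at convergence; fits are per-orthogroup (whether the published runs
pooled the single-copy panel is ambiguous, and per-orthogroup is the
defensible unit).

## Supermatrix phylogeny utilities

Single-copy orthogroups (exactly one gene in every listed genome, outgroups
included) are aligned externally; the package filters each alignment to
conserved blocks, concatenates, and builds a desk-scale distance tree.
The conserved-block rule keeps a column when its gap fraction is at most
0.5 (the published "gaps allowed in up to half the sequences") and its
modal residue reaches 0.5 of the sequences, then drops candidate runs
shorter than 5 columns (the published minimum block length). The full
Gblocks scoring scheme distinguishes conserved from highly conserved
columns and bounds nonconserved stretches; only the two published
parameters are honoured, the rest replaced by this transparent
three-parameter rule. The published `-e=.2` flag is an output-filename
extension, not an algorithm parameter, and is ignored. Filtering is
idempotent and kept-column indices map filtered content back to the source
exactly.

Tree building is neighbor-joining on pairwise p-distances (sites gapped in
either sequence excluded pairwise), with bootstrap support as the fraction
of site-resampling replicates containing each bipartition, and optional
outgroup rooting. Maximum-likelihood tree search is deliberately out of
scope: NJ with bootstrap is the desk-scale stand-in, adequate for the
package's structural tests (exact recovery on additive distances), not a
replacement for ML inference on real data. Three sequences return the
single unresolved topology.

## The LRR-RLK cascade

A protein is an LRR-RLK candidate when its precomputed domain-hit table
shows at least one passing protein-kinase hit (PF00069), one passing LRR
hit (any of the eight standard LRR profiles), and one transmembrane
segment; proteins without a TM segment are excluded. Profile searching and
TM prediction happen upstream — the module consumes their tabular output
through a documented adapter schema. Subfamily assignment replaces
per-genome phylogenetic co-clustering with nearest-reference assignment
under a distance threshold (default 1.0 substitutions/site, exposed):
each candidate takes the subfamily of its nearest member of the
19-subfamily reference panel, exact ties broken by reference id, and
anything beyond the threshold falls into the 20th, unclassified subfamily
LRR-XVI. How the published analysis resolved proteins co-clustering with
two subfamilies is unstated; nearest-reference is this package's
documented policy.

## What the synthetic generators emulate

`simulate_pangenome()` reproduces the statistical skeleton of a
multi-genome orthogroup matrix: 61 genomes in groups of 13/11/12/25 by
default, class proportions equal to the reported composition
(12843 : 3735 : 28790 : 13698 over 59066 groups), occupancy drawn to
satisfy each class exactly (uniform over the class's count range, since no
within-class distribution is published), geometric copy numbers with mean
1.1 (the ratio of reported gene and occupancy totals), and genes laid out
in orthogroup order on one contig per genome so ranks and collinearity are
defined. Per-class group counts are allocated by largest-remainder
rounding, so realized proportions match the configuration deterministically.
It does **not** emulate real gene content, transposable elements, assembly
artifacts, sequence divergence within orthogroups, or realistic contig
fragmentation — so passing recovery tests demonstrate the correctness of
the algorithms under their stated assumptions, not robustness to
annotation noise.

`implant_duplications()` adds truth-labelled signal: tandem arrays as
adjacent extra copies, duplicated blocks as a second collinear run of 20
single-copy anchors on a fresh contig (two focal runs anchored to one
outgroup run). `spike_annotation_enrichment()` plants a term at baseline
rate outside a foreground and `odds`-times that rate inside (`odds = 1` is
the null; the product must stay a probability). `simulate_codon_alignment()`
evolves codons by exact matrix exponentials per branch — deterministic
under seed, and exactly matched to the likelihood engine, which is why
omega = 0 forbids nonsynonymous change mechanically.

Every generator is deterministic under its seed and restores the caller's
RNG state.

## Problem sizes used by the tests and the acceptance script

The package's own verification uses desk-scale problem sizes chosen to
make every stochastic check stable: 200 null simulations of 300-codon
alignments on a 6-taxon tree for the LRT calibration; 20 replicates of
500-codon alignments for foreground-omega recovery; 1000 null spike-ins
over a 2000-gene universe for the enrichment type-I rate; 400 all-core
orthogroups with 6 tandem arrays and 2 twenty-anchor blocks for
duplication recovery; exhaustive enumeration of all hypergeometric tables
with background up to 60 genes; 100 random 30-codon pairs against the
NG86 enumeration oracle. These sizes are the package's standing choices
and are the ones `scripts/acceptance.R` re-runs.

## Known limitations

* NG86 only; maximum-likelihood pairwise estimators (YN00-style) and
  gamma-corrected variants are future work.
* F3x4 and uniform codon frequencies only; universal code only (the code
  table is a configuration point).
* GO terms are tested without ontology propagation.
* The openness criterion is a descriptive power-law diagnostic, not a
  population-genetic model.
* NJ + bootstrap is a stand-in for ML phylogenetics.
* The WGD rule identifies duplication via one outgroup; it does not date
  duplications, separate triplication from older rounds, or subclassify
  proximal/dispersed duplicates.
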