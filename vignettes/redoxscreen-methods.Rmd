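---
title: "Methods: models, parameters and design choices in redoxscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in redoxscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxscreen)
```

redoxscreen implements the downstream analysis of a genome-wide RNAi
oxidative-stress screen: effect-size statistics over viability readings,
reduction of BLAST hits to a target-gene catalog, interaction-network
construction around those targets, pathway over-representation with term
clustering, and drug-target mining. This vignette documents the models and
the choices behind them.

## Effect-size model

Each siRNA condition is compared with the negative control at one timepoint
via Cohen's d: the mean difference divided by the Bessel-corrected
two-sample pooled SD,
$s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}$. The 95% CI uses
the large-sample normal approximation
$d \pm 1.96\,\mathrm{SE}$ with
$\mathrm{SE} = \sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}$ — the
standard asymptotic variance of a standardized mean difference. An exact
noncentral-t interval would differ at the third decimal for screen-sized
samples and is not worth the dependency.

Estimates are computed per timepoint with no cross-timepoint pooling:
robustness across timepoints is a question for a repeated-measures
mixed model, which is outside this package's scope.

**Bin convention.** Effect sizes are classified as large (0.8, ∞),
medium [0.5, 0.8], small [0.2, 0.5), very small [0.01, 0.2), none
(−∞, 0.01). Verbal descriptions like "between 0.5 and 0.8" are ambiguous at
the boundaries; this convention keeps "> 0.8" and "< 0.01" literal and
assigns every finite value exactly one bin. Negative d (siRNAs that *reduce*
survival) classifies by signed value and therefore lands in "none": the
screen selects protective effects, and a harmful siRNA is not a weak
protective one.

**Degenerate inputs.** A zero pooled SD with unequal means raises a
distinct `infinite_effect` condition rather than returning `Inf`; equal
constant samples give d = 0. Fewer than two replicates per arm raises
`insufficient_data`.

`ddct_fold_change` implements relative qPCR quantification,
$2^{-\Delta\Delta C_t}$ against a reference transcript and control
condition; `-log2` of the result recovers ΔΔCt to machine precision.

## Synthetic screen generator

`simulate_screen` emulates plate readings: the negative control has mean
100 survival units, siRNA *i* has mean $100 + d_i\,\sigma$ where $d_i$ is
its planted standardized difference (cycled through one representative
value per bin, `c(1.2, 0.65, 0.35, 0.1, 0)`, by default) and $\sigma$ is
the reading noise SD; noise is Gaussian and homoscedastic across
conditions. Defaults mirror the screen geometry the package targets:
181 siRNAs, 4 replicates, readings at 19, 24, 48, 72, 120 and 144 h.
Nothing is published about the true noise distribution of resazurin-based
viability readings at this scale, so Gaussian homoscedastic noise is a
deliberate simplification — it is the simplest model under which the
planted values are exactly the population effect sizes.

Because Cohen's d is scale-invariant, its sampling error depends only on
the replicate counts, not on $\sigma$: shrinking the noise shrinks the
planted mean shifts proportionally, so the estimate does *not* converge to
$d_i$ as $\sigma \to 0$, and at $\sigma = 0$ the planted effect vanishes
with the noise. The generator therefore offers `noise = "exact"`, which
replaces the random residuals by a fixed pattern with exact sample mean 0
and SD 1 in every condition–timepoint cell. Under this mode the estimated
d equals the planted d to machine precision at any $\sigma$ — it realizes
the zero-noise *limit* of the estimator as an implementable setting, and is
what the exact-recovery tests use.

A consequence worth stating: with Gaussian noise, the sampling SD of d at
$n$ replicates per arm is about $\sqrt{2/n + d^2/(4n)}$ (~0.32 at
$n = 20$), while the narrow bins are only ~0.1–0.3 wide. Per-siRNA bin
assignment at screen-like replicate counts is therefore intrinsically noisy
— roughly half of siRNAs land in their planted bin at 20 replicates per
arm, and near-complete recovery would need hundreds of replicates.
`scripts/acceptance.R` measures this recovery rate rather than assuming
it; the exact mode exists precisely so that correctness of the estimator
and classifier can be separated from this irreducible sampling noise.

## Hit reduction

The reducer applies, in order: accession-prefix whitelist
(NM/NR/NP/XM/XR/XP — transcript and protein RefSeq-style records, which is
how "mRNA, RNA or protein molecule types" is operationalized), per-query
minimum E-value with **ties retained** (several equally good targets per
siRNA are biologically plausible for short randomized queries, and a
catalog can legitimately hold more target genes than queries), removal of
hits lacking an Entrez annotation, and per-query case-insensitive symbol
deduplication keeping the minimum-E occurrence (symbol case is
inconsistent across sources). Accession version suffixes are stripped
before annotation lookup; annotation tables are versionless. Because decoy
E-values in the generator always exceed the planted best hit by at least
one order of magnitude, prefix filtering and best-hit selection commute on
generated tables — asserted as a property test. Biotype tallies count each
unique Entrez gene once regardless of how many queries hit it, so the
tally always sums to the unique-gene count.

## Interaction networks

Edges carry STRING-style integer combined scores in [41, 998]; duplicate
unordered pairs collapse to the maximum score and self-loops are dropped.
Shell expansion is role-tagged: shell-1 nodes have at least one edge at
score ≥ t1 to a target; shell-2 nodes have at least one edge at ≥ t2 to a
shell-1 node and are neither targets nor shell-1. Thresholds are inclusive.
Default t1 = t2 = 900 ("very high confidence"), with 700 ("high
confidence") as the conventional relaxed setting; the second shell stays at
900 because the candidate space grows too fast otherwise.

The edge set is the **induced subgraph** over the selected nodes
(shell1–shell1 and shell2–shell2 edges included, at the applicable
threshold) — the convention of interactive STRING viewers — rather than
only target-touching edges; the choice matters for connectivity statistics
and is therefore fixed and documented. Summaries count only nodes with at
least one interaction, and report one-decimal percentages of that total.
The LCC is computed with igraph and cross-checked in the tests against a
union-find oracle. The targets-only network column uses shells = 0 at
t1 = 900; no authoritative threshold exists for that configuration, so the
default very-high setting is used.

Evidence-channel filtering of interaction tables is out of scope: the
loader consumes whatever table it is given and assumes any
evidence-type restriction happened upstream.

## Enrichment and term clustering

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ (via `stats::phyper`; the tests cross-check every feasible
configuration with $N \le 12$ against full combinatorial enumeration). The
universe defaults to the union of all collection annotations, and the query
is intersected with the universe before testing. BH-FDR is applied across
the whole tested collection (`stats::p.adjust`, cross-checked against the
hand-written step-up); significance means adjusted p < 0.05. Collections
can be concatenated before testing for an integrated multi-knowledgebase
run, in which case the adjustment is joint. No gene-set size filters are
applied by default; both bounds are exposed as options.

Term clustering follows the ClueGO construction: the kappa score between
two significant terms is Cohen's κ of their gene-membership indicators
over the union of all significant terms' genes (the reference universe is
not defined by the original method description; the union is the smallest
universe that makes all memberships well defined). Each term seeds a
candidate group of itself plus all terms with κ ≥ 0.5; groups sharing more
than 50% of the smaller group's terms merge, to a fixed point. Seeding and
merging operate over terms sorted by identifier, so the outcome is
independent of input order. The leading term is the member with the
smallest adjusted p, ties broken toward the lexicographically smaller
identifier. κ is undefined when expected agreement is 1 (both sets empty,
or both equal to the reference); `kappa_score` raises a distinct condition
there, while the clusterer treats identical sets as perfect agreement
(κ = 1) before the formula is consulted, which resolves the only
degenerate case that can actually arise from distinct significant terms.
Note that BH re-application is *not* idempotent (each pass re-multiplies
sorted values by $m/i$), so no such property is claimed or tested.

## Drug mining

Two table dialects normalize to one record schema; the development-stage
vocabulary is closed to approved/patented/other, with unknown tokens
warning and mapping to "other". Within one database, intersections use the
drug identifier — name variants across salts and formulations make names
unreliable inside a database. Across databases, where identifiers do not
correspond, identity is the normalized name (lowercase, trimmed, internal
whitespace collapsed), one match per name. Intersections default to
approved drugs only, matching how common-drug tables in screen reports are
presented. "Patented" is kept as a distinct status because target-database
reports count it separately.

The packaged fixture (`inst/extdata/common_drugs_*_synthetic.tsv`) carries
real drug names and database codes for twenty approved drugs but
**synthetic** gene assignments (the real assignments are not published);
file names and this vignette flag it accordingly. It is constructed so the
within-DB intersection of the two gene lists is exactly the fourteen drugs
without a TTD code and the cross-database name match is exactly the six
drugs with one.

## Pipeline and configuration

`validate_config` fills defaults (900/900/700 scores, 0.05 adjusted-p,
0.5 kappa) and reports all violations at once. Simulation blocks must
carry an explicit seed — there is no wall-clock seeding anywhere, so a
config fully determines every output byte; the manifest records an MD5 per
output file plus the config hash. Stages communicate through files, so any
stage can be rerun from prior outputs. In the simulated world the planted
interactome modules mix catalog genes with dedicated interactor nodes,
making the 1st shell non-empty and known, and the enrichment query is the
planted catalog's Entrez set — the stages chain exactly as they would on
real data.

## What the generators do not emulate

No sequence-level siRNA:mRNA matching or thermodynamics (BLAST itself is
consumed, never run); no evidence channels or score calibration of real
interactomes (modules are planted cliques at the very-high tier, background
attachment is sparse and low-scoring); no realistic gene-set overlap
topology (background sets are uniform draws, so their query overlaps are
hypergeometric by construction — which is precisely what makes the planted
set's p-value interpretable); no pharmacological direction-of-action
reasoning (choosing an antagonist over an agonist is a human decision).
Passing closure tests therefore demonstrates correctness of the
*computations*, not fidelity of any distributional detail of real assays.

## Problem sizes

The test suite and acceptance script run the full pipeline over 20 seeds at
30 siRNAs × 20 replicates, 30 queries over a 100-gene pool, 15-node planted
interactomes over 25 background nodes, 25 gene sets over a 600-gene
universe, and drug tables with 4 planted common and 2 cross-database drugs
— sizes chosen so each closure check is exact (catalog, LCC, drug counts)
or high-powered (enrichment) while the whole suite stays fast; oracle
comparisons run at the largest sizes where enumeration is still exact
(N ≤ 12 for the hypergeometric, ≤ 50 nodes for components).

## Known limitations

Per-timepoint effect sizes ignore within-siRNA correlation across
timepoints; the CI is asymptotic; catalog reduction trusts the annotation
table (no live identifier resolution); network construction assumes the
interaction table's identifiers already match the catalog's; kappa
clustering reproduces the documented behaviour of the reference tool but
not its "GO term fusion" preprocessing; drug mining does not parse real
DrugBank XML or TTD flat files, only the generic dialects.
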