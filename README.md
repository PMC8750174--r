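# redoxscreen

Computational analysis of genome-wide RNAi oxidative-stress viability
screens. The package covers the full downstream arm of such a screen — from
raw plate readings to drug-repurposing candidates — for researchers running
randomized siRNA libraries under lethal oxidant challenge (e.g. H2O2 on
airway epithelial cells) and asking which silenced transcripts protect the
cell, what those targets do together, and which approved drugs already reach
them.

## What it computes

1. **Per-siRNA effect sizes** (`screen_effects`). For each siRNA and
   timepoint, Cohen's d against the negative control,
   d = (x̄_test − x̄_control) / s_p with the Bessel-corrected pooled SD, a
   95% normal-approximation CI
   (SE = sqrt((n1+n2)/(n1·n2) + d²/(2(n1+n2)))), and a five-bin
   classification: large (> 0.8), medium [0.5, 0.8], small [0.2, 0.5),
   very small [0.01, 0.2), none (< 0.01). `ddct_fold_change` gives qPCR
   2^−ΔΔCt fold changes for follow-up knockdown validation.
2. **Target-gene catalog** (`reduce_hits`). BLAST tabular (outfmt 6) hits
   are reduced per query: RefSeq-style accession prefix whitelist
   (NM/NR/NP/XM/XR/XP), lowest-E-value hits (ties kept), removal of hits
   without an Entrez annotation, case-insensitive per-query symbol
   deduplication; the catalog reports unique Entrez IDs and a biotype tally.
3. **PPI networks** (`expand_network`). STRING-links-style scored edges
   (combined scores 41–998), role-tagged expansion around the targets by
   1st/2nd interaction shells at inclusive confidence thresholds
   (defaults 900 very-high / 700 high), induced-subgraph edges, largest
   connected component, and summary tables with one-decimal percentages.
4. **Over-representation analysis** (`run_ora`, `cluster_terms`).
   Hypergeometric upper-tail tests of a gene list against GMT collections,
   BH-FDR across the collection (significant at adjusted p < 0.05), and
   kappa-score clustering of significant terms (κ ≥ 0.5 seeds groups,
   >50%-shared groups merge, the minimum-adjusted-p member leads).
5. **Drug mining** (`drug_mining_report`). Gene lists crossed against
   drug-target tables in DrugBank-like and TTD-like dialects: drugs per
   list, approved/patented subsets, within-database intersections by drug
   id, cross-database intersections by normalized drug name, and
   per-pathway drug coverage.

Every input has a synthetic generator with planted ground truth
(`simulate_screen`, `simulate_hits_and_annotation`, `simulate_interactome`,
`simulate_genesets`, `simulate_drug_tables`), so the entire pipeline can be
exercised and validated offline. `run_pipeline` drives all stages from one
validated config (YAML/JSON or list) and writes a hashed output manifest;
`inst/cli/redoxscreen.R` exposes the same stages as shell subcommands.

## Worked example

```r
library(redoxscreen)

# a 181-siRNA screen: 4 replicates, readings at 19-144 h
scr <- simulate_screen(n_sirnas = 181, replicates = 4, timepoints = 6,
                       noise_sd = 10, seed = 1)
eff <- screen_effects(scr$readings, "negative_control")
summarize_screen(eff, 19)
#>      large     medium      small very_small       none
#>         43         30         30         26         52

cohen_delta(c(2.0, 2.2, 1.8, 2.0), c(1.0, 1.2, 0.8, 1.0))[c("delta", "ci_low", "ci_high")]
#> $delta      6.123724
#> $ci_low     2.818494
#> $ci_high    9.428955

# BLAST hits -> target catalog
sim <- simulate_hits_and_annotation(n_genes = 500, n_queries = 167, seed = 2)
reduce_hits(sim$hits, sim$annotation)
#> Target catalog: 167 annotated target genes over 167 queries; 167 unique Entrez IDs
#> Biotype tally: lncRNA=10, protein coding=149, pseudogene=6, TEC=2

# very-high-confidence 1st-shell network around ten targets
si <- simulate_interactome(module_sizes = c(20, 8, 5), n_background = 50, seed = 3)
edges <- load_interactions(si$interactions)
net <- expand_network(si$truth$planted_modules[[1]][1:10], edges, shells = 1, t1 = 900)
summarize_network(net, si$truth$planted_modules[[1]][1:10])
#> Total genes (>=1 interaction): 20
#> siRNA target genes: 10 (50.0%)
#> Total interactions: 190
#> Flagged genes: 0 (0.0%)
#> LCC size: 20 (100.0%)
```

The bin counts are the screen's result: how many siRNAs conferred large
through no protection at the first reading. The catalog print shows how many
annotated target genes survived hit reduction and their biotype composition.
The network summary mirrors a screen-report table: connected genes, the
target fraction, interaction count, and the largest connected component with
its percentage of the network.

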