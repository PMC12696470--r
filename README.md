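# saltol

Dual-method evaluation of crop saline-alkaline tolerance and downstream
candidate-gene discovery, as a tested R package.

## What it is for

Breeding programmes screen cultivar panels for tolerance to
saline-alkaline soil by measuring physiological indicators — antioxidant
enzymes (SOD, CAT, POD), soluble protein (SP), total antioxidant capacity
(AOC), and the damage/osmolyte markers MDA and Pro — under control and
stress conditions, then need to collapse the panel into a defensible
tolerance ranking and connect it to transcriptome data. `saltol`
implements that workflow:

* **Ranking.** Per-cultivar change rates
  `x_ij = (mean_stress − mean_control)/mean_control` are standardized by
  direction (min–max for positive indicators, reversed for negative ones
  such as MDA and Pro). The membership-function composite is
  `u_i = Σ_j w_j X_ij` (equal weights by default, entropy weights
  `w_j = (1 − e_j)/Σ(1 − e_j)` as an option). TOPSIS cross-validates the
  ranking through relative closeness `C_i = D_i− / (D_i+ + D_i−)` to the
  per-indicator ideal `A+ = max_i X_ij` and anti-ideal `A− = min_i X_ij`.
  Concordance between the two orderings is reported as closed-form
  Spearman ρ, Kendall τ and the count of rank reversals.
* **Discovery.** Threshold differential expression per
  (cultivar, tissue) group (fold change > 1.5 and BH FDR < 0.05 on a
  log2 Welch test), intersection across all groups, a from-scratch
  weighted co-expression core (soft-thresholded adjacency `|cor|^β`,
  topological overlap, average-linkage module detection with eigengene
  merging at 0.25 and minimum module size 30, module–trait correlation),
  top-30 intramodular hub selection, and the final candidate set =
  trait-linked hubs ∩ shared DEGs.
* **Synthetic ground truth.** Seeded generators plant a tolerance
  gradient, DEG sets with a 39-gene shared core, co-expression modules
  tied to traits, and 13 hub-and-shared candidate genes, so every stage
  is testable without external data.

## Worked example

```r
library(saltol)

# a simulated 9-cultivar, 7-indicator panel with known tolerance order
panel <- simulatePhysioPanel(seed = 20)
res <- rankCultivars(panel)
res$membership
#> MembershipResult (higher = more tolerant)
#>   ranking: cv09 > cv05 > cv04 > cv06 > cv03 > cv07 > cv02 > cv08 > cv01
res$concordance
#> ConcordanceResult: Spearman rho = 1.0000, Kendall tau = 1.0000, 0 reversals
```

Both methods recover the planted order exactly at the default 2%
measurement noise; `res$concordance` quantifies their agreement, and
`res$scoreCorrelation` gives the score-level (u vs C) Pearson
correlation.

The full discovery pipeline on a simulated expression study:

```r
cfg <- pipelineConfig(simulation = list(), seed = 20)
rep <- runPipeline(cfg)
rep$summary$nShared        # genes differential in all four groups
#> [1] 39
rep$summary$traitModules   # modules passing the trait-link gate
#> [1] 5 6 7
rep$summary$nCandidates    # trait-linked hubs that are shared DEGs
#> [1] 13
head(rep$candidates, 4)
#>       gene module  kWithin
#> 1 gene0001      5 16.67575
#> 2 gene0002      5 16.61866
#> 3 gene0003      5 16.57953
#> 4 gene0004      5 15.50683
```

The 39 shared genes and the 13 candidates are exactly the generator's
planted sets (`groundTruth(rep$study)$sharedSet`, `$candidates`). Setting
`outDir` in `pipelineConfig()` persists every intermediate
(`membership.tsv`, `topsis.tsv`, `concordance.json`, per-group DEG
tables, `modules.tsv`, `module_trait.tsv`, `hubs.tsv`, `candidates.tsv`,
`report.json`).

Two reference nine-cultivar orderings that differ by one adjacent swap
illustrate the concordance arithmetic:

```r
a <- c("JD1","CD32","QN52","TQ1","TD5","TD15","JD46","JD49","QN54")
b <- c("JD1","QN52","CD32","TQ1","TD5","TD15","JD46","JD49","QN54")
compareRankings(a, b)
#> ConcordanceResult: Spearman rho = 0.9833, Kendall tau = 0.9444, 2 reversals
```

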