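# macmic

Chromatin features that are strongly correlated across the genome —
H3K4me3 and H3K27ac at active promoters, say — colocalize for an obvious
reason. The interesting pairs are the ones that colocalize *more than their
correlation predicts*: classic examples are bivalent domains, where H3K4me3
and H3K27me3 share thousands of loci in embryonic stem cells even though the
two marks are nearly uncorrelated genome-wide, and CTCF sitting inside a
subset of super-enhancers. `macmic` scores feature pairs for exactly this
excess, and provides the downstream gene-ranking and CTCF-associated
super-enhancer machinery that makes the scores interpretable.

## The score

For each feature, peak signal is aggregated over every gene's promoter
window (3 kb upstream to 10 kb downstream of the TSS, strand-aware) into a
per-gene signal vector. For a pair of features *X*, *Y* the association is
measured by mutual information

> I(X;Y) = H(X) + H(Y) − H(X,Y),  H(X) = −Σᵢ P(xᵢ) log P(xᵢ)

where the sum runs over genes and P(xᵢ) is the Poisson probability of the
observed promoter signal of gene *i* under a background rate (two estimation
modes: uniform genome-wide background × window width, or the mean promoter
signal). The joint term is available as the per-gene product-Poisson form
(the default, mirroring the per-gene marginal sums) or as a standard
equal-occupancy binned estimator (`joint_mode = "empirical"`), and `|r|`
(absolute Pearson correlation) can replace mutual information entirely
(`assoc = "abs-pearson"`).

Colocalization C is the genome-wide count of ≥ 1-bp overlap events between
the two features' peaks. Across a panel of pairs, ordinary least squares of
C on I gives each pair an expected count C_expected, and

> MACMIC = (C_observed − C_expected) / C_expected

Large positive scores flag pairs with far more shared loci than their
statistical dependence explains; an externally studentized residual gives
each pair a two-sided p-value.

Also included, for working with the scored pairs:

* **Gene ranking** — per-feature promoter-width ranks, per-gene rank
  products (RP = r₁·r₂, restricted to genes where the two features
  colocalize in the promoter), top-N gene groups and set-overlap
  percentages.
* **Super-enhancer classification** — ROSE-style stitching (12.5 kb) and
  rank-signal inflection calling, high-confidence CTCF peaks (height above
  the upper quartile), CSE/OSE partition of super-enhancers, CSE/OSE gene
  assignment, and the enlarged-typical-enhancer null simulation.
* **Synthetic panels** — a seeded generator that plants per-gene signal
  correlation and genome-wide colocalization counts *independently*, plus a
  hockey-stick enhancer landscape with known super-enhancer labels: every
  claim the package makes is testable without downloading a single dataset.

## Worked example

Simulate a small panel: five background pairs whose signal correlation and
colocalization rise together, and one bivalent-like pair with independent
signals (ρ = 0) but 150 planted shared loci.

```r
library(macmic)
library(dplyr)

targets <- bind_rows(
  tibble::tibble(cell_type = sprintf("bg%02d", 1:5), feature_a = "H3K4me3",
                 feature_b = "H3K27ac", rho = c(0.2, 0.4, 0.5, 0.7, 0.85),
                 c_star = c(40L, 70L, 90L, 130L, 150L)),
  tibble::tibble(cell_type = "hesc", feature_a = "H3K4me3",
                 feature_b = "H3K27me3", rho = 0, c_star = 150L))

pan <- simulate_panel(targets, n_genes = 1000, seed = 42)
panel <- score_panel(pan$manifest, pan$tracks, pan$genes, joint_mode = "empirical")
panel
#> MACMIC panel: 6 pairs (assoc = mi, joint_mode = empirical)
#> Colocalization ~ association OLS fit: C = 70.79 + 112.4 * I (6 pairs, residual SE 42.13)
#> # A tibble: 5 × 11
#>   pair_id     cell_type feature_a feature_b     I C_observed C_expected   macmic
#> 1 hesc:H3K27… hesc      H3K27me3  H3K4me3   0.122        150       84.5  0.774
#> 2 bg04:H3K27… bg04      H3K27ac   H3K4me3   0.414        130      117.   0.108
#> 3 bg05:H3K27… bg05      H3K27ac   H3K4me3   0.713        150      151.  -0.00601
#> ...
```

The bivalent-like pair has the lowest mutual information (0.12) yet as many
observed overlap events (150) as the most correlated background pair, so it
tops the ranking with MACMIC 0.77 — 77% more colocalization than the panel
regression predicts at that association level. `tidy(panel)` returns the
full pair table, `glance(panel)` the regression summary, and
`autoplot(panel)` the MI-versus-colocalization scatter with the fitted line.

A thin command-line wrapper over the same functions ships in
`inst/cli/macmic.R` (subcommands `score`, `rank-genes`, `call-se`,
`classify-cse`, `enlarge-sim`, `simulate`).

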