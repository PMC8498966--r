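---
title: "Scoring excess colocalization of chromatin features: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring excess colocalization of chromatin features: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macmic)
```

# The problem and the model

Two chromatin features can share genomic loci for two very different
reasons: because their signals rise and fall together across the genome
(correlation), or because a specific subset of loci recruits both marks
even though the marks are otherwise unrelated. Bivalent H3K4me3/H3K27me3
domains and CTCF inside super-enhancers are the canonical second case.
This package separates the two by regressing a pair's genome-wide
colocalization count on its statistical association and scoring the
relative excess:

$$\mathrm{MACMIC} = \frac{C_\mathrm{observed} - C_\mathrm{expected}}{C_\mathrm{expected}}$$

where $C_\mathrm{observed}$ counts ≥ 1-bp overlap events between the two
peak tracks, and $C_\mathrm{expected}$ is the prediction of a panel-wide
ordinary-least-squares fit of $C$ on the association value $I$. The score
is dimensionless and scale-free: doubling sequencing depth (which scales
all counts together on a well-fit panel) leaves it unchanged.

## Association: mutual information over promoter signals

Association is computed over per-gene promoter signals: each feature's
peaks are mapped to gene promoter windows (3 kb upstream to 10 kb
downstream of the TSS, strand-aware, clipped at position 0), and the
summed peak signal in gene $i$'s window is $x_i$. The entropies are
per-gene sums

$$H(X) = -\sum_{i=1}^{n} P(x_i)\,\log P(x_i), \qquad
  H(X,Y) = -\sum_{i=1}^{n} P(x_i, y_i)\,\log P(x_i, y_i),$$

with $I(X;Y) = H(X) + H(Y) - H(X,Y)$ and $P(x_i)$ the Poisson probability
of the observed signal under a background rate $\lambda_i$. Two points
deserve emphasis, because this estimator is *not* the textbook
distribution-level mutual information:

* the sums run over genes, not over distinct signal values — duplicating
  every gene doubles $H$;
* in the default `joint_mode = "product-poisson"`, the joint probability is
  the product of the two marginal Poisson probabilities, so $I$ depends on
  the joint distribution only through the per-gene *pairing* of marginal
  probabilities.

We implement this per-gene Poisson form exactly as the method defines it,
and additionally provide `joint_mode = "empirical"`: a standard plug-in
histogram estimator on $B \times B$ equal-occupancy bins (default
$B = 16$), in which all three entropies are distribution-level binned
estimates. The empirical mode has the properties one expects of mutual
information — it is near zero (up to the well-known
$(B-1)^2/2n$ plug-in bias) for independent signals and equals the marginal
entropy for identical ones — and our simulation studies therefore use it
whenever the analysis requires $I$ to track a planted signal correlation.
The product-Poisson mode remains the default for fidelity to the method's
printed definition; the two modes are both recorded in every output.
`assoc = "abs-pearson"` substitutes $|r|$ for $I$ throughout, as a linear
sanity check.

## The background rate λ

The method's definition does not pin down $\lambda$. We expose two modes:

* `lambda_mode = "global"` (default): a uniform-background expectation,
  track-wide total signal divided by the effective genome length, times
  each gene's window width. This is the natural null for "how surprising is
  this much signal here" and follows the broad-promoter-mark precedent of
  Poisson background models in ChIP-seq;
* `lambda_mode = "promoter-mean"`: the mean observed promoter signal,
  identical for every gene — a promoter-centric null that discounts the
  genome-wide enrichment of promoter marks.

Continuous signals are rounded to the nearest integer before pmf
evaluation (Poisson is a counting distribution; the rounding rule is
tested). All pmf work is done in log space, and each entropy term is
evaluated as $e^{\log p}(-\log p)$ so that $p \to 0$ gives a clean 0
rather than $0 \cdot \infty$.

## Colocalization counting

A colocalization event is a ≥ 1-bp overlap between one peak of feature A
and one peak of feature B; coordinates are 0-based half-open throughout,
so touching intervals do not overlap. The default counts intersecting
A×B *peak pairs* — one A peak spanning two B peaks yields two events —
which reads "number of overlapping events" literally and is symmetric in
the arguments. Because the alternative reading (count merged intersection
loci) is also defensible, `mode = "merged-loci"` provides it; the two
differ only when peaks are nested or chained. Counting is delegated to
interval trees (GenomicRanges) and is checked against an exhaustive
all-pairs oracle in the test suite.

## The regression and the residual test

One OLS line is fitted across the whole panel (all cell types pooled),
matching the panel-wide definition of the expected count; per-cell-type
fits are a trivial variation the user can run by subsetting the manifest.
Pairs are flagged by the externally studentized residual referred to a
$t$ distribution with $n - 3$ degrees of freedom, two-sided, with the
direction (above/below the line) reported alongside. This choice is not
dictated by the method's prose ("the residual is equal to zero" names no
test); it is the standard outlier diagnostic for simple regression, and we
verify its calibration empirically: on null panels the p-values are
uniform (Kolmogorov–Smirnov check in the acceptance suite).

When the fitted line predicts $C_\mathrm{expected} \le 0$ (possible at very
low association), the score is reported as missing rather than clamped: a
clamped denominator would fabricate arbitrarily extreme scores precisely
where the regression is least informative.

# Gene ranking

Genes are ranked per feature by total promoter peak width (rank 1 =
widest; ties broken by gene id so ranks are always a permutation of
$1..n$; zero-width genes rank last). For a feature pair, each gene's rank
product is $RP_i = r_{1,i} \cdot r_{2,i}$, and genes whose promoters show
no ≥ 1-bp colocalization of the two features are removed before ranking.
The method's displayed formula prints a product over all genes, which
would be a single scalar; the per-gene product is the only reading
consistent with ranking *genes* by it, and is what we implement. Gene
groups default to the top 500 (configurable), and set-overlap summaries
report percentages at both one-decimal and integer precision, since both
conventions appear in practice.

# Super-enhancers, CSEs and OSEs

H3K27ac peaks within 12,500 bp are stitched; stitched enhancers are ranked
by total signal ascending; with both axes scaled to $[0,1]$, the cutoff is
placed where the tangent slope of the rank-signal curve first reaches 1,
and enhancers above it are super-enhancers. These are the standard
rank-ordering parameters; since the upstream method does not restate them,
all are configurable (stitch distance, and no TSS-exclusion window by
default because none is specified). The implementation is validated
against an exhaustive slope search and against generated landscapes with
known super/typical labels (recall ≥ 0.9 required at signal ratio 50).

High-confidence CTCF peaks are those with height strictly greater than the
upper quartile of the track's peak heights, computed with the
linear-interpolation (type-7) quantile — the R default; the strict
comparison follows "larger than", so an all-equal track yields none.
Super-enhancers containing at least one high-confidence CTCF peak are
CSEs, the rest OSEs; the two classes partition the super-enhancers by
construction. CSE/OSE genes are genes whose body overlaps an enhancer of
the class by ≥ 1 bp; a gene touching both classes is assigned to CSE (the
more specific call; logged). Because no ordering criterion is specified
for "top CSE genes", we order by the strongest overlapping enhancer's
total signal, descending — a divergence risk we flag explicitly.

The enlargement null asks whether CTCF association of super-enhancers is a
mere size effect: each typical enhancer is matched to a random
super-enhancer (with replacement, since the two counts rarely agree) and
grown symmetrically about its midpoint to the matched width, clipping at
position 0 with the deficit moved to the other side so widths match
exactly. On fixtures where CTCF is planted preferentially in wide
enhancers, enlarged typicals gain CTCF association relative to raw
typicals but stay below true super-enhancers — the qualitative pattern the
simulation is designed to detect.

# What the generator emulates — and what it does not

`simulate_panel()` plants, per feature pair, (i) a per-gene signal
correlation $\rho$ via a Gaussian copula (eigen square root, so exactly
singular targets like $\rho = 1$ remain generable) on signal magnitudes
(Gaussian, mean 100, sd 20, floored at 1 — essentially never truncated),
and (ii) a target colocalization count $C^\*$ as dedicated overlapping
peak pairs in per-pair intergenic stripes with sub-width jitter. Promoter
peaks of different features occupy disjoint window offsets, so $\rho$ and
$C^\*$ are independently tunable — exactly the decoupling the score is
designed to detect, and the reason a planted excess pair is recoverable
ground truth. Feasibility (window slots, stripe capacity, events per
genome) is validated before anything is generated; generation is a pure
function of its arguments, including the mandatory seed, and written
panels are byte-identical across runs.

What the toy panels do *not* emulate: multi-peak promoters with realistic
width distributions, chromosome-scale coordinate structure, copy-number
and mappability artifacts, signal autocorrelation along the genome, or
peak-caller noise. Passing tests demonstrate the algorithms are
implemented correctly and calibrated on their stated assumptions, not that
the biological conclusions transfer to any particular real dataset.
`simulate_enhancer_landscape()` similarly gives a heavy-tailed
(lognormal-width, gamma-density) enhancer landscape with a planted
super/typical split and optionally CTCF placed with probability rising
steeply with enhancer width, plus uniform background CTCF — enough
structure to exercise the inflection caller, the CSE/OSE partition and the
enlargement null, no more.

# Numerical and interface choices

* Coordinates are 0-based half-open everywhere; GTF input is shifted on
  read. Multi-transcript genes collapse to the most upstream TSS on the
  gene's strand with the union of extents as the body — deterministic, and
  consistent with one-promoter-per-gene scoring; the upstream tool's
  transcript choice is unknown, so this is our convention.
* Plain BED tracks carry no signal; height and total signal fall back to
  peak width so width-based analyses run, but mutual information refuses
  such degenerate tracks unless explicitly allowed.
* narrowPeak `signalValue` maps to peak height; total signal is
  `signalValue × width` (narrowPeak stores no summed signal). The height
  column used for the CTCF quartile is therefore configurable in effect by
  supplying TSV input with explicit `height`.
* Ties: width ranking breaks by gene id; width groups break by
  (chrom, start); panel output breaks by (score desc, observed count desc,
  pair id). Every ordering in the package is deterministic.
* All randomness in a run flows from explicit seeds; `score_panel()` itself
  is deterministic given its inputs.

Problem sizes in the test and acceptance suites are chosen to make the
statistical checks sharp at desk scale: 100 random 30-peak fixtures for
the overlap oracle, 200-gene vectors for entropy oracles, 225-pair panels
for regression calibration (the size of the motivating somatic-cell
panel), 20 seeded 16-pair panels at 600 genes for planted-pair recovery,
and 1000-enhancer landscapes for the super-enhancer checks.

# Known limitations

* The per-gene Poisson mutual information is nonstandard; under the
  product-Poisson joint it measures dependence only through per-gene
  probability pairing, which is why the empirical mode exists and is used
  for correlation-sensitive validation.
* No multiple-testing correction is applied across pairs (none is defined
  for the method); users comparing many panels should correct downstream.
* Expected counts from a straight line can be non-positive at low
  association; affected pairs are reported as missing, not scored.
* The ROSE-style caller implements the rank-signal inflection rule only;
  TSS exclusion and input normalization, which production super-enhancer
  callers offer, are out of scope here.
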