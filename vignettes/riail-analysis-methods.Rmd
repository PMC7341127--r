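---
title: "Methods: linkage mapping, eQTL hotspots and mediation in RIAIL panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage mapping, eQTL hotspots and mediation in RIAIL panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riailmap)
```

# Overview

`riailmap` implements the statistical chain used to dissect complex traits
in two-parent recombinant inbred advanced intercross line (RIAIL) panels:
marker-regression linkage mapping with permutation thresholds and a forward
search, panel-scale expression-QTL mapping with a permutation FDR, Poisson
bin-enrichment detection of eQTL hotspots, and linear-structural-equation
mediation analysis that asks whether a gene's expression transmits a QTL's
effect onto an organismal trait. Because real microarray and genotype
resources are large and external, the package carries its own simulation
module whose planted ground truth exercises every stage.

This vignette is the package's account of the models, the defaults and the
numerical choices, and of what the synthetic data do and do not establish.

# The genotype model and the simulator

A RIAIL genome is a fine mosaic of two parental haplotypes. The simulator
builds each chromosome independently: a Bernoulli(0.5) starting allele, a
Poisson crossover count with mean `map_expansion * L / 100` for a
chromosome of genetic length `L` cM, breakpoints uniform in genetic
distance, and allele alternation at each breakpoint. This is the Haldane
(no-interference) model; under it the recombinant fraction between markers
separated by `d` cM is `r/2 = (1 - e^(-2d/100))/2`, and the test suite
checks the simulated panel against that closed form within binomial error.

Two simplifications are deliberate. First, advanced intercrossing is not
simulated generation by generation; its only consequence the downstream
statistics see — a denser breakpoint structure, i.e. an expanded effective
map — is captured by the single `map_expansion` scalar. Its default of 4 is
a round value typical of the map expansion reported for multi-generation
intercross panels; no published value exists for the panel that motivated
this package, so the parameter is exposed. Second, crossover interference
is omitted: none of the implemented statistics is sensitive to it, and the
no-interference model keeps the recombination fraction analytic.

Markers live on 6 chromosomes of 50 cM each by default (a nematode-like
genome), with physical positions an affine image of genetic positions at
40,000 bp/cM and a 1-based origin. The constant bp/cM factor is artificial
— real genomes have recombination-rate domains — but it makes both
coordinate systems exercisable at once: the 1 Mb local-eQTL window (25 cM
worth of sequence at this scaling) and the 5 cM hotspot bins land on the
same map. Genotypes are coded 0/1 rather than -1/+1; the LOD statistic is
correlation-based and therefore invariant to any affine recoding, and 0/1
matches homozygous-inbred biology. Missing genotypes are a dedicated `NA`
sentinel handled pairwise-complete downstream.

Traits are a sum of additive marker effects plus Gaussian noise scaled so
the genetic fraction of the variance matches `heritability_target` against
the realized genetic variance of the panel. Gaussian noise is the implied
model throughout: the organismal traits this chain is applied to are
residuals from linear models.

# Linkage mapping

## The LOD statistic

For trait values `y` and genotype codes `g` at one marker over the `n`
lines with both observed, the scan statistic is

```
LOD = -n * ln(1 - R^2) / (2 * ln 10),   R = cor(g, y)
```

which is the marker-regression likelihood-ratio statistic in closed form.
`n` is per-marker (pairwise-complete), so panels with scattered missing
genotypes are scanned without dropping lines globally. Two numerical
guards: `1 - R^2` is floored at `1e-16`, so a perfectly separating marker
yields a large finite LOD (about `3.47 n`) rather than infinity; and
monomorphic markers, whose correlation is undefined, report `NA` LOD. The
whole scan is one crossprod of standardized matrices when data are
complete, and the test suite pins the blocked result to a naive per-marker
loop at `1e-10`.

## Permutation threshold

The 5% genome-wide threshold is the empirical 95th percentile of
per-permutation maximum LOD scores over `n_perm = 1000` trait
permutations. Permutation destroys genotype-phenotype linkage while
preserving the trait distribution and the marker correlation structure, so
the maxima form the correct genome-wide null. `alpha = 0` is special-cased
to an infinite threshold: a 0% error rate is not attainable from finitely
many permutations, and this keeps "no QTL at alpha 0" exactly true.

## Forward search and annotation

The marker with the highest LOD above the threshold is recorded, the
original trait is residualized by OLS on the genotype columns of all
recorded peaks, and the residuals are rescanned; iteration stops when no
marker passes or `max_qtl` is hit. Duplicated (collinear) cofactor columns
are dropped with a warning. The threshold is computed once, on the
original trait, and reused across iterations — one genome-wide error rate
per trait; `recompute_threshold = TRUE` re-permutes each iteration's
residuals instead, for users who prefer a per-iteration null. Ties at the
argmax break to the lowest genomic coordinate, deterministically.

Each QTL is annotated on the scan of the iteration that found it: the 95%
confidence interval walks outward from the peak to the first marker on
each side whose LOD falls strictly below `peak - 1.5` (that marker is
included as the bound — the "proximal" convention; the alternative
last-marker-above convention differs by at most one marker and is noted
here as a documented choice), or the terminal marker if the chromosome end
comes first. Variance explained is `1 - 10^(-2 LOD / n)`, which round-trips
to the peak marker's `R^2` exactly; the allelic effect is the difference
of genotype-class trait means (parent B minus parent A).

# Expression QTL and hotspots

## Permutation FDR

All probes are scanned at once and each probe's genome-wide maximum LOD
retained. The line labels of the entire expression matrix are permuted
jointly (10 permutations by default) — joint permutation preserves the
inter-probe correlation structure, which per-probe shuffling (available as
an option) would destroy. For each candidate threshold `t` on the grid
2–10 in steps of 0.01,

```
FDR(t) = mean permuted #(max LOD > t) / observed #(max LOD > t)
```

and the selected threshold is the smallest grid value with FDR below the
5% target — the most permissive threshold that still controls the FDR.
Strict `>` is used in both counts, mirroring the estimator's definition.
When the observed count is zero the ratio is defined as 0 if the permuted
mean is also 0 and infinite otherwise; if no grid value attains the
target, `NA` is returned with a warning rather than a silently extreme
threshold.

## Local versus distant, and hotspot detection

An eQTL is local when its peak marker lies on the probe's chromosome
within 1 Mb of the probe's start position, distant otherwise (any
cross-chromosome linkage is distant regardless of bp distance). For
hotspot detection the genome is cut into 5 cM bins per chromosome
(half-open `[start, end)`, final partial bin kept with its right edge
closed so terminal markers are counted), each distant eQTL is assigned by
its peak marker's genetic position, and bin counts are tested against a
Poisson null with mean `lambda = counted eQTL / total bins`. A bin is a
hotspot when its count strictly exceeds the smallest `k` with
`CDF(k; lambda) >= 1 - 0.01 / n_bins` — the Bonferroni-corrected 99th
percentile, computed by `qpois` and pinned in the tests to a direct
term-by-term CDF summation. `lambda` uses the distant-eQTL count (the
quantity actually binned); a caller who prefers total QTL over total bins
can pass `lambda_all`. A `lod_floor` of 5 or 6 reproduces the usual
robustness filters, and `hotspot_permutation_check` scatters the observed
eQTL uniformly over bins to confirm the test rarely flags anything under
the null (the Bonferroni expectation is below one spurious bin per
dataset).

# Mediation

For QTL genotype `G`, candidate mediator expression `M` and trait `Y`,
three OLS fits give the decomposition: `M ~ G` (slope `a`), `Y ~ M + G`
(slopes `b` and `c'`) and `Y ~ G` (slope `c`). The indirect (mediated)
effect is `a*b`, the direct effect `c'`, and `c = c' + a*b` holds exactly
by OLS algebra — the module's primary self-check, asserted at `1e-8` on
every fitted dataset. The mediated proportion `a*b/c` is reported but
never used for ranking: under inconsistent mediation (direct and indirect
effects of opposite sign, or |indirect| > |total|) it leaves `[0, 1]` and
is not interpretable.

Inference is a nonparametric percentile bootstrap: lines are resampled
with replacement (1000 resamples by default), the indirect effect
recomputed, and the two-sided p-value is `2 * min(frac <= 0, frac >= 0)`
with a half-count correction for finite resamples; the 95% CI is the
2.5–97.5 percentile interval. Resampling observations (not residuals) was
chosen as the assumption-lighter variant. Degenerate resamples (a single
genotype class or a constant mediator) are skipped. The ranking across a
candidate set uses |indirect effect| — the sign only encodes the direction
of the expression effect — and probes at or above the 90th percentile are
prioritized. A probe's percentile is the fraction of candidates with
strictly smaller score, so with distinct scores at most `ceiling(0.1 n)`
probes are flagged (exactly one of 10, four of 49). Per-probe bootstrap
seeds derive deterministically from the master seed, so results are
independent of evaluation order.

# Phenotype processing

The organismal traits this chain maps are control-regressed residuals:
one OLS line of drug-condition replicate values on per-strain control
means (`drug ~ mean_control`), fit jointly across strains, whose residuals
isolate drug-specific variation. If every control mean is equal the
regressor collapses and the fallback is intercept-only (residuals around
the grand mean). The derived trait `median.norm.EXT = median.EXT /
median.TOF` normalizes optical density by animal length. Residuals can be
affinely rescaled to `[0, 1]` for plotting; constant vectors are an error,
and the transform is idempotent on normalized input. Broad-sense
heritability comes from the random-effects model `phenotype ~ 1 +
(1|strain)` fit by REML (`lme4`), `H2 = var_strain / (var_strain +
var_resid)`, with negative component estimates truncated at zero before
forming the ratio; for exactly balanced designs a method-of-moments ANOVA
estimator is available and agrees in expectation. Pairwise strain
contrasts use Tukey's HSD on `phenotype ~ strain`. Whether control
regression should pool across assay batches is not determinable in
general; the implementation pools, and batch-wise use is a matter of
calling it per batch.

# Study conditions and what the tests show

The default synthetic conditions — 300 lines, 600 markers on 6
chromosomes, map expansion 4, 500 expression probes of which 20% carry
local eQTL of 0.8 SD, one 50-gene hotspot, and a mediated drug trait with
`a = 0.8`, `b = 0.5`, `c' = 0.2`, noise SD 0.5 — are fixed as the
package's desk-scale study conditions and are not tuned per analysis. At
those sizes the validation suite establishes: permutation thresholds are
calibrated (500 null traits, 1000 permutations each, exceedance within the
binomial band around 5%); the permutation-FDR threshold controls the
realized eQTL FDR at 5% within Monte-Carlo error over 20 replicates; a
planted 50-eQTL hotspot is flagged, and uniform scatter is not, in at
least 95% of 100 simulations; the mediation estimator recovers an indirect
effect of 0.40 with about 95% bootstrap-CI coverage over 200 replicates
and ranks the planted mediator first among 49 candidates in at least 90%
of runs; and heritability is recovered within 0.1 at 50 strains by 10
replicates.

What passing does **not** show: the simulator draws Gaussian,
homoscedastic noise with independent probes (beyond the planted hotspot),
equal-length chromosomes, uniform recombination and no genotyping error.
Real panels have correlated expression modules, segregation distortion,
heavy-tailed traits and batch structure; calibration there should be
checked with the same permutation machinery on the real data, which is
exactly what the permutation threshold and FDR procedures are for.

# Known limitations

- No interval mapping between markers and no mixed-model association:
  the scan is single-marker regression, as the LOD closed form requires.
- One mediator at a time; no sensitivity analysis for unmeasured
  genotype-independent confounding of the mediator-outcome path.
- The hotspot Poisson null assumes exchangeable bins; strong global
  distortions of eQTL placement would need the permutation check rather
  than the analytic quantile.
- The simulator is not a pedigree-level breeding simulator; epistasis,
  GxE and genotyping error are out of scope.
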