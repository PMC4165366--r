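---
title: "Detecting allele-specific expression by meta-analysis of SNV-level allelic counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific expression by meta-analysis of SNV-level allelic counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseMeta)
```

## The problem

In a diploid sample, the two haplotypes of a gene can be transcribed at
unequal rates (allele-specific expression, ASE). RNA-Seq reads overlapping
heterozygous exonic SNVs carry the signal: at SNV $s$ with $n_s$ total
reads, $x_{\mathrm{ref},s}$ support the reference allele and
$x_{\mathrm{alt},s} = n_s - x_{\mathrm{ref},s}$ the alternative. The
quantity of interest is the gene-level *major haplotype frequency* (MAF):
0.5 means balanced expression, 1 means monoallelic. Two obstacles shape the
method:

* counts from several SNVs of one gene must be aggregated into one
  gene-level measure, with heterogeneous coverage across SNVs; and
* for most samples (and for all somatic mutations) the haplotype phase of
  the SNVs is unknown, so it is not known which alleles sit together.

## One-sample model

Haplotype-1 supporting counts at a SNV are modelled as beta-binomial,
$$X_{1,s} \sim \mathrm{BB}(n_s,\; \mu = f_s(p_1),\; \rho),$$
with mean $n\mu$ and variance $\mu(1-\mu)\,n\,(\rho(n-1)+1)$. Here $p_1$ is
the gene-level haplotype-1 frequency, $\rho \in [0,1)$ absorbs
extra-binomial noise ($\rho = 0$ is exactly binomial), and $f_s(\cdot)$
maps transcript frequencies to read-observation probabilities. With no
technical bias $f_s$ is the identity; a global *pre-existing allelic bias*
(e.g. reference-mapping bias) is expressed through $f = f_{\mathrm{ref}}(0.5)$,
the probability of observing the reference allele when expression is
balanced, via the odds weighting
$$\mu = \frac{p\,f}{p\,f + (1-p)(1-f)}.$$

Each SNV's anchored count is variance-stabilized with the Freeman–Tukey
double arcsine,
$$z = \sin^{-1}\!\sqrt{\tfrac{x}{n+1}} + \sin^{-1}\!\sqrt{\tfrac{x+1}{n+1}}
\;\approx\; N\!\left(2\sin^{-1}\!\sqrt{p},\; \tfrac{1}{n+0.5}\right),$$
and scores are combined across SNVs by fixed-effects inverse-variance
weighting with per-SNV variance $(\rho(n-1)+1)/(n+0.5)$ (first-order
propagation of the beta-binomial variance). The combined score is
backtransformed by exact inversion of the mean map,
$p = \sin^2(z/2)$, giving the gene-level MAF estimate $T_{FT}$; Cochran's
$Q = \sum_s w_s (z_s - \bar z)^2$ measures inter-SNV heterogeneity of ASE,
which can indicate isoform-specific ASE. The DerSimonian–Laird $\tau^2$ is
computed as a diagnostic but never enters the point estimate: the printed
estimator is fixed-effects, and all inference comes from simulation, so the
choice does not affect p-values.

### Bias correction

When $f \neq 0.5$, each SNV's score is corrected *before* combination:
the score is mapped back to a read-scale proportion, inverted through the
odds map at the anchored allele's own null probability ($f$ when the
anchored allele is the reference, $1-f$ otherwise), and re-transformed.
At the mean this inversion is exact, and the identical correction runs
inside the null simulation, so calibration does not depend on its
first-order accuracy. The same composition of variance inflation and odds
mapping is used throughout; it is a stated approximation for extreme bias
or overdispersion, which is why defaults keep both mild.

## Pseudo-phasing and simulated nulls

When phase is unknown, a *voting* rule assigns the allele with the larger
read count at each SNV to a putative major haplotype (ties go to the
reference allele, deterministically). Under the null this folds each
count to $\max(X, n-X)$, so the nominal normal theory above becomes
anti-conservative — the reason nominal meta-analysis p-values are never
reported. Instead, holding every $n_s$ fixed, reference counts are redrawn
from the null ($\mu = f$, overdispersion $\rho$), the voting rule and the
full statistic pipeline are re-applied, and
$$p_{\mathrm{ASE}} = \frac{\#\{T^{sim} \ge T_{FT}\}}{N_{sim}}, \qquad
  p_{\mathrm{het}} = \frac{\#\{Q^{sim} \ge Q\}}{N_{sim}},$$
both floored at $1/(N_{sim}+1)$ so BH adjustment never sees a zero. For a
single SNV this construction converges to the two-sided exact binomial
test, which the test suite verifies against `binom.test` at every count
value. When true haplotype labels are supplied, no voting is done; the
major haplotype is whichever haplotype has the larger combined frequency
(the gene-level fold $\max(p, 1-p)$), and the same simulation machinery is
used for consistency.

Two implementation details matter for reproducibility and speed:

* the null distribution depends on a gene only through the multiset of its
  per-SNV totals (plus $\rho$, $f$, phasing mode), so genes sharing that
  shape share one simulation (`new_null_cache()`); cache admission is
  capped to bound memory, and a miss simply recomputes;
* each simulation's RNG stream is derived from the user seed and the shape
  key, so results are independent of gene order and identical count data
  always produce identical results.

## Two-sample (differential) ASE

For paired designs (tumor vs. matched normal), the measure is the
haplotype-frequency difference $D = p_{1,T} - p_{1,N}$; the test is
asymmetric, anchored on a *sample of interest*. Voting phasing is derived
exclusively from that sample and imposed on the other; per-SNV scores are
plain frequency differences
$z_s = x_{T,s}/n_{T,s} - x_{N,s}/n_{N,s}$ with null variance
$p(1-p)(1/n_T + 1/n_N)$ at the common frequency $p$ (each term inflated by
$\rho(n-1)+1$), combined by inverse-variance weighting into $T_{PD}$. No
variance-stabilizing transform exists on this scale, so the estimate is
more exposed to outlying SNVs than the one-sample path — a known
limitation.

The null simulation needs the common frequency $p$. The natural pooled
ratio of anchored counts is biased upward under balance, because voting
always anchors the larger count; simulating at an inflated $p$
*understates* the phasing-induced inflation of the statistic and makes the
test anti-conservative. The generation parameter is therefore estimated by
moment matching: $p$ is chosen so that the *expected* pooled anchored
count — computed exactly from the binomial folding distribution at each
SNV — equals the observed one (`uniroot` on $[0.5, 1)$). The raw pooled
ratio (exported as `estimate_null_p()`) still normalizes $Q$, identically
in the observed and simulated pipelines. Measured on 1,000 null genes,
residual miscalibration from plugging in a noisy estimate is within about
one Monte-Carlo standard error (±1.5 percentage points on the p-value
CDF); the one-sample path has no such plug-in and is calibrated exactly up
to Monte-Carlo error.

## Calling rules

`call_ase()` implements the assignment rules: a gene is called ASE when
its BH-adjusted ASE p-value is ≤ 0.05 *and* the effect size passes
(estimated MAF ≥ 0.7 one-sample; $D$ ≥ 0.2 two-sample — the analogue of
0.5 + 0.2). The effect-size gate exists because deeply covered genes reach
significance at allelic ratios too close to 1:1 to be biologically
interesting. Two-sample calls additionally require one-sample support in
the sample of interest. Genes with BH-adjusted heterogeneity p ≤ 0.05 are
flagged as possibly isoform-specific; that adjustment runs over multi-SNV
genes only, since single-SNV genes have no $Q$ test and would dilute the
family. The multiple-testing family is one sample's tested genes; the
package performs no adjustment inside `run_one_sample()` /
`run_two_sample()` themselves.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rho` | 0 (benchmark: 0.004) | beta-binomial overdispersion; 0.004 is a realistic RNA-Seq estimate and the benchmark setting |
| `f_ref` | 0.5 | global reference-allele observation probability at balanced expression; estimate with `estimate_global_bias()` |
| `n_sim` | 1e5 | null replicates per gene shape; 1e6 for final analyses, 1e4 in the scaled benchmark |
| `fdr_level` | 0.05 | BH level for calling |
| `maf_cutoff` / `maf_diff_cutoff` | 0.7 / 0.2 | effect-size gates |
| filters | 5 reads, 10%, 10 reads, 10 bp, 76 bp | DNA het support, DNA allele fraction, RNA coverage, variant proximity, read-sharing spacing |

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the method
assumes: genes stratified by SNV count (1–4, 5+ drawn 5–8) and per-SNV
coverage (10–20 … 50+, drawn 50–100), uniform within the bin; a fraction
of genes (default 25%) carry ASE with a constant signal MAF, one allele
per SNV assigned at random to the major haplotype and drawn beta-binomial
at the bias-mapped $\mu$; the rest draw reference counts at $\mu = f$.
Two-sample mode adds a balanced second sample. What it does *not* emulate:
real coverage distributions (the original benchmark reweighted strata by a
real sample's gene mix, so data-weighted overall TPR numbers are not
reproducible here — only within-stratum behavior), alignment artifacts,
correlated reads across nearby SNVs, isoform-specific signal, more than
two haplotypes, and locus-specific bias. Passing benchmarks therefore
demonstrate correctness of the statistics under the model's assumptions,
not robustness to every artifact of real data; the input filters exist
precisely to push real data toward those assumptions.

## Numerical choices and degenerate inputs

* Count ties in voting go to the reference allele; the null applies the
  same rule, so calibration absorbs the choice (how the original
  implementation breaks ties is not documented).
* Backtransform clips to $[0, \pi]$; bias maps reject boundary arguments;
  the pooled two-sample frequency is clipped to $[1/(N+2), 1-1/(N+2)]$ so
  the null never degenerates to zero variance.
* Empirical p-values use $\ge$ comparisons exactly as defined and are
  floored, never interpolated.
* A gene that fails (e.g. mixed labeled/unlabeled SNVs) yields a flagged
  record with an explanatory `note`, never a crashed batch.
* $(\mu, \rho)$ map to beta shapes $\alpha = \mu(1-\rho)/\rho$,
  $\beta = (1-\mu)(1-\rho)/\rho$; $\rho = 0$ short-circuits to binomial
  sampling.

## Problem sizes used in the shipped checks

The test suite and the acceptance script use a scaled benchmark profile
chosen to keep a desk-scale run comfortable while leaving Monte-Carlo
error well below the margins being tested: 10 replicates × 200 genes for
the single-stratum power check, 10 replicates × 40 genes/stratum × 3
signal levels for the FDR grid, $N_{sim} = 10^4$ with shape caching
($10^5$ for the single-SNV exact-test comparison), 2,000 genes for null
calibration, and 500 replicates for estimator recovery. The full-scale
profile (100 replicates, $N_{sim} = 10^6$) is available through the same
function arguments.

## Known limitations

* Exactly two haplotypes per gene are assumed; a duplicated-then-mutated
  third haplotype will be forced into two.
* The bias/overdispersion composition is first-order; extreme $f$ or
  $\rho$ values are out of its comfort zone.
* The two-sample scale is not variance-stabilized (outlier sensitivity),
  and its null uses a plug-in frequency estimate with the small residual
  miscalibration quantified above.
* The read-sharing merge is a distance heuristic (76 bp default): true
  read-level overlap information is not available from count tables.
* Voting phasing is not a haplotype reconstruction method; it is reliable
  only for genes with strong ASE, which is exactly the regime where the
  calls matter, and the simulation correction pays for it everywhere else.
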