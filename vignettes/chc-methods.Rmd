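---
title: "Inferring LOH by cohort heterozygosity comparison: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring LOH by cohort heterozygosity comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chcloh)
```

## The model

Loss of heterozygosity (LOH) converts a germ-line heterozygous genotype
into a somatic homozygote. When patient-matched normal samples are
unavailable, per-sample LOH calling is impossible; the cohort
heterozygosity comparison sidesteps this by working cross-sectionally.
At every SNP shared by an unmatched case cohort (size $n_c$) and a
control cohort (size $n_r$) it compares the observed heterozygosity
frequencies and defines

$$\Delta = \hat h_{\mathrm{control}} - \hat h_{\mathrm{case}},$$

so recurrent LOH in cases, which depletes heterozygotes, produces
positive $\Delta$ (negative values are reported but never suggestive).
Because the signal is a *frequency deficit*, it is blind to copy number
and therefore detects copy-neutral LOH, but it can only find loci lost
recurrently across the cohort — it deliberately does not produce
per-sample calls.

The procedure has four screening stages:

1. **Complete-call filter.** Any SNP with at least one absent call
   (`NoCall`) in either cohort is removed entirely. Removed SNPs are
   *invisible* downstream: they neither extend nor break contiguity.
2. **Informative-marker selection.** A SNP enters the comparison only if
   its annotated population heterozygosity value satisfies
   $HV \ge \max(1/n_c, 1/n_r)$ — the condition under which at least one
   heterozygote is expected in each cohort. At $n = 4$ this keeps
   roughly the upper half of a 250K-class array's markers.
3. **Delta thresholding.** $\Delta \ge \Delta_T$ flags a SNP as
   suggestive (inclusive comparison).
4. **Contiguity.** Within a chromosome, a maximal run of at least
   `cpt` consecutive suggestive SNPs (again inclusive) becomes an
   inferred-LOH region with enrichment score $ES = \sum \Delta$.

## The delta threshold

$\Delta_T$ is an effect-size calculation: the smallest cohort
heterozygosity difference detectable at one-sided level $\alpha$ with
power $1-\beta$ when per-cohort heterozygosity frequencies are treated as
approximately normal with common standard deviation $\sigma$:

$$\Delta_T = (z_{1-\alpha} + z_{1-\beta})\,\sigma\,\sqrt{2/n}.$$

With the defaults $\sigma = 0.3$, $\alpha = 0.05$, $1-\beta = 0.8$ this
gives $0.527$ at $n = 4$ and $0.334$ at $n = 10$, rounded (by default, to
one decimal) to the working thresholds 0.5 and 0.3. The unrounded value
is always retained on the returned object and echoed to the log. Points
worth making explicit:

* **Which $n$?** The case cohort size, by default. The control cohort is
  typically a large reference panel whose sampling noise is not limiting;
  `chc_params(threshold_n = "min")` switches to the conservative
  $\min(n_c, n_r)$.
* **Sidedness.** The test is one-sided: only case-ward heterozygosity
  deficits indicate LOH.
* **$\sigma = 0.3$** is a pragmatic prior on the spread of $\Delta$ at
  array SNPs; it is user-settable, and the empirical SD of the delta
  track is a reasonable data-driven substitute when cohorts are large.
* **Manual override.** `chc_params(delta_threshold = ...)` bypasses the
  formula entirely (e.g. running at 0.4 with $n = 10$ trades some power
  for specificity); the fitted object reports both the computed and the
  effective threshold so the provenance of every run is visible.
* A threshold $\ge 1$ is legal but useless (no frequency difference can
  reach it); the constructor warns. `n < 2` is an error.

The package's acceptance tests verify the unrounded thresholds against a
Monte-Carlo oracle: simulating two-sample normal shifts of exactly
$\Delta_T$ and checking that the one-sided rejection rate is 0.80
(100{,}000 replicates).

## Region calling semantics

Contiguity is defined over the *visible* track — retained, informative
SNPs — in coordinate order within a chromosome:

* a retained informative SNP with $\Delta < \Delta_T$ **breaks** a run;
* a removed or non-informative SNP is skipped and does **not** break it;
* runs never cross chromosome boundaries;
* both comparisons ($\Delta \ge \Delta_T$, length $\ge$ `cpt`) are
  inclusive;
* no physical-gap rule is imposed: two suggestive SNPs megabases apart
  but adjacent on the filtered track are contiguous. This mirrors the
  marker-index (not base-pair) nature of the screen; users worried about
  sparse coverage should inspect region `n_snps` against `size_bp`.

Regions are ranked by enrichment score, with deterministic tie-breaking
by larger SNP count, then (chromosome, start). Identical inputs produce
byte-identical output tables; a brute-force enumerator over every
contiguous window reproduces the caller exactly on thousands of fuzzed
tracks in the test suite.

Region coordinates are 1-based inclusive positions of the first and last
SNP of the run (region size is therefore `end - start`, the span between
its terminal SNPs); BED export converts to 0-based half-open and rescales
ES linearly so the top region scores 1000.

## Evaluation conventions

Against a set of validated LOH marker positions (for example from the
matched tumor/normal caller), a region encompassing any marker has
distance exactly 0; otherwise its distance is the minimum over markers on
that chromosome of the distance to the nearer region *end* (not the
midpoint). "Within 100 kb" is inclusive ($\le 10^5$ bp). Regions on
chromosomes with no validated marker have undefined distance and are
excluded from distance summaries with a warning. When merging per-sample
region lists into independent regions, intervals whose covered bases are
contiguous — overlapping *or* book-ended — merge, which is the
base-coverage union (the bedtools convention); support counts distinct
contributing samples.

The matched-pair caller itself uses the standard convention: germ-line
heterozygote to tumor homozygote is LOH, heterozygote conserved is
retention, homozygous germ line is non-informative, any absent call is
`NO_CALL`. A homozygote flipping to the *opposite* homozygote is
classified non-informative and logged as a discordance: LOH requires
germ-line heterozygosity, and such flips are overwhelmingly genotyping
error. No HMM or regional smoothing is applied — the validation surface
is deliberately per-SNP.

## The simulator

`simulate_cohorts()` emulates the data-generating assumptions of the
method, not a whole genotyping pipeline:

* Each SNP's annotated heterozygosity value $HV \sim U(h_{\min},
  h_{\max})$ (default $[0.05, 0.5]$, the range an array annotation
  spans) is converted to a minor allele frequency $p$ solving
  $2p(1-p) = HV$, and genotypes are drawn under Hardy–Weinberg
  equilibrium — so control heterozygosity is an unbiased estimator of
  HV, matching the method's use of annotation HV as expected
  heterozygosity. $HV > 0.5$ has no real solution and is rejected.
* Planted segments model **copy-neutral** LOH: in an affected fraction
  of case samples, each heterozygous call inside the segment converts,
  with probability `penetrance`, to a homozygote drawn in proportion to
  the conditional HWE homozygote frequencies $p^2 : (1-p)^2$. Missing
  calls are *not* increased, since copy-neutral events do not disturb
  hybridization.
* Missing calls (default rate 0.01) and symmetric genotyping errors
  (default 0.005, a call replaced by one of the other two categories
  uniformly) are applied last, rates typical of 250K-era arrays.
* In `simulate_matched_pair()` errors apply to the tumor sample only:
  the germ line is the reference, which keeps the false-LOH rate among
  heterozygous germ-line SNPs equal to the error rate.
* Positions use uniform inter-SNP gaps with a 12 kb mean (250K-array
  density); a fixed seed reproduces the full output exactly.

What the simulator does **not** emulate — and what green tests therefore
do not establish about real data: linkage disequilibrium between
markers, HV mis-annotation and population stratification between case
and control cohorts, batch- or cluster-correlated genotyping error,
tumor purity mixtures, and copy-number change. Stratification in
particular can produce systematic nonzero $\Delta$ that the null
calibration here cannot detect.

## Benchmark configurations and what they show

Two presets fix the study conditions used throughout the tests
(4 chromosomes × 1500 SNPs, 10 + 10 samples):

* `sim_preset_recovery()`: ten planted 8-SNP segments, penetrance 1.0,
  all case samples affected, $HV \sim U(0.3, 0.5)$, scored at the manual
  threshold 0.4 and CPT 5.
* `sim_preset_null()`: no segments, default HV distribution, scored at
  the power-formula threshold; over 20 seeds the mean number of false
  regions per 6000-SNP genome stays below one.

Precision under the recovery preset is essentially perfect: a run of
five ≥ 0.4 deltas almost never arises outside a planted segment.
Sensitivity, however, is intrinsically low at these cohort sizes, and it
is worth being quantitative about why. Inside a fully penetrant segment
the case heterozygosity is 0, so a SNP is suggestive iff the *observed
control* heterozygosity reaches 0.4 — i.e. at least 4 of 10 control
samples heterozygous, an event of probability 0.35–0.83 for
$HV \in [0.3, 0.5]$ (mean ≈ 0.6). The chance that 8 such Bernoulli SNPs
contain a run of 5 successes is then only ≈ 0.18, so most planted
segments are missed; the acceptance suite measures ≈ 0.12 over its
pinned seeds and records the shortfall rather than relaxing the
configuration. This is the method's documented small-cohort caveat —
low-heterozygosity LOH regions are detected adjacent to, rather than
over, their markers — made concrete: sensitivity at small $n$ demands
either larger cohorts (which lower $\Delta_T$), longer affected
segments, or markers of high population heterozygosity.

## Numerical and degenerate-input choices

* Heterozygosity frequencies are exact ratios of counts; deltas inherit
  double precision, and region contracts are asserted to $10^{-9}$.
* An empty region list is valid everywhere (header-only TSV, empty BED).
* `heterozygosity_frequency()` refuses empty input and any `NoCall`,
  enforcing the upstream-filter contract rather than silently dropping.
* Pearson correlation with a zero-variance argument is reported as
  undefined, never computed; the two-sample comparison defaults to the
  pooled-variance Student test with a Welch option.
* Chromosome labels are normalized by stripping a `chr` prefix and
  ordered 1–22, X, Y, MT, then others; sex chromosomes are processed but
  flagged in the log, with no male-hemizygosity correction (cohort sex
  composition is unknown to the package; X/Y regions should be
  interpreted with care).
* SNPs without an annotated HV are dropped from the informative set by
  default; `na_action = "substitute"` falls back to observed control
  heterozygosity.
* Genotype tables are read through a configurable dialect; heterozygous
  token variants (`BA`, `het`) normalize to `AB`, recognized no-call
  tokens to `NoCall`, and any unrecognized token becomes `NoCall` with a
  counted warning.

## Test problem sizes

The suite runs entirely on generated data: fuzzed delta tracks of 5–40
SNPs (1000+ cases against the brute-force oracle), 6000-SNP genomes for
the pipeline, recovery and null benchmarks, a 12{,}000-SNP track for the
matched-pair error-rate check, and 100{,}000 Monte-Carlo replicates for
the power oracle — sizes chosen so every property is measured with
comfortable statistical margin while the whole suite stays fast.

## Known limitations

* No per-sample LOH inference, by construction.
* No multiple-testing control beyond the $\Delta_T$/CPT pair.
* The power formula assumes approximate normality of $\Delta$; at very
  small cohorts the frequencies are coarsely discrete and the rounded
  threshold should be read as a working convention, not an exact level.
* Sensitivity at small cohort sizes is limited as quantified above.
* Population mismatch between case and control cohorts is not modelled
  or corrected; choose ethnicity-matched controls.
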