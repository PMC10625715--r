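---
title: "Calling m6A from global A-to-I deamination sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling m6A from global A-to-I deamination sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etamr)
```

## The readout and its model

Enzymatic deamination converts unmethylated adenosine to inosine, read as
G after reverse transcription; N6-methyladenosine (m6A) resists the
enzyme. A site's sequencing signature is therefore a binomial draw over
its reads: each read shows a *persistent A* with probability

$$\pi_A \;=\; 1 - c\,s\,(1-m),$$

where

* `c` — the **sample conversion rate**, the probability that the
  deaminase converts an unmethylated, fully accessible A in this sample
  (unitless, typically ≈ 0.99);
* `s` — the **site accessibility**, the probability scale on which the
  deaminase can act at this position (0 = fully blocked by structure or
  protein, 1 = fully exposed);
* `m` — the **methylation level**, the fraction of molecules methylated
  at the site.

Conversion requires all three things at once: a competent sample, an
accessible site, and the absence of the methyl mark. This factorisation
is the single generative assumption of the package; the simulator draws
from it and every estimator inverts it. It also implies the two derived
quantities used throughout: `true_m = apparent_m / s` and
`exposed_m = true_m × s`, the "visible" methylation that survives both
filters and stoichiometry.

Counts other than A or G (sequencing errors, mispriming) are recorded but
never enter the model, which is binomial on A vs G only. All coordinates
are 0-based and strand-resolved (a genomic T on the minus strand is an A
site); motifs are reported in the RNA alphabet.

## Estimators

**Conversion rate.** Most A sites in a transcriptome are unmethylated,
so `c` is estimated by the pooled ratio `sum(g)/sum(a+g)` over sites with
coverage ≥ 20 (`estimate_conversion_rate()`). The pooled ratio is the MLE
under a shared-rate binomial. An optional symmetric trim of the per-site
conversion distribution guards against methylated or edited outliers; the
default is no trimming. Note that with heterogeneous accessibility the
pooled estimate converges to `c·E[s]` rather than `c`; the downstream
accessibility estimates are then expressed relative to the same baseline,
so the two-stage pipeline remains internally consistent.

**Apparent methylation.** With `s = 1`, $\pi_A = m + (1-m)(1-c)$ and the
binomial MLE has the closed form
`clip((a/(a+g) − (1−c))/c, 0, 1)` (`apparent_methylation()`); the clip
implements the constrained argmax on `[0, 1]`. The test suite verifies
exact agreement with a grid-search maximiser of the log-likelihood at
step 1e-5.

**Accessibility.** The modification-free IVT control has `m = 0`
everywhere, so `raw_s = clip((g/(a+g))/c, 0, 1)`
(`raw_accessibility()`).

**Accessibility shrinkage.** At low coverage `raw_s` is noisy and, at
nearly fully accessible sites, biased low: errors there are one-sided
(the clipped ratio cannot exceed 1, and a single persistent-A read drags
it down by `≈ 1/n`). `shrink_accessibility()` estimates the count-driven
part of this trend with an OLS model of `raw_s` on the control A and G
counts (the A+G total is collinear and dropped), trained on 2,000
randomly sampled sites; 10-fold cross-validation reports the model's
out-of-fold error. Each site is then corrected *upward* by its estimated
shortfall against the high-coverage anchor (the mean raw estimate over
above-median-coverage training sites), capped at `1/(c(n+1))`:

```
shrunken_s = clip( raw_s + min( max(0, anchor − pred), 1/(c(n+1)) ) )
```

Two properties motivated this one-sided form over a symmetric blend of
raw estimate and model prediction. First, `raw_s` is a deterministic
function of the predictors `(a, g)`, so a flexible regression simply
reproduces the raw estimate and blending cannot improve it. Second, at
accessible sites the errors are one-sided, so any mean-preserving
transformation (including residualising against the fitted trend) leaves
the mean absolute error unchanged; only an upward correction can reduce
it. The cap matters in the other direction: a genuinely blocked site at
high coverage has a shortfall far larger than `1/(c(n+1))`, which
sampling bias cannot explain, so such sites are left essentially
untouched. When genuine accessibility variation is correlated with the
counts the correction is deliberately partial; the raw estimates are
always retained in the output.

**FTO (demethylase) controls.** Without an IVT control, accessibility
and methylation are separated by comparing deaminated RNA with and
without prior FTO treatment. Both arms share `s`; methylation is `m`
untreated and `m(1−e)` after treatment with efficiency `e`.
`joint_fit_fto()` maximises the sum of the two binomial log-likelihoods
over `(m, s) ∈ [0,1]²` by a dense grid (step 0.005) followed by bounded
quasi-Newton refinement. `e` is fixed at the upper bound estimated from
fully methylated spike-in probes (`estimate_fto_efficiency()`, the
clipped survival ratio `1 − m̂₊/m̂₋`); using the bound makes `m̂`
conservatively low. If the likelihood surface is flat along a ridge
(small `e` confounds `m` and `s`) the solution with maximal `s` — and,
among those, minimal `m` — is reported: the conservative "accessible,
less methylated" call. `e = 0` makes the model unidentifiable and is
rejected.

## Site calling

`call_sites()` evaluates every site with coverage ≥ 10 in *both* samples
and not on the exclusion list (typically known endogenous A-to-I editing
sites, which show a persistent G excess in both samples and are nearly
disjoint from genuine methylation). Each evaluated site receives:

* a one-sided Fisher exact p-value for the alternative that the treated
  sample retains *more* persistent A than the control — one-sided because
  methylation can only increase persistence, and the demethylase
  comparison is explicitly directional;
* a Benjamini–Hochberg q-value over the family of all evaluated sites
  (the FDR procedure is the standard step-up; the family is defined after
  coverage filtering and exclusion);
* accessibility-adjusted `true_m` and `exposed_m`.

A site passes when `q < 0.05` **and** `exposed_m ≥ 0.10`. Failed sites
are retained with `passed = FALSE` so that secondary analyses (e.g.
methylation of all evaluated sites, load of partially methylated
transcripts) remain possible. `quantify_target_site()` applies the same
conversion-background inversion to a single amplicon or trace-derived A
fraction.

## Downstream statistics

* `classify_motif()` labels the 5-mer context DRACH / non-DRACH
  (D = A/G/U, R = A/G, then A, C, H = A/C/U).
* `fit_calibration()` fits persistent-A % against designed m6A % across
  spike-in probes by OLS; on the published five-probe series the fit has
  r² that rounds to 1.00 and slope ≈ 0.967.
* `neighbor_gaps()` / `permutation_gap_null()` test spatial clustering:
  the observed median within-transcript gap is compared with 10 draws of
  the same number of sites from all candidate A positions, either
  unconstrained or with drawn 5-mer frequencies matched exactly to the
  observed call set. Gap analysis uses spliced transcript coordinates
  when an annotation is supplied (`map_to_transcript()`), genomic
  positions otherwise — a within-transcript distance is the biologically
  meaningful one. Sampling is pooled across the transcriptome by
  default; `scope = "per_transcript"` allocates draws proportionally to
  each transcript's candidate count.
* `methylation_load()` sums methylation levels over a transcript's
  called sites (sites at 0.3, 0.7 and 1.0 give a load of 2.0);
  `bin_by_load()` ranks methylated transcripts by load into
  high/medium/low tertiles (ties broken by transcript id, remainders
  assigned top-down, so bin sizes differ by at most 1) plus a `none` bin;
  `compare_half_lives()` summarises half-lives per bin and applies
  one-tailed Wilcoxon rank-sum tests against the unmethylated reference
  (alternative: methylated bins decay faster). `spike_in_amount()`
  implements the spike-in dosage formula `y = d·v·c/t` (attomole per µg).

## The simulator

`sim_config()` fixes the study conditions; all generators are
deterministic under the seed.

| parameter | default | meaning |
|---|---|---|
| `conversion_rate_treated`, `conversion_rate_control` | 0.99 | near-complete deamination, as achieved by the optimised enzyme |
| `accessibility_distribution` | 92% of sites ≥ 0.9 (mostly exactly 1), rest uniform(0.2, 0.9) | the strongly 1-skewed accessibility seen in cellular transcriptomes |
| `methylation_distribution` | uniform(0.05, 1) | methylation levels spread close to evenly across the range |
| `coverage_distribution` | negative binomial, mean 50 | overdispersed read depth |
| `drach_fraction` | 0.85 | fraction of m6A sites planted at DRACH centres, matching the strong writer-complex preference |
| `editing_fraction` | 0.005 | A sites given endogenous A-to-I editing, simulated as a persistent G excess in *both* samples (editing level uniform(0.2, 1)), so callers see them as hyper-converted, not methylated |
| `fto_efficiency` | 0.9 | demethylase removes most but not all m6A |
| `poorly_processed_fraction` | 0.05 | reads from fragments that largely escaped the enzyme (conversion multiplied by 0.2), the population the >50%-unconverted read filter removes |

Desk-scale configurations place m6A at a few percent of A sites —
denser than a mammalian transcriptome (≈ 0.4%) — so that a few thousand
simulated sites contain enough signal to exercise every stage; the
calling statistics are per-site and unaffected by the overall density
except through the BH family.

What the simulator does *not* emulate: alignment and mapping artefacts,
UMI collisions, sequence-dependent enzyme kinetics beyond the single
`s` scale, correlated methylation of neighbouring molecules, and
transcript-abundance-driven coverage. Passing tests therefore validate
the statistical machinery under the stated generative law, not the
upstream read processing, which is out of scope (count tables are the
package's input boundary).

## Numerical choices and degenerate inputs

* All probability-scale estimates are clipped to `[0, 1]`; clipping is
  the constrained MLE, not a post-hoc fix.
* `a + g = 0` is rejected by the estimators; sites absent from either
  table are simply not evaluated (no accessibility estimate is possible
  without control counts).
* Accessibility 0 leaves `true_m` missing and `exposed_m = 0`.
* Reads with zero reference-A positions pass the read filter: the
  unconverted fraction is 0/0 and keeping them is conservative for
  coverage. The threshold is strict (`> 0.5` removes; exactly half is
  kept).
* The FTO grid step (0.005) bounds the distance of the grid optimum from
  the refined one; the refinement never decreases the likelihood, and
  ridge ties are broken toward maximal `s`.
* Fisher p-values are computed from the hypergeometric tail directly
  (`phyper`), which is exact and vectorised; the tests cross-check
  against both an explicit enumeration and `stats::fisher.test`.
* Tertile remainders and ties in load binning follow fixed rules (stated
  above) so that bin membership is reproducible.

## Problem sizes used in the checks

The bundled verification runs are sized for quick, repeatable execution:
1,000 random inputs for the MLE oracle, 500 tables for the Fisher
oracle, 2,000 sites per level at coverage 200 for stoichiometry
recovery, a 10,000-site fully null screen for FDR control, 50 random
inputs against a 201×201 grid for the FTO fit, 4,000 sites at mean
coverage ~15 for the shrinkage comparison, and 10-repetition permutation
nulls on ~3,000-candidate transcriptomes for the clustering test.

## Known limitations

* The two-stage IVT adjustment `true_m = apparent_m/s` matches the exact
  inversion of the generative law only for accessible sites (`s ≈ 1`);
  at strongly blocked sites it overestimates, which the `exposed_m`
  filter deliberately down-weights. The FTO path fits the law exactly
  but needs the efficiency bound.
* The conversion-rate estimator absorbs mean accessibility (see above);
  per-sample rates are comparable only under similar accessibility
  profiles.
* The shrinkage correction assumes the site population is dominated by a
  shared accessibility scale; a transcriptome in which most sites are
  blocked would violate the anchor assumption.
* Half-life comparison consumes a precomputed half-life table; decay
  fitting from time-course data is out of scope.
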