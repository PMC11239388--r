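---
title: "Methods: two-sample MR with two-step mediation in twostepmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with two-step mediation in twostepmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepmr)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instruments
for an exposure. For SNP $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its
association with the exposure in one GWAS and $\hat\beta_{Yj}$ (SE
$\sigma_{Yj}$) its association with the outcome in another, non-overlapping
GWAS. If SNP $j$ is a valid instrument (relevant, independent of
confounders, and affecting the outcome only through the exposure), the Wald
ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect $\theta$.
Binary traits are kept on the log-odds scale throughout; odds ratios appear
only when printing, so the asymmetry of OR-scale intervals falls out of the
exponential transform rather than being modelled.

The estimator family combines the per-SNP ratios under progressively weaker
assumptions:

* **IVW** — weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
  through the origin with weights $1/\sigma_{Yj}^2$. Requires all
  instruments valid (or balanced pleiotropy). The default is
  *multiplicative random effects*: the fixed-effect SE is inflated by the
  weighted residual SD, floored at 1 so overdispersion widens intervals but
  underdispersion never narrows them. The source analysis did not state its
  IVW variant; given the significant heterogeneity it reported for two of
  its three outcomes, the random-effects reading is the safer default, and
  `re_mode = "fixed"` remains available.
* **MR-Egger** — the same regression with a free intercept, after orienting
  all pairs to $\hat\beta_{Xj} \ge 0$. The intercept estimates directional
  pleiotropy; the slope remains consistent under the InSiDE assumption.
  Inference uses $t_{n-2}$; IVW uses the normal — the conventional pairing.
* **Weighted median** — the ratio at cumulative normalized weight 0.5
  (weights: inverse first-order ratio variance
  $\hat\beta_{Xj}^2/\sigma_{Yj}^2$), linearly interpolated between order
  statistics. Consistent when valid instruments carry $>$50% of the weight.
* **Weighted / simple mode** — the mode of a normal-kernel density over the
  ratios, bandwidth $\varphi \cdot 0.9\,\min(\mathrm{sd},
  \mathrm{mad})\,n^{-1/5}$ with $\varphi = 1$ by default; consistent when
  the largest cluster of ratios is valid.

SEs for the median and mode estimators come from a parametric bootstrap
(resampling both effect columns from their sampling distributions, default
1000 replicates). A seed is mandatory — there is no silent nondeterminism
anywhere in the package.

## Instrument selection

`select_instruments()` applies three filters in sequence and logs every
exclusion: the association threshold (`p_threshold`, default $5\times
10^{-6}$, the suggestive threshold the source analysis used for its binary
exposure; $5\times10^{-8}$ is conventional for large continuous-trait GWAS
and is the default for mediator instruments in the pipeline — both are
plain configuration, neither is hard-coded); greedy LD clumping
(best-p-first, ties broken lexicographically for determinism; $r^2 <
0.001$ within 10,000 kb by default, windows measured center-to-center on
the same chromosome); and the instrument-strength screen $F =
\hat\beta^2/\mathrm{SE}^2 > 10$, applied after clumping. LD is an explicit
input (`ld_info`): the package never computes LD from genotypes, and SNP
pairs absent from the matrix are treated as unlinked, which makes results
reproducible and reference-panel-agnostic. `filter_confounders()` is a
local stand-in for a secondary-trait web lookup: a plain annotation table
of (SNP, trait) pairs drives the exclusion, and the filtered analysis is
reported *alongside* the primary, not in its place.

## Harmonization

`harmonize()` aligns the outcome to the exposure's effect allele: identical
orientation is kept, swapped orientation negates the outcome effect (and
reflects its allele frequency), and strand-complement codings are resolved
before those two rules. Palindromic SNPs (A/T, C/G) carry no strand
information in their alleles; they are oriented by allele frequency only
when both frequencies lie outside $0.5 \pm$ `palindromic_eaf_tol` (default
0.08, the community-standard ambiguity band 0.42–0.58), and dropped
otherwise — also when either frequency is missing. Indels and multi-allelic
records are dropped as incompatible. Harmonization is idempotent, and
pre-flipping the outcome file's coding changes nothing — both properties
are tested.

## Diagnostics

Cochran's $Q$ is computed on the Wald ratios with first-order weights
against the fixed-effect IVW center (the textbook form), with
$I^2 = \max(0, (Q - \mathrm{df})/Q)$; the Egger intercept test and
leave-one-out IVW (same residual mode as the headline analysis) complete
the block, plus per-SNP Wald ratios as forest-plot data. The number of
SNPs surviving harmonization is always reported — published $Q$ values
without their degrees of freedom cannot otherwise be interpreted.

## Meta-analysis and mediation

Replication is pooled on the log-OR scale: `ci_to_se()` inverts printed
OR intervals, `meta_fixed()` pools with inverse-variance weights, and
`meta_random_dl()` (DerSimonian–Laird) is the sensitivity companion.
Fixed-effect is the default because it reproduces the published pooled
estimate from the published inputs; the original report named only its
software, not its model.

`two_step_mediation()` decomposes a total effect $\alpha$ into the
mediator pathway $\beta_1\beta_2$ and the direct remainder
$\alpha - \beta_1\beta_2$ (exact by construction, not approximate). SEs
use the first-order delta method assuming independence of the three
estimates — justified by non-overlapping GWAS samples, and stated openly
because no covariance treatment is possible from summary data alone. The
proportion mediated $\beta_1\beta_2/\alpha$ uses the ratio delta method in
the algebraically equivalent form
$\mathrm{var} = \mathrm{var}_{\mathrm{ind}}/\alpha^2 +
\mathrm{ind}^2\,\mathrm{var}_\alpha/\alpha^4$, which stays defined when
the indirect effect is zero. A proportion outside $[0,1]$ (inconsistent
mediation) is flagged, not rejected. The second-order product-variance
term is available behind `second_order = TRUE`.

On the published inputs the package reports a delta-method CI of roughly
10–64% around the 37% point estimate, noticeably narrower than the
published 4.6–73.2% interval; the original CI method was not described
(plausibly a bootstrap or a covariance-aware delta), so the package
reports its own interval and documents the discrepancy rather than chasing
the printed one.

```{r mediation-example}
two_step_mediation(
  alpha = c(log(1.13), ci_to_se(1.05, 1.21)),
  beta1 = c(log(1.12), ci_to_se(1.08, 1.17)),
  beta2 = c(log(1.49), ci_to_se(1.35, 1.64)))
```

## The synthetic-data generator

`simulate_study()` generates summary statistics directly — per-SNP true
effects plus sampling noise with $\mathrm{SE} = 1/\sqrt{2\,
\mathrm{maf}(1-\mathrm{maf})\,n}$, the standard large-sample per-allele
approximation — because every estimator in scope consumes only summary
data, and summary-level generation is orders of magnitude faster than
individual-level genotypes. What it emulates: instrument-strength effect
distributions with a floor (so instruments resemble a post-selection GWAS
set), LD blocks whose members tag one shared signal (so clumping has real
work to do), allele-frequency noise, per-SNP horizontal pleiotropy
(balanced or directional), and the causal chain
exposure $\to$ mediator $\to$ outcome with an optional direct path. What
it does not emulate: case-control SE refinements, winner's-curse
distortion of the published exposure effects, sample overlap between the
three GWAS (they are non-overlapping by construction, matching the
mediation independence assumption), and real LD panels.

Defaults are the stated world of the motivating analysis: direct effect
$\theta_{\mathrm{direct}} = 0.077$ log-odds, exposure$\to$mediator
$\delta = 0.113$, mediator$\to$outcome $\kappa = 0.399$ (implied total
$0.077 + 0.113 \times 0.399 = 0.122$, implied proportion mediated
$0.369$), $m = 100$ instruments, GWAS sizes $3\times10^5$. The effect-size
scale (`gamma_sd = 0.03`, floor 0.015) puts the minimum instrument $F$
near 25 — the order of magnitude of a suggestive-threshold GWAS
instrument set; MAF is uniform on $[0.05, 0.5]$.

Two generator choices deserve explanation:

* **Mediator-specific instruments.** If the mediator's only genetic signal
  were inherited from the exposure ($\delta\gamma_j$), a mediator→outcome
  MR with those SNPs would estimate $\theta_{\mathrm{direct}}/\delta +
  \kappa$ (the exclusion restriction fails), and the recovered proportion
  mediated would collapse to 1. Real mediators have their own GWAS hits,
  so the generator adds `m_med_snps` SNPs with mediator-specific effects
  $\eta_j$ (zero exposure effect, outcome effect $\kappa\eta_j$). All
  three tables still share one SNP universe.
* **Directional pleiotropy is aligned with the exposure-increasing
  allele.** A constant outcome-scale shift would cancel once Egger orients
  pairs to $\hat\beta_{Xj} \ge 0$ (exposure effects carry both signs),
  silently turning "directional" into balanced. Drawing the pleiotropic
  effect as $\mathrm{sign}(\gamma_j)\,N(\mu, \sigma)$ makes it directional
  in the orientation the Egger intercept is defined in — the standard
  construction in MR simulation studies. The balanced type is
  distributionally unchanged. The directional SD is fixed at half the mean
  (0.01 against mean 0.02) where only the mean is specified.

## What a green test establishes

The calibration suite runs the full select–harmonize–estimate chain on
hundreds of seeded replicates: under the global null the IVW test rejects
at its nominal 5% (within three binomial SEs at 500 replicates); under
balanced pleiotropy the IVW estimate stays unbiased; under directional
pleiotropy the Egger intercept rejects essentially always. Parameter
recovery at the stated effect scale (200 replicates) reproduces the total
effect and proportion mediated within Monte-Carlo error — read as three
SEs of the replicate mean — and the delta-method proportion CI covers the
truth in 93–97% of replicates.

The recovery protocol runs the estimators on the generator's *known*
instrument sets rather than re-running p-value selection. This isolates
what the check is about — estimator consistency — from selection-induced
winner's curse, which at this instrument strength biases the chain-level
estimate downward by roughly 2% and is a property of thresholded selection
itself, not of the estimators. The pipeline tests exercise the full
selection chain separately with per-replicate (3-SE) tolerances. None of
this establishes performance on real GWAS data: the generator's clean
noise model, independent samples and panel-free LD are idealizations.

## Numerical choices and degenerate inputs

Ratio weights use the first-order variance $\sigma_{Yj}^2/
\hat\beta_{Xj}^2$ (no NOME correction). The weighted-median interpolation
returns an endpoint when the half-weight falls outside the order
statistics. The mode search special-cases an all-equal ratio vector
(returning that value exactly for any bandwidth) and floors the bandwidth
at $10^{-8}$. $Q = 0$ yields $I^2 = 0$, $p = 1$. A zero exposure effect is
a hard error for a single Wald ratio but only a flagged row in the batch
single-SNP display. Invalid summary-statistics rows are dropped with a
logged reason rather than aborting, since large public files routinely
contain a few malformed lines; drop accounting is exact and tested.
Simulated p-values are floored at $10^{-320}$ to stay inside $(0,1]$ in
double precision.

## Known limitations

Multiple outcomes are analysed independently with no multiplicity
adjustment (matching the motivating analysis's $\alpha = 0.05$); no
multivariable MR, MR-PRESSO, Steiger filtering or contamination-mixture
estimators; no proxy-SNP search or reference-panel strand inference; no
VCF input or liftover — positions are opaque coordinates compared only
within clumping windows. The mediation CI ignores any covariance between
the three MR estimates, which is exactly right only for non-overlapping
samples.
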