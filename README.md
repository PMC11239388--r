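# twostepmr

Two-sample Mendelian randomization (MR) with two-step mediation analysis,
for epidemiologists working from GWAS summary statistics. The package
implements the complete workflow used in MR studies of a binary exposure,
a candidate mediator and a disease outcome — for example, obstructive
sleep apnea as exposure, body-mass index as mediator and osteoarthritis as
outcome: instrument selection, allele harmonization, the standard
estimator family, heterogeneity/pleiotropy diagnostics, bidirectional
analysis, replication meta-analysis and mediation decomposition — plus a
summary-level GWAS simulator so the whole chain can be exercised and
calibrated without any real cohort data.

## The statistics

For SNP *j* with exposure association β̂_Xj (SE σ_Xj) and outcome
association β̂_Yj (SE σ_Yj) from non-overlapping GWAS, the Wald ratio
β̂_Yj/β̂_Xj estimates the causal effect θ under the instrumental-variable
assumptions. The estimator family:

- **IVW**: weighted regression through the origin, weights 1/σ_Yj²;
  multiplicative random effects by default (residual SD inflation floored
  at 1).
- **MR-Egger**: adds a free intercept estimating directional pleiotropy;
  t inference with n − 2 df.
- **Weighted median**: interpolated ratio at half the cumulative weight;
  robust to <50% invalid weight.
- **Weighted / simple mode**: kernel-density mode of the ratios.
- Diagnostics: Cochran's Q with I², Egger intercept test, leave-one-out,
  single-SNP forest data.

Instruments are selected by p-value threshold (default 5×10⁻⁶), greedy LD
clumping (r² < 0.001 within 10,000 kb, explicit LD matrix input), and the
strength screen F = β²/SE² > 10, with an annotation-table confounder
exclusion pass. Replication is pooled by fixed-effect (or
DerSimonian–Laird) inverse-variance meta-analysis on the log-OR scale.
Two-step mediation decomposes the total effect α into indirect β₁β₂ and
direct α − β₁β₂, with a delta-method proportion mediated β₁β₂/α.

## Worked example

Published MR results are consumed as OR (CI) triplets. Decomposing a total
effect of OR 1.13 (1.05–1.21) through a mediator with exposure→mediator
OR 1.12 (1.08–1.17) and mediator→outcome OR 1.49 (1.35–1.64):

```r
library(twostepmr)
two_step_mediation(
  alpha = c(log(1.13), ci_to_se(1.05, 1.21)),
  beta1 = c(log(1.12), ci_to_se(1.08, 1.17)),
  beta2 = c(log(1.49), ci_to_se(1.35, 1.64)))
#> Two-step mediation MR (log-odds scale)
#>   total (alpha)    = 0.1222 (se 0.0362)
#>   indirect (b1*b2) = 0.0452 (se 0.0099)
#>   direct           = 0.0770 (se 0.0375)
#>   proportion mediated = 37.0% [10.3%, 63.7%], p = 0.00662
```

About 37% of the exposure's effect on the outcome travels through the
mediator; the direct pathway (0.077 log-odds, OR ≈ 1.08) remains the
larger share. Pooling a discovery estimate with a replication cohort:

```r
studies <- meta_input(label = c("discovery", "replication"),
                      or = c(1.13, 1.04),
                      ci_low = c(1.05, 0.93), ci_high = c(1.21, 1.15))
meta_fixed(studies)
#> Meta-analysis (fixed, k = 2): OR = 1.101 [1.038, 1.168], p = 0.00132
#>   between-study Q = 1.62 (df 1, p = 0.203), tau2 = 0
```

A fully synthetic end-to-end run:

```r
sim <- simulate_study(simulation_config(seed = 42))
inst <- select_instruments(sim$exposure, ld = sim$ld)   # p<5e-6, clump, F>10
h <- harmonize(inst_table(inst, sim$exposure), sim$outcome)
mr_ivw(h)
#> ivw: beta = 0.1082 (se 0.0110), OR = 1.114 [1.090, 1.139], p = 8.33e-23, nsnp = 82
cochran_q(h)
#> Cochran Q = 59.51 on 81 df, p = 0.965, I2 = 0.0%
```

The estimate recovers the generator's true total effect (0.122 log-odds,
OR 1.13) within sampling error, with no excess heterogeneity. `run_full()`
orchestrates forward, reverse, meta and mediation blocks from one
`analysis_config()` with full provenance (config hash + seed).

## Analysis workflow

`analysis/01_simulate_study.R` … `analysis/07_calibration.R` are numbered
narrative drivers that generate the synthetic study at the motivating
effect scale, select instruments, run forward/reverse MR with all
diagnostics, pool the replication, decompose the mediation and calibrate
the tests under null and pleiotropic worlds, writing tables under
`results/`. Run them in order with `Rscript analysis/01_simulate_study.R`
etc.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from the package's own machinery, the proportion of the
exposure–outcome effect mediated by the mediator implied by the three
published IVW odds ratios (total 1.13, exposure→mediator 1.12,
mediator→outcome 1.49), reported as a percentage, and writes it as JSON.
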