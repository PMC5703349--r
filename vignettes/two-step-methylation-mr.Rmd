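---
title: "Two-step Mendelian randomization with DNA methylation as mediator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step Mendelian randomization with DNA methylation as mediator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimediate)
```

## The question and the design

Maternal micronutrient status during pregnancy — here circulating vitamin
B12 — is associated with offspring cognitive outcomes, but such associations
are heavily confounded by socioeconomic factors that shape diet, methylation
and child development alike. Two-step epigenetic Mendelian randomization
(MR) asks whether DNA methylation in cord blood *mediates* such an exposure–
outcome relationship, using genetic variants as instruments at each step:

* **Step 1** uses a maternal variant that robustly shifts circulating B12
  (a *FUT2*-type instrument) and scans the child's cord-blood methylome for
  CpG sites whose methylation associates with the maternal dose. Because
  alleles are assigned at meiosis independently of socioeconomic
  confounders, a dose–methylation association supports a causal
  exposure→methylation effect. The causal effect per pg/ml is the Wald
  ratio: the genotype–methylation coefficient divided by an external
  genotype–B12 coefficient (a two-sample design).
* **Step 2** instruments methylation itself. For each exposure-responsive
  CpG, a cis-mQTL (a SNP within ±1 Mb associated with that CpG's
  methylation at p < 1e-7, LD-clumped to independence) serves as the
  instrument; the child's IQ is regressed on the cis dosage in samples
  *excluded* from mQTL discovery, and the Wald ratio estimates IQ points
  per unit proportion methylated.

Chaining the two steps gives the mediated effect: IQ points per (by
convention) 10 pg/ml of maternal B12 acting through one CpG,

$$\hat\theta_{med} = \hat\beta_{IV}^{(2)} \times \hat\beta_{IV}^{(1)} \times 10 .$$

## Estimators

**Wald ratio and its standard error.** For coefficients
$\hat\beta_{GY}$ (genotype–outcome) and $\hat\beta_{GX}$
(genotype–exposure),

$$\hat\beta_{IV} = \frac{\hat\beta_{GY}}{\hat\beta_{GX}}, \qquad
\mathrm{SE} = \sqrt{\frac{se_{GY}^2}{\hat\beta_{GX}^2} +
\frac{\hat\beta_{GY}^2\, se_{GX}^2}{\hat\beta_{GX}^4}} ,$$

the first-order delta method. The covariance cross-term is identically zero
in a two-sample design (independent samples) and is omitted. P-values for
IV estimates are two-sided normal on $z = \hat\beta_{IV}/\mathrm{SE}$,
while the per-CpG OLS scan uses the t distribution with residual degrees of
freedom — a deliberate asymmetry: the ratio estimator is justified only
asymptotically, the OLS t-test exactly under normal errors. The test suite
checks the delta-method SE against a 100,000-draw parametric bootstrap; the
two agree closely once the instrument is strong
($|\hat\beta_{GX}|/se_{GX} > 10$), and the package flags (but does not
refuse) weaker instruments at $|\hat\beta_{GX}|/se_{GX} < 3$, a state a
rare-variant instrument can legitimately reach.

**Methylome scan.** One covariate-adjusted OLS per CpG of beta-values
(proportion methylated, clamped into $(10^{-6}, 1-10^{-6})$ at load) on
instrument dosage. Probes on X/Y are removed, as are probes failing a
detection-p filter (threshold 0.05; by default a probe fails if any sample
fails, configurable as a fraction since the stricter per-sample rule is a
convention choice). Outliers are trimmed per CpG at 3× the interquartile
range beyond the nearest quartile — standard EWAS practice made explicit and
configurable (`outlier_k`, `Inf` disables). Multiple testing uses
Benjamini–Hochberg q-values and Bonferroni with the number of probes
actually tested as denominator (overridable, since array-wide counts are
sometimes preferred). Calibration is summarized by the genomic inflation
factor λ (median implied 1-df chi-square over its null median).

**Cis-instrument discovery.** Same-chromosome SNPs within the window are
fitted with the scan's OLS engine (roles swapped), thresholded, and greedily
clumped: accept the best p, drop everything with squared dosage correlation
above `r2_threshold` (default 0.1 — the method names clumping without a
threshold, so a common stringent default is used and exposed), repeat. Ties
break by smaller distance, then variant id, making the output invariant to
input order. LD is computed in the analysis sample; no reference panel.

**Sample partitioning.** Step-2 instruments are selected in the discovery
(arrayed) samples and evaluated against IQ only in the disjoint outcome
samples. Selecting and evaluating in the same sample inflates the
instrument–outcome association through the shared methylation noise
(winner's curse); the test suite demonstrates this directly with a weak
cis-mQTL whose selection at p < 1e-4 truncates about a third of replicates —
the no-exclusion estimate is visibly biased, the partitioned one is not.
The default discovery fraction is 0.15, echoing designs where only a small
arrayed subset of a large genotyped cohort carries methylation data.

## The synthetic cohort generator

No individual-level cohort is distributable, so the package generates
cohorts with exactly the causal structure the analysis assumes:

* maternal instrument dosage under Hardy–Weinberg equilibrium at MAF 0.4 by
  default (0.004 available to emulate a rare instrument in a European
  cohort, 0.459 for the East-Asian exposure panel of the published B12
  GWAS);
* B12 (pg/ml) $= 300 + 70.21\,d + 30\,C + \varepsilon$, with residual SD
  210 so the instrument explains about 5% of exposure variance — the value
  used in standard MR power statements — and $C$ a latent standard-normal
  "socioeconomic" confounder;
* methylation on the logit scale: each CpG has a baseline $b_0$ (0.5 for
  responsive CpGs, uniform 0.2–0.8 otherwise) and
  $\beta = \mathrm{logit}^{-1}\!\big(\mathrm{logit}(b_0) + s(B12 - \mu) +
  c\,d_{cis} + 0.15\,C + \varepsilon_m\big)$ with logit-scale noise SD
  0.15. The logistic squash keeps beta-values in (0,1) while remaining
  locally linear at small effects, matching the linear scan model. Slopes
  are specified on the beta-value scale at baseline and converted by
  $1/(b_0(1-b_0))$;
* three responsive CpGs with B12 effects −3.7, +5.5 and +4.5 ×10⁻⁴
  proportion per pg/ml. The published per-allele coefficients cannot be
  transplanted directly: their printed units are internally inconsistent
  (a proportion-scale residual SD implied by one table exceeds the maximum
  possible for a (0,1) variable), so effects were chosen once to be
  realistic EWAS magnitudes detectable at the default sample sizes;
* cis-mQTLs of −0.26 and −0.44 proportion per allele (MAF 0.43 and 0.40) on
  the second and third responsive CpGs; the first responsive CpG carries no
  cis-SNP, so every pipeline run exercises the "non-instrumentable CpG"
  path. Effect-free SNPs inside each window give discovery something to
  reject;
* IQ scores (total/verbal/performance) centred at 100 with noise SD 14.7
  plus confounder loading 3, marginally close to SD 15; methylation effects
  of +8 and −6 IQ points per unit proportion at the two instrumentable
  CpGs, sized so the two-step chain is estimable at the default cohort
  sizes;
* observed covariates (maternal BMI, education, smoking) generated
  correlated with $C$, so covariate adjustment removes confounding only
  partially — which is precisely what lets the tests separate adjusted OLS
  from IV.

Ground truth is recorded per cohort. Because the squash makes the model
nonlinear, the recorded "true" effect is the *realized average marginal
effect* $s \cdot \overline{\beta(1-\beta)}$ — the average-derivative
estimand an OLS slope targets — rather than the nominal logit slope; the
same convention covers the cis effects and the implied mediated effect.
Replicate $r$ of a simulation study reuses the parameter set with seed
$+r$; one RNG stream drives each cohort, so a fixed seed reproduces it bit
for bit.

**What the generator does not emulate:** realistic LD beyond one causal
cis-SNP per CpG, array batch structure, cell-composition heterogeneity,
relatedness, missing data patterns, or probe-level technical artifacts.
Passing tests therefore certify the estimators and their calibration under
the assumed causal structure, not robustness to those real-data features.

## Numerical and design choices

* All tables are tab-separated UTF-8 with one header row, `NA` for missing;
  positions 1-based, chromosome labels without a `chr` prefix; dosages are
  expected allele counts in [0,2] so imputed data fit naturally.
* Result writers order rows by (chromosome, position) and format p-values
  in scientific notation, so output bytes are independent of input order.
* `adjust_bh`/`adjust_bonferroni` accept a test count larger than the
  p-value vector, which is how a printed top-k table from a 468,622-probe
  scan is adjusted; they delegate to `stats::p.adjust` and are tested
  against an exhaustive min-over-ranks oracle.
* Degenerate inputs: constant dosage is an error in the scan but only drops
  the offending candidate (with a warning) in clumping; a CpG with no
  qualifying cis-SNP yields an empty candidate list, and the pipeline
  reports it as non-instrumentable instead of failing.
* `regression_power` uses noncentrality $f^2(n-2)$, the
  degrees-of-freedom-matched convention for a single-predictor F-test.

### Calibration caveat for single-cohort λ

With one realized instrument dose vector, a latent confounder that loads on
every CpG induces a shared noncentrality proportional to the chance
dose–confounder correlation of that cohort; λ then fluctuates far more than
p-value exchangeability would suggest (values near 1.25 arise at n = 400
from this mechanism alone). This is cohort-level confounding — the thing
surrogate-variable methods absorb in real analyses, which are out of scope
here — not mis-calibration of the regression. The null-calibration tests
therefore generate methylation without the shared confounder; the
confounding tests keep it, and measure its effect where it belongs, in the
OLS-vs-IV comparison.

## Problem sizes used by the test suite

The property tests run at sizes chosen to give each check adequate power
while keeping the full suite under a minute on one core: null calibration
on 5,000 CpGs at n = 400; Wald-ratio recovery and the confounding contrast
over 200 replicates at n = 2,000; estimator type-I error over 1,000
replicates at n = 500; the winner's-curse demonstration over 500 replicates
of n = 600 split in half; end-to-end mediated-effect recovery over 100
replicates at n = 2,000 per arm.

## Limitations

Single-instrument estimation only: no IVW/Egger/median multi-instrument
estimators and no pleiotropy diagnostics, so horizontal pleiotropy of the
instrument is an untested assumption, exactly as in the single-SNP design
the package implements. Array normalization, surrogate-variable estimation
and cell-composition deconvolution are presumed done upstream; batch and
cell-composition columns are consumed as supplied covariates. The
observational and IV regressions use different covariate sets by design
(full list vs age at testing only), so their comparison mixes estimator and
adjustment differences just as the source design does.
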