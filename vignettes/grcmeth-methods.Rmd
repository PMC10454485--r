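---
title: "Methods: cell-type-resolved, genotype-risk-corrected blood methylation analysis"
author: "grcmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved, genotype-risk-corrected blood methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grcmeth)
```

# The problem

Whole-blood DNA methylation is a composite signal: each sample's beta value at
a CpG is (approximately) a mixture of the cell-type-specific methylation
states of the immune cells in the draw, weighted by their proportions. A
case/control methylation study in blood therefore has to disentangle three
confounded sources of signal:

1. **composition** — the disease may shift cell-type proportions themselves;
2. **genotype** — methylation is partly under genetic control (methQTLs), so
   a methylation "association" may just re-detect a genetic risk locus;
3. **cell-type-specific methylation change** — the signal of interest, which
   whole-blood averaging dilutes by the carrier cell type's fraction.

`grcmeth` implements the full chain for this setting: reference-based
deconvolution of six immune-cell fractions (B cells, NK cells, CD4+ and CD8+
T cells, monocytes, neutrophils), a per-CpG logistic EWAS with and without
correction for known genetic risk, a genotype-risk-corrected methylation
score compared against genetic scores by ROC, per-cell-type interaction
models attributing differential methylation to individual cell types, a
causal inference test for genotype → methylation → disease mediation, and
cis-window methQTL ANOVA. A seeded synthetic-cohort generator provides data
with known ground truth for every one of these questions; the whole test
suite runs against it.

# Models and procedures

## Beta and M values

Methylation is carried as beta values (methylated fraction, in $[0,1]$).
Linear modelling uses M-values, $M = \log_2\!\big(\beta/(1-\beta)\big)$, with
betas clipped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-3}$,
before the transform. The clip keeps $|M| \lesssim 10$ and the transform
exactly invertible away from the bounds ($\beta = 2^M/(1+2^M)$); the package
round-trips to $10^{-10}$.

## Deconvolution

Cell fractions are estimated per sample by least squares of the sample's
betas at the signature CpGs onto the six reference profiles, with the
sum-to-one equality imposed in closed form inside the solve; negative
coefficients (rare with a well-separated reference) are truncated to zero and
the row renormalised. When no non-negativity constraint binds this is exactly
the solution of the quadratic programme
$\min_f \|y - Xf\|^2$ s.t. $f \ge 0,\ \sum_k f_k = 1$;
the test suite checks agreement with an exact active-set-enumeration QP
oracle to within 0.005 per fraction. An intercept can be added
(`intercept = TRUE`) when sample and reference betas are on different scales;
it is off by default because simulated mixtures share the reference scale.
Group differences in estimated fractions are tested per cell type with
Welch's t-test (Wilcoxon selectable) — the two-group test is a deliberate
choice; nothing in the downstream chain depends on which of the two is used.

## Whole-blood EWAS

Each CpG is tested with logistic regression:

$$\text{case/control} \sim \beta_{\text{CpG}} + \text{age} + \text{sex} +
\text{cell fractions} + \text{region}$$

with a Wald test on the beta coefficient. One cell fraction (neutrophils,
the largest) is dropped to break the sum-to-one collinearity. The effect
size attached to each CpG is the plain case-minus-control mean beta
difference ($\Delta\beta$, positive = hypermethylated in cases). Defaults:
genome-wide significance $p < 9.8\times10^{-8}$, large effect
$|\Delta\beta| > 0.02$. Perfect separation or a constant CpG yields a
flagged non-estimable row (p missing, never silently 0), and a failing CpG
never aborts the scan. Batch is available as an optional covariate
(`include_batch`) for data where batch structure survives upstream
correction.

The genotype-risk-corrected (grc) EWAS adds two covariates: the risk
haplotype tag-SNP dosage (0/1/2) and a polygenic risk score. CpGs whose
whole-blood association is genotype-driven lose significance here; CpGs
acting independently of genotype keep it. This contrast is tested directly
against simulated ground truth.

## DMR combination

Candidate regions are maximal runs of CpGs on one chromosome with inter-CpG
gaps ≤ 1000 bp and ≥ 3 members (both configurable; region definition is this
package's own, chosen because upstream pipelines vary). Each region combines
its members' DMP p-values three ways — Fisher's $\chi^2 = -2\sum\ln p$ on
$2k$ df, Stouffer's $Z = \sum z_i/\sqrt{k}$ from one-sided transforms
$z_i = \Phi^{-1}(1-p_i)$, and the harmonic mean of the members' BH-adjusted
p-values — and is called significant only if all three are ≤ 0.05. The
"Fisher" component is the p-value combination method: an exact contingency
test has no role in combining per-CpG p-values, so the combination reading
is the only coherent one. BH is used wherever an FDR is needed. Member
p-values of exactly zero are clipped to the smallest positive double and
flagged. Coordinates are 1-based closed internally; BED export converts to
0-based half-open.

## Cell-type-specific DMPs

For each cell type $k$ the package fits, per CpG, the interaction model on
M-values:

$$M \sim f_k + f_k \times \text{phenotype} + \text{age} + \text{sex}$$

One model per cell type, rather than one joint model over all six — a joint
model with 12+ composition terms is overburdened and loses power, which is
the motivation for the per-cell-type adaptation. Two consequences matter:

* **No phenotype main effect** (the printed formula is followed literally;
  `include_phenotype_main` adds one). Without it, the interaction
  coefficient also absorbs the group mean difference scaled by
  $1/\bar f_k$ — this scaling is precisely what makes the estimate cut
  discriminate the source cell type: a shift originating in B cells
  ($\bar f \approx 0.06$) produces a B-model estimate an order of magnitude
  larger than the neutrophil-model estimate ($\bar f \approx 0.64$) for the
  same whole-blood signal.
* **M-values, not betas**, as the response: beta-scale responses make the
  interaction estimate depend on the baseline fraction, a known bias of
  composition-interaction models on the beta scale.

A (CpG, cell type) pair is significant when the interaction estimate is
outside $\pm 2$ (M-units per unit fraction) **and** $p < 9.8\times10^{-8}$.
The $\pm2$ cut is scale-dependent (M-units against a fraction covariate in
$[0,1]$); it is kept as the recorded default and exposed as a parameter.
"Covariates" is read as age + sex; region is optional
(`include_region`) since its membership in the original covariate set is
not determinable.

## Causal inference test

`cit_test(L, G, T)` asks whether methylation $G$ mediates the effect of
genotype $L$ on binary trait $T$. Four conditions, omnibus p = their
maximum:

1. $T \sim L$ (logistic Wald, the same machinery as the EWAS);
2. $G \sim L \mid T$ (linear, t-test on $L$);
3. $T \sim G \mid L$ (logistic Wald on $G$);
4. $L \perp T \mid G$ — an **equivalence** test whose null is *dependence*.

For (4) the no-mediation null is simulated: the mediator is reconstituted as
$G^{*b} = \widehat G(L) + \text{permuted residuals}$, which preserves the
$L$–$G$ association while severing any $G$–$T$ link, so in each permuted
dataset $L$ retains its full conditional association with $T$ given $G^{*b}$.
The statistic is the Rao score $\chi^2$ for $L$ in the logistic model of $T$
given $G$ (one IRLS fit per permutation — chosen for speed; asymptotically
equivalent to the Wald/LRT forms), and

$$p_4 = \frac{1 + \#\{S^{*b} \le S_{\text{obs}}\}}{B + 1}.$$

A small $p_4$ means the observed conditional $L$–$T$ association is weaker
than essentially every no-mediation draw — evidence *for* conditional
independence, as an equivalence test requires. $B = 500$ by default; fewer
than 100 permutations is recorded as a warning. Samples are put in a
canonical order internally so the omnibus p is invariant to input ordering
and fully reproducible given the seed.

Interpretation limits: condition (4) is sensitive to measurement noise on
$G$ — noise leaves genuine residual $L$–$T$ dependence given the *observed*
mediator, and the CIT (correctly) refuses to call complete mediation.
Mediation through a noisily measured mediator therefore needs either a
well-measured mediator or external replication. The haplotype is
operationalised as its tag-SNP dosage; phasing is out of scope. Risk
haplotype selection (`select_risk_haplotype`) is a per-haplotype 2×2
$\chi^2$ (this haplotype vs all others × case/control), continuity-corrected
and flagged when an expected cell is below 5, with lexicographic flagged
tie-breaking.

## Risk scores and ROC

The genotype-risk-corrected methylation score is
$\text{score}_s = \sum_i \beta_{si}\,\Delta\beta_i$ over the DMPs surviving
the grc-EWAS, with the grc-EWAS $\Delta\beta$ as weights. Genetic risk is the
tag-SNP dosage plus a polygenic score (weighted dosage sum; missing dosages
are mean-imputed per SNP — the score analogue of pairwise exclusion).
Scores are combined by logistic regression and compared as classifiers by
AUC — the Mann–Whitney pair statistic with ties counted ½ — with a DeLong
confidence interval by default (bootstrap selectable, seeded; which CI
flavour is used does not change any downstream decision). In all
self-assessments the weights are estimated on a training split and the AUC
reported on a held-out split *as well as* in-sample, to keep the in-sample
optimism visible; external weight estimation is the intended use on real
data. Polygenic weight discovery (clumping/thresholding) is out of scope;
weights are supplied or simulated.

## methQTL

Each CpG is tested against SNPs within ±18 kb (closed bounds, same
chromosome) by one-way ANOVA of its beta values across genotype groups
(AA/AB/BB) — beta, not M, because the grouping formula names the beta value.
Within each CpG's window, significance is Bonferroni-corrected
($\alpha/m$, $m$ = window SNPs); nominal testing is selectable since the
policy behind published "significant association" fractions is typically
unstated. A DMP counts as "modulated" if ≥ 1 window SNP passes. Genotype QC
runs SNP call rate (≥ 98%) → sample call rate (≥ 95%) → Hardy–Weinberg
(1-df $\chi^2$ on genotype counts; the exact test is not needed at these
sample sizes and the $\chi^2$ is deterministic and closed-form testable);
monomorphic SNPs are retained and flagged. Missing dosages are excluded
pairwise per test; no imputation in testing paths.

# The synthetic cohort generator

`generate_cohort(sim_config(...))` draws, in order: genotypes (tag SNP,
methQTL SNPs, polygenic and null SNPs), per-sample mediator and
direct-effect CpG signals, a phenotype from a logistic model, cell fractions
from group-specific Dirichlet distributions, and finally the beta matrix as
a six-profile mixture with implanted signals and measurement noise. Sampling
is retrospective: batches are drawn until the case and control quotas are
filled, so group sizes are exact and the marginal haplotype odds ratio is
preserved.

Defaults are the package's standing study conditions:

| parameter | default | rationale |
|---|---|---|
| group sizes | 208 / 402 | discovery-scale case/control design |
| cell-fraction means | NK 0.021/0.031, CD8T 0.095/0.106, CD4T 0.081/0.071 (case/control) | the reported blood-composition differences; B/monocytes/neutrophils split the remainder at plausible blood proportions (0.06/0.09/rest) and do not differ by group |
| Dirichlet concentration | 200 | tight, blood-like inter-individual variability |
| signature CpGs | 33 per type, margin 0.65 beta | well-separated reference |
| haplotype | frequency 0.15, marginal OR 3 | the major-risk-locus scale |
| mediator CpGs | 1; 0.20 beta/allele; intrinsic SD 0.05 | methQTL of the tag SNP carrying the haplotype effect in chain mode |
| polygenic SNPs | 20, log-OR ~ N(0, 0.1) truncated at ±0.2, freq U(0.1, 0.9) | weak polygenic background |
| cell-specific effects | 20 CpGs in B/monocytes, Δβ ±0.15 at baselines 0.10/0.90 | the cell types carrying the real signal; extreme baselines give the M-scale interaction estimates their intended ±2+ magnitude |
| noise | Gaussian on beta, SD 0.02, clipped | array-scale technical noise; a beta-distributed model is selectable |

Three causal modes share one interface: **chain** (haplotype → mediator
methylation → disease; per-CpG slope $\log(\text{OR})/(n_{\text{med}}\,
\delta)$ so the marginal haplotype OR is the configured one), **independent**
(haplotype → disease directly; mediator is a passive methQTL), and
**reverse** (disease shifts mediator methylation). These are exactly the
three hypotheses the CIT discriminates.

Scenario settings used in the validation suite, chosen once from the causal
structure each check describes:

* *genotype-correction*: mediator intrinsic SD 0.01 — a CpG "driven
  entirely" by the haplotype — plus one genotype-independent CpG
  (log-odds 12 per beta unit), n = 1400;
* *CIT operating characteristics*: mediator intrinsic SD 0.08 with
  measurement noise 0.005 — a strong, well-measured mediator, the regime in
  which complete mediation through the observed mediator actually holds —
  n = 1000, B = 500;
* *csDMP attribution*: Δβ 0.15 implanted only in the B-cell profile at
  baselines 0.10/0.90, noise 0.005–0.01, n = 600;
* *score comparison*: ten direct-effect CpGs at log-odds 14 per beta unit
  vs the OR-3 haplotype plus weak polygenic background — methylation
  dominating genetics — n = 1200, split 50/50 train/held-out.

What the generator does **not** emulate: array chemistry and probe-type
effects, batch structure, linkage disequilibrium between SNPs, spatial
correlation of CpGs beyond the implanted signals, and cell-type reference
uncertainty (the reference is known, not estimated from sorted cells).
Passing tests therefore demonstrate the statistical machinery is correct
under the mixture model's assumptions — not that real-array preprocessing
(normalisation, batch correction) is handled, which is explicitly outside
this package.

# Numerical choices

* Logistic fits use `stats::glm.fit` with Wald tests from the weighted-QR
  covariance; separation and rank deficiency produce flagged non-estimable
  rows. Collinear covariates are dropped with a warning.
* Per-cell-type OLS scans share one design matrix per cell type, so all
  CpGs are solved in a single QR — the full grid is seconds, not minutes.
* Zero p-values are clipped to the smallest positive double and flagged;
  degenerate ANOVA (zero within-group variance, unequal means) reports the
  smallest representable p with a flag rather than 0.
* Filters are idempotent; all windows closed; all tie-breaks lexicographic
  and flagged.
* Every stochastic routine takes an explicit seed; the pipeline derives all
  stage seeds from one master seed, and a rerun is byte-identical.

Problem sizes in the validation suite (600–1400 samples, 60–2000 CpGs,
50–100 seed replicates, B = 500 permutations) are the package's chosen
desk-scale study conditions: large enough for the implanted effects to sit
in the clearly-powered regime, small enough that the entire suite runs on a
single CPU in minutes.

# Known limitations

* Deconvolution assumes the reference spans the sample's cell types;
  unmodelled cell types bias fractions toward their nearest reference
  profile.
* The grc-EWAS removes *linear* genotype effects of the supplied loci only;
  uncorrected or interacting genetic risk remains in the "corrected" score.
* The CIT omnibus is a max of non-independent p-values; it is conservative
  as an overall error rate and is validated here by operating
  characteristics, not analytic size.
* The csDMP estimate cut of ±2 is tied to the M-value/fraction scale and
  to fraction variability; it is a decision rule, not an effect-size
  estimate.
* With no phenotype main effect, per-cell-type interaction estimates for
  different cell types are correlated through the shared group contrast,
  scaled by $1/\bar f_k$. The magnitude cut therefore protects against
  false attribution to *abundant* cell types (neutrophils), but a
  *low-abundance* type (NK, $\bar f \approx 0.03$) can clear the cut on a
  signal it does not carry. `include_phenotype_main = TRUE` absorbs the
  group contrast into a main effect and gives clean attribution across all
  six types, at a power cost (detection then rests on fraction variability
  alone); the suite exercises both variants.
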