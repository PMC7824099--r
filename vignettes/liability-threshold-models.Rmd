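---
title: "Liability-threshold risk models for diabetic cardiovascular disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold risk models for diabetic cardiovascular disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcvdrisk)
```

## The model

`dcvdrisk` models disease on the classical liability-threshold (probit)
scale. Liability is a latent variable, standard normal in the population;
an individual develops disease when liability exceeds
$T = \Phi^{-1}(1 - K)$, where $K$ is the disease prevalence. The package
defaults to $K = 0.17$ — the prevalence of cardiovascular disease among
Korean adults with type 2 diabetes, the setting the package was built
around — and a liability-scale heritability $h^2 = 0.5$.

Measured risk factors shift the liability mean. For a SNP with
risk-allele frequency $p$ and per-allele effect $r$, genotype frequencies
come from Hardy–Weinberg equilibrium and per-genotype penetrances follow
the additive (multiplicative-per-allele) relative-risk model

$$f_g = f_0\, r^g, \qquad \sum_g P(g)\, f_g = K ,$$

which fixes $f_0 = K / \sum_g P(g) r^g$ in closed form. The liability
mean shifts $\mu_g$ then solve

$$1 - \Phi\!\left(\frac{T - \mu_g}{\sqrt{1 - v}}\right) = f_g,
\qquad v = \sum_g P(g)\,\mu_g^2 ,$$

i.e. conditional on genotype the remaining liability is normal with
variance $1 - v$, where $v$ is the variance the locus itself explains.
Categorical covariates use the same machinery with their category
frequencies and odds ratios in place of genotypes. An individual's
measured liability is the sum of their per-factor shifts,
$L = \sum_i \mu_{g_i} + \sum_j \mu_{c_j}$, the total explained variance
is $V = \sum v$ (exactly additive because factors are independent in the
model), and the posterior disease risk is

$$P(D \mid L) = 1 - \Phi\!\left(\frac{T - L}{\sqrt{1 - V}}\right).$$

### Effect-size scale

The package reads per-allele (and per-category) effects as **relative
risks on the penetrance scale** by default (`effect_scale = "rr"`). This
is the convention of the liability framework the model follows, it keeps
per-genotype penetrance ratios exactly $(1, r, r^2)$, and for the modest
effects typical of SNP panels it is numerically almost indistinguishable
from the odds-ratio reading. An odds-scale conversion
(`effect_scale = "or"`, solving $\mathrm{odds}(f_g) =
\mathrm{odds}(f_0)\,r^g$ on the logit scale by bracketed root-finding)
is provided for users whose weights are genuine odds ratios from
case-control data with common outcomes.

### Family history

Family history enters as a conditional-liability update, not as an extra
covariate (a covariate coding can always be had by adding a binary
`covariate_scheme`). With relative-pair liability correlation
$\rho = \tfrac12 h^2$ and $V_g$ of the genetic variance already captured
by the measured SNPs, a positive history of one affected first-degree
relative adds

$$\Delta = \tfrac12\,(h^2 - V_g)\,\frac{\phi(T)}{K}$$

to the measured liability — the mean of the *unmeasured* shared polygenic
component given that the relative exceeded the threshold. Negative or
unknown family history leaves liability unchanged; treating unknown as
negative is conservative (it never inflates an individual's risk).

### Lifetime risk

`lifetime_risk()` cumulates an individual's hazard over a life table of
age- and sex-specific incidence (per 1000 person-years) and disease-free
mortality (per 10,000 person-years), treating death before disease as a
competing event. The individual's hazard in a band is the band incidence
times the individual's risk ratio (posterior risk / prevalence). Within a
band hazards are constant, so the increment uses the exact
competing-exponential form
$S \cdot \frac{h}{h+m}\,(1 - e^{-(h+m)w})$ rather than the rectangle
$S\,h\,w$; this reproduces the closed form $1 - e^{-\lambda T}$ exactly
when mortality is zero, for any band width. Band hazards above 1 per
person-year are capped with a warning. The bundled life-table fixture
(`make_life_tables()`) carries the published summary rates — incidence
15.67 (women) and 13.47 (men) per 1000 person-years, disease-free
mortality 19.5 (men) and 7.3 (women) per 10,000 — held constant across
5-year bands from 40 to 69, because the full age-resolved national
tables behind the original analysis are not published. Lifetime-risk
numbers from this fixture are therefore illustrative, not reproductions.

## Scores and evaluation

The polygenic risk score is $\mathrm{PRS} = \sum_i \log(OR_i)\,x_i$
(natural log — the regression-coefficient convention), and the
nongenetic score is its covariate analogue
$\sum_j \log(OR_{j,c_j})$. All score types are mapped to a common 0–10
scale by min-max normalization
$X_N = (X - X_{\min})/X_{\mathrm{range}} \times 10$; the normalization
parameters are fitted once on a reference sample (cases plus controls)
and persisted, and held-out values falling outside the reference range
are clipped to $[0, 10]$ with a recorded count, keeping the scale
contract. Because the map is strictly increasing, every rank-based
statistic (the AUC in particular) is identical before and after
normalization — a property the tests assert.

Evaluation follows the field's standard toolkit:

- **AUC**: Mann–Whitney with ties counted one half, confidence intervals
  by the DeLong asymptotic method (deterministic, unlike a bootstrap);
  an independent brute-force all-pairs count serves as the test oracle.
- **Per-point OR**: univariate logistic regression of status on the
  normalized score; the exponentiated slope is the odds ratio per
  1-point increase on the 0–10 scale.
- **Continuous NRI**: $\mathrm{NRI}_e = P(\text{up} \mid \text{case}) -
  P(\text{down} \mid \text{case})$, $\mathrm{NRI}_{ne}$ symmetrically for
  controls, ties contributing to neither (the standard convention; the
  source does not state its tie handling), overall the sum.
- **Cross-validation**: stratified folds (168 cases split over 10
  unstratified folds would risk case-free folds); normalization
  parameters are fitted on training folds only.
- **Per-cohort evaluation** over the simulated multi-cohort labels,
  skipping single-class strata with a recorded reason.

Risk stratification uses an inclusive cutoff (score $\ge$ cutoff is high
risk, matching the published "0.21 or greater") and pooled-sample
quartile boundaries at the 25/50/75th linear-interpolation percentiles
with boundary ties assigned to the lower group. Pooling cases and
controls for the quartiles is a choice the source leaves open; the
pooled version is recorded in the pipeline manifest.

## The synthetic cohort generator

Because the original cohort data are access-restricted, the package
ships a generator (`simulate_cohort()`) that draws cohorts with exactly
the statistical structure the model assumes:

- genotypes i.i.d. Hardy–Weinberg at the panel's risk-allele
  frequencies (dosage $\sim$ Binomial(2, $p$));
- liability = sum of the model's centered shifts plus a normal residual
  of variance $1 - V$, so liability is N(0, 1) marginally and
  thresholding at $T$ reproduces the prevalence;
- family history from one first-degree relative whose liability
  correlates with the index person at $\tfrac12 h^2$, affected when it
  exceeds the same threshold;
- four cohort labels assigned uniformly, supporting per-cohort
  evaluation without modelling cohort effects.

Default covariates emulate the published case-control characteristics
table without claiming its exact distributions: age truncated normal
(mean 57, sd 9, range 40–69 — the cohorts' age span), sex
Bernoulli(0.52), BMI lognormal (mean 25.2, sd 3.5), serum creatinine
lognormal (mean 0.91, sd 0.45 mg/dL). Continuous covariates are cut at
population tertiles into ordinal 0/1/2 codes (binary covariates 0/1) —
the minimal faithful reading of the source's "categorized into 0, 1,
or 2", which states no cut points. Per-category odds ratios are derived
programmatically from the published per-unit odds ratios (age 1.07 per
year, BMI 1.06 per kg/m², creatinine 2.62 per mg/dL, male sex 1.07)
evaluated at the tertile means of the generating distributions.

What the generator deliberately does **not** emulate: linkage
disequilibrium between loci, population stratification, genotyping
error, imputation uncertainty, cohort-specific effects, and covariate
correlations (age and BMI are independent here). Passing tests therefore
show that the estimators are correct under the model's own assumptions,
not that real DCVD data satisfy those assumptions.

## Numerical choices

- The mean-shift equation inverts in closed form via `qnorm`, so only
  the explained variance $v$ needs a fixed-point iteration (tolerance
  1e-10, at most 100 iterations, step halved when the iterates
  oscillate). The odds-scale baseline penetrance uses `uniroot` on the
  logit scale (bracket ±40, tolerance 1e-12).
- Shifts are centered exactly ($\sum_g P(g)\mu_g = 0$ to machine
  precision). The stored penetrances then satisfy the prevalence
  constraint exactly, while the *integrated* posterior risk carries a
  second-order bias (about $3\times10^{-4}$ for a strong single locus at
  $K = 0.17$, far less for SNP-panel effects) — well inside the
  Monte-Carlo bands the calibration tests use. Exact centering was
  preferred because downstream additivity and mean-zero properties are
  exact by construction.
- Implied penetrances $\ge 1$ (an effect too large for the prevalence)
  and factor sets explaining $\ge$ 100% of liability variance are
  errors, not silent truncations.
- Degenerate inputs: zero contingency cells flag the OR unestimable
  (mirroring the published discrete table, which had no low-risk
  cases); perfect separation in a logistic fit warns and clears the
  `converged` flag; constant raw scores inside the pipeline map to the
  0–10 midpoint so null configurations still evaluate.
- All randomness flows from one master seed; per-stage seeds are
  derived deterministically so adding a stage does not shift another
  stage's stream. Fixed seed gives byte-identical cohorts.

## Problem sizes

The test suite and acceptance script use cohorts of 200,000 samples for
prevalence/calibration checks (binomial 3-SE band of ±0.25 percentage
points around 17%), 20,000–50,000 for distributional properties, 2378 —
the size of the original case-control sample — for association power
checks, and $10^6$ draws for the Monte-Carlo oracles of the penetrance
and family-history conversions. These sizes make the Monte-Carlo error
small against each assertion's tolerance while keeping the full suite
around ten seconds.

## Known limitations

- The bundled 47-SNP panel's published per-allele effects (1.02–1.14)
  explain only ~0.75% of liability variance, which yields simulated
  AUCs near 0.56 — far below the AUC of 0.73 the original study reports
  for the corresponding model. The source is ambiguous about the scale
  of those published coefficients (they derive from a linear mixed
  model, not a logistic fit); the package treats supplied weights as
  per-allele relative risks and documents that assumption rather than
  rescaling them. Real-data AUC/NRI values are, in any case, not
  reproducible without the restricted cohort data.
- Liability effects are additive: no dominance, no epistasis, no
  gene-environment interaction.
- The conditional family-history update shifts the mean only; the
  (small) variance reduction from conditioning is ignored.
- Life-table fixtures are flat across age bands; supply a real
  age-resolved table via `read_life_table()` for serious lifetime-risk
  work.

```{r example}
panel <- dcvd_snp_panel()
m <- liability_model(panel, prevalence = 0.17, heritability = 0.5)
summary(m)

cohort <- simulate(m, nsim = 2000, seed = 7)
L <- measured_liability(m, dosages = cohort$dosages)
auc_rank(L, cohort$samples$status)
```
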