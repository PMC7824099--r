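# dcvdrisk

Liability-threshold (probit) risk modelling for cardiovascular disease in
patients with type 2 diabetes (DCVD), with polygenic risk scores, discrete
and quartile risk stratification, incidence-based lifetime risk, and a
synthetic cohort generator that makes the whole pipeline testable without
access-restricted cohort data.

## Who this is for

Statistical geneticists and epidemiologists who want to combine a published
SNP weight panel (risk-allele frequencies and per-allele effect sizes) with
categorical clinical covariates into a single latent-liability risk model,
and to evaluate competing models (genetic vs nongenetic vs multifactorial;
liability vs log-OR score) with the field's standard metrics: rank AUC with
DeLong intervals, per-point odds ratios, continuous net reclassification
improvement (NRI), stratified 10-fold cross-validation and per-cohort
analyses.

## The model

Disease liability is a latent standard-normal variable; an individual is
affected when liability exceeds the threshold `T = Φ⁻¹(1 − K)` for
prevalence `K`. Each measured factor shifts the liability mean:

- A SNP with risk-allele frequency `p` and per-allele relative risk `r`
  gets per-genotype penetrances `f_g = f₀ r^g` (g = 0, 1, 2 risk alleles)
  constrained so that `Σ P_HWE(g) f_g = K`, and centered mean shifts `μ_g`
  solving `1 − Φ((T − μ_g)/√(1 − v)) = f_g`, where `v = Σ P(g) μ_g²` is the
  liability variance the locus explains (found by fixed-point iteration).
- Categorical covariates (ordinal 0/1/2 or binary) go through identical
  machinery with their category frequencies and odds ratios.
- An individual's measured liability is the sum of their shifts,
  `L = Σᵢ μ_{g_i} + Σⱼ μ_{c_j}`; posterior disease risk is
  `1 − Φ((T − L)/√(1 − V))` with `V` the total variance explained.
- Positive family history adds the conditional mean of the unmeasured
  polygenic liability given one affected first-degree relative,
  `Δ = ½ (h² − V_g) φ(T) / K`.
- Lifetime risk cumulates `risk-ratio × age/sex-specific incidence`
  against disease-free mortality as a competing event over a life table.

The polygenic risk score is the usual `PRS = Σ log(ORᵢ) xᵢ`; all scores are
mapped to a common 0–10 scale by min-max normalization with persisted
parameters.

## Worked example

```r
library(dcvdrisk)
panel <- dcvd_snp_panel()          # bundled 47-SNP weight table
m <- liability_model(panel, prevalence = 0.17, heritability = 0.5)
m
#> Liability-threshold risk model (genetic)
#>   prevalence K = 0.170  (threshold T = 0.9542)
#>   heritability h2 = 0.50
#>   47 loci, genetic variance explained = 0.0075
#>   total variance explained V = 0.0075
#>   family-history liability shift = 0.3666

cohort <- simulate(m, nsim = 2378, seed = 42)   # study-sized cohort
L   <- measured_liability(m, dosages = cohort$dosages)
glt <- minmax_normalize(L, score_type = "liability")

auc_rank(glt, cohort$samples$status)
#> GLT47 AUC 0.556 (0.526-0.586)
per_point_or(glt, cohort$samples$status)
#> OR per 1-point increase 1.14 (1.05-1.23)

q <- quartile_assign(glt, cohort$samples$status)
q$counts
#>   group cases controls case_fraction
#> 1    Q1    80      515     0.134
#> 2    Q2   101      493     0.170
#> 3    Q3   112      482     0.189
#> 4    Q4   132      463     0.222
q$or_q4_q1$or
#> 1.84

risk <- posterior_risk(L, m$variance_explained, 0.17)
lifetime_risk(max(risk) / 0.17, make_life_tables(), "female")
#> 0.539   # top-risk individual, cumulated from age 40
```

The printed numbers mean: the threshold 0.9542 is the liability cutoff
placing 17% of the population above it; the 47 published per-allele
effects explain 0.75% of liability variance, which yields a modest AUC of
0.56 on a cohort simulated under those exact effects; case fractions rise
monotonically across score quartiles (13% → 22%, Q4-vs-Q1 OR 1.84); and
the highest-risk individual's 28% posterior risk translates into a 54%
lifetime risk from age 40 under the bundled incidence/mortality table.

A pipeline wrapper builds all six model variants (nGLT/nGRS, GLT/PRS,
MLT/MRS, each with and without family history) in one call:

```r
res <- run_pipeline(list(n = 2378, seed = 1))
res$evaluations
```

A thin shell interface is installed at `inst/cli/dcvdrisk`
(`simulate`, `assoc`, `prs`, `run` subcommands).

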