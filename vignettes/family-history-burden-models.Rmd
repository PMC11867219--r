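---
title: "Family-history-weighted burden models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-history-weighted burden models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhburden)
```

## The problem

In large population cohorts, cases of any single disease are far outnumbered
by unaffected participants, and power to detect rare-variant associations is
limited by the effective number of cases. Unaffected participants with an
affected first-degree relative carry part of a case's genetic information:
a first-degree relative shares half of their alleles with the proband, so a
positive family history is, to first order, worth half a case. `fhburden`
implements association models that exploit this.

## Models

The burden genotype is collapsed to a carrier indicator per gene:
$G_i = 1$ if the sample carries at least one qualifying variant allele. The
regression is *reversed* — carrier status is the outcome and phenotype the
covariate — because the 2x2 odds ratio is symmetric in its margins, and the
reversal makes adding family history a one-line change of covariate:

* null: $\mathrm{logit}\,P(G=1) = \alpha + \beta_3\,\mathrm{Sex}$
* Model 1: $\ldots + \beta_1\,\mathrm{Case}$
* Model 2: $\ldots + \beta_1\,\mathrm{Case} + \beta_2\,\mathrm{FH}$
* Model 3: $\ldots + \beta_1(\mathrm{Case} + k\,\mathrm{FH})$

Model 3 constrains $\beta_2 = k\beta_1$ and yields a 1-df likelihood-ratio
test against the null; Model 2 yields a 2-df test. The allele-sharing
argument makes $k = 1/2$ locally optimal for small effects. For a rare
allele with case-control odds ratio $e^{\beta_1}$, the frequency among
subjects with an affected first-degree relative implies
$e^{\beta_2} = (e^{\beta_1}+1)/2$, so the locally optimal weight

$$k^\*(\beta_1) = \frac{\log((e^{\beta_1}+1)/2)}{\beta_1}$$

(`optimal_k()`) rises above $1/2$ with effect size — about 0.585 at an odds
ratio of 2, 0.683 at 5. Model 2's ratio $\hat k_T = \hat\beta_2/\hat\beta_1$
estimates the weight empirically. Because fixing $k = 1/2$ overstates
$\beta_1$ when the true effect is large, Model 3 is a discovery tool, not a
risk-estimation tool.

For common variants with genotypes 0/1/2, collapsing wastes information;
`fit_adjacent_categories()` fits the adjacent-categories analogue
$\log P(G=j+1)/P(G=j) = \alpha_{j0} + \eta$ with shared slopes across the
two transitions, so $\beta_1$ is a per-allele log odds ratio.

## The pedigree score test and its reduction

With full pedigree data, the locally most powerful score test weights each
family member's incidence-adjusted disease indicator by twice their kinship
with the genotyped proband:

$$U = \sum_i \sum_j \left(D_{ij} - \Lambda_0(t_{ij})\right)\,
2\phi_{ij0}\,(g_{i0} - 2p), \qquad
V = 2p(1-p)\sum_i (S_i - \bar S)^2,$$

where $S_i$ is pedigree $i$'s weighted phenotype sum and $\Lambda_0$ the
population cumulative hazard (supplied as a piecewise-constant age-band
table; `incidence_model()`). The variance uses the population ($1/N$)
divisor so that $V = N\,\mathrm{var}(S)$ on the quoted scale. Weights are
1, 1/2, 1/4, 0 for self, first-degree, second-degree and unrelated. When
only a binary first-degree family-history summary exists and the disease is
rare enough that the $\Lambda_0$ terms are negligible, the test reduces to
regressing genotype on the composite $u = d + f/2$ (`reduced_phenotype()`;
$f$ is capped at 1 by default because multiple affected relatives are not
distinguished in the targeted analyses) — precisely the Model 3 composite
with $k = 1/2$. Only the proband is genotyped; genotyped relatives are
rejected with an explicit message, as incorporating them is a different
(more powerful) design.

## Effective sample sizes

For margins $N_{00}, N_{01}, N_{10}, N_{11}$ (controls/cases without/with
family history), each strategy's expected score-test Z obeys
$E(Z\mid\beta) = \beta\sqrt{2p(1-p)}\sqrt{N_\mathrm{eff}/2}$ with

* $N_\mathrm{eff1} = 2N_0N_1/N$ (plain case-control),
* $N_\mathrm{eff2} = \big(N_{00}N_{01} + N_{01}N_{10} + N_{10}N_{11} +
  4(N_{00}N_{10} + N_{01}N_{11}) + 9N_{00}N_{11}\big)/(2N)$
  (the $d + f/2$ composite; equal to $2N\,\mathrm{var}(u)$),
* $N_\mathrm{eff3} = N_{00}(N_{01} + 2N_{10} + 3N_{11})^2 /
  \big(2N(N_{01}+N_{10}+N_{11})\big)$ (proxy-case pooling,
  $y=\max(d,f)$).

Two numerical corrections are built in deliberately. First, the
$N_\mathrm{eff3}$ denominator is implemented with the margin
$N_{01}+N_{10}+N_{11}$: this is the unique form under which the expression
collapses to $2N_0N_1/N$ when $N_{01}=N_{11}=0$, the self-consistency
check all three formulas must satisfy (the tests enforce it on random
margins). Second, the proxy-strategy expected Z is implemented as $\beta$
times the design factor so that $E(Z\mid 0)=0$ for every method. Note that
$N_\mathrm{eff2} \ge N_\mathrm{eff1}$ is a property of *cohort-like*
compositions — family history a minority in each stratum and at least as
frequent among cases as controls (so $\mathrm{cov}(d,f)\ge 0$) — not an
algebraic identity for arbitrary margins; the property tests are scoped
accordingly.

## The Monte-Carlo engine

`generate_cohort()` draws sex, case status given sex, and family history
given sex and case by binomial sampling at the configured proportions;
`generate_carriers()` then draws each phenotype cell's carrier count from
$\mathrm{Binomial}\big(n_\mathrm{cell},\,
\mathrm{expit}(\alpha + \beta_1\mathrm{Case} + \beta_2\mathrm{FH} +
\beta_3\mathrm{Sex})\big)$ with $\beta_1 = \log\mathrm{OR}$ and
$\beta_2 = k_\mathrm{gen}\log\mathrm{OR}$. Because all model covariates are
binary, the 2x2x2 phenotype table crossed with carrier status is sufficient
for every fit, so each replicate costs one 8-row weighted IRLS per model
(~1 ms) and full 5000-replicate runs at $n = 450{,}000$ finish in well
under a minute. A property test verifies that the grouped sampler matches
explicit per-individual Bernoulli simulation in the first two moments of
the null LRT statistic.

Default study conditions (all `sim_config()` arguments):

| parameter | default | meaning |
|---|---|---|
| `n` | 450,000 | cohort size per replicate |
| `reps` | 5,000 | Monte-Carlo replicates |
| `alpha` | log(0.001) | logit-scale intercept: baseline aggregate carrier frequency 0.001, typical of PTV burdens in a gene |
| `beta3` | log(1.15) | sex effect on carrier odds |
| `k_generate`, `k_fit` | 0.5 | family-history weight generating/fitting |
| `levels` | 0.05, 2.5e-6 | nominal and exome-wide (~20,000 genes) significance; rejection is strict `<` |

The packaged compositions (`cancer_proportions()`) are the breast,
prostate, bowel and lung cohort structures: 54% female, sex-specific
prevalences from 0.049% (male breast) to 7.9% (female breast), and
family-history rates of 8–23% by stratum.

**Sex coding.** The generator attaches $\beta_3$ to the sex coded 1;
the source analyses do not state the direction. We examined both codings
against the published breast-cancer operating characteristics: with
$\beta_3$ on females the analytic 1-df LRT noncentrality at OR = 2 is 17.7,
with $\beta_3$ on males it is 15.4, and only the latter reproduces the
reported power (the information about $\beta_1$ comes almost entirely from
the female stratum for breast cancer, so inflating female carrier frequency
by 15% inflates power even after sex adjustment). The default is therefore
`sex_one = "male"`; it is a single config switch.

**Determinism.** Each replicate's seed is a counter-based hash of the
master seed, a scenario stream id (encoding OR and $k_\mathrm{gen}$) and
the replicate counter, all below $2^{31}$, so replicates can be regenerated
in isolation and in any order. Runs differing only in `k_fit` share
replicates — deliberate common random numbers, which makes the
k-sensitivity comparison a paired one.

**Degenerate replicates.** Replicates where any fit separates
($|\hat\beta| > 15$) or fails to converge are excluded from the rejection
denominator and tallied (`n_degenerate`); at carrier frequency 0.001 and
$n = 450{,}000$ this affects well under 0.1% of replicates.

## Numerical choices

* Binary-model fitting is iteratively reweighted least squares
  (`stats::glm.fit`) on the grouped cell table, with relative-deviance
  tolerance $10^{-10}$ and at most 100 iterations. A tighter tolerance sits
  below the deviance's floating-point accumulation noise at $n=450{,}000$
  and manufactures spurious non-convergence; at $10^{-10}$ IRLS's quadratic
  convergence still leaves coefficients accurate to well below $10^{-8}$
  (the grouped-vs-expanded and cross-ratio tests assert this).
* The log-likelihood is the Bernoulli form (no binomial coefficient), so
  grouped and per-record representations give identical values, not merely
  values equal up to a constant.
* The adjacent-categories model is a constrained multinomial; it is fitted
  by BFGS with the analytic gradient followed by Newton polishing steps
  until the score norm is below $10^{-8}\,n$, with the covariance from the
  inverse observed information. When no homozygote is present the model
  reduces exactly to the single-transition logistic fit, which is returned
  directly.
* Separation is flagged, never silently repaired; no penalised fallback is
  applied by default because the targeted analyses use plain ML.
* Missing dosages count as non-carrier evidence by default (dominant
  carrier coding), with the per-gene missing-call count reported; a
  `missing = "drop"` switch sets affected samples' carrier status to `NA`
  instead.
* The NMD-escape rule measures the penultimate exon's final 50 bp along the
  coding strand, inclusive of its 3'-most base, with 1-based inclusive
  intervals; a penultimate exon `[101, 200]` on the + strand excludes
  positions 151–200. Single-exon genes escape NMD entirely, so every exonic
  PTV position is excluded. Intronic positions are an error rather than a
  guess. Allele-frequency filtering is strict (`<`) on both the reference
  and the in-sample frequency, the latter computed over non-missing calls.

## What the generator does and does not emulate

The simulated cohorts reproduce the phenotype *composition* of the target
cohorts (sex, prevalence, family-history rates) and the carrier-generating
logistic model. They do not simulate relatives' genotypes, linkage
disequilibrium, relatedness between cohort members, covariate structure
(e.g. ancestry principal components), genotyping error, or multi-gene
exome-wide scans. Passing power tests therefore validate the models'
operating characteristics under the stated generating process — not
robustness to the confounding present in real cohort data, which the
covariate interface merely accommodates.

## Known limitations

* Family history is binary; multiple affected relatives are not weighted
  individually (the capped reduction ignores them by design).
* Only the proband's genotype enters the pedigree score test.
* Model 3 with fixed $k$ biases $\hat\beta_1$ upward for large effects;
  use case-control estimates from independent data for risk quantification.
* The grouped fast path requires the covariates to be exactly the three
  binaries; arbitrary covariates fall back to the per-record path.
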