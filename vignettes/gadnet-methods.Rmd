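---
title: "Methods: driver discovery, mutual predictability and two-gene prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: driver discovery, mutual predictability and two-gene prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gadnet implements a three-stage inference chain for multi-omics tumor
cohorts, together with a fully labeled synthetic cohort generator that makes
every stage testable against planted ground truth. This vignette documents
the statistical models, the tunable parameters and their defaults, the
numerical choices, and the limits of what the synthetic benchmark can show.

## Stage 1 — genetic alteration-driven genes

Differential expression uses an empirical-Bayes moderated t-statistic.  For
gene $g$ with tumor/normal group sizes $n_t, n_n$, the pooled residual
variance $s_g^2$ has $d = n_t + n_n - 2$ degrees of freedom.  A scaled
inverse-chi-square prior $(d_0, s_0^2)$ is fitted by matching the first two
moments of $\log s_g^2$ (closed form via digamma/trigamma, with Newton
inversion of the trigamma function), giving the posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$ and

$$\tilde t_g = \frac{\bar x_{g,t} - \bar x_{g,n}}
  {\tilde s_g \sqrt{1/n_t + 1/n_n}}$$

on $d_0 + d$ degrees of freedom (capped at the pooled residual df of the
whole matrix, so an infinite prior still yields a proper reference).  When
the observed log-variances are underdispersed relative to chi-square noise,
$d_0 = \infty$ and the prior variance is the plain mean of the sample
variances.  Differentially expressed genes (DEGs) require BH FDR < 0.05 and
a two-sided fold change beyond 2 ($|\log_2 FC| > 1$); the fold-change rule
is two-sided because strong down-regulation (fold changes far below 1) is as
informative as up-regulation.

The three driver filters are:

* **methylation-driven** — differential promoter methylation (per-gene Welch
  t-test on beta values, BH FDR < 0.05) *and* a negative Pearson correlation
  between expression and beta across tumor samples with BH-adjusted
  p < 0.05 (adjusted over the tested gene set).  Correlation is computed on
  tumor samples only: matched tumor multi-omics is what cohort data provide,
  and pooling groups would manufacture correlation from group differences
  (a `tumor_only = FALSE` flag exists);
* **CNA-driven** — DEGs lying in significantly amplified or deleted regions
  (gene lists of the kind GISTIC 2.0 emits; the package consumes calls, it
  does not compute them).  The default is the plain intersection; a
  concordance flag restricts to amplified-and-up plus deleted-and-down;
* **mutation-driven** — DEGs carrying non-silent mutations in at least
  `min_samples` distinct tumors.  `min_samples` defaults to 1, the
  permissive reading of "significantly mutated after removing silent
  mutations"; the silent class list defaults to `"Silent"` and is
  configurable to richer MAF vocabularies.

Category overlaps are scored with the inclusive upper-tail hypergeometric
test $P(X \ge k)$; the universe size is an explicit argument because it is a
genuine analysis choice — the pipeline defaults to the number of genes
present in all modalities.

"FDR" is Benjamini–Hochberg throughout (the field default and the default
`adjust` of linear-model differential-expression pipelines).

## Stage 2 — mutual predictability on the functional-linkage network

The substrate is a positive-weighted undirected gene network whose edge
weights encode the probability that two genes share a biological process.
For a driver gene, its direct neighbors are ranked by edge weight; the
recovery AUC of the drug-response-gene (DRG) set is the probability that a
randomly chosen DRG neighbor outranks a randomly chosen non-DRG neighbor,
ties counted half — the tie-corrected Mann–Whitney statistic, identical to
the trapezoid area under the ROC curve swept over weight cutoffs (an
explicit cutoff-sweep oracle ships in the package and the two are asserted
equal on an exhaustive tie battery).  The mutual predictability of a
(driver, DRG) pair is the geometric mean of the two directional AUCs, and
the top 100 pairs per driver category form the alteration-driven networks.

Numerical/design choices:

* AUCs with an empty positive or negative class among the neighbors are
  *undefined* and the pair is excluded, not imputed at 0.5 — an AUC over an
  empty class is meaningless and imputation would flood the top-k with
  noise;
* the positive sets are the *full* driver and DRG sets, including the
  partner gene (no leave-one-out), with a `leave_one_out` flag for
  sensitivity analysis.  A consequence worth knowing: with set-level
  positives each directional AUC depends only on one gene and the opposing
  set, so the pair score is a product of two per-gene neighborhood
  enrichments — pairs rank highly because both genes sit in DRG-/driver-rich
  neighborhoods;
* ranking ties are broken deterministically (score, then AUC sum, then gene
  ids) so repeated runs produce identical tables;
* top-k is per driver category, with a pooled mode behind a flag.

## Stage 3 — two-gene prognostic signatures

Genes passing a univariate Cox screen (Wald p < 0.1 on standardized
expression) enter per-pair evaluation: a two-covariate Cox fit gives the
risk score $r_i = \hat\beta_1 z_{1i} + \hat\beta_2 z_{2i}$, dichotomized at
the cohort median (samples exactly at the median go to the low-risk group,
for determinism).  The groups are compared by Kaplan–Meier/log-rank, and a
multivariable Cox model of the high-risk indicator adjusted for age
(young ≤ 55 / old), ER, PR and stage (early I/II / late III/IV) yields the
adjusted hazard ratio; BH FDR across the evaluated pairs flags prognostic
pairs at FDR < 0.05.  Time-dependent discrimination uses the
cumulative-case/dynamic-control AUC with inverse-probability-of-censoring
weights from the Kaplan–Meier estimate of the censoring distribution, at
1/3/5-year horizons by default.

Numerical choices: Cox models maximize the Breslow-ties log partial
likelihood by Newton–Raphson with step-halving (tolerance $10^{-8}$ on the
score max-norm, 100 iterations max); standard errors come from the inverse
observed information.  Breslow ties are the simplest well-defined
likelihood and adequate for continuous synthetic times — users comparing
against R defaults should note `survival::coxph` uses Efron ties unless
told otherwise.  Monotone likelihoods (separation) are reported as
non-converged fits with a diagnostic rather than errors; perfectly
collinear designs raise a singular-information error.  Expression is
z-scored across the clinical samples before fitting so that coefficients
and the median split are scale-free; unknown covariate values are handled
complete-case (no imputation); the univariate screen treats expression as
continuous.

## The synthetic cohort: what it emulates and what it does not

`cohort_config()` defaults describe a breast-cancer-like study at desk
scale: 2000 genes, 100 tumor and 40 normal samples, 10 planted drivers per
alteration category, 15 DRGs, and 3 functional modules.  The planted
structure is:

* expression: log2-scale Gaussian noise (sd 1) around per-gene baselines;
* methylation-driven genes: tumor beta shifted by ±0.25 (alternating
  hyper/hypo) with expression coupled through a slope of −6 per beta unit;
  with per-sample beta noise of sd 0.1 this puts the planted inverse
  expression–methylation correlation at $E[r] \approx -0.5$, the coupling
  strength typical of cis-driven genes, and the implied expression shift at
  1.5 log2 units;
* CNA-driven genes: calls of ±2 in 70% of tumors with 1.2 log2 units of
  expression per call unit; each driver is accompanied by one *decoy*
  region gene that carries calls but no expression coupling, so the
  region∩DEG filter has genuine negatives;
* mutation-driven genes: per-tumor mutation probability 0.3 against a
  background of 5×10⁻⁴ per gene per tumor (a sparse, panel-scale somatic
  rate chosen so the permissive `min_samples = 1` rule remains meaningful);
  20% of events are flagged silent; drivers also get a ±1.5 log2 tumor
  shift;
* network: module pairs linked with probability 0.8 and Beta(8,2) weights,
  background pairs with probability 0.01 and Beta(2,8) weights; drivers are
  spread round-robin over the modules and 3 DRGs sit in each, so every
  planted (driver, DRG) pair shares a module and the per-category module
  pairs (10 × 9 = 90) fit inside the top-100 cut;
* survival: exponential proportional hazards on the standardized expression
  of one planted pair (the first module-1 methylation driver and the first
  module-1 DRG) with β = (0.7, 0.7), baseline hazard log(2)/1500 per day
  (median ~4 years) and independent exponential censoring at 2×10⁻⁴
  (roughly 30% censored).  The exponential baseline is a simulation
  convenience: it gives closed-form times with a known true β for
  parameter-recovery tests, while the fitted model remains semi-parametric.

Every modality draws from its own named RNG substream of one master seed,
so regeneration is byte-identical and adding a modality never perturbs
another's draws.  DRGs are assigned to drugs uniformly at random; the drug
label is annotation only.

What the generator does **not** emulate: TCGA marginal distributions, batch
or subtype structure, probe-level methylation (betas are gene-level promoter
summaries), segment-level copy number, correlated clinical covariates, or
any real network's weight distribution (the Beta families are a free
modeling choice).  Passing the planted-recovery tests therefore shows that
the filters and scores recover the structures they are defined on, at
realistic effect sizes and sample sizes — not that they would achieve the
same operating characteristics on real cohort data, where effect sizes are
heterogeneous and confounding is real.

## Problem sizes used in the test battery

The packaged tests run the default 2000-gene cohort end-to-end and
additionally use: an exhaustive tie battery (all two-level weight tuples ×
all label subsets, neighborhood sizes 2–6) plus 1000 random 12-neighbor
rankings for the AUC oracle; exhaustive draw enumeration for all
hypergeometric configurations with universes up to 12; a grid-search
partial-likelihood oracle (step 10⁻³) on ≤6-subject Cox fixtures plus 200
simulation replicates at n = 1000; 2000 label permutations for log-rank
calibration; and 200 batches of 5000 null p-values for FDR calibration.
These sizes were chosen to make the checks exhaustive where exhaustiveness
is cheap and statistically well-powered where it is not.

## Known limitations

* No Efron tie handling, stratification, time-varying covariates or
  proportionality diagnostics in the Cox module.
* No probe-to-promoter methylation mapping, no GISTIC computation, no
  enrichment analysis and no drug–target database integration: region gene
  lists and DRG annotations are inputs.
* Readers reject missing cells rather than imputing; real-data users must
  complete their matrices upstream.
* The mutual-predictability score does not test pair-specific association
  beyond shared neighborhood enrichment (see the set-level positives note
  above); a leave-one-out flag is the provided sensitivity analysis.
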