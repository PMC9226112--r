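# gadnet

Multi-omics discovery of **g**enetic **a**lteration-**d**riven gene
**net**works and two-gene prognostic signatures.

In tumor cohorts, part of the differential expression between tumor and
normal tissue is attributable to an upstream genetic alteration of the gene
itself: promoter hyper-/hypomethylation (recognizable by an inverse
correlation between expression and methylation beta), copy-number
amplification or deletion (region membership in GISTIC-style calls), or
recurrent non-silent somatic mutation. gadnet identifies these
*alteration-driven* genes, asks which of them are functionally coupled to
*drug-response genes* (DRGs), and evaluates the resulting gene pairs as
survival signatures. It is aimed at computational biologists analyzing
matched expression/methylation/CNA/mutation/survival data, and ships a
fully labeled synthetic cohort generator so the whole chain can be
validated against planted ground truth.

## The methods in brief

* **Driver discovery.** Differential expression by an empirical-Bayes
  moderated t-statistic (prior `(d0, s0^2)` fitted by digamma/trigamma
  moment matching of `log s^2`; posterior variance
  `(d0*s0^2 + d*s^2)/(d0+d)`), DEGs at BH FDR < 0.05 and fold change > 2
  two-sided; methylation drivers additionally need Pearson `r < 0` between
  expression and beta across tumors at adjusted p < 0.05; CNA drivers are
  DEGs inside amplified/deleted regions; mutation drivers are DEGs with
  non-silent mutations. Category overlaps get an inclusive upper-tail
  hypergeometric `P(X >= k)`.
* **Mutual predictability.** On a positive-weighted functional-linkage
  network, each gene's direct neighbors are ranked by edge weight; the AUC
  with which that ranking recovers the opposing category set (tie-corrected
  Mann–Whitney, equal to the cutoff-sweep ROC area) is computed in both
  directions and the pair score is `sqrt(AUC_driver * AUC_drg)`. The top
  100 pairs per driver category form the alteration-driven networks.
* **Prognostic pairs.** Univariate Cox screen (p < 0.1), two-gene Cox risk
  score `b1*z1 + b2*z2` split at the median, Kaplan–Meier/log-rank,
  multivariable Cox adjusted for age/ER/PR/stage, BH FDR across pairs
  (prognostic at FDR < 0.05), and IPCW time-dependent AUC at 1/3/5 years.
  Cox fits maximize the Breslow-ties partial likelihood by Newton–Raphson.

See `vignettes/gadnet-methods.Rmd` for the full model description, defaults
and limitations.

## Worked example

```r
library(gadnet)

cfg <- cohort_config(seed = 42)           # 2000 genes, 100 tumor / 40 normal
sim <- generate_cohort(cfg)               # cohort + planted truth labels
net <- index_network(generate_network(cfg, sim$truth))

de   <- moderated_t_test(sim$cohort$expr)
degs <- select_degs(de)                   # FDR < 0.05 & |log2FC| > 1
dm   <- diff_methylation(sim$cohort$meth)
drivers <- methylation_driven(dm, sim$cohort$expr, sim$cohort$meth)
drivers
#> <driver_gene_set> category: methylation, 10 gene(s)
head(drivers$evidence[, c("gene", "delta_beta", "direction", "r", "adjusted_p")], 3)
#>     gene delta_beta direction          r   adjusted_p
#> 1 G00001  0.2515170     hyper -0.6574272 1.088980e-12
#> 2 G00002 -0.2984045      hypo -0.4622816 1.607632e-06
#> 3 G00003  0.2596112     hyper -0.5287307 5.208455e-08
```

Ten methylation-driven genes are recovered, each with its beta shift,
direction and the inverse expression–methylation correlation that triggered
it. Scoring them against the DRG set on the network:

```r
pairs <- top_pairs(net, drivers, sim$cohort$drg, k = 100)
head(pairs[, c("driver", "drg", "auc_driver", "auc_drg", "score", "rank")], 3)
#>   driver    drg auc_driver   auc_drg     score rank
#> 1 G00009 G00041          1 0.9259259 0.9622504    1
#> 2 G00009 G00038          1 0.9000000 0.9486833    2
#> 3 G00009 G00034          1 0.8916667 0.9442810    3
```

`auc_driver = 1` says every DRG among G00009's neighbors outranks every
non-DRG neighbor; the score is the geometric mean of the two directional
AUCs. Evaluating the candidates as two-gene risk scores:

```r
prog <- evaluate_pairs(pairs, sim$cohort$expr, sim$cohort$clinical)
prog[prog$flagged, c("driver", "drg", "adj_hr", "adj_ci_lower",
                     "adj_ci_upper", "logrank_p", "fdr", "td_auc_1825")]
#>   driver    drg   adj_hr adj_ci_lower adj_ci_upper    logrank_p          fdr td_auc_1825
#> 1 G00001 G00031 4.761745     2.701898     8.391958 4.652036e-10 1.348087e-07   0.8877174
#> 2 G00001 G00037 3.043874     1.787290     5.183919 1.060296e-06 4.172866e-05   0.8059153
```

The planted prognostic pair (G00001, G00031) is flagged: its high-risk
group has an adjusted hazard ratio of 4.8 (95% CI 2.7–8.4) after
controlling for age/ER/PR/stage, and the risk score discriminates 5-year
outcomes with a time-dependent AUC of 0.89. (The second row shares the
planted driver and inherits part of its signal.)

The same chain runs from the shell over a YAML config:

```sh
Rscript inst/cli/gadnet.R run-all config.yaml     # simulate -> drivers -> score -> survival
Rscript inst/cli/gadnet.R validate network edges.tsv
```

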