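#' Configuration for the synthetic multi-omics cohort generator
#'
#' Bundles every tunable of the synthetic cohort: cohort sizes, planted-effect
#' magnitudes for each alteration modality, network module structure, and the
#' survival model of the planted prognostic pair.  The defaults describe a
#' breast-cancer-like tumor/normal cohort at desk scale: 2000 genes, 100 tumor
#' and 40 normal samples, ten planted driver genes per alteration category, and
#' three functional modules coupling drivers to drug-response genes (DRGs).
#'
#' @param n_genes Number of genes in the universe.
#' @param n_tumor,n_normal Number of tumor / normal samples.
#' @param n_meth_driven,n_cna_driven,n_mut_driven Number of planted
#'   methylation-, copy-number- and mutation-driven genes (may be zero for a
#'   null cohort).
#' @param n_drg Number of drug-response genes; the first
#'   `module_count * module_drg` of them are placed inside network modules.
#' @param n_drugs Number of distinct drugs DRGs are annotated with.
#' @param logfc_de Log2 fold-change magnitude of planted differential
#'   expression (applied to mutation-driven genes in tumors).
#' @param delta_beta Methylation beta shift of planted hyper-/hypomethylated
#'   genes in tumors; must keep betas inside (0, 1).
#' @param meth_expr_slope Coupling coefficient of expression on beta for
#'   methylation-driven genes; must be negative (inverse regulation).
#' @param cna_dosage Expression shift in log2 units per unit copy-number call.
#' @param cna_alter_frac Fraction of tumors carrying the nonzero call at a
#'   planted CNA gene.
#' @param mut_rate_background,mut_rate_driver Per-gene per-tumor Bernoulli
#'   mutation rates for background genes and planted mutation-driven genes.
#' @param silent_fraction Fraction of mutation events flagged silent.
#' @param module_count Number of planted functional modules in the network.
#' @param module_drg DRGs placed in each module.
#' @param module_filler Unplanted filler genes placed in each module.
#' @param within_module_edge_prob,background_edge_prob Edge probabilities
#'   inside modules and elsewhere.
#' @param within_weight_params,background_weight_params Beta-distribution
#'   shape pairs for within-module and background edge weights; the
#'   within-module family should be stochastically larger.
#' @param surv_beta Length-2 vector of true log-hazard coefficients for the
#'   planted prognostic pair (on standardized expression).
#' @param baseline_hazard Exponential baseline hazard (per day).
#' @param censor_rate Rate of the independent exponential censoring time.
#' @param expr_noise_sd,beta_noise_sd Gaussian noise standard deviations of
#'   expression (log2 units) and methylation beta.
#' @param seed Master RNG seed; all modality substreams derive from it.
#'
#' @return A validated object of class `cohort_config`.
#' @seealso [generate_cohort()], [generate_network()]
#' @export
cohort_config <- function(n_genes = 2000L,
                          n_tumor = 100L,
                          n_normal = 40L,
                          n_meth_driven = 10L,
                          n_cna_driven = 10L,
                          n_mut_driven = 10L,
                          n_drg = 15L,
                          n_drugs = 5L,
                          logfc_de = 1.5,
                          delta_beta = 0.25,
                          meth_expr_slope = -6,
                          cna_dosage = 1.2,
                          cna_alter_frac = 0.7,
                          mut_rate_background = 5e-4,
                          mut_rate_driver = 0.3,
                          silent_fraction = 0.2,
                          module_count = 3L,
                          module_drg = 3L,
                          module_filler = 6L,
                          within_module_edge_prob = 0.8,
                          background_edge_prob = 0.01,
                          within_weight_params = c(8, 2),
                          background_weight_params = c(2, 8),
                          surv_beta = c(0.7, 0.7),
                          baseline_hazard = log(2) / 1500,
                          censor_rate = 2e-4,
                          expr_noise_sd = 1,
                          beta_noise_sd = 0.1,
                          seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
    n_normal = as.integer(n_normal),
    n_meth_driven = as.integer(n_meth_driven),
    n_cna_driven = as.integer(n_cna_driven),
    n_mut_driven = as.integer(n_mut_driven),
    n_drg = as.integer(n_drg), n_drugs = as.integer(n_drugs),
    logfc_de = logfc_de, delta_beta = delta_beta,
    meth_expr_slope = meth_expr_slope, cna_dosage = cna_dosage,
    cna_alter_frac = cna_alter_frac,
    mut_rate_background = mut_rate_background,
    mut_rate_driver = mut_rate_driver,
    silent_fraction = silent_fraction,
    module_count = as.integer(module_count),
    module_drg = as.integer(module_drg),
    module_filler = as.integer(module_filler),
    within_module_edge_prob = within_module_edge_prob,
    background_edge_prob = background_edge_prob,
    within_weight_params = as.numeric(within_weight_params),
    background_weight_params = as.numeric(background_weight_params),
    surv_beta = as.numeric(surv_beta),
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    expr_noise_sd = expr_noise_sd, beta_noise_sd = beta_noise_sd,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid cohort_config field '", field, "': ", why, call. = FALSE)
  }
  for (f in c("n_genes", "n_tumor", "n_normal", "n_drugs")) {
    if (!is_count(cfg[[f]])) bad(f, "must be a positive integer")
  }
  for (f in c("n_meth_driven", "n_cna_driven", "n_mut_driven", "n_drg",
              "module_count", "module_drg", "module_filler")) {
    if (!is_count(cfg[[f]], allow_zero = TRUE)) {
      bad(f, "must be a nonnegative integer")
    }
  }
  if (cfg$n_normal < 2 || cfg$n_tumor < 2) {
    bad("n_tumor/n_normal", "each group needs at least 2 samples")
  }
  planted <- cfg$n_meth_driven + cfg$n_cna_driven + cfg$n_mut_driven + cfg$n_drg
  # CNA decoys (one per planted CNA gene) and module fillers also need genes.
  needed <- planted + cfg$n_cna_driven + cfg$module_count * cfg$module_filler
  if (needed > cfg$n_genes) {
    bad("n_genes", sprintf(
      "planted genes, CNA decoys and module fillers need %d genes but n_genes = %d",
      needed, cfg$n_genes
    ))
  }
  if (cfg$module_count * cfg$module_drg > cfg$n_drg) {
    bad("module_drg", "module_count * module_drg exceeds n_drg")
  }
  for (f in c("cna_alter_frac", "mut_rate_background", "mut_rate_driver",
              "silent_fraction", "within_module_edge_prob",
              "background_edge_prob")) {
    if (!is_prob(cfg[[f]])) bad(f, "must be a probability in [0, 1]")
  }
  for (f in c("logfc_de", "cna_dosage", "expr_noise_sd", "beta_noise_sd")) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0) bad(f, "must be >= 0")
  }
  if (!is_number(cfg$delta_beta) || cfg$delta_beta < 0 || cfg$delta_beta >= 0.5) {
    bad("delta_beta", "must lie in [0, 0.5) so betas stay inside (0, 1)")
  }
  if (!is_number(cfg$meth_expr_slope) || cfg$meth_expr_slope > 0) {
    bad("meth_expr_slope", "must be <= 0 (inverse expression-methylation coupling)")
  }
  for (f in c("within_weight_params", "background_weight_params")) {
    v <- cfg[[f]]
    if (length(v) != 2L || !all(is.finite(v)) || any(v <= 0)) {
      bad(f, "must be two positive Beta shape parameters")
    }
  }
  if (length(cfg$surv_beta) != 2L || !all(is.finite(cfg$surv_beta))) {
    bad("surv_beta", "must be two finite log-hazard coefficients")
  }
  for (f in c("baseline_hazard", "censor_rate")) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0) bad(f, "must be >= 0")
  }
  if (cfg$baseline_hazard <= 0) bad("baseline_hazard", "must be > 0")
  if (!is_count(cfg$seed, allow_zero = TRUE)) {
    bad("seed", "must be a nonnegative integer")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  genes: %d  tumor: %d  normal: %d  seed: %d\n",
              x$n_genes, x$n_tumor, x$n_normal, x$seed))
  cat(sprintf("  planted drivers: %d meth / %d cna / %d mut;  DRGs: %d\n",
              x$n_meth_driven, x$n_cna_driven, x$n_mut_driven, x$n_drg))
  cat(sprintf("  modules: %d (x%d DRGs, x%d fillers)\n",
              x$module_count, x$module_drg, x$module_filler))
  invisible(x)
}
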