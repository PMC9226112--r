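# Synthetic multi-omics cohort with planted, fully labeled effects.
#
# The generator emulates the shape of a TCGA-style breast-cancer cohort:
# log2 expression with tumor/normal labels, gene-level promoter methylation
# betas, GISTIC-style integer copy-number calls with amplified/deleted region
# gene lists, a non-silent/silent somatic mutation table, right-censored
# overall survival with binary clinical covariates, and a positive-weighted
# functional-linkage network with planted modules coupling driver genes to
# drug-response genes (DRGs).

# Deterministic role layout over the gene universe (no RNG): planted drivers
# first, then DRGs, then one CNA decoy per planted CNA gene (region member
# without expression coupling), then module filler genes.
assign_roles <- function(cfg) {
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  pos <- 0L
  take <- function(n) {
    out <- if (n > 0L) genes[(pos + 1L):(pos + n)] else character()
    pos <<- pos + n
    out
  }
  meth <- take(cfg$n_meth_driven)
  cna <- take(cfg$n_cna_driven)
  mut <- take(cfg$n_mut_driven)
  drg <- take(cfg$n_drg)
  decoy <- take(cfg$n_cna_driven)
  filler <- take(cfg$module_count * cfg$module_filler)

  alt_sign <- function(n) if (n > 0L) rep_len(c(1L, -1L), n) else integer()

  # Module membership: all drivers round-robin across modules; the first
  # module_count * module_drg DRGs in blocks of module_drg; fillers in blocks.
  drivers <- c(meth, cna, mut)
  module <- integer(0)
  if (cfg$module_count > 0L) {
    module <- stats::setNames(rep(0L, cfg$n_genes), genes)
    if (length(drivers)) {
      module[drivers] <- rep_len(seq_len(cfg$module_count), length(drivers))
    }
    n_mod_drg <- cfg$module_count * cfg$module_drg
    if (n_mod_drg > 0L) {
      module[drg[seq_len(n_mod_drg)]] <-
        rep(seq_len(cfg$module_count), each = cfg$module_drg)
    }
    if (length(filler)) {
      module[filler] <- rep(seq_len(cfg$module_count), each = cfg$module_filler)
    }
  }

  list(
    genes = genes,
    meth = meth, meth_sign = alt_sign(length(meth)),   # +1 hyper, -1 hypo
    cna = cna, cna_sign = alt_sign(length(cna)),       # +1 amp,   -1 del
    mut = mut, mut_sign = alt_sign(length(mut)),       # expression shift sign
    drg = drg, decoy = decoy, decoy_sign = alt_sign(length(decoy)),
    filler = filler, module = module
  )
}

#' Generate a labeled synthetic multi-omics cohort
#'
#' Draws every modality from its own named RNG substream of the master seed,
#' so the same configuration is byte-identical across runs and adding one
#' modality never perturbs another's draws.  Planted structure:
#'
#' * methylation-driven genes: tumor beta shifted by `+/- delta_beta`
#'   (alternating hyper/hypo) and expression coupled to beta through the
#'   negative slope `meth_expr_slope`;
#' * CNA-driven genes: calls of `+2` (amplified) or `-2` (deleted) in a
#'   `cna_alter_frac` fraction of tumors, shifting expression by
#'   `cna_dosage * call`; one decoy region gene per driver carries calls but
#'   no expression coupling;
#' * mutation-driven genes: elevated per-tumor mutation rate plus a
#'   `+/- logfc_de` tumor expression shift;
#' * survival: exponential proportional hazards on the standardized tumor
#'   expression of the planted pair (first module-1 methylation driver, first
#'   module-1 DRG), independently exponentially censored.
#'
#' @param config A [cohort_config()].
#' @return A list with components `cohort` (class `omics_cohort`: `expr`,
#'   `meth`, `cna`, `mut`, `clinical`, `drg`) and `truth` (class
#'   `truth_labels` recording every planted set, the module assignment, the
#'   true driver-DRG pairs and the planted survival pair/coefficients).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  roles <- assign_roles(cfg)
  genes <- roles$genes
  tumor <- sprintf("T%04d", seq_len(cfg$n_tumor))
  normal <- sprintf("N%04d", seq_len(cfg$n_normal))
  samples <- c(tumor, normal)
  group <- stats::setNames(rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal)),
                           samples)
  n_s <- length(samples)

  ## --- methylation -------------------------------------------------------
  meth_out <- eval_with_seed(substream_seed(cfg$seed, "methylation"), function() {
    base_beta <- stats::runif(cfg$n_genes, 0.2, 0.5)
    beta <- matrix(base_beta, cfg$n_genes, n_s) +
      matrix(stats::rnorm(cfg$n_genes * n_s, 0, cfg$beta_noise_sd),
             cfg$n_genes, n_s)
    dimnames(beta) <- list(genes, samples)
    if (length(roles$meth)) {
      shift <- roles$meth_sign * cfg$delta_beta
      beta[roles$meth, tumor] <- beta[roles$meth, tumor] + shift
    }
    pmin(pmax(beta, 1e-4), 1 - 1e-4)
  })

  ## --- copy number -------------------------------------------------------
  cna_out <- eval_with_seed(substream_seed(cfg$seed, "cna"), function() {
    call <- matrix(0L, cfg$n_genes, cfg$n_tumor, dimnames = list(genes, tumor))
    planted <- c(roles$cna, roles$decoy)
    signs <- c(roles$cna_sign, roles$decoy_sign)
    for (i in seq_along(planted)) {
      hit <- stats::rbinom(cfg$n_tumor, 1L, cfg$cna_alter_frac) == 1L
      call[planted[i], hit] <- 2L * signs[i]
    }
    amp <- planted[signs > 0]
    del <- planted[signs < 0]
    list(call = call, amp = amp, del = del)
  })

  ## --- mutations ---------------------------------------------------------
  mut_out <- eval_with_seed(substream_seed(cfg$seed, "mutation"), function() {
    rate <- rep(cfg$mut_rate_background, cfg$n_genes)
    names(rate) <- genes
    rate[roles$mut] <- cfg$mut_rate_driver
    hits <- matrix(stats::rbinom(cfg$n_genes * cfg$n_tumor, 1L,
                                 rep(rate, times = cfg$n_tumor)),
                   cfg$n_genes, cfg$n_tumor, dimnames = list(genes, tumor))
    idx <- which(hits == 1L, arr.ind = TRUE)
    silent <- stats::rbinom(nrow(idx), 1L, cfg$silent_fraction) == 1L
    data.frame(gene = genes[idx[, 1L]], sample = tumor[idx[, 2L]],
               variant_class = ifelse(silent, "silent", "nonsilent"),
               stringsAsFactors = FALSE)
  })

  ## --- expression --------------------------------------------------------
  expr <- eval_with_seed(substream_seed(cfg$seed, "expression"), function() {
    baseline <- stats::runif(cfg$n_genes, 4, 10)
    e <- matrix(baseline, cfg$n_genes, n_s) +
      matrix(stats::rnorm(cfg$n_genes * n_s, 0, cfg$expr_noise_sd),
             cfg$n_genes, n_s)
    dimnames(e) <- list(genes, samples)
    # methylation coupling: expression = baseline + slope * beta + noise
    if (length(roles$meth)) {
      e[roles$meth, ] <- e[roles$meth, ] +
        cfg$meth_expr_slope * meth_out[roles$meth, ]
    }
    # copy-number dosage on tumors
    if (length(roles$cna)) {
      e[roles$cna, tumor] <- e[roles$cna, tumor] +
        cfg$cna_dosage * cna_out$call[roles$cna, , drop = FALSE]
    }
    # mutation-driven tumor shift
    if (length(roles$mut)) {
      e[roles$mut, tumor] <- e[roles$mut, tumor] +
        roles$mut_sign * cfg$logfc_de
    }
    e
  })

  ## --- clinical covariates -----------------------------------------------
  clin_cov <- eval_with_seed(substream_seed(cfg$seed, "clinical"), function() {
    data.frame(
      sample = tumor,
      age_group = ifelse(stats::rbinom(cfg$n_tumor, 1L, 0.5) == 1L, "old", "young"),
      er = ifelse(stats::rbinom(cfg$n_tumor, 1L, 0.6) == 1L, "pos", "neg"),
      pr = ifelse(stats::rbinom(cfg$n_tumor, 1L, 0.55) == 1L, "pos", "neg"),
      stage = ifelse(stats::rbinom(cfg$n_tumor, 1L, 0.3) == 1L, "late", "early"),
      stringsAsFactors = FALSE
    )
  })

  ## --- survival ----------------------------------------------------------
  surv_pair <- NULL
  mod_drg <- roles$drg[seq_len(cfg$module_count * cfg$module_drg)]
  if (length(roles$meth) && length(mod_drg)) {
    d1 <- roles$meth[roles$module[roles$meth] == 1L]
    g1 <- mod_drg[roles$module[mod_drg] == 1L]
    if (length(d1) && length(g1)) surv_pair <- c(d1[1L], g1[1L])
  }
  surv <- eval_with_seed(substream_seed(cfg$seed, "survival"), function() {
    lp <- rep(0, cfg$n_tumor)
    if (!is.null(surv_pair)) {
      z1 <- as.numeric(scale(expr[surv_pair[1L], tumor]))
      z2 <- as.numeric(scale(expr[surv_pair[2L], tumor]))
      lp <- cfg$surv_beta[1L] * z1 + cfg$surv_beta[2L] * z2
    }
    t_event <- stats::rexp(cfg$n_tumor, rate = cfg$baseline_hazard * exp(lp))
    t_cens <- if (cfg$censor_rate > 0) {
      stats::rexp(cfg$n_tumor, rate = cfg$censor_rate)
    } else {
      rep(Inf, cfg$n_tumor)
    }
    data.frame(os_time = pmax(pmin(t_event, t_cens), 1e-3),
               os_event = as.integer(t_event <= t_cens))
  })

  clinical <- clinical_table(cbind(clin_cov[1L], surv, clin_cov[-1L]))

  ## --- DRG annotation ----------------------------------------------------
  drg_df <- eval_with_seed(substream_seed(cfg$seed, "drg"), function() {
    if (length(roles$drg) == 0L) return(NULL)
    data.frame(gene = roles$drg,
               drug = sprintf("drug_%02d",
                              sample.int(cfg$n_drugs, length(roles$drg),
                                         replace = TRUE)),
               stringsAsFactors = FALSE)
  })

  ## --- truth labels ------------------------------------------------------
  # Expected tumor log2 fold changes of planted genes (for DE truth labels).
  exp_lfc <- stats::setNames(rep(0, cfg$n_genes), genes)
  if (length(roles$meth)) {
    exp_lfc[roles$meth] <- cfg$meth_expr_slope * roles$meth_sign * cfg$delta_beta
  }
  if (length(roles$cna)) {
    exp_lfc[roles$cna] <- 2 * roles$cna_sign * cfg$cna_dosage * cfg$cna_alter_frac
  }
  if (length(roles$mut)) exp_lfc[roles$mut] <- roles$mut_sign * cfg$logfc_de
  de_up <- names(exp_lfc)[exp_lfc > 0]
  de_down <- names(exp_lfc)[exp_lfc < 0]

  true_pairs <- data.frame(driver = character(), drg = character(),
                           category = character(), stringsAsFactors = FALSE)
  if (length(mod_drg)) {
    cats <- list(methylation = roles$meth, cna = roles$cna, mut = roles$mut)
    names(cats) <- c("methylation", "cna", "mutation")
    for (cat in names(cats)) {
      for (d in cats[[cat]]) {
        partners <- mod_drg[roles$module[mod_drg] == roles$module[[d]]]
        if (length(partners)) {
          true_pairs <- rbind(true_pairs, data.frame(
            driver = d, drg = partners, category = cat,
            stringsAsFactors = FALSE
          ))
        }
      }
    }
  }

  truth <- structure(list(
    de_genes_up = de_up,
    de_genes_down = de_down,
    meth_driven = data.frame(
      gene = roles$meth,
      direction = ifelse(roles$meth_sign > 0, "hyper", "hypo"),
      stringsAsFactors = FALSE
    ),
    cna_driven = data.frame(
      gene = roles$cna,
      call_sign = roles$cna_sign,
      stringsAsFactors = FALSE
    ),
    mut_driven = roles$mut,
    drg = if (is.null(drg_df)) {
      data.frame(gene = character(), drug = character(), stringsAsFactors = FALSE)
    } else {
      drg_df
    },
    module_assignment = roles$module[roles$module > 0L],
    true_pairs = true_pairs,
    surv_pair = surv_pair,
    surv_beta_true = cfg$surv_beta
  ), class = "truth_labels")

  cohort <- structure(list(
    expr = expression_matrix(expr, group),
    meth = methylation_matrix(meth_out, group),
    cna = cna_calls(cna_out$call, cna_out$amp, cna_out$del),
    mut = mutation_table(mut_out),
    clinical = clinical,
    drg = if (is.null(drg_df)) NULL else drg_annotation(drg_df)
  ), class = "omics_cohort")

  list(cohort = cohort, truth = truth)
}

#' Generate the weighted functional-linkage network
#'
#' Samples an undirected simple graph over the cohort's gene universe: pairs
#' sharing a planted module are linked with probability
#' `within_module_edge_prob` and Beta-distributed weights from
#' `within_weight_params` (stochastically heavier); all other pairs are linked
#' with probability `background_edge_prob` and weights from
#' `background_weight_params`.  Every planted driver-DRG pair shares a module
#' and is therefore preferentially embedded in heavy edges.
#'
#' @param config The [cohort_config()] used for [generate_cohort()].
#' @param truth The matching `truth_labels`.
#' @return A [functional_network()] over all cohort genes.
#' @export
generate_network <- function(config, truth) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  module <- stats::setNames(rep(0L, cfg$n_genes), genes)
  if (length(truth$module_assignment)) {
    module[names(truth$module_assignment)] <- truth$module_assignment
  }
  eval_with_seed(substream_seed(cfg$seed, "network"), function() {
    # full upper triangle as index vectors (n_genes ~ 2e3 -> ~2e6 pairs)
    n <- cfg$n_genes
    i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L) + i
    same_mod <- module[i] == module[j] & module[i] > 0L
    p <- ifelse(same_mod, cfg$within_module_edge_prob, cfg$background_edge_prob)
    keep <- stats::runif(length(i)) < p
    i <- i[keep]; j <- j[keep]; same_mod <- same_mod[keep]
    w <- numeric(length(i))
    if (any(same_mod)) {
      w[same_mod] <- stats::rbeta(sum(same_mod),
                                  cfg$within_weight_params[1L],
                                  cfg$within_weight_params[2L])
    }
    if (any(!same_mod)) {
      w[!same_mod] <- stats::rbeta(sum(!same_mod),
                                   cfg$background_weight_params[1L],
                                   cfg$background_weight_params[2L])
    }
    w <- pmin(pmax(w, 1e-9), 1)   # Beta draws of 0/1 are measure-zero; clamp
    functional_network(
      data.frame(from = genes[i], to = genes[j], weight = w,
                 stringsAsFactors = FALSE),
      nodes = genes
    )
  })
}

#' Write every cohort artifact to a directory
#'
#' Writes the expression/methylation matrices with their shared group sidecar,
#' CNA calls and region lists, mutations, clinical table, DRG annotation,
#' network edge list and the truth labels, using the `omics_io` formats.
#'
#' @param sim Result of [generate_cohort()].
#' @param network Result of [generate_network()] (optional).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(sim, network = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    expression = p("expression.tsv"), groups = p("sample_groups.tsv"),
    methylation = p("methylation.tsv"), cna_calls = p("cna_calls.tsv"),
    cna_amp = p("cna_amp_genes.txt"), cna_del = p("cna_del_genes.txt"),
    mutations = p("mutations.tsv"), clinical = p("clinical.tsv"),
    drg = p("drg.tsv"), network = p("network.tsv"), nodes = p("genes.txt"),
    truth = p("truth_labels.json")
  )
  write_matrix(sim$cohort$expr, paths["expression"], paths["groups"])
  write_matrix(sim$cohort$meth, paths["methylation"], paths["groups"])
  write_cna(sim$cohort$cna, paths["cna_calls"], paths["cna_amp"], paths["cna_del"])
  write_mutations(sim$cohort$mut, paths["mutations"])
  write_clinical(sim$cohort$clinical, paths["clinical"])
  if (!is.null(sim$cohort$drg)) write_drg(sim$cohort$drg, paths["drg"])
  if (!is.null(network)) write_network(network, paths["network"], paths["nodes"])
  write_truth_labels(sim$truth, paths["truth"])
  invisible(paths)
}
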