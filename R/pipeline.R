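# End-to-end orchestration: simulate -> drivers -> score -> survival, driven
# by a single YAML run configuration.  Every stage reads the previous stage's
# TSV artifacts from the configured directory and appends its counts to a
# deterministic manifest, so each number in the outputs is traceable to
# (config, seed).

default_thresholds <- function() {
  list(fdr = 0.05, fc = 2, meth_fdr = 0.05, corr_p = 0.05,
       screen_p = 0.1, top_k = 100L, pair_fdr = 0.05, min_mut_samples = 1L)
}

default_flags <- function() {
  list(concordance = FALSE, leave_one_out = FALSE, pooled = FALSE)
}

#' Load and validate a pipeline run configuration
#'
#' The YAML file holds: `outdir`, `seed`, exactly one of a `cohort` block
#' (simulate mode: [cohort_config()] overrides) or a `real` block (paths to
#' existing input files), plus optional `thresholds`, `flags` and `horizons`.
#' Thresholds default to: DEG FDR < 0.05 and fold change > 2, methylation
#' FDR < 0.05, correlation adjusted p < 0.05, screen p < 0.1, top-k 100,
#' pair FDR < 0.05.
#'
#' @param path Path to the YAML config.
#' @return A validated list of class `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$outdir)) stop("config field 'outdir' is required", call. = FALSE)
  has_sim <- !is.null(raw$cohort) || isTRUE(raw$simulate)
  has_real <- !is.null(raw$real)
  if (has_sim == has_real) {
    stop("config must contain exactly one of 'cohort' (simulate) or 'real'",
         call. = FALSE)
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  thr <- utils::modifyList(default_thresholds(), raw$thresholds %||% list())
  for (f in c("fdr", "meth_fdr", "corr_p", "screen_p", "pair_fdr")) {
    if (!is_prob(thr[[f]])) {
      stop("config threshold '", f, "' must be in [0, 1]", call. = FALSE)
    }
  }
  if (!is_number(thr$fc) || thr$fc < 1) {
    stop("config threshold 'fc' must be >= 1", call. = FALSE)
  }
  if (!is_count(thr$top_k)) {
    stop("config threshold 'top_k' must be a positive integer", call. = FALSE)
  }
  flags <- utils::modifyList(default_flags(), raw$flags %||% list())
  horizons <- raw$horizons %||% c(365, 1095, 1825)
  cohort <- NULL
  if (has_sim) {
    args <- raw$cohort %||% list()
    args$seed <- seed
    cohort <- do.call(cohort_config, args)
  }
  structure(list(outdir = raw$outdir, seed = seed, cohort = cohort,
                 real = raw$real, thresholds = thr, flags = flags,
                 horizons = as.numeric(horizons)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

artifact_paths <- function(outdir) {
  p <- function(f) file.path(outdir, f)
  list(
    expression = p("expression.tsv"), groups = p("sample_groups.tsv"),
    methylation = p("methylation.tsv"), cna_calls = p("cna_calls.tsv"),
    cna_amp = p("cna_amp_genes.txt"), cna_del = p("cna_del_genes.txt"),
    mutations = p("mutations.tsv"), clinical = p("clinical.tsv"),
    drg = p("drg.tsv"), network = p("network.tsv"), nodes = p("genes.txt"),
    truth = p("truth_labels.json"),
    diff_expression = p("diffstats_expression.tsv"),
    diff_methylation = p("diffstats_methylation.tsv"),
    drivers_methylation = p("drivers_methylation.tsv"),
    drivers_cna = p("drivers_cna.tsv"),
    drivers_mutation = p("drivers_mutation.tsv"),
    driver_summary = p("driver_summary.json"),
    pairs_methylation = p("pairs_methylation.tsv"),
    pairs_cna = p("pairs_cna.tsv"),
    pairs_mutation = p("pairs_mutation.tsv"),
    pairs_pooled = p("pairs_pooled.tsv"),
    prognosis = p("prognosis.tsv"),
    survival_summary = p("survival_summary.json"),
    manifest = p("manifest.json")
  )
}

input_paths <- function(config) {
  if (!is.null(config$cohort)) return(artifact_paths(config$outdir))
  req <- c("expression", "groups", "methylation", "cna_calls", "cna_amp",
           "cna_del", "mutations", "clinical", "drg", "network")
  missing <- setdiff(req, names(config$real))
  if (length(missing)) {
    stop("real-data config missing paths: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- artifact_paths(config$outdir)
  out[req] <- config$real[req]
  out
}

write_stats_tsv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.12g", out[[col]])
  }
  write_tsv_raw(out, path)
}

update_manifest <- function(outdir, config, stage, counts) {
  path <- artifact_paths(outdir)$manifest
  manifest <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    list(config_hash = fnv1a_hash(unclass(config)[setdiff(names(config),
                                                          "outdir")]),
         seed = config$seed,
         package_version = as.character(utils::packageVersion("gadnet")),
         stages = list())
  }
  manifest$stages[[stage]] <- counts
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

read_stage_inputs <- function(paths) {
  need <- c(paths$expression, paths$groups, paths$methylation,
            paths$cna_calls, paths$mutations, paths$clinical, paths$drg,
            paths$network)
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing upstream artifact(s) ", paste(missing, collapse = ", "),
         "; run the 'simulate' verb (or point the 'real' block at them) first",
         call. = FALSE)
  }
  nodes <- if (file.exists(paths$nodes)) readLines(paths$nodes) else NULL
  list(
    expr = read_matrix(paths$expression, paths$groups, "expression"),
    meth = read_matrix(paths$methylation, paths$groups, "methylation"),
    cna = read_cna(paths$cna_calls, paths$cna_amp, paths$cna_del),
    mut = read_mutations(paths$mutations),
    clinical = read_clinical(paths$clinical),
    drg = read_drg(paths$drg),
    network = read_network(paths$network, nodes = nodes)
  )
}

#' Run one pipeline stage (or the whole chain)
#'
#' Verbs: `simulate` writes the synthetic cohort and network; `drivers` runs
#' differential expression/methylation and the three driver filters plus
#' category-overlap tests; `score` computes the per-category top-k mutual
#' predictability pairs; `survival` evaluates the scored pairs as prognostic
#' signatures; `run-all` chains all four; `validate` checks an input file
#' against its format contract.
#'
#' @param verb One of `simulate`, `drivers`, `score`, `survival`, `run-all`.
#' @param config A `run_config` from [load_run_config()] (or a path to one).
#' @return Invisibly, a named list of the stage's main outputs.
#' @export
run_stage <- function(verb = c("simulate", "drivers", "score", "survival",
                               "run-all"),
                      config) {
  verb <- match.arg(verb)
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  out <- switch(verb,
    "simulate" = stage_simulate(config),
    "drivers" = stage_drivers(config),
    "score" = stage_score(config),
    "survival" = stage_survival(config),
    "run-all" = {
      res <- list()
      if (!is.null(config$cohort)) res$simulate <- stage_simulate(config)
      res$drivers <- stage_drivers(config)
      res$score <- stage_score(config)
      res$survival <- stage_survival(config)
      res
    }
  )
  message(sprintf("[gadnet] %s finished in %.1fs", verb,
                  proc.time()[["elapsed"]] - t0))
  invisible(out)
}

stage_simulate <- function(config) {
  if (is.null(config$cohort)) {
    stop("'simulate' needs a cohort block in the config", call. = FALSE)
  }
  sim <- generate_cohort(config$cohort)
  net <- generate_network(config$cohort, sim$truth)
  write_cohort(sim, net, config$outdir)
  update_manifest(config$outdir, config, "simulate", list(
    n_genes = config$cohort$n_genes,
    n_tumor = config$cohort$n_tumor,
    n_normal = config$cohort$n_normal,
    n_edges = nrow(net$edges),
    n_mutation_records = nrow(sim$cohort$mut)
  ))
  list(sim = sim, network = net)
}

stage_drivers <- function(config) {
  paths <- input_paths(config)
  inp <- read_stage_inputs(paths)
  thr <- config$thresholds
  de <- moderated_t_test(inp$expr)
  degs <- select_degs(de, fc_thresh = thr$fc, fdr_thresh = thr$fdr)
  dm <- diff_methylation(inp$meth)
  meth_set <- methylation_driven(dm, inp$expr, inp$meth,
                                 fdr_thresh = thr$meth_fdr,
                                 corr_p_thresh = thr$corr_p)
  cna_set <- cna_driven(inp$cna, degs$up, degs$down,
                        require_concordance = config$flags$concordance)
  mut_set <- mutation_driven(inp$mut, degs$up, degs$down,
                             min_samples = thr$min_mut_samples)
  out_paths <- artifact_paths(config$outdir)
  write_stats_tsv(de, out_paths$diff_expression)
  write_stats_tsv(dm, out_paths$diff_methylation)
  write_stats_tsv(meth_set$evidence, out_paths$drivers_methylation)
  write_stats_tsv(cna_set$evidence, out_paths$drivers_cna)
  write_stats_tsv(mut_set$evidence, out_paths$drivers_mutation)
  universe <- nrow(inp$expr$values)
  overlaps <- list(
    meth_cna = overlap_significance(meth_set$genes, cna_set$genes, universe),
    meth_mut = overlap_significance(meth_set$genes, mut_set$genes, universe),
    cna_mut = overlap_significance(cna_set$genes, mut_set$genes, universe)
  )
  summary <- list(
    n_up = length(degs$up), n_down = length(degs$down),
    n_methylation_driven = length(meth_set$genes),
    n_cna_driven = length(cna_set$genes),
    n_mutation_driven = length(mut_set$genes),
    universe = universe,
    overlaps = overlaps
  )
  jsonlite::write_json(summary, out_paths$driver_summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  update_manifest(config$outdir, config, "drivers", summary[1:6])
  list(de = de, degs = degs, dm = dm, methylation = meth_set, cna = cna_set,
       mutation = mut_set, overlaps = overlaps)
}

read_driver_sets <- function(config) {
  out_paths <- artifact_paths(config$outdir)
  need <- c(out_paths$drivers_methylation, out_paths$drivers_cna,
            out_paths$drivers_mutation)
  if (any(!file.exists(need))) {
    stop("missing driver tables under ", config$outdir,
         "; run the 'drivers' verb first", call. = FALSE)
  }
  read_set <- function(path, category) {
    df <- read_tsv_raw(path)
    new_driver_gene_set(category, df$gene %||% character(), df)
  }
  list(methylation = read_set(out_paths$drivers_methylation, "methylation"),
       cna = read_set(out_paths$drivers_cna, "cna"),
       mutation = read_set(out_paths$drivers_mutation, "mutation"))
}

stage_score <- function(config) {
  paths <- input_paths(config)
  out_paths <- artifact_paths(config$outdir)
  if (!file.exists(paths$network)) {
    stop("missing network artifact ", paths$network,
         "; run 'simulate' (or supply it in the real block) first",
         call. = FALSE)
  }
  nodes <- if (file.exists(paths$nodes)) readLines(paths$nodes) else NULL
  net <- index_network(read_network(paths$network, nodes = nodes))
  drg <- read_drg(paths$drg)
  sets <- read_driver_sets(config)
  k <- config$thresholds$top_k
  loo <- config$flags$leave_one_out
  res <- list()
  for (cat in names(sets)) {
    res[[cat]] <- suppressWarnings(
      top_pairs(net, sets[[cat]], drg, k = k, leave_one_out = loo)
    )
    write_stats_tsv(res[[cat]], out_paths[[paste0("pairs_", cat)]])
  }
  if (isTRUE(config$flags$pooled)) {
    pooled_drivers <- unique(unlist(lapply(sets, `[[`, "genes")))
    res$pooled <- suppressWarnings(
      top_pairs(net, pooled_drivers, drg, k = k, category = "pooled",
                leave_one_out = loo)
    )
    write_stats_tsv(res$pooled, out_paths$pairs_pooled)
  }
  update_manifest(config$outdir, config, "score",
                  lapply(res, nrow))
  res
}

stage_survival <- function(config) {
  paths <- input_paths(config)
  out_paths <- artifact_paths(config$outdir)
  cats <- c("methylation", "cna", "mutation")
  pair_files <- out_paths[paste0("pairs_", cats)]
  have <- file.exists(unlist(pair_files))
  if (!any(have)) {
    stop("missing pair tables under ", config$outdir,
         "; run the 'score' verb first", call. = FALSE)
  }
  candidates <- do.call(rbind, lapply(unlist(pair_files[have]), function(f) {
    df <- read_tsv_raw(f)
    if (nrow(df) == 0L) return(NULL)
    df$score <- as.numeric(df$score)
    df
  }))
  expr <- read_matrix(paths$expression, paths$groups, "expression")
  clinical <- read_clinical(paths$clinical)
  res <- evaluate_pairs(candidates, expr, clinical,
                        fdr_thresh = config$thresholds$pair_fdr,
                        p_screen = config$thresholds$screen_p,
                        horizons = config$horizons)
  write_stats_tsv(res, out_paths$prognosis)
  dropped <- attr(res, "dropped")
  summary <- list(
    n_candidates = if (is.null(candidates)) 0L else nrow(candidates),
    n_evaluated = nrow(res),
    n_flagged = if (nrow(res)) sum(res$flagged) else 0L,
    n_dropped = nrow(dropped)
  )
  jsonlite::write_json(summary, out_paths$survival_summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  update_manifest(config$outdir, config, "survival", summary)
  res
}

#' Validate an input file against its format contract
#'
#' @param path File to check.
#' @param kind One of `expression`, `methylation`, `mutations`, `clinical`,
#'   `drg`, `network`, `cna` (for `cna`, `path` is the calls file and
#'   `amp`/`del` must be given; for matrices, `groups` must be given).
#' @param groups,amp,del Companion file paths where the format needs them.
#' @return `TRUE` invisibly on success; signals an error describing the first
#'   violation otherwise.
#' @export
validate_file <- function(path, kind, groups = NULL, amp = NULL, del = NULL) {
  switch(kind,
    expression = read_matrix(path, groups, "expression"),
    methylation = read_matrix(path, groups, "methylation"),
    mutations = read_mutations(path),
    clinical = read_clinical(path),
    drg = read_drg(path),
    network = read_network(path),
    cna = read_cna(path, amp, del),
    stop("unknown kind: ", kind, call. = FALSE)
  )
  invisible(TRUE)
}
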