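# Typed containers for every on-disk artifact plus TSV readers/writers.
# All files are plain TSV, UTF-8, '.' decimal, no quoting; matrices carry a
# header row of sample ids and gene ids in the first column, with sample group
# membership in a two-column sidecar file.

group_levels <- c("tumor", "normal")

#' Expression matrix container
#'
#' A log2-scale genes-by-samples expression matrix with a tumor/normal group
#' label per sample.
#'
#' @param values Numeric matrix, rows named by gene, columns by sample.
#' @param group Named character vector mapping every sample to `"tumor"` or
#'   `"normal"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, group) {
  check_omics_matrix(values, group, kind = "expression")
  structure(list(values = values, group = group[colnames(values)]),
            class = "expression_matrix")
}

#' Methylation beta matrix container
#'
#' Gene-level promoter methylation beta values in `[0, 1]`, genes by samples.
#'
#' @param beta Numeric matrix of beta values with gene/sample dimnames.
#' @param group Named character vector mapping samples to tumor/normal.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(beta, group) {
  check_omics_matrix(beta, group, kind = "methylation")
  structure(list(beta = beta, group = group[colnames(beta)]),
            class = "methylation_matrix")
}

check_omics_matrix <- function(values, group, kind) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop(kind, " values must be a numeric matrix", call. = FALSE)
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop(kind, " matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene id: ", genes[duplicated(genes)][1L], call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1L], call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite %s value at gene %s, sample %s",
                 kind, genes[bad[1L]], samples[bad[2L]]), call. = FALSE)
  }
  if (kind == "methylation" && (any(values < 0) || any(values > 1))) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("beta value outside [0,1] at gene %s, sample %s",
                 genes[bad[1L]], samples[bad[2L]]), call. = FALSE)
  }
  if (is.null(names(group)) || !all(samples %in% names(group))) {
    missing <- setdiff(samples, names(group))
    stop("samples missing a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(group %in% group_levels)) {
    stop("group labels must be one of: ", paste(group_levels, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' GISTIC-style gene-level copy-number calls
#'
#' @param call Integer matrix (genes x tumor samples) with entries in
#'   `{-2,-1,0,1,2}`.
#' @param amp_genes,del_genes Character vectors of genes lying in significantly
#'   amplified / deleted regions; a gene may belong to at most one class.
#' @return An object of class `cna_calls`.
#' @export
cna_calls <- function(call, amp_genes = character(), del_genes = character()) {
  if (!is.matrix(call) || is.null(rownames(call)) || is.null(colnames(call))) {
    stop("call must be a matrix with gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(call)) || anyDuplicated(colnames(call))) {
    stop("duplicate gene or sample id in CNA calls", call. = FALSE)
  }
  if (any(!call %in% -2:2)) {
    bad <- which(!matrix(call %in% -2:2, nrow(call)), arr.ind = TRUE)[1L, ]
    stop(sprintf("copy-number call outside {-2..2} at gene %s, sample %s",
                 rownames(call)[bad[1L]], colnames(call)[bad[2L]]),
         call. = FALSE)
  }
  both <- intersect(amp_genes, del_genes)
  if (length(both)) {
    stop("genes in both amplified and deleted regions: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  storage.mode(call) <- "integer"
  structure(list(call = call,
                 amp_genes = sort(unique(as.character(amp_genes))),
                 del_genes = sort(unique(as.character(del_genes)))),
            class = "cna_calls")
}

#' Somatic mutation table
#'
#' Long-format records of (gene, sample, variant class) where the variant
#' class is already collapsed to silent / nonsilent.
#'
#' @param df Data frame with columns `gene`, `sample`, `variant_class`.
#' @return An object of class `mutation_table` (a data frame).
#' @export
mutation_table <- function(df) {
  needed <- c("gene", "sample", "variant_class")
  if (!all(needed %in% names(df))) {
    stop("mutation table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[needed]
  df$gene <- as.character(df$gene)
  df$sample <- as.character(df$sample)
  df$variant_class <- as.character(df$variant_class)
  if (!all(df$variant_class %in% c("silent", "nonsilent"))) {
    stop("variant_class must be 'silent' or 'nonsilent'", call. = FALSE)
  }
  if (anyDuplicated(df)) {
    stop("exact duplicate mutation records present", call. = FALSE)
  }
  class(df) <- c("mutation_table", "data.frame")
  df
}

#' Clinical / survival table
#'
#' One row per tumor sample: overall-survival time and event plus binary
#' clinicopathological covariates (age group at 55, ER, PR, stage I/II vs
#' III/IV, each possibly unknown).
#'
#' @param df Data frame with columns `sample`, `os_time`, `os_event`,
#'   `age_group`, `er`, `pr`, `stage`.
#' @return An object of class `clinical_table` (a data frame).
#' @export
clinical_table <- function(df) {
  needed <- c("sample", "os_time", "os_event", "age_group", "er", "pr", "stage")
  if (!all(needed %in% names(df))) {
    stop("clinical table needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[needed]
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample in clinical table: ",
         df$sample[duplicated(df$sample)][1L], call. = FALSE)
  }
  if (any(!is.finite(df$os_time)) || any(df$os_time <= 0)) {
    stop("os_time must be finite and > 0", call. = FALSE)
  }
  if (!all(df$os_event %in% c(0L, 1L))) {
    stop("os_event must be 0 or 1", call. = FALSE)
  }
  df$os_event <- as.integer(df$os_event)
  checks <- list(age_group = c("young", "old"),
                 er = c("pos", "neg", "unknown"),
                 pr = c("pos", "neg", "unknown"),
                 stage = c("early", "late", "unknown"))
  for (col in names(checks)) {
    df[[col]] <- as.character(df[[col]])
    if (!all(df[[col]] %in% checks[[col]])) {
      stop(col, " must be one of: ", paste(checks[[col]], collapse = ", "),
           call. = FALSE)
    }
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Drug-response gene annotation
#'
#' @param df Data frame with columns `gene`, `drug`; genes are unique within a
#'   drug and at least one record is required.
#' @return An object of class `drg_annotation` (a data frame).
#' @export
drg_annotation <- function(df) {
  if (!all(c("gene", "drug") %in% names(df)) || nrow(df) == 0L) {
    stop("DRG annotation needs at least one (gene, drug) record", call. = FALSE)
  }
  df <- as.data.frame(df)[c("gene", "drug")]
  df$gene <- as.character(df$gene)
  df$drug <- as.character(df$drug)
  if (anyDuplicated(df)) {
    stop("duplicate (gene, drug) record in DRG annotation", call. = FALSE)
  }
  class(df) <- c("drg_annotation", "data.frame")
  df
}

#' Weighted functional-linkage network
#'
#' Undirected simple graph over genes with edge weights in `(0, 1]`; edges are
#' stored canonically with `from < to`.
#'
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @param nodes Optional character vector of node ids; defaults to the genes
#'   appearing in `edges`, and may include isolated genes.
#' @return An object of class `functional_network`.
#' @export
functional_network <- function(edges, nodes = NULL) {
  needed <- c("from", "to", "weight")
  if (!all(needed %in% names(edges))) {
    stop("network edges need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  edges <- as.data.frame(edges)[needed]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) {
    stop("self-loop edge at gene ",
         edges$from[edges$from == edges$to][1L], call. = FALSE)
  }
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0) ||
      any(edges$weight > 1)) {
    stop("edge weights must lie in (0, 1]", call. = FALSE)
  }
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate undirected edge %s - %s", d$from, d$to),
         call. = FALSE)
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$from, edges$to)))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node id", call. = FALSE)
    stray <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(stray)) {
      stop("edge endpoint not in node set: ", stray[1L], call. = FALSE)
    }
    nodes <- sort(nodes)
  }
  structure(list(nodes = nodes, edges = edges), class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## TSV readers / writers
## ---------------------------------------------------------------------------

read_tsv_raw <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "",
                    stringsAsFactors = FALSE)
}

write_tsv_raw <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

read_group_sidecar <- function(path) {
  df <- read_tsv_raw(path)
  if (!all(c("sample", "group") %in% names(df))) {
    stop("group sidecar needs columns sample, group: ", path, call. = FALSE)
  }
  stats::setNames(df$group, df$sample)
}

#' Read a gene-by-sample matrix with its group sidecar
#'
#' The matrix file is a TSV whose header row holds sample ids and whose first
#' column (`gene`) holds gene ids; the sidecar is a two-column TSV mapping
#' `sample` to `group` (tumor/normal).  Parse failures report the offending
#' file line.
#'
#' @param path Path to the matrix TSV.
#' @param groups_path Path to the sample-group sidecar TSV.
#' @param kind `"expression"` or `"methylation"`.
#' @return An [expression_matrix()] or [methylation_matrix()].
#' @export
read_matrix <- function(path, groups_path, kind = c("expression", "methylation")) {
  kind <- match.arg(kind)
  df <- read_tsv_raw(path)
  if (names(df)[1L] != "gene") {
    stop("first column of ", path, " must be 'gene'", call. = FALSE)
  }
  genes <- df$gene
  if (anyDuplicated(genes)) {
    i <- which(duplicated(genes))[1L]
    stop(sprintf("duplicate gene '%s' at line %d of %s", genes[i], i + 1L, path),
         call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at line %d (gene %s), column %s of %s",
                 bad[1L] + 1L, genes[bad[1L]], colnames(num)[bad[2L]], path),
         call. = FALSE)
  }
  if (kind == "methylation" && (any(num < 0) || any(num > 1))) {
    bad <- which(num < 0 | num > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("beta outside [0,1] at line %d (gene %s), column %s of %s",
                 bad[1L] + 1L, genes[bad[1L]], colnames(num)[bad[2L]], path),
         call. = FALSE)
  }
  group <- read_group_sidecar(groups_path)
  if (kind == "expression") expression_matrix(num, group)
  else methylation_matrix(num, group)
}

#' Write a matrix container and its group sidecar
#'
#' @param x An `expression_matrix` or `methylation_matrix`.
#' @param path,groups_path Output TSV paths.
#' @return Invisibly, `x`.
#' @export
write_matrix <- function(x, path, groups_path) {
  vals <- if (inherits(x, "expression_matrix")) x$values else x$beta
  df <- data.frame(gene = rownames(vals),
                   as.data.frame(format_num(vals), check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
  write_tsv_raw(data.frame(sample = names(x$group), group = unname(x$group),
                           stringsAsFactors = FALSE), groups_path)
  invisible(x)
}

format_num <- function(m) {
  out <- matrix(sprintf("%.12g", m), nrow(m), dimnames = dimnames(m))
  out
}

#' Read GISTIC-style thresholded gene-level copy-number calls
#'
#' @param path_calls TSV with a `gene` column plus one integer column per
#'   tumor sample; calls must lie in `{-2,-1,0,1,2}`.
#' @param path_amp,path_del One-gene-per-line text files listing genes in
#'   significantly amplified / deleted regions.
#' @return A [cna_calls()] object.
#' @export
read_cna <- function(path_calls, path_amp, path_del) {
  df <- read_tsv_raw(path_calls)
  if (names(df)[1L] != "gene") {
    stop("first column of ", path_calls, " must be 'gene'", call. = FALSE)
  }
  genes <- df$gene
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  if (any(is.na(num)) || any(num != round(num)) || any(!num %in% -2:2)) {
    bad <- which(is.na(num) | num != round(num) |
                   !matrix(num %in% -2:2, nrow(num)), arr.ind = TRUE)[1L, ]
    stop(sprintf("call outside {-2..2} at line %d (gene %s), column %s of %s",
                 bad[1L] + 1L, genes[bad[1L]], colnames(num)[bad[2L]],
                 path_calls), call. = FALSE)
  }
  amp <- readLines(path_amp, warn = FALSE)
  del <- readLines(path_del, warn = FALSE)
  cna_calls(num, amp[nzchar(amp)], del[nzchar(del)])
}

#' Write copy-number calls and region gene lists
#' @param x A `cna_calls` object.
#' @param path_calls,path_amp,path_del Output paths.
#' @return Invisibly, `x`.
#' @export
write_cna <- function(x, path_calls, path_amp, path_del) {
  df <- data.frame(gene = rownames(x$call),
                   as.data.frame(x$call, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_raw(df, path_calls)
  writeLines(x$amp_genes, path_amp)
  writeLines(x$del_genes, path_del)
  invisible(x)
}

#' Read a minimal MAF-like somatic mutation file
#'
#' Columns `Hugo_Symbol`, `Tumor_Sample_Barcode`, `Variant_Classification`.
#' Variant classes in `silent_classes` map to `silent`; every other class maps
#' to `nonsilent`.
#'
#' @param path Input TSV.
#' @param silent_classes Character vector of class names treated as silent.
#' @return A [mutation_table()].
#' @export
read_mutations <- function(path, silent_classes = "Silent") {
  df <- read_tsv_raw(path)
  needed <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  if (!all(needed %in% names(df))) {
    stop("mutation file needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  mutation_table(data.frame(
    gene = df$Hugo_Symbol,
    sample = df$Tumor_Sample_Barcode,
    variant_class = ifelse(df$Variant_Classification %in% silent_classes,
                           "silent", "nonsilent"),
    stringsAsFactors = FALSE
  ))
}

#' Write a mutation table in the minimal MAF-like layout
#' @param x A `mutation_table`.
#' @param path Output TSV.
#' @return Invisibly, `x`.
#' @export
write_mutations <- function(x, path) {
  write_tsv_raw(data.frame(
    Hugo_Symbol = x$gene,
    Tumor_Sample_Barcode = x$sample,
    Variant_Classification = ifelse(x$variant_class == "silent",
                                    "Silent", "Nonsilent"),
    stringsAsFactors = FALSE
  ), path)
  invisible(x)
}

#' Read a clinical/survival TSV
#'
#' Unknown ER/PR/stage strings are mapped to `"unknown"` with a warning;
#' missing required columns or nonpositive times are errors.
#'
#' @param path Input TSV with columns sample, os_time, os_event, age_group,
#'   er, pr, stage.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- read_tsv_raw(path)
  needed <- c("sample", "os_time", "os_event", "age_group", "er", "pr", "stage")
  if (!all(needed %in% names(df))) {
    stop("clinical file needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  df$os_time <- suppressWarnings(as.numeric(df$os_time))
  df$os_event <- suppressWarnings(as.integer(df$os_event))
  known <- list(er = c("pos", "neg", "unknown"),
                pr = c("pos", "neg", "unknown"),
                stage = c("early", "late", "unknown"))
  for (col in names(known)) {
    bad <- !(df[[col]] %in% known[[col]])
    if (any(bad)) {
      warning(sprintf("%d unknown %s value(s) in %s mapped to 'unknown'",
                      sum(bad), col, path), call. = FALSE)
      df[[col]][bad] <- "unknown"
    }
  }
  clinical_table(df)
}

#' Write a clinical table
#' @param x A `clinical_table`.
#' @param path Output TSV.
#' @return Invisibly, `x`.
#' @export
write_clinical <- function(x, path) {
  df <- as.data.frame(x)
  df$os_time <- sprintf("%.12g", df$os_time)
  write_tsv_raw(df, path)
  invisible(x)
}

#' Read / write a drug-response-gene annotation TSV
#' @param path Two-column TSV with header `gene`, `drug`.
#' @return A [drg_annotation()].
#' @export
read_drg <- function(path) {
  df <- read_tsv_raw(path)
  if (!all(c("gene", "drug") %in% names(df))) {
    stop("DRG file needs columns gene, drug: ", path, call. = FALSE)
  }
  drg_annotation(df)
}

#' @rdname read_drg
#' @param x A `drg_annotation`.
#' @return Invisibly, `x`.
#' @export
write_drg <- function(x, path) {
  write_tsv_raw(as.data.frame(x), path)
  invisible(x)
}

#' Read a weighted edge-list network TSV
#'
#' Three columns (`from`, `to`, `weight`); duplicate undirected edges,
#' self-loops and weights outside `(0, 1]` are errors.
#'
#' @param path Input TSV.
#' @param nodes Optional full node set (to retain isolated genes).
#' @return A [functional_network()].
#' @export
read_network <- function(path, nodes = NULL) {
  df <- read_tsv_raw(path)
  if (!all(c("from", "to", "weight") %in% names(df))) {
    stop("network file needs columns from, to, weight: ", path, call. = FALSE)
  }
  df$weight <- suppressWarnings(as.numeric(df$weight))
  if (any(is.na(df$weight))) {
    i <- which(is.na(df$weight))[1L]
    stop(sprintf("non-numeric weight at line %d of %s", i + 1L, path),
         call. = FALSE)
  }
  functional_network(df, nodes = nodes)
}

#' Write a network edge list (plus optional node list for isolated genes)
#' @param x A `functional_network`.
#' @param path Output edge TSV.
#' @param nodes_path Optional path for a one-per-line node list.
#' @return Invisibly, `x`.
#' @export
write_network <- function(x, path, nodes_path = NULL) {
  df <- x$edges
  df$weight <- sprintf("%.12g", df$weight)
  write_tsv_raw(df, path)
  if (!is.null(nodes_path)) writeLines(x$nodes, nodes_path)
  invisible(x)
}

#' Write / read planted ground-truth labels as JSON
#'
#' Gene sets are serialized as sorted arrays so output is deterministic.
#'
#' @param truth A `truth_labels` object from [generate_cohort()].
#' @param path JSON path.
#' @return Invisibly, `truth` (write) or the reconstructed list (read).
#' @export
write_truth_labels <- function(truth, path) {
  ser <- list(
    de_genes_up = sort(truth$de_genes_up),
    de_genes_down = sort(truth$de_genes_down),
    meth_driven = truth$meth_driven[order(truth$meth_driven$gene), ],
    cna_driven = truth$cna_driven[order(truth$cna_driven$gene), ],
    mut_driven = sort(truth$mut_driven),
    drg = truth$drg[order(truth$drg$gene), ],
    module_assignment = as.list(truth$module_assignment),
    true_pairs = truth$true_pairs[order(truth$true_pairs$category,
                                        truth$true_pairs$driver,
                                        truth$true_pairs$drg), ],
    surv_pair = truth$surv_pair,
    surv_beta_true = truth$surv_beta_true
  )
  jsonlite::write_json(ser, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(truth)
}

#' @rdname write_truth_labels
#' @export
read_truth_labels <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$module_assignment <- unlist(raw$module_assignment)
  raw$true_pairs <- as.data.frame(raw$true_pairs, stringsAsFactors = FALSE)
  raw$meth_driven <- as.data.frame(raw$meth_driven, stringsAsFactors = FALSE)
  raw$cna_driven <- as.data.frame(raw$cna_driven, stringsAsFactors = FALSE)
  raw$drg <- as.data.frame(raw$drg, stringsAsFactors = FALSE)
  structure(raw, class = "truth_labels")
}
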