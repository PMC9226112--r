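# Identification of genetic alteration-driven genes:
#   * differential expression via an empirical-Bayes moderated t-statistic,
#   * differential methylation via per-gene Welch t-tests,
#   * methylation-driven genes via inverse expression-methylation correlation,
#   * CNA-driven genes via region membership of differentially expressed genes,
#   * mutation-driven genes via recurrent non-silent mutation,
#   * hypergeometric overlap significance between driver categories.

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: sort p
#' ascending, take `adj_i = min_{j >= i} p_j * m / j`, clip at 1, return in
#' input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the original order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

# Newton inversion of the trigamma function (solve trigamma(x) = y, y > 0).
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes squeezing of per-gene sample variances
#'
#' Fits a scaled inverse-chi-square prior `(d0, s0^2)` to per-gene residual
#' variances by matching the first two moments of `log(s^2)` (digamma /
#' trigamma closed form), then returns the posterior variances
#' `(d0 * s0^2 + d * s^2) / (d0 + d)`.  When the observed log-variances are
#' underdispersed relative to chi-square sampling noise the prior degrees of
#' freedom are infinite and every posterior variance equals `s0^2`.
#'
#' @param s2 Per-gene sample variances.
#' @param df Residual degrees of freedom (scalar, shared by all genes).
#' @param prior_df,prior_var Optional overrides of the estimated prior; useful
#'   for studying the ordinary-t (`prior_df = 0`) and z-statistic
#'   (`prior_df = Inf`) limits.
#' @return List with `var_prior`, `df_prior`, `var_post`.
#' @export
squeeze_variance <- function(s2, df, prior_df = NULL, prior_var = NULL) {
  stopifnot(length(df) == 1L, df > 0)
  if (is.null(prior_df) || is.null(prior_var)) {
    z <- log(s2[s2 > 0])
    if (length(z) < 2L) {
      d0 <- Inf
      s0 <- if (length(z)) exp(mean(z) - digamma(df / 2) + log(df / 2)) else 1
    } else {
      evar <- stats::var(z) - trigamma(df / 2)
      emean <- mean(z) - digamma(df / 2) + log(df / 2)
      if (evar > 0) {
        d0 <- 2 * trigamma_inverse(evar)
        s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
      } else {
        # log-variances underdispersed vs chi-square noise: infinite prior df;
        # the prior variance is then the plain mean of the sample variances
        d0 <- Inf
        s0 <- mean(s2)
      }
    }
  } else {
    d0 <- prior_df
    s0 <- prior_var
  }
  var_post <- if (is.infinite(d0)) {
    rep(s0, length(s2))
  } else {
    (d0 * s0 + df * s2) / (d0 + df)
  }
  list(var_prior = s0, df_prior = d0, var_post = var_post)
}

#' Moderated two-group t-test on a log2 expression matrix
#'
#' Per gene: `log2fc = mean(tumor) - mean(normal)`, pooled residual variance
#' with `n - 2` degrees of freedom, empirical-Bayes shrinkage of the variances
#' via [squeeze_variance()], moderated
#' `t = log2fc / (s_tilde * sqrt(1/n_t + 1/n_n))` on `d0 + d` degrees of
#' freedom, two-sided p-values and BH FDR over all genes.  A zero-variance
#' gene with zero effect gets `t = 0, p = 1` (with a message when the prior
#' cannot rescue it).
#'
#' @param expr An [expression_matrix()] with both groups of size >= 2.
#' @param prior_df,prior_var Optional prior overrides (see
#'   [squeeze_variance()]).
#' @return Data frame with one row per gene: `gene`, `mean_tumor`,
#'   `mean_normal`, `log2fc`, `t`, `df`, `p`, `fdr`, `direction`; the fitted
#'   prior is attached as attributes `df_prior` and `var_prior`.
#' @export
moderated_t_test <- function(expr, prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- expr$values
  tum <- names(expr$group)[expr$group == "tumor"]
  nor <- names(expr$group)[expr$group == "normal"]
  n1 <- length(tum)
  n2 <- length(nor)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  m1 <- rowMeans(x[, tum, drop = FALSE])
  m2 <- rowMeans(x[, nor, drop = FALSE])
  lfc <- m1 - m2
  ss1 <- rowSums((x[, tum, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, nor, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  if (all(s2 == 0)) {
    message("all gene variances are zero; statistics degenerate")
  }
  sq <- squeeze_variance(s2, d, prior_df = prior_df, prior_var = prior_var)
  se <- sqrt(sq$var_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  if (any(se == 0 & lfc == 0)) {
    message(sum(se == 0 & lfc == 0),
            " zero-variance gene(s) with zero effect set to t = 0, p = 1")
  }
  # total df capped at the pooled residual df of the whole matrix, so an
  # infinite prior still yields a proper reference distribution
  df_total <- min(sq$df_prior + d, d * length(lfc))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(
    gene = rownames(x),
    mean_tumor = m1, mean_normal = m2, log2fc = lfc,
    t = tstat, df = rep(df_total, length(lfc)), p = p,
    fdr = benjamini_hochberg(p),
    direction = ifelse(lfc >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  out
}

#' Select differentially expressed genes by FDR and fold change
#'
#' Keeps genes with `fdr < fdr_thresh` and a two-sided fold change beyond
#' `fc_thresh` (`2^log2fc > fc_thresh` up, `2^log2fc < 1/fc_thresh` down).
#'
#' @param stats Output of [moderated_t_test()].
#' @param fc_thresh Fold-change threshold (default 2).
#' @param fdr_thresh FDR threshold (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
select_degs <- function(stats, fc_thresh = 2, fdr_thresh = 0.05) {
  if (nrow(stats) == 0L) stop("empty differential statistics", call. = FALSE)
  cut <- log2(fc_thresh)
  sig <- stats$fdr < fdr_thresh
  list(up = stats$gene[sig & stats$log2fc > cut],
       down = stats$gene[sig & stats$log2fc < -cut])
}

#' Differential methylation by per-gene Welch t-tests
#'
#' @param meth A [methylation_matrix()] with >= 2 samples per group.
#' @return Data frame per gene: `gene`, `mean_tumor`, `mean_normal`,
#'   `delta_beta`, `t`, `df`, `p`, `fdr`, `direction` (hyper/hypo).
#' @export
diff_methylation <- function(meth) {
  stopifnot(inherits(meth, "methylation_matrix"))
  x <- meth$beta
  tum <- names(meth$group)[meth$group == "tumor"]
  nor <- names(meth$group)[meth$group == "normal"]
  n1 <- length(tum)
  n2 <- length(nor)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  m1 <- rowMeans(x[, tum, drop = FALSE])
  m2 <- rowMeans(x[, nor, drop = FALSE])
  v1 <- rowSums((x[, tum, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, nor, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  delta <- m1 - m2
  tstat <- ifelse(se2 > 0, delta / sqrt(se2),
                  ifelse(delta == 0, 0, sign(delta) * Inf))
  # Welch-Satterthwaite degrees of freedom
  df_w <- ifelse(se2 > 0,
                 se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
                 n1 + n2 - 2)
  p <- ifelse(is.infinite(tstat), 0, 2 * stats::pt(-abs(tstat), df = df_w))
  p[tstat == 0 & delta == 0] <- 1
  data.frame(
    gene = rownames(x),
    mean_tumor = m1, mean_normal = m2, delta_beta = delta,
    t = tstat, df = df_w, p = p, fdr = benjamini_hochberg(p),
    direction = ifelse(delta >= 0, "hyper", "hypo"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

new_driver_gene_set <- function(category, genes, evidence) {
  structure(list(category = category, genes = genes, evidence = evidence),
            class = "driver_gene_set")
}

#' @export
print.driver_gene_set <- function(x, ...) {
  cat(sprintf("<driver_gene_set> category: %s, %d gene(s)\n",
              x$category, length(x$genes)))
  invisible(x)
}

#' Methylation-driven genes: differential methylation with inverse coupling
#'
#' For every differentially methylated gene (`fdr < fdr_thresh` in `dm`),
#' computes the Pearson correlation between expression and beta across tumor
#' samples and keeps genes with negative correlation and BH-adjusted p below
#' `corr_p_thresh` (adjustment over the tested gene set).
#'
#' @param dm Output of [diff_methylation()].
#' @param expr,meth The cohort expression and methylation matrices.
#' @param fdr_thresh Differential-methylation FDR cut (default 0.05).
#' @param corr_p_thresh Adjusted correlation p cut (default 0.05).
#' @param tumor_only Correlate across tumor samples only (default) or all
#'   shared samples.
#' @return A `driver_gene_set` whose evidence records `delta_beta`,
#'   `direction`, `r`, `p`, `adjusted_p` per gene.
#' @export
methylation_driven <- function(dm, expr, meth, fdr_thresh = 0.05,
                               corr_p_thresh = 0.05, tumor_only = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(meth, "methylation_matrix"))
  cand <- dm[dm$fdr < fdr_thresh, , drop = FALSE]
  shared <- intersect(colnames(expr$values), colnames(meth$beta))
  if (tumor_only) shared <- shared[expr$group[shared] == "tumor"]
  keep <- cand$gene %in% rownames(expr$values) &
    cand$gene %in% rownames(meth$beta)
  if (any(!keep)) {
    warning(sum(!keep), " differentially methylated gene(s) missing from a ",
            "matrix were skipped", call. = FALSE)
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    return(new_driver_gene_set("methylation", character(),
                               data.frame(gene = character(), delta_beta = numeric(),
                                          direction = character(), r = numeric(),
                                          p = numeric(), adjusted_p = numeric(),
                                          stringsAsFactors = FALSE)))
  }
  res <- vapply(cand$gene, function(g) {
    ct <- stats::cor.test(expr$values[g, shared], meth$beta[g, shared],
                          method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  }, numeric(2))
  ev <- data.frame(
    gene = cand$gene,
    delta_beta = cand$delta_beta,
    direction = cand$direction,
    r = res["r", ], p = res["p", ],
    adjusted_p = benjamini_hochberg(res["p", ]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  hit <- ev$r < 0 & ev$adjusted_p < corr_p_thresh
  new_driver_gene_set("methylation", ev$gene[hit], ev[hit, , drop = FALSE])
}

#' CNA-driven genes: differentially expressed genes in altered regions
#'
#' Default rule is the plain intersection of the amplified/deleted region gene
#' lists with the up/down DEG sets; with `require_concordance = TRUE` only
#' amplified-and-up plus deleted-and-down genes are kept.
#'
#' @param cna A [cna_calls()] object.
#' @param up_genes,down_genes DEG sets from [select_degs()].
#' @param require_concordance Logical flag (default `FALSE`).
#' @return A `driver_gene_set` with `region` and `direction` evidence.
#' @export
cna_driven <- function(cna, up_genes, down_genes, require_concordance = FALSE) {
  stopifnot(inherits(cna, "cna_calls"))
  degs <- c(up_genes, down_genes)
  region <- c(stats::setNames(rep("amp", length(cna$amp_genes)), cna$amp_genes),
              stats::setNames(rep("del", length(cna$del_genes)), cna$del_genes))
  hits <- intersect(names(region), degs)
  if (require_concordance) {
    hits <- c(intersect(cna$amp_genes, up_genes),
              intersect(cna$del_genes, down_genes))
  }
  hits <- sort(hits)
  ev <- data.frame(
    gene = hits,
    region = unname(region[hits]),
    direction = ifelse(hits %in% up_genes, "up", "down"),
    stringsAsFactors = FALSE
  )
  new_driver_gene_set("cna", hits, ev)
}

#' Mutation-driven genes: recurrently non-silently mutated DEGs
#'
#' A gene counts as mutated when it carries non-silent records in at least
#' `min_samples` distinct tumor samples; the driver set is the intersection
#' with the DEG sets.
#'
#' @param mut A [mutation_table()].
#' @param up_genes,down_genes DEG sets from [select_degs()].
#' @param min_samples Minimum number of distinct non-silently mutated samples
#'   (default 1).
#' @return A `driver_gene_set` with `n_mutated_samples` and `direction`
#'   evidence.
#' @export
mutation_driven <- function(mut, up_genes, down_genes, min_samples = 1L) {
  stopifnot(inherits(mut, "mutation_table"))
  ns <- mut[mut$variant_class == "nonsilent", , drop = FALSE]
  counts <- if (nrow(ns)) {
    tapply(ns$sample, ns$gene, function(s) length(unique(s)))
  } else {
    integer(0)
  }
  mutated <- names(counts)[counts >= min_samples]
  hits <- sort(intersect(mutated, c(up_genes, down_genes)))
  ev <- data.frame(
    gene = hits,
    n_mutated_samples = as.integer(counts[hits]),
    direction = ifelse(hits %in% up_genes, "up", "down"),
    stringsAsFactors = FALSE
  )
  new_driver_gene_set("mutation", hits, ev)
}

#' Hypergeometric overlap significance of two gene sets
#'
#' Inclusive upper-tail hypergeometric test: with a universe of size `N`,
#' `|A|` successes, `|B|` draws and observed overlap `k`, returns
#' `P(X >= k)`.
#'
#' @param setA,setB Character vectors of genes (subsets of the universe).
#' @param universe_size Number of genes in the universe.
#' @return List with `overlap` (k) and `p`.
#' @export
overlap_significance <- function(setA, setB, universe_size) {
  a <- unique(setA)
  b <- unique(setB)
  if (length(a) > universe_size || length(b) > universe_size) {
    stop("universe smaller than one of the sets", call. = FALSE)
  }
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(a), universe_size - length(a), length(b),
                     lower.tail = FALSE)
  list(overlap = k, p = p)
}
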