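# Differential analysis, the three driver filters, overlap significance and
# the BH adjustment.

test_that("moderated t matches an independent evaluation of the shrinkage formula", {
  # heterogeneous true variances so the prior degrees of freedom are finite
  set.seed(13)
  samples <- c(sprintf("T%02d", 1:8), sprintf("N%02d", 1:8))
  sds <- sqrt(1 / rgamma(200, shape = 3, rate = 3))
  m <- matrix(rnorm(200 * 16, 6, rep(sds, 16)), 200, 16,
              dimnames = list(sprintf("g%03d", 1:200), samples))
  grp <- setNames(rep(c("tumor", "normal"), each = 8), samples)
  em <- expression_matrix(m, grp)
  res <- moderated_t_test(em)
  expect_true(is.finite(attr(res, "df_prior")))
  x <- em$values
  tum <- names(em$group)[em$group == "tumor"]
  nor <- names(em$group)[em$group == "normal"]
  n1 <- length(tum); n2 <- length(nor); d <- n1 + n2 - 2
  m1 <- rowMeans(x[, tum]); m2 <- rowMeans(x[, nor])
  s2 <- (rowSums((x[, tum] - m1)^2) + rowSums((x[, nor] - m2)^2)) / d
  d0 <- attr(res, "df_prior"); s0 <- attr(res, "var_prior")
  s2post <- (d0 * s0 + d * s2) / (d0 + d)
  t_oracle <- (m1 - m2) / sqrt(s2post * (1 / n1 + 1 / n2))
  expect_equal(res$t, unname(t_oracle), tolerance = 1e-12)
  expect_equal(res$p, unname(2 * pt(-abs(t_oracle), df = d0 + d)),
               tolerance = 1e-12)
  # prior is a genuine moment-matched fit: trigamma inversion is consistent
  z <- log(s2)
  expect_equal(trigamma(d0 / 2), var(z) - trigamma(d / 2), tolerance = 1e-6)
})

test_that("moderated t agrees with the limma empirical-Bayes pipeline", {
  em <- make_expr(n_genes = 150, n_tumor = 6, n_normal = 6, seed = 17)
  res <- moderated_t_test(em)
  design <- cbind(1, as.integer(em$group == "tumor"))
  fit <- limma::eBayes(limma::lmFit(em$values, design))
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(attr(res, "df_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(res$fdr,
               unname(p.adjust(fit$p.value[, 2], "BH")), tolerance = 1e-10)
})

test_that("null effects and degenerate variances are handled", {
  em <- make_expr(n_genes = 40, n_tumor = 6, n_normal = 6, seed = 5)
  # identical group means for one gene -> t = 0, p = 1
  em$values["g001", ] <- rep(c(1, 2, 3, 1, 2, 3), 2)
  res <- moderated_t_test(em)
  expect_equal(res$t[res$gene == "g001"], 0)
  expect_equal(res$p[res$gene == "g001"], 1)
})

test_that("equal sample variances drive the prior df to infinity (z-form limit)", {
  # every gene shares the same residuals -> var(log s^2) = 0 -> d0 = Inf
  base <- rnorm(12)
  m <- t(sapply(1:30, function(i) base + i))
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12))
  grp <- setNames(rep(c("tumor", "normal"), each = 6), colnames(m))
  em <- expression_matrix(m, grp)
  res <- moderated_t_test(em)
  expect_identical(attr(res, "df_prior"), Inf)
  s0 <- attr(res, "var_prior")
  z_form <- res$log2fc / (sqrt(s0) * sqrt(1 / 6 + 1 / 6))
  expect_equal(res$t, z_form, tolerance = 1e-10)
})

test_that("DEG selection applies the FDR and two-sided fold-change rule", {
  stats <- data.frame(gene = c("a", "b", "c", "d"),
                      log2fc = c(3, -1.5, 0.5, 2),
                      fdr = c(0.06, 0.01, 0.001, 0.04))
  sel <- select_degs(stats)
  expect_false("a" %in% c(sel$up, sel$down))  # fails FDR despite huge fold
  expect_true("b" %in% sel$down)              # FC < 1/2 counts as down
  expect_false("c" %in% c(sel$up, sel$down))  # effect too small
  expect_true("d" %in% sel$up)
  # threshold degeneracy: fc_thresh = 1 keeps every FDR-passing gene
  sel1 <- select_degs(stats, fc_thresh = 1)
  expect_setequal(c(sel1$up, sel1$down), c("b", "c", "d"))
})

test_that("differential methylation Welch test behaves at the extremes", {
  beta <- matrix(0.4, 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  grp <- setNames(rep(c("tumor", "normal"), each = 5), colnames(beta))
  set.seed(1)
  beta[2, ] <- c(rep(0.8, 5), rep(0.2, 5))           # constant but different
  beta[3, ] <- 0.4 + rnorm(10, 0, 0.01)              # pure noise
  dm <- diff_methylation(methylation_matrix(beta, grp))
  expect_equal(dm$p[1], 1)          # identical betas
  expect_equal(dm$p[2], 0)          # perfect separation
  expect_gt(dm$p[3], 0.01)
  expect_equal(dm$direction[2], "hyper")
})

test_that("planted methylation shifts are recovered with near-complete power", {
  set.seed(21)
  n_t <- 60; n_n <- 30
  samples <- c(sprintf("T%02d", 1:n_t), sprintf("N%02d", 1:n_n))
  beta <- matrix(runif(200, 0.2, 0.5), 200, n_t + n_n,
                 dimnames = list(sprintf("g%03d", 1:200), samples)) +
    matrix(rnorm(200 * (n_t + n_n), 0, 0.05), 200)
  planted <- sprintf("g%03d", 1:10)
  beta[planted, 1:n_t] <- beta[planted, 1:n_t] + 0.3
  beta <- pmin(pmax(beta, 1e-4), 1 - 1e-4)
  grp <- setNames(rep(c("tumor", "normal"), c(n_t, n_n)), samples)
  dm <- diff_methylation(methylation_matrix(beta, grp))
  hyper <- dm$gene[dm$fdr < 0.05 & dm$direction == "hyper"]
  expect_true(all(planted %in% hyper))
})

test_that("methylation-driven genes require a negative expression correlation", {
  sim <- generate_cohort(small_cohort_config(seed = 31L))
  expr <- sim$cohort$expr
  meth <- sim$cohort$meth
  # plant a perfect inverse coupling and a strong positive one
  set.seed(77)
  m2 <- rbind(expr$values,
              neg = 10 - 2 * meth$beta[1, ] + rnorm(ncol(expr$values), 0, 1e-3),
              pos = 2 + 2 * meth$beta[2, ] + rnorm(ncol(expr$values), 0, 1e-3))
  b2 <- rbind(meth$beta, neg = meth$beta[1, ], pos = meth$beta[2, ])
  # make both differentially methylated by fiat
  dm <- data.frame(gene = c("neg", "pos"), delta_beta = c(0.3, 0.3),
                   direction = "hyper", fdr = c(0.001, 0.001))
  ds <- methylation_driven(dm,
                           expression_matrix(m2, expr$group),
                           methylation_matrix(b2, meth$group))
  expect_true("neg" %in% ds$genes)
  expect_false("pos" %in% ds$genes)   # excluded despite tiny p: r > 0
  ev <- ds$evidence
  expect_lt(ev$r[ev$gene == "neg"], -0.95)
})

test_that("CNA-driven rule honors region membership and the concordance flag", {
  call <- matrix(0L, 3, 2, dimnames = list(c("amp_up", "amp_down", "del_down"),
                                           c("t1", "t2")))
  cna <- cna_calls(call, amp_genes = c("amp_up", "amp_down"),
                   del_genes = "del_down")
  up <- "amp_up"; down <- c("amp_down", "del_down")
  loose <- cna_driven(cna, up, down)
  expect_setequal(loose$genes, c("amp_up", "amp_down", "del_down"))
  strict <- cna_driven(cna, up, down, require_concordance = TRUE)
  expect_setequal(strict$genes, c("amp_up", "del_down"))  # amp-and-down out
  none <- cna_driven(cna, character(), character())
  expect_length(none$genes, 0)
})

test_that("mutation-driven rule ignores silent records and applies recurrence", {
  mut <- mutation_table(data.frame(
    gene = c("s_only", "s_only", "rec", "rec", "rec", "once", "rec_not_de"),
    sample = c("t1", "t2", "t1", "t2", "t3", "t1", "t1"),
    variant_class = c("silent", "silent", "nonsilent", "nonsilent",
                      "nonsilent", "nonsilent", "nonsilent")
  ))
  up <- c("s_only", "rec", "once")
  ds <- mutation_driven(mut, up, character())
  expect_setequal(ds$genes, c("rec", "once"))
  expect_false("s_only" %in% ds$genes)
  expect_false("rec_not_de" %in% ds$genes)
  ds3 <- mutation_driven(mut, up, character(), min_samples = 3L)
  expect_identical(ds3$genes, "rec")
  expect_equal(ds3$evidence$n_mutated_samples, 3L)
})

test_that("hypergeometric overlap equals exhaustive draw enumeration", {
  # identical sets in a small universe: N = 10, |A| = |B| = k = 2 -> 1/45
  os <- overlap_significance(c("a", "b"), c("a", "b"),
                             universe_size = 10)
  expect_equal(os$p, 1 / 45, tolerance = 1e-12)
  # worked combinatorial sum: N = 20, |A| = 5, |B| = 6, k = 3
  A <- paste0("g", 1:5); B <- paste0("g", c(1:3, 18:20))
  os <- overlap_significance(A, B, 20)
  expect_equal(os$overlap, 3)
  expect_equal(os$p, 5090 / 38760, tolerance = 1e-12)
  # inclusive upper tail: k = 0 gives p = 1
  expect_equal(overlap_significance(paste0("a", 1:3), paste0("b", 1:3), 12)$p, 1)
  # spot enumeration checks
  for (case in list(c(9, 4, 3, 2), c(12, 6, 5, 3), c(7, 3, 3, 1))) {
    N <- case[1]; a <- case[2]; b <- case[3]; k <- case[4]
    A <- paste0("u", seq_len(a))
    B <- paste0("u", c(seq_len(k), seq(a + 1, length.out = b - k)))
    expect_equal(overlap_significance(A, B, N)$p,
                 hyper_enum_oracle(N, a, b, k), tolerance = 1e-12)
  }
  expect_error(overlap_significance(paste0("g", 1:5), "g1", 3), "universe")
})

test_that("BH adjustment matches hand step-up values and its invariants", {
  expect_equal(benjamini_hochberg(c(0.005, 0.04, 0.5)), c(0.015, 0.06, 0.5))
  expect_equal(benjamini_hochberg(rep(0.03, 4)), rep(0.03, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  p <- runif(100)
  adj <- benjamini_hochberg(p)
  # monotone along sorted p, permutation-equivariant
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  perm <- sample(100)
  expect_equal(benjamini_hochberg(p[perm]), adj[perm])
})
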