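# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive implementations, independent of the package
# code paths they check.

# A scaled-down cohort for fast unit tests (the acceptance tests use the
# package defaults).
small_cohort_config <- function(seed = 11L, ...) {
  cohort_config(n_genes = 300L, n_tumor = 60L, n_normal = 30L,
                n_meth_driven = 6L, n_cna_driven = 6L, n_mut_driven = 6L,
                n_drg = 9L, module_drg = 2L, module_filler = 4L,
                seed = seed, ...)
}

# Small gene universe but a default-sized patient cohort, for survival tests
# that need the planted pair's marginal effects at full power.
surv_cohort_config <- function(seed = 23L, ...) {
  cohort_config(n_genes = 300L, n_tumor = 100L, n_normal = 40L,
                n_meth_driven = 6L, n_cna_driven = 6L, n_mut_driven = 6L,
                n_drg = 9L, module_drg = 2L, module_filler = 4L,
                seed = seed, ...)
}

# Build a neighbor_ranking by hand (already weight-sorted or not; the AUC is
# order-independent).
make_ranking <- function(neighbors, weights, center = "center") {
  ord <- order(-weights, neighbors)
  structure(data.frame(neighbor = neighbors[ord], weight = weights[ord],
                       stringsAsFactors = FALSE),
            class = c("neighbor_ranking", "data.frame"), center = center)
}

# Small expression fixture: genes x samples Gaussian matrix with group labels.
make_expr <- function(n_genes = 50, n_tumor = 8, n_normal = 8, seed = 1,
                      sd = 1, shift = NULL) {
  set.seed(seed)
  samples <- c(sprintf("T%02d", seq_len(n_tumor)),
               sprintf("N%02d", seq_len(n_normal)))
  m <- matrix(rnorm(n_genes * length(samples), 6, sd),
              n_genes, length(samples),
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
  if (!is.null(shift)) {
    m[names(shift), seq_len(n_tumor)] <-
      m[names(shift), seq_len(n_tumor)] + rep(shift, each = n_tumor)
  }
  grp <- stats::setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                         samples)
  expression_matrix(m, grp)
}

# Naive Breslow-ties log partial likelihood (single covariate), evaluated by
# explicit risk-set loops; the grid maximizer is the Cox oracle.
breslow_loglik_1d <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

grid_cox_1d <- function(x, time, event, lo = -5, hi = 5, step = 1e-3) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, breslow_loglik_1d, numeric(1),
               x = x, time = time, event = event)
  grid[which.max(ll)]
}

# Exhaustive-draw hypergeometric upper tail: enumerate every size-b draw from
# a universe 1..N with A = {1..a}; P(X >= k) is the fraction of draws with at
# least k elements inside A.
hyper_enum_oracle <- function(N, a, b, k) {
  draws <- utils::combn(N, b)
  overlap <- colSums(draws <= a)
  mean(overlap >= k)
}

# Simulate exponential proportional-hazards data with a given coefficient on
# a standard-normal covariate, with exponential censoring.
sim_ph <- function(n, beta, censor_rate = 0.25 * 0.01, base_rate = 0.01) {
  x <- rnorm(n)
  t_event <- rexp(n, rate = base_rate * exp(beta * x))
  t_cens <- rexp(n, rate = censor_rate)
  list(x = x, time = pmax(pmin(t_event, t_cens), 1e-6),
       event = as.integer(t_event <= t_cens))
}
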