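# Prognostic evaluation of candidate driver-DRG pairs:
# univariate Cox screening on standardized expression, a two-gene Cox risk
# score dichotomized at its median, Kaplan-Meier / log-rank comparison of the
# risk groups, covariate-adjusted Cox (age, ER, PR, stage), BH FDR over the
# evaluated pairs, and IPCW time-dependent ROC at fixed horizons.

#' Cox proportional-hazards fit (Breslow ties, Newton-Raphson)
#'
#' Maximizes the Breslow-ties log partial likelihood by Newton-Raphson with
#' step-halving; convergence when the score's max-norm drops below `tol`.
#' Standard errors come from the inverse observed information; Wald z and
#' two-sided p per coefficient.  Monotone likelihood (separation) is reported
#' through `converged = FALSE` with a diagnostic rather than an error; a
#' singular information matrix is an error.
#'
#' @param x Covariate matrix (or vector), one row per subject.
#' @param time Follow-up times (> 0).
#' @param event Event indicators in `{0, 1}`; at least one event required.
#' @param tol Convergence tolerance on the score max-norm (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return Object of class `cox_fit`: `coef`, `se`, `z`, `p`, `hr`,
#'   `ci_lower`, `ci_upper` (95% Wald), `loglik`, `iter`, `converged`,
#'   `diagnostic`.
#' @export
fit_cox <- function(x, time, event, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  stopifnot(length(time) == n, length(event) == n)
  if (!all(is.finite(x)) || !all(is.finite(time)) || any(time <= 0)) {
    stop("covariates must be finite and times positive", call. = FALSE)
  }
  if (!all(event %in% c(0, 1)) || sum(event) < 1) {
    stop("need binary event indicators with at least one event", call. = FALSE)
  }
  if (any(apply(x, 2L, function(col) length(unique(col)) == 1L))) {
    stop("constant covariate in design", call. = FALSE)
  }
  ord <- order(time)
  x <- x[ord, , drop = FALSE]
  time <- time[ord]
  event <- as.integer(event[ord])
  p <- ncol(x)
  ev <- which(event == 1L)
  first_at_time <- match(time, time)   # first index of each tied time block
  fe <- first_at_time[ev]

  pair_idx <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  xx <- x[, pair_idx[, 1L], drop = FALSE] * x[, pair_idx[, 2L], drop = FALSE]

  breslow <- function(beta) {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    s0 <- rev(cumsum(rev(w)))
    s1 <- rev_cumsum_matrix(x * w)
    s2 <- rev_cumsum_matrix(xx * w)
    s0e <- s0[fe]
    s1e <- s1[fe, , drop = FALSE] / s0e
    ll <- sum(eta[ev]) - sum(log(s0e))
    score <- colSums(x[ev, , drop = FALSE]) - colSums(s1e)
    info <- matrix(0, p, p)
    s2e <- colSums(s2[fe, , drop = FALSE] / s0e)
    cross <- crossprod(s1e)
    for (r in seq_len(nrow(pair_idx))) {
      a <- pair_idx[r, 1L]; b <- pair_idx[r, 2L]
      info[a, b] <- info[b, a] <- s2e[r] - cross[a, b]
    }
    list(ll = ll, score = score, info = info)
  }

  beta <- rep(0, p)
  cur <- breslow(beta)
  converged <- FALSE
  diagnostic <- ""
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$score), error = function(e) NULL)
    if (is.null(step)) stop("singular information matrix", call. = FALSE)
    new_beta <- beta + step
    new <- breslow(new_beta)
    halvings <- 0L
    while ((!is.finite(new$ll) || new$ll < cur$ll - 1e-12) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new <- breslow(new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    cur <- new
    if (max(abs(cur$score)) < tol) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 25) {
      diagnostic <- "coefficient diverging; likely monotone likelihood (separation)"
      break
    }
  }
  if (!converged && nchar(diagnostic) == 0L) {
    diagnostic <- sprintf("score norm %.3g after %d iterations",
                          max(abs(cur$score)), iter)
  }
  if (converged && max(abs(beta)) > 15) {
    # a saturated score can pass the tolerance numerically even though the
    # likelihood is monotone; such coefficients are not interpretable
    converged <- FALSE
    diagnostic <- "coefficient diverging; likely monotone likelihood (separation)"
  }
  vcov <- tryCatch(solve(cur$info), error = function(e) NULL)
  if (is.null(vcov)) stop("singular information matrix", call. = FALSE)
  se <- sqrt(pmax(diag(vcov), 0))
  z <- ifelse(se > 0, beta / se, NA_real_)
  nm <- colnames(x)
  structure(list(
    coef = stats::setNames(beta, nm),
    se = stats::setNames(se, nm),
    z = stats::setNames(z, nm),
    p = stats::setNames(2 * stats::pnorm(-abs(z)), nm),
    hr = stats::setNames(exp(beta), nm),
    ci_lower = stats::setNames(exp(beta - 1.96 * se), nm),
    ci_upper = stats::setNames(exp(beta + 1.96 * se), nm),
    loglik = cur$ll, iter = iter,
    converged = converged, diagnostic = diagnostic,
    vcov = vcov
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit>", if (x$converged) "converged" else
    paste("NOT converged:", x$diagnostic), "\n")
  print(data.frame(coef = x$coef, se = x$se, z = x$z, p = x$p, HR = x$hr,
                   lower95 = x$ci_lower, upper95 = x$ci_upper))
  invisible(x)
}

# Standardize expression of given genes across the clinical (tumor) samples.
standardized_expression <- function(expr, clinical, genes) {
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing)) {
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- t(expr$values[genes, clinical$sample, drop = FALSE])
  scale(m)
}

#' Univariate Cox screen on standardized expression
#'
#' Single-covariate Cox per gene (expression z-scored across the clinical
#' samples); genes with Wald `p < p_thresh` pass.  Non-converged genes are
#' excluded with a warning.
#'
#' @param expr An [expression_matrix()].
#' @param clinical A [clinical_table()] (its samples define the cohort).
#' @param genes Genes to screen.
#' @param p_thresh Screening threshold (default 0.1).
#' @return Character vector of passing genes, with the per-gene table as
#'   attribute `screen`.
#' @export
univariate_screen <- function(expr, clinical, genes, p_thresh = 0.1) {
  genes <- unique(genes)
  zx <- standardized_expression(expr, clinical, genes)
  res <- lapply(genes, function(g) {
    fit <- tryCatch(fit_cox(zx[, g, drop = FALSE], clinical$os_time,
                            clinical$os_event),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(data.frame(gene = g, coef = NA_real_, p = NA_real_,
                        converged = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(gene = g, coef = unname(fit$coef), p = unname(fit$p),
               converged = TRUE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  if (any(!tab$converged)) {
    warning(sum(!tab$converged), " gene(s) dropped from the screen ",
            "(non-converged Cox fit)", call. = FALSE)
  }
  out <- tab$gene[tab$converged & tab$p < p_thresh]
  attr(out, "screen") <- tab
  out
}

#' Two-gene Cox risk score with median dichotomization
#'
#' Fits a two-covariate Cox model on the pair's standardized expression, forms
#' `risk_i = beta1 * z1i + beta2 * z2i`, and splits at the median risk score;
#' samples exactly at the median go to the low-risk group (deterministic).
#'
#' @param expr An [expression_matrix()].
#' @param clinical A [clinical_table()].
#' @param pair Character vector of the two genes.
#' @return List of class `pair_risk`: `pair`, `fit` (the [fit_cox()] result),
#'   `beta`, `risk` (named by sample), `group` (high/low factor), `degenerate`
#'   flag (single-group split).
#' @export
pair_risk_score <- function(expr, clinical, pair) {
  stopifnot(length(pair) == 2L)
  zx <- standardized_expression(expr, clinical, pair)
  fit <- fit_cox(zx, clinical$os_time, clinical$os_event)
  if (!fit$converged) {
    stop("pair Cox fit did not converge: ", fit$diagnostic, call. = FALSE)
  }
  risk <- drop(zx %*% fit$coef)
  names(risk) <- clinical$sample
  med <- stats::median(risk)
  group <- factor(ifelse(risk > med, "high", "low"), levels = c("low", "high"))
  list_out <- list(pair = pair, fit = fit, beta = fit$coef, risk = risk,
                   group = group,
                   degenerate = length(unique(group)) < 2L)
  class(list_out) <- "pair_risk"
  list_out
}

#' Two-group log-rank test
#'
#' At each distinct event time, observed minus expected events in the first
#' group under the hypergeometric margins; the summed statistic is referred
#' to chi-square with 1 degree of freedom.
#'
#' @param time,event Survival times and event indicators.
#' @param group Two-level factor or vector.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2L) {
    stop("log-rank test needs exactly two nonempty groups", call. = FALSE)
  }
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  g1 <- group == levels(group)[1L]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    if ((n1 == 0L || n1 == n) && t == times[1L]) {
      stop("a group has zero at-risk subjects at the first event time",
           call. = FALSE)
    }
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chi2 <- if (v > 0) o_minus_e^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimate
#'
#' Events at tied times are processed before censorings (the usual
#' right-continuous convention).
#'
#' @param time,event Survival times and event indicators.
#' @return Object of class `km_curve`: data frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` at each distinct observed time.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  times <- sort(unique(time))
  n_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(times, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = times, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_curve", "data.frame"))
}

# Step-function evaluation of a KM curve: S(t) (right-continuous), with
# S(t) = 1 before the first observed time.
km_surv_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0L, 1, km$surv[pmax(idx, 1L)])
}

#' Covariate-adjusted Cox model of the risk group
#'
#' Cox regression of survival on the high-risk indicator plus the binary
#' clinical covariates (old age = 1, ER+ = 1, PR+ = 1, late stage = 1).
#' Samples with an unknown covariate value are excluded (complete case); a
#' covariate left with a single level is dropped with a warning.
#'
#' @param group Risk-group factor (levels low/high) named or ordered as
#'   `clinical$sample`.
#' @param clinical A [clinical_table()].
#' @return A [fit_cox()] result on the retained design, with attribute
#'   `n_used`.
#' @export
adjusted_cox <- function(group, clinical) {
  stopifnot(length(group) == nrow(clinical))
  design <- data.frame(
    risk_high = as.integer(group == "high"),
    age_old = ifelse(clinical$age_group == "old", 1L,
                     ifelse(clinical$age_group == "young", 0L, NA_integer_)),
    er_pos = ifelse(clinical$er == "pos", 1L,
                    ifelse(clinical$er == "neg", 0L, NA_integer_)),
    pr_pos = ifelse(clinical$pr == "pos", 1L,
                    ifelse(clinical$pr == "neg", 0L, NA_integer_)),
    stage_late = ifelse(clinical$stage == "late", 1L,
                        ifelse(clinical$stage == "early", 0L, NA_integer_))
  )
  all_unknown <- vapply(design, function(col) all(is.na(col)), logical(1))
  if (any(all_unknown)) {
    warning("covariate(s) dropped (all values unknown): ",
            paste(names(design)[all_unknown], collapse = ", "), call. = FALSE)
    design <- design[, !all_unknown, drop = FALSE]
  }
  keep <- stats::complete.cases(design)
  design <- design[keep, , drop = FALSE]
  constant <- vapply(design, function(col) length(unique(col)) == 1L, logical(1))
  if (any(constant)) {
    warning("constant covariate(s) dropped after complete-case filtering: ",
            paste(names(design)[constant], collapse = ", "), call. = FALSE)
    design <- design[, !constant, drop = FALSE]
  }
  fit <- fit_cox(as.matrix(design), clinical$os_time[keep],
                 clinical$os_event[keep])
  attr(fit, "n_used") <- sum(keep)
  fit
}

#' IPCW time-dependent ROC AUC (cumulative cases, dynamic controls)
#'
#' At horizon `t`, cases are subjects with an event by `t` and controls are
#' subjects still at risk beyond `t`.  Both are weighted by the inverse of
#' the Kaplan-Meier estimate of the censoring survival function (cases at
#' their own event time, controls at `t`), and the AUC is the tie-corrected
#' weighted Mann-Whitney statistic of the risk scores.
#'
#' @param score Risk scores (higher = worse prognosis).
#' @param time,event Survival data.
#' @param horizon Evaluation time `t`.
#' @return The AUC(t), or `NA_real_` when there are no cases or no controls
#'   by `t`.
#' @export
td_auc <- function(score, time, event, horizon) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon)
  if (length(cases) == 0L || length(controls) == 0L) return(NA_real_)
  # censoring distribution: KM with flipped indicator; at tied times the
  # death is processed first, so G(t-) is evaluated just before each time
  km_c <- km_estimate(time, 1 - event)
  g_at <- function(t) {
    s <- km_surv_at(km_c, t - 1e-9)
    pmax(s, 1e-12)
  }
  w_case <- 1 / g_at(time[cases])
  w_ctrl <- rep(1 / g_at(horizon), length(controls))
  sc <- score[cases]
  sx <- score[controls]
  cmp <- outer(sc, sx, function(a, b) (a > b) + 0.5 * (a == b))
  ww <- outer(w_case, w_ctrl)
  sum(cmp * ww) / sum(ww)
}

#' Evaluate candidate pairs as two-gene prognostic signatures
#'
#' For each candidate pair: univariate screen of both genes
#' (`p < p_screen`), two-gene risk score with median split, log-rank test of
#' the risk groups, covariate-adjusted Cox, and IPCW time-dependent AUC at
#' the given horizons.  BH FDR is computed across the adjusted multivariate
#' risk-group p-values of all evaluated pairs; pairs with `fdr < fdr_thresh`
#' are flagged as prognostic.  Per-pair failures (screen, degenerate split,
#' non-convergence) drop the pair with a recorded reason and never abort the
#' batch.
#'
#' @param candidates Data frame of pairs (columns `driver`, `drg`, optionally
#'   `category`, `score`), e.g. from [top_pairs()].
#' @param expr An [expression_matrix()].
#' @param clinical A [clinical_table()].
#' @param fdr_thresh Prognostic FDR threshold (default 0.05).
#' @param p_screen Univariate screening threshold (default 0.1).
#' @param horizons Time-dependent ROC horizons in the time unit of
#'   `clinical$os_time` (default 1, 3 and 5 years in days).
#' @param skip_screen Evaluate every pair regardless of the univariate screen.
#' @return Data frame with one row per evaluated pair: coefficients, log-rank
#'   chi-square and p, adjusted HR/CI/p for the risk group, `fdr`, `flagged`,
#'   and one `td_auc_<horizon>` column per horizon.  Dropped pairs are
#'   recorded in attribute `dropped` (pair plus reason).
#' @export
evaluate_pairs <- function(candidates, expr, clinical, fdr_thresh = 0.05,
                           p_screen = 0.1, horizons = c(365, 1095, 1825),
                           skip_screen = FALSE) {
  empty <- data.frame(driver = character(), drg = character(),
                      category = character(), stringsAsFactors = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  genes <- unique(c(candidates$driver, candidates$drg))
  passed <- if (skip_screen) genes
            else univariate_screen(expr, clinical, genes, p_thresh = p_screen)
  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(candidates))) {
    d <- candidates$driver[i]
    g <- candidates$drg[i]
    cat_i <- if ("category" %in% names(candidates)) candidates$category[i]
             else NA_character_
    if (!skip_screen && !(d %in% passed && g %in% passed)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        driver = d, drg = g, reason = "failed univariate screen",
        stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch({
      pr <- pair_risk_score(expr, clinical, c(d, g))
      if (pr$degenerate) stop("degenerate risk split (single group)")
      lr <- logrank_test(clinical$os_time, clinical$os_event, pr$group)
      ac <- adjusted_cox(pr$group, clinical)
      if (!ac$converged) stop("adjusted Cox did not converge: ", ac$diagnostic)
      aucs <- vapply(horizons, function(h) {
        td_auc(pr$risk, clinical$os_time, clinical$os_event, h)
      }, numeric(1))
      row <- data.frame(
        driver = d, drg = g, category = cat_i,
        beta_driver = unname(pr$beta[1L]), beta_drg = unname(pr$beta[2L]),
        n_high = sum(pr$group == "high"), n_low = sum(pr$group == "low"),
        logrank_chi2 = lr$chi2, logrank_p = lr$p,
        adj_hr = unname(ac$hr["risk_high"]),
        adj_ci_lower = unname(ac$ci_lower["risk_high"]),
        adj_ci_upper = unname(ac$ci_upper["risk_high"]),
        adj_p = unname(ac$p[names(ac$coef) == "risk_high"]),
        stringsAsFactors = FALSE
      )
      for (k in seq_along(horizons)) {
        row[[paste0("td_auc_", horizons[k])]] <- aucs[k]
      }
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        driver = d, drg = g, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) {
    out$fdr <- benjamini_hochberg(out$adj_p)
    out$flagged <- out$fdr < fdr_thresh
    rownames(out) <- NULL
  }
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(driver = character(), drg = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}
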