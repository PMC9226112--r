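# Cox fitting, risk scores, log-rank, Kaplan-Meier, adjusted models and the
# time-dependent AUC.

test_that("fit_cox matches the grid-search Breslow oracle on tiny datasets", {
  battery <- list(
    list(x = c(1, 0, 1, 0), time = c(1, 2, 3, 4), event = c(1, 1, 1, 1)),
    list(x = c(0.5, -0.2, 1.1, 0.3, -0.7), time = c(2, 1, 4, 3, 5),
         event = c(1, 0, 1, 1, 0)),
    list(x = c(1, 1, 0, 0, 1, 0), time = c(1, 1, 2, 2, 3, 4),  # ties
         event = c(1, 1, 1, 0, 1, 1)),
    list(x = c(-1, 2, 0.5, -0.5, 1.5, 0), time = c(3, 1, 2, 5, 4, 6),
         event = c(1, 1, 0, 1, 1, 1))
  )
  for (d in battery) {
    bhat <- grid_cox_1d(d$x, d$time, d$event)
    fit <- fit_cox(d$x, d$time, d$event)
    expect_true(fit$converged)
    expect_lt(abs(unname(fit$coef) - bhat), 2e-3)
  }
  # the four-subject worked example sits near 0.94
  fit <- fit_cox(c(1, 0, 1, 0), c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(unname(fit$coef), 0.9406, tolerance = 1e-3)
})

test_that("fit_cox agrees with survival::coxph under Breslow ties", {
  set.seed(14)
  n <- 80
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  time <- ceiling(rexp(n, 0.02))          # integer times force ties
  event <- rbinom(n, 1, 0.7)
  event[1] <- 1
  fit <- fit_cox(x, time, event)
  ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_true(all(fit$ci_lower < fit$hr & fit$hr < fit$ci_upper))
})

test_that("fit_cox recovers a null and a planted coefficient", {
  set.seed(30)
  d <- sim_ph(800, beta = 0)
  fit <- fit_cox(d$x, d$time, d$event)
  expect_lt(abs(unname(fit$coef)), 3 * unname(fit$se))
  d <- sim_ph(1000, beta = 0.7)
  fit <- fit_cox(d$x, d$time, d$event)
  expect_lt(abs(unname(fit$coef) - 0.7), 3 * unname(fit$se))
})

test_that("degenerate designs are rejected or diagnosed", {
  expect_error(fit_cox(rep(1, 4), c(1, 2, 3, 4), c(1, 1, 0, 1)), "constant")
  expect_error(fit_cox(c(1, 0, 1), c(1, 2, 3), c(0, 0, 0)), "event")
  # monotone likelihood: the covariate perfectly orders events first
  x <- c(5, 4, 3, -3, -4, -5)
  fit <- fit_cox(x, c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 1, 1, 1))
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation|score norm")
})

test_that("univariate screen keeps genes below the threshold and reports the table", {
  cfg <- surv_cohort_config()
  sim <- generate_cohort(cfg)
  genes <- c(sim$truth$surv_pair, sim$truth$mut_driven[1:3])
  passed <- univariate_screen(sim$cohort$expr, sim$cohort$clinical, genes)
  tab <- attr(passed, "screen")
  expect_setequal(passed, tab$gene[tab$converged & tab$p < 0.1])
  expect_true(all(sim$truth$surv_pair %in% passed))
  all_in <- univariate_screen(sim$cohort$expr, sim$cohort$clinical, genes,
                              p_thresh = 1)
  expect_setequal(all_in, genes)
})

test_that("pair risk scores split at the median with ties to low", {
  cfg <- surv_cohort_config()
  sim <- generate_cohort(cfg)
  pr <- pair_risk_score(sim$cohort$expr, sim$cohort$clinical,
                        sim$truth$surv_pair)
  expect_equal(length(pr$risk), nrow(sim$cohort$clinical))
  med <- median(pr$risk)
  expect_setequal(names(pr$risk)[pr$group == "high"],
                  names(pr$risk)[pr$risk > med])
  # even n, continuous scores -> equal halves; high group has more events
  expect_equal(sum(pr$group == "high"), sum(pr$group == "low"))
  ev <- tapply(sim$cohort$clinical$os_event, pr$group, mean)
  expect_gt(ev[["high"]], ev[["low"]])
})

test_that("risk groups and inference are invariant to expression shifts", {
  cfg <- surv_cohort_config(seed = 27L)
  sim <- generate_cohort(cfg)
  pair <- sim$truth$surv_pair
  base <- pair_risk_score(sim$cohort$expr, sim$cohort$clinical, pair)
  shifted <- sim$cohort$expr
  shifted$values[pair[1], ] <- shifted$values[pair[1], ] + 7
  alt <- pair_risk_score(shifted, sim$cohort$clinical, pair)
  expect_equal(alt$group, base$group)
  expect_equal(alt$beta, base$beta, tolerance = 1e-8)
  lr1 <- logrank_test(sim$cohort$clinical$os_time,
                      sim$cohort$clinical$os_event, base$group)
  lr2 <- logrank_test(sim$cohort$clinical$os_time,
                      sim$cohort$clinical$os_event, alt$group)
  expect_equal(lr1$chi2, lr2$chi2)
})

test_that("log-rank reproduces the worked example and survdiff", {
  lr <- logrank_test(c(1, 2, 3, 4, 5, 6), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr$chi2, 5.0517, tolerance = 1e-4)
  expect_equal(lr$p, 0.0246, tolerance = 1e-3)
  set.seed(3)
  time <- ceiling(rexp(50, 0.1)); event <- rbinom(50, 1, 0.8)
  event[1] <- 1
  grp <- rep(c("A", "B"), 25)
  lr <- logrank_test(time, event, grp)
  ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(lr$chi2, ref$chisq, tolerance = 1e-8)
  # identical groups give exactly zero
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("A", "B"), 3))
  expect_equal(lr0$chi2, 0)
  expect_error(logrank_test(1:4, c(1, 1, 1, 1), rep("A", 4)), "two")
})

test_that("Kaplan-Meier is the product-limit estimator", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0))
  expect_equal(km_estimate(c(1, 2, 3), c(0, 0, 0))$surv, c(1, 1, 1))
  # no censoring: equals the empirical survivor function
  set.seed(4)
  t <- sample(1:20, 30, replace = TRUE)
  km <- km_estimate(t, rep(1, 30))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 1e-12))
  # agrees with survival::survfit including censoring
  set.seed(5)
  t <- ceiling(rexp(40, 0.1)); e <- rbinom(40, 1, 0.6)
  km <- km_estimate(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_equal(km$surv[km$time %in% sf$time], sf$surv, tolerance = 1e-12)
})

test_that("adjusted Cox handles confounder-free data and collinearity", {
  set.seed(44)
  n <- 400
  risk <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.01 * exp(0.8 * risk))
  event <- rbinom(n, 1, 0.8)
  event[1] <- 1
  clin <- clinical_table(data.frame(
    sample = sprintf("t%03d", 1:n), os_time = pmax(time, 1e-3),
    os_event = event,
    age_group = sample(c("young", "old"), n, TRUE),
    er = sample(c("pos", "neg"), n, TRUE),
    pr = sample(c("pos", "neg"), n, TRUE),
    stage = sample(c("early", "late"), n, TRUE)
  ))
  group <- factor(ifelse(risk == 1, "high", "low"), c("low", "high"))
  adj <- adjusted_cox(group, clin)
  unadj <- fit_cox(matrix(risk, ncol = 1), clin$os_time, clin$os_event)
  expect_lt(abs(adj$coef[["risk_high"]] - unadj$coef[[1]]),
            3 * adj$se[["risk_high"]])
  # perfect collinearity with stage -> singular information
  clin2 <- clin
  clin2$stage <- ifelse(risk == 1, "late", "early")
  expect_error(adjusted_cox(group, clin2), "singular")
  # an all-unknown covariate is dropped with a warning
  clin3 <- clin
  clin3$er <- "unknown"
  expect_warning(adj3 <- adjusted_cox(group, clin3), "er_pos")
  expect_false("er_pos" %in% names(adj3$coef))
})

test_that("time-dependent AUC reduces to the plain AUC without censoring", {
  set.seed(55)
  n <- 120
  score <- rnorm(n)
  time <- rexp(n, 0.02 * exp(score))
  event <- rep(1, n)
  h <- median(time)
  a <- td_auc(score, time, event, h)
  cases <- time <= h
  plain <- mean(outer(score[cases], score[!cases],
                      function(p, q) (p > q) + 0.5 * (p == q)))
  expect_equal(a, plain, tolerance = 1e-12)
  # a perfect marker: score = -time separates cases from controls fully
  expect_equal(td_auc(-time, time, event, h), 1)
  expect_true(is.na(td_auc(score, time, event, min(time) - 1)))
})

test_that("time-dependent AUC is calibrated at one half for a useless marker", {
  set.seed(66)
  aucs <- replicate(150, {
    n <- 100
    time <- rexp(n, 0.02)
    cens <- rexp(n, 0.005)
    td_auc(rnorm(n), pmin(time, cens), as.integer(time <= cens),
           quantile(pmin(time, cens), 0.5))
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("evaluate_pairs flags the planted pair and tolerates failures", {
  expect_equal(nrow(evaluate_pairs(NULL, NULL, NULL)), 0)
  cfg <- surv_cohort_config()
  sim <- generate_cohort(cfg)
  truth <- sim$truth
  # planted pair among module pairs not involving the survival genes
  nulls <- truth$true_pairs[!(truth$true_pairs$driver %in% truth$surv_pair |
                                truth$true_pairs$drg %in% truth$surv_pair), ]
  cand <- rbind(
    data.frame(driver = truth$surv_pair[1], drg = truth$surv_pair[2],
               category = "methylation", stringsAsFactors = FALSE),
    nulls[1:20, c("driver", "drg", "category")]
  )
  res <- evaluate_pairs(cand, sim$cohort$expr, sim$cohort$clinical)
  hit <- res[res$driver == truth$surv_pair[1] &
               res$drg == truth$surv_pair[2], ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$flagged)
  expect_gt(hit$adj_hr, 1)
  flagged_nulls <- res$flagged & !(res$driver %in% truth$surv_pair |
                                     res$drg %in% truth$surv_pair)
  expect_lte(sum(flagged_nulls) / nrow(cand), 0.05)
  dropped <- attr(res, "dropped")
  expect_equal(nrow(res) + nrow(dropped), nrow(cand))
})
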