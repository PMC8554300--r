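test_that("OLS matches the hand-solved toy and stats::lm", {
  toy <- toy_regression()
  fit <- ols(toy$y, toy$X)
  expect_equal(fit$intercept, toy$expected[["intercept"]])
  expect_equal(fit$coef, unname(toy$expected[c("b1", "b2")]))
  # permuting rows leaves coefficients unchanged
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(ols(toy$y[perm], toy$X[perm, ])$coef, fit$coef)
  # exact interpolation with no noise
  x <- cbind(1:6, c(2, 1, 4, 3, 6, 5))
  y <- 2 + 0.5 * x[, 1] - 0.2 * x[, 2]
  f2 <- ols(y, x)
  expect_equal(f2$coef, c(0.5, -0.2))
  expect_equal(f2$sigma2, 0, tolerance = 1e-20)
  # SEs against the reference implementation
  set.seed(61)
  X <- matrix(rnorm(150), 50, 3)
  yy <- drop(X %*% c(1, -1, 0.5)) + rnorm(50)
  f3 <- ols(yy, X)
  lmf <- summary(lm(yy ~ X))
  expect_equal(f3$coef, unname(coef(lmf)[-1, 1]))
  expect_equal(f3$se, unname(coef(lmf)[-1, 2]))
  expect_error(ols(yy, cbind(X, X[, 1])), "rank deficient")
})

test_that("percent bias is signed relative error in percent", {
  expect_equal(percent_bias(0.35, 0.35), 0)
  expect_equal(percent_bias(0.9, 1.0), -10)
  expect_equal(percent_bias(0.315, 0.35), -10)
  expect_equal(percent_bias(c(0.33, 0.44), 0.4), c(-17.5, 10))
  expect_error(percent_bias(0.5, 0), "non-zero")
})

test_that("standardization rescales coefficients by the sd ratio", {
  fit <- list(coef = c(0.4, 0.3), se = c(0.05, 0.04))
  same <- standardized_fit(fit, c(1, 1), 1)
  expect_equal(same$coef, fit$coef)
  sc <- standardized_fit(fit, c(2, 0.5), 2)
  expect_equal(sc$coef, c(0.4, 0.075))
  expect_true(sc$standardized)
  expect_error(standardized_fit(fit, c(-1, 1), 1), "positive")
})

test_that("attenuation of the standardized-mean-score slope matches the errors-in-variables closed form", {
  # continuous (uncategorized) items, one big replication: the SMS slope
  # bias has the closed form 100 * (sqrt(rho) (1 - phi^2)/(1 - rho phi^2) - 1)
  # with rho the omega reliability of the analyzed items
  for (profile in c("high", "low")) {
    cond <- get_condition("stronger", 300, profile, 4)
    rho <- mcdonald_omega(loading_set(profile, 4))
    phi <- 0.30
    closed <- 100 * (sqrt(rho) * (1 - phi^2) / (1 - rho * phi^2) - 1)
    smp <- generate_sample(cond, seed = 62, n = 1e5,
                           categorize_items = FALSE)
    fit <- ols(smp$y1, cbind(sms(smp$items)$values, smp$covariate))
    bias <- percent_bias(fit$coef[1], 0.35)
    expect_equal(bias, closed, tolerance = 1.5)
  }
})

test_that("replication seeds are deterministic and distinct across conditions", {
  s1 <- scorebias:::rep_seed(1, 7, 3)
  expect_identical(s1, scorebias:::rep_seed(1, 7, 3))
  expect_false(s1 == scorebias:::rep_seed(1, 8, 3))
  expect_false(s1 == scorebias:::rep_seed(1, 7, 4))
  expect_false(s1 == scorebias:::rep_seed(2, 7, 3))
  # large base seeds must not overflow 32-bit integers
  expect_true(is.integer(scorebias:::rep_seed(2^20, 36, 500)))
})

test_that("run_condition produces the bias-summary layout with flag accounting", {
  cond <- get_condition("stronger", 300, "high", 4)
  cfg <- run_config(n_reps = 3, methods = c("SMS", "RFS", "SEM"),
                    base_seed = 5)
  res <- run_condition(cond, cfg)
  s <- res$summary
  expect_setequal(unique(s$method), c("SMS", "RFS", "SEM"))
  expect_setequal(unique(s$coefficient), c("skill", "covariate"))
  expect_true(all(s$n_reps + s$n_flagged == 3))
  expect_true(all(is.finite(s$mean_pct_bias)))
  # determinism: identical config -> identical summary
  res2 <- run_condition(cond, cfg)
  expect_identical(res$summary, res2$summary)
  # correlation matrix only reported when all five scores run
  expect_null(res$score_cor)
})

test_that("make_tables lays out per-condition methods in the conventional column order", {
  cond4 <- get_condition("stronger", 300, "high", 4)
  cfg <- run_config(n_reps = 2, methods = c("SMS", "SEM"), base_seed = 6,
                    conditions = cond4$condition_id)
  study <- run_study(cfg)
  tabs <- make_tables(study$summary)
  expect_named(tabs, c("skill", "covariate"))
  expect_equal(nrow(tabs$skill), 36)
  expect_equal(names(tabs$skill)[6:12],
               c("SMS", "EBM", "RFS", "WLE", "EAP", "PV", "SEM"))
  # unrun methods appear as explicit gaps; unrun conditions as NA rows
  ran <- tabs$skill$condition_id == cond4$condition_id
  expect_true(all(is.na(tabs$skill$WLE)))
  expect_true(all(is.finite(tabs$skill$SMS[ran])))
  # byte-identical rerun
  study2 <- run_study(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  make_tables(study$summary, d1, study$score_cor)
  make_tables(study2$summary, d2, study2$score_cor)
  f1 <- file.path(d1, "bias_skill.csv"); f2 <- file.path(d2, "bias_skill.csv")
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(d1, d2), recursive = TRUE)
})
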