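test_that("latent regression conditioning behaves under null and informative backgrounds", {
  cond <- get_condition("stronger", 1000, "high", 8)
  big <- generate_sample(cond, seed = 41, n = 20000)
  # null conditioning: background unrelated to theta
  set.seed(411)
  noise <- matrix(rnorm(2 * big$n), ncol = 2)
  lr0 <- fit_latent_regression(big$items, noise)
  expect_true(lr0$converged)
  expect_lt(max(abs(lr0$cond_slopes)), 0.03)
  expect_equal(lr0$residual_var, 1, tolerance = 0.05)
  # informative conditioning must reduce residual variance
  lr <- fit_latent_regression(big$items,
                              cbind(big$covariate, big$y1, big$y2))
  expect_true(lr$converged)
  expect_lt(lr$residual_var, 1)
  # EM ascent (small tolerance: the latent metric is re-standardized on a
  # fixed grid each iteration)
  expect_true(all(diff(lr$loglik_history) > -1e-4))
  expect_error(fit_latent_regression(big$items,
                                     cbind(big$covariate, big$covariate)),
               "rank deficient")
})

test_that("plausible-value draws are seed-stable with per-draw stream discipline", {
  cond <- get_condition("stronger", 300, "mixed", 4)
  smp <- generate_sample(cond, seed = 42)
  lr <- fit_latent_regression(smp$items,
                              cbind(smp$covariate, smp$y1, smp$y2))
  pv10 <- draw_pv(lr, 10, seed = 7)
  pv10b <- draw_pv(lr, 10, seed = 7)
  pv1 <- draw_pv(lr, 1, seed = 7)
  expect_identical(pv10, pv10b)
  expect_equal(dim(pv10), c(300L, 10L))
  expect_equal(pv1[, 1], pv10[, 1])
  expect_true(all(is.finite(pv10)))
})

test_that("the PV sampler reproduces a known discrete posterior", {
  # flat likelihood: hand the sampler a posterior that is exactly the
  # conditioning normal N(0.8, 0.3^2) discretized on the grid, and check
  # the draws' moments (node jitter adds h^2/12 = 0.0075 of variance)
  quad <- scorebias:::gpcm_quadrature()
  w <- dnorm(quad$nodes, 0.8, 0.3)
  model <- list(posterior = matrix(w / sum(w), 500, 41, byrow = TRUE),
                quadrature = quad)
  pv <- draw_pv(model, 10, seed = 8)
  expect_equal(mean(pv), 0.8, tolerance = 0.01)
  expect_equal(var(as.numeric(pv)), 0.3^2 + 0.3^2 / 12, tolerance = 0.01)
})

test_that("per-person PV spread matches the quadrature posterior and shrinks with information", {
  cond_lo <- get_condition("stronger", 1000, "low", 4)
  cond_hi <- get_condition("stronger", 1000, "high", 12)
  v <- numeric(2)
  for (i in 1:2) {
    cond <- list(cond_lo, cond_hi)[[i]]
    smp <- generate_sample(cond, seed = 43)
    lr <- fit_latent_regression(smp$items, cbind(smp$covariate, smp$y1, smp$y2))
    pv <- draw_pv(lr, 50, seed = 9)
    # posterior variance from the quadrature weights directly
    nodes <- lr$quadrature$nodes
    pm <- drop(lr$posterior %*% nodes)
    pv_var_direct <- drop(lr$posterior %*% nodes^2) - pm^2
    expect_equal(mean(apply(pv, 1, var)), mean(pv_var_direct) + 0.3^2 / 12,
                 tolerance = 0.02)
    v[i] <- mean(pv_var_direct)
  }
  expect_lt(v[2], v[1])  # more items, higher loadings -> tighter posterior
})

test_that("Rubin pooling matches hand-computed combining rules", {
  p <- pool_rubin(rbind(0.4, 0.6), rbind(0.01, 0.01))
  expect_equal(p$coef, 0.5)
  expect_equal(p$within_var, 0.01)
  expect_equal(p$between_var, 0.02)
  expect_equal(p$total_var, 0.01 + 1.5 * 0.02)
  # identical fits: B = 0, T = W
  p2 <- pool_rubin(matrix(0.3, 5, 2), matrix(0.02, 5, 2))
  expect_equal(p2$between_var, c(0, 0))
  expect_equal(p2$total_var, p2$within_var)
  # order invariance
  est <- cbind(c(0.2, 0.5, 0.9), c(1, 2, 3))
  se2 <- cbind(c(0.01, 0.02, 0.03), c(0.1, 0.1, 0.2))
  p3 <- pool_rubin(est, se2)
  p4 <- pool_rubin(est[c(3, 1, 2), ], se2[c(3, 1, 2), ])
  expect_equal(p3, p4)
  expect_error(pool_rubin(rbind(0.4), rbind(0.01)), "m >= 2")
})

test_that("pooled PV regression recovers the structural coefficient at scale", {
  cond <- get_condition("stronger", 1000, "high", 12)
  smp <- generate_sample(cond, seed = 44, n = 10000)
  lr <- fit_latent_regression(smp$items, cbind(smp$covariate, smp$y1, smp$y2))
  pv <- draw_pv(lr, 10, seed = 10)
  est <- se2 <- matrix(NA_real_, 10, 2)
  for (l in 1:10) {
    f <- ols(smp$y1, cbind(pv[, l], smp$covariate))
    est[l, ] <- f$coef
    se2[l, ] <- f$se^2
  }
  pooled <- pool_rubin(est, se2)
  expect_lt(abs(pooled$coef[1] - 0.35), 0.02)
  expect_lt(abs(pooled$coef[2] - 0.30), 0.02)
})
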