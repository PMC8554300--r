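test_that("GPCM category probabilities normalize, respect symmetry, and reduce to the 2-PL", {
  p <- gpcm_category_probs(1.3, c(-2, -0.5, 0.5, 2), seq(-4, 4, by = 0.5))
  expect_equal(rowSums(p), rep(1, nrow(p)))
  expect_true(all(p > 0 & p < 1))
  # symmetric steps at theta = 0: category distribution symmetric
  ps <- gpcm_category_probs(1, c(-1.5, -0.5, 0.5, 1.5), 0)
  expect_equal(as.numeric(ps), rev(as.numeric(ps)))
  # one step -> dichotomous item: P(category 2) = logistic(a(theta - b))
  th <- seq(-3, 3, by = 0.25)
  p2 <- gpcm_category_probs(1.7, -0.4, th)
  expect_equal(p2[, 2], plogis(1.7 * (th + 0.4)))
  expect_error(gpcm_category_probs(-1, 0, 0), "positive")
})

test_that("the GPCM EM ascends its marginal likelihood and respects pattern sufficiency", {
  cond <- get_condition("stronger", 300, "mixed", 4)
  smp <- generate_sample(cond, seed = 31)
  fit <- fit_gpcm(smp$items)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_history) > -1e-6))
  # duplicating every row: identical estimates, doubled loglik
  fit2 <- fit_gpcm(rbind(smp$items, smp$items))
  expect_equal(fit2$a, fit$a, tolerance = 1e-6)
  expect_equal(fit2$b[[1]], fit$b[[1]], tolerance = 1e-6)
  expect_equal(fit2$loglik, 2 * fit$loglik, tolerance = 1e-4)
})

test_that("estimated discriminations preserve the rank order of generating loadings", {
  cond <- get_condition("stronger", 300, "mixed", 4)  # distinct loadings .9 .7 .6 .4
  big <- generate_sample(cond, seed = 32, n = 1e5)
  fit <- fit_gpcm(big$items)
  expect_true(fit$converged)
  expect_equal(order(fit$a), order(c(0.9, 0.7, 0.6, 0.4)))
})

test_that("test information is nonnegative, vanishes without discrimination, and matches the 2-PL closed form", {
  toy <- toy_gpcm()
  th <- seq(-6, 6, length.out = 101)
  expect_true(all(test_information(toy$params, th) >= 0))
  # a -> 0 limit
  p0 <- toy$params
  p0$a <- rep(1e-6, 3)
  expect_lt(max(test_information(p0, th)), 1e-9)
  # single dichotomous item: information = a^2 P (1 - P)
  p1 <- list(a = 2.1, b = list(0.3))
  P <- plogis(2.1 * (th - 0.3))
  expect_equal(test_information(p1, th), 2.1^2 * P * (1 - P))
})

test_that("WLE, EAP and EBM match brute-force grid oracles on the toy fixture", {
  toy <- toy_gpcm()
  oracle <- grid_score_oracle(toy$params, toy$items)
  expect_equal(wle(toy$params, toy$items)$values, oracle$wle, tolerance = 2e-4)
  expect_equal(ebm(toy$params, toy$items)$values, oracle$ebm, tolerance = 2e-4)
  expect_equal(eap(toy$params, toy$items)$values, oracle$eap, tolerance = 2e-4)
  # symmetric-item fixture: all-middle pattern scores 0 for the symmetric
  # scorers (first toy item set is symmetric only for item 1; use a fully
  # symmetric toy instead)
  sym <- list(a = c(1, 1.5, 0.8),
              b = replicate(3, c(-1.5, -0.5, 0.5, 1.5), simplify = FALSE),
              ncat = rep(5L, 3), category_levels = replicate(3, 1:5, simplify = FALSE),
              latent_mean = 0, latent_var = 1,
              quadrature = scorebias:::gpcm_quadrature(), collapsed = FALSE)
  mid <- matrix(3L, 1, 3)
  expect_equal(wle(sym, mid)$values, 0, tolerance = 1e-6)
  expect_equal(ebm(sym, mid)$values, 0, tolerance = 1e-6)
  expect_equal(eap(sym, mid)$values, 0, tolerance = 1e-10)
})

test_that("scores are monotone in the response pattern and finite at the extremes", {
  toy <- toy_gpcm()
  pats <- rbind(rep(1L, 3), rep(3L, 3), rep(5L, 3))
  w <- wle(toy$params, pats)$values
  expect_true(all(diff(w) > 0))
  expect_true(all(is.finite(w)))
  e <- ebm(toy$params, pats)$values
  expect_true(all(diff(e) > 0))
})

test_that("EAP shrinks, EBM hugs EAP, and all five scores intercorrelate near unity", {
  cond <- get_condition("stronger", 1000, "high", 8)
  smp <- generate_sample(cond, seed = 33)
  gp <- fit_gpcm(smp$items)
  e <- eap(gp)$values
  w <- wle(gp)$values
  m <- ebm(gp)$values
  expect_lt(var(e), 1)        # posterior-mean shrinkage below prior variance
  expect_lt(var(e), var(w))   # EAP shrinks, WLE anti-shrinks
  expect_gt(cor(m, e), 0.99)
  cfa <- fit_cfa(smp$items)
  sc <- cbind(sms(smp$items)$values, m, rfs(cfa, smp$items)$values, w, e)
  expect_gt(min(cor(sc)), 0.97)
  # zero-discrimination items: posterior flat -> EAP at prior mean
  flat <- list(a = rep(1e-8, 3),
               b = replicate(3, c(-1, 0, 0.5, 1), simplify = FALSE),
               ncat = rep(5L, 3), category_levels = replicate(3, 1:5, simplify = FALSE),
               latent_mean = 0, latent_var = 1,
               quadrature = scorebias:::gpcm_quadrature(), collapsed = FALSE)
  pats <- rbind(c(1L, 5L, 2L), c(5L, 5L, 5L))
  expect_equal(eap(flat, pats)$values, c(0, 0), tolerance = 1e-6)
  expect_equal(ebm(flat, pats)$values, c(0, 0), tolerance = 1e-4)
})

test_that("unobserved categories are collapsed and flagged rather than fatal", {
  cond <- get_condition("stronger", 300, "low", 4)
  smp <- generate_sample(cond, seed = 34)
  items <- smp$items
  items[items[, 2] == 5L, 2] <- 4L  # remove category 5 from item 2
  fit <- fit_gpcm(items)
  expect_true(fit$collapsed)
  expect_equal(fit$ncat[2], 4L)
  expect_length(fit$b[[2]], 3L)
  expect_true(fit$converged)
  expect_length(wle(fit)$values, 300L)
})

test_that("item parameters round-trip through the delimited export", {
  toy <- toy_gpcm()
  path <- tempfile(fileext = ".tsv")
  write_gpcm_params(toy$params, path)
  df <- read.delim(path)
  expect_equal(df$a, toy$a)
  expect_equal(as.numeric(df[2, c("b1", "b2", "b3", "b4")]), toy$b[[2]])
  unlink(path)
})
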