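#' Toy GPCM fixture with printed-in-code parameters
#'
#' Three 5-category items with discriminations (1.0, 1.5, 0.8) and
#' symmetric step parameters, plus a small deterministic response matrix.
#' Expected WLE/EAP/EBM values for any pattern can be recomputed by the
#' brute-force grid oracles below, so scoring code is checked against
#' enumeration rather than against itself.
#'
#' @return List with `a`, `b` (list of step vectors), `items` (8 x 3
#'   response patterns), and a `params` object usable by the scoring
#'   functions.
#' @export
toy_gpcm <- function() {
  a <- c(1.0, 1.5, 0.8)
  b <- list(c(-1.5, -0.5, 0.5, 1.5),
            c(-2.0, -1.0, 1.0, 2.0),
            c(-1.2, -0.4, 0.4, 1.2))
  items <- rbind(
    c(3, 3, 3), c(1, 1, 1), c(5, 5, 5), c(2, 3, 4),
    c(4, 4, 4), c(1, 3, 5), c(2, 2, 2), c(5, 4, 3)
  )
  storage.mode(items) <- "integer"
  params <- structure(list(
    a = a, b = b, ncat = rep(5L, 3), category_levels = replicate(3, 1:5, simplify = FALSE),
    items = items, latent_mean = 0, latent_var = 1,
    quadrature = gpcm_quadrature(), collapsed = FALSE, converged = TRUE
  ), class = "gpcm_fit")
  list(a = a, b = b, items = items, params = params)
}

#' Brute-force grid oracles for person scoring
#'
#' Enumerate the weighted likelihood (WLE), the posterior mean (EAP, via
#' trapezoid-free Riemann sum with normal prior weights) and the posterior
#' mode (EBM) for each response pattern on a fine theta grid. Resolution
#' defaults to 1e-4 on `[-6, 6]`, an order of magnitude finer than any
#' assertion tolerance. Independent of the production scoring path: only
#' [gpcm_category_probs()] is shared, itself checked against a logistic
#' closed form elsewhere.
#'
#' @param params A GPCM parameter object (e.g. `toy_gpcm()$params`).
#' @param items Response matrix to score.
#' @param resolution Grid step.
#' @return Data.frame with columns `wle`, `eap`, `ebm`, one row per
#'   pattern.
#' @export
grid_score_oracle <- function(params, items, resolution = 1e-4) {
  grid <- seq(-6, 6, by = resolution)
  n <- nrow(items)
  out <- data.frame(wle = numeric(n), eap = numeric(n), ebm = numeric(n))
  info <- test_information(params, grid)
  lprior <- stats::dnorm(grid, params$latent_mean, sqrt(params$latent_var),
                         log = TRUE)
  for (i in seq_len(n)) {
    ll <- numeric(length(grid))
    for (j in seq_along(params$a)) {
      p <- gpcm_category_probs(params$a[j], params$b[[j]], grid)
      ll <- ll + log(p[, items[i, j]])
    }
    out$wle[i] <- grid[which.max(ll + 0.5 * log(info))]
    lpost <- ll + lprior
    w <- exp(lpost - max(lpost))
    out$eap[i] <- sum(grid * w) / sum(w)
    out$ebm[i] <- grid[which.max(lpost)]
  }
  out
}

#' Toy regression fixture with hand-solvable normal equations
#'
#' Five observations and two predictors chosen so the 3 x 3 normal
#' equations solve by hand; `expected` holds the hand-derived
#' coefficients.
#'
#' @return List with `y`, `X` (5 x 2), and `expected` coefficients
#'   `(intercept, b1, b2)`.
#' @export
toy_regression <- function() {
  # X columns centered and orthogonal: X'X diagonal, so the slopes are
  # b_j = (x_j'y)/(x_j'x_j) and the intercept is mean(y).
  x1 <- c(-2, -1, 0, 1, 2)
  x2 <- c(1, -1, 0, -1, 1)  # sum 0, orthogonal to x1
  y <- c(1, 2, 3, 4, 10)
  # by hand: x1'y = -2 -2 + 0 + 4 + 20 = 20, x1'x1 = 10  -> b1 = 2
  #          x2'y =  1 -2 + 0 - 4 + 10 =  5, x2'x2 = 4   -> b2 = 1.25
  #          intercept = mean(y) = 4
  list(y = y, X = cbind(x1 = x1, x2 = x2),
       expected = c(intercept = 4, b1 = 2, b2 = 1.25))
}
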