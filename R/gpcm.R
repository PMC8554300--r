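#' @useDynLib scorebias, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 41 equally spaced quadrature nodes on [-6, 6] with standard-normal
# density weights renormalized to sum 1 (rectangular quadrature).
gpcm_quadrature <- function(n_nodes = 41L, range = c(-6, 6)) {
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  w <- stats::dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

#' GPCM category probabilities
#'
#' Probability of each of the `C` ordered categories of one generalized
#' partial credit item at ability `theta`:
#' `P(c) = exp(sum_{t<=c-1} a (theta - b_t)) / sum_c' exp(...)`, with the
#' empty sum equal to 0. Evaluated with log-sum-exp stabilization.
#'
#' @param a Item discrimination, `a > 0`.
#' @param b Numeric vector of `C - 1` step parameters.
#' @param theta Ability value(s).
#' @return A `length(theta) x C` matrix of probabilities (rows sum to 1).
#' @examples
#' gpcm_category_probs(1, c(-1.5, -0.5, 0.5, 1.5), 0)
#' @export
gpcm_category_probs <- function(a, b, theta) {
  if (a <= 0) stop("discrimination `a` must be positive")
  C <- length(b) + 1L
  bcum <- c(0, cumsum(b))
  eta <- a * (outer(theta, 0:(C - 1)) - rep(bcum, each = length(theta)))
  mx <- eta[, 1]
  for (cc in 2:C) mx <- pmax(mx, eta[, cc])
  p <- exp(eta - mx)
  p / rowSums(p)
}

#' Fit a generalized partial credit model by marginal maximum likelihood
#'
#' EM with 41-node rectangular Gaussian quadrature on `[-6, 6]` and a
#' standard-normal latent distribution. Convergence: maximum absolute
#' parameter change below `tol` (default 1e-4) or 500 iterations. A
#' category never observed in the sample is collapsed into its lower
#' neighbour for estimation and the fit is flagged (`collapsed`), so
#' sparse replications are scored rather than dropped.
#'
#' @param items n x k matrix of ordinal responses in 1..5.
#' @param max_iter EM iteration cap.
#' @param tol Convergence tolerance on parameter change.
#' @return An object of class `gpcm_fit`: list with `a` (discriminations),
#'   `b` (list of step-parameter vectors, on the possibly collapsed
#'   scale), `category_maps` (original category -> estimation category),
#'   `latent_mean` (0), `latent_var` (1), `quadrature`, `posterior`
#'   (n x Q node posteriors under the N(0,1) prior), `loglik`,
#'   `loglik_history`, `converged`, `collapsed`.
#' @export
fit_gpcm <- function(items, max_iter = 500L, tol = 1e-4) {
  items <- as.matrix(items)
  storage.mode(items) <- "integer"
  n <- nrow(items); k <- ncol(items)
  levels <- vector("list", k)
  x <- items
  ncat <- integer(k)
  for (j in seq_len(k)) {
    obs <- sort(unique(items[, j]))
    if (length(obs) < 2L) stop("item ", j, " shows fewer than 2 categories")
    levels[[j]] <- obs
    x[, j] <- match(items[, j], obs)
    ncat[j] <- length(obs)
  }
  quad <- gpcm_quadrature()
  maxC <- max(ncat)
  b0 <- matrix(0, k, maxC - 1L)
  for (j in seq_len(k)) {
    b0[j, seq_len(ncat[j] - 1L)] <-
      seq(-1.5, 1.5, length.out = ncat[j] - 1L)
  }
  fit <- gpcm_em_cpp(x, ncat, quad$nodes, quad$weights,
                     rep(1, k), b0, matrix(0, 1, 1), FALSE,
                     as.integer(max_iter), tol)
  b <- lapply(seq_len(k), function(j) fit$b[j, seq_len(ncat[j] - 1L)])
  structure(list(
    a = as.numeric(fit$a), b = b, ncat = ncat, category_levels = levels,
    items = x, latent_mean = 0, latent_var = 1, quadrature = quad,
    posterior = fit$posterior, loglik = fit$loglik,
    loglik_history = as.numeric(fit$loglik_history),
    iterations = fit$iterations, converged = fit$converged,
    collapsed = any(ncat < 5L)
  ), class = "gpcm_fit")
}

#' @export
print.gpcm_fit <- function(x, ...) {
  cat(sprintf("<gpcm_fit> %d items, loglik %.2f, %s in %d EM iterations%s\n",
              length(x$a), x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$iterations,
              if (x$collapsed) " (categories collapsed)" else ""))
  invisible(x)
}

# log-likelihood of each person's response pattern at a per-person theta
# (theta may be scalar or length-n); responses already on the collapsed
# scale stored in params$items
gpcm_person_loglik <- function(params, theta, items = params$items) {
  n <- nrow(items)
  theta <- rep_len(theta, n)
  ll <- numeric(n)
  for (j in seq_along(params$a)) {
    p <- gpcm_category_probs(params$a[j], params$b[[j]], theta)
    ll <- ll + log(p[cbind(seq_len(n), items[, j])])
  }
  ll
}

#' GPCM test information
#'
#' Sum over items of `a_j^2 * Var_c(s_c)` where the category scores
#' `s_c = 0..C-1` and the variance is over the category distribution at
#' `theta`. Strictly positive whenever some `a_j > 0`.
#'
#' @param params A [fit_gpcm()] object (or any list with `a`, `b`).
#' @param theta Ability value(s).
#' @return Numeric vector of information values, `length(theta)`.
#' @export
test_information <- function(params, theta) {
  info <- numeric(length(theta))
  for (j in seq_along(params$a)) {
    p <- gpcm_category_probs(params$a[j], params$b[[j]], theta)
    s <- 0:(ncol(p) - 1L)
    es <- drop(p %*% s)
    es2 <- drop(p %*% s^2)
    info <- info + params$a[j]^2 * (es2 - es^2)
  }
  info
}

# shared machinery for WLE/EBM: grid scan at the quadrature nodes to
# bracket the per-person maximizer, then golden-section refinement; both
# run in compiled code (gpcm_score_cpp)
score_by_argmax <- function(params, items, type, method) {
  storage.mode(items) <- "integer"
  k <- length(params$a)
  maxC <- max(params$ncat)
  bmat <- matrix(0, k, max(maxC - 1L, 1L))
  for (j in seq_len(k)) bmat[j, seq_len(params$ncat[j] - 1L)] <- params$b[[j]]
  vals <- gpcm_score_cpp(items, params$ncat, params$a, bmat,
                         params$quadrature$nodes, type,
                         params$latent_mean, params$latent_var)
  score_vector(method, vals)
}

#' Warm's weighted likelihood estimate (WLE)
#'
#' Per-person maximizer of `log L(x | theta) + 0.5 * log I(theta)` over
#' `[-6, 6]`, where `I` is the test information. The information weight
#' keeps the estimate finite for all-lowest and all-highest patterns.
#'
#' @param params A converged [fit_gpcm()] object.
#' @param items n x k ordinal matrix (defaults to the fitted responses).
#' @return A score vector object with `method = "WLE"`.
#' @export
wle <- function(params, items = NULL) {
  items <- gpcm_recode(params, items)
  score_by_argmax(params, items, type = 1L, method = "WLE")
}

#' Expected a posteriori (EAP) score
#'
#' Posterior mean of `theta` over the quadrature grid under the
#' `N(latent_mean, latent_var)` prior. Values lie strictly inside the node
#' range and shrink toward the prior mean.
#'
#' @inheritParams wle
#' @return A score vector object with `method = "EAP"`.
#' @export
eap <- function(params, items = NULL) {
  post <- if (is.null(items)) params$posterior else {
    gpcm_posterior(params, gpcm_recode(params, items))
  }
  score_vector("EAP", drop(post %*% params$quadrature$nodes))
}

#' Empirical Bayes modal (EBM / MAP) score
#'
#' Per-person posterior mode: continuous maximizer of
#' `log L(x | theta) + log g(theta)` on `[-6, 6]` with the same normal
#' prior as [eap()].
#'
#' @inheritParams wle
#' @return A score vector object with `method = "EBM"`.
#' @export
ebm <- function(params, items = NULL) {
  items <- gpcm_recode(params, items)
  score_by_argmax(params, items, type = 2L, method = "EBM")
}

# map raw 1..5 responses onto the (possibly collapsed) estimation scale;
# a category unseen at fit time joins its lower neighbour
gpcm_recode <- function(params, items) {
  if (is.null(items)) return(params$items)
  items <- as.matrix(items)
  storage.mode(items) <- "integer"
  if (!params$collapsed) return(items)
  out <- items
  for (j in seq_len(ncol(items))) {
    out[, j] <- pmax(findInterval(items[, j], params$category_levels[[j]]), 1L)
  }
  out
}

# node posteriors for arbitrary response matrix under the N(0,1) prior
gpcm_posterior <- function(params, items) {
  quad <- params$quadrature
  n <- nrow(items)
  llg <- matrix(vapply(seq_along(quad$nodes),
                       function(q) gpcm_person_loglik(params, quad$nodes[q], items),
                       numeric(n)),
                n, length(quad$nodes))
  w <- exp(sweep(llg, 1, apply(llg, 1, max)))
  w <- sweep(w, 2, quad$weights, `*`)
  sweep(w, 1, rowSums(w), `/`)
}

#' Export / import GPCM item parameters
#'
#' Writes the fitted discriminations and step parameters as a
#' tab-delimited table (`item, a, b1..b4`) so scoring is reproducible
#' without refitting.
#'
#' @param params A [fit_gpcm()] object.
#' @param path Output path.
#' @export
write_gpcm_params <- function(params, path) {
  k <- length(params$a)
  bmat <- matrix(NA_real_, k, 4)
  for (j in seq_len(k)) bmat[j, seq_along(params$b[[j]])] <- params$b[[j]]
  df <- data.frame(item = seq_len(k), a = params$a,
                   b1 = bmat[, 1], b2 = bmat[, 2], b3 = bmat[, 3], b4 = bmat[, 4])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
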