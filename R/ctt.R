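#' Standardized mean scores
#'
#' Per-person item mean, centered at the sample mean of the means and
#' divided by their sample (n-1) standard deviation.
#'
#' @param items n x k numeric matrix of item responses.
#' @return A score vector object: list with `method = "SMS"`, `values`,
#'   `standardized = TRUE`.
#' @export
sms <- function(items) {
  items <- as.matrix(items)
  if (nrow(items) < 2L) stop("need at least 2 respondents")
  m <- rowMeans(items)
  s <- stats::sd(m)
  if (s < .Machine$double.eps^0.5) {
    stop("degenerate sample: row means have zero variance")
  }
  score_vector("SMS", (m - mean(m)) / s, standardized = TRUE)
}

score_vector <- function(method, values, standardized = FALSE) {
  structure(list(method = method, values = as.numeric(values),
                 standardized = standardized),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> %s, n = %d, %s\n", x$method, length(x$values),
              if (x$standardized) "standardized" else "latent metric"))
  invisible(x)
}

#' One-factor confirmatory factor analysis by maximum likelihood
#'
#' Fits `X = Lambda xi + delta` with factor variance fixed at 1 by
#' minimizing the normal-theory discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - k` over loadings and
#' residual variances, with an analytic gradient. Ordinal responses are
#' treated as continuous, matching common practice for 5-category scales.
#' Residual variances are floored at 1e-4; hitting the floor (Heywood
#' case) flags the fit but does not raise.
#'
#' @param items n x k numeric matrix (k >= 3), or ignored when `S` given.
#' @param S Optional k x k sample covariance to fit directly.
#' @param n_obs Number of observations behind `S` (only used for loglik).
#' @return List with `loadings`, `residual_variances`, `factor_variance`
#'   (1), `implied_cov`, `discrepancy`, `loglik`, `converged`, `heywood`.
#' @export
fit_cfa <- function(items = NULL, S = NULL, n_obs = NULL) {
  if (is.null(S)) {
    items <- as.matrix(items)
    n_obs <- nrow(items)
    S <- stats::cov(items)
  }
  k <- ncol(S)
  if (k < 3L) stop("one-factor model needs k >= 3 items for identification")
  floor_res <- 1e-4
  obj <- function(par) {
    lam <- par[1:k]; psi <- par[(k + 1):(2 * k)]
    Sig <- tcrossprod(lam); diag(Sig) <- diag(Sig) + psi
    cf <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(cf)) return(1e10)
    ldet <- 2 * sum(log(diag(cf)))
    ldet + sum(diag(chol2inv(cf) %*% S))
  }
  grad <- function(par) {
    lam <- par[1:k]; psi <- par[(k + 1):(2 * k)]
    Sig <- tcrossprod(lam); diag(Sig) <- diag(Sig) + psi
    Sinv <- chol2inv(chol(Sig))
    E <- Sinv %*% (Sig - S) %*% Sinv
    c(2 * drop(E %*% lam), diag(E))
  }
  start <- c(rep(0.5, k), rep(0.75, k))
  fit <- stats::nlminb(start, obj, grad,
                       lower = c(rep(-Inf, k), rep(floor_res, k)),
                       control = list(iter.max = 500, rel.tol = 1e-10))
  lam <- fit$par[1:k]
  if (sum(lam) < 0) lam <- -lam  # sign convention: positive composite loading
  psi <- fit$par[(k + 1):(2 * k)]
  Sig <- tcrossprod(lam); diag(Sig) <- diag(Sig) + psi
  cf <- chol(S)
  logdetS <- 2 * sum(log(diag(cf)))
  disc <- obj(fit$par) - logdetS - k
  ll <- if (is.null(n_obs)) NA_real_ else {
    -0.5 * n_obs * (k * log(2 * pi) + obj(fit$par))
  }
  list(loadings = lam, residual_variances = psi, factor_variance = 1,
       implied_cov = Sig, discrepancy = disc, loglik = ll,
       converged = fit$convergence == 0, heywood = any(psi <= floor_res * 1.01))
}

#' Regression factor scores
#'
#' Linear projection `Phi Lambda' Sigma^-1 x_i` of the column-centered
#' responses onto the factor, with `Phi = 1`. Scores are in the latent
#' metric up to the usual regression-score shrinkage, so
#' `standardized = FALSE`.
#'
#' @param params A fit from [fit_cfa()].
#' @param items n x k numeric matrix scored by the fitted model.
#' @return A score vector object with `method = "RFS"`.
#' @export
rfs <- function(params, items) {
  items <- as.matrix(items)
  x <- scale(items, center = TRUE, scale = FALSE)
  w <- solve(params$implied_cov, params$loadings)  # Sigma^-1 Lambda
  score_vector("RFS", drop(x %*% w) * params$factor_variance)
}
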