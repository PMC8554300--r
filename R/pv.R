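#' Latent-regression GPCM for plausible-value generation
#'
#' Jointly estimates the GPCM item parameters and the conditioning model
#' `g(theta | c) = N(mu + beta' c, sigma^2)` by marginal ML via EM on the
#' quadrature grid, with each person's prior centred at their conditioning
#' mean. The joint model has a location/scale indeterminacy (a shift or
#' rescaling of theta can be absorbed by the item and regression
#' parameters), resolved by standardizing the latent marginal to mean 0
#' and variance 1 each M-step — the metric of the generating model.
#'
#' @param items n x k ordinal response matrix.
#' @param background n x p numeric matrix of conditioning variables
#'   (without intercept; one is added), full column rank.
#' @param max_iter,tol EM controls, as in [fit_gpcm()].
#' @return An object of class `latreg_fit`: the [fit_gpcm()] fields plus
#'   `cond_intercept`, `cond_slopes`, `residual_var`, `background_names`,
#'   and `posterior` computed under the conditioning prior.
#' @export
fit_latent_regression <- function(items, background, max_iter = 500L,
                                  tol = 1e-4) {
  items <- as.matrix(items)
  storage.mode(items) <- "integer"
  background <- as.matrix(background)
  if (nrow(background) != nrow(items)) stop("row mismatch items/background")
  Cmat <- cbind(1, background)
  if (qr(Cmat)$rank < ncol(Cmat)) {
    stop("background matrix is rank deficient")
  }
  k <- ncol(items)
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
    b0[j, seq_len(ncat[j] - 1L)] <- seq(-1.5, 1.5, length.out = ncat[j] - 1L)
  }
  fit <- gpcm_em_cpp(x, ncat, quad$nodes, quad$weights,
                     rep(1, k), b0, Cmat, TRUE,
                     as.integer(max_iter), tol)
  b <- lapply(seq_len(k), function(j) fit$b[j, seq_len(ncat[j] - 1L)])
  coefs <- as.numeric(fit$reg_coef)
  structure(list(
    a = as.numeric(fit$a), b = b, ncat = ncat, category_levels = levels,
    items = x, quadrature = quad,
    cond_intercept = coefs[1], cond_slopes = coefs[-1],
    residual_var = fit$sigma2,
    background = background,
    background_names = colnames(background) %||% paste0("bg", seq_len(ncol(background))),
    posterior = fit$posterior, loglik = fit$loglik,
    loglik_history = as.numeric(fit$loglik_history),
    iterations = fit$iterations, converged = fit$converged,
    collapsed = any(ncat < 5L)
  ), class = "latreg_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.latreg_fit <- function(x, ...) {
  cat(sprintf(
    "<latreg_fit> %d items, %d background variables, sigma2 = %.3f, %s\n",
    length(x$a), length(x$cond_slopes), x$residual_var,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Draw plausible values
#'
#' For each person, `m` independent draws from the discrete posterior over
#' quadrature nodes proportional to
#' `L(x_i | theta_q) * N(theta_q; mu + beta' c_i, sigma^2)`, with a
#' uniform jitter within the node spacing. Item and conditioning
#' parameters are held fixed at their MML estimates. Draw `l` of an
#' `m`-draw call consumes the same random numbers as draw `l` of any
#' longer call with the same seed, so the first column is stable in `m`.
#'
#' @param model A converged [fit_latent_regression()] object.
#' @param m Number of plausible values per person (default 10).
#' @param seed Integer seed.
#' @return An n x m matrix of plausible values.
#' @export
draw_pv <- function(model, m = 10L, seed) {
  if (m < 1L) stop("`m` must be >= 1")
  post <- model$posterior
  nodes <- model$quadrature$nodes
  h <- diff(nodes[1:2])
  n <- nrow(post)
  # row-wise cumulative sums via one triangular matmul
  ut <- 1 * upper.tri(diag(length(nodes)), diag = TRUE)
  cum <- post %*% ut
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, n, m)
  for (l in seq_len(m)) {
    u <- stats::runif(n)
    idx <- rowSums(cum < u) + 1L
    idx <- pmin(idx, length(nodes))
    draws[, l] <- nodes[idx] + stats::runif(n, -h / 2, h / 2)
  }
  colnames(draws) <- paste0("pv_", seq_len(m))
  draws
}

#' Pool per-imputation regression fits by Rubin's rules
#'
#' Point estimate = mean of the `m` estimates; within-imputation variance
#' `W` = mean of squared SEs; between-imputation variance `B` = sample
#' variance of the estimates; total variance `T = W + (1 + 1/m) B`.
#'
#' @param estimates m x p matrix (or list of vectors) of coefficient
#'   estimates, one row per imputation.
#' @param squared_ses m x p matrix of squared standard errors.
#' @return List with `coef`, `within_var`, `between_var`, `total_var`,
#'   `m`.
#' @examples
#' pool_rubin(rbind(0.4, 0.6), rbind(0.01, 0.01))
#' @export
pool_rubin <- function(estimates, squared_ses) {
  est <- as.matrix(estimates)
  se2 <- as.matrix(squared_ses)
  m <- nrow(est)
  if (m < 2L) stop("Rubin pooling needs m >= 2 imputations")
  stopifnot(all(dim(est) == dim(se2)))
  W <- colMeans(se2)
  B <- apply(est, 2, stats::var)
  list(coef = colMeans(est), within_var = W, between_var = B,
       total_var = W + (1 + 1 / m) * B, m = m)
}

#' Write plausible values as a delimited table
#'
#' @param draws Matrix from [draw_pv()].
#' @param path Output path.
#' @export
write_pv <- function(draws, path) {
  df <- data.frame(person = seq_len(nrow(draws)), draws)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
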