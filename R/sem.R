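#' Model-implied covariance of the structural equation model
#'
#' Path model: k items load on the latent skill theta (variance fixed at
#' 1), the observed covariate C covaries freely with theta, and the
#' outcome is `Y = beta theta + gamma C + e`. Variable order:
#' `X_1..X_k, C, Y`.
#'
#' @param lambda Loadings (length k).
#' @param psi Item residual variances (length k, positive).
#' @param phi_c Covariance of theta with C.
#' @param v_c Variance of C.
#' @param beta,gamma Structural coefficients of theta and C on Y.
#' @param psi_y Outcome residual variance.
#' @return `(k + 2) x (k + 2)` symmetric matrix.
#' @export
sem_implied_covariance <- function(lambda, psi, phi_c, v_c, beta, gamma,
                                   psi_y) {
  k <- length(lambda)
  stopifnot(length(psi) == k, all(psi > 0))
  S <- matrix(0, k + 2, k + 2)
  S[1:k, 1:k] <- tcrossprod(lambda)
  diag(S)[1:k] <- diag(S)[1:k] + psi
  S[1:k, k + 1] <- S[k + 1, 1:k] <- lambda * phi_c
  cty <- beta + gamma * phi_c              # cov(theta, Y)
  S[1:k, k + 2] <- S[k + 2, 1:k] <- lambda * cty
  S[k + 1, k + 1] <- v_c
  S[k + 1, k + 2] <- S[k + 2, k + 1] <- beta * phi_c + gamma * v_c
  S[k + 2, k + 2] <- beta^2 + gamma^2 * v_c + 2 * beta * gamma * phi_c + psi_y
  S
}

# F_ML and analytic gradient for the parameter vector
# (lambda_1..k, psi_1..k, phi_c, v_c, beta, gamma, psi_y)
sem_objective <- function(par, S, k) {
  lam <- par[1:k]; psi <- par[(k + 1):(2 * k)]
  phi_c <- par[2 * k + 1]; v_c <- par[2 * k + 2]
  beta <- par[2 * k + 3]; gamma <- par[2 * k + 4]; psi_y <- par[2 * k + 5]
  Sig <- sem_implied_covariance(lam, psi, phi_c, v_c, beta, gamma, psi_y)
  cf <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(cf)) return(list(value = 1e10, gradient = NULL))
  Sinv <- chol2inv(cf)
  val <- 2 * sum(log(diag(cf))) + sum(Sinv * S)
  E <- Sinv %*% (Sig - S) %*% Sinv
  p <- k + 2
  iC <- k + 1; iY <- k + 2
  t_vec <- c(lam, phi_c, beta + gamma * phi_c)
  Et <- drop(E %*% t_vec)
  g_lam <- 2 * Et[1:k]
  g_psi <- diag(E)[1:k]
  ejy_lam <- sum(E[1:k, iY] * lam)
  g_phi <- 2 * (sum(E[1:k, iC] * lam) + E[iC, iY] * beta + gamma * ejy_lam +
                  E[iY, iY] * beta * gamma)
  g_vc <- E[iC, iC] + 2 * gamma * E[iC, iY] + gamma^2 * E[iY, iY]
  g_beta <- 2 * (ejy_lam + E[iC, iY] * phi_c +
                   E[iY, iY] * (beta + gamma * phi_c))
  g_gamma <- 2 * (phi_c * ejy_lam + E[iC, iY] * v_c +
                    E[iY, iY] * (gamma * v_c + beta * phi_c))
  g_psiy <- E[iY, iY]
  list(value = val,
       gradient = c(g_lam, g_psi, g_phi, g_vc, g_beta, g_gamma, g_psiy))
}

#' Fit the structural equation model by normal-theory maximum likelihood
#'
#' Minimizes `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - (k + 2)` over
#' the free parameters of [sem_implied_covariance()] by quasi-Newton
#' (`nlminb`) with an analytic gradient. Items (5-category ordinal in the
#' study) are treated as continuous. Start values: measurement part from
#' [fit_cfa()], structural part from OLS of the outcome on the
#' standardized mean score and the covariate. On failure the search
#' restarts once from perturbed starts, then flags non-convergence.
#'
#' @param items n x k matrix (k >= 3), or `NULL` when `S` is supplied.
#' @param covariate,outcome Length-n vectors, or `NULL` when `S` given.
#' @param S Optional `(k + 2) x (k + 2)` covariance of
#'   `(X_1..X_k, C, Y)` to fit directly (e.g. a population covariance).
#' @param k Number of items (required with `S`).
#' @return List with `loadings`, `residuals`, `theta_cov_corr` (estimated
#'   corr(theta, C)), `beta_hat`, `gamma_hat`, `y_residual`,
#'   `discrepancy`, `converged`.
#' @export
fit_sem <- function(items = NULL, covariate = NULL, outcome = NULL,
                    S = NULL, k = NULL) {
  if (is.null(S)) {
    items <- as.matrix(items)
    k <- ncol(items)
    dat <- cbind(items, covariate, outcome)
    S <- stats::cov(dat)
    sms_vals <- sms(items)$values
    st_ols <- stats::coef(stats::lm(outcome ~ sms_vals + covariate))
    beta0 <- unname(st_ols[2]); gamma0 <- unname(st_ols[3])
    cfa0 <- fit_cfa(items)
    lam0 <- cfa0$loadings; psi0 <- pmax(cfa0$residual_variances, 1e-3)
    phi0 <- stats::cov(sms_vals, covariate)
  } else {
    if (is.null(k)) stop("`k` must be given with `S`")
    lam0 <- rep(0.5, k); psi0 <- rep(0.75, k)
    phi0 <- 0.2; beta0 <- 0.3; gamma0 <- 0.3
  }
  if (k < 3L) stop("one-factor measurement model needs k >= 3 items")
  psiy0 <- max(S[k + 2, k + 2] - beta0^2 - gamma0^2, 0.3)
  start <- c(lam0, psi0, phi0, S[k + 1, k + 1], beta0, gamma0, psiy0)
  lower <- c(rep(-Inf, k), rep(1e-4, k), -5, 1e-4, -Inf, -Inf, 1e-4)

  run <- function(st) {
    stats::nlminb(
      st,
      function(p) sem_objective(p, S, k)$value,
      function(p) {
        g <- sem_objective(p, S, k)$gradient
        if (is.null(g)) rep(0, length(p)) else g
      },
      lower = lower,
      control = list(iter.max = 1000, rel.tol = 1e-12, abs.tol = 0)
    )
  }
  fit <- run(start)
  grad_norm <- max(abs(sem_objective(fit$par, S, k)$gradient))
  if (grad_norm > 1e-5) {
    set.seed(1L)
    fit2 <- run(start * stats::runif(length(start), 0.9, 1.1))
    if (fit2$objective < fit$objective) fit <- fit2
    grad_norm <- max(abs(sem_objective(fit$par, S, k)$gradient))
  }
  par <- fit$par
  lam <- par[1:k]
  if (sum(lam) < 0) {  # reflect the factor so loadings are positive
    lam <- -lam
    par[2 * k + 1] <- -par[2 * k + 1]
    par[2 * k + 3] <- -par[2 * k + 3]
  }
  cf <- chol(S)
  disc <- fit$objective - 2 * sum(log(diag(cf))) - (k + 2)
  list(
    loadings = lam,
    residuals = par[(k + 1):(2 * k)],
    theta_cov_corr = par[2 * k + 1] / sqrt(par[2 * k + 2]),
    v_c = par[2 * k + 2],
    beta_hat = par[2 * k + 3],
    gamma_hat = par[2 * k + 4],
    y_residual = par[2 * k + 5],
    discrepancy = disc,
    converged = grad_norm < 1e-3
  )
}

#' Export a SEM fit as a parameter table
#'
#' @param fit A [fit_sem()] result.
#' @param path Output path for the tab-delimited (parameter, estimate)
#'   table.
#' @export
write_sem_fit <- function(fit, path) {
  k <- length(fit$loadings)
  df <- data.frame(
    parameter = c(paste0("lambda", seq_len(k)), paste0("psi", seq_len(k)),
                  "phi", "v_c", "beta", "gamma", "psi_y"),
    estimate = c(fit$loadings, fit$residuals, fit$theta_cov_corr, fit$v_c,
                 fit$beta_hat, fit$gamma_hat, fit$y_residual)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
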