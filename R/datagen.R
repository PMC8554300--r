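#' Population parameters of the generating model
#'
#' The generating model: a standard-normal latent skill `theta` measured by
#' k congeneric items, a covariate `C` with corr(theta, C) = 0.30, and two
#' continuous outcomes regressed on both. For `Y1` the skill dominates
#' (`beta1 > gamma1`), for `Y2` the covariate does (`beta2 < gamma2`).
#' Structural coefficients are fixed at (0.35, 0.30) for the stronger
#' outcome and (0.20, 0.30) for the weaker; outcome residual variances are
#' set so each outcome has unit variance, keeping the generating metric
#' fully standardized. Continuous item scores are cut at
#' (-1.5, -0.5, 0.5, 1.5) into five ordinal categories, which yields a
#' symmetric bell-shaped category histogram under a standard-normal item.
#'
#' @param cond One row of [build_design()] (data.frame or list with
#'   `n_items`, `loading_profile`, `sample_size`, `rsro`).
#' @return A list with elements `lambdas`, `phi`, `beta1`, `gamma1`,
#'   `sigma2_y1`, `beta2`, `gamma2`, `sigma2_y2`, `thresholds`, and the
#'   analyzed outcome's (`beta`, `gamma`) under `beta`/`gamma` (the truth
#'   values that percent bias is benchmarked against).
#' @export
population_params <- function(cond) {
  lam <- loading_set(cond$loading_profile, cond$n_items)
  phi <- 0.30
  beta1 <- 0.35; gamma1 <- 0.30
  beta2 <- 0.20; gamma2 <- 0.30
  s2 <- function(b, g) 1 - b^2 - g^2 - 2 * b * g * phi
  stopifnot(s2(beta1, gamma1) > 0, s2(beta2, gamma2) > 0)
  analyzed <- if (identical(cond$rsro, "stronger")) c(beta1, gamma1) else c(beta2, gamma2)
  list(
    lambdas = lam,
    phi = phi,
    beta1 = beta1, gamma1 = gamma1, sigma2_y1 = s2(beta1, gamma1),
    beta2 = beta2, gamma2 = gamma2, sigma2_y2 = s2(beta2, gamma2),
    thresholds = c(-1.5, -0.5, 0.5, 1.5),
    beta = analyzed[1], gamma = analyzed[2],
    outcome = if (identical(cond$rsro, "stronger")) "y1" else "y2"
  )
}

#' Exact population covariance of the continuous variables
#'
#' Model-implied covariance matrix of the pre-categorization item scores
#' `X*_1..X*_k`, the covariate `C`, both outcomes and the latent skill
#' `theta`, in that order. All variables have unit variance by
#' construction, so the matrix doubles as a correlation matrix. Used as an
#' oracle for moment-convergence tests and for fitting estimators directly
#' to the population.
#'
#' @inheritParams population_params
#' @return Symmetric `(k + 4) x (k + 4)` matrix with dimnames
#'   `x1..xk, c, y1, y2, theta`.
#' @export
population_covariance <- function(cond) {
  p <- population_params(cond)
  lam <- p$lambdas; k <- length(lam); phi <- p$phi
  nm <- c(paste0("x", seq_len(k)), "c", "y1", "y2", "theta")
  S <- matrix(0, k + 4, k + 4, dimnames = list(nm, nm))
  # items: lambda_j lambda_l off-diagonal, 1 on the diagonal
  S[1:k, 1:k] <- tcrossprod(lam)
  diag(S)[1:k] <- 1
  # covariances of theta with everything (path tracing)
  cov_theta <- c(lam, phi,
                 p$beta1 + p$gamma1 * phi,
                 p$beta2 + p$gamma2 * phi, 1)
  S[k + 4, ] <- S[, k + 4] <- cov_theta
  # covariate column
  cov_c <- c(lam * phi, 1,
             p$beta1 * phi + p$gamma1,
             p$beta2 * phi + p$gamma2, phi)
  S[k + 1, ] <- S[, k + 1] <- cov_c
  # outcomes: cov(X*_j, Y) = lambda_j * cov(theta, Y)
  cy1 <- p$beta1 + p$gamma1 * phi
  cy2 <- p$beta2 + p$gamma2 * phi
  S[1:k, k + 2] <- S[k + 2, 1:k] <- lam * cy1
  S[1:k, k + 3] <- S[k + 3, 1:k] <- lam * cy2
  S[k + 2, k + 2] <- S[k + 3, k + 3] <- 1
  # cov(Y1, Y2) = b1*c(theta,y2) ... via structural paths:
  S[k + 2, k + 3] <- S[k + 3, k + 2] <-
    p$beta1 * cy2 + p$gamma1 * (p$beta2 * phi + p$gamma2)
  S[k + 4, k + 4] <- 1
  S
}

#' Cut a continuous score into one of five ordered categories
#'
#' Returns `1 + ` the number of thresholds strictly below the value, so the
#' map is monotone non-decreasing and a value of 0 with symmetric
#' thresholds lands in the middle category.
#'
#' @param value Numeric vector of continuous scores.
#' @param thresholds Four ascending cut points.
#' @return Integer vector of categories in 1..5.
#' @export
categorize <- function(value, thresholds = c(-1.5, -0.5, 0.5, 1.5)) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly increasing")
  }
  findInterval(value, thresholds, left.open = TRUE) + 1L
}

#' Simulate one replication
#'
#' Draws `(theta, C)` bivariate standard normal with correlation 0.30,
#' continuous item scores `X*_j = lambda_j * theta + eps_j` with
#' independent normal residuals of variance `1 - lambda_j^2`, both
#' outcomes from the structural model, and categorizes the items to five
#' ordinal categories (unless `categorize_items = FALSE`, which returns
#' the continuous items — used by the closed-form attenuation oracle).
#' Identical `(cond, seed)` gives a bit-identical sample.
#'
#' @inheritParams population_params
#' @param seed Integer seed for the replication.
#' @param n Optional sample-size override (defaults to the condition's).
#' @param categorize_items Categorize items to 1..5 (default TRUE).
#' @return A list with `theta`, `items` (n x k matrix, ordinal unless
#'   `categorize_items = FALSE`), `covariate`, `y1`, `y2`, and the
#'   generating `params`.
#' @export
generate_sample <- function(cond, seed, n = NULL, categorize_items = TRUE) {
  p <- population_params(cond)
  if (is.null(n)) n <- cond$sample_size
  k <- length(p$lambdas)
  set.seed(as.integer(seed))
  theta <- rnorm(n)
  covariate <- p$phi * theta + sqrt(1 - p$phi^2) * rnorm(n)
  xstar <- theta %o% p$lambdas +
    matrix(rnorm(n * k), n, k) %*% diag(sqrt(1 - p$lambdas^2), k)
  y1 <- p$beta1 * theta + p$gamma1 * covariate + sqrt(p$sigma2_y1) * rnorm(n)
  y2 <- p$beta2 * theta + p$gamma2 * covariate + sqrt(p$sigma2_y2) * rnorm(n)
  items <- if (categorize_items) {
    matrix(categorize(xstar, p$thresholds), n, k)
  } else {
    xstar
  }
  colnames(items) <- paste0("item_", seq_len(k))
  list(theta = theta, items = items, covariate = covariate,
       y1 = y1, y2 = y2, params = p, n = n, k = k)
}

#' Write / read a simulated sample as a delimited table
#'
#' Column layout: `theta, item_1..item_k, covariate, y1, y2`.
#'
#' @param sample A list from [generate_sample()].
#' @param path File path for the tab-delimited table.
#' @export
write_sample <- function(sample, path) {
  df <- data.frame(theta = sample$theta, sample$items,
                   covariate = sample$covariate, y1 = sample$y1, y2 = sample$y2)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sample
#' @return `read_sample()` returns the same list structure as
#'   [generate_sample()] minus `params`.
#' @export
read_sample <- function(path) {
  df <- utils::read.delim(path)
  item_cols <- grep("^item_", names(df))
  items <- as.matrix(df[, item_cols, drop = FALSE])
  list(theta = df$theta, items = items, covariate = df$covariate,
       y1 = df$y1, y2 = df$y2, n = nrow(df), k = length(item_cols))
}
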