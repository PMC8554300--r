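#' Ordinary least squares with conventional standard errors
#'
#' QR-based least squares of `outcome` on an intercept plus `predictors`,
#' returning coefficients and the usual `sigma^2 (X'X)^{-1}` standard
#' errors. The first predictor column is conventionally the skill proxy
#' and the second the covariate.
#'
#' @param outcome Length-n numeric vector.
#' @param predictors n x p numeric matrix (intercept added internally).
#' @return List with `coef`, `se` (both excluding the intercept),
#'   `intercept`, `sigma2`, `df`.
#' @export
ols <- function(outcome, predictors) {
  X <- cbind(`(Intercept)` = 1, as.matrix(predictors))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("predictor matrix is rank deficient")
  cf <- qr.coef(qx, outcome)
  res <- outcome - drop(X %*% cf)
  df <- length(outcome) - ncol(X)
  s2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(s2 * diag(XtX_inv))
  list(coef = unname(cf[-1]), se = unname(se[-1]),
       intercept = unname(cf[1]), sigma2 = s2, df = df)
}

#' Percent bias of an estimate
#'
#' `100 * (estimate - truth) / truth`; negative values indicate
#' attenuation.
#'
#' @param estimate Estimated value(s).
#' @param truth Non-zero population value.
#' @return Percent bias, same length as `estimate`.
#' @examples
#' percent_bias(0.315, 0.35)  # -10
#' @export
percent_bias <- function(estimate, truth) {
  if (any(truth == 0)) stop("`truth` must be non-zero")
  100 * (estimate - truth) / truth
}

#' Rescale a regression fit to standardized coefficients
#'
#' Multiplies each coefficient by `predictor sd / outcome sd`, the usual
#' standardization applied when scores are not already on the outcome's
#' scale.
#'
#' @param fit A fit from [ols()] (list with `coef`, `se`).
#' @param predictor_sds Vector of predictor standard deviations (same
#'   order as `fit$coef`).
#' @param outcome_sd Outcome standard deviation.
#' @return The fit with rescaled `coef`/`se` and `standardized = TRUE`.
#' @export
standardized_fit <- function(fit, predictor_sds, outcome_sd) {
  if (any(predictor_sds <= 0) || outcome_sd <= 0) stop("sds must be positive")
  fit$coef <- fit$coef * predictor_sds / outcome_sd
  fit$se <- fit$se * predictor_sds / outcome_sd
  fit$standardized <- TRUE
  fit
}

#' Run configuration
#'
#' @param n_reps Replications per condition (the full study design uses 500;
#'   100 keeps a full sweep at desk scale).
#' @param methods Subset of `c("SMS","EBM","RFS","WLE","EAP","PV","SEM")`.
#' @param base_seed Integer base seed; per-replication seeds are
#'   `(base_seed * 1e6 + condition_id * 1e4 + rep) mod (2^31 - 1)`, so
#'   each condition runs its own deterministic stream from a common base.
#' @param n_pv Plausible values per person (default 10).
#' @param conditions Optional vector of condition ids (default: all 36).
#' @return A `run_config` list.
#' @export
run_config <- function(n_reps = 100L,
                       methods = c("SMS", "EBM", "RFS", "WLE", "EAP", "PV", "SEM"),
                       base_seed = 1L, n_pv = 10L, conditions = NULL) {
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("SMS", "EBM", "RFS", "WLE", "EAP", "PV", "SEM"))
  stopifnot(n_reps >= 1L, n_pv >= 1L)
  list(n_reps = as.integer(n_reps), methods = methods,
       base_seed = as.integer(base_seed), n_pv = as.integer(n_pv),
       conditions = conditions)
}

rep_seed <- function(base_seed, condition_id, rep) {
  as.integer((base_seed * 1e6 + condition_id * 1e4 + rep) %% 2147483647)
}

score_methods <- c("SMS", "EBM", "RFS", "WLE", "EAP")

# analyze one replication of one condition; returns per-method skill and
# covariate coefficients (raw scale) plus score sds and the correlation
# matrix of scores and outcomes
analyze_replication <- function(cond, config, rep) {
  seed <- rep_seed(config$base_seed, cond$condition_id, rep)
  smp <- generate_sample(cond, seed)
  p <- smp$params
  y <- if (p$outcome == "y1") smp$y1 else smp$y2
  methods <- config$methods
  out <- list()
  scores <- list()

  need_gpcm <- any(c("EBM", "WLE", "EAP") %in% methods)
  need_cfa <- "RFS" %in% methods

  if ("SMS" %in% methods) scores$SMS <- sms(smp$items)
  if (need_cfa) {
    cfa <- fit_cfa(smp$items)
    scores$RFS <- rfs(cfa, smp$items)
    if (!cfa$converged) out$flag_RFS <- TRUE
  }
  if (need_gpcm) {
    gp <- fit_gpcm(smp$items)
    if (!gp$converged) out$flag_EBM <- out$flag_WLE <- out$flag_EAP <- TRUE
    if ("WLE" %in% methods) scores$WLE <- wle(gp)
    if ("EAP" %in% methods) scores$EAP <- eap(gp)
    if ("EBM" %in% methods) scores$EBM <- ebm(gp)
  }

  fits <- list()
  for (mth in intersect(score_methods, methods)) {
    fit <- ols(y, cbind(scores[[mth]]$values, smp$covariate))
    fit$score_sd <- stats::sd(scores[[mth]]$values)
    fits[[mth]] <- fit
  }

  if ("PV" %in% methods) {
    lr <- fit_latent_regression(smp$items,
                                cbind(c = smp$covariate, y1 = smp$y1, y2 = smp$y2))
    if (!lr$converged) out$flag_PV <- TRUE
    pv <- draw_pv(lr, config$n_pv, seed = (seed + 1000003) %% 2147483647)
    est <- se2 <- matrix(NA_real_, config$n_pv, 2)
    for (l in seq_len(config$n_pv)) {
      f <- ols(y, cbind(pv[, l], smp$covariate))
      est[l, ] <- f$coef
      se2[l, ] <- f$se^2
    }
    pooled <- pool_rubin(est, se2)
    fits$PV <- list(coef = pooled$coef, se = sqrt(pooled$total_var))
  }

  if ("SEM" %in% methods) {
    sem <- fit_sem(smp$items, smp$covariate, y)
    if (!sem$converged) out$flag_SEM <- TRUE
    fits$SEM <- list(coef = c(sem$beta_hat, sem$gamma_hat))
  }

  out$fits <- fits
  out$outcome_sd <- stats::sd(y)
  out$cov_sd <- stats::sd(smp$covariate)
  if (all(score_methods %in% names(scores))) {
    sc <- cbind(sapply(score_methods, function(m) scores[[m]]$values),
                Y1 = smp$y1, Y2 = smp$y2)
    out$score_cor <- stats::cor(sc)
  }
  out
}

#' Run all replications of one design condition
#'
#' For each replication: generate a sample, compute the requested scores,
#' regress the condition's outcome on (score, covariate) per method, pool
#' plausible-value regressions by Rubin's rules, fit the SEM, and record
#' percent bias of the skill and covariate coefficients against the
#' generating values. Replications where a method's estimation did not
#' converge are excluded from that method's average and counted in
#' `n_flagged`. Also accumulates the mean correlation matrix of the five
#' scores and the two outcomes.
#'
#' @param cond One row of [build_design()].
#' @param config A [run_config()].
#' @return List with `summary` (a data.frame in the bias-summary layout:
#'   condition_id, method, coefficient, standardized, mean_pct_bias,
#'   sd_pct_bias, n_reps, n_flagged) and `score_cor` (averaged 7 x 7
#'   correlation matrix, or NULL when not all scores were run).
#' @export
run_condition <- function(cond, config = run_config()) {
  p <- population_params(cond)
  truth <- c(skill = p$beta, covariate = p$gamma)
  methods <- config$methods
  n_reps <- config$n_reps

  # bias[rep, method, coefficient, standardized?]
  rows <- list()
  acc <- array(NA_real_, c(n_reps, length(methods), 2),
               dimnames = list(NULL, methods, c("skill", "covariate")))
  acc_std <- acc
  flags <- stats::setNames(integer(length(methods)), methods)
  cor_sum <- NULL
  cor_n <- 0L
  n_failed <- 0L

  for (r in seq_len(n_reps)) {
    res <- tryCatch(analyze_replication(cond, config, r),
                    error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      if (n_failed > 0.1 * n_reps) {
        stop("more than 10% of replications failed: ",
             conditionMessage(res))
      }
      next
    }
    for (mth in methods) {
      if (isTRUE(res[[paste0("flag_", mth)]])) {
        flags[mth] <- flags[mth] + 1L
        next
      }
      f <- res$fits[[mth]]
      if (is.null(f)) next
      acc[r, mth, ] <- percent_bias(f$coef[1:2], truth)
      if (mth %in% c("EBM", "RFS", "WLE", "EAP")) {
        fs <- standardized_fit(f, c(f$score_sd, res$cov_sd), res$outcome_sd)
        acc_std[r, mth, ] <- percent_bias(fs$coef[1:2], truth)
      }
    }
    if (!is.null(res$score_cor)) {
      cor_sum <- if (is.null(cor_sum)) res$score_cor else cor_sum + res$score_cor
      cor_n <- cor_n + 1L
    }
  }

  for (mth in methods) {
    for (coefn in c("skill", "covariate")) {
      v <- acc[, mth, coefn]
      rows[[length(rows) + 1L]] <- data.frame(
        condition_id = cond$condition_id, method = mth, coefficient = coefn,
        standardized = FALSE,
        mean_pct_bias = mean(v, na.rm = TRUE),
        sd_pct_bias = stats::sd(v[!is.na(v)]),
        n_reps = sum(!is.na(v)), n_flagged = flags[[mth]] + n_failed
      )
      vs <- acc_std[, mth, coefn]
      if (any(!is.na(vs))) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition_id = cond$condition_id, method = mth, coefficient = coefn,
          standardized = TRUE,
          mean_pct_bias = mean(vs, na.rm = TRUE),
          sd_pct_bias = stats::sd(vs[!is.na(vs)]),
          n_reps = sum(!is.na(vs)), n_flagged = flags[[mth]] + n_failed
        )
      }
    }
  }
  list(summary = do.call(rbind, rows),
       score_cor = if (cor_n > 0L) cor_sum / cor_n else NULL)
}

#' Run the full study over a set of conditions
#'
#' @param config A [run_config()]; `config$conditions` selects condition
#'   ids (default all 36).
#' @param progress Print one line per condition.
#' @return List with `summary` (row-bound bias summaries joined to the
#'   design factors), `score_cor` (correlation matrix pooled across
#'   replications and then conditions), `design`.
#' @export
run_study <- function(config = run_config(), progress = FALSE) {
  design <- build_design()
  ids <- config$conditions %||% design$condition_id
  summaries <- list()
  cor_sum <- NULL
  cor_n <- 0L
  for (id in ids) {
    cond <- design[design$condition_id == id, ]
    res <- run_condition(cond, config)
    summaries[[length(summaries) + 1L]] <- res$summary
    if (!is.null(res$score_cor)) {
      cor_sum <- if (is.null(cor_sum)) res$score_cor else cor_sum + res$score_cor
      cor_n <- cor_n + 1L
    }
    if (progress) {
      message(sprintf("condition %2d/%d done", id, max(ids)))
    }
  }
  summary <- do.call(rbind, summaries)
  summary <- merge(design, summary, by = "condition_id", sort = TRUE)
  list(summary = summary,
       score_cor = if (cor_n > 0L) cor_sum / cor_n else NULL,
       design = design)
}

#' Lay out bias summaries as wide per-condition tables
#'
#' One wide table per coefficient: rows are the 36 conditions in canonical
#' order, columns the methods in the order SMS, EBM, RFS, WLE, EAP, PV,
#' SEM; cells are mean percent bias. Methods not run leave explicit NA
#' gaps.
#'
#' @param summary The `summary` data.frame from [run_study()].
#' @param output_dir Optional directory; when given, writes
#'   `bias_skill.csv`, `bias_covariate.csv` (and, if present,
#'   `score_correlations.csv` from `score_cor`).
#' @param score_cor Optional pooled correlation matrix to write alongside.
#' @return Named list of data.frames `skill` and `covariate`.
#' @export
make_tables <- function(summary, output_dir = NULL, score_cor = NULL) {
  method_order <- c("SMS", "EBM", "RFS", "WLE", "EAP", "PV", "SEM")
  design <- build_design()
  out <- list()
  for (coefn in c("skill", "covariate")) {
    sub <- summary[summary$coefficient == coefn & !summary$standardized, ]
    tab <- design[, c("condition_id", "rsro", "sample_size",
                      "loading_profile", "n_items")]
    for (mth in method_order) {
      v <- rep(NA_real_, nrow(tab))
      s <- sub[sub$method == mth, ]
      v[match(s$condition_id, tab$condition_id)] <- s$mean_pct_bias
      tab[[mth]] <- round(v, 2)
    }
    out[[coefn]] <- tab
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$skill, file.path(output_dir, "bias_skill.csv"),
                     row.names = FALSE)
    utils::write.csv(out$covariate, file.path(output_dir, "bias_covariate.csv"),
                     row.names = FALSE)
    if (!is.null(score_cor)) {
      utils::write.csv(round(score_cor, 4),
                       file.path(output_dir, "score_correlations.csv"))
    }
  }
  out
}
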