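#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch–Satterthwaite degrees of freedom
#' and a two-sided p-value. When both groups have zero variance and equal
#' means the statistic is defined as 0 (p = 1), a case [stats::t.test()]
#' rejects.
#'
#' @param a,b numeric vectors, at least 2 values each.
#' @return list with `t`, `df`, `p`, and the group means.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 values per group")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("zero variance in both groups with unequal means")
  }
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' Assemble the long-format concept-knowledge table
#'
#' One row per (subject, test type) with accuracy in `[0, 1]`: the run-1
#' FBD accuracy plus the SCI and FCI inventory scores; subjects missing an
#' inventory simply contribute no row for it.
#'
#' @param behavior cohort behavior data.frame (columns `subject_id`,
#'   `group`, `fbd_run1`, `sci_acc`, `fci_acc`).
#' @return data.frame(`subject_id`, `group`, `test_type`, `accuracy`).
#' @export
behavior_long <- function(behavior) {
  pieces <- list(
    data.frame(subject_id = behavior$subject_id, group = behavior$group,
               test_type = "fbd", accuracy = behavior$fbd_run1),
    data.frame(subject_id = behavior$subject_id, group = behavior$group,
               test_type = "sci", accuracy = behavior$sci_acc),
    data.frame(subject_id = behavior$subject_id, group = behavior$group,
               test_type = "fci", accuracy = behavior$fci_acc))
  out <- do.call(rbind, pieces)
  out[!is.na(out$accuracy), ]
}

#' Mixed-effects model of concept knowledge from a neural score
#'
#' Fits `accuracy ~ score + (1 | subject) + (1 | test_type)`: the neural
#' score as a fixed effect on the composite concept-knowledge outcome, with
#' random intercepts absorbing subject-level shifts and test-type difficulty
#' (and tolerating missing inventory rows without imputation). REML is used
#' for reporting (set `REML = FALSE` for fits entering likelihood-ratio
#' comparisons). The standardized slope is
#' `beta_std = beta * sd(score) / sd(accuracy)`; the p-value is the normal
#' approximation of the Wald statistic (flagged approximate for small n).
#'
#' @param scores either a data.frame with columns `subject_id` and `score`,
#'   or a list of [neural_score_record]s (run-1 records are selected by
#'   `run_id` if present).
#' @param behavior_long long-format table from [behavior_long()].
#' @param REML logical (default TRUE).
#' @return list of class `mixed_model_result`: `beta`, `beta_std`, `se`,
#'   `p`, `loglik`, `n_obs`, `ranef_var` (subject, test type, residual),
#'   `converged`, `fit` (the lme4 object).
#' @export
fit_score_model <- function(scores, behavior_long, REML = TRUE) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, as.data.frame))
    scores <- scores[scores$method == scores$method[1L], ]
  }
  stopifnot(all(c("subject_id", "score") %in% names(scores)))
  dat <- merge(behavior_long, scores[, c("subject_id", "score")],
               by = "subject_id")
  dat <- dat[!is.na(dat$score) & !is.na(dat$accuracy), ]
  if (nrow(dat) < 4L) stop("too few observations for the mixed model")
  if (stats::sd(dat$score) == 0)
    stop("score is constant across subjects; slope is inestimable")
  fit <- lme4::lmer(accuracy ~ score + (1 | subject_id) + (1 | test_type),
                    data = dat, REML = REML,
                    control = lme4::lmerControl(check.conv.singular =
                                                  "ignore"))
  beta <- unname(lme4::fixef(fit)["score"])
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["score"]]
  z <- beta / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  structure(list(
    beta = beta,
    beta_std = beta * stats::sd(dat$score) / stats::sd(dat$accuracy),
    se = se,
    p = 2 * stats::pnorm(-abs(z)),
    loglik = as.numeric(stats::logLik(fit)),
    n_obs = nrow(dat),
    ranef_var = stats::setNames(vc$vcov, vc$grp),
    converged = conv,
    approx_small_n = nrow(dat) <= 30L,
    fit = fit), class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    "<mixed_model_result: beta %.4f (std %.3f), p %.4g, n %d%s>\n",
    x$beta, x$beta_std, x$p, x$n_obs,
    if (!x$converged) ", NOT CONVERGED" else ""))
  invisible(x)
}

#' Likelihood-ratio comparison of nested score models
#'
#' Refits both models by maximum likelihood and computes
#' `chi2 = 2 * (logLik_composite - logLik_base)` on 1 degree of freedom (the
#' composite adds exactly one score predictor to the base). The base
#' predictors must be a subset of the composite's.
#'
#' @param base_predictors character vector of score-column names in `data`
#'   for the base model (may be empty for an intercept-only base).
#' @param composite_predictors character vector for the composite model.
#' @param data long-format table from [behavior_long()] with one extra
#'   numeric column per named predictor.
#' @return list of class `model_comparison_result`: `chi2`, `df`, `p`,
#'   `loglik_base`, `loglik_composite`.
#' @export
lrt_compare <- function(base_predictors, composite_predictors, data) {
  if (!all(base_predictors %in% composite_predictors))
    stop("base model is not nested in the composite model")
  added <- setdiff(composite_predictors, base_predictors)
  if (length(added) > 1L)
    stop("composite must add at most one predictor to the base")
  mm_formula <- function(preds) {
    rhs <- paste(c(preds, "(1 | subject_id)", "(1 | test_type)"),
                 collapse = " + ")
    stats::as.formula(paste("accuracy ~", rhs))
  }
  keep <- stats::complete.cases(
    data[, c("accuracy", "subject_id", "test_type", composite_predictors)])
  data <- data[keep, ]
  ctl <- lme4::lmerControl(check.conv.singular = "ignore")
  fb <- lme4::lmer(mm_formula(base_predictors), data = data, REML = FALSE,
                   control = ctl)
  fc <- lme4::lmer(mm_formula(composite_predictors), data = data,
                   REML = FALSE, control = ctl)
  chi2 <- 2 * (as.numeric(stats::logLik(fc)) - as.numeric(stats::logLik(fb)))
  if (chi2 < 0) {
    if (chi2 < -1e-6) stop("negative LRT statistic beyond tolerance")
    chi2 <- 0
  }
  df <- length(added)
  structure(list(chi2 = chi2, df = df,
                 p = if (df == 0L) 1 else
                   stats::pchisq(chi2, df = df, lower.tail = FALSE),
                 loglik_base = as.numeric(stats::logLik(fb)),
                 loglik_composite = as.numeric(stats::logLik(fc))),
            class = "model_comparison_result")
}

#' @export
print.model_comparison_result <- function(x, ...) {
  cat(sprintf("<model_comparison: chi2(%d) = %.3f, p = %.4g>\n",
              x$df, x$chi2, x$p))
  invisible(x)
}
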