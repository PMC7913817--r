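# Matched case-control statistical battery: Wilcoxon signed-rank
# comparisons, Spearman correlations, nonparametric ROC/AUC with
# Hanley-McNeil standard errors, odds ratios per SD decrease, and forward
# stepwise logistic regression. Every test is two-sided at 0.05 and no
# multiplicity correction is applied, matching common practice for
# exploratory case-control imaging studies.

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped; the p-value is exact (by enumeration of
#' sign assignments) for up to 25 non-zero untied differences and a normal
#' approximation with tie and continuity correction otherwise. Backed by
#' [stats::wilcox.test()].
#'
#' @param diffs Numeric vector of paired differences (case minus control,
#'   or any consistent direction).
#' @param exact_max Largest n for which the exact null distribution is used.
#' @return List: `w_plus`, `w_minus`, `p`, `n_used` (non-zero pairs),
#'   `method`, and `degenerate = TRUE` with `p = 1` when all differences
#'   are zero.
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 25L) {
  diffs <- diffs[!is.na(diffs)]
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L)
    return(list(w_plus = 0, w_minus = 0, p = 1, n_used = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  ties <- any(duplicated(abs(d)))
  use_exact <- n <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    d, exact = use_exact, correct = TRUE))
  list(w_plus = w_plus, w_minus = w_minus, p = wt$p.value, n_used = n,
       method = if (use_exact) "exact" else "normal approximation",
       degenerate = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with a two-sided p-value from the
#' t-approximation. Backed by [stats::cor.test()].
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return List: `r`, `p`, `n`, and `defined = FALSE` when either input is
#'   constant.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = n, defined = TRUE)
}

#' Nonparametric ROC analysis of one candidate predictor
#'
#' AUC as the Mann-Whitney pair statistic (ties count one half) under the
#' stated orientation, its standard error by the Hanley-McNeil formula, and
#' a two-sided normal test of AUC against 0.5.
#'
#' @param controls,cases Predictor values in the two groups.
#' @param orientation `"lower"` if lower values indicate a case (the usual
#'   direction for BMD), `"higher"` otherwise.
#' @return Object of class `roc_result`: `auc`, `se`, `p`, group sizes and
#'   the orientation.
#' @export
roc_auc <- function(controls, cases, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  controls <- controls[!is.na(controls)]
  cases <- cases[!is.na(cases)]
  n0 <- length(controls); n1 <- length(cases)
  if (n0 == 0L || n1 == 0L) stop("both groups must be non-empty")
  sgn <- if (orientation == "lower") -1 else 1
  r <- rank(c(sgn * controls, sgn * cases))
  auc <- (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n0 * n1))
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se)
       else if (abs(auc - 0.5) < .Machine$double.eps) 1 else 0
  structure(list(auc = auc, se = se, p = p, n_controls = n0, n_cases = n1,
                 orientation = orientation),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (SE %.3f), p vs 0.5 = %.4g; %d controls / %d cases; %s value indicates case\n",
              x$auc, x$se, x$p, x$n_controls, x$n_cases, x$orientation))
  invisible(x)
}

#' Odds ratio per SD decrease from univariate logistic regression
#'
#' Fits case status on the standardized, sign-flipped predictor
#' `(mean - x) / SD` so that the odds ratio is per one-SD decrease, with a
#' Wald 95% confidence interval. The scaling SD is the pooled whole-sample
#' SD by default.
#'
#' @param values Predictor values.
#' @param status 0/1 (or logical) case status.
#' @param sd_scale Scaling SD; default `sd(values)`.
#' @return Object of class `or_result`: `or`, `ci` (length 2), `p` (Wald),
#'   `sd_scale`, `coef`, and `separation = TRUE` with infinite CI markers
#'   under complete separation.
#' @export
or_per_sd <- function(values, status, sd_scale = NULL) {
  ok <- stats::complete.cases(values, status)
  values <- values[ok]; status <- as.integer(status[ok])
  if (length(unique(status)) != 2L) stop("both statuses must be present")
  if (is.null(sd_scale)) sd_scale <- stats::sd(values)
  if (!is.finite(sd_scale) || sd_scale <= 0) stop("scaling SD must be positive")
  z <- (mean(values) - values) / sd_scale
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(status ~ z, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- stats::coef(fit)[["z"]]
  se <- sqrt(stats::vcov(fit)["z", "z"])
  ci <- exp(b + c(-1, 1) * stats::qnorm(0.975) * se)
  p <- 2 * stats::pnorm(-abs(b / se))
  if (separated) ci <- c(0, Inf)
  structure(list(or = exp(b), ci = ci, p = p, sd_scale = sd_scale,
                 coef = b, se = se, separation = separated),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR per SD decrease %.3f (95%% CI %.3f-%.3f), Wald p = %.4g%s\n",
              x$or, x$ci[1], x$ci[2], x$p,
              if (x$separation) " [complete separation]" else ""))
  invisible(x)
}

#' Forward stepwise logistic regression
#'
#' Forward selection on candidate predictors: at each step the candidate
#' with the smallest Rao score-test p-value (given the current model) is
#' entered if that p-value is below `p_enter`; selection stops otherwise.
#' Ties are broken by candidate order. The final model is refit and each
#' entered predictor is reported with its Wald p-value and its odds ratio
#' per SD decrease (with Wald 95% CI), scaled by the whole-sample SD.
#'
#' @param data Data frame of candidate predictors (numeric columns).
#' @param status 0/1 (or logical) case status.
#' @param candidates Column names to consider; default all columns.
#' @param p_enter Entry threshold on the score-test p-value.
#' @return Object of class `stepwise_logit`: `entered` (in entry order),
#'   `entry_p`, a per-predictor `summary` data frame (coefficient, OR per
#'   SD decrease, CI, Wald p), the final `fit`, and `p_enter`. An empty
#'   model (no candidate passes at step 1) is a valid result.
#' @export
stepwise_logistic <- function(data, status, candidates = names(data),
                              p_enter = 0.05) {
  stopifnot(length(candidates) >= 1L)
  flags <- new.env(parent = emptyenv()); flags$separation <- FALSE
  quiet_glm <- function(expr) withCallingHandlers(expr, warning = function(w) {
    msg <- conditionMessage(w)
    if (grepl("fitted probabilities numerically 0 or 1|did not converge", msg)) {
      if (grepl("fitted probabilities", msg)) flags$separation <- TRUE
      invokeRestart("muffleWarning")
    }
  })
  ok <- stats::complete.cases(data[candidates]) & !is.na(status)
  df <- data[ok, candidates, drop = FALSE]
  df$.status <- as.integer(status[ok])
  entered <- character(0)
  entry_p <- numeric(0)
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    base_f <- if (length(entered))
      stats::reformulate(entered, ".status") else .status ~ 1
    fit0 <- quiet_glm(stats::glm(base_f, family = stats::binomial(), data = df))
    ps <- vapply(remaining, function(v) {
      fit1 <- quiet_glm(
        stats::update(fit0, stats::reformulate(c(entered, v), ".status")))
      stats::anova(fit0, fit1, test = "Rao")[["Pr(>Chi)"]][2]
    }, numeric(1))
    j <- which.min(ps)
    if (!is.finite(ps[j]) || ps[j] >= p_enter) break
    entered <- c(entered, remaining[j])
    entry_p <- c(entry_p, ps[[j]])
    remaining <- setdiff(remaining, remaining[j])
  }
  if (length(entered)) {
    fit <- quiet_glm(stats::glm(stats::reformulate(entered, ".status"),
                                family = stats::binomial(), data = df))
    cf <- summary(fit)$coefficients
    smry <- do.call(rbind, lapply(entered, function(v) {
      b <- cf[v, "Estimate"]; se <- cf[v, "Std. Error"]
      s <- stats::sd(df[[v]])
      lim <- sort(exp(-s * (b + c(-1, 1) * stats::qnorm(0.975) * se)))
      data.frame(predictor = v, coef = b,
                 or_per_sd_decrease = exp(-b * s),
                 ci_low = lim[1], ci_high = lim[2],
                 p_wald = cf[v, "Pr(>|z|)"], stringsAsFactors = FALSE)
    }))
  } else {
    fit <- stats::glm(.status ~ 1, family = stats::binomial(), data = df)
    smry <- data.frame(predictor = character(0), coef = numeric(0),
                       or_per_sd_decrease = numeric(0), ci_low = numeric(0),
                       ci_high = numeric(0), p_wald = numeric(0))
  }
  structure(list(entered = entered, entry_p = entry_p, summary = smry,
                 fit = fit, p_enter = p_enter, n = nrow(df),
                 separation_seen = flags$separation),
            class = "stepwise_logit")
}

#' @export
print.stepwise_logit <- function(x, ...) {
  if (!length(x$entered)) {
    cat("Stepwise logistic regression: no predictor entered (all score p >=",
        x$p_enter, ")\n")
  } else {
    cat("Stepwise logistic regression (entry order, score-test entry p <",
        x$p_enter, "):\n")
    s <- x$summary
    s$entry_p <- x$entry_p
    print.data.frame(
      data.frame(predictor = s$predictor,
                 or_per_sd_decrease = round(s$or_per_sd_decrease, 3),
                 ci = sprintf("%.2f-%.2f", s$ci_low, s$ci_high),
                 p_wald = signif(s$p_wald, 3),
                 entry_p = signif(s$entry_p, 3)),
      row.names = FALSE)
  }
  invisible(x)
}

#' Simulate the AUC sampling distribution of a two-group normal model
#'
#' Draws `reps` case-control cohorts of `n` per group from the stated
#' group normals (optionally truncated at zero, as appropriate for
#' volumetric fat measures whose SDs approach their means) and computes
#' the nonparametric AUC of each cohort. Used to place a printed AUC from
#' a small matched study within its own sampling distribution.
#'
#' @param control_mean,control_sd,case_mean,case_sd Group parameters.
#' @param n Subjects per group.
#' @param reps Number of simulated cohorts.
#' @param orientation Passed to [roc_auc()].
#' @param truncate_at_zero Redraw negative values (truncated normal).
#' @param seed Integer seed.
#' @return Object of class `auc_simulation`: the vector of simulated
#'   `aucs`, their `median` and central 95% interval `ci95`, plus the
#'   simulation settings.
#' @export
simulate_auc_distribution <- function(control_mean, control_sd,
                                      case_mean, case_sd,
                                      n = 17L, reps = 2000L,
                                      orientation = "lower",
                                      truncate_at_zero = FALSE,
                                      seed = 1L) {
  if (n < 1L || reps < 1L) stop("n and reps must be positive")
  set.seed(as.integer(seed))
  draw <- function(m, s) {
    x <- stats::rnorm(n, m, s)
    if (truncate_at_zero) {
      while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), m, s)
    }
    x
  }
  aucs <- vapply(seq_len(reps), function(i) {
    roc_auc(draw(control_mean, control_sd), draw(case_mean, case_sd),
            orientation = orientation)$auc
  }, numeric(1))
  structure(list(aucs = aucs, median = stats::median(aucs),
                 ci95 = unname(stats::quantile(aucs, c(0.025, 0.975))),
                 n = n, reps = reps, orientation = orientation,
                 truncate_at_zero = truncate_at_zero, seed = seed),
            class = "auc_simulation")
}

#' @export
print.auc_simulation <- function(x, ...) {
  cat(sprintf("Simulated AUC sampling distribution (%d cohorts of %d + %d):\n",
              x$reps, x$n, x$n))
  cat(sprintf("  median %.3f, central 95%% interval %.3f-%.3f\n",
              x$median, x$ci95[1], x$ci95[2]))
  invisible(x)
}
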