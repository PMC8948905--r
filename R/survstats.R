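#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] into a tidy step-function table, optionally
#' stratified by group. Censoring tied with an event time is handled
#' events-first, the product-limit convention.
#'
#' @param time non-negative event/censoring times (years).
#' @param event logical (or 0/1) event indicators.
#' @param group optional grouping labels.
#' @return A data.frame of class `km_curve` with columns `group` (if
#'   given), `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  time <- as.numeric(time)
  if (length(time) == 0) stop("empty sample")
  if (any(is.na(time)) || any(time < 0) || any(!is.finite(time))) {
    stop("times must be finite and non-negative")
  }
  event <- as.logical(event)
  if (length(event) != length(time)) stop("times and events differ in length")
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  } else {
    g <- factor(group)
    if (length(g) != length(time)) stop("group length mismatch")
    fit <- survival::survfit(survival::Surv(time, event) ~ g)
    strata <- rep(names(fit$strata), fit$strata)
    out <- data.frame(group = sub("^g=", "", strata), time = fit$time,
                      n_risk = fit$n.risk, n_event = fit$n.event,
                      n_censor = fit$n.censor, surv = fit$surv)
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test between survival curves
#'
#' Standard unweighted log-rank test; the statistic is compared to a
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group grouping labels, at least two non-empty groups.
#' @return list with `statistic`, `df`, `p_value`, `n`, `n_events`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) < 2) stop("log-rank needs at least two non-empty groups")
  if (any(table(g) == 0)) stop("log-rank group with zero members")
  event <- as.logical(event)
  if (sum(event) < 1) stop("log-rank needs at least one event")
  sd <- survival::survdiff(survival::Surv(as.numeric(time), event) ~ g)
  df <- nlevels(g) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = length(time), n_events = sum(event))
}

#' Univariable Cox model for a binary high-risk indicator
#'
#' Fits a proportional-hazards model by partial-likelihood maximization
#' with Efron handling of ties, returning the hazard ratio with its Wald
#' 95% confidence interval on the log scale. Degenerate fits (monotone
#' likelihood / complete separation, or non-convergence) raise an error
#' rather than returning an extreme estimate.
#'
#' @inheritParams km_estimate
#' @param highrisk logical (or 0/1): TRUE for the high-risk group.
#' @return list of class `cox_fit` with `coefficient`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `n_events`.
#' @export
cox_fit <- function(time, event, highrisk) {
  highrisk <- as.logical(highrisk)
  event <- as.logical(event)
  if (length(unique(highrisk)) < 2) stop("both covariate levels must be present")
  if (sum(event) < 1) stop("no events: hazard ratio is not estimable")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(as.numeric(time), event) ~ highrisk,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        stop("Cox fit did not converge (possible complete separation): ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) {
    stop("Cox fit did not converge (degenerate estimate)")
  }
  structure(list(
    coefficient = beta, se = se, hr = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    n = length(time), n_events = sum(event)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH (high vs low/moderate): HR %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$hr, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  invisible(x)
}

#' ROC curve and AUC for an ordinal risk score
#'
#' The AUC is the Mann-Whitney probability that a random case outranks a
#' random non-case, ties counted 1/2 (midrank formula). The curve has one
#' operating point per "predict positive at or above this level" rule,
#' plus the trivial corners; for the three-level risk scores that is at
#' most two interior points.
#'
#' @param scores ordinal scores: numeric, ordered factor, or the category
#'   labels `"low"`/`"moderate"`/`"high"`.
#' @param outcome logical (or 0/1) event indicators; both classes required.
#' @return list of class `roc_ordinal` with `auc` and `curve`
#'   (data.frame `threshold`, `fpr`, `tpr`).
#' @export
auc_ordinal <- function(scores, outcome) {
  if (is.character(scores) && all(scores %in% risk_levels())) {
    scores <- risk_rank(scores)
  }
  scores <- as.numeric(if (is.factor(scores)) unclass(scores) else scores)
  outcome <- as.logical(outcome)
  if (length(scores) != length(outcome)) stop("scores and outcome differ in length")
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)
  auc <- (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[!outcome] >= t), 0)),
    tpr = c(0, vapply(thr, function(t) mean(scores[outcome] >= t), 0))
  )
  structure(list(auc = auc, curve = curve), class = "roc_ordinal")
}

#' @export
print.roc_ordinal <- function(x, ...) {
  cat(sprintf("ordinal ROC: AUC = %.3f (%d operating points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

#' 2x2 confusion matrix
#'
#' @param tp,fp,fn,tn non-negative integer cell counts (true/false
#'   positives, false/true negatives).
#' @return list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion-matrix cells must be non-negative integers")
  }
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("2x2: tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Diagnostic metrics of a 2x2 table
#'
#' @param cm a [confusion_matrix()], or `tp` when the four counts are
#'   given positionally.
#' @param fp,fn,tn optional counts when not passing a `confusion_matrix`.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`. A metric
#'   with a zero denominator is `NA` with a warning naming it.
#' @examples
#' confusion_metrics(confusion_matrix(tp = 9, fp = 18, fn = 4, tn = 42))
#' @export
confusion_metrics <- function(cm, fp = NULL, fn = NULL, tn = NULL) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion_matrix(cm, fp, fn, tn)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning("undefined metric (zero denominator): ", what, call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  list(sensitivity = safe(cm$tp, cm$tp + cm$fn, "sensitivity"),
       specificity = safe(cm$tn, cm$tn + cm$fp, "specificity"),
       ppv = safe(cm$tp, cm$tp + cm$fp, "ppv"),
       npv = safe(cm$tn, cm$tn + cm$fn, "npv"))
}

#' Reconstruct a 2x2 table from published summary numbers
#'
#' Inverts the usual reporting of a diagnostic validation: given the cohort
#' size, the number of events, the number of score-positive (high-risk)
#' patients and the printed sensitivity, the four cells follow by
#' arithmetic. `tp` is rounded half away from zero.
#'
#' @param n total patients.
#' @param d number of events.
#' @param n_positive number of high-risk (test-positive) patients.
#' @param sensitivity printed sensitivity in `[0, 1]`.
#' @return A [confusion_matrix()]. Inconsistent summaries (any negative
#'   cell) raise an error.
#' @examples
#' reconstruct_confusion(73, 13, 27, 0.692)  # tp=9 fp=18 fn=4 tn=42
#' @export
reconstruct_confusion <- function(n, d, n_positive, sensitivity) {
  if (d < 0 || d > n || n_positive < 0 || n_positive > n ||
      sensitivity < 0 || sensitivity > 1) {
    stop("invalid summary inputs")
  }
  tp <- floor(sensitivity * d + 0.5)   # round half away from zero (all >= 0)
  fn <- d - tp
  fp <- n_positive - tp
  tn <- n - d - fp
  if (min(tp, fn, fp, tn) < 0) {
    stop("inconsistent summaries: reconstruction yields a negative cell")
  }
  confusion_matrix(tp, fp, fn, tn)
}

#' Cohen's kappa for two binary raters
#'
#' Unweighted kappa, `(p_o - p_e) / (1 - p_e)`, with `p_e` the chance
#' agreement from the raters' marginals. When both raters are the same
#' constant (`p_e = 1`, perfect agreement) kappa is 1 by convention.
#'
#' @param rater_a,rater_b logical (or 0/1) vectors of equal length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(rater_a, rater_b) {
  a <- as.logical(rater_a); b <- as.logical(rater_b)
  if (length(a) != length(b)) stop("rater vectors differ in length")
  n <- length(a)
  if (n < 1 || anyNA(a) || anyNA(b)) stop("raters must be non-empty and complete")
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}
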