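#' ROC curve and AUC
#'
#' Candidate thresholds are -Inf, the midpoints between adjacent
#' distinct scores, and +Inf; a sample is called positive (predicted
#' C2 / high-risk) when its score is >= the threshold. The AUC is the
#' Mann-Whitney probability estimate computed from average ranks, which
#' equals the trapezoidal area under the empirical ROC (ties count 1/2)
#' and is invariant under strictly monotone score transforms.
#'
#' @param scores Numeric scores (higher = more C2-like).
#' @param labels 0/1 vector (1 = C2).
#' @return Object of class `cms_roc`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, plus the input `scores`/`labels`.
#' @export
roc_auc <- function(scores, labels) {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2L)
    stop("ROC requires both classes present")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), 0)
  structure(list(thresholds = thr, sensitivity = sens,
                 specificity = spec, auc = auc_rank(scores, labels),
                 scores = scores, labels = labels),
            class = "cms_roc")
}

#' @export
print.cms_roc <- function(x, ...) {
  cat("ROC over", length(x$scores), "samples; AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Youden cutoff
#'
#' The threshold maximizing Youden's J = sensitivity + specificity - 1
#' over the ROC's candidate thresholds. On ties the lowest qualifying
#' threshold is returned, which assigns patients to high-risk only when
#' forced. Scores >= the cutoff are called high-risk (predicted C2).
#'
#' @param roc A [roc_auc()] result.
#' @return The cutoff (numeric scalar).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "cms_roc"))
  if (length(unique(roc$scores)) < 2L)
    stop("all scores identical: no informative cutoff")
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  min(roc$thresholds[best])
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit estimates per group for right-censored data, and the
#' two-sided log-rank chi-square with `groups - 1` degrees of freedom.
#'
#' @param time Follow-up time (days), >= 0.
#' @param event 0 = censored, 1 = event.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List: `curves` (data frame group/time/n_risk/n_event/surv),
#'   `statistic`, `df`, `p_value`.
#' @export
km_logrank <- function(time, event, group) {
  ok <- !(is.na(time) | is.na(event) | is.na(group))
  time <- time[ok]; event <- event[ok]; group <- factor(group[ok])
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  if (any(table(group) == 0L)) stop("a group has zero subjects")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata_lab <- sub("^group=", "", rep(names(fit$strata), fit$strata))
  curves <- data.frame(group = strata_lab, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  list(curves = curves, statistic = unname(sd$chisq), df = df,
       p_value = p)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Breslow tie approximation.
#' Categorical covariates are expanded against declared reference
#' levels (conventional defaults: HPV-16, stage I, lowest-intensity
#' treatment).
#'
#' @param data Data frame holding time, event and covariate columns.
#' @param time_col,event_col Column names of the endpoint.
#' @param covariates Character vector of covariate column names.
#' @param reference_levels Named list, e.g.
#'   `list(stage = "I", hpv_type = "HPV16")`.
#' @return List: `table` (data frame term/hr/ci_low/ci_high/p/n/n_event),
#'   `fit` (the `coxph` object), `converged`.
#' @export
fit_coxph <- function(data, time_col, event_col, covariates,
                      reference_levels = list()) {
  keep <- stats::complete.cases(data[c(time_col, event_col, covariates)])
  data <- data[keep, , drop = FALSE]
  if (sum(data[[event_col]]) < 1) stop("no events: cannot fit Cox model")
  for (cv in covariates) {
    if (is.character(data[[cv]]) || is.factor(data[[cv]])) {
      data[[cv]] <- factor(data[[cv]])
      ref <- reference_levels[[cv]]
      if (!is.null(ref) && ref %in% levels(data[[cv]]))
        data[[cv]] <- stats::relevel(data[[cv]], ref = ref)
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "breslow")
  sm <- summary(fit)
  converged <- all(is.finite(sm$coefficients[, "se(coef)"])) &&
    all(abs(sm$coefficients[, "coef"]) < 15)
  if (!converged)
    warning("possible separation/collinearity: unstable coefficients")
  tab <- data.frame(term = rownames(sm$coefficients),
                    hr = sm$coefficients[, "exp(coef)"],
                    ci_low = sm$conf.int[, "lower .95"],
                    ci_high = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$n <- sm$n; tab$n_event <- sm$nevent
  list(table = tab, fit = fit, converged = converged)
}

#' Concordance indices and DeLong comparison of two classifications
#'
#' Harrell's C (comparable pairs only; higher score assumed to carry
#' higher risk) is computed per score vector against the survival
#' endpoint. DeLong's two-sided test compares the two classifiers'
#' AUCs against the binary CMS-class endpoint. When the two score
#' vectors are identical the AUC difference has zero variance and the
#' p-value is defined as 1.
#'
#' @param scores_a,scores_b Two score vectors over the same subjects.
#' @param time,event Survival endpoint (optional; NULL skips the
#'   C-index).
#' @param labels 0/1 CMS labels for the DeLong AUC comparison.
#' @return List: `c_index_a`, `c_index_b`, `auc_a`, `auc_b`,
#'   `delong_p`.
#' @export
cindex_delong <- function(scores_a, scores_b, time = NULL, event = NULL,
                          labels = NULL) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must cover the same subjects")
  c_a <- c_b <- NA_real_
  if (!is.null(time)) {
    if (sum(event) == 0 && length(unique(time)) == 1L)
      stop("no comparable pairs in the survival data")
    df <- data.frame(time = time, event = event, a = scores_a,
                     b = scores_b)
    # reverse: higher score = higher risk = shorter survival
    c_a <- survival::concordance(survival::Surv(time, event) ~ a,
                                 data = df, reverse = TRUE)$concordance
    c_b <- survival::concordance(survival::Surv(time, event) ~ b,
                                 data = df, reverse = TRUE)$concordance
  }
  auc_a <- auc_b <- delong_p <- NA_real_
  if (!is.null(labels)) {
    auc_a <- auc_rank(scores_a, labels)
    auc_b <- auc_rank(scores_b, labels)
    if (isTRUE(all.equal(scores_a, scores_b))) {
      delong_p <- 1
    } else {
      ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<")
      rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<")
      tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
      delong_p <- as.numeric(tst$p.value)
      if (!is.finite(delong_p)) delong_p <- 1
    }
  }
  list(c_index_a = c_a, c_index_b = c_b, auc_a = auc_a, auc_b = auc_b,
       delong_p = delong_p)
}

#' Stratify scored patients and test survival separation
#'
#' Applies the Youden cutoff learned on the discovery scores to the
#' validation scores, then runs KM + log-rank on the requested endpoint.
#'
#' @param discovery_scores,discovery_labels Scores and 0/1 CMS labels of
#'   the discovery set (cutoff selection).
#' @param validation_scores Scores of the held-out cohort.
#' @param time,event Endpoint of the held-out cohort, aligned with
#'   `validation_scores`.
#' @return List: `cutoff`, `group` (low-/high-risk per validation
#'   patient), `km` (from [km_logrank()]).
#' @export
stratify_survival <- function(discovery_scores, discovery_labels,
                              validation_scores, time, event) {
  cutoff <- youden_cutoff(roc_auc(discovery_scores, discovery_labels))
  group <- ifelse(validation_scores >= cutoff, "high-risk", "low-risk")
  if (length(unique(group)) < 2L)
    return(list(cutoff = cutoff, group = group, km = NULL))
  list(cutoff = cutoff, group = group,
       km = km_logrank(time, event, group))
}
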