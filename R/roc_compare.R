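#' In-sample predicted probabilities from a logistic fit
#'
#' @param fit A converged `logistic_fit`.
#' @param X Design matrix, column-compatible with the fit.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predicted_probabilities <- function(fit, X) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  X <- as.matrix(X)
  if (ncol(X) != length(fit$beta)) {
    stop("design matrix has ", ncol(X), " columns but fit has ",
         length(fit$beta), " coefficients", call. = FALSE)
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), names(fit$beta))) {
    stop("design matrix columns do not match fit coefficients",
         call. = FALSE)
  }
  stats::plogis(drop(X %*% fit$beta))
}

check_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("scores/labels contain missing values", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos < 1L || n_neg < 1L) {
    stop("need at least one case and one control", call. = FALSE)
  }
  list(n_pos = n_pos, n_neg = n_neg)
}

#' Mann-Whitney AUC
#'
#' The area under the ROC curve as the two-sample concordance probability:
#' over all case-control pairs, the fraction where the case scores higher,
#' counting ties as 1/2. Computed by the rank formulation, which equals the
#' all-pairs count.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 outcome labels (1 = case).
#' @return List: `auc`, `n_pos`, `n_neg`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  n <- check_labels(scores, labels)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n$n_pos * (n$n_pos + 1) / 2) /
    (n$n_pos * n$n_neg)
  list(auc = auc, n_pos = n$n_pos, n_neg = n$n_neg)
}

# DeLong structural components via midranks: V10 (one per case) is the mean
# over controls of the pairwise kernel (1 if case > control, 1/2 tie, 0
# else); V01 symmetric. mean(V10) = mean(V01) = AUC.
delong_components <- function(scores, labels) {
  n <- check_labels(scores, labels)
  pos <- labels == 1
  tz <- rank(scores, ties.method = "average")
  tx <- rank(scores[pos], ties.method = "average")
  ty <- rank(scores[!pos], ties.method = "average")
  v10 <- (tz[pos] - tx) / n$n_neg
  v01 <- 1 - (tz[!pos] - ty) / n$n_pos
  list(v10 = v10, v01 = v01, n_pos = n$n_pos, n_neg = n$n_neg,
       auc = mean(v10))
}

#' Standard error of an AUC
#'
#' `"delong"` uses the structural-components variance
#' var(V10)/n_pos + var(V01)/n_neg. `"hanley_mcneil"` uses the closed form
#' in the AUC and the class counts, with Q1 = A/(2-A) and
#' Q2 = 2A^2/(1+A).
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 outcome labels.
#' @param method `"delong"` (default) or `"hanley_mcneil"`.
#' @return Standard error (scalar).
#' @export
auc_standard_error <- function(scores, labels,
                               method = c("delong", "hanley_mcneil")) {
  method <- match.arg(method)
  n <- check_labels(scores, labels)
  if (method == "delong") {
    if (n$n_pos < 2L || n$n_neg < 2L) {
      stop("DeLong variance needs at least 2 cases and 2 controls",
           call. = FALSE)
    }
    comp <- delong_components(scores, labels)
    sqrt(stats::var(comp$v10) / comp$n_pos +
           stats::var(comp$v01) / comp$n_neg)
  } else {
    a <- auc_mann_whitney(scores, labels)$auc
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    sqrt((a * (1 - a) + (n$n_pos - 1) * (q1 - a^2) +
            (n$n_neg - 1) * (q2 - a^2)) / (n$n_pos * n$n_neg))
  }
}

#' Full ROC summary for one score vector
#'
#' AUC, standard error and a 95% (by default) confidence interval. Linear
#' CIs (auc +- z * se) are truncated to \[0, 1\]; `ci = "logit"` transforms
#' instead.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 outcome labels.
#' @param se_method Passed to [auc_standard_error()].
#' @param level Confidence level.
#' @param ci `"linear"` (default) or `"logit"`.
#' @return A `roc_result`: `auc`, `se`, `ci_low`, `ci_high`, `n_pos`,
#'   `n_neg`.
#' @export
roc_result <- function(scores, labels,
                       se_method = c("delong", "hanley_mcneil"),
                       level = 0.95, ci = c("linear", "logit")) {
  ci <- match.arg(ci)
  a <- auc_mann_whitney(scores, labels)
  se <- auc_standard_error(scores, labels, se_method)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  if (ci == "linear") {
    lo <- max(0, a$auc - zq * se)
    hi <- min(1, a$auc + zq * se)
  } else {
    if (a$auc <= 0 || a$auc >= 1 || se == 0) {
      lo <- hi <- a$auc
    } else {
      la <- stats::qlogis(a$auc)
      lse <- se / (a$auc * (1 - a$auc))
      lo <- stats::plogis(la - zq * lse)
      hi <- stats::plogis(la + zq * lse)
    }
  }
  structure(list(auc = a$auc, se = se, ci_low = lo, ci_high = hi,
                 n_pos = a$n_pos, n_neg = a$n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%.3f-%.3f), se = %.4f, %d cases / %d controls\n",
              x$auc, x$ci_low, x$ci_high, x$se, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare the AUCs of two risk models on the same outcome
#'
#' `"independent"` treats the two AUCs as independent:
#' z = (auc1 - auc2) / sqrt(se1^2 + se2^2). `"paired_delong"` subtracts
#' twice the covariance of the paired DeLong structural components from the
#' variance of the difference, which is the correct test when both models
#' score the same patients. Both score vectors must be aligned to the same
#' label vector.
#'
#' @param scores1,scores2 Risk scores of the two models over the same
#'   records.
#' @param labels Shared 0/1 outcome labels.
#' @param method `"independent"` (default) or `"paired_delong"`.
#' @return An `auc_comparison`: `auc1`, `auc2` (`roc_result`s), `z`, `p`,
#'   `method`.
#' @export
compare_aucs <- function(scores1, scores2, labels,
                         method = c("independent", "paired_delong")) {
  method <- match.arg(method)
  r1 <- roc_result(scores1, labels)
  r2 <- roc_result(scores2, labels)
  if (method == "independent") {
    v <- r1$se^2 + r2$se^2
  } else {
    c1 <- delong_components(scores1, labels)
    c2 <- delong_components(scores2, labels)
    cv <- stats::cov(c1$v10, c2$v10) / c1$n_pos +
      stats::cov(c1$v01, c2$v01) / c1$n_neg
    v <- r1$se^2 + r2$se^2 - 2 * cv
  }
  d <- r1$auc - r2$auc
  if (v <= 0) {
    if (abs(d) > .Machine$double.eps^0.5) {
      stop("zero variance of the AUC difference with unequal AUCs: ",
           "z undefined", call. = FALSE)
    }
    z <- 0
  } else {
    z <- d / sqrt(v)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(auc1 = r1, auc2 = r2, z = z, p = p, method = method),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC comparison (%s): %.3f vs %.3f, z = %.3f, p = %.4g\n",
              x$method, x$auc1$auc, x$auc2$auc, x$z, x$p))
  invisible(x)
}

#' Discrimination band of an AUC
#'
#' Rule-of-thumb banding: AUC < 0.7 poor; 0.7 <= AUC < 0.8 fair;
#' AUC >= 0.8 good.
#'
#' @param auc Numeric AUC values in \[0, 1\].
#' @return Character vector in \{"poor", "fair", "good"\}.
#' @export
discrimination_band <- function(auc) {
  if (any(auc < 0 | auc > 1, na.rm = TRUE)) {
    stop("AUC must lie in [0, 1]", call. = FALSE)
  }
  ifelse(auc < 0.7, "poor", ifelse(auc < 0.8, "fair", "good"))
}
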