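#' Design specification for an outcome model
#'
#' Defines the ordered covariate terms of a logistic model. Supported terms:
#' `intercept`; `age` (years, linear); `sex` (indicator, female reference);
#' `tertile` (two indicators for medium and high FI risk, low reference);
#' `asa` (pre-operative ASA class, linear 1--5 by default or two indicators
#' for III and IV/V with I/II reference under categorical coding); `fi`
#' (continuous FI score). Reference categories never appear as columns, and
#' design columns follow the listed term order.
#'
#' @param terms Character vector of term names, in order.
#' @param asa_coding `"linear"` or `"categorical"`; only used if `"asa"` is
#'   among the terms.
#' @return A `design_spec` object.
#' @export
design_spec <- function(terms = c("intercept", "tertile", "age", "sex"),
                        asa_coding = c("linear", "categorical")) {
  asa_coding <- match.arg(asa_coding)
  allowed <- c("intercept", "age", "sex", "tertile", "asa", "fi")
  bad <- setdiff(terms, allowed)
  if (length(bad)) {
    stop("unknown design terms: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(terms)) stop("duplicate design terms", call. = FALSE)
  structure(list(terms = terms, asa_coding = asa_coding),
            class = "design_spec")
}

#' Build the design matrix and outcome vector for one model
#'
#' Applies complete-covariate analysis per model: rows with a missing
#' outcome, missing or unassigned tertile/FI (where used), or unknown ASA
#' (where ASA is a covariate) are dropped. For the new-nursing-home outcome
#' the missing-outcome rule automatically excludes patients admitted from a
#' nursing home, for whom that outcome is undefined.
#'
#' @param data data.frame containing the outcome column and the covariate
#'   columns needed by `spec` (`age`, `sex`, `tertile`, `asa`, `fi`).
#' @param outcome Name of the 0/1 outcome column.
#' @param spec A [design_spec()].
#' @return List: `X` (numeric design matrix), `y` (0/1 vector), `n` (rows
#'   retained), `rows` (logical keep-mask over `data`).
#' @export
build_design <- function(data, outcome, spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  if (!outcome %in% names(data)) {
    stop("outcome column not found: ", outcome, call. = FALSE)
  }
  y <- data[[outcome]]
  keep <- !is.na(y)
  for (term in spec$terms) {
    keep <- keep & switch(term,
      intercept = TRUE,
      age = !is.na(data$age),
      sex = !is.na(data$sex),
      tertile = !is.na(data$tertile),
      asa = !is.na(data$asa) & data$asa != "unknown",
      fi = !is.na(data$fi)
    )
  }
  if (!any(keep)) stop("zero rows retained for model", call. = FALSE)
  d <- data[keep, , drop = FALSE]
  cols <- list()
  for (term in spec$terms) {
    cols <- c(cols, switch(term,
      intercept = list("(Intercept)" = rep(1, nrow(d))),
      age = list(age = as.numeric(d$age)),
      sex = {
        if (length(unique(d$sex)) < 2L) {
          stop("covariate 'sex' has a single level in retained rows",
               call. = FALSE)
        }
        list(sexmale = as.numeric(d$sex == "male"))
      },
      tertile = {
        if (length(unique(as.character(d$tertile))) < 2L) {
          stop("covariate 'tertile' has a single level in retained rows",
               call. = FALSE)
        }
        list(tertilemedium = as.numeric(d$tertile == "medium"),
             tertilehigh = as.numeric(d$tertile == "high"))
      },
      asa = {
        asa_num <- as.integer(as.character(d$asa))
        if (length(unique(asa_num)) < 2L) {
          stop("covariate 'asa' has a single level in retained rows",
               call. = FALSE)
        }
        if (spec$asa_coding == "linear") {
          list(asa = as.numeric(asa_num))
        } else {
          list(asa_iii = as.numeric(asa_num == 3L),
               asa_iv_v = as.numeric(asa_num >= 4L))
        }
      },
      fi = list(fi = as.numeric(d$fi))
    ))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, y = as.numeric(d[[outcome]]), n = nrow(d), rows = keep)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with step-halving, so the deviance trace
#' is non-increasing. Convergence is declared when the deviance changes by
#' less than `tol` between iterations. The coefficient covariance is the
#' inverse observed information at the optimum. Any coefficient magnitude
#' exceeding `separation_bound` rejects the fit as (quasi-)separated: no
#' plausible clinical odds ratio approaches exp(15), and under separation
#' the deviance flattens while the coefficients diverge.
#'
#' @param X Numeric design matrix, full column rank.
#' @param y 0/1 outcome vector, `length(y) == nrow(X)`.
#' @param tol Deviance-change convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @param separation_bound Coefficient-magnitude bound used to flag
#'   separation on convergence failure (default 15).
#' @return A `logistic_fit`: `beta`, `cov`, `n`, `converged`, `iterations`,
#'   `deviance`, `deviance_trace`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 100,
                         separation_bound = 15) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("X and y dimensions differ", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (all(y == 0) || all(y == 1)) {
    stop("outcome is single-class; logistic MLE does not exist",
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  p <- ncol(X)
  beta <- rep(0, p)
  dev <- function(b) {
    eta <- drop(X %*% b)
    # numerically stable -2*loglik: log(1+exp(eta)) - y*eta
    2 * sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
  }
  d_old <- dev(beta)
  trace <- d_old
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(X * w)
    step <- drop(solve(xtw %*% X, xtw %*% z)) - beta
    d_new <- dev(beta + step)
    halvings <- 0L
    while (d_new > d_old + 1e-12 && halvings < 30L) {
      step <- step / 2
      d_new <- dev(beta + step)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    trace <- c(trace, d_new)
    if (abs(d_old - d_new) < tol) {
      converged <- TRUE
      d_old <- d_new
      break
    }
    d_old <- d_new
  }
  if (max(abs(beta)) > separation_bound) {
    # under (quasi-)separation the deviance can flatten out while the
    # coefficients run away, so the bound is checked regardless of the
    # deviance-based convergence flag
    stop("coefficient magnitude exceeds ", separation_bound,
         ": data are (quasi-)separated", call. = FALSE)
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  info <- t(X * w) %*% X
  covb <- solve(info)
  covb <- (covb + t(covb)) / 2
  names(beta) <- colnames(X)
  dimnames(covb) <- list(colnames(X), colnames(X))
  structure(list(beta = beta, cov = covb, n = nrow(X),
                 converged = converged, iterations = iter,
                 deviance = d_old, deviance_trace = trace),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, deviance = %.4f, %s in %d iterations\n",
              x$n, x$deviance,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(round(x$beta, 4))
  invisible(x)
}

#' Adjusted odds ratios with Wald confidence intervals
#'
#' For every non-intercept term: aOR = exp(beta), Wald CI
#' exp(beta +- z * se), and a two-sided p-value from the Wald z statistic
#' against the standard normal.
#'
#' @param fit A converged `logistic_fit`.
#' @param level Confidence level, default 0.95.
#' @return data.frame: `term`, `aOR`, `ci_low`, `ci_high`, `p`.
#' @export
adjusted_odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) {
    stop("cannot extract odds ratios from a non-converged fit",
         call. = FALSE)
  }
  keep <- names(fit$beta) != "(Intercept)"
  b <- fit$beta[keep]
  se <- sqrt(diag(fit$cov))[keep]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- b / se
  data.frame(term = names(b),
             aOR = exp(b),
             ci_low = exp(b - zq * se),
             ci_high = exp(b + zq * se),
             p = 2 * stats::pnorm(-abs(z)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit one outcome model on a scored, outcome-annotated cohort
#'
#' Convenience wrapper: builds the design per `spec` and fits the logistic
#' model.
#'
#' @param data Scored cohort with outcome columns (see
#'   [prepare_analysis()]).
#' @param outcome Outcome column name.
#' @param spec A [design_spec()].
#' @param ... Passed to [fit_logistic()].
#' @return List: `fit` (`logistic_fit`), `design` (from [build_design()]),
#'   `outcome`, `spec`.
#' @export
fit_outcome_model <- function(data, outcome, spec = design_spec(), ...) {
  design <- build_design(data, outcome, spec)
  fit <- fit_logistic(design$X, design$y, ...)
  list(fit = fit, design = design, outcome = outcome, spec = spec)
}

#' Join FI scores and derived outcomes into one analysis table
#'
#' @param scored Scored admission table from [score_admissions()].
#' @return The scored table with the six outcome columns appended.
#' @export
prepare_analysis <- function(scored) {
  stopifnot(all(c("fi", "complete", "tertile") %in% names(scored)))
  out <- derive_outcomes(scored)
  stopifnot(identical(out$record_id, scored$record_id))
  # the derived 0/1 outcome replaces the raw yes/no/not_applicable field
  scored$new_nh_admission <- NULL
  cbind(scored, out[, setdiff(names(out), "record_id")])
}
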