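scored_fixture <- function() {
  data.frame(
    record_id = paste0("r", 1:9),
    age = c(70, 75, 80, 85, 90, 72, 78, 84, 66),
    sex = rep(c("female", "male", "female"), 3),
    asa = c("1", "2", "3", "4", "unknown", "2", "3", "3", "1"),
    fi = c(0.02, 0.03, 0.08, 0.10, 0.12, 0.20, 0.25, 0.30, 0.04),
    tertile = factor(c("low", "low", "medium", "medium", "medium",
                       "high", "high", "high", "low"),
                     levels = c("low", "medium", "high")),
    y = c(0, 0, 0, 1, 0, 1, 1, 0, 0),
    stringsAsFactors = FALSE
  )
}

test_that("the design matrix dummy-codes tertiles with low as reference", {
  d <- scored_fixture()[1:3, ]
  d$tertile <- factor(c("low", "medium", "high"),
                      levels = c("low", "medium", "high"))
  des <- build_design(d, "y", design_spec(c("intercept", "tertile")))
  expect_identical(colnames(des$X),
                   c("(Intercept)", "tertilemedium", "tertilehigh"))
  expect_equal(unname(des$X[, "tertilemedium"]), c(0, 1, 0))
  expect_equal(unname(des$X[, "tertilehigh"]), c(0, 0, 1))
})

test_that("unknown ASA rows are excluded only from ASA-containing models", {
  d <- scored_fixture()
  with_asa <- build_design(d, "y",
                           design_spec(c("intercept", "age", "asa")))
  expect_identical(with_asa$n, 8L)
  without_asa <- build_design(d, "y", design_spec(c("intercept", "age")))
  expect_identical(without_asa$n, 9L)
  cat_asa <- build_design(d, "y",
                          design_spec(c("intercept", "asa"), "categorical"))
  expect_identical(colnames(cat_asa$X),
                   c("(Intercept)", "asa_iii", "asa_iv_v"))
})

test_that("rows with undefined outcomes are dropped (new-nursing-home rule)", {
  d <- scored_fixture()
  d$new_nh <- c(0, 1, NA, 0, 1, 0, NA, 1, 0)
  des <- build_design(d, "new_nh", design_spec(c("intercept", "age")))
  expect_identical(des$n, 7L)
  d$all_na <- NA_real_
  expect_error(build_design(d, "all_na", design_spec(c("intercept"))),
               "zero rows")
  d$sex <- "female"
  expect_error(build_design(d, "y", design_spec(c("intercept", "sex"))),
               "sex")
})

test_that("the intercept-only MLE is the log-odds of the event rate", {
  y <- c(rep(1, 30), rep(0, 70))
  fit <- fit_logistic(matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")),
                      y)
  expect_equal(unname(fit$beta), log(30 / 70), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("a saturated 2x2 fit reproduces the closed-form odds ratio and Woolf variance", {
  # high-vs-low tertile delirium table: 649/3691 exposed events,
  # 266/4830 unexposed events
  dat <- two_by_two(649, 3691, 266, 4830)
  fit <- fit_logistic(dat$X, dat$y)
  or_closed <- (649 / 3042) / (266 / 4564)
  expect_equal(exp(unname(fit$beta["exposed"])), or_closed,
               tolerance = 1e-6)
  expect_equal(or_closed, 3.660578, tolerance = 1e-6)
  woolf_var <- 1 / 649 + 1 / 3042 + 1 / 266 + 1 / 4564
  expect_equal(unname(fit$cov["exposed", "exposed"]), woolf_var,
               tolerance = 1e-6)
  # Wald interval equals the Woolf interval
  ors <- adjusted_odds_ratios(fit)
  z <- qnorm(0.975)
  expect_equal(ors$ci_low, exp(log(or_closed) - z * sqrt(woolf_var)),
               tolerance = 1e-6)
  expect_equal(ors$ci_high, exp(log(or_closed) + z * sqrt(woolf_var)),
               tolerance = 1e-6)
})

test_that("IRLS agrees with stats::glm on random multi-covariate problems", {
  set.seed(33)
  for (i in 1:10) {
    n <- 400
    X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = runif(n),
               x3 = rbinom(n, 1, 0.4))
    beta <- c(-0.5, 0.8, -1.2, 0.5)
    y <- rbinom(n, 1, plogis(drop(X %*% beta)))
    fit <- fit_logistic(X, y)
    ref <- glm.fit(X, y, family = binomial())
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$deviance, ref$deviance, tolerance = 1e-6)
  }
})

test_that("the deviance trace is monotone non-increasing", {
  set.seed(44)
  X <- cbind("(Intercept)" = 1, x = rnorm(500), z = rnorm(500))
  y <- rbinom(500, 1, plogis(0.3 + 2 * X[, "x"]))
  fit <- fit_logistic(X, y)
  expect_true(all(diff(fit$deviance_trace) <= 1e-10))
})

test_that("degenerate fits are rejected with informative errors", {
  X <- cbind("(Intercept)" = rep(1, 50), x = rnorm(50))
  expect_error(fit_logistic(X, rep(0, 50)), "single-class")
  Xc <- cbind(X, x_copy = X[, "x"])
  expect_error(fit_logistic(Xc, rbinom(50, 1, 0.5)), "collinear")
  # perfectly separated covariate
  xs <- c(rep(-1, 25), rep(1, 25))
  ys <- c(rep(0, 25), rep(1, 25))
  expect_error(fit_logistic(cbind("(Intercept)" = 1, x = xs), ys),
               "separat")
})

test_that("centring age leaves tertile odds ratios unchanged", {
  d <- prepare_analysis(score_admissions(
    simulate_ihfd(sim_config(n = 4000, seed = 55))))
  spec <- design_spec(c("intercept", "tertile", "age", "sex"))
  des <- build_design(d, "death_overall", spec)
  fit1 <- fit_logistic(des$X, des$y)
  Xc <- des$X
  Xc[, "age"] <- Xc[, "age"] - mean(Xc[, "age"])
  fit2 <- fit_logistic(Xc, des$y)
  for (term in c("tertilemedium", "tertilehigh")) {
    expect_equal(fit1$beta[[term]], fit2$beta[[term]], tolerance = 1e-8)
  }
})

test_that("odds ratios require convergence and carry Wald intervals", {
  fit <- structure(list(beta = c("(Intercept)" = 0, x = 0),
                        cov = diag(c(0.1, 0.04)), n = 10L,
                        converged = FALSE, iterations = 100L,
                        deviance = 1, deviance_trace = 1),
                   class = "logistic_fit")
  expect_error(adjusted_odds_ratios(fit), "non-converged")
  fit$converged <- TRUE
  dimnames(fit$cov) <- list(names(fit$beta), names(fit$beta))
  ors <- adjusted_odds_ratios(fit)
  expect_equal(ors$aOR, 1)
  expect_equal(ors$ci_low, exp(-qnorm(0.975) * 0.2), tolerance = 1e-9)
  expect_equal(ors$ci_high, exp(qnorm(0.975) * 0.2), tolerance = 1e-9)
  expect_equal(ors$p, 1)
})
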