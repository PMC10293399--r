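#' Cohort characteristics by FI tertile
#'
#' Table-1-style summary of the complete-FI cohort: per tertile, n, mean
#' (SD) age, % female, and % per ASA band (I/II, III, IV/V, unknown),
#' fracture type and surgery type. Percentages are of the tertile n and are
#' kept at full precision (rounding is a rendering concern). Empty tertiles
#' yield `NA` entries rather than zero divisions.
#'
#' @param scored Scored admission table ([score_admissions()]).
#' @return List: `n` (named tertile counts), `mean_age`, `sd_age`,
#'   `pct_female` (named vectors), and `rows` (long data.frame of
#'   characteristic/level counts and percentages by tertile).
#' @export
summarise_by_tertile <- function(scored) {
  stopifnot(all(c("fi", "complete", "tertile") %in% names(scored)))
  d <- scored[scored$complete & !is.na(scored$tertile), , drop = FALSE]
  terts <- c("low", "medium", "high")
  tert <- factor(as.character(d$tertile), levels = terts)
  n <- table(tert)
  stat_by <- function(x, f) {
    vapply(terts, function(t) {
      if (n[[t]] == 0L) NA_real_ else f(x[tert == t])
    }, numeric(1))
  }
  asa_band <- ifelse(d$asa == "unknown", "unknown",
                     ifelse(d$asa %in% c("1", "2"), "I_II",
                            ifelse(d$asa == "3", "III", "IV_V")))
  level_rows <- function(characteristic, values, levels) {
    do.call(rbind, lapply(levels, function(lv) {
      cnt <- vapply(terts, function(t) sum(values == lv & tert == t),
                    numeric(1))
      pct <- ifelse(as.vector(n) == 0L, NA_real_, 100 * cnt / as.vector(n))
      data.frame(characteristic = characteristic, level = lv,
                 tertile = terts, n = cnt, pct = pct,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  rows <- rbind(
    level_rows("sex", d$sex, c("female", "male")),
    level_rows("asa_band", asa_band, c("I_II", "III", "IV_V", "unknown")),
    level_rows("fracture_type", d$fracture_type,
               c("intracapsular", "intertrochanteric_subtrochanteric",
                 "other")),
    level_rows("surgery_type", d$surgery_type,
               c("arthroplasty", "internal_fixation", "other_surgery",
                 "non_operative"))
  )
  list(n = stats::setNames(as.vector(n), terts),
       mean_age = stat_by(d$age, mean),
       sd_age = stat_by(d$age, stats::sd),
       pct_female = stat_by(d$sex == "female", function(x) 100 * mean(x)),
       rows = rows)
}

#' Tertile-adjusted outcome models for all six outcomes
#'
#' For each outcome (delirium, prolonged LOS, 7- and 14-day and overall
#' inpatient mortality, new nursing-home admission), tabulates per-tertile
#' event counts and percentages among complete-FI records and fits the
#' logistic model outcome ~ FI tertile + age + sex (low tertile reference),
#' extracting adjusted odds ratios with 95% Wald CIs. A model failure
#' (separation, single-level covariate) is reported for that outcome
#' without aborting the others.
#'
#' @param data Analysis table from [prepare_analysis()].
#' @param terms Model terms, default `c("intercept", "tertile", "age",
#'   "sex")`.
#' @return List: `table` (long data.frame: outcome, tertile, n_events, n,
#'   pct, aOR, ci_low, ci_high, p), `fits` (named list of `logistic_fit` or
#'   `NULL`), `errors` (named character).
#' @export
analyse_outcomes <- function(data,
                             terms = c("intercept", "tertile", "age",
                                       "sex")) {
  outcomes <- c("delirium", "prolonged_los", "death_7d", "death_14d",
                "death_overall", "new_nh_admission")
  spec <- design_spec(terms)
  terts <- c("low", "medium", "high")
  complete <- data$complete & !is.na(data$tertile)
  fits <- list()
  errors <- character(0)
  rows <- list()
  for (oc in outcomes) {
    y <- data[[oc]]
    keep <- complete & !is.na(y)
    tert <- factor(as.character(data$tertile[keep]), levels = terts)
    yk <- y[keep]
    cnt <- vapply(terts, function(t) sum(yk[tert == t]), numeric(1))
    tot <- as.vector(table(tert))
    ors <- data.frame(term = c("tertilemedium", "tertilehigh"),
                      aOR = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    fit <- tryCatch({
      m <- fit_outcome_model(data, oc, spec)
      fits[[oc]] <- m$fit
      full <- adjusted_odds_ratios(m$fit)
      ors <- full[full$term %in% ors$term, ]
      m$fit
    }, error = function(e) {
      errors[[oc]] <<- conditionMessage(e)
      fits[[oc]] <<- NULL
      NULL
    })
    rows[[oc]] <- data.frame(
      outcome = oc, tertile = terts, n_events = cnt, n = tot,
      pct = ifelse(tot == 0L, NA_real_, 100 * cnt / tot),
      aOR = c(NA, ors$aOR), ci_low = c(NA, ors$ci_low),
      ci_high = c(NA, ors$ci_high), p = c(NA, ors$p),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fits = fits, errors = errors)
}

#' Nested risk-model AUC comparison for all outcomes
#'
#' For each of the four headline outcomes, fits Model 1 (age, sex, ASA) and
#' Model 2 (age, sex, ASA + continuous FI score) on the same records
#' (complete FI, known ASA, outcome defined), computes each model's
#' in-sample AUC with 95% CI, and tests the AUC difference.
#'
#' @param data Analysis table from [prepare_analysis()].
#' @param asa_coding `"linear"` (default) or `"categorical"`.
#' @param method AUC comparison method, `"independent"` (default, mirrors
#'   standard audit-software output) or `"paired_delong"` (correct for
#'   nested models scored on the same patients).
#' @param outcomes Outcome columns to compare.
#' @return List: `table` (data.frame: outcome, n, auc and CI per model,
#'   bands, z, p, method), `comparisons` (named list of `auc_comparison`),
#'   `errors` (named character).
#' @export
compare_models <- function(data, asa_coding = c("linear", "categorical"),
                           method = c("independent", "paired_delong"),
                           outcomes = c("delirium", "prolonged_los",
                                        "death_overall",
                                        "new_nh_admission")) {
  asa_coding <- match.arg(asa_coding)
  method <- match.arg(method)
  spec1 <- design_spec(c("intercept", "age", "sex", "asa"), asa_coding)
  spec2 <- design_spec(c("intercept", "age", "sex", "asa", "fi"),
                       asa_coding)
  comparisons <- list()
  errors <- character(0)
  rows <- list()
  for (oc in outcomes) {
    res <- tryCatch({
      # restrict to rows usable by the larger model so both models score
      # the same patients
      d2 <- build_design(data, oc, spec2)
      shared <- data[d2$rows, , drop = FALSE]
      d1 <- build_design(shared, oc, spec1)
      stopifnot(d1$n == d2$n)
      f1 <- fit_logistic(d1$X, d1$y)
      f2 <- fit_logistic(d2$X, d2$y)
      p1 <- predicted_probabilities(f1, d1$X)
      p2 <- predicted_probabilities(f2, d2$X)
      cmp <- compare_aucs(p1, p2, d1$y, method)
      comparisons[[oc]] <- cmp
      data.frame(outcome = oc, n = d1$n,
                 auc_model1 = cmp$auc1$auc,
                 ci_low_model1 = cmp$auc1$ci_low,
                 ci_high_model1 = cmp$auc1$ci_high,
                 band_model1 = discrimination_band(cmp$auc1$auc),
                 auc_model2 = cmp$auc2$auc,
                 ci_low_model2 = cmp$auc2$ci_low,
                 ci_high_model2 = cmp$auc2$ci_high,
                 band_model2 = discrimination_band(cmp$auc2$auc),
                 z = cmp$z, p = cmp$p, method = method,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      errors[[oc]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) rows[[oc]] <- res
  }
  list(table = if (length(rows)) do.call(rbind, c(rows, list(
         make.row.names = FALSE))) else NULL,
       comparisons = comparisons, errors = errors)
}

# stable content hash for provenance (polynomial rolling hash, base 31,
# modulus 2^31-1)
content_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15)),
             collapse = "\n")
  h <- 0
  m <- 2147483647
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Simulate-or-ingest, map deficits, score the FI, stratify tertiles, fit
#' the tertile-adjusted outcome models and the nested risk-model AUC
#' comparison, and write a scored-cohort CSV, a model-estimates CSV, and a
#' machine-readable JSON report plus human-readable markdown tables to
#' `out_dir`. Every stochastic step is controlled by the single configured
#' seed, so repeated runs are byte-identical.
#'
#' @param input `"simulate"` (default) or path to an admission CSV.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param config A [sim_config()] (simulate mode only), or `NULL` for
#'   defaults.
#' @param seed Integer seed overriding the config seed.
#' @param map Code map, or path to a YAML/JSON map, or `NULL` for the
#'   default.
#' @param tertiles `"fixed"` (default) or `"empirical"`.
#' @param asa_coding `"linear"` or `"categorical"` for the risk models.
#' @param auc_test `"independent"` or `"delong"` (paired DeLong).
#' @param policy FI missingness policy, see [compute_fi()].
#' @param quiet Suppress progress messages.
#' @return A `run_report` list: `cohort_summary`, `outcome_table`,
#'   `auc_table`, `errors`, `provenance`, plus `scored` (the scored
#'   cohort), invisibly.
#' @export
run_pipeline <- function(input = "simulate", out_dir = NULL, config = NULL,
                         seed = NULL, map = NULL,
                         tertiles = c("fixed", "empirical"),
                         asa_coding = c("linear", "categorical"),
                         auc_test = c("independent", "delong"),
                         policy = c("complete_case", "renormalise"),
                         quiet = FALSE) {
  tertiles <- match.arg(tertiles)
  asa_coding <- match.arg(asa_coding)
  auc_test <- match.arg(auc_test)
  policy <- match.arg(policy)
  say <- function(...) if (!quiet) message(...)
  map <- if (is.null(map)) default_code_map()
         else if (is.character(map)) read_code_map(map)
         else validate_code_map(map)

  if (identical(input, "simulate")) {
    cfg <- if (is.null(config)) sim_config() else config
    stopifnot(inherits(cfg, "sim_config"))
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    say("simulate: n = ", cfg$n, ", seed = ", cfg$seed)
    cohort <- simulate_ihfd(cfg, map)
  } else {
    cfg <- NULL
    cohort <- read_admissions(input)
    say("ingest: ", nrow(cohort), " records from ", input)
  }

  scored <- score_admissions(cohort, map, scheme = tertiles, policy = policy)
  scheme <- attr(scored, "tertile_scheme")
  n_complete <- sum(scored$complete)
  say("score: ", nrow(scored), " records in, ", n_complete,
      " with complete FI (", sprintf("%.1f", 100 * n_complete /
                                       nrow(scored)), "%)")

  data <- prepare_analysis(scored)
  cohort_summary <- summarise_by_tertile(data)
  say("summarise: tertile n = ",
      paste(cohort_summary$n, collapse = " / "))
  models <- analyse_outcomes(data)
  for (oc in names(models$errors)) {
    say("model failure [", oc, "]: ", models$errors[[oc]])
  }
  auc_method <- if (auc_test == "delong") "paired_delong" else "independent"
  aucs <- compare_models(data, asa_coding, auc_method)
  for (oc in names(aucs$errors)) {
    say("AUC failure [", oc, "]: ", aucs$errors[[oc]])
  }

  report <- structure(list(
    cohort_summary = cohort_summary,
    outcome_table = models$table,
    auc_table = aucs$table,
    errors = c(models$errors, aucs$errors),
    tertile_scheme = unclass(scheme),
    provenance = list(
      input = if (identical(input, "simulate")) "simulate" else input,
      n_records = nrow(scored),
      n_complete_fi = n_complete,
      seed = if (is.null(cfg)) NA else cfg$seed,
      config_hash = content_hash(list(cfg = cfg, map = map,
                                      tertiles = tertiles,
                                      asa_coding = asa_coding,
                                      auc_test = auc_test,
                                      policy = policy)),
      package_version = as.character(utils::packageVersion("hipfi"))
    )
  ), class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_admissions(scored, file.path(out_dir, "scored_cohort.csv"))
    utils::write.csv(models$table,
                     file.path(out_dir, "model_estimates.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    writeLines(render_report_md(report), file.path(out_dir, "report.md"))
    say("wrote: ", paste(c("scored_cohort.csv", "model_estimates.csv",
                           "report.json", "report.md"), collapse = ", "),
        " in ", out_dir)
  }
  report$scored <- scored
  invisible(report)
}

fmt_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", x))

render_report_md <- function(report) {
  cs <- report$cohort_summary
  out <- c("# Frailty-index cohort report", "",
           sprintf("Records: %d; complete FI: %d. Tertile scheme (%s): low <= %.4g < medium <= %.4g < high.",
                   report$provenance$n_records,
                   report$provenance$n_complete_fi,
                   report$tertile_scheme$method,
                   report$tertile_scheme$upper_low,
                   report$tertile_scheme$upper_medium),
           "", "## Cohort characteristics by FI tertile", "",
           "| characteristic | low | medium | high |",
           "|---|---|---|---|",
           sprintf("| n | %d | %d | %d |", cs$n[1], cs$n[2], cs$n[3]),
           sprintf("| mean age (SD) | %s | %s | %s |",
                   sprintf("%.1f (%.1f)", cs$mean_age, cs$sd_age)[1],
                   sprintf("%.1f (%.1f)", cs$mean_age, cs$sd_age)[2],
                   sprintf("%.1f (%.1f)", cs$mean_age, cs$sd_age)[3]))
  fem <- cs$rows[cs$rows$characteristic == "sex" &
                   cs$rows$level == "female", ]
  out <- c(out, sprintf("| female, n (%%) | %d (%s) | %d (%s) | %d (%s) |",
                        fem$n[1], fmt_pct(fem$pct[1]),
                        fem$n[2], fmt_pct(fem$pct[2]),
                        fem$n[3], fmt_pct(fem$pct[3])))
  for (ch in c("asa_band", "fracture_type", "surgery_type")) {
    sub <- cs$rows[cs$rows$characteristic == ch, ]
    for (lv in unique(sub$level)) {
      r <- sub[sub$level == lv, ]
      out <- c(out, sprintf("| %s: %s, n (%%) | %d (%s) | %d (%s) | %d (%s) |",
                            ch, lv,
                            r$n[1], fmt_pct(r$pct[1]),
                            r$n[2], fmt_pct(r$pct[2]),
                            r$n[3], fmt_pct(r$pct[3])))
    }
  }
  out <- c(out, "", "## Outcomes by FI tertile (aOR adjusted for age and sex; low tertile reference)",
           "", "| outcome | tertile | events/n (%) | aOR (95% CI) | p |",
           "|---|---|---|---|---|")
  ot <- report$outcome_table
  for (i in seq_len(nrow(ot))) {
    aor <- if (is.na(ot$aOR[i])) "ref/-" else
      sprintf("%.2f (%.2f-%.2f)", ot$aOR[i], ot$ci_low[i], ot$ci_high[i])
    pv <- if (is.na(ot$p[i])) "" else
      if (ot$p[i] < 0.001) "< 0.001" else sprintf("%.3f", ot$p[i])
    out <- c(out, sprintf("| %s | %s | %d/%d (%s) | %s | %s |",
                          ot$outcome[i], ot$tertile[i], ot$n_events[i],
                          ot$n[i], fmt_pct(ot$pct[i]), aor, pv))
  }
  out <- c(out, "", "## AUC comparison: Model 1 (age, sex, ASA) vs Model 2 (+ FI score)",
           "", "| outcome | n | AUC model 1 (95% CI) | AUC model 2 (95% CI) | p |",
           "|---|---|---|---|---|")
  at <- report$auc_table
  if (!is.null(at)) {
    for (i in seq_len(nrow(at))) {
      pv <- if (at$p[i] < 0.001) "< 0.001" else sprintf("%.3f", at$p[i])
      out <- c(out, sprintf(
        "| %s | %d | %.2f (%.2f-%.2f) [%s] | %.2f (%.2f-%.2f) [%s] | %s |",
        at$outcome[i], at$n[i],
        at$auc_model1[i], at$ci_low_model1[i], at$ci_high_model1[i],
        at$band_model1[i],
        at$auc_model2[i], at$ci_low_model2[i], at$ci_high_model2[i],
        at$band_model2[i], pv))
    }
  }
  out <- c(out, "",
           sprintf("Provenance: seed %s, config hash %s, hipfi %s.",
                   report$provenance$seed, report$provenance$config_hash,
                   report$provenance$package_version))
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_report_md(x), sep = "\n")
  invisible(x)
}
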