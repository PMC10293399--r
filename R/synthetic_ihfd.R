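#' Default age-prevalence parameters for the 15 comorbidity deficits
#'
#' Each condition is generated from a logistic-in-age model:
#' logit P(present) = logit(prevalence80) + slope * (age - 80). Baseline
#' prevalences are realistic for an older European hip-fracture population
#' (hypertension most common; Parkinson's and chronic liver disease rare);
#' slopes make deficits accumulate with age without saturating early.
#'
#' @return data.frame: `condition`, `prevalence80`, `slope`.
#' @export
default_condition_params <- function() {
  data.frame(
    condition = fi_conditions(),
    prevalence80 = c(0.07, 0.02, 0.04, 0.06, 0.22, 0.08, 0.12, 0.04,
                     0.05, 0.05, 0.02, 0.05, 0.04, 0.01, 0.08),
    slope = c(0.04, 0.03, 0.06, 0.01, 0.03, 0.00, 0.09, 0.04,
              0.05, 0.01, 0.02, 0.02, 0.00, -0.02, 0.05),
    stringsAsFactors = FALSE
  )
}

# prevalences reflect admission-episode administrative coding (conditions
# recorded only if active/relevant during the admission), which sits well
# below community survey prevalence; they are calibrated so the fixed FI
# cutpoints 0.05/0.15 split the default cohort into roughly balanced
# low/medium/high risk groups, as in the registry the index was derived in.

#' Default per-outcome logistic coefficients for outcome simulation
#'
#' Ground-truth log-odds models on FI tertile (low reference), age in single
#' years and male sex, for the four directly simulated outcomes. Tertile
#' log-odds-ratios default to the adjusted odds ratios reported for the
#' national cohort in which the index was derived (delirium 2.20/2.74,
#' prolonged LOS 2.88/4.38, overall inpatient mortality 4.75/14.74, new
#' nursing-home admission 2.22/4.38 for medium/high); intercepts are
#' calibrated so the low-tertile event rates at that cohort's low-tertile
#' age/sex mix (mean age 76.9, 28.5% male) match its low-tertile outcome
#' proportions (5.5%, 5.9%, 0.6%, 2.2%).
#'
#' @return Named list of coefficient vectors
#'   `c(intercept, medium, high, age, male)`.
#' @export
default_outcome_coefficients <- function() {
  ref_age <- 76.9
  ref_male <- 0.285
  mk <- function(p_low, or_med, or_high, b_age, b_male) {
    c(intercept = stats::qlogis(p_low) - b_age * ref_age - b_male * ref_male,
      medium = log(or_med), high = log(or_high),
      age = b_age, male = b_male)
  }
  list(
    delirium = mk(0.055, 2.20, 2.74, b_age = 0.03, b_male = 0.10),
    prolonged_los = mk(0.059, 2.88, 4.38, b_age = 0.01, b_male = 0.00),
    death_overall = mk(0.006, 4.75, 14.74, b_age = 0.07, b_male = 0.50),
    new_nh_admission = mk(0.022, 2.22, 4.38, b_age = 0.05, b_male = 0.00)
  )
}

#' Simulation configuration for a synthetic hip-fracture cohort
#'
#' Defaults emulate the marginal structure of the Irish national
#' hip-fracture audit cohort from which the 21-item FI was derived: mean
#' (SD) age 80.4 (8.8) truncated at 60, 69.6% female, and item-missingness
#' rates of 1010/14615 (previous fracture), 940/14615, 1120/14615 and
#' 1178/14615 (NMS indoor, outdoor, shopping).
#'
#' @param n Cohort size.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param age_mean,age_sd,age_floor Age distribution (normal truncated at
#'   `age_floor`, rounded to whole years).
#' @param p_female Probability of female sex.
#' @param condition_params data.frame as [default_condition_params()].
#' @param prev_fracture_prevalence Probability of previous fragility
#'   fracture.
#' @param pre_ulcer_prevalence Probability of a pre-admission pressure
#'   ulcer (coded L89, no new in-hospital ulcer recorded).
#' @param new_ulcer_rate Probability of an audit-recorded new in-hospital
#'   pressure ulcer in patients without a pre-admission ulcer.
#' @param p_nursing_home Probability of nursing-home provenance.
#' @param nms_severity_slope Per-year log-odds shift towards worse NMS
#'   levels.
#' @param nms_cutpoints List of 3 cumulative-logit cutpoint vectors (length
#'   3 each) for indoor, outdoor, shopping at age 80.
#' @param asa_unknown_rate Probability that ASA is recorded as unknown.
#' @param missing_prev_fracture,missing_nms_indoor,missing_nms_outdoor,missing_nms_shopping
#'   Marginal item missingness rates.
#' @param missing_propensity Fraction of records prone to missingness; items
#'   go unrecorded only within this subset (at rate marginal/propensity), so
#'   missingness overlaps across items as observed in registry audits. The
#'   default 0.16 yields a complete-FI fraction near 85.5% at the default
#'   marginal rates.
#' @param p_noise_code Probability of one extra diagnosis code unrelated to
#'   any FI condition.
#' @param outcome_coefficients Named list as
#'   [default_outcome_coefficients()].
#' @param death_day_rate Geometric-like decay rate of the death-day
#'   distribution over days 1--60.
#' @param los_meanlog,los_sdlog Lognormal parameters of the short-stay LOS
#'   component (truncated below 30 days).
#' @param los_long_rate Geometric rate of the extra days beyond 30 in the
#'   prolonged-stay component.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 14615, seed = 1L,
                       age_mean = 80.4, age_sd = 8.8, age_floor = 60,
                       p_female = 0.696,
                       condition_params = default_condition_params(),
                       prev_fracture_prevalence = 0.15,
                       pre_ulcer_prevalence = 0.02,
                       new_ulcer_rate = 0.04,
                       p_nursing_home = 0.10,
                       nms_severity_slope = 0.08,
                       nms_cutpoints = list(
                         indoor = c(1.10, 2.44, 3.18),
                         outdoor = c(0.62, 1.73, 2.44),
                         shopping = c(0.41, 1.10, 1.73)),
                       asa_unknown_rate = 0.085,
                       missing_prev_fracture = 1010 / 14615,
                       missing_nms_indoor = 940 / 14615,
                       missing_nms_outdoor = 1120 / 14615,
                       missing_nms_shopping = 1178 / 14615,
                       missing_propensity = 0.16,
                       p_noise_code = 0.3,
                       outcome_coefficients = default_outcome_coefficients(),
                       death_day_rate = 0.05,
                       los_meanlog = log(12), los_sdlog = 0.5,
                       los_long_rate = 0.08) {
  cfg <- as.list(environment())
  probs <- c(p_female = p_female,
             prev_fracture_prevalence = prev_fracture_prevalence,
             pre_ulcer_prevalence = pre_ulcer_prevalence,
             new_ulcer_rate = new_ulcer_rate,
             p_nursing_home = p_nursing_home,
             asa_unknown_rate = asa_unknown_rate,
             missing_prev_fracture = missing_prev_fracture,
             missing_nms_indoor = missing_nms_indoor,
             missing_nms_outdoor = missing_nms_outdoor,
             missing_nms_shopping = missing_nms_shopping,
             p_noise_code = p_noise_code)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(is.data.frame(condition_params),
            all(c("condition", "prevalence80", "slope") %in%
                  names(condition_params)),
            setequal(condition_params$condition, fi_conditions()),
            all(condition_params$prevalence80 >= 0 &
                  condition_params$prevalence80 <= 1))
  need <- c("delirium", "prolonged_los", "death_overall",
            "new_nh_admission")
  if (!all(need %in% names(outcome_coefficients)) ||
      !all(vapply(outcome_coefficients[need], length, 1L) == 5L)) {
    stop("outcome_coefficients must name ", paste(need, collapse = ", "),
         ", each length 5 (intercept, medium, high, age, male)",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Emission code set per condition: prefixes that do not extend another
# condition's prefix, so a generated code flags exactly its own condition
# and the generator round-trips through the deficit mapping.
emission_codes <- function(map) {
  map <- validate_code_map(map)
  norm <- lapply(map, normalise_icd)
  out <- lapply(names(map), function(cond) {
    other <- unlist(norm[setdiff(names(map), cond)], use.names = FALSE)
    keep <- vapply(norm[[cond]], function(p) !any(startsWith(p, other)),
                   logical(1))
    map[[cond]][keep]
  })
  names(out) <- names(map)
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty)) {
    stop("no unambiguous emission code for condition(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  out
}

draw_nms <- function(n, cutpoints, eta) {
  u <- stats::runif(n)
  lev <- 1L + (u > stats::plogis(cutpoints[1] - eta)) +
    (u > stats::plogis(cutpoints[2] - eta)) +
    (u > stats::plogis(cutpoints[3] - eta))
  nms_levels()[lev]
}

#' Generate a synthetic hip-fracture admission cohort
#'
#' Draws a seeded cohort in the [admission_columns()] schema: truncated
#' normal ages rounded to years; per-condition logistic-in-age comorbidity
#' flags, each present condition emitting one ICD code sampled from its
#' unambiguous prefix set (so the deficit mapping recovers the generating
#' flags exactly); age-shifted ordinal-logit NMS levels; ASA drawn
#' conditional on the comorbidity count; nursing-home provenance; and item
#' missingness applied to the recorded previous-fracture and NMS fields.
#'
#' Outcome fields are filled with survival placeholders (baseline LOS, no
#' deaths); [simulate_outcomes()] overwrites them from the configured
#' tertile-driven models. The attached `"truth"` attribute carries each
#' record's generating deficits, FI and fixed-scheme tertile computed before
#' missingness masking.
#'
#' @param cfg A [sim_config()].
#' @param map Code map used for code emission, default
#'   [default_code_map()].
#' @return Admission data.frame with attribute `"truth"`.
#' @export
generate_cohort <- function(cfg = sim_config(), map = default_code_map()) {
  stopifnot(inherits(cfg, "sim_config"))
  emit <- emission_codes(map)
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  n <- cfg$n

  # offset the pre-truncation mean so the truncated marginal mean equals
  # age_mean (left truncation alone would inflate it by ~0.25 y)
  mu <- cfg$age_mean
  for (k in 1:25) {
    a <- (cfg$age_floor - mu) / cfg$age_sd
    mu <- cfg$age_mean -
      cfg$age_sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  }
  age <- round(stats::rnorm(n, mu, cfg$age_sd))
  while (any(age < cfg$age_floor)) {
    i <- age < cfg$age_floor
    age[i] <- round(stats::rnorm(sum(i), mu, cfg$age_sd))
  }
  sex <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")

  cp <- cfg$condition_params
  flags <- matrix(0L, n, length(fi_conditions()),
                  dimnames = list(NULL, fi_conditions()))
  for (i in seq_len(nrow(cp))) {
    pr <- stats::plogis(stats::qlogis(cp$prevalence80[i]) +
                          cp$slope[i] * (age - 80))
    flags[, cp$condition[i]] <- as.integer(stats::runif(n) < pr)
  }

  prev_frac <- as.integer(stats::runif(n) < cfg$prev_fracture_prevalence)
  pre_ulcer <- as.integer(stats::runif(n) < cfg$pre_ulcer_prevalence)
  new_pu <- ifelse(pre_ulcer == 1L, "no",
                   ifelse(stats::runif(n) < cfg$new_ulcer_rate, "yes", "no"))

  nh <- stats::runif(n) < cfg$p_nursing_home
  adm_from <- nh & stats::runif(n) < 0.8
  disch_to <- nh & (!adm_from | stats::runif(n) < 0.8)

  eta_nms <- cfg$nms_severity_slope * (age - 80)
  nms_in <- draw_nms(n, cfg$nms_cutpoints$indoor, eta_nms)
  nms_out <- draw_nms(n, cfg$nms_cutpoints$outdoor, eta_nms)
  nms_shop <- draw_nms(n, cfg$nms_cutpoints$shopping, eta_nms)

  # ASA conditional on deficit burden: latent logistic on comorbidity count
  latent <- 0.45 * rowSums(flags) + 0.04 * (age - 80) + stats::rlogis(n)
  asa <- as.character(cut(latent, c(-Inf, 0.45, 3.6, 6, 8, Inf),
                          labels = FALSE))
  asa[stats::runif(n) < cfg$asa_unknown_rate] <- "unknown"

  fracture_type <- sample(c("intracapsular",
                            "intertrochanteric_subtrochanteric", "other"),
                          n, replace = TRUE, prob = c(0.51, 0.43, 0.06))
  surgery_type <- sample(c("arthroplasty", "internal_fixation",
                           "other_surgery", "non_operative"),
                         n, replace = TRUE, prob = c(0.50, 0.445, 0.02,
                                                     0.035))
  primary <- c(intracapsular = "S72.00",
               intertrochanteric_subtrochanteric = "S72.10",
               other = "S72.8")[fracture_type]

  noise_pool <- c("R29.6", "E87.5", "N39.0", "Z50.1", "W19", "R26.8")
  noise <- ifelse(stats::runif(n) < cfg$p_noise_code,
                  sample(noise_pool, n, replace = TRUE), NA)

  dx_codes <- unname(primary)
  append_code <- function(dx, code, on) {
    ifelse(on, paste(dx, code, sep = ";"), dx)
  }
  for (cond in fi_conditions()) {
    pool <- emit[[cond]]
    code <- if (length(pool) == 1L) rep(pool, n) else
      sample(pool, n, replace = TRUE)
    dx_codes <- append_code(dx_codes, code, flags[, cond] == 1L)
  }
  dx_codes <- append_code(dx_codes, "L89", pre_ulcer == 1L)
  l89_coded_new <- new_pu == "yes" & stats::runif(n) < 0.8
  dx_codes <- append_code(dx_codes, "L89", l89_coded_new)
  dx_codes <- append_code(dx_codes, noise, !is.na(noise))

  # baseline (pre-outcome) stay length; overwritten by simulate_outcomes()
  los <- pmax(1L, pmin(29L, as.integer(round(
    stats::rlnorm(n, cfg$los_meanlog, cfg$los_sdlog)))))

  cohort <- data.frame(
    record_id = sprintf("R%06d", seq_len(n)),
    age = as.integer(age),
    sex = sex,
    asa = asa,
    dx_codes = dx_codes,
    prev_fracture = ifelse(prev_frac == 1L, "yes", "no"),
    new_pu_hosp = new_pu,
    nms_indoor = nms_in,
    nms_outdoor = nms_out,
    nms_shopping = nms_shop,
    adm_from_nh = ifelse(adm_from, "yes", "no"),
    disch_to_nh = ifelse(disch_to, "yes", "no"),
    fracture_type = fracture_type,
    surgery_type = surgery_type,
    los_days = los,
    inpatient_death = "no",
    death_day = NA_integer_,
    new_nh_admission = ifelse(adm_from, "not_applicable", "no"),
    stringsAsFactors = FALSE
  )

  # ground truth before missingness masking
  true_fi <- (rowSums(flags) + prev_frac + pre_ulcer +
                recode_nms(nms_in) + recode_nms(nms_out) +
                recode_nms(nms_shop) + as.integer(nh)) / 21
  truth <- data.frame(record_id = cohort$record_id, flags,
                      previous_fracture = prev_frac,
                      pre_admission_pressure_ulcer = pre_ulcer,
                      nursing_home = as.integer(nh),
                      fi = true_fi,
                      tertile = assign_tertile(true_fi, fixed_tertiles()),
                      stringsAsFactors = FALSE, check.names = FALSE)

  # Overlapping missingness: items go unrecorded only in missingness-prone
  # records (audit-gap model), preserving the configured marginal rates
  # while concentrating incompleteness in fewer records.
  q <- max(cfg$missing_propensity, cfg$missing_prev_fracture,
           cfg$missing_nms_indoor, cfg$missing_nms_outdoor,
           cfg$missing_nms_shopping)
  prone <- stats::runif(n) < q
  mask <- function(rate) prone & stats::runif(n) < rate / q
  cohort$prev_fracture[mask(cfg$missing_prev_fracture)] <- NA
  cohort$nms_indoor[mask(cfg$missing_nms_indoor)] <- NA
  cohort$nms_outdoor[mask(cfg$missing_nms_outdoor)] <- NA
  cohort$nms_shopping[mask(cfg$missing_nms_shopping)] <- NA

  attr(cohort, "truth") <- truth
  validate_admissions(cohort)
  cohort
}

#' Simulate adverse outcomes on a tertile-assigned cohort
#'
#' Draws each of delirium, prolonged LOS, overall inpatient death and new
#' nursing-home admission as Bernoulli with
#' logit = intercept + b_med 1\[medium\] + b_high 1\[high\] + b_age age +
#' b_male 1\[male\], per `cfg$outcome_coefficients`. A delirium draw appends
#' a secondary F05 code; deaths get a day drawn from a truncated
#' geometric-like distribution over 1--60 (capped at the final LOS, so only
#' the 7/14-day split is affected, never the configured mortality model);
#' LOS is drawn from a short-stay lognormal truncated below 30 days or a
#' prolonged component of 30+ days according to the prolonged-LOS draw; new
#' nursing-home admission is simulated only for records not admitted from a
#' nursing home. Uses `set.seed(cfg$seed + 1)` so outcome draws are
#' reproducible but independent of the cohort-generation stream.
#'
#' @param records Admission table with a non-missing `tertile` column
#'   (factor low/medium/high).
#' @param cfg A [sim_config()].
#' @return The records with `dx_codes`, `los_days`, `inpatient_death`,
#'   `death_day`, `new_nh_admission` replaced by simulated values (and the
#'   `tertile` column preserved).
#' @export
simulate_outcomes <- function(records, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!"tertile" %in% names(records) || anyNA(records$tertile)) {
    stop("every record needs an assigned tertile to simulate outcomes",
         call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed) + 1L)
  n <- nrow(records)
  med <- as.numeric(records$tertile == "medium")
  high <- as.numeric(records$tertile == "high")
  male <- as.numeric(records$sex == "male")
  draw <- function(b) {
    eta <- b[["intercept"]] + b[["medium"]] * med + b[["high"]] * high +
      b[["age"]] * records$age + b[["male"]] * male
    as.integer(stats::runif(n) < stats::plogis(eta))
  }
  oc <- cfg$outcome_coefficients
  delirium <- draw(oc$delirium)
  prolonged <- draw(oc$prolonged_los)
  death <- draw(oc$death_overall)
  new_nh <- draw(oc$new_nh_admission)

  out <- records
  out$dx_codes <- ifelse(delirium == 1L,
                         paste0(out$dx_codes, ";F05"), out$dx_codes)

  short <- pmax(1L, pmin(29L, as.integer(round(
    stats::rlnorm(n, cfg$los_meanlog, cfg$los_sdlog)))))
  long <- 30L + stats::rgeom(n, cfg$los_long_rate)
  out$los_days <- ifelse(prolonged == 1L, long, short)

  day_probs <- (1 - cfg$death_day_rate)^(0:59)
  dday <- sample.int(60L, n, replace = TRUE, prob = day_probs)
  out$inpatient_death <- ifelse(death == 1L, "yes", "no")
  out$death_day <- ifelse(death == 1L, pmin(dday, out$los_days),
                          NA_integer_)

  from_nh <- out$adm_from_nh == "yes"
  out$new_nh_admission <- ifelse(from_nh, "not_applicable",
                                 ifelse(new_nh == 1L, "yes", "no"))
  validate_admissions(out)
  out
}

#' Generate a full synthetic cohort with outcomes in one call
#'
#' Runs [generate_cohort()] and [simulate_outcomes()], feeding the
#' generator's ground-truth tertile to the outcome models so every record
#' (including those with FI-relevant missingness) receives outcomes, as in
#' a real registry.
#'
#' @param cfg A [sim_config()].
#' @param map Code map, default [default_code_map()].
#' @return Admission data.frame with attribute `"truth"`.
#' @export
simulate_ihfd <- function(cfg = sim_config(), map = default_code_map()) {
  cohort <- generate_cohort(cfg, map)
  truth <- attr(cohort, "truth")
  tmp <- cohort
  tmp$tertile <- truth$tertile
  tmp <- simulate_outcomes(tmp, cfg)
  tmp$tertile <- NULL
  attr(tmp, "truth") <- truth
  tmp
}
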