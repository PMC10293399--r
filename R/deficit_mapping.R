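#' Column schema of an admission table
#'
#' One row per hip-fracture admission. `dx_codes` is a semicolon-delimited
#' list of ICD-10-AM codes, first position = primary diagnosis (HIPE list
#' ordering). Missing values are empty fields in CSV and `NA` in R.
#'
#' @return Character vector of required column names.
#' @export
admission_columns <- function() {
  c("record_id", "age", "sex", "asa", "dx_codes",
    "prev_fracture", "new_pu_hosp",
    "nms_indoor", "nms_outdoor", "nms_shopping",
    "adm_from_nh", "disch_to_nh",
    "fracture_type", "surgery_type",
    "los_days", "inpatient_death", "death_day", "new_nh_admission")
}

nms_levels <- function() {
  c("no_difficulty_no_aid", "with_aid", "with_help", "unable")
}

#' Validate an admission table against the schema
#'
#' Checks column presence, age floor (study population is 60+), value domains
#' for categorical fields, and record-level consistency: `death_day` present
#' iff `inpatient_death == "yes"`, and `new_nh_admission` is
#' `"not_applicable"` iff the patient was admitted from a nursing home.
#'
#' @param admissions data.frame in the [admission_columns()] schema.
#' @return The admission table, invisibly, with `record_id` as character.
#' @export
validate_admissions <- function(admissions) {
  if (!is.data.frame(admissions) || nrow(admissions) == 0L) {
    stop("admission table is empty or not a data.frame", call. = FALSE)
  }
  miss <- setdiff(admission_columns(), names(admissions))
  if (length(miss)) {
    stop("admission table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  admissions$record_id <- as.character(admissions$record_id)
  if (anyDuplicated(admissions$record_id)) {
    stop("duplicate record_id values", call. = FALSE)
  }
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stop(what, " (rows ",
           paste(utils::head(which(cond), 5L), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  bad_row(is.na(admissions$age) | admissions$age < 60,
          "age must be >= 60 years")
  bad_row(!admissions$sex %in% c("female", "male"), "sex must be female/male")
  bad_row(!as.character(admissions$asa) %in% c(as.character(1:5), "unknown"),
          "asa must be 1-5 or 'unknown'")
  for (col in c("new_pu_hosp", "adm_from_nh", "disch_to_nh",
                "inpatient_death")) {
    bad_row(!admissions[[col]] %in% c("yes", "no"),
            paste0(col, " must be yes/no"))
  }
  bad_row(!is.na(admissions$prev_fracture) &
            !admissions$prev_fracture %in% c("yes", "no"),
          "prev_fracture must be yes/no or missing")
  for (col in c("nms_indoor", "nms_outdoor", "nms_shopping")) {
    bad_row(!is.na(admissions[[col]]) &
              !admissions[[col]] %in% nms_levels(),
            paste0(col, " has unrecognised level"))
  }
  bad_row(!admissions$fracture_type %in%
            c("intracapsular", "intertrochanteric_subtrochanteric", "other"),
          "unrecognised fracture_type")
  bad_row(!admissions$surgery_type %in%
            c("arthroplasty", "internal_fixation", "other_surgery",
              "non_operative"),
          "unrecognised surgery_type")
  bad_row(is.na(admissions$los_days) | admissions$los_days < 0,
          "los_days must be a non-negative integer")
  dead <- admissions$inpatient_death == "yes"
  bad_row(dead & is.na(admissions$death_day),
          "death_day absent for inpatient death")
  bad_row(!dead & !is.na(admissions$death_day),
          "death_day present without inpatient death")
  bad_row(dead & !is.na(admissions$death_day) & admissions$death_day < 1,
          "death_day must be a positive integer")
  from_nh <- admissions$adm_from_nh == "yes"
  bad_row(from_nh & admissions$new_nh_admission != "not_applicable",
          "new_nh_admission must be not_applicable for nursing-home residents")
  bad_row(!from_nh & !admissions$new_nh_admission %in% c("yes", "no"),
          "new_nh_admission must be yes/no for community-dwelling patients")
  invisible(admissions)
}

split_codes <- function(dx_codes) {
  out <- strsplit(ifelse(is.na(dx_codes), "", as.character(dx_codes)), ";",
                  fixed = TRUE)
  lapply(out, function(x) trimws(x[nzchar(trimws(x))]))
}

#' Extract the 15 comorbidity deficit flags from diagnosis codes
#'
#' A condition flags 1 iff any diagnosis code of the admission matches any of
#' the condition's prefixes (dot-insensitive; duplicates are idempotent).
#' Absence of any matching code yields 0, never missing: under administrative
#' coding conventions an unrecorded condition is treated as not present.
#'
#' @param admissions Validated admission table.
#' @param map Code map, default [default_code_map()].
#' @return Integer matrix, one row per admission, 15 named 0/1 columns.
#' @export
extract_comorbidity_deficits <- function(admissions, map = default_code_map()) {
  map <- validate_code_map(map)
  codes <- split_codes(admissions$dx_codes)
  n_codes <- lengths(codes)
  flat <- normalise_icd(unlist(codes, use.names = FALSE))
  row_of <- rep.int(seq_along(codes), n_codes)
  out <- matrix(0L, nrow = nrow(admissions), ncol = length(map),
                dimnames = list(NULL, names(map)))
  for (cond in names(map)) {
    hit <- rep(FALSE, length(flat))
    for (p in normalise_icd(map[[cond]])) {
      hit <- hit | startsWith(flat, p)
    }
    out[unique(row_of[hit]), cond] <- 1L
  }
  out
}

#' Derive the pre-admission pressure ulcer deficit
#'
#' A coded L89 diagnosis in the absence of an audit-recorded new in-hospital
#' pressure ulcer indicates an ulcer that predates the admission.
#'
#' @param admissions Validated admission table.
#' @return Integer 0/1 vector.
#' @export
derive_pressure_ulcer <- function(admissions) {
  flag <- admissions$new_pu_hosp
  if (anyNA(flag) || any(!flag %in% c("yes", "no"))) {
    bad <- which(is.na(flag) | !flag %in% c("yes", "no"))
    stop("new_pu_hosp missing/invalid for record(s): ",
         paste(admissions$record_id[utils::head(bad, 5L)], collapse = ", "),
         call. = FALSE)
  }
  codes <- split_codes(admissions$dx_codes)
  has_l89 <- vapply(codes, function(x) {
    length(x) > 0L && any(startsWith(normalise_icd(x), "L89"))
  }, logical(1))
  as.integer(has_l89 & flag == "no")
}

#' Derive the nursing-home provenance deficit
#'
#' A patient counts as a nursing-home resident if recorded as admitted from
#' or discharged back to a nursing home.
#'
#' @param admissions Validated admission table.
#' @return Integer 0/1 vector.
#' @export
derive_nursing_home <- function(admissions) {
  as.integer(admissions$adm_from_nh == "yes" |
               admissions$disch_to_nh == "yes")
}

#' Build the 21-item deficit table for a cohort
#'
#' Combines the 15 comorbidity flags, previous fragility fracture (registry
#' yes/no, may be missing), pre-admission pressure ulcer, the three New
#' Mobility Score items recoded to \{0, 0.33, 0.67, 1\} (may be missing) and
#' nursing-home provenance. Only previous fracture and the NMS items can be
#' missing; every other item is fully determined by the record.
#'
#' @param admissions Validated admission table.
#' @param map Code map, default [default_code_map()].
#' @param exact_thirds Recode NMS with exact 1/3, 2/3 instead of the printed
#'   constants 0.33, 0.67. Default `FALSE`.
#' @return data.frame: `record_id` plus the 21 columns of [fi_items()].
#' @export
derive_deficits <- function(admissions, map = default_code_map(),
                            exact_thirds = FALSE) {
  admissions <- validate_admissions(admissions)
  com <- extract_comorbidity_deficits(admissions, map)
  yesno <- function(x) ifelse(is.na(x), NA_integer_,
                              as.integer(x == "yes"))
  out <- data.frame(record_id = admissions$record_id, com,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$previous_fracture <- yesno(admissions$prev_fracture)
  out$pre_admission_pressure_ulcer <- derive_pressure_ulcer(admissions)
  out$nms_indoor <- recode_nms(admissions$nms_indoor, exact_thirds)
  out$nms_outdoor <- recode_nms(admissions$nms_outdoor, exact_thirds)
  out$nms_shopping <- recode_nms(admissions$nms_shopping, exact_thirds)
  out$nursing_home <- derive_nursing_home(admissions)
  out[, c("record_id", fi_items())]
}

#' Derive the six dichotomous adverse outcomes
#'
#' * `delirium`: ICD-10 F05 in any non-first (secondary) diagnosis position;
#'   a first-listed F05 is treated as the primary diagnosis and not counted.
#' * `prolonged_los`: acute length of stay of 30 days or more (inclusive).
#' * `death_7d`, `death_14d`: inpatient death by day 7 / day 14.
#' * `death_overall`: any inpatient death.
#' * `new_nh_admission`: new nursing-home admission on discharge; defined
#'   only for patients not admitted from a nursing home (`NA` otherwise).
#'
#' @param admissions Validated admission table.
#' @return data.frame: `record_id` plus six 0/1 outcome columns
#'   (`new_nh_admission` may be `NA`).
#' @export
derive_outcomes <- function(admissions) {
  admissions <- validate_admissions(admissions)
  codes <- split_codes(admissions$dx_codes)
  delirium <- vapply(codes, function(x) {
    length(x) > 1L && any(startsWith(normalise_icd(x[-1L]), "F05"))
  }, logical(1))
  dead <- admissions$inpatient_death == "yes"
  dday <- admissions$death_day
  data.frame(
    record_id = admissions$record_id,
    delirium = as.integer(delirium),
    prolonged_los = as.integer(admissions$los_days >= 30),
    death_7d = as.integer(dead & !is.na(dday) & dday <= 7),
    death_14d = as.integer(dead & !is.na(dday) & dday <= 14),
    death_overall = as.integer(dead),
    new_nh_admission = ifelse(admissions$adm_from_nh == "yes", NA_integer_,
                              as.integer(admissions$new_nh_admission == "yes")),
    stringsAsFactors = FALSE
  )
}

#' Read an admission table from CSV
#'
#' Empty fields are read as missing. The table is validated against the
#' schema; violations are reported with row numbers.
#'
#' @param path CSV path.
#' @return Validated admission data.frame.
#' @export
read_admissions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  int_cols <- c("age", "los_days", "death_day")
  chr_cols <- setdiff(admission_columns(), int_cols)
  classes <- c(stats::setNames(rep("integer", length(int_cols)), int_cols),
               stats::setNames(rep("character", length(chr_cols)), chr_cols))
  present <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = classes[names(classes) %in% present],
                        na.strings = c("", "NA"))
  if (nrow(df) == 0L) stop("empty admission CSV: ", path, call. = FALSE)
  validate_admissions(df)
}

#' Write an admission table to CSV
#'
#' Missing values are written as empty fields, round-tripping with
#' [read_admissions()].
#'
#' @param admissions Admission data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_admissions <- function(admissions, path) {
  utils::write.csv(admissions, path, row.names = FALSE, na = "")
  invisible(path)
}
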