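#' Recode a New Mobility Score item to a fractional deficit
#'
#' The four ordinal levels of each NMS item (indoor mobility, outdoor
#' mobility, shopping) are recoded so that higher values mean worse
#' pre-morbid mobility: no difficulty and no aid = 0; with a walking aid =
#' 0.33; with help from another person = 0.67; unable = 1. Missing levels
#' propagate to missing.
#'
#' The fractional constants are the literal printed values 0.33/0.67 by
#' default; `exact_thirds = TRUE` switches to 1/3 and 2/3.
#'
#' @param level Character vector of NMS levels (`no_difficulty_no_aid`,
#'   `with_aid`, `with_help`, `unable`) or `NA`.
#' @param exact_thirds Use exact thirds instead of the two-decimal constants.
#' @return Numeric vector in \{0, 0.33, 0.67, 1\} (or thirds), `NA` preserved.
#' @export
recode_nms <- function(level, exact_thirds = FALSE) {
  vals <- if (exact_thirds) c(0, 1 / 3, 2 / 3, 1) else c(0, 0.33, 0.67, 1)
  names(vals) <- nms_levels()
  level <- as.character(level)
  known <- is.na(level) | level %in% names(vals)
  if (!all(known)) {
    stop("unrecognised NMS level: ",
         paste(sQuote(unique(level[!known])), collapse = ", "), call. = FALSE)
  }
  unname(vals[level])
}

#' Compute the frailty index from a deficit table
#'
#' The FI of a record is the sum of its 21 item values divided by 21, giving
#' a score in \[0, 1\]. The default missingness policy is complete-case: a
#' record with any missing item gets no FI (`complete = FALSE`, `fi = NA`).
#' The alternative `"renormalise"` policy divides the sum of non-missing
#' items by the count of non-missing items; it is never the default.
#'
#' @param deficits Deficit table from [derive_deficits()] (`record_id` plus
#'   the 21 item columns).
#' @param policy `"complete_case"` (default) or `"renormalise"`.
#' @return data.frame: `record_id`, `fi`, `complete`.
#' @export
compute_fi <- function(deficits, policy = c("complete_case", "renormalise")) {
  policy <- match.arg(policy)
  items <- fi_items()
  miss <- setdiff(items, names(deficits))
  if (length(miss)) {
    stop("deficit table lacks items: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(deficits[, items])
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("deficit values must lie in [0, 1]", call. = FALSE)
  }
  complete <- rowSums(is.na(m)) == 0L
  fi <- switch(policy,
    complete_case = ifelse(complete, rowSums(m) / length(items), NA_real_),
    renormalise = rowSums(m, na.rm = TRUE) / rowSums(!is.na(m))
  )
  data.frame(record_id = deficits$record_id, fi = fi, complete = complete,
             stringsAsFactors = FALSE)
}

#' Fixed tertile cutpoints
#'
#' The default risk stratification uses fixed FI cutpoints 0.05 and 0.15
#' (low: FI <= 0.05; medium: 0.05 < FI <= 0.15; high: FI > 0.15), the
#' boundaries reported for the national hip-fracture cohort in which this
#' index was derived. Fixed cutpoints make runs on different cohorts
#' comparable; data-driven cutpoints are available via
#' [empirical_tertiles()].
#'
#' @param upper_low Upper bound (inclusive) of the low tertile.
#' @param upper_medium Upper bound (inclusive) of the medium tertile.
#' @return A `tertile_scheme` object.
#' @export
fixed_tertiles <- function(upper_low = 0.05, upper_medium = 0.15) {
  new_tertile_scheme(upper_low, upper_medium, "fixed")
}

new_tertile_scheme <- function(upper_low, upper_medium, method) {
  if (!is.numeric(upper_low) || !is.numeric(upper_medium) ||
      is.na(upper_low) || is.na(upper_medium) ||
      upper_low < 0 || upper_low >= upper_medium || upper_medium >= 1) {
    stop("tertile cutpoints must satisfy 0 <= upper_low < upper_medium < 1",
         call. = FALSE)
  }
  structure(list(upper_low = upper_low, upper_medium = upper_medium,
                 method = method),
            class = "tertile_scheme")
}

#' @export
print.tertile_scheme <- function(x, ...) {
  cat(sprintf("FI tertile scheme (%s): low <= %.4g < medium <= %.4g < high\n",
              x$method, x$upper_low, x$upper_medium))
  invisible(x)
}

#' Empirical tertile cutpoints from observed FI values
#'
#' Cutpoints are the 1/3 and 2/3 empirical quantiles under the
#' inclusive-rank convention: the smallest observed value v such that at
#' least ceiling(k*n/3) observations are <= v. All observations equal to a
#' cutpoint fall in the lower group.
#'
#' @param fi_values Numeric FI values in \[0, 1\]; `NA` dropped.
#' @return A `tertile_scheme` with `method = "empirical"`.
#' @export
empirical_tertiles <- function(fi_values) {
  x <- fi_values[!is.na(fi_values)]
  if (any(x < 0 | x > 1)) stop("FI values must lie in [0, 1]", call. = FALSE)
  if (length(unique(x)) < 3L) {
    stop("empirical tertiles need at least 3 distinct FI values",
         call. = FALSE)
  }
  s <- sort(x)
  n <- length(s)
  q <- function(k) s[ceiling(k * n / 3)]
  upper_low <- q(1)
  upper_medium <- q(2)
  if (upper_low >= upper_medium) {
    stop("tied FI distribution: empirical tertile cutpoints coincide (",
         format(upper_low), "); tertiles undefined", call. = FALSE)
  }
  new_tertile_scheme(upper_low, upper_medium, "empirical")
}

#' Assign FI risk tertiles
#'
#' low iff fi <= upper_low; medium iff upper_low < fi <= upper_medium; high
#' otherwise. Boundaries are inclusive downwards, so ties at a cutpoint land
#' in the lower group.
#'
#' @param fi Numeric FI values in \[0, 1\] (`NA` allowed, propagates).
#' @param scheme A `tertile_scheme`, default [fixed_tertiles()].
#' @return Factor with levels `low`, `medium`, `high` (`NA` preserved).
#' @export
assign_tertile <- function(fi, scheme = fixed_tertiles()) {
  stopifnot(inherits(scheme, "tertile_scheme"))
  ok <- is.na(fi) | (fi >= 0 & fi <= 1)
  if (!all(ok)) {
    stop("FI values outside [0, 1]: ",
         paste(format(utils::head(fi[!ok], 5L)), collapse = ", "),
         call. = FALSE)
  }
  lab <- ifelse(fi <= scheme$upper_low, "low",
                ifelse(fi <= scheme$upper_medium, "medium", "high"))
  factor(lab, levels = c("low", "medium", "high"))
}

#' Score a cohort: deficits, FI and tertile in one step
#'
#' Runs [derive_deficits()], [compute_fi()] and [assign_tertile()] and
#' appends `fi`, `complete` and `tertile` to the admission table. Records
#' without a complete deficit set get `complete = FALSE`, `fi = NA` and
#' `tertile = NA` under the default policy.
#'
#' @param admissions Validated admission table.
#' @param map Code map, default [default_code_map()].
#' @param scheme `tertile_scheme`, a string `"fixed"`/`"empirical"`, or
#'   `NULL` for the default fixed scheme. `"empirical"` derives cutpoints
#'   from the scored cohort itself.
#' @param policy FI missingness policy, see [compute_fi()].
#' @param exact_thirds See [derive_deficits()].
#' @return The admission table with `fi`, `complete`, `tertile` appended,
#'   plus attribute `"tertile_scheme"`.
#' @export
score_admissions <- function(admissions, map = default_code_map(),
                             scheme = fixed_tertiles(),
                             policy = c("complete_case", "renormalise"),
                             exact_thirds = FALSE) {
  policy <- match.arg(policy)
  admissions <- validate_admissions(admissions)
  deficits <- derive_deficits(admissions, map, exact_thirds)
  fires <- compute_fi(deficits, policy)
  if (is.character(scheme)) {
    scheme <- switch(match.arg(scheme, c("fixed", "empirical")),
                     fixed = fixed_tertiles(),
                     empirical = empirical_tertiles(fires$fi))
  } else if (is.null(scheme)) {
    scheme <- fixed_tertiles()
  }
  out <- admissions
  out$fi <- fires$fi
  out$complete <- fires$complete
  out$tertile <- assign_tertile(fires$fi, scheme)
  attr(out, "tertile_scheme") <- scheme
  out
}
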