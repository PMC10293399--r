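#' Canonical comorbidity names of the 21-item frailty index
#'
#' The 15 dichotomous chronic conditions contributing comorbidity deficits,
#' in canonical order. Each is flagged from ICD-10-AM diagnosis codes via a
#' [code_map] of code-prefix stems.
#'
#' @return Character vector of length 15.
#' @export
fi_conditions <- function() {
  c("ischemic_heart_disease",
    "peripheral_vascular_disease",
    "congestive_heart_failure",
    "copd",
    "hypertension",
    "diabetes_mellitus",
    "dementia",
    "stroke_hemiplegia",
    "chronic_renal_disease",
    "cancer",
    "parkinsons_disease",
    "arthritis",
    "reflux_peptic_ulcer",
    "chronic_liver_disease",
    "atrial_fibrillation")
}

#' Names of all 21 frailty-index items
#'
#' The 15 comorbidity flags plus previous fragility fracture, pre-admission
#' pressure ulcer, the three New Mobility Score items and nursing-home
#' provenance.
#'
#' @return Character vector of length 21.
#' @export
fi_items <- function() {
  c(fi_conditions(),
    "previous_fracture",
    "pre_admission_pressure_ulcer",
    "nms_indoor", "nms_outdoor", "nms_shopping",
    "nursing_home")
}

#' Default ICD-10-AM prefix map for the 15 comorbidity deficits
#'
#' Broad, literature-standard ICD-10 code stems per condition, chosen for
#' sensitivity (e.g. hypertension I10--I15, diabetes E10--E14, COPD J40--J44,
#' atrial fibrillation I48). These defaults are deliberately approximate and
#' fully overridable: supply your own map as a named list or load one from
#' YAML/JSON with [read_code_map()].
#'
#' @return Named list: condition name -> character vector of code prefixes.
#' @seealso [validate_code_map()], [match_code()]
#' @export
default_code_map <- function() {
  map <- list(
    ischemic_heart_disease      = c("I20", "I21", "I22", "I23", "I24", "I25"),
    peripheral_vascular_disease = c("I70", "I71", "I72", "I73"),
    congestive_heart_failure    = c("I50", "I11.0", "I13.0", "I13.2"),
    copd                        = c("J40", "J41", "J42", "J43", "J44"),
    hypertension                = c("I10", "I11", "I12", "I13", "I15"),
    diabetes_mellitus           = c("E10", "E11", "E13", "E14"),
    dementia                    = c("F00", "F01", "F02", "F03", "G30"),
    stroke_hemiplegia           = c("I60", "I61", "I62", "I63", "I64",
                                    "I69", "G81"),
    chronic_renal_disease       = c("N18", "N19"),
    cancer                      = paste0("C", 0:9),
    parkinsons_disease          = c("G20", "G21", "G22"),
    arthritis                   = c("M05", "M06", "M15", "M16", "M17",
                                    "M18", "M19"),
    reflux_peptic_ulcer         = c("K21", "K25", "K26", "K27", "K28"),
    chronic_liver_disease       = c("K70", "K73", "K74"),
    atrial_fibrillation         = "I48"
  )
  validate_code_map(map)
}

# hypertension stems exclude I14 (unassigned in ICD-10) and avoid nesting
# with the CHF dot-level stems only across conditions, which is permitted.

#' Normalise an ICD-10 code for dot-insensitive comparison
#'
#' Uppercases and strips dots, so \code{"I25.1"} and \code{"i251"} compare
#' equal. ICD-10-AM dialects differ in dot usage.
#'
#' @param code Character vector of ICD codes.
#' @return Character vector of normalised codes.
#' @export
normalise_icd <- function(code) {
  if (length(code) == 0L) return(character(0))
  code <- toupper(gsub(".", "", as.character(code), fixed = TRUE))
  bad <- is.na(code) | !grepl("^[A-Z]", code)
  if (any(bad)) {
    stop("malformed ICD code (no leading letter): ",
         paste(sQuote(unique(code[bad])), collapse = ", "), call. = FALSE)
  }
  code
}

#' Test whether an ICD code matches any of a set of prefixes
#'
#' Dot-insensitive prefix matching: the normalised code must start with a
#' normalised prefix. A code shorter than the prefix never matches.
#'
#' @param code Single ICD-10 code string (non-empty).
#' @param prefixes Character vector of ICD code stems.
#' @return `TRUE` or `FALSE`.
#' @examples
#' match_code("I25.1", "I25")  # TRUE
#' match_code("I2", "I25")     # FALSE
#' @export
match_code <- function(code, prefixes) {
  if (length(code) != 1L || is.na(code) || !nzchar(code)) {
    stop("'code' must be a single non-empty string", call. = FALSE)
  }
  code <- normalise_icd(code)
  any(startsWith(code, normalise_icd(prefixes)))
}

#' Validate a comorbidity code map
#'
#' Checks the structural invariants of a code map: exactly the 15 canonical
#' condition entries ([fi_conditions()]), every prefix a syntactically valid
#' ICD-10 stem (leading letter, digits, optional dot-suffix), and no prefix
#' nested inside another prefix of the same condition.
#'
#' @param map Named list: condition -> character vector of prefixes.
#' @return The map, invisibly reordered to canonical condition order.
#' @export
validate_code_map <- function(map) {
  if (!is.list(map)) stop("code map must be a named list", call. = FALSE)
  want <- fi_conditions()
  missing_cond <- setdiff(want, names(map))
  extra_cond <- setdiff(names(map), want)
  if (length(missing_cond) || length(extra_cond)) {
    stop("code map must have exactly the 15 canonical conditions; missing: ",
         paste(missing_cond, collapse = ", "), "; unexpected: ",
         paste(extra_cond, collapse = ", "), call. = FALSE)
  }
  for (cond in want) {
    p <- as.character(map[[cond]])
    if (length(p) == 0L) {
      stop("condition ", sQuote(cond), " has an empty prefix set",
           call. = FALSE)
    }
    ok <- grepl("^[A-Za-z][0-9]+(\\.[0-9A-Za-z]+)?$", p)
    if (!all(ok)) {
      stop("condition ", sQuote(cond), " has malformed prefixes: ",
           paste(sQuote(p[!ok]), collapse = ", "), call. = FALSE)
    }
    np <- normalise_icd(p)
    if (anyDuplicated(np)) {
      stop("condition ", sQuote(cond), " has duplicate prefixes",
           call. = FALSE)
    }
    for (i in seq_along(np)) {
      nested <- startsWith(np[-i], np[i])
      if (any(nested)) {
        stop("condition ", sQuote(cond), " has nested prefixes: ",
             sQuote(p[i]), " is a prefix of ",
             paste(sQuote(p[-i][nested]), collapse = ", "), call. = FALSE)
      }
    }
    map[[cond]] <- p
  }
  invisible(map[want])
}

#' Read a comorbidity code map from YAML or JSON
#'
#' @param path Path to a YAML (`.yaml`/`.yml`) or JSON file mapping each of
#'   the 15 condition names to a list of ICD-10 code prefixes.
#' @return Validated code map (named list), in canonical condition order.
#' @export
read_code_map <- function(path) {
  if (!file.exists(path)) stop("code map file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- lapply(raw, as.character)
  map <- validate_code_map(raw)
  map
}

#' Write a code map to YAML
#'
#' @param map Validated code map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_code_map <- function(map, path) {
  map <- validate_code_map(map)
  yaml::write_yaml(lapply(map, as.list), path)
  invisible(path)
}
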