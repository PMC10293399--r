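# Fixture builders and independent brute-force oracles used across tests.

make_admission <- function(id = "r1", age = 80, sex = "female", asa = "2",
                           dx = "S72.00", prev = "no", new_pu = "no",
                           nms_in = "no_difficulty_no_aid",
                           nms_out = "no_difficulty_no_aid",
                           nms_shop = "no_difficulty_no_aid",
                           adm_nh = "no", disch_nh = "no",
                           fracture = "intracapsular",
                           surgery = "arthroplasty",
                           los = 10, death = "no", death_day = NA,
                           new_nh = "no") {
  data.frame(record_id = id, age = age, sex = sex, asa = asa,
             dx_codes = paste(dx, collapse = ";"),
             prev_fracture = prev, new_pu_hosp = new_pu,
             nms_indoor = nms_in, nms_outdoor = nms_out,
             nms_shopping = nms_shop,
             adm_from_nh = adm_nh, disch_to_nh = disch_nh,
             fracture_type = fracture, surgery_type = surgery,
             los_days = los, inpatient_death = death,
             death_day = as.integer(death_day),
             new_nh_admission = if (adm_nh == "yes") "not_applicable"
                                else new_nh,
             stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  for (i in seq_along(rows)) rows[[i]]$record_id <- paste0("r", i)
  do.call(rbind, rows)
}

# brute-force comorbidity flags: full scan over the code x prefix
# cross-product, independent of the package's vectorised matcher
brute_comorbidity <- function(codes, map) {
  norm <- function(x) toupper(gsub(".", "", x, fixed = TRUE))
  vapply(map, function(prefixes) {
    hit <- FALSE
    for (code in codes) for (p in prefixes) {
      if (startsWith(norm(code), norm(p))) hit <- TRUE
    }
    as.integer(hit)
  }, integer(1))
}

# brute-force all-pairs Mann-Whitney AUC
brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (x in cases) for (y in controls) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(cases) * length(controls))
}

# closed-form 2x2 logistic data: exposed/unexposed event counts
two_by_two <- function(a, n1, b, n0) {
  x <- c(rep(1, n1), rep(0, n0))
  y <- c(rep(1, a), rep(0, n1 - a), rep(1, b), rep(0, n0 - b))
  list(X = cbind("(Intercept)" = rep(1, n1 + n0), exposed = x), y = y)
}

random_codes <- function(k) {
  letters_pool <- c("I", "E", "J", "F", "G", "N", "C", "M", "K", "L", "S")
  paste0(sample(letters_pool, k, replace = TRUE),
         sample(10:99, k, replace = TRUE),
         ifelse(runif(k) < 0.5, "", paste0(".", sample(0:9, k,
                                                       replace = TRUE))))
}
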