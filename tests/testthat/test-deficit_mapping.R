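test_that("prefix matching is dot-insensitive and length-aware", {
  expect_true(match_code("I25.1", "I25"))
  expect_true(match_code("i251", "I25"))
  expect_false(match_code("I2", "I25"))
  expect_true(match_code("L89", "L89"))
  expect_false(match_code("L90", "L89"))
  expect_error(match_code("251", "I25"), "malformed")
  expect_error(match_code("", "I25"), "non-empty")
})

test_that("the default code map satisfies its structural invariants", {
  map <- default_code_map()
  expect_length(map, 15L)
  expect_setequal(names(map), fi_conditions())
  # non-nesting within condition
  for (cond in names(map)) {
    p <- toupper(gsub(".", "", map[[cond]], fixed = TRUE))
    for (i in seq_along(p)) {
      expect_false(any(startsWith(p[-i], p[i])),
                   label = paste("nested prefixes in", cond))
    }
  }
  expect_error(validate_code_map(map[-1]), "missing")
  broken <- map
  broken$hypertension <- c("I10", "I10.1")
  expect_error(validate_code_map(broken), "nested")
})

test_that("comorbidity extraction matches direct expectations", {
  map <- default_code_map()
  fracture_only <- make_admission(dx = "S72.0")
  expect_true(all(extract_comorbidity_deficits(fracture_only, map) == 0L))

  rec <- make_admission(dx = c("S72.00", "I10", "E11.9"))
  flags <- extract_comorbidity_deficits(rec, map)[1, ]
  expect_identical(unname(flags[c("hypertension", "diabetes_mellitus")]),
                   c(1L, 1L))
  expect_identical(sum(flags), 2L)
  # cross-checked against an exhaustive scan of the shipped map
  expect_identical(unname(flags),
                   unname(brute_comorbidity(c("S72.00", "I10", "E11.9"),
                                            map)))

  dup <- make_admission(dx = c("S72.00", "I10", "I10"))
  expect_identical(unname(extract_comorbidity_deficits(dup, map)[1, "hypertension"]),
                   1L)
})

test_that("comorbidity extraction equals the brute-force prefix oracle on random code lists", {
  map <- default_code_map()
  set.seed(101)
  for (i in 1:60) {
    codes <- c("S72.00", random_codes(sample(0:9, 1)))
    rec <- make_admission(dx = codes)
    expect_identical(unname(extract_comorbidity_deficits(rec, map)[1, ]),
                     unname(brute_comorbidity(codes, map)),
                     label = paste("codes:", paste(codes, collapse = ";")))
  }
})

test_that("adding a diagnosis code never flips a comorbidity flag to 0", {
  map <- default_code_map()
  set.seed(202)
  for (i in 1:25) {
    codes <- c("S72.00", random_codes(sample(1:6, 1)))
    base <- extract_comorbidity_deficits(make_admission(dx = codes), map)
    more <- extract_comorbidity_deficits(
      make_admission(dx = c(codes, random_codes(2))), map)
    expect_true(all(more >= base))
  }
})

test_that("pre-admission pressure ulcer needs L89 without a new in-hospital ulcer", {
  expect_identical(derive_pressure_ulcer(
    make_admission(dx = c("S72.00", "L89"), new_pu = "no")), 1L)
  expect_identical(derive_pressure_ulcer(
    make_admission(dx = c("S72.00", "L89"), new_pu = "yes")), 0L)
  expect_identical(derive_pressure_ulcer(
    make_admission(dx = "S72.00", new_pu = "no")), 0L)
  # dotted sub-codes of L89 count too
  expect_identical(derive_pressure_ulcer(
    make_admission(dx = c("S72.00", "L89.2"), new_pu = "no")), 1L)
  rec <- make_admission()
  rec$new_pu_hosp <- NA
  expect_error(derive_pressure_ulcer(rec), "r1")
})

test_that("nursing-home provenance is admitted-from OR discharged-to", {
  expect_identical(derive_nursing_home(make_admission(adm_nh = "yes")), 1L)
  expect_identical(derive_nursing_home(make_admission(disch_nh = "yes")), 1L)
  expect_identical(derive_nursing_home(make_admission()), 0L)
})

test_that("outcome derivation applies the documented thresholds", {
  expect_identical(derive_outcomes(make_admission(los = 30))$prolonged_los, 1L)
  expect_identical(derive_outcomes(make_admission(los = 29))$prolonged_los, 0L)
  d <- derive_outcomes(make_admission(death = "yes", death_day = 10))
  expect_identical(c(d$death_7d, d$death_14d, d$death_overall),
                   c(0L, 1L, 1L))
  d7 <- derive_outcomes(make_admission(death = "yes", death_day = 7))
  expect_identical(c(d7$death_7d, d7$death_14d), c(1L, 1L))
  # death_day without a death (and vice versa) is rejected at validation
  bad <- make_admission(death = "yes")
  expect_error(derive_outcomes(bad), "death_day")
})

test_that("delirium requires F05 in a non-first (secondary) position", {
  expect_identical(derive_outcomes(
    make_admission(dx = c("S72.00", "F05")))$delirium, 1L)
  expect_identical(derive_outcomes(
    make_admission(dx = c("S72.00", "F05.1")))$delirium, 1L)
  # first-listed F05 is the primary diagnosis and never counted
  expect_identical(derive_outcomes(
    make_admission(dx = c("F05", "S72.00")))$delirium, 0L)
  expect_identical(derive_outcomes(
    make_admission(dx = "F05"))$delirium, 0L)
})

test_that("new nursing-home admission is undefined for nursing-home residents", {
  res <- derive_outcomes(make_admission(adm_nh = "yes", disch_nh = "yes"))
  expect_true(is.na(res$new_nh_admission))
  expect_identical(derive_outcomes(
    make_admission(new_nh = "yes"))$new_nh_admission, 1L)
})

test_that("deficit derivation is deterministic and only NMS/previous fracture can be missing", {
  rec <- make_admission(dx = c("S72.00", "I48", "C5"), prev = NA,
                        nms_in = NA)
  d1 <- derive_deficits(rec)
  d2 <- derive_deficits(rec)
  expect_identical(d1, d2)
  expect_true(is.na(d1$previous_fracture))
  expect_true(is.na(d1$nms_indoor))
  comorb <- unlist(d1[1, fi_conditions()])
  expect_false(anyNA(comorb))
  expect_identical(unname(comorb[c("atrial_fibrillation", "cancer")]),
                   c(1L, 1L))
})

test_that("admission CSV round-trips losslessly", {
  coh <- make_cohort(
    make_admission(dx = c("S72.00", "I10"), prev = NA),
    make_admission(age = 91, sex = "male", asa = "unknown", nms_out = NA),
    make_admission(adm_nh = "yes", death = "yes", death_day = 3, los = 3)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_admissions(coh, path)
  back <- read_admissions(path)
  expect_identical(back$prev_fracture, coh$prev_fracture)
  expect_equal(back, coh, ignore_attr = TRUE)
  # empty file is a schema error
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(admission_columns(), collapse = ","), empty)
  expect_error(read_admissions(empty), "empty")
})

test_that("schema violations are reported with row numbers", {
  coh <- make_cohort(make_admission(), make_admission(age = 59))
  expect_error(validate_admissions(coh), "rows 2")
  coh2 <- make_cohort(make_admission(), make_admission(adm_nh = "yes"))
  coh2$new_nh_admission[2] <- "no"
  expect_error(validate_admissions(coh2), "not_applicable")
})
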