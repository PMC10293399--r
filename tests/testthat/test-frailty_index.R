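test_that("NMS recoding uses the printed ordinal fractions", {
  expect_identical(recode_nms(c("no_difficulty_no_aid", "with_aid",
                                "with_help", "unable")),
                   c(0, 0.33, 0.67, 1))
  expect_identical(recode_nms(c("with_aid", NA)), c(0.33, NA))
  expect_identical(recode_nms("with_help", exact_thirds = TRUE), 2 / 3)
  expect_error(recode_nms("walks_fine"), "walks_fine")
})

deficit_row <- function(values = list()) {
  d <- as.list(setNames(rep(0, 21), fi_items()))
  d[names(values)] <- values
  cbind(data.frame(record_id = "r1", stringsAsFactors = FALSE),
        as.data.frame(d, check.names = FALSE))
}

test_that("the FI is the proportion of the 21 deficits present", {
  expect_equal(compute_fi(deficit_row())$fi, 0)
  saturated <- deficit_row(setNames(as.list(rep(1, 21)), fi_items()))
  expect_equal(compute_fi(saturated)$fi, 1)
  r <- deficit_row(list(hypertension = 1, arthritis = 1, nms_indoor = 0.33))
  expect_equal(compute_fi(r)$fi, 2.33 / 21, tolerance = 1e-12)
})

test_that("any missing item makes the record incomplete under the default policy", {
  r <- deficit_row(list(nms_shopping = NA))
  res <- compute_fi(r)
  expect_false(res$complete)
  expect_true(is.na(res$fi))
  # renormalised policy divides by the non-missing count instead
  r2 <- deficit_row(list(hypertension = 1, nms_shopping = NA))
  expect_equal(compute_fi(r2, policy = "renormalise")$fi, 1 / 20)
  expect_false(compute_fi(r2, policy = "renormalise")$complete)
})

test_that("raising one item of a complete vector raises the FI by delta/21", {
  set.seed(7)
  for (i in 1:20) {
    vals <- setNames(as.list(c(sample(0:1, 17, replace = TRUE),
                               sample(c(0, 0.33, 0.67, 1), 3, TRUE),
                               sample(0:1, 1))),
                     fi_items())
    base <- deficit_row(vals)
    item <- sample(fi_items(), 1)
    delta <- if (vals[[item]] < 1) 1 - vals[[item]] else -vals[[item]]
    bumped <- base
    bumped[[item]] <- bumped[[item]] + delta
    expect_equal(compute_fi(bumped)$fi - compute_fi(base)$fi, delta / 21,
                 tolerance = 1e-12)
    expect_true(compute_fi(base)$fi >= 0 && compute_fi(base)$fi <= 1)
  }
})

test_that("fixed tertile assignment respects the inclusive boundaries", {
  sch <- fixed_tertiles()
  expect_identical(as.character(assign_tertile(c(0, 0.05, 0.0501, 0.10,
                                                 0.15, 0.1501, 0.20, 1),
                                               sch)),
                   c("low", "low", "medium", "medium", "medium", "high",
                     "high", "high"))
  expect_error(assign_tertile(1.2, sch), "outside")
  expect_error(fixed_tertiles(0.3, 0.2), "cutpoints")
})

test_that("tertile labels partition [0,1] and are monotone in the FI", {
  sch <- fixed_tertiles()
  fi <- seq(0, 1, by = 0.01)
  lab <- assign_tertile(fi, sch)
  expect_false(anyNA(lab))
  expect_true(all(diff(as.integer(lab)) >= 0))
})

test_that("empirical tertiles follow the inclusive-rank quantile convention", {
  values <- 0.01 * (1:9)
  # brute-force oracle: smallest observed v with at least ceil(k*n/3)
  # observations <= v
  rank_cut <- function(x, k) {
    s <- sort(x)
    need <- ceiling(k * length(x) / 3)
    s[min(which(vapply(s, function(v) sum(x <= v), 0) >= need))]
  }
  sch <- empirical_tertiles(values)
  expect_equal(sch$upper_low, rank_cut(values, 1))
  expect_equal(sch$upper_medium, rank_cut(values, 2))
  expect_equal(sch$upper_low, 0.03)
  expect_equal(sch$upper_medium, 0.06)

  set.seed(11)
  for (i in 1:10) {
    x <- round(runif(sample(10:200, 1)), 3)
    if (length(unique(x)) < 3) next
    sch <- tryCatch(empirical_tertiles(x), error = function(e) NULL)
    if (is.null(sch)) next
    expect_equal(sch$upper_low, rank_cut(x, 1))
    expect_equal(sch$upper_medium, rank_cut(x, 2))
  }
})

test_that("empirical tertiles reject degenerate distributions and keep ties together", {
  expect_error(empirical_tertiles(rep(0.1, 50)), "distinct")
  expect_error(empirical_tertiles(c(0.1, 0.2)), "distinct")
  # heavy ties at a cutpoint all land in the lower group
  x <- c(rep(0.05, 10), seq(0.1, 0.9, length.out = 20))
  sch <- empirical_tertiles(x)
  expect_equal(sch$upper_low, 0.05)
  lab <- assign_tertile(x, sch)
  expect_true(all(lab[x == 0.05] == "low"))
  # both cutpoints swallowed by the tie mass: tertiles undefined
  expect_error(empirical_tertiles(c(rep(0.05, 30), 0.2, 0.4, 0.6)),
               "coincide")
})

test_that("empirical tertile group sizes differ from n/3 by at most 1 on tie-free data", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(c(30, 31, 32, 100, 101), 1)
    x <- sample(seq(0.001, 0.999, length.out = 5000), n)
    sch <- empirical_tertiles(x)
    sizes <- table(assign_tertile(x, sch))
    expect_true(all(abs(sizes - n / 3) <= 1),
                label = paste("sizes", paste(sizes, collapse = "/")))
  }
})

test_that("score_admissions appends fi, completeness and tertile consistently", {
  coh <- make_cohort(
    make_admission(dx = c("S72.00", "I10", "I48")),          # fi = 2/21
    make_admission(dx = "S72.00", nms_in = "unable"),        # fi = 1/21
    make_admission(dx = "S72.00", prev = NA),                # incomplete
    make_admission(dx = c("S72.00", "I10", "I21", "F03", "N18"),
                   nms_in = "with_help", adm_nh = "yes")     # high burden
  )
  scored <- score_admissions(coh)
  expect_equal(scored$fi,
               c(2 / 21, 1 / 21, NA, (4 + 0.67 + 1) / 21),
               tolerance = 1e-12)
  expect_identical(scored$complete, c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(as.character(scored$tertile),
                   c("medium", "low", NA, "high"))
  expect_s3_class(attr(scored, "tertile_scheme"), "tertile_scheme")
})
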