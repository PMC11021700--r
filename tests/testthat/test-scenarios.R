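boundary_baseline <- function() {
  data.frame(
    id = 1:6,
    smoking = factor(c("current", "ex", "never", "current", "current", "current"),
                     levels = c("never", "ex", "current")),
    sbp = c(139.99, 140, 150, 140, 130, 160),
    tchdl = c(4.99, 5, 6, 5, 3.4, 7),
    bplm = c(0L, 0L, 1L, 0L, 0L, 1L),
    llm = c(0L, 1L, 0L, 0L, 0L, 0L))
}

test_that("eligibility thresholds are inclusive and medication-aware", {
  bl <- boundary_baseline()
  expect_identical(eligible(bl, scenario("I")),
                   c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(eligible(bl, scenario("IIa")),
                   c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(eligible(bl, scenario("IIb")),
                   c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(eligible(bl, scenario("IIIa")),
                   c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(eligible(bl, scenario("IIIb")),
                   c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("covariate modification is idempotent and touches only its fields", {
  bl <- default_cohort()$baseline
  for (id in c("I", "IIa", "IIb", "IIIa", "IIIb")) {
    sp <- scenario(id)
    el <- bl[eligible(bl, sp), , drop = FALSE]
    once <- modify_records(el, sp)
    twice <- modify_records(once, sp)
    expect_identical(once, twice)
    touched <- switch(id, I = "smoking", IIa = "sbp", IIb = c("bplm", "sbp"),
                      IIIa = "tchdl", IIIb = c("llm", "tchdl"))
    expect_identical(once[setdiff(names(el), touched)],
                     el[setdiff(names(el), touched)])
  }
})

test_that("modification targets the scenario's post-intervention values", {
  bl <- boundary_baseline()
  el <- bl[eligible(bl, scenario("IIb")), ]
  m <- modify_records(el, scenario("IIb"))
  expect_true(all(m$bplm == 1L))
  expect_true(all(m$sbp == 130))
  m2 <- modify_records(el, scenario("IIb", variant = "medication_only"))
  expect_true(all(m2$bplm == 1L))
  expect_identical(m2$sbp, el$sbp)
  expect_error(modify_records(bl, scenario("IIb")), "not eligible")
})

test_that("the index-visit rule picks the right visit and reads treatment", {
  bl <- data.frame(id = 1:4,
                   smoking = factor(rep("current", 4),
                                    levels = c("never", "ex", "current")),
                   sbp = rep(150, 4), tchdl = rep(6, 4),
                   bplm = rep(0L, 4), llm = rep(0L, 4))
  fu <- data.frame(
    id         = c(1,    1,   2,    3,   4),
    visit_time = c(6,    18,  25,   24,  12),
    smoking    = factor(c("ex", "current", "ex", "ex", "current"),
                        levels = c("never", "ex", "current")),
    sbp        = c(120, 145, 150, 130, 150),
    tchdl      = c(3.5, 6,   6,   3.6, 6),
    bplm       = 0L, llm = 0L)

  sp <- scenario("I")
  a <- derive_treatment(bl, fu, sp)
  expect_identical(a$included, c(TRUE, FALSE, TRUE, TRUE))
  # person 1: latest in-window visit (18) shows a current smoker
  expect_identical(a$A, c(0L, NA_integer_, 1L, 0L))
  expect_identical(a$index_time, c(18, NA, 24, 12))

  first <- derive_treatment(bl, fu, scenario("I", index_visit = "first"))
  expect_identical(first$A[1], 1L)   # first visit (6) shows an ex-smoker
  expect_identical(first$index_time[1], 6)

  # treatment thresholds at the index visit are inclusive
  a2 <- derive_treatment(bl, fu, scenario("IIa"))
  expect_identical(a2$A, c(0L, NA_integer_, 1L, 0L))
  fu2 <- fu; fu2$sbp[5] <- 130   # person 4's only visit
  expect_identical(derive_treatment(bl, fu2, scenario("IIa"))$A[4], 1L)
  fu3 <- fu; fu3$tchdl[5] <- 3.5
  expect_identical(derive_treatment(bl, fu3, scenario("IIIa"))$A[4], 1L)
})

test_that("scenario objects validate and load from YAML overrides", {
  expect_error(scenario("IV"), "arg")
  expect_error(scenario("I", window_months = 0), "positive")
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c("IIa:", "  window_months: 12", "  index_visit: first"), path)
  sc <- scenarios_from_yaml(path)
  expect_identical(sc$IIa$window_months, 12L)
  expect_identical(sc$IIa$index_visit, "first")
  expect_identical(sc$I$window_months, 24)
  expect_identical(sc$IIb$variant, "with_factor_change")
})
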