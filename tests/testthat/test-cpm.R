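# Simple two-sex exponential survival data with one binary predictor whose
# true log hazard ratio is known.
simple_survival_data <- function(n = 20000, log_hr = 0.5, seed = 21) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.4)
  sex <- factor(sample(c("female", "male"), n, replace = TRUE),
                levels = c("female", "male"))
  lambda <- 0.002 * exp(log_hr * x)
  t_ev <- rexp(n, lambda)
  data.frame(id = seq_len(n), sex = sex, x = x,
             event_time = pmin(t_ev, 80),
             event_type = factor(ifelse(t_ev <= 80, "cvd", "admin_censor"),
                                 levels = c("cvd", "death_other", "dropout",
                                            "admin_censor")))
}

test_that("a known log hazard ratio is recovered in both sex strata", {
  dat <- simple_survival_data()
  fit <- fit_cpm(dat, predictors = "x")
  for (sx in c("female", "male")) {
    m <- fit[[sx]]
    expect_lt(abs(m$coefficients[["x"]] - 0.5), 3 * m$se[["x"]])
  }
})

test_that("a pure-noise predictor gets a coefficient within 3 SE of zero", {
  coh <- default_cohort()
  bl <- coh$baseline
  set.seed(77)
  bl$noise <- rnorm(nrow(bl))
  fit <- fit_cpm(bl, predictors = c(default_predictors(), "noise"))
  for (sx in c("female", "male"))
    expect_lt(abs(fit[[sx]]$coefficients[["noise"]]),
              3 * fit[[sx]]$se[["noise"]])
})

test_that("coefficients maximize the partial likelihood (brute force)", {
  # six untied records per stratum, checked against a grid-free 1-d optimum
  # of the exact Cox partial likelihood
  base <- data.frame(
    id = 1:6,
    x = c(1, 0, 1, 0, 1, 0),
    event_time = c(5, 8, 13, 21, 34, 55),
    event_type = factor(c("cvd", "cvd", "admin_censor", "cvd", "cvd",
                          "admin_censor"),
                        levels = c("cvd", "death_other", "dropout",
                                   "admin_censor")))
  dat_f <- base; dat_f$sex <- "female"
  dat_m <- base; dat_m$sex <- "male"; dat_m$id <- 7:12
  dat <- rbind(dat_f, dat_m)
  dat$sex <- factor(dat$sex, levels = c("female", "male"))
  fit <- fit_cpm(dat, predictors = "x")

  partial_loglik <- function(beta) {
    ll <- 0
    for (i in which(base$event_type == "cvd")) {
      risk_set <- base$event_time >= base$event_time[i]
      ll <- ll + beta * base$x[i] -
        log(sum(exp(beta * base$x[risk_set])))
    }
    ll
  }
  opt <- optimize(partial_loglik, c(-10, 10), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(fit$female$coefficients[["x"]]), opt$maximum,
               tolerance = 1e-4)
})

test_that("the reference profile's predicted risk equals 1 - S0(horizon)", {
  coh <- default_cohort()
  fit <- fit_cpm(coh$baseline)
  for (sx in c("female", "male")) {
    m <- fit[[sx]]
    ref <- m$reference_profile
    ref$sex <- factor(sx, levels = c("female", "male"))
    r <- predict_risk(m, ref)$risk
    expect_equal(r, 1 - m$baseline_survival, tolerance = 1e-10)
  }
})

test_that("predicted risk is monotone in a positive-coefficient predictor", {
  coh <- default_cohort()
  fit <- fit_cpm(coh$baseline)
  m <- fit$male
  expect_gt(m$coefficients[["sbp"]], 0)
  grid <- m$reference_profile[rep(1, 5), ]
  grid$sbp <- seq(110, 190, by = 20)
  r <- predict_risk(m, grid)$risk
  expect_true(all(diff(r) > 0))
})

test_that("mean predicted risk matches the observed incidence (calibration)", {
  coh <- default_cohort()
  bl <- coh$baseline
  fit <- fit_cpm(bl)
  pred <- predict_risk(fit, bl)$risk
  obs <- mean(bl$event_type == "cvd" & bl$event_time <= 60)
  expect_lt(abs(mean(pred) - obs), 0.01)
  expect_gt(mean(pred), 0.02)  # cohort-level risk sits in the low percents
  expect_lt(mean(pred), 0.05)
  # men carry higher mean risk, as published
  expect_gt(mean(pred[bl$sex == "male"]), mean(pred[bl$sex == "female"]))
})

test_that("degenerate designs and misuse raise informative errors", {
  coh <- default_cohort()
  bl <- coh$baseline
  bl$sbp_copy <- bl$sbp
  expect_error(fit_cpm(bl, predictors = c("sbp", "sbp_copy")), "collinear")
  expect_error(fit_cpm(bl, predictors = "not_a_column"), "not_a_column")
  few <- bl[bl$event_type != "cvd", ][1:50, ]
  expect_error(fit_cpm(few, predictors = "sbp"), "fewer than 2")
  fit <- fit_cpm(bl)
  expect_error(predict_risk(fit$male, bl, horizon_months = 12), "horizon")
  expect_error(predict_risk(fit$male, bl[, c("id", "sex")]), "lacks predictor")
})

test_that("the JSON serialization carries what absolute risk needs", {
  coh <- default_cohort()
  fit <- fit_cpm(coh$baseline)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  cpm_to_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_named(back, c("female", "male"))
  expect_equal(back$male$baseline_survival, fit$male$baseline_survival,
               tolerance = 1e-12)
  expect_equal(unlist(back$female$coefficients),
               fit$female$coefficients, tolerance = 1e-12)
})
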