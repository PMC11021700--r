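# ---- solver ---------------------------------------------------------------

test_that("the internal logistic solver agrees with stats::glm", {
  set.seed(5)
  n <- 500
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  colnames(x) <- c("(Intercept)", "z", "b")
  eta <- -0.5 + 0.8 * x[, 2] - 1.2 * x[, 3]
  y <- rbinom(n, 1, plogis(eta))
  w <- sample(1:3, n, replace = TRUE)
  ours <- riskintervene:::fit_logit(x, y, weights = w)
  ref <- glm.fit(x, y, weights = w, family = binomial())
  expect_equal(unname(ours$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(ours$aic, ref$aic, tolerance = 1e-6)
})

test_that("the person-month solver equals the generic solver on the expansion", {
  set.seed(6)
  n <- 120
  xper <- cbind(`(Intercept)` = 1, z = rnorm(n), A = rbinom(n, 1, 0.5))
  m <- sample(3:10, n, replace = TRUE)
  person <- rep(seq_len(n), m)
  k <- unlist(lapply(m, seq_len)) - 1
  eta <- (xper %*% c(2, 0.4, -0.3))[person] - 0.05 * k
  y <- rbinom(length(k), 1, plogis(eta))
  w <- runif(length(k), 0.5, 2)
  a <- riskintervene:::fit_logit_pm(xper, k, person, y, weights = w)
  b <- riskintervene:::fit_logit(cbind(xper[person, ], k = k), y, weights = w)
  expect_equal(unname(a$coefficients), unname(b$coefficients),
               tolerance = 1e-6)
  expect_equal(a$fitted, b$fitted, tolerance = 1e-6)
})

# ---- selection weights ----------------------------------------------------

test_that("an empty covariate set gives everyone the marginal selection weight", {
  df <- data.frame(id = 1:10)
  assign <- data.frame(id = 1:10, included = rep(c(TRUE, FALSE), c(4, 6)),
                       index_time = NA_real_, A = NA_integer_)
  sw <- fit_selection_weights(df, assign, covariates = character(0))
  expect_equal(sw$weights$p_included, rep(0.4, 10), tolerance = 1e-9)
  expect_equal(sw$weights$selection_weight[1:4], rep(2.5, 4), tolerance = 1e-9)
  expect_true(all(is.na(sw$weights$selection_weight[5:10])))
})

test_that("selection weights restore the full-cohort covariate distribution", {
  set.seed(8)
  n <- 20000
  z <- rbinom(n, 1, 0.3)
  p_inc <- plogis(-1.5 + 2 * z)
  inc <- runif(n) < p_inc
  df <- data.frame(id = seq_len(n), z = z)
  assign <- data.frame(id = df$id, included = inc, index_time = NA_real_,
                       A = NA_integer_)
  sw <- fit_selection_weights(df, assign, covariates = "z")
  w <- sw$weights$selection_weight[inc]
  z_reweighted <- sum(w * z[inc]) / sum(w)
  expect_gt(mean(z[inc]), mean(z) + 0.1)          # selection is real
  expect_lt(abs(z_reweighted - mean(z)), 0.01)    # and the weights undo it
})

# ---- treatment weights ----------------------------------------------------

test_that("stabilized weights on a two-stratum table are the exact ratios", {
  d <- two_stratum_data()
  tw <- fit_treatment_weights(d, d$A, confounders = "L", use_spline = FALSE)
  expect_equal(tw$model$p_marginal, 0.6, tolerance = 1e-9)
  expected <- ifelse(d$L == 0,
                     ifelse(d$A == 1, 0.6 / 0.4, 0.4 / 0.6),
                     ifelse(d$A == 1, 0.6 / 0.8, 0.4 / 0.2))
  expect_equal(tw$weights$sw_treatment, expected, tolerance = 1e-7)
})

test_that("an empty confounder set gives stabilized weights exactly 1", {
  d <- two_stratum_data()
  tw <- fit_treatment_weights(d, d$A, confounders = character(0))
  expect_identical(tw$model$chosen, "marginal")
  expect_equal(tw$weights$sw_treatment, rep(1, nrow(d)), tolerance = 1e-12)
  expect_error(fit_treatment_weights(d, rep(1, nrow(d)), "L"),
               "both treatment groups")
})

# ---- person-month expansion -----------------------------------------------

test_that("the person-month expansion counts months and flags correctly", {
  bl <- data.frame(id = 1:5,
                   event_time = c(14.5, 30, 100, 11, 72),
                   event_type = factor(c("cvd", "death_other", "cvd",
                                         "cvd", "admin_censor"),
                                       levels = c("cvd", "death_other",
                                                  "dropout", "admin_censor")))
  assign <- data.frame(id = 1:5, included = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                       index_time = c(12, 24, 10, 12, 12),
                       A = c(1L, 0L, 1L, 0L, 1L))
  pm <- expand_person_months(bl, assign, horizon_months = 60)
  # person 1: event 2.5 months after index -> 3 rows, D = 1 in the last
  p1 <- pm[pm$id == 1, ]
  expect_identical(nrow(p1), 3L)
  expect_identical(p1$k, 0:2)
  expect_identical(p1$D, c(0L, 0L, 1L))
  expect_identical(sum(p1$C), 0L)
  # person 2: competing death 6 months after index -> C = 1 in month 6
  p2 <- pm[pm$id == 2, ]
  expect_identical(nrow(p2), 6L)
  expect_identical(p2$C, c(0L, 0L, 0L, 0L, 0L, 1L))
  expect_identical(sum(p2$D), 0L)
  # person 3: event beyond the horizon -> 60 clean rows
  p3 <- pm[pm$id == 3, ]
  expect_identical(nrow(p3), 60L)
  expect_identical(sum(p3$D) + sum(p3$C), 0L)
  # person 4: event before the index visit -> contributes nothing
  expect_identical(nrow(pm[pm$id == 4, ]), 0L)
  # person 5: event at exactly the horizon boundary counts inside it
  p5 <- pm[pm$id == 5, ]
  expect_identical(nrow(p5), 60L)
  expect_identical(p5$C[60], 1L)
})

# ---- censoring weights ----------------------------------------------------

test_that("with no censoring every censoring weight is exactly 1", {
  bl <- data.frame(id = 1:3, event_time = c(100, 90, 80),
                   event_type = factor(rep("admin_censor", 3),
                                       levels = c("cvd", "death_other",
                                                  "dropout", "admin_censor")),
                   z = c(0.1, -0.2, 0.5))
  assign <- data.frame(id = 1:3, included = TRUE, index_time = c(1, 2, 3),
                       A = c(1L, 0L, 1L))
  pm <- expand_person_months(bl, assign)
  cw <- fit_censoring_weights(pm, bl, confounders = "z", x0 = character(0))
  expect_identical(cw$model$n_censored, 0L)
  expect_identical(cw$sw_censor, rep(1, nrow(pm)))
})

test_that("censoring weights equal the cumulative product of their models", {
  # dropout makes censoring within the horizon non-trivial
  coh <- generate_cohort(enriched_config(n = 8000, seed = 14, dropout_5y = 0.15,
                                         dropout_confounding = 0.4))
  sp <- scenario("I")
  el <- coh$baseline[eligible(coh$baseline, sp), , drop = FALSE]
  assign <- derive_treatment(el, coh$followup, sp)
  pm <- expand_person_months(el, assign)
  expect_gt(sum(pm$C), 0)
  inc <- el[match(unique(pm$id), el$id), , drop = FALSE]
  cw <- fit_censoring_weights(pm, inc, confounders = default_confounders(sp),
                              x0 = default_x0(sp))
  # recompute the stabilized weight for one multi-month person from the
  # reported model coefficients
  ids <- unique(pm$id)
  pick <- ids[which(tabulate(match(pm$id, ids)) >= 12)][1]
  rows <- which(pm$id == pick)
  covs <- unique(c(default_confounders(sp), default_x0(sp)))
  X <- cbind(riskintervene:::build_design(inc, covs)[
    match(pick, inc$id), , drop = FALSE][rep(1, length(rows)), , drop = FALSE],
    A = pm$A[rows], k = pm$k[rows])
  p_den <- plogis(drop(X[, names(cw$model$denominator), drop = FALSE] %*%
                         cw$model$denominator))
  Xn <- cbind(1, pm$A[rows], pm$k[rows])
  p_num <- plogis(drop(Xn %*% cw$model$numerator))
  expect_equal(cw$sw_censor[rows], cumprod(p_num / p_den), tolerance = 1e-8)
})

# ---- marginal structural model --------------------------------------------

test_that("the MSM recovers a constant hazard with no treatment effect", {
  set.seed(10)
  n <- 4000
  h <- 0.02
  A <- rep(c(0L, 1L), each = n / 2)
  t_ev <- rgeom(n, h) + 1L       # event in month t
  bl <- data.frame(id = seq_len(n),
                   event_time = ifelse(t_ev <= 60, t_ev - 0.5, 70),
                   event_type = factor(ifelse(t_ev <= 60, "cvd",
                                              "admin_censor"),
                                       levels = c("cvd", "death_other",
                                                  "dropout", "admin_censor")))
  assign <- data.frame(id = bl$id, included = TRUE, index_time = 0, A = A)
  pm <- expand_person_months(bl, assign)
  fit <- fit_msm(pm)
  b <- fit$coefficients
  expect_lt(abs(plogis(b[["beta0"]]) - h), 0.005)
  expect_lt(abs(b[["beta2"]]), 3 * fit$se[["beta2"]] + 1e-9)
  rr <- rr_at_horizon(fit)
  expect_lt(abs(rr$rr - 1), 0.15)
})

test_that("rescaling all weights leaves the MSM fit unchanged", {
  coh <- enriched_cohort()
  sp <- scenario("I")
  el <- coh$baseline[eligible(coh$baseline, sp), , drop = FALSE]
  assign <- derive_treatment(el, coh$followup, sp)
  pm <- expand_person_months(el, assign)
  set.seed(2)
  w <- runif(nrow(pm), 0.5, 2)
  f1 <- fit_msm(pm, w)
  f2 <- fit_msm(pm, 7 * w)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_error(fit_msm(pm, -w), "non-negative")
})

test_that("marginal survival matches its closed form and is monotone", {
  h0 <- 0.01; h1 <- 0.004
  fit <- structure(list(coefficients = c(beta0 = qlogis(h0), beta1 = 0,
                                         beta2 = qlogis(h1) - qlogis(h0),
                                         beta3 = 0)),
                   class = "msm_fit")
  s0 <- marginal_survival(fit, 0)
  s1 <- marginal_survival(fit, 1)
  expect_equal(s0$s, (1 - h0)^(0:60), tolerance = 1e-12)
  expect_equal(s1$s, (1 - h1)^(0:60), tolerance = 1e-12)
  expect_identical(s0$s[1], 1)
  expect_true(all(diff(s0$s) < 0))
  expect_true(all(s0$s > 0 & s0$s <= 1))
  rr <- rr_at_horizon(fit)
  expect_equal(rr$rr, (1 - (1 - h1)^60) / (1 - (1 - h0)^60),
               tolerance = 1e-12)
  # no treatment terms -> relative risk exactly 1
  null_fit <- structure(list(coefficients = c(beta0 = qlogis(h0), beta1 = 0,
                                              beta2 = 0, beta3 = 0)),
                        class = "msm_fit")
  expect_identical(rr_at_horizon(null_fit)$rr, 1)
})

# ---- full pipeline --------------------------------------------------------

test_that("the pipeline equals the same estimate composed from its parts", {
  coh <- enriched_cohort(n = 10000, seed = 4)
  sp <- scenario("I")
  est <- estimate_ipw_rr(coh, sp, bootstrap = 0)

  el <- coh$baseline[eligible(coh$baseline, sp), , drop = FALSE]
  assign <- derive_treatment(el, coh$followup, sp)
  pm <- expand_person_months(el, assign)
  inc_ids <- unique(pm$id)
  inc <- el[match(inc_ids, el$id), , drop = FALSE]
  A <- assign$A[match(inc_ids, assign$id)]
  sel <- fit_selection_weights(el, assign)
  tw <- fit_treatment_weights(inc, A, default_confounders(sp))
  cw <- fit_censoring_weights(pm, inc, default_confounders(sp),
                              default_x0(sp))
  per <- sel$weights$selection_weight[match(inc_ids, sel$weights$id)] *
    tw$weights$sw_treatment
  w_row <- per[match(pm$id, inc_ids)] * cw$sw_censor
  msm <- fit_msm(pm, w_row)
  rr <- rr_at_horizon(msm)$rr
  expect_equal(est$rr, rr, tolerance = 1e-5)
  expect_identical(est$diagnostics$treatment_spec, tw$model$chosen)
  cmp <- attr(est, "components")
  expect_equal(cmp$treatment$weights$sw_treatment, tw$weights$sw_treatment,
               tolerance = 1e-6)
  expect_equal(cmp$msm$coefficients, msm$coefficients, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("the pipeline bootstrap returns a covering percentile interval", {
  coh <- enriched_cohort(n = 10000, seed = 4)
  est <- estimate_ipw_rr(coh, scenario("I"), bootstrap = 25, seed = 99)
  expect_true(is.finite(est$ci_low) && is.finite(est$ci_high))
  expect_lte(est$ci_low, est$rr)
  expect_gte(est$ci_high, est$rr)
  expect_identical(est$diagnostics$bootstrap, 25)
  # resampling is seed-deterministic
  est2 <- estimate_ipw_rr(coh, scenario("I"), bootstrap = 25, seed = 99)
  expect_identical(est$ci_low, est2$ci_low)
})

test_that("the pipeline rejects degenerate treatment splits", {
  coh <- enriched_cohort(n = 10000, seed = 4)
  bl <- coh$baseline
  # nobody quits: every eligible visit shows a current smoker
  fu <- coh$followup
  fu$smoking[] <- "current"
  expect_error(estimate_ipw_rr(list(baseline = bl, followup = fu),
                               scenario("I"), bootstrap = 0),
               "both treated and untreated")
})
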