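#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()].  The generator
#' emulates the statistical structure of a primary-care CVD risk-assessment
#' cohort (the PREDICT study design): baseline risk-factor profiles matching
#' published marginal distributions, a covariate-dependent return-to-follow-up
#' process, confounded uptake of one intervention, and proportional-hazards
#' time-to-CVD outcomes in which the true 5-year relative risk of the
#' intervention is known by construction.
#'
#' @param n_participants Number of participants (positive integer).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param scenario Active intervention scenario, one of `"I"` (smoking
#'   cessation), `"IIa"` (lowering SBP), `"IIb"` (BP-lowering medication),
#'   `"IIIa"` (lowering TC/HDL-C), `"IIIb"` (lipid-lowering medication).
#'   Treatment uptake and the embedded causal effect refer to this scenario.
#' @param true_rr True 5-year relative risk of the active intervention
#'   (treated vs untreated cumulative CVD risk at 60 months after the index
#'   visit, averaged over the eligible population).  Either a single positive
#'   number or a named vector with an entry for `scenario`.
#' @param confounding_strength Multiplier on the log-odds coefficients linking
#'   measured confounders (diabetes, age, SBP, TC/HDL-C, BP medication) to
#'   treatment uptake.  `0` gives unconfounded uptake.
#' @param status_confounding Loading of the latent health-burden factor on
#'   *baseline* treated-like status (e.g. being an ex-smoker at baseline).
#'   This is what biases the non-causal covariate-conditioning approach; it
#'   does not affect the validity of IPW, whose confounders are measured.
#' @param latent_hazard Log-hazard coefficient of the latent health-burden
#'   factor (an unmeasured frailty shared with several covariates).
#' @param followup_prob_base Marginal probability of returning for at least
#'   one follow-up visit within the 2-year window.
#' @param uptake_prob Marginal uptake probability of the active intervention
#'   among eligible returners.  Default: scenario-specific values
#'   (0.11 for smoking cessation, matching the published quit fraction).
#' @param covariate_params List of per-field distribution parameters (means,
#'   SDs, truncation bounds, category proportions and latent loadings); see
#'   [default_covariate_params()].
#' @param selection_coefs Named log-odds coefficients of the return-visit
#'   model (the intercept is calibrated internally to `followup_prob_base`).
#' @param hazard_coefs Named log-hazard coefficients of the outcome model.
#' @param cvd_risk_5y Target marginal 5-year CVD risk (default 3%, the
#'   published cohort incidence).
#' @param sex_risk_ratio Male:female ratio of mean 5-year risk (default
#'   4.28/3.01, the published refit means).
#' @param death_5y Five-year probability of death from other causes
#'   (competing event, treated as censoring in the analyses).
#' @param dropout_5y Five-year probability of loss to follow-up; 0 disables
#'   dropout.
#' @param dropout_confounding Log-hazard coefficient linking the measured
#'   confounder score to dropout (informative censoring when nonzero).
#' @param horizon_months Risk horizon (60 = 5 years).
#' @param admin_censor_months Administrative censoring time from baseline;
#'   defaults to 84 so a full 60 months of post-index follow-up is observable
#'   for any index visit within the 2-year window.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 10000L,
                             seed = 1L,
                             scenario = "I",
                             true_rr = 0.8,
                             confounding_strength = 0.6,
                             status_confounding = 0.6,
                             latent_hazard = 0.35,
                             followup_prob_base = 0.243,
                             uptake_prob = NULL,
                             covariate_params = default_covariate_params(),
                             selection_coefs = default_selection_coefs(),
                             hazard_coefs = default_hazard_coefs(),
                             cvd_risk_5y = 0.03,
                             sex_risk_ratio = 4.28 / 3.01,
                             death_5y = 0.015,
                             dropout_5y = 0,
                             dropout_confounding = 0,
                             horizon_months = 60L,
                             admin_censor_months = 84L) {
  scenario <- match.arg(scenario, scenario_ids())
  if (length(n_participants) != 1L || is.na(n_participants) ||
      n_participants < 1)
    stopf("n_participants must be a positive integer, got %s",
          paste(n_participants, collapse = ","))
  if (!is.null(names(true_rr))) {
    if (!scenario %in% names(true_rr))
      stopf("true_rr has names but no entry for scenario %s", scenario)
    true_rr <- unname(true_rr[[scenario]])
  }
  if (!is.finite(true_rr) || true_rr <= 0)
    stopf("true_rr must be a positive number, got %s", true_rr)
  for (p in c(followup_prob_base = followup_prob_base,
              cvd_risk_5y = cvd_risk_5y, death_5y = death_5y,
              dropout_5y = dropout_5y)) {
    if (!is.finite(p) || p < 0 || p > 1)
      stopf("probabilities must lie in [0,1], got %s", p)
  }
  if (is.null(uptake_prob))
    uptake_prob <- c(I = 0.11, IIa = 0.20, IIb = 0.25,
                     IIIa = 0.15, IIIb = 0.20)[[scenario]]
  if (uptake_prob <= 0 || uptake_prob >= 1)
    stopf("uptake_prob must lie in (0,1), got %s", uptake_prob)
  if (admin_censor_months < horizon_months)
    stopf("admin_censor_months (%d) must be >= horizon_months (%d)",
          admin_censor_months, horizon_months)
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    scenario = scenario, true_rr = true_rr,
    confounding_strength = confounding_strength,
    status_confounding = status_confounding,
    latent_hazard = latent_hazard,
    followup_prob_base = followup_prob_base,
    uptake_prob = uptake_prob,
    covariate_params = covariate_params,
    selection_coefs = selection_coefs,
    hazard_coefs = hazard_coefs,
    cvd_risk_5y = cvd_risk_5y, sex_risk_ratio = sex_risk_ratio,
    death_5y = death_5y, dropout_5y = dropout_5y,
    dropout_confounding = dropout_confounding,
    horizon_months = as.integer(horizon_months),
    admin_censor_months = as.integer(admin_censor_months)
  ), class = "generator_config")
}

#' Default baseline covariate distribution parameters
#'
#' Marginals follow the published cohort description: age 53 (SD 9.8) years in
#' 30--74, 56% male, SBP 130 (15) mmHg, TC/HDL 4.1 (1.2), 54% European, 15%
#' current / 17% ex / 68% never smokers, 10% family history, 11% diabetes, 1%
#' atrial fibrillation, 23%/17%/10% on BP-lowering / lipid-lowering /
#' antithrombotic medication.  `rho` entries are loadings on a shared latent
#' health-burden factor that induces realistic covariate correlations (the
#' published tables give marginals only).
#'
#' @return A named list of per-field parameter lists.
#' @export
default_covariate_params <- function() {
  list(
    age    = list(mean = 53, sd = 9.8, lower = 30, upper = 74),
    p_male = 0.56,
    sbp    = list(mean = 130, sd = 15, lower = 80, upper = 230, rho = 0.3),
    tchdl  = list(mean = 4.1, sd = 1.2, lower = 1.5, upper = 12, rho = 0.3),
    p_european = 0.54,
    smoking = list(never = 0.68, ex = 0.17, current = 0.15),
    family_history = list(p = 0.10, rho = 0.2),
    diabetes = list(p = 0.11, rho = 0.5),
    af = list(p = 0.01, rho = 0.3),
    bplm = list(p = 0.23, rho = 0.4),
    llm = list(p = 0.17, rho = 0.4),
    atm = list(p = 0.10, rho = 0.4),
    nzdep_rho = 0.2
  )
}

#' Default return-visit selection coefficients
#'
#' Log-odds coefficients of the logistic model for having at least one
#' follow-up visit within 2 years.  The large diabetes coefficient reproduces
#' the published contrast (29% diabetes prevalence among returners vs 11%
#' overall); the intercept is calibrated at generation time to the configured
#' marginal return probability.
#'
#' @return Named numeric vector.
#' @export
default_selection_coefs <- function() {
  c(diabetes = 2.0, z_age = 0.30, bplm = 0.60, llm = 0.40, atm = 0.30,
    smoke_current = 0.20, family_history = 0.30, z_tchdl = 0.15)
}

#' Default outcome-model log-hazard coefficients
#'
#' Per-unit log-hazard ratios of the exponential proportional-hazards outcome
#' model (continuous predictors are scaled internally: age per 10 years, SBP
#' per 20 mmHg, TC/HDL per 1.2 units).  The sex-specific baseline hazards are
#' calibrated at generation time to the configured marginal 5-year risk.
#'
#' @return Named numeric vector.
#' @export
default_hazard_coefs <- function() {
  c(age10 = 0.35, sbp20 = 0.25, tchdl_u = 0.20,
    smoke_current = 0.55, smoke_ex = 0.30,
    diabetes = 0.45, af = 0.55, family_history = 0.25,
    nzdep = 0.05, eth_other = 0.15,
    bplm = 0.10, llm = 0.05, atm = 0.15)
}

scenario_ids <- function() c("I", "IIa", "IIb", "IIIa", "IIIb")

# Measured-confounder score driving treatment uptake (and, optionally,
# informative dropout).  Built only from observed baseline fields so that the
# IPW confounder sets can fully adjust for it.
confounder_score <- function(bl) {
  0.8 * bl$diabetes + 0.3 * (bl$age - 53) / 9.8 +
    0.3 * (bl$sbp - 130) / 15 + 0.2 * (bl$tchdl - 4.1) / 1.2 + 0.3 * bl$bplm
}

# Calibrate a logistic intercept so the marginal mean of expit(b0 + offset)
# equals target.
calibrate_intercept <- function(offset, target) {
  uniroot(function(b0) mean(expit(b0 + offset)) - target,
          lower = -20, upper = 20, tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Draws baseline and follow-up tables with the structure the three
#' risk-under-intervention approaches assume: correlated baseline covariates,
#' a selective return-visit process, confounded uptake of the active
#' scenario's intervention at the index visit, and proportional-hazards CVD
#' outcomes in which uptake multiplies the hazard from the index visit onward
#' by a hazard ratio calibrated (by root finding) so the population 5-year
#' risk ratio equals `config$true_rr`.
#'
#' @param config A [generator_config()].
#' @return A list of class `ri_cohort` with elements `baseline` (one row per
#'   participant), `followup` (one row per follow-up visit) and `truth` (the
#'   embedded effect: true RR, calibrated hazard ratio, per-person monthly
#'   hazards, uptake indicator and index times).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    stopf("config must be built with generator_config()")
  set.seed(config$seed)
  n <- config$n_participants
  cp <- config$covariate_params
  sc <- config$scenario

  ## --- baseline covariates ------------------------------------------------
  u <- rnorm(n)  # latent health-burden factor
  age <- rtruncnorm(n, cp$age$mean, cp$age$sd, cp$age$lower, cp$age$upper)
  sex <- factor(ifelse(runif(n) < cp$p_male, "male", "female"),
                levels = c("female", "male"))
  sbp <- pmin(pmax(cp$sbp$mean + cp$sbp$sd *
                     (cp$sbp$rho * u + sqrt(1 - cp$sbp$rho^2) * rnorm(n)),
                   cp$sbp$lower), cp$sbp$upper)
  tchdl <- pmin(pmax(cp$tchdl$mean + cp$tchdl$sd *
                       (cp$tchdl$rho * u + sqrt(1 - cp$tchdl$rho^2) * rnorm(n)),
                     cp$tchdl$lower), cp$tchdl$upper)
  ethnicity <- factor(ifelse(runif(n) < cp$p_european, "European", "Other"),
                      levels = c("European", "Other"))
  # Deprivation quintile: uniform marginal, mildly tilted by the latent factor.
  dep_score <- cp$nzdep_rho * u + sqrt(1 - cp$nzdep_rho^2) * rnorm(n)
  nzdep <- findInterval(pnorm(dep_score), c(0.2, 0.4, 0.6, 0.8)) + 1L

  # Smoking status: ordered thresholds on a score loaded (status_confounding)
  # on the latent factor, so current smokers carry the highest burden and
  # ex-smokers an intermediate one while the marginal category proportions
  # stay exact.  This is the mechanism that confounds the *baseline*
  # ex-vs-current contrast exploited by the non-causal approach.
  s <- config$status_confounding
  smoke_score <- s * u + sqrt(max(1 - s^2, 1e-8)) * rnorm(n)
  p_cur <- cp$smoking[["current"]]; p_ex <- cp$smoking[["ex"]]
  smoking <- factor(
    ifelse(smoke_score > qnorm(1 - p_cur), "current",
           ifelse(smoke_score > qnorm(1 - p_cur - p_ex), "ex", "never")),
    levels = c("never", "ex", "current"))

  family_history <- rbinary_latent(u, cp$family_history$p, cp$family_history$rho)
  diabetes <- rbinary_latent(u, cp$diabetes$p, cp$diabetes$rho)
  af <- rbinary_latent(u, cp$af$p, cp$af$rho)
  bplm <- rbinary_latent(u, cp$bplm$p, cp$bplm$rho)
  llm <- rbinary_latent(u, cp$llm$p, cp$llm$rho)
  atm <- rbinary_latent(u, cp$atm$p, cp$atm$rho)

  bl <- data.frame(
    id = seq_len(n), age = round(age, 2), sex = sex, ethnicity = ethnicity,
    nzdep = nzdep, smoking = smoking, family_history = family_history,
    diabetes = diabetes, af = af, sbp = round(sbp, 2),
    tchdl = round(tchdl, 3), bplm = bplm, llm = llm, atm = atm,
    stringsAsFactors = FALSE)

  ## --- hazard model and effect calibration --------------------------------
  hc <- config$hazard_coefs
  lp_core <- function(ex_coef) {
    hc[["age10"]] * (bl$age - 53) / 10 +
      hc[["sbp20"]] * (bl$sbp - 130) / 20 +
      hc[["tchdl_u"]] * (bl$tchdl - 4.1) / 1.2 +
      hc[["smoke_current"]] * (bl$smoking == "current") +
      ex_coef * (bl$smoking == "ex") +
      hc[["diabetes"]] * bl$diabetes + hc[["af"]] * bl$af +
      hc[["family_history"]] * bl$family_history +
      hc[["nzdep"]] * (bl$nzdep - 3) + hc[["eth_other"]] * (bl$ethnicity == "Other") +
      hc[["bplm"]] * bl$bplm + hc[["llm"]] * bl$llm + hc[["atm"]] * bl$atm +
      config$latent_hazard * u
  }
  H <- config$horizon_months
  risk_f <- config$cvd_risk_5y /
    (1 - cp$p_male + cp$p_male * config$sex_risk_ratio)
  sex_target <- c(female = risk_f, male = risk_f * config$sex_risk_ratio)

  calibrate <- function(ex_coef) {
    lp <- lp_core(ex_coef)
    base <- vapply(c("female", "male"), function(sx) {
      idx <- bl$sex == sx
      uniroot(function(lb) {
        mean(1 - exp(-exp(lb + lp[idx]) * H)) - sex_target[[sx]]
      }, lower = -25, upper = -2, tol = 1e-12)$root
    }, numeric(1))
    lambda <- exp(ifelse(bl$sex == "male", base[["male"]], base[["female"]]) + lp)
    list(base = base, lambda = lambda)
  }

  # True-effect embedding: find the hazard ratio whose implied population
  # 5-year risk ratio over the eligible cohort equals true_rr.  For smoking
  # cessation the baseline ex-smoker coefficient is then tied to
  # current + log(HR), so prevalent ex-smokers and sustained quitters share
  # the same hazard; with status_confounding = 0 this makes the non-causal
  # and causal contrasts agree by construction.
  eligible_idx <- switch(sc,
    I    = bl$smoking == "current",
    IIa  = bl$sbp >= 140,
    IIb  = bl$sbp >= 140 & bl$bplm == 0,
    IIIa = bl$tchdl >= 5,
    IIIb = bl$tchdl >= 5 & bl$llm == 0)
  if (!any(eligible_idx))
    stopf("no participants eligible for scenario %s; enlarge the cohort", sc)

  solve_hr <- function(lambda) {
    le <- lambda[eligible_idx]
    r0 <- mean(1 - exp(-le * H))
    uniroot(function(hr) mean(1 - exp(-le * hr * H)) / r0 - config$true_rr,
            lower = 1e-4, upper = 1e4, tol = 1e-12)$root
  }
  cal <- calibrate(hc[["smoke_ex"]])
  hr <- solve_hr(cal$lambda)
  if (sc == "I") {  # tie ex coefficient to the embedded effect and re-solve
    for (it in 1:2) {
      cal <- calibrate(hc[["smoke_current"]] + log(hr))
      hr <- solve_hr(cal$lambda)
    }
  }
  lambda <- cal$lambda

  ## --- return-visit process ----------------------------------------------
  selc <- config$selection_coefs
  sel_lp <- selc[["diabetes"]] * bl$diabetes +
    selc[["z_age"]] * (bl$age - 53) / 9.8 +
    selc[["bplm"]] * bl$bplm + selc[["llm"]] * bl$llm + selc[["atm"]] * bl$atm +
    selc[["smoke_current"]] * (bl$smoking == "current") +
    selc[["family_history"]] * bl$family_history +
    selc[["z_tchdl"]] * (bl$tchdl - 4.1) / 1.2
  sel_b0 <- calibrate_intercept(sel_lp, config$followup_prob_base)
  returner <- runif(n) < expit(sel_b0 + sel_lp)

  ## --- follow-up visits ---------------------------------------------------
  ret_ids <- bl$id[returner]
  n_ret <- length(ret_ids)
  n_visits <- pmin(1L + rpois(n_ret, 1), 3L)
  fu_id <- rep(ret_ids, n_visits)
  visit_time <- round(runif(length(fu_id), 0.5, 24), 2)
  ord <- order(fu_id, visit_time)
  fu_id <- fu_id[ord]; visit_time <- visit_time[ord]
  fu <- data.frame(
    id = fu_id, visit_time = visit_time,
    smoking = bl$smoking[fu_id],
    sbp = round(pmax(bl$sbp[fu_id] + rnorm(length(fu_id), 0, 3), 80), 2),
    tchdl = round(pmax(bl$tchdl[fu_id] + rnorm(length(fu_id), 0, 0.25), 1.2), 3),
    bplm = bl$bplm[fu_id], llm = bl$llm[fu_id], atm = bl$atm[fu_id],
    stringsAsFactors = FALSE)

  # index visit = latest within the window (all visits are drawn in (0, 24])
  last_of <- tapply(seq_along(fu$id), fu$id, function(i) i[which.max(fu$visit_time[i])])
  index_row <- unlist(last_of, use.names = FALSE)
  index_time <- setNames(rep(NA_real_, n), bl$id)
  index_time[as.character(fu$id[index_row])] <- fu$visit_time[index_row]

  ## --- treatment uptake at the index visit --------------------------------
  can_treat <- returner & eligible_idx
  uptake <- rep(FALSE, n)
  if (any(can_treat)) {
    up_lp <- config$confounding_strength * confounder_score(bl)
    up_b0 <- calibrate_intercept(up_lp[can_treat], config$uptake_prob)
    udraw <- runif(n)
    uptake[can_treat] <- udraw[can_treat] < expit(up_b0 + up_lp[can_treat])
  }

  # Keep the scenario's treatment-defining variable on the untreated side of
  # the rule for eligible non-uptakers (at every visit, so the first-visit
  # sensitivity mode stays meaningful), and set it to a treated value at the
  # index visit for uptakers.
  elig_fu <- eligible_idx[fu$id]
  nonup_fu <- elig_fu & !uptake[fu$id]
  up_index <- index_row[uptake[fu$id[index_row]]]
  if (sc == "IIa" || sc == "IIb") {
    fu$sbp[nonup_fu] <- pmax(fu$sbp[nonup_fu], 131)
  }
  if (sc == "IIIa" || sc == "IIIb") {
    fu$tchdl[nonup_fu] <- pmax(fu$tchdl[nonup_fu], 3.6)
  }
  if (length(up_index)) {
    switch(sc,
      I = { fu$smoking[up_index] <- "ex" },
      IIa = { fu$sbp[up_index] <- round(runif(length(up_index), 112, 130), 2) },
      IIb = {
        fu$bplm[up_index] <- 1L
        fu$sbp[up_index] <- round(pmax(fu$sbp[up_index] -
                                         runif(length(up_index), 5, 15), 90), 2)
      },
      IIIa = { fu$tchdl[up_index] <- round(runif(length(up_index), 2.2, 3.5), 3) },
      IIIb = {
        fu$llm[up_index] <- 1L
        fu$tchdl[up_index] <- round(pmax(fu$tchdl[up_index] -
                                           runif(length(up_index), 0.3, 1.2), 1.5), 3)
      })
  }

  ## --- outcomes -----------------------------------------------------------
  # CVD time: piecewise-exponential with a step change (x hazard ratio) at
  # the index visit for uptakers.
  e_cvd <- rexp(n)
  t0 <- ifelse(uptake, index_time[as.character(bl$id)], Inf)
  t_cvd <- ifelse(e_cvd <= lambda * pmin(t0, Inf) | !uptake,
                  e_cvd / lambda,
                  t0 + (e_cvd - lambda * t0) / (lambda * hr))
  mu_death <- -log(1 - config$death_5y) / H
  t_death <- rexp(n, rate = max(mu_death, 1e-12))
  if (config$death_5y == 0) t_death <- rep(Inf, n)

  # Dropout drawn last so that disabling it leaves everything above
  # byte-identical (simulation oracle for the censoring weights).
  t_drop <- rep(Inf, n)
  if (config$dropout_5y > 0) {
    mu_d <- -log(1 - config$dropout_5y) / H *
      exp(config$dropout_confounding * confounder_score(bl))
    t_drop <- rexp(n, rate = mu_d)
  }

  t_admin <- config$admin_censor_months
  times <- cbind(cvd = t_cvd, death_other = t_death, dropout = t_drop,
                 admin_censor = t_admin)
  which_min <- max.col(-times, ties.method = "first")
  bl$event_time <- round(times[cbind(seq_len(n), which_min)], 4)
  bl$event_type <- factor(colnames(times)[which_min],
                          levels = c("cvd", "death_other", "dropout",
                                     "admin_censor"))

  structure(list(
    baseline = bl, followup = fu,
    truth = list(scenario = sc, true_rr = config$true_rr, hazard_ratio = hr,
                 base_log_hazard = cal$base, lambda = lambda,
                 eligible = eligible_idx, uptake = uptake,
                 index_time = unname(index_time), returner = returner,
                 latent = u),
    config = config
  ), class = "ri_cohort")
}

#' @export
print.ri_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic risk-assessment cohort: %d participants, %d follow-up visits\n",
    nrow(x$baseline), nrow(x$followup)))
  cat(sprintf("  scenario %s, true 5-year RR %.3f (hazard ratio %.3f)\n",
              x$truth$scenario, x$truth$true_rr, x$truth$hazard_ratio))
  cat(sprintf("  returners: %.1f%%; uptake among eligible returners: %.1f%%\n",
              100 * mean(x$truth$returner),
              100 * mean(x$truth$uptake[x$truth$returner & x$truth$eligible])))
  invisible(x)
}

#' True standardized risk ratio of a generated cohort
#'
#' Computes, from the generator's stored per-person hazards, the exact
#' counterfactual 5-year risk ratio (everyone eligible treated at their index
#' date vs nobody treated) that the estimation pipeline targets.  Used as the
#' oracle in parameter-recovery checks.
#'
#' @param cohort An `ri_cohort`.
#' @return The true relative risk (a number; equals `config$true_rr` up to
#'   the calibration tolerance).
#' @export
true_standardized_rr <- function(cohort) {
  tr <- cohort$truth
  H <- cohort$config$horizon_months
  le <- tr$lambda[tr$eligible]
  mean(1 - exp(-le * tr$hazard_ratio * H)) / mean(1 - exp(-le * H))
}
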