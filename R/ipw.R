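#' Default confounder sets per scenario
#'
#' Confounders `L` of the treatment model, chosen as all measured
#' pre-treatment risk factors for the outcome except the scenario's own
#' treatment variable (smoking status is omitted for scenario I, where the
#' target population is homogeneous in it; the medication being initiated is
#' omitted for IIb/IIIb).
#'
#' @param spec A [scenario()].
#' @return Character vector of baseline variable names.
#' @export
default_confounders <- function(spec) {
  base <- c("sex", "age", "ethnicity", "nzdep", "family_history",
            "diabetes", "af", "sbp", "tchdl", "atm")
  switch(spec$id,
    I    = c(base, "llm", "bplm"),
    IIa  = c(base, "smoking", "llm", "bplm"),
    IIb  = c(base, "smoking", "llm"),
    IIIa = c(base, "smoking", "llm", "bplm"),
    IIIb = c(base, "smoking", "bplm"))
}

#' Default additional prognostic factors for the censoring model
#'
#' @param spec A [scenario()].
#' @return Character vector of baseline variable names.
#' @export
default_x0 <- function(spec) {
  switch(spec$id,
    I    = c("diabetes", "af", "sbp", "tchdl", "bplm", "atm", "llm"),
    IIa  = c("diabetes", "af", "atm", "llm"),
    IIb  = c("diabetes", "af", "atm", "llm"),
    IIIa = c("diabetes", "af", "atm", "bplm"),
    IIIb = c("diabetes", "af", "bplm", "atm"))
}

# Build a numeric design matrix (with intercept) from named baseline
# variables; factors are expanded by treatment contrasts and zero-variance
# columns dropped (e.g. smoking among baseline current smokers).
build_design <- function(data, vars, spline = FALSE) {
  if (length(vars) == 0)
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  for (v in vars) {
    x <- data[[v]]
    if (is.null(x)) stopf("variable '%s' not found", v)
    if (is.factor(x) || is.character(x)) {
      x <- as.factor(x)
      for (lv in levels(x)[-1]) cols[[paste0(v, lv)]] <- as.numeric(x == lv)
    } else if (spline && length(unique(x)) >= 8) {
      qs <- quantile(x, c(0.05, 0.35, 0.65, 0.95), names = FALSE)
      basis <- splines::ns(x, knots = qs[2:3], Boundary.knots = qs[c(1, 4)])
      for (j in seq_len(ncol(basis))) cols[[paste0(v, "_ns", j)]] <- basis[, j]
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  m <- do.call(cbind, cols)
  keep <- c(TRUE, apply(m[, -1, drop = FALSE], 2, function(z) {
    length(unique(z)) > 1
  }))
  m[, keep, drop = FALSE]
}

#' Inverse-probability-of-selection weights for the return-visit process
#'
#' Fits a logistic model of inclusion (having at least one follow-up visit
#' within the window) on baseline covariates over the full eligible cohort,
#' and returns `1 / p_hat` for included participants.  These weights restore
#' the full-cohort covariate distribution among the included.
#'
#' @param baseline Eligible baseline records (included and excluded).
#' @param assignments Output of [derive_treatment()] for the same records.
#' @param covariates Baseline variables of the selection model.
#' @param mult Optional person-level frequency weights (bootstrap).
#' @param start Optional warm-start coefficients.
#' @return List with `model` (coefficients, fitted range) and `weights`
#'   (data.frame `id`, `p_included`, `selection_weight`; the weight is `NA`
#'   for excluded participants, who are dropped downstream).
#' @export
fit_selection_weights <- function(baseline, assignments,
                                  covariates = default_predictors(),
                                  mult = NULL, start = NULL) {
  stopifnot(identical(baseline$id, assignments$id))
  X <- build_design(baseline, covariates)
  y <- as.numeric(assignments$included)
  fit <- fit_logit(X, y, weights = mult, start = start)
  p <- fit$fitted
  if (any(p < 1e-8 | p > 1 - 1e-8))
    stopf(paste("selection model is separated (fitted probabilities at 0/1);",
                "reduce the covariate set"))
  w <- ifelse(assignments$included, 1 / p, NA_real_)
  list(model = list(coefficients = fit$coefficients, aic = fit$aic),
       weights = data.frame(id = baseline$id, p_included = p,
                            selection_weight = w))
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Fits the marginal model `logit Pr(A=1) = gamma0` and the conditional
#' model `logit Pr(A=1|L)` with both a linear and a restricted-cubic-spline
#' specification for continuous confounders (4 knots at the 5th/35th/65th/
#' 95th percentiles); the specification with the lower AIC supplies the
#' denominator.  The stabilized weight is `Pr(A=1)/Pr(A=1|L)` for the
#' treated and `(1-Pr(A=1))/(1-Pr(A=1|L))` for the untreated; its sample
#' mean is approximately 1.
#'
#' @param data Included baseline records (one row per included participant).
#' @param A Treatment indicator (0/1), aligned with `data`.
#' @param confounders Confounder variable names (empty set gives weights
#'   exactly 1).
#' @param use_spline Compare the spline specification (default) or fit the
#'   linear one only.
#' @param mult,start_lin,start_spl Bootstrap frequency weights / warm starts.
#' @return List with `model` (class `treatment_model`: coefficients of the
#'   chosen specification, `aic_linear`, `aic_spline`, `chosen`,
#'   `p_marginal`) and `weights` (data.frame `id`, `p_treatment`,
#'   `sw_treatment`).
#' @export
fit_treatment_weights <- function(data, A, confounders,
                                  use_spline = TRUE, mult = NULL,
                                  start_lin = NULL, start_spl = NULL) {
  if (length(unique(A)) < 2)
    stopf("both treatment groups must be non-empty")
  if (is.null(mult)) mult <- rep(1, length(A))
  p_marg <- sum(mult * A) / sum(mult)
  if (length(confounders) == 0) {
    p <- rep(p_marg, length(A))
    aic_lin <- aic_spl <- NA_real_
    chosen <- "marginal"
    coefs <- c(`(Intercept)` = logit(p_marg))
  } else {
    Xl <- build_design(data, confounders, spline = FALSE)
    fl <- fit_logit(Xl, A, weights = mult, start = start_lin)
    aic_lin <- fl$aic
    if (use_spline) {
      Xs <- build_design(data, confounders, spline = TRUE)
      fs <- fit_logit(Xs, A, weights = mult, start = start_spl)
      aic_spl <- fs$aic
    } else {
      fs <- NULL; aic_spl <- NA_real_
    }
    if (use_spline && aic_spl < aic_lin) {
      p <- fs$fitted; chosen <- "spline"; coefs <- fs$coefficients
    } else {
      p <- fl$fitted; chosen <- "linear"; coefs <- fl$coefficients
    }
  }
  n_lo <- sum(p <= 1e-6); n_hi <- sum(p >= 1 - 1e-6)
  if (n_lo + n_hi > 0)
    warnf("possible positivity violation: %d fitted probabilities <= 1e-6, %d >= 1-1e-6",
          n_lo, n_hi)
  sw <- ifelse(A == 1, p_marg / p, (1 - p_marg) / (1 - p))
  list(model = structure(list(coefficients = coefs, p_marginal = p_marg,
                              aic_linear = aic_lin, aic_spline = aic_spl,
                              chosen = chosen),
                         class = "treatment_model"),
       weights = data.frame(id = data$id, p_treatment = p, sw_treatment = sw))
}

#' @export
print.treatment_model <- function(x, ...) {
  cat(sprintf(
    "Treatment model (%s spec chosen; AIC linear %.1f, spline %.1f), Pr(A=1) = %.3f\n",
    x$chosen, x$aic_linear, x$aic_spline, x$p_marginal))
  invisible(x)
}

#' Expand included participants into person-month rows
#'
#' One row per person-month from the index visit (time origin) until the
#' first of the CVD event, censoring (competing death, dropout) or the
#' horizon.  `D = 1` only in the event month; `C = 1` in the month censoring
#' occurs.  Participants whose event or censoring time precedes their index
#' visit contribute no rows.
#'
#' @param baseline Eligible baseline records.
#' @param assignments Output of [derive_treatment()]; only included rows
#'   with non-missing `A` are expanded.
#' @param horizon_months Months of follow-up after the index visit
#'   (default 60).
#' @return A data.frame with columns `id`, `A`, `k` (0-based month), `D`,
#'   `C`.
#' @export
expand_person_months <- function(baseline, assignments, horizon_months = 60) {
  inc <- assignments[assignments$included, , drop = FALSE]
  bl <- baseline[match(inc$id, baseline$id), , drop = FALSE]
  if (any(bl$event_time < 0)) stopf("negative event times")
  t_rel <- bl$event_time - inc$index_time
  keep <- t_rel > 0
  inc <- inc[keep, , drop = FALSE]; bl <- bl[keep, , drop = FALSE]
  t_rel <- t_rel[keep]
  ends_within <- t_rel <= horizon_months
  m <- ifelse(ends_within, ceiling(t_rel), horizon_months)
  is_event <- ends_within & bl$event_type == "cvd"
  is_censor <- ends_within & bl$event_type %in% c("death_other", "dropout",
                                                  "admin_censor")
  id <- rep(inc$id, m)
  A <- rep(inc$A, m)
  k <- sequence(m) - 1L
  last <- cumsum(m)
  D <- integer(length(k)); C <- integer(length(k))
  D[last[is_event]] <- 1L
  C[last[is_censor]] <- 1L
  data.frame(id = id, A = A, k = k, D = D, C = C)
}

#' Stabilized inverse-probability-of-censoring weights
#'
#' Treats censoring (loss to follow-up and competing death) as a
#' time-varying treatment: a pooled logistic model of remaining uncensored
#' on treatment, confounders, prognostic factors and month (denominator) and
#' on treatment and month alone (numerator).  The cumulative product of
#' numerator/denominator probabilities up to month `k` is the stabilized
#' censoring weight for that person-month.  With no censoring events all
#' weights are exactly 1.
#'
#' @param pm Person-month table from [expand_person_months()].
#' @param data Included baseline records (covariate source), matched to `pm`
#'   by `id`.
#' @param confounders,x0 Variable names for the denominator model.
#' @param mult Person-level frequency weights aligned with `data`.
#' @param start_den,start_num Warm starts.
#' @return List with `model` (coefficient sets) and `sw_censor` (one weight
#'   per `pm` row).
#' @export
fit_censoring_weights <- function(pm, data, confounders, x0,
                                  mult = NULL, start_den = NULL,
                                  start_num = NULL) {
  if (sum(pm$C) == 0) {
    return(list(model = list(n_censored = 0L), sw_censor = rep(1, nrow(pm))))
  }
  ridx <- match(pm$id, data$id)
  w <- if (is.null(mult)) NULL else mult[ridx]
  covs <- unique(c(confounders, x0))
  Xden <- cbind(build_design(data, covs)[ridx, , drop = FALSE],
                A = pm$A, k = pm$k)
  Xnum <- cbind(`(Intercept)` = 1, A = pm$A, k = pm$k)
  y <- 1 - pm$C
  fden <- fit_logit(Xden, y, weights = w, start = start_den,
                    family = quasibinomial())
  fnum <- fit_logit(Xnum, y, weights = w, start = start_num,
                    family = quasibinomial())
  lr <- log(fnum$fitted) - log(fden$fitted)
  cs <- cumsum(lr)
  first <- which(!duplicated(pm$id))
  offset <- rep(c(0, cs[first[-1] - 1L]), diff(c(first, nrow(pm) + 1L)))
  sw <- exp(cs - offset)
  list(model = list(denominator = fden$coefficients,
                    numerator = fnum$coefficients,
                    n_censored = sum(pm$C)),
       sw_censor = sw)
}

#' Fit the marginal structural hazard model
#'
#' Weighted pooled logistic regression of the discrete-time hazard:
#' `logit Pr(D_{k+1}=1 | D_k=0) = beta0 + beta1 k + beta2 A + beta3 A k`,
#' fitted on uncensored person-month rows with the supplied weights
#' (typically selection x stabilized treatment x cumulative censoring).
#' Because the four regressors depend only on the cell `(k, A)`, the fit is
#' performed on the weighted cell aggregates, which is exactly equivalent
#' and much faster.
#'
#' @param pm Person-month table (rows with `C = 1` are excluded).
#' @param weights Per-row analysis weights (default 1).
#' @return An object of class `msm_fit` with `coefficients`
#'   (`beta0`,`beta1`,`beta2`,`beta3`), naive `se`, and the weighted cell
#'   table.
#' @export
fit_msm <- function(pm, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(pm))
  if (any(!is.finite(weights)) || any(weights < 0))
    stopf("weights must be non-negative and finite")
  use <- pm$C == 0 & weights > 0
  k <- pm$k[use]; A <- pm$A[use]; D <- pm$D[use]; w <- weights[use]
  cell <- paste(k, A)
  agg <- rowsum(cbind(w = w, wD = w * D), cell)
  ka <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  kc <- as.numeric(ka[, 1]); Ac <- as.numeric(ka[, 2])
  wtot <- agg[, "w"]
  ybar <- agg[, "wD"] / wtot
  X <- cbind(`(Intercept)` = 1, k = kc, A = Ac, `A:k` = kc * Ac)
  fit <- fit_logit(X, ybar, weights = wtot)
  beta <- setNames(fit$coefficients, c("beta0", "beta1", "beta2", "beta3"))
  # naive model-based covariance (valid only for unweighted data; interval
  # estimation uses the person-level bootstrap)
  mu <- fit$fitted
  XtWX <- crossprod(X, X * (wtot * mu * (1 - mu)))
  vc <- tryCatch(solve(XtWX), error = function(e) matrix(NA, 4, 4))
  structure(list(coefficients = beta, se = setNames(sqrt(diag(vc)), names(beta)),
                 n_person_months = sum(w > 0), cells = nrow(agg)),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Pooled-logistic marginal structural hazard model\n")
  print(round(rbind(estimate = x$coefficients, naive_se = x$se), 5))
  invisible(x)
}

#' Marginal counterfactual survival curve
#'
#' `S(K) = prod_{k=0}^{K-1} (1 - expit(beta0 + beta1 k + beta2 a + beta3 a k))`
#' for intervention level `a`.
#'
#' @param fit An `msm_fit`.
#' @param level Intervention level, 0 or 1.
#' @param horizon_months Number of months (default 60).
#' @return A data.frame with columns `k` (0..horizon) and `s` (survival
#'   probability; `s[k=0] = 1`).
#' @export
marginal_survival <- function(fit, level, horizon_months = 60) {
  b <- fit$coefficients
  k <- 0:(horizon_months - 1)
  h <- expit(b[["beta0"]] + b[["beta1"]] * k + b[["beta2"]] * level +
               b[["beta3"]] * level * k)
  data.frame(k = 0:horizon_months, s = c(1, cumprod(1 - h)))
}

#' Relative risk at the horizon from a fitted MSM
#'
#' `RR = (1 - S_1(h)) / (1 - S_0(h))`, the ratio of counterfactual
#' cumulative risks under treatment and no treatment.
#'
#' @param fit An `msm_fit`.
#' @param horizon_months Horizon (default 60).
#' @return An `effect_estimate` with `method = "ipw"` and no interval (the
#'   interval comes from the person-level bootstrap in
#'   [estimate_ipw_rr()]).
#' @export
rr_at_horizon <- function(fit, horizon_months = 60) {
  s1 <- marginal_survival(fit, 1, horizon_months)
  s0 <- marginal_survival(fit, 0, horizon_months)
  r0 <- 1 - s0$s[horizon_months + 1]
  r1 <- 1 - s1$s[horizon_months + 1]
  if (r0 <= 0) stopf("untreated cumulative risk is zero; RR undefined")
  effect_estimate(rr = r1 / r0, method = "ipw")
}
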