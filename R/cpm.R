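#' Default predictor set of the clinical prediction model
#'
#' The risk-assessment variables of the published score: age, ethnicity,
#' deprivation, smoking status, family history, diabetes, atrial
#' fibrillation, SBP, TC/HDL ratio and the three medication indicators.  Sex
#' is not listed because models are fitted separately by sex.
#'
#' @return Character vector of predictor names.
#' @export
default_predictors <- function() {
  c("age", "ethnicity", "nzdep", "smoking", "family_history", "diabetes",
    "af", "sbp", "tchdl", "bplm", "llm", "atm")
}

#' Fit the sex-specific proportional-hazards clinical prediction model
#'
#' Fits one Cox proportional-hazards model per sex stratum (Efron ties) for
#' incident CVD within the horizon, and stores everything needed to
#' reproduce absolute risks: coefficients, a reference covariate profile
#' (means of continuous predictors, modal categories) and the baseline
#' survival at the horizon for that profile (Breslow-type estimate via
#' [survival::survfit()]).
#'
#' @param baseline Baseline table (one row per participant) with `sex`,
#'   `event_time` (months), `event_type` and the predictors.
#' @param predictors Character vector of predictor names; interaction terms
#'   may be given as `"a:b"`.
#' @param horizon_months Risk horizon in months (default 60).
#' @return An object of class `cpm_set`: a list with elements `female` and
#'   `male`, each of class `cpm`.
#' @export
fit_cpm <- function(baseline, predictors = default_predictors(),
                    horizon_months = 60) {
  missing_cols <- setdiff(unique(unlist(strsplit(predictors, ":"))),
                          names(baseline))
  if (length(missing_cols))
    stopf("unknown predictor(s): %s", paste(missing_cols, collapse = ", "))
  models <- lapply(c(female = "female", male = "male"), function(sx) {
    dat <- baseline[baseline$sex == sx, , drop = FALSE]
    fit_cpm_stratum(dat, predictors, horizon_months, sx)
  })
  structure(models, class = "cpm_set")
}

fit_cpm_stratum <- function(dat, predictors, horizon, sex) {
  time <- pmin(dat$event_time, horizon)
  status <- as.integer(dat$event_type == "cvd" & dat$event_time <= horizon)
  if (sum(status) < 2)
    stopf("fewer than 2 CVD events in the %s stratum; cannot fit", sex)
  rhs <- paste(predictors, collapse = " + ")
  fml <- as.formula(paste("survival::Surv(time, status) ~", rhs))
  dat$time <- time; dat$status <- status
  fit <- survival::coxph(fml, data = dat, ties = "efron", model = TRUE)
  beta <- coef(fit)
  if (anyNA(beta))
    stopf("singular design in the %s stratum; collinear predictor(s): %s",
          sex, paste(names(beta)[is.na(beta)], collapse = ", "))

  # Reference profile: continuous at the stratum mean, categories at the mode.
  vars <- unique(unlist(strsplit(predictors, ":")))
  ref <- lapply(vars, function(v) {
    x <- dat[[v]]
    if (is.factor(x)) factor(names(which.max(table(x))), levels = levels(x))
    else mean(x)
  })
  ref <- as.data.frame(setNames(ref, vars))
  sf <- survival::survfit(fit, newdata = ref)
  s0 <- summary(sf, times = horizon, extend = TRUE)$surv[1]

  xlev <- fit$xlevels
  mm_ref <- stats::model.matrix(stats::delete.response(terms(fit)),
                                data = ref, xlev = xlev)
  lp_ref <- drop(mm_ref[, names(beta), drop = FALSE] %*% beta)

  structure(list(
    sex = sex, predictors = predictors, coefficients = beta,
    se = setNames(sqrt(diag(fit$var)), names(beta)),
    terms = stats::delete.response(terms(fit)),
    xlevels = xlev, reference_profile = ref, lp_reference = lp_ref,
    baseline_survival = s0, horizon_months = horizon,
    n = nrow(dat), n_events = sum(status)
  ), class = "cpm")
}

#' @export
print.cpm <- function(x, ...) {
  cat(sprintf("Clinical prediction model (%s), %d-month horizon\n",
              x$sex, x$horizon_months))
  cat(sprintf("  n = %d, events = %d, S0(horizon) at reference = %.5f\n",
              x$n, x$n_events, x$baseline_survival))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
print.cpm_set <- function(x, ...) {
  lapply(x, print)
  invisible(x)
}

#' Predict absolute risk at the model horizon
#'
#' Computes `1 - S0(h)^exp(lp - lp_ref)` for each record, where `S0(h)` is
#' the stored baseline survival at the horizon for the reference profile.
#'
#' @param model A `cpm` (single stratum) or `cpm_set` (records are routed to
#'   the stratum matching their `sex`).
#' @param newdata Data frame of records carrying the model's predictors (and
#'   `sex` when `model` is a `cpm_set`).
#' @param horizon_months Must equal the horizon the model was fitted for.
#' @return A data.frame with columns `id` (if present in `newdata`) and
#'   `risk` in `[0, 1]`.
#' @export
predict_risk <- function(model, newdata, horizon_months = 60) {
  if (inherits(model, "cpm_set")) {
    risk <- numeric(nrow(newdata))
    for (sx in c("female", "male")) {
      idx <- which(newdata$sex == sx)
      if (length(idx))
        risk[idx] <- predict_risk(model[[sx]], newdata[idx, , drop = FALSE],
                                  horizon_months)$risk
    }
  } else {
    if (!inherits(model, "cpm")) stopf("model must be a cpm or cpm_set")
    if (horizon_months != model$horizon_months)
      stopf("model stores the %d-month horizon; got %d",
            model$horizon_months, horizon_months)
    vars <- unique(unlist(strsplit(model$predictors, ":")))
    missing_cols <- setdiff(vars, names(newdata))
    if (length(missing_cols))
      stopf("newdata lacks predictor(s): %s",
            paste(missing_cols, collapse = ", "))
    mm <- stats::model.matrix(model$terms, data = newdata, xlev = model$xlevels)
    lp <- drop(mm[, names(model$coefficients), drop = FALSE] %*%
                 model$coefficients)
    risk <- 1 - model$baseline_survival^exp(lp - model$lp_reference)
  }
  out <- data.frame(risk = pmin(pmax(risk, 0), 1))
  if ("id" %in% names(newdata)) out <- cbind(id = newdata$id, out)
  out
}

#' Serialize a fitted prediction model to JSON
#'
#' Stores stratum, predictor list, coefficients, reference profile and
#' baseline survival with stable key order, so risks are exactly
#' reproducible from the file.
#'
#' @param model A `cpm_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
cpm_to_json <- function(model, path) {
  if (!inherits(model, "cpm_set")) stopf("model must be a cpm_set")
  ser <- lapply(model, function(m) list(
    sex = m$sex, predictors = m$predictors,
    coefficients = as.list(m$coefficients),
    reference_profile = lapply(m$reference_profile, function(v)
      if (is.factor(v)) as.character(v) else unname(v)),
    lp_reference = m$lp_reference,
    baseline_survival = m$baseline_survival,
    horizon_months = m$horizon_months))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
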