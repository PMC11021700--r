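#' Estimate the intervention's 5-year relative risk by IPW
#'
#' Runs the full causal pipeline for one scenario on a cohort: derive
#' treatment status from follow-up visits, fit return-visit selection
#' weights on the eligible cohort, stabilized treatment weights on the
#' included, censoring weights on the person-month expansion, fit the
#' weighted pooled-logistic marginal structural model, and return the
#' relative risk at the horizon with a person-level nonparametric bootstrap
#' percentile interval.  Every weight model and the MSM are refitted in
#' each bootstrap replicate (resampling is implemented as person-level
#' frequency weights on design matrices built once, with warm starts from
#' the point fit; the treatment-model specification chosen by AIC at the
#' point fit is kept fixed across replicates).
#'
#' @param cohort An `ri_cohort`, or a list with `baseline` and `followup`.
#' @param spec A [scenario()].
#' @param confounders,x0 Variable names (scenario defaults from
#'   [default_confounders()] / [default_x0()]).
#' @param selection_covariates Covariates of the return-visit model.
#' @param horizon_months Risk horizon after the index visit (default 60).
#' @param use_spline Compare spline vs linear treatment models by AIC.
#' @param bootstrap Number of bootstrap replicates (0 skips the interval).
#' @param seed Optional seed for the bootstrap resampling.
#' @param truncate Optional two quantiles, e.g. `c(0.01, 0.99)`, at which
#'   stabilized treatment weights are winsorized.  Off by default so
#'   positivity problems surface instead of being silently truncated.
#' @return An `effect_estimate` (`method = "ipw"`) whose `diagnostics` carry
#'   weight summaries, the chosen treatment-model specification and AICs and
#'   group sizes, and whose `components` attribute holds the fitted pieces
#'   (assignments, weights, `msm_fit`, survival curves, bootstrap draws).
#' @export
estimate_ipw_rr <- function(cohort, spec,
                            confounders = default_confounders(spec),
                            x0 = default_x0(spec),
                            selection_covariates = default_predictors(),
                            horizon_months = 60,
                            use_spline = TRUE,
                            bootstrap = 200L,
                            seed = NULL,
                            truncate = NULL) {
  baseline <- cohort$baseline; followup <- cohort$followup
  el <- baseline[eligible(baseline, spec), , drop = FALSE]
  if (!nrow(el)) stopf("no eligible participants for scenario %s", spec$id)
  assign <- derive_treatment(el, followup, spec)
  pm <- expand_person_months(el, assign, horizon_months)

  ## ---- static structures, built once -------------------------------------
  inc_ids <- unique(pm$id)
  inc <- el[match(inc_ids, el$id), , drop = FALSE]
  A_inc <- assign$A[match(inc_ids, assign$id)]
  if (length(unique(A_inc)) < 2)
    stopf("scenario %s: need both treated and untreated included participants",
          spec$id)
  inc_idx_el <- match(inc_ids, el$id)
  pm_person <- match(pm$id, inc_ids)
  n_el <- nrow(el); n_pm <- nrow(pm)

  Xsel <- build_design(el, selection_covariates)
  y_sel <- as.numeric(assign$included)
  Xtr_lin <- build_design(inc, confounders, spline = FALSE)
  Xtr_spl <- if (use_spline) build_design(inc, confounders, spline = TRUE)
             else NULL

  any_censor <- sum(pm$C) > 0
  y_cen <- 1 - pm$C
  if (any_censor) {
    # person-level part of the censoring denominator design; only `k` varies
    # within person, which fit_logit_pm() exploits
    Xcen_per <- cbind(build_design(inc, unique(c(confounders, x0))), A = A_inc)
  }
  # cell structures: code = A * horizon + k (0-based), used for the censoring
  # numerator and the MSM, whose regressors depend on (A, k) only
  cell <- pm$A * horizon_months + pm$k + 1L
  n_cell <- 2L * horizon_months
  cell_k <- rep(0:(horizon_months - 1L), 2L)
  cell_A <- rep(c(0L, 1L), each = horizon_months)
  Xcell_num <- cbind(`(Intercept)` = 1, A = cell_A, k = cell_k)
  Xcell_msm <- cbind(`(Intercept)` = 1, k = cell_k, A = cell_A,
                     `A:k` = cell_A * cell_k)
  first_row <- which(!duplicated(pm$id))
  run_lengths <- diff(c(first_row, n_pm + 1L))
  msm_use <- pm$C == 0
  D_pm <- pm$D

  cell_sums <- function(w, wy) {
    ws <- numeric(n_cell); wys <- numeric(n_cell)
    s <- rowsum(cbind(w, wy), cell)
    idx <- as.integer(rownames(s))
    ws[idx] <- s[, 1]; wys[idx] <- s[, 2]
    cbind(ws, wys)
  }

  fit_cells <- function(X, ws, wys, start = NULL) {
    keep <- ws > 0
    fit_logit(X[keep, , drop = FALSE], wys[keep] / ws[keep],
              weights = ws[keep], start = start)$coefficients
  }

  ## ---- one full pipeline evaluation --------------------------------------
  run <- function(mult_el, warm = NULL, fixed_spec = NULL, tol = 1e-9) {
    w_el <- if (is.null(mult_el)) rep(1, n_el) else mult_el
    sel <- fit_logit(Xsel, y_sel, weights = w_el, start = warm$sel, tol = tol)
    if (any(sel$fitted < 1e-8 | sel$fitted > 1 - 1e-8))
      stopf(paste("selection model is separated (fitted probabilities at",
                  "0/1); reduce the covariate set"))
    m_inc <- w_el[inc_idx_el]
    p_marg <- sum(m_inc * A_inc) / sum(m_inc)

    aic_lin <- aic_spl <- NA_real_
    if (ncol(Xtr_lin) == 1L && is.null(Xtr_spl)) {
      p_trt <- rep(p_marg, length(A_inc)); chosen <- "marginal"
      trt_coef <- c(`(Intercept)` = logit(p_marg))
    } else {
      chosen <- fixed_spec
      if (is.null(chosen) || chosen == "linear") {
        fl <- fit_logit(Xtr_lin, A_inc, weights = m_inc,
                        start = warm$trt_lin, tol = tol)
        aic_lin <- fl$aic
      }
      if (!is.null(Xtr_spl) && (is.null(chosen) || chosen == "spline")) {
        fs <- fit_logit(Xtr_spl, A_inc, weights = m_inc,
                        start = warm$trt_spl, tol = tol)
        aic_spl <- fs$aic
      }
      if (is.null(chosen))
        chosen <- if (!is.na(aic_spl) && aic_spl < aic_lin) "spline" else "linear"
      ft <- if (chosen == "spline") fs else fl
      p_trt <- ft$fitted; trt_coef <- ft$coefficients
    }
    sw_t <- ifelse(A_inc == 1, p_marg / p_trt, (1 - p_marg) / (1 - p_trt))
    if (!is.null(truncate)) {
      bounds <- quantile(sw_t, truncate, names = FALSE)
      sw_t <- pmin(pmax(sw_t, bounds[1]), bounds[2])
    }

    mrow <- m_inc[pm_person]
    if (any_censor) {
      den <- fit_logit_pm(Xcen_per, pm$k, pm_person, y_cen, weights = mrow,
                          start = warm$cen_den, tol = tol)
      cs_num <- cell_sums(mrow, mrow * y_cen)
      num_coef <- fit_cells(Xcell_num, cs_num[, 1], cs_num[, 2],
                            start = warm$cen_num)
      p_num <- expit(drop(Xcell_num %*% num_coef))[cell]
      lr <- log(p_num) - log(den$fitted)
      cs <- cumsum(lr)
      offset <- rep(c(0, cs[first_row[-1] - 1L]), run_lengths)
      sw_c <- exp(cs - offset)
      cen_info <- list(denominator = den$coefficients, numerator = num_coef,
                       n_censored = sum(pm$C))
    } else {
      sw_c <- rep(1, n_pm)
      cen_info <- list(n_censored = 0L)
    }

    selw_inc <- 1 / sel$fitted[inc_idx_el]
    w_row <- (selw_inc * sw_t)[pm_person] * sw_c * mrow
    wm <- ifelse(msm_use, w_row, 0)
    cs_msm <- cell_sums(wm, wm * D_pm)
    beta <- setNames(fit_cells(Xcell_msm, cs_msm[, 1], cs_msm[, 2],
                               start = warm$msm),
                     c("beta0", "beta1", "beta2", "beta3"))
    msm <- structure(list(coefficients = beta, se = rep(NA_real_, 4),
                          n_person_months = sum(wm > 0),
                          cells = sum(cs_msm[, 1] > 0)),
                     class = "msm_fit")
    rr <- rr_at_horizon(msm, horizon_months)$rr
    list(rr = rr, msm = msm, chosen = chosen, trt_coef = trt_coef,
         aic_linear = aic_lin, aic_spline = aic_spl, p_marg = p_marg,
         sel_coef = sel$coefficients, p_sel = sel$fitted,
         sw_t = sw_t, sw_c = sw_c, cen = cen_info,
         w_row = w_row, selw_inc = selw_inc)
  }

  point <- run(NULL)

  ci <- c(NA_real_, NA_real_)
  boot_rr <- numeric(0)
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    warm <- list(sel = point$sel_coef,
                 trt_lin = if (point$chosen == "linear") point$trt_coef,
                 trt_spl = if (point$chosen == "spline") point$trt_coef,
                 cen_den = point$cen$denominator,
                 cen_num = point$cen$numerator,
                 msm = point$msm$coefficients)
    boot_rr <- vapply(seq_len(bootstrap), function(b) {
      mult <- tabulate(sample.int(n_el, n_el, replace = TRUE), n_el)
      tryCatch(run(mult, warm, fixed_spec = point$chosen, tol = 1e-7)$rr,
               error = function(e) NA_real_)
    }, numeric(1))
    ok <- boot_rr[is.finite(boot_rr)]
    if (length(ok) >= 20)
      ci <- quantile(ok, c(0.025, 0.975), names = FALSE)
  }

  est <- effect_estimate(
    rr = point$rr,
    ci_low = if (is.na(ci[1])) NA_real_ else min(ci[1], point$rr),
    ci_high = if (is.na(ci[2])) NA_real_ else max(ci[2], point$rr),
    method = "ipw", n = length(inc_ids),
    diagnostics = list(
      n_eligible = n_el, n_included = length(inc_ids),
      n_treated = sum(A_inc), n_untreated = sum(1 - A_inc),
      mean_sw_treatment = mean(point$sw_t),
      max_sw_treatment = max(point$sw_t),
      mean_combined = mean(point$w_row),
      aic_linear = point$aic_linear, aic_spline = point$aic_spline,
      treatment_spec = point$chosen,
      n_censored = point$cen$n_censored,
      bootstrap = bootstrap,
      bootstrap_failures = sum(!is.finite(boot_rr))))
  if (abs(est$diagnostics$mean_sw_treatment - 1) > 0.05)
    warnf(paste("mean stabilized treatment weight %.3f deviates from 1 by",
                "more than 0.05; check the treatment model"),
          est$diagnostics$mean_sw_treatment)
  attr(est, "components") <- list(
    assignments = assign,
    selection = list(coefficients = point$sel_coef,
                     weights = data.frame(id = el$id, p_included = point$p_sel,
                                          selection_weight = ifelse(
                                            assign$included, 1 / point$p_sel,
                                            NA_real_))),
    treatment = list(coefficients = point$trt_coef, chosen = point$chosen,
                     p_marginal = point$p_marg,
                     weights = data.frame(id = inc_ids,
                                          sw_treatment = point$sw_t)),
    censoring = point$cen, msm = point$msm,
    survival = list(treated = marginal_survival(point$msm, 1, horizon_months),
                    untreated = marginal_survival(point$msm, 0, horizon_months)),
    person_months = pm, row_weights = point$w_row, boot_rr = boot_rr)
  est
}
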