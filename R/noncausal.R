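#' Paired risks under no action and under covariate modification
#'
#' The non-causal approach: for each eligible record, predict absolute risk
#' from the clinical prediction model as-is (`risk_original`) and after
#' applying the scenario's covariate modification (`risk_intervention`),
#' using the same sex-stratum model for both.  The individual relative risk
#' is their ratio and the absolute risk change (ARC) their difference
#' (without minus under, so benefit is positive).
#'
#' This approach is not grounded in causal theory: it treats a model
#' coefficient as if it were a causal effect, which holds only under
#' restrictive assumptions.  It is provided because it is widely used in
#' practice and as the comparator the causal approaches are judged against.
#'
#' @param model A `cpm_set` from [fit_cpm()].
#' @param records Baseline records, all eligible for `spec`.
#' @param spec A [scenario()].
#' @return A data.frame of class `paired_risks`: `id`, `risk_original`,
#'   `risk_intervention`, `individual_rr`, `arc`.
#' @export
risk_pairs <- function(model, records, spec) {
  ok <- eligible(records, spec)
  if (!all(ok))
    stopf("risk_pairs: %d record(s) not eligible for scenario %s",
          sum(!ok), spec$id)
  orig <- predict_risk(model, records)$risk
  modd <- predict_risk(model, modify_records(records, spec))$risk
  out <- data.frame(id = records$id, risk_original = orig,
                    risk_intervention = modd,
                    individual_rr = modd / orig, arc = orig - modd)
  class(out) <- c("paired_risks", "data.frame")
  out
}

#' Average the individual relative risks (non-causal effect estimate)
#'
#' Point estimate is the arithmetic mean of the individual relative risks.
#' The 95% interval is mean +/- 1.96 x SD of the individual relative risks —
#' a descriptive spread of the per-person ratios, not a sampling-based
#' confidence interval (the convention is documented in the vignette).
#'
#' @param pairs A `paired_risks` data frame.
#' @return An `effect_estimate` with `method = "noncausal"`.
#' @export
mean_rr <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0)
    stopf("mean_rr: empty input")
  m <- mean(pairs$individual_rr)
  s <- if (nrow(pairs) > 1) sd(pairs$individual_rr) else 0
  effect_estimate(rr = m, ci_low = m - 1.96 * s, ci_high = m + 1.96 * s,
                  method = "noncausal", n = nrow(pairs))
}

#' Construct an effect estimate
#'
#' @param rr Relative risk (treated vs untreated cumulative risk at the
#'   horizon).
#' @param ci_low,ci_high 95% interval bounds.
#' @param method One of `"noncausal"`, `"ipw"`, `"external"`.
#' @param n Number of participants behind the estimate.
#' @param diagnostics Optional named list (weight summaries, AICs, ...).
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(rr, ci_low = NA_real_, ci_high = NA_real_,
                            method, n = NA_integer_, diagnostics = list()) {
  if (!is.finite(rr) || rr < 0) stopf("rr must be a non-negative number")
  if (is.finite(ci_low) && is.finite(ci_high) &&
      (ci_low > rr + 1e-12 || ci_high < rr - 1e-12))
    stopf("interval [%g, %g] does not contain the point estimate %g",
          ci_low, ci_high, rr)
  structure(list(rr = rr, ci_low = ci_low, ci_high = ci_high,
                 method = method, n = n, diagnostics = diagnostics),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("RR %.3f (95%% interval %.3f-%.3f), method: %s, n = %s\n",
              x$rr, x$ci_low, x$ci_high, x$method, format(x$n)))
  invisible(x)
}

#' Write an effect estimate to JSON
#'
#' @param x An `effect_estimate`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
effect_to_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
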