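#' Built-in registry of externally reported intervention effects
#'
#' Relative risks (with 95% CIs) for the five scenarios, taken from the
#' published overview-of-systematic-reviews evidence used by the Million
#' Hearts longitudinal ASCVD risk tool: smoking cessation 0.73 (0.62–0.85);
#' SBP lowering through lifestyle 0.65 (0.57–0.75) per 10 mmHg; BP-lowering
#' medication 0.73 (0.67–0.81); lipid lowering through lifestyle 0.75
#' (0.70–0.80) per 1 mmol/L LDL; lipid-lowering medication (statins) 0.75
#' (0.70–0.81).  The per-dose effects are mapped onto the categorical
#' scenarios without dose adjustment, mirroring how they are used in the
#' two-stage comparison.
#'
#' @return A data.frame with columns `scenario_id`, `rr`, `ci_low`,
#'   `ci_high`, `source`.
#' @export
builtin_effects <- function() {
  data.frame(
    scenario_id = scenario_ids(),
    rr      = c(0.73, 0.65, 0.73, 0.75, 0.75),
    ci_low  = c(0.62, 0.57, 0.67, 0.70, 0.70),
    ci_high = c(0.85, 0.75, 0.81, 0.80, 0.81),
    source = c(
      "overview of systematic reviews: smoking cessation",
      "overview of systematic reviews: per 10 mmHg SBP reduction",
      "overview of systematic reviews: BP-lowering therapy",
      "overview of systematic reviews: per 1 mmol/L LDL reduction",
      "overview of systematic reviews: statin therapy"),
    stringsAsFactors = FALSE)
}

#' Look up an external effect by scenario
#'
#' @param scenario_id One of the five scenario ids.
#' @param effects Effects table (defaults to [builtin_effects()]).
#' @return One-row data.frame.
#' @export
external_effect <- function(scenario_id, effects = builtin_effects()) {
  row <- effects[effects$scenario_id == scenario_id, , drop = FALSE]
  if (nrow(row) != 1)
    stopf("no external effect registered for scenario '%s'", scenario_id)
  row
}

#' Load an external-effects table from YAML
#'
#' Entries are keyed by scenario id with fields `rr`, `ci_low`, `ci_high`
#' and optional `source`.
#'
#' @param path YAML file path.
#' @return A data.frame shaped like [builtin_effects()].
#' @export
effects_from_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  rows <- lapply(names(spec), function(id) {
    e <- spec[[id]]
    if (is.null(e$rr) || e$rr <= 0)
      stopf("effect for scenario '%s' must have rr > 0", id)
    data.frame(scenario_id = id, rr = e$rr,
               ci_low = e$ci_low %||% NA_real_,
               ci_high = e$ci_high %||% NA_real_,
               source = e$source %||% "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Combine predicted risks with an external relative risk
#'
#' The two-stage identity: `risk_intervention = risk_original x RR`, capped
#' at 1 (with a warning when the cap binds).  The relative effect is applied
#' uniformly — treatment effects are assumed constant on the relative scale,
#' so every person's individual RR equals the external RR.
#'
#' @param risks A data.frame with columns `id` and `risk` (from
#'   [predict_risk()]), or a bare numeric vector of risks.
#' @param effect A one-row effects table (see [external_effect()]) or a
#'   single positive number.
#' @return A `paired_risks` data frame.
#' @export
combine_risk <- function(risks, effect) {
  if (is.numeric(effect)) effect <- data.frame(rr = effect)
  if (!is.finite(effect$rr) || effect$rr <= 0)
    stopf("external relative risk must be > 0, got %s", effect$rr)
  if (is.numeric(risks)) risks <- data.frame(id = seq_along(risks), risk = risks)
  if (any(risks$risk < 0 | risks$risk > 1))
    stopf("risks must lie in [0, 1]")
  scaled <- risks$risk * effect$rr
  if (any(scaled > 1))
    warnf("%d combined risk(s) exceeded 1 and were capped", sum(scaled > 1))
  out <- data.frame(id = risks$id, risk_original = risks$risk,
                    risk_intervention = pmin(scaled, 1),
                    individual_rr = effect$rr,
                    arc = risks$risk - pmin(scaled, 1))
  class(out) <- c("paired_risks", "data.frame")
  out
}
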