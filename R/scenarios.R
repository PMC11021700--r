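#' Define an intervention scenario
#'
#' Builds the specification of one of the five interventions: eligibility at
#' baseline, the covariate modification applied by the non-causal approach,
#' and the treatment definition used by the IPW approach.
#'
#' * `I` — smoking cessation: current smokers; smoking set to ex; treated if
#'   ex-smoker at the index visit.
#' * `IIa` — lowering SBP (lifestyle): SBP >= 140; SBP set to 130; treated if
#'   SBP <= 130 at the index visit.
#' * `IIb` — BP-lowering medication: SBP >= 140 and BPLM = 0; BPLM set to 1
#'   (and SBP to 130 under the `with_factor_change` variant); treated if
#'   BPLM = 1 at the index visit.
#' * `IIIa` — lowering TC/HDL (lifestyle): TC/HDL >= 5; TC/HDL set to 3.5;
#'   treated if TC/HDL <= 3.5 at the index visit.
#' * `IIIb` — lipid-lowering medication: TC/HDL >= 5 and LLM = 0; LLM set to
#'   1 (and TC/HDL to 3.5 under `with_factor_change`); treated if LLM = 1 at
#'   the index visit.
#'
#' Thresholds are inclusive: SBP exactly 140 is eligible, TC/HDL exactly 3.5
#' at follow-up counts as treated.
#'
#' @param id Scenario id, one of `"I"`, `"IIa"`, `"IIb"`, `"IIIa"`, `"IIIb"`.
#' @param window_months Length of the follow-up window in which treatment
#'   status is ascertained (default 24).
#' @param variant For the medication scenarios (IIb/IIIb): whether the
#'   non-causal modification also sets the risk factor to its target value
#'   (`"with_factor_change"`, the default) or changes only the medication
#'   indicator (`"medication_only"`).
#' @param index_visit Which follow-up visit within the window defines
#'   treatment status: `"latest"` (default) or `"first"` (sensitivity mode).
#' @return An object of class `scenario`.
#' @export
scenario <- function(id, window_months = 24,
                     variant = c("with_factor_change", "medication_only"),
                     index_visit = c("latest", "first")) {
  id <- match.arg(id, scenario_ids())
  variant <- match.arg(variant)
  index_visit <- match.arg(index_visit)
  if (window_months <= 0) stopf("window_months must be positive")
  structure(list(id = id, window_months = window_months, variant = variant,
                 index_visit = index_visit),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  lab <- c(I = "smoking cessation", IIa = "lowering SBP (lifestyle)",
           IIb = "BP-lowering medication", IIIa = "lowering TC/HDL (lifestyle)",
           IIIb = "lipid-lowering medication")[[x$id]]
  cat(sprintf("Scenario %s: %s (window %g months, %s, index = %s visit)\n",
              x$id, lab, x$window_months, x$variant, x$index_visit))
  invisible(x)
}

#' The built-in registry of the five scenarios
#'
#' @param ... Passed to [scenario()] (e.g. `index_visit = "first"`).
#' @return Named list of `scenario` objects.
#' @export
scenarios <- function(...) {
  setNames(lapply(scenario_ids(), scenario, ...), scenario_ids())
}

#' Load scenario overrides from a YAML file
#'
#' Each top-level entry is a scenario id mapping to optional fields
#' `window_months`, `variant` and `index_visit`.
#'
#' @param path YAML file path.
#' @return Named list of `scenario` objects (unlisted scenarios keep their
#'   defaults).
#' @export
scenarios_from_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  out <- scenarios()
  for (id in names(spec)) {
    s <- spec[[id]]
    out[[id]] <- scenario(id,
      window_months = s$window_months %||% 24,
      variant = s$variant %||% "with_factor_change",
      index_visit = s$index_visit %||% "latest")
  }
  out
}

#' Baseline eligibility for a scenario
#'
#' @param records Baseline data frame.
#' @param spec A [scenario()].
#' @return Logical vector, one entry per record.
#' @export
eligible <- function(records, spec) {
  switch(spec$id,
    I    = records$smoking == "current",
    IIa  = records$sbp >= 140,
    IIb  = records$sbp >= 140 & records$bplm == 0,
    IIIa = records$tchdl >= 5,
    IIIb = records$tchdl >= 5 & records$llm == 0)
}

#' Apply a scenario's covariate modification (non-causal approach)
#'
#' Returns the records with the scenario's predictors set to their
#' post-intervention values and every other field untouched.  Every record
#' must either be eligible or already be in the post-intervention state
#' (so the modification is idempotent).
#'
#' @param records Baseline data frame (all rows eligible for `spec`).
#' @param spec A [scenario()].
#' @return Modified copy of `records`.
#' @export
modify_records <- function(records, spec) {
  already <- switch(spec$id,
    I    = records$smoking == "ex",
    IIa  = records$sbp == 130,
    IIb  = records$bplm == 1,
    IIIa = records$tchdl == 3.5,
    IIIb = records$llm == 1)
  ok <- eligible(records, spec) | already
  if (!all(ok))
    stopf("modify_records: %d record(s) not eligible for scenario %s (first: row %d)",
          sum(!ok), spec$id, which(!ok)[1])
  out <- records
  factor_change <- spec$variant == "with_factor_change"
  switch(spec$id,
    I    = { out$smoking[] <- "ex" },
    IIa  = { out$sbp <- rep(130, nrow(out)) },
    IIb  = { out$bplm <- rep(1L, nrow(out))
             if (factor_change) out$sbp <- rep(130, nrow(out)) },
    IIIa = { out$tchdl <- rep(3.5, nrow(out)) },
    IIIb = { out$llm <- rep(1L, nrow(out))
             if (factor_change) out$tchdl <- rep(3.5, nrow(out)) })
  out
}

#' Derive treatment status from follow-up visits
#'
#' Implements the index-visit rule: a participant is included if they have at
#' least one follow-up visit within the window; the index visit is the one
#' closest to the window's end (`"latest"`, default) or the first visit in
#' sensitivity mode; the treatment indicator `A` is read off the index
#' visit's measurements according to the scenario.  Exclusion is a state,
#' not an error: excluded participants get `included = FALSE` and `A = NA`.
#'
#' @param baseline Baseline data frame (only eligible rows are assessed;
#'   ineligible rows are dropped from the output).
#' @param followup Follow-up visit data frame.
#' @param spec A [scenario()].
#' @return A data.frame with columns `id`, `included`, `index_time`, `A`.
#' @export
derive_treatment <- function(baseline, followup, spec) {
  el <- baseline[eligible(baseline, spec), , drop = FALSE]
  fu <- followup[followup$id %in% el$id &
                   followup$visit_time > 0 &
                   followup$visit_time <= spec$window_months, , drop = FALSE]
  pick <- if (spec$index_visit == "latest") which.max else which.min
  idx_rows <- vapply(split(seq_len(nrow(fu)), factor(fu$id, levels = el$id)),
                     function(i) if (length(i)) i[pick(fu$visit_time[i])] else NA_integer_,
                     integer(1))
  included <- !is.na(idx_rows)
  index_time <- ifelse(included, fu$visit_time[idx_rows], NA_real_)
  A <- rep(NA_integer_, nrow(el))
  if (any(included)) {
    ir <- idx_rows[included]
    A[included] <- as.integer(switch(spec$id,
      I    = fu$smoking[ir] == "ex",
      IIa  = fu$sbp[ir] <= 130,
      IIb  = fu$bplm[ir] == 1,
      IIIa = fu$tchdl[ir] <= 3.5,
      IIIb = fu$llm[ir] == 1))
  }
  data.frame(id = el$id, included = included, index_time = index_time, A = A)
}
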