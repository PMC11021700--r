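#' Write a cohort to delimited text files
#'
#' Writes `baseline.csv` and `followup.csv` (comma-separated, with header)
#' under `dir`.  Factors are stored as their labels; the files round-trip
#' through [read_cohort()] field-for-field.
#'
#' @param cohort An `ri_cohort`, or a list with elements `baseline` and
#'   `followup` shaped like the generator's output.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(baseline = file.path(dir, "baseline.csv"),
             followup = file.path(dir, "followup.csv"))
  write.csv(cohort$baseline, paths[["baseline"]], row.names = FALSE)
  write.csv(cohort$followup, paths[["followup"]], row.names = FALSE)
  invisible(paths)
}

baseline_numeric_cols <- c("id", "age", "nzdep", "family_history", "diabetes",
                           "af", "sbp", "tchdl", "bplm", "llm", "atm",
                           "event_time")
followup_numeric_cols <- c("id", "visit_time", "sbp", "tchdl", "bplm", "llm",
                           "atm")

check_numeric <- function(df, cols, file) {
  for (cl in intersect(cols, names(df))) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
    if (length(bad))
      stopf("%s: non-numeric value '%s' in row %d, column '%s'",
            file, raw[bad[1]], bad[1], cl)
    df[[cl]] <- val
  }
  df
}

#' Read a cohort from delimited text files
#'
#' Reads the files produced by [write_cohort()], validating that numeric
#' columns parse (malformed rows are reported with their row number and
#' column name) and restoring the factor levels the analyses expect.
#'
#' @param dir Directory containing `baseline.csv` and `followup.csv`.
#' @return A list with `baseline` and `followup` data frames.
#' @export
read_cohort <- function(dir) {
  bpath <- file.path(dir, "baseline.csv")
  fpath <- file.path(dir, "followup.csv")
  for (p in c(bpath, fpath)) if (!file.exists(p)) stopf("missing file: %s", p)
  bl <- read.csv(bpath, stringsAsFactors = FALSE, colClasses = "character")
  fu <- read.csv(fpath, stringsAsFactors = FALSE, colClasses = "character")
  bl <- check_numeric(bl, baseline_numeric_cols, "baseline.csv")
  fu <- check_numeric(fu, followup_numeric_cols, "followup.csv")
  for (cl in c("id", "nzdep", "family_history", "diabetes", "af", "bplm",
               "llm", "atm"))
    if (cl %in% names(bl)) bl[[cl]] <- as.integer(bl[[cl]])
  for (cl in c("id", "bplm", "llm", "atm"))
    if (cl %in% names(fu)) fu[[cl]] <- as.integer(fu[[cl]])
  bl$sex <- factor(bl$sex, levels = c("female", "male"))
  bl$ethnicity <- factor(bl$ethnicity, levels = c("European", "Other"))
  bl$smoking <- factor(bl$smoking, levels = c("never", "ex", "current"))
  bl$event_type <- factor(bl$event_type,
                          levels = c("cvd", "death_other", "dropout",
                                     "admin_censor"))
  if (nrow(fu)) fu$smoking <- factor(fu$smoking,
                                     levels = c("never", "ex", "current"))
  else fu$smoking <- factor(character(), levels = c("never", "ex", "current"))
  validate_baseline(bl)
  list(baseline = bl, followup = fu)
}

validate_baseline <- function(bl) {
  if (any(bl$age < 30 - 1e-9 | bl$age > 74 + 1e-9))
    stopf("baseline.csv: age outside [30, 74] in row %d",
          which(bl$age < 30 | bl$age > 74)[1])
  if (any(bl$sbp <= 0)) stopf("baseline.csv: non-positive sbp in row %d",
                              which(bl$sbp <= 0)[1])
  if (any(bl$tchdl <= 0)) stopf("baseline.csv: non-positive tchdl in row %d",
                                which(bl$tchdl <= 0)[1])
  if (any(bl$event_time < 0)) stopf("baseline.csv: negative event_time in row %d",
                                    which(bl$event_time < 0)[1])
  invisible(bl)
}
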