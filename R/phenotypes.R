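#' Derive LDL cholesterol by the Friedewald equation
#'
#' LDL-c = TC - HDL-c - TG/5, all in mg/dl. The equation assumes a fixed
#' TG:VLDL ratio of 5:1 and is not applicable at TG >= 400 mg/dl; such
#' values return `NA` (with a warning) unless `tg_limit = Inf`.
#'
#' @param tc total cholesterol, mg/dl (> 0).
#' @param hdl HDL cholesterol, mg/dl (> 0).
#' @param tg triglycerides, mg/dl (> 0).
#' @param tg_limit applicability bound on TG, mg/dl; values at or above it
#'   are flagged invalid. Default 400; set `Inf` to disable.
#' @return numeric vector of LDL-c (mg/dl) with `NA` where TG exceeds the
#'   bound. Carries attribute `"invalid"`, a logical vector marking the
#'   flagged entries.
#' @export
#' @examples
#' friedewald_ldl(216, 55.3, 104)  # 139.9
friedewald_ldl <- function(tc, hdl, tg, tg_limit = 400) {
  n <- max(length(tc), length(hdl), length(tg))
  tc <- rep_len(as.numeric(tc), n)
  hdl <- rep_len(as.numeric(hdl), n)
  tg <- rep_len(as.numeric(tg), n)
  bad <- !is.na(tc) & !is.na(hdl) & !is.na(tg) &
    (tc <= 0 | hdl <= 0 | tg <= 0)
  if (any(bad)) .fail("tc, hdl and tg must all be positive (mg/dl)")
  ldl <- tc - hdl - tg / 5
  invalid <- !is.na(tg) & tg >= tg_limit
  if (any(invalid)) {
    warning(sprintf(
      "%d subject(s) with TG >= %g mg/dl: Friedewald LDL-c set to NA",
      sum(invalid), tg_limit
    ), call. = FALSE)
    ldl[invalid] <- NA_real_
  }
  attr(ldl, "invalid") <- invalid
  ldl
}

#' Classify dyslipidemia phenotypes
#'
#' Applies the diagnostic cutoffs used for the Spanish adult population:
#' hypercholesterolemia TC >= 200 mg/dl, high LDL-c >= 130 mg/dl,
#' hypoalphalipoproteinemia HDL-c < 40 mg/dl in men and < 50 mg/dl in
#' women, hypertriglyceridemia TG >= 150 mg/dl.
#'
#' @param tc,ldl,hdl,tg lipid concentrations in mg/dl.
#' @param sex character or factor, `"F"`/`"M"`. If missing for a subject,
#'   the sex-specific HDL flag is `NA`; the other flags are still computed.
#' @return data.frame with logical columns `hypercholesterolemia`,
#'   `high_ldl`, `low_hdl`, `hypertriglyceridemia`.
#' @export
classify_dyslipidemia <- function(tc, ldl, hdl, tg, sex) {
  n <- max(length(tc), length(ldl), length(hdl), length(tg), length(sex))
  tc <- rep_len(as.numeric(tc), n)
  ldl <- rep_len(as.numeric(ldl), n)
  hdl <- rep_len(as.numeric(hdl), n)
  tg <- rep_len(as.numeric(tg), n)
  sex <- rep_len(as.character(sex), n)
  if (!all(sex %in% c("F", "M", NA_character_)))
    .fail("sex must be 'F' or 'M' (or NA)")
  hdl_cut <- ifelse(sex == "M", 40, 50)  # NA sex -> NA cutoff -> NA flag
  data.frame(
    hypercholesterolemia = tc >= 200,
    high_ldl = ldl >= 130,
    low_hdl = hdl < hdl_cut,
    hypertriglyceridemia = tg >= 150
  )
}

#' Prevalence report for dyslipidemia flags
#'
#' Counts and percentages per condition over a cohort. Percentages are
#' rounded half away from zero to the nearest integer; the unrounded value
#' is kept alongside.
#'
#' @param flags data.frame of logical columns as returned by
#'   [classify_dyslipidemia()] (any set of logical columns works).
#' @return data.frame with one row per condition: `condition`, `count`,
#'   `n` (non-missing), `pct` (integer), `pct_raw`.
#' @export
prevalence_report <- function(flags) {
  if (!is.data.frame(flags) || nrow(flags) == 0L)
    .fail("'flags' must be a data.frame with at least one subject")
  out <- lapply(names(flags), function(cn) {
    x <- flags[[cn]]
    n <- sum(!is.na(x))
    k <- sum(x, na.rm = TRUE)
    raw <- if (n > 0) 100 * k / n else NA_real_
    data.frame(
      condition = cn, count = k, n = n,
      pct = round_half_up(raw), pct_raw = raw
    )
  })
  do.call(rbind, out)
}

#' Table-style cohort summary
#'
#' Mean +/- SD for continuous variables and count (percent) for binary
#' ones, in the layout of a clinical characteristics table.
#'
#' @param cohort a cohort data.frame (see [simulate_cohort()]).
#' @return data.frame with columns `variable`, `summary`, `mean`, `sd`,
#'   `count`, `pct`.
#' @export
cohort_summary <- function(cohort) {
  cont <- c(
    age = "Age (years)", weight = "Weight (kg)", bmi = "BMI (kg/m2)",
    tfat = "TFAT (kg)", vfat = "VFAT (kg)", glucose = "Glucose (mg/dl)",
    tc = "TC (mg/dl)", hdl = "HDL-c (mg/dl)", ldl = "LDL-c (mg/dl)",
    tg = "TG (mg/dl)", energy = "Energy (kcal)",
    carb_pct = "Carbohydrates (%E)", prot_pct = "Protein (%E)",
    fat_pct = "Fat (%E)", chol_intake = "Cholesterol intake (mg/d)",
    mets = "METs"
  )
  bin <- c(smoker = "Smokers (%)", drinker = "Drinkers (%)")
  rows <- list()
  for (v in names(cont)) {
    if (!v %in% names(cohort)) next
    m <- mean(cohort[[v]], na.rm = TRUE)
    s <- stats::sd(cohort[[v]], na.rm = TRUE)
    rows[[v]] <- data.frame(
      variable = cont[[v]],
      summary = sprintf("%.1f ± %.1f", m, s),
      mean = m, sd = s, count = NA_integer_, pct = NA_real_
    )
  }
  for (v in names(bin)) {
    if (!v %in% names(cohort)) next
    x <- cohort[[v]]
    n <- sum(!is.na(x))
    k <- sum(x, na.rm = TRUE)
    rows[[v]] <- data.frame(
      variable = bin[[v]],
      summary = sprintf("%d (%.1f%%)", k, 100 * k / n),
      mean = NA_real_, sd = NA_real_, count = k, pct = 100 * k / n
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort summary as TSV and markdown
#'
#' @param summary data.frame from [cohort_summary()].
#' @param path_tsv,path_md output file paths (either may be `NULL`).
#' @return invisibly, the summary.
#' @export
write_cohort_summary <- function(summary, path_tsv = NULL, path_md = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(summary, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(path_md)) {
    lines <- c(
      "| Variable | Value |", "|---|---|",
      sprintf("| %s | %s |", summary$variable, summary$summary)
    )
    writeLines(lines, path_md)
  }
  invisible(summary)
}
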