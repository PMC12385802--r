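#' Programme performance metrics
#'
#' Computes the pilot's descriptive indicators from a triaged participant
#' table: uptake (respondents over the eligible target population),
#' eligibility rate (eligible over respondents), PSA-test compliance
#' (tested, still-pending, and authorization-expired fractions of eligible
#' men), referral rate among tested men, the risk-category counts, and the
#' per-health-authority tabulation. Percentages are rounded half-up to one
#' decimal.
#'
#' Men who answered but did not test are classified as expired when more
#' days than the authorization window have elapsed between their
#' questionnaire and the data cutoff, and pending otherwise.
#'
#' @param records triaged participant table ([triage_table()]).
#' @param n_target size of the invited (no recent PSA) target population;
#'   must be at least the number of respondents.
#' @param data_cutoff date at which compliance is evaluated; defaults to the
#'   attribute stamped by [generate_cohort()], else the latest date in the
#'   table.
#' @param expiry_days authorization validity in days (default from the
#'   cohort attribute, else 90).
#' @return A list of class `metrics_report` with counts (`n_target`,
#'   `n_answered`, `n_eligible`, `n_temp_excluded`, `n_perm_excluded`,
#'   `n_tested`, `n_pending`, `n_expired`, `n_referred`), percentages
#'   (`uptake_pct`, `eligibility_pct`, `tested_pct`, `pending_pct`,
#'   `expired_pct`, `referral_pct`), `category_counts` (named vector over
#'   risk categories plus `FH_POSITIVE`), and `per_ats` (tibble of
#'   participants / eligible / temporarily ineligible by health authority).
#' @export
compute_metrics <- function(records, n_target,
                            data_cutoff = NULL, expiry_days = NULL) {
  stopifnot(is.data.frame(records))
  if (!"eligibility_outcome" %in% names(records)) {
    stop("records must be triaged first (see triage_table())", call. = FALSE)
  }
  data_cutoff <- data_cutoff %||% attr(records, "data_cutoff") %||%
    suppressWarnings(max(c(records$questionnaire_date, records$test_date),
                         na.rm = TRUE))
  expiry_days <- expiry_days %||% attr(records, "expiry_days") %||% 90L

  answered <- !is.na(records$answered_questionnaire) &
    records$answered_questionnaire
  n_answered <- sum(answered)
  if (n_target < n_answered) {
    stop("`n_target` cannot be smaller than the number of respondents",
         call. = FALSE)
  }
  eo <- records$eligibility_outcome
  n_temp <- sum(!is.na(eo) & eo == "NOT_ELIGIBLE_TEMPORARY")
  n_perm <- sum(!is.na(eo) & eo == "NOT_ELIGIBLE_PERMANENT")
  eligible <- !is.na(eo) & eo %in% c("ELIGIBLE_FH_NEG", "ELIGIBLE_FH_POS")
  n_eligible <- sum(eligible)

  tested <- !is.na(records$psa_ng_ml)
  n_tested <- sum(tested & eligible)
  not_tested <- eligible & !tested
  elapsed <- as.numeric(data_cutoff) -
    as.numeric(records$questionnaire_date)
  expired <- not_tested & !is.na(elapsed) & elapsed > expiry_days
  n_expired <- sum(expired)
  n_pending <- sum(not_tested) - n_expired

  referred <- tested & !is.na(records$risk_category) &
    records$risk_category == "REFER_UROLOGY"
  n_referred <- sum(referred)

  cats <- c("LOW_5YR", "INTERMEDIATE_2YR", "REFER_UROLOGY")
  category_counts <- vapply(cats, function(k) {
    sum(tested & !is.na(records$risk_category) & records$risk_category == k)
  }, integer(1))
  category_counts["FH_POSITIVE"] <-
    sum(tested & !is.na(records$fh_positive) & records$fh_positive)

  per_ats <- records |>
    dplyr::filter(answered) |>
    dplyr::group_by(ats = .data$ats) |>
    dplyr::summarise(
      participants = dplyr::n(),
      eligible = sum(.data$eligibility_outcome %in%
                       c("ELIGIBLE_FH_NEG", "ELIGIBLE_FH_POS")),
      temporarily_ineligible =
        sum(.data$eligibility_outcome == "NOT_ELIGIBLE_TEMPORARY"),
      .groups = "drop"
    )

  structure(
    list(
      n_target = n_target, n_answered = n_answered,
      n_eligible = n_eligible, n_temp_excluded = n_temp,
      n_perm_excluded = n_perm, n_tested = n_tested,
      n_pending = n_pending, n_expired = n_expired, n_referred = n_referred,
      uptake_pct = pct1(n_answered, n_target),
      eligibility_pct = pct1(n_eligible, n_answered),
      tested_pct = pct1(n_tested, n_eligible),
      pending_pct = pct1(n_pending, n_eligible),
      expired_pct = pct1(n_expired, n_eligible),
      referral_pct = pct1(n_referred, n_tested),
      category_counts = category_counts,
      per_ats = per_ats,
      data_cutoff = data_cutoff
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Screening programme metrics (data cutoff ",
      format(x$data_cutoff), ")\n", sep = "")
  cat(sprintf("  target population   %8d\n", x$n_target))
  cat(sprintf("  respondents         %8d  (uptake %.1f%%)\n",
              x$n_answered, x$uptake_pct))
  cat(sprintf("  eligible            %8d  (%.1f%% of respondents)\n",
              x$n_eligible, x$eligibility_pct))
  cat(sprintf("  excluded temp/perm  %8d / %d\n",
              x$n_temp_excluded, x$n_perm_excluded))
  cat(sprintf("  PSA tested          %8d  (%.1f%% of eligible)\n",
              x$n_tested, x$tested_pct))
  cat(sprintf("  pending / expired   %8d / %d  (%.1f%% / %.1f%%)\n",
              x$n_pending, x$n_expired, x$pending_pct, x$expired_pct))
  cat(sprintf("  referred to urology %8d  (%.1f%% of tested)\n",
              x$n_referred, x$referral_pct))
  invisible(x)
}

#' Risk-stratification table of tested men
#'
#' Tabulates first-level screening outcomes the way the programme reports
#' them: three FH-negative PSA bands plus a single row for all FH-positive
#' men (an FH-positive man whose PSA also exceeds the referral threshold is
#' counted in the family-history row only), with percentages of the tested
#' total (half-up, one decimal) and the recommended action, plus a total
#' row. Because of rounding, printed percentages may sum to 100 +/- 0.3.
#'
#' @param records triaged participant table; only rows with a PSA value
#'   (tested men) are tabulated.
#' @param thresholds protocol thresholds, see [protocol_defaults()].
#' @return A tibble with columns `category`, `n`, `pct`,
#'   `recommended_action`.
#' @export
category_table <- function(records, thresholds = protocol_defaults()) {
  stopifnot(is.data.frame(records))
  if (!"risk_category" %in% names(records)) {
    stop("records must be triaged first (see triage_table())", call. = FALSE)
  }
  t <- records[!is.na(records$psa_ng_ml), ]
  fh <- !is.na(t$fh_positive) & t$fh_positive
  psa <- t$psa_ng_ml
  n_low <- sum(!fh & psa < thresholds$psa_low)
  n_mid <- sum(!fh & psa >= thresholds$psa_low & psa <= thresholds$psa_refer)
  n_hi  <- sum(!fh & psa > thresholds$psa_refer)
  n_fh  <- sum(fh)
  n_tot <- nrow(t)
  tibble::tibble(
    category = c("FH-negative, PSA < 1.0 ng/mL",
                 "FH-negative, PSA 1.0-3.0 ng/mL",
                 "FH-negative, PSA > 3.0 ng/mL",
                 "FH-positive (any PSA)",
                 "Total"),
    n = c(n_low, n_mid, n_hi, n_fh, n_tot),
    pct = c(pct1(n_low, n_tot), pct1(n_mid, n_tot), pct1(n_hi, n_tot),
            pct1(n_fh, n_tot), if (n_tot > 0) 100 else 0),
    recommended_action = c("Routine recall in 5 years",
                           "Shorter recall in 2 years",
                           "Refer to urology (DRE)",
                           "Refer to urology (DRE)", "-")
  )
}
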