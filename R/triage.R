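#' Assess questionnaire eligibility
#'
#' Applies the pre-screening exclusion logic of the digital questionnaire.
#' A "yes" to prior prostate cancer or a known pathogenic mutation is a
#' permanent exclusion; otherwise a "yes" to a PSA test in the last 2 years
#' or a prostate diagnostic procedure in the last 5 years defers the man
#' temporarily. Permanent exclusions dominate temporary ones when both
#' apply. "unknown" is treated as "no" throughout, including for family
#' history.
#'
#' @param answers named list or named character vector with elements
#'   `psa_last_2y`, `prostate_procedure_last_5y`, `prior_prostate_cancer`,
#'   `known_pathogenic_mutation`, `fh_first_degree`, each one of
#'   `"yes"`, `"no"`, `"unknown"`.
#' @return One of `"NOT_ELIGIBLE_PERMANENT"`, `"NOT_ELIGIBLE_TEMPORARY"`,
#'   `"ELIGIBLE_FH_POS"`, `"ELIGIBLE_FH_NEG"`.
#' @export
#' @examples
#' assess_eligibility(list(
#'   psa_last_2y = "no", prostate_procedure_last_5y = "no",
#'   prior_prostate_cancer = "no", known_pathogenic_mutation = "no",
#'   fh_first_degree = "yes"
#' ))
assess_eligibility <- function(answers) {
  fields <- c("psa_last_2y", "prostate_procedure_last_5y",
              "prior_prostate_cancer", "known_pathogenic_mutation",
              "fh_first_degree")
  answers <- as.list(answers)
  for (f in fields) {
    v <- answers[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("questionnaire answer `%s` is missing", f), call. = FALSE)
    }
    if (!v %in% c("yes", "no", "unknown")) {
      stop(sprintf("`%s` must be one of \"yes\", \"no\", \"unknown\"", f),
           call. = FALSE)
    }
  }
  if (answers$prior_prostate_cancer == "yes" ||
      answers$known_pathogenic_mutation == "yes") {
    return("NOT_ELIGIBLE_PERMANENT")
  }
  if (answers$psa_last_2y == "yes" ||
      answers$prostate_procedure_last_5y == "yes") {
    return("NOT_ELIGIBLE_TEMPORARY")
  }
  if (answers$fh_first_degree == "yes") "ELIGIBLE_FH_POS" else "ELIGIBLE_FH_NEG"
}

#' First-level PSA / family-history risk stratification
#'
#' The protocol's entry triage: a positive first-degree family history is an
#' independent referral criterion at any PSA; otherwise PSA below 1.0 ng/mL
#' is low risk (5-year recall), PSA from 1.0 to 3.0 ng/mL inclusive is
#' intermediate (2-year recall), and PSA strictly above 3.0 ng/mL is
#' screening-positive (urology referral). Exactly 3.0 is intermediate
#' because referral is triggered only by PSA > 3.0; exactly 1.0 is
#' intermediate, the conservative (shorter-recall) reading of the 1-3 band.
#'
#' @param psa_ng_ml non-negative PSA values (ng/mL); vectorized. `NA` is
#'   propagated (untested men carry no category).
#' @param fh_positive logical vector, positive first-degree family history.
#' @param thresholds protocol thresholds, see [protocol_defaults()].
#' @return Character vector over `{"LOW_5YR", "INTERMEDIATE_2YR",
#'   "REFER_UROLOGY"}` (or `NA` where `psa_ng_ml` is `NA` and family history
#'   is not positive).
#' @export
#' @examples
#' classify_risk(c(0.5, 2.0, 3.0, 3.1), fh_positive = FALSE)
#' classify_risk(0.4, fh_positive = TRUE)   # referred despite very low PSA
classify_risk <- function(psa_ng_ml, fh_positive,
                          thresholds = protocol_defaults()) {
  n <- max(length(psa_ng_ml), length(fh_positive))
  psa <- rep_len(as.numeric(psa_ng_ml), n)
  fh <- rep_len(as.logical(fh_positive), n)
  if (any(!is.na(psa) & psa < 0)) {
    stop("PSA values must be non-negative", call. = FALSE)
  }
  out <- rep(NA_character_, n)
  out[!is.na(fh) & fh] <- "REFER_UROLOGY"
  rest <- (is.na(fh) | !fh) & !is.na(psa)
  out[rest & psa < thresholds$psa_low] <- "LOW_5YR"
  out[rest & psa >= thresholds$psa_low & psa <= thresholds$psa_refer] <-
    "INTERMEDIATE_2YR"
  out[rest & psa > thresholds$psa_refer] <- "REFER_UROLOGY"
  out
}

#' Triage a participant table
#'
#' Appends the eligibility outcome and first-level risk category to a
#' participant table. Eligibility is read off the resolved
#' `exclusion_status` / `fh_positive` columns; the risk category is computed
#' with [classify_risk()] for tested men (those with a PSA value) and left
#' missing otherwise. Men referred to urology are placed in the
#' `AWAITING_UROLOGY` pathway state. A separate `psa_over_3` flag preserves
#' the information that an FH-positive man also exceeded the PSA threshold
#' (summary tables count him in the family-history row only). Row order is
#' preserved and the operation is idempotent.
#'
#' @param records participant tibble as produced by [generate_cohort()].
#' @param thresholds protocol thresholds, see [protocol_defaults()].
#' @return `records` with columns `eligibility_outcome`, `risk_category`,
#'   `psa_over_3` appended and `pathway_state` set for referred men.
#' @export
triage_table <- function(records, thresholds = protocol_defaults()) {
  stopifnot(is.data.frame(records))
  dup <- unique(records$participant_id[duplicated(records$participant_id)])
  if (length(dup) > 0) {
    stop("duplicate participant_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    records$eligibility_outcome <- character()
    records$risk_category <- character()
    records$psa_over_3 <- logical()
    return(records)
  }

  elig <- rep(NA_character_, nrow(records))
  ans <- records$answered_questionnaire
  ex <- records$exclusion_status
  elig[ans & !is.na(ex) & ex == "permanent"] <- "NOT_ELIGIBLE_PERMANENT"
  elig[ans & !is.na(ex) & ex == "temporary"] <- "NOT_ELIGIBLE_TEMPORARY"
  ok <- ans & !is.na(ex) & ex == "none"
  elig[ok & !is.na(records$fh_positive) & records$fh_positive] <-
    "ELIGIBLE_FH_POS"
  elig[ok & (is.na(records$fh_positive) | !records$fh_positive)] <-
    "ELIGIBLE_FH_NEG"

  tested <- !is.na(records$psa_ng_ml)
  risk <- rep(NA_character_, nrow(records))
  risk[tested] <- classify_risk(records$psa_ng_ml[tested],
                                records$fh_positive[tested], thresholds)

  records$eligibility_outcome <- elig
  records$risk_category <- risk
  records$psa_over_3 <- tested & records$psa_ng_ml > thresholds$psa_refer
  records$pathway_state <- ifelse(
    !is.na(risk) & risk == "REFER_UROLOGY", "AWAITING_UROLOGY",
    records$pathway_state
  )
  records
}
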