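## Deterministic fixture cohort mirroring the aggregate results published
## for the Lombardy pilot's first eight months (Nov 2024 - Jun 2025).
## Individual-level pilot data are not public; this reconstruction fixes
## every marginal count the programme reported and spreads PSA values
## deterministically inside each band, so the triage, metrics and pathway
## stages can be exercised and checked against the printed tables.

pilot_ats_table <- tibble::tibble(
  ats = c("ATS Milano", "ATS Insubria", "ATS Montagna", "ATS Brianza",
          "ATS Bergamo", "ATS Brescia", "ATS Val Padana", "ATS Pavia"),
  participants = c(3401L, 1296L, 237L, 1184L, 624L, 910L, 595L, 311L),
  eligible = c(2366L, 919L, 169L, 782L, 508L, 680L, 431L, 217L),
  temporarily_ineligible = c(1035L, 377L, 68L, 402L, 116L, 230L, 164L, 94L)
)

# expand a per-ATS count vector into one label per row
ats_fill <- function(counts) rep(pilot_ats_table$ats, counts)

#' Synthetic pilot fixture cohort
#'
#' A deterministic participant table whose aggregate counts match the
#' Lombardy pilot's published eight-month results: 8558 respondents of a
#' 97,849-man target population, 2486 temporary exclusions (the printed
#' totals leave no permanent ones), 6072 eligible of whom 1412 tested,
#' 3263 still pending and 1397 past the 90-day authorization; among tested
#' men, 824 FH-negative with PSA < 1, 364 FH-negative with PSA 1-3, 29
#' FH-negative with PSA > 3 and 195 FH-positive (3 of whom also exceed
#' 3 ng/mL); 644 of the eligible are FH-positive overall. Per-authority
#' participant, eligible and temporarily-ineligible counts match the
#' published tabulation. PSA values are spread evenly inside each band;
#' dates are fixed so compliance states are unambiguous. The table is
#' synthetic: only its margins are real.
#'
#' @param tested_only if `TRUE`, return only the 1412 tested records.
#' @return A participant tibble (see [generate_cohort()] for columns) with
#'   `data_cutoff` and `expiry_days` attributes.
#' @export
#' @examples
#' category_table(triage_table(pilot_cohort(tested_only = TRUE)))
pilot_cohort <- function(tested_only = FALSE) {
  cutoff <- as.Date("2025-06-30")

  ## tested men: 1412, in reporting order low / intermediate / elevated / FH+
  psa_low <- seq(0.10, 0.99, length.out = 824)
  psa_mid <- seq(1.00, 3.00, length.out = 364)   # both boundaries inclusive
  psa_hi  <- seq(3.20, 9.00, length.out = 29)
  psa_fh  <- c(seq(0.40, 2.80, length.out = 192), 4.2, 5.1, 6.3)
  tested <- tibble::tibble(
    fh_positive = rep(c(FALSE, TRUE), c(824 + 364 + 29, 195)),
    psa_ng_ml = c(psa_low, psa_mid, psa_hi, psa_fh),
    questionnaire_date = as.Date("2025-01-15"),
    test_date = as.Date("2025-02-14"),
    exclusion_status = "none"
  )

  if (tested_only) {
    n <- nrow(tested)
    out <- tibble::tibble(
      participant_id = sprintf("T%06d", seq_len(n)),
      ats = rep_len(pilot_ats_table$ats, n),
      answered_questionnaire = TRUE,
      exclusion_status = tested$exclusion_status,
      fh_positive = tested$fh_positive,
      psa_ng_ml = tested$psa_ng_ml,
      questionnaire_date = tested$questionnaire_date,
      test_date = tested$test_date,
      pathway_state = NA_character_,
      pirads = NA_integer_,
      prostate_volume_cc = NA_real_,
      biopsy_result = "not_done"
    )
    attr(out, "data_cutoff") <- cutoff
    attr(out, "expiry_days") <- 90L
    return(out)
  }

  ## untested eligible men: 3263 pending (authorization still open at the
  ## cutoff) and 1397 expired; 449 FH-positives among them bring the
  ## eligible total to 644
  pending <- tibble::tibble(
    fh_positive = rep(c(TRUE, FALSE), c(300, 2963)),
    psa_ng_ml = NA_real_,
    questionnaire_date = as.Date("2025-06-01"),
    test_date = as.Date(NA),
    exclusion_status = "none"
  )
  expired <- tibble::tibble(
    fh_positive = rep(c(TRUE, FALSE), c(149, 1248)),
    psa_ng_ml = NA_real_,
    questionnaire_date = as.Date("2024-12-01"),
    test_date = as.Date(NA),
    exclusion_status = "none"
  )
  excluded <- tibble::tibble(
    fh_positive = NA,
    psa_ng_ml = NA_real_,
    questionnaire_date = as.Date("2025-02-01"),
    test_date = as.Date(NA),
    exclusion_status = "temporary"
  )[rep(1L, 2486), ]

  eligible <- dplyr::bind_rows(tested, pending, expired)
  eligible$ats <- ats_fill(pilot_ats_table$eligible)
  excluded$ats <- ats_fill(pilot_ats_table$temporarily_ineligible)

  out <- dplyr::bind_rows(eligible, excluded)
  out$participant_id <- sprintf("P%06d", seq_len(nrow(out)))
  out$answered_questionnaire <- TRUE
  out$pathway_state <- NA_character_
  out$pirads <- NA_integer_
  out$prostate_volume_cc <- NA_real_
  out$biopsy_result <- ifelse(is.na(out$psa_ng_ml), NA_character_,
                              "not_done")
  out <- out[, c("participant_id", "ats", "answered_questionnaire",
                 "exclusion_status", "fh_positive", "psa_ng_ml",
                 "questionnaire_date", "test_date", "pathway_state",
                 "pirads", "prostate_volume_cc", "biopsy_result")]
  attr(out, "data_cutoff") <- cutoff
  attr(out, "expiry_days") <- 90L
  out
}

#' Size of the pilot's target population
#'
#' The 97,849 men in the invited birth cohorts with no PSA test recorded in
#' the previous two years — the uptake denominator that goes with
#' [pilot_cohort()].
#'
#' @return An integer count.
#' @export
pilot_target_population <- function() 97849L

#' Published yield-projection scenarios
#'
#' The four participation scenarios of the programme's yield projection:
#' the observed pilot cohort (1412 men screened at the age-50 incidence of
#' 21.1/100,000/yr) and the 50-69 age band (861,163 eligible men at
#' 97.6/100,000/yr) at 15\%, 30\% and 40\% participation, all over a 2-year
#' round at 87\% test sensitivity.
#'
#' @return A list of [projection_scenario()] objects.
#' @export
#' @examples
#' scenario_grid(pilot_scenarios())
pilot_scenarios <- function() {
  list(
    projection_scenario(n_screened = 1412, incidence_per_100k_yr = 21.1,
                        label = "50 yr - current situation"),
    projection_scenario(861163, 0.15, incidence_per_100k_yr = 97.6,
                        label = "50-69 yr, 15% participation"),
    projection_scenario(861163, 0.30, incidence_per_100k_yr = 97.6,
                        label = "50-69 yr, 30% participation"),
    projection_scenario(861163, 0.40, incidence_per_100k_yr = 97.6,
                        label = "50-69 yr, 40% participation")
  )
}

#' Published standard-care vs screening comparison arms
#'
#' The three utilization comparisons for 50-year-old men: standard care in
#' 2023 (16,933 PSA tests) versus the screening pilot (1412 tests, with
#' pilot counts adjusted pro-rata for episodes not yet completed, hence the
#' fractional events).
#'
#' @return A named list; each element holds `arm1` (standard care), `arm2`
#'   (screening pilot) and `outcome`.
#' @export
#' @examples
#' with(pilot_comparisons()$mri, compare_proportions(arm1, arm2))
pilot_comparisons <- function() {
  list(
    urology = list(outcome = "Urologist visits",
                   arm1 = arm_counts(4240, 16933),
                   arm2 = arm_counts(261, 1412)),
    mri = list(outcome = "MRI usage",
               arm1 = arm_counts(312, 16933),
               arm2 = arm_counts(16.8, 1412)),
    biopsy = list(outcome = "Biopsy rate",
                  arm1 = arm_counts(57, 16933),
                  arm2 = arm_counts(4.8, 1412))
  )
}
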