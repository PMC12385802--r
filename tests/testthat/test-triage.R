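base_answers <- list(
  psa_last_2y = "no", prostate_procedure_last_5y = "no",
  prior_prostate_cancer = "no", known_pathogenic_mutation = "no",
  fh_first_degree = "no"
)
answer <- function(...) utils::modifyList(base_answers, list(...))

test_that("questionnaire exclusion logic follows the protocol", {
  expect_equal(assess_eligibility(answer(psa_last_2y = "yes")),
               "NOT_ELIGIBLE_TEMPORARY")
  expect_equal(assess_eligibility(answer(prostate_procedure_last_5y = "yes")),
               "NOT_ELIGIBLE_TEMPORARY")
  expect_equal(assess_eligibility(answer(prior_prostate_cancer = "yes")),
               "NOT_ELIGIBLE_PERMANENT")
  expect_equal(assess_eligibility(answer(known_pathogenic_mutation = "yes")),
               "NOT_ELIGIBLE_PERMANENT")
  # permanent dominates temporary when both apply
  expect_equal(assess_eligibility(answer(prior_prostate_cancer = "yes",
                                         psa_last_2y = "yes")),
               "NOT_ELIGIBLE_PERMANENT")
  # unknown answers are treated as no, including family history
  all_unknown <- lapply(base_answers, function(x) "unknown")
  expect_equal(assess_eligibility(all_unknown), "ELIGIBLE_FH_NEG")
  expect_equal(assess_eligibility(answer(fh_first_degree = "yes")),
               "ELIGIBLE_FH_POS")
})

test_that("incomplete or malformed questionnaires are rejected by name", {
  expect_error(assess_eligibility(base_answers[-1]), "psa_last_2y")
  expect_error(assess_eligibility(answer(fh_first_degree = "maybe")),
               "fh_first_degree")
})

# independently written truth table for the first-level triage, straight
# from the protocol text: FH+ always referred; otherwise <1 low, 1-3
# inclusive intermediate, >3 referred
risk_oracle <- function(psa, fh) {
  if (fh) return("REFER_UROLOGY")
  if (psa < 1.0) return("LOW_5YR")
  if (psa <= 3.0) return("INTERMEDIATE_2YR")
  "REFER_UROLOGY"
}

test_that("classify_risk matches the brute-force truth table on a boundary grid", {
  psa_grid <- c(0, 0.4, 0.5, 0.999999, 1.0, 1.0000001, 2, 2.9999999,
                3.0, 3.0000001, 4, 10, 100)
  for (fh in c(FALSE, TRUE)) {
    got <- classify_risk(psa_grid, fh)
    want <- vapply(psa_grid, risk_oracle, character(1), fh = fh)
    expect_equal(got, want)
    # partition: exactly one category everywhere on the grid
    expect_false(any(is.na(got)))
  }
  expect_error(classify_risk(-0.1, FALSE), "non-negative")
})

test_that("risk severity is non-decreasing in PSA for FH-negative men", {
  severity <- c(LOW_5YR = 1, INTERMEDIATE_2YR = 2, REFER_UROLOGY = 3)
  psa <- sort(c(seq(0, 10, by = 0.05), 0.9999, 1, 3, 3.0001))
  s <- severity[classify_risk(psa, FALSE)]
  expect_true(all(diff(s) >= 0))
})

test_that("triage_table reproduces the pilot stratification and preserves rows", {
  expect_equal(nrow(triage_table(make_records(numeric(), logical()))), 0)

  tr <- triage_table(pilot_cohort(tested_only = TRUE))
  counts <- table(tr$risk_category)
  expect_equal(unname(counts["LOW_5YR"]), 824)
  expect_equal(unname(counts["INTERMEDIATE_2YR"]), 364)
  expect_equal(unname(counts["REFER_UROLOGY"]), 224)  # 29 PSA + 195 FH
  expect_equal(tr$participant_id, pilot_cohort(tested_only = TRUE)$participant_id)
  # idempotent
  expect_equal(triage_table(tr), tr)
  # FH-positive men with PSA above threshold keep a single category plus a flag
  expect_equal(sum(tr$psa_over_3 & tr$fh_positive), 3)

  all_fh <- triage_table(make_records(psa = runif(50, 0.2, 0.9), fh = TRUE))
  expect_true(all(all_fh$risk_category == "REFER_UROLOGY"))
})

test_that("duplicate participant identifiers are reported", {
  rec <- make_records(c(0.5, 2), FALSE, id = c("A", "A"))
  expect_error(triage_table(rec), "duplicate.*A")
})

test_that("referral fraction decomposes into FH and high-PSA components", {
  cfg <- cohort_config(n_target_population = 40000, uptake_prob = 1,
                       temp_exclusion_prob = 0, perm_exclusion_prob = 0,
                       test_completion_prob = 1, seed = 12)
  tr <- triage_table(generate_cohort(cfg))
  p_fh <- mean(tr$fh_positive)
  p_hi <- plnorm(3, cfg$psa_log_mu, cfg$psa_log_sigma, lower.tail = FALSE)
  expected <- p_fh + (1 - p_fh) * p_hi
  observed <- mean(tr$risk_category == "REFER_UROLOGY")
  expect_lt(abs(observed - expected), 0.01)
})
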