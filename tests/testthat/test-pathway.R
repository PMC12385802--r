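# independently written truth table for the MRI decision rule, transcribed
# from the protocol: PI-RADS 4-5 biopsy; PI-RADS 3 splits on density 0.10;
# PI-RADS 1-2 splits on density 0.20
mri_oracle <- function(pirads, density) {
  if (pirads %in% c(4, 5)) return("BIOPSY_INDICATED")
  if (pirads == 3) {
    if (density >= 0.10) return("BIOPSY_INDICATED")
    return("FOLLOWUP_1YR")
  }
  if (density >= 0.20) return("CONSIDER_BIOPSY")
  "SURVEILLANCE_1YR"
}

test_that("mri_decision is total and matches the truth table on an exhaustive grid", {
  densities <- c(0, 0.05, 0.0999999, 0.10, 0.1000001, 0.15, 0.1999999,
                 0.20, 0.2000001, 0.25, 0.5, 2)
  grid <- expand.grid(pirads = 1:5, density = densities)
  got <- mri_decision(grid$pirads, grid$density)
  want <- mapply(mri_oracle, grid$pirads, grid$density)
  expect_equal(got, unname(want))
  expect_false(any(is.na(got)))
})

test_that("mri_decision rejects invalid scores and densities", {
  expect_error(mri_decision(0, 0.1), "1..5")
  expect_error(mri_decision(6, 0.1), "1..5")
  expect_error(mri_decision(3.5, 0.1), "1..5")
  expect_error(mri_decision(3, -0.01), "non-negative")
})

awaiting <- function(n) {
  r <- make_records(psa = rep(4, n), fh = FALSE)
  r$pathway_state <- "AWAITING_UROLOGY"
  r
}

test_that("urology outcomes follow the configured probabilities", {
  sure <- pathway_probabilities(1, 0, 0, 0, 0)
  expect_true(all(urology_outcome(awaiting(50), sure) ==
                    "UROLOGY_LOW_RISK_PSA_1YR"))

  # frequencies observed among the pilot's completed visits
  set.seed(31)
  probs <- pathway_probabilities(0.91, 0.07, 0, 0.01, 0.01)
  draws <- urology_outcome(awaiting(10000), probs)
  expect_lt(abs(mean(draws == "UROLOGY_LOW_RISK_PSA_1YR") - 0.91), 0.01)

  wrong <- make_records(0.5, FALSE)
  wrong$pathway_state <- "LOW_5YR"
  expect_error(urology_outcome(wrong, probs), "AWAITING_UROLOGY")
})

test_that("pathway probability validation catches inconsistent inputs", {
  expect_error(pathway_probabilities(0.5, 0.5, 0.5, 0, 0), "sum to 1")
  expect_error(pathway_probabilities(pirads_pmf = c(1, 0, 0, 0)),
               "pirads_pmf")
  expect_error(pathway_probabilities(biopsy_positive_prob = 2), "probability")
})

test_that("every referred man ends in exactly one terminal state", {
  tr <- triage_table(generate_cohort(cohort_config(
    n_target_population = 15000, uptake_prob = 1, temp_exclusion_prob = 0,
    perm_exclusion_prob = 0, test_completion_prob = 1, seed = 8)))
  res <- run_pathway(tr, pathway_probabilities(), seed = 81)
  n_ref <- sum(tr$risk_category == "REFER_UROLOGY", na.rm = TRUE)
  expect_equal(res$summary$n_referred, n_ref)
  expect_equal(sum(res$summary$terminal_counts), n_ref)
  # no one lost or duplicated
  expect_equal(nrow(res$records), nrow(tr))
  ref_states <- res$records$pathway_state[!is.na(res$records$risk_category) &
                                            res$records$risk_category ==
                                            "REFER_UROLOGY"]
  expect_false(any(ref_states == "AWAITING_UROLOGY"))
})

test_that("pathway composition behaves in forced and empty limits", {
  # no referrals -> no activity
  low <- triage_table(make_records(psa = rep(0.5, 20), fh = FALSE))
  res0 <- run_pathway(low, pathway_probabilities(), seed = 1)
  expect_equal(res0$summary$n_referred, 0L)
  expect_equal(res0$summary$n_mri, 0L)
  expect_equal(res0$summary$n_biopsy, 0L)
  expect_equal(nrow(res0$events), 0)

  # no MRI branch -> no MRIs
  tr <- triage_table(make_records(psa = rep(5, 500), fh = FALSE))
  res1 <- run_pathway(tr, pathway_probabilities(1, 0, 0, 0, 0), seed = 2)
  expect_equal(res1$summary$n_mri, 0L)

  # everyone to MRI with PI-RADS forced to 4 -> MRIs == biopsies
  all_mri <- pathway_probabilities(0, 1, 0, 0, 0,
                                   pirads_pmf = c(0, 0, 0, 1, 0))
  res2 <- run_pathway(tr, all_mri, seed = 3)
  expect_equal(res2$summary$n_mri, 500L)
  expect_equal(res2$summary$n_biopsy, 500L)
  expect_equal(res2$summary$n_biopsy_positive +
                 sum(res2$summary$terminal_counts["BIOPSY_NEGATIVE"]), 500)

  expect_error(run_pathway(make_records(1, FALSE)), "triaged")
})

test_that("pathway runs are reproducible under a seed and logged coherently", {
  tr <- triage_table(make_records(psa = runif(300, 3.5, 9), fh = FALSE))
  a <- run_pathway(tr, pathway_probabilities(), seed = 55)
  b <- run_pathway(tr, pathway_probabilities(), seed = 55)
  expect_identical(a$records, b$records)
  expect_identical(a$events, b$events)
  # event log starts from the referral state for every referred man
  expect_setequal(unique(a$events$from_state[a$events$step == 1]),
                  "AWAITING_UROLOGY")
})
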