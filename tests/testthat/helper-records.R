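# minimal participant table builder for unit tests
make_records <- function(psa, fh, id = sprintf("X%04d", seq_along(psa)),
                         ats = "ATS Milano") {
  n <- length(psa)
  tibble::tibble(
    participant_id = id,
    ats = rep_len(ats, n),
    answered_questionnaire = TRUE,
    exclusion_status = "none",
    fh_positive = rep_len(fh, n),
    psa_ng_ml = psa,
    questionnaire_date = as.Date("2025-01-01"),
    test_date = as.Date("2025-01-20"),
    pathway_state = NA_character_,
    pirads = NA_integer_,
    prostate_volume_cc = NA_real_,
    biopsy_result = "not_done"
  )
}
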