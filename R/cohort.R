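## Default share of participants by local health authority (ATS), taken from
## the pilot's first eight months of enrollment. Used only as sampling
## weights for the synthetic geographic label.
ats_weights_default <- c(
  "ATS Milano"    = 3401,
  "ATS Insubria"  = 1296,
  "ATS Montagna"  = 237,
  "ATS Brianza"   = 1184,
  "ATS Bergamo"   = 624,
  "ATS Brescia"   = 910,
  "ATS Val Padana" = 595,
  "ATS Pavia"     = 311
)

#' Configuration of the synthetic screening cohort
#'
#' Bundles the behavioural and distributional parameters of the
#' synthetic-cohort generator. Defaults reproduce the conditions observed in
#' the Lombardy pilot's activation phase (passive invitation, men turning
#' 50): 8.7\% uptake, roughly 29\% temporary exclusions for recent testing,
#' 23.3\% PSA completion within the 90-day authorization window, and a PSA
#' distribution calibrated so that 67.7\% / 97.6\% of FH-negative tested men
#' fall below 1.0 / 3.0 ng/mL (the pilot's observed stratification).
#'
#' @param n_target_population number of men in the invited birth cohorts.
#' @param uptake_prob probability an invited man completes the online
#'   questionnaire.
#' @param temp_exclusion_prob probability a respondent is temporarily
#'   excluded (PSA test in the last 2 years or prostate procedure in the
#'   last 5).
#' @param perm_exclusion_prob probability of a permanent exclusion (prior
#'   prostate cancer or known pathogenic mutation); the pilot reported this
#'   as "<1\%", default 0.5\%.
#' @param fh_prob probability of a positive first-degree family history
#'   (father, brother or son with prostate cancer). The pilot reports 10.6\%
#'   among eligible respondents and 13.8\% among tested men; the generator
#'   samples family history independently of test completion, and defaults
#'   to 0.138 so the tested stratification matches the reported one.
#' @param psa_log_mu,psa_log_sigma location and scale of log-PSA (ng/mL);
#'   defaults come from [calibrate_psa_distribution()] on the pilot's
#'   FH-negative category fractions (824/1217 below 1, 1188/1217 below 3).
#' @param test_completion_prob probability an eligible man obtains the PSA
#'   test within the authorization window.
#' @param expiry_days validity of the test authorization, days.
#' @param enrollment_start,data_cutoff calendar window over which
#'   questionnaire dates are drawn uniformly; eligible men who neither
#'   tested nor still have time left are counted as expired.
#' @param ats_weights named numeric vector of sampling weights for the
#'   health-authority label.
#' @param seed integer RNG seed; all randomness in [generate_cohort()] flows
#'   from it.
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_target_population = 1000, seed = 1)
#' cfg$psa_log_mu
cohort_config <- function(n_target_population = 97849,
                          uptake_prob = 0.087,
                          temp_exclusion_prob = 0.286,
                          perm_exclusion_prob = 0.005,
                          fh_prob = 0.138,
                          psa_log_mu = NULL,
                          psa_log_sigma = NULL,
                          test_completion_prob = 0.233,
                          expiry_days = 90L,
                          enrollment_start = as.Date("2024-11-01"),
                          data_cutoff = as.Date("2025-06-30"),
                          ats_weights = ats_weights_default,
                          seed = 20241101L) {
  if (is.null(psa_log_mu) || is.null(psa_log_sigma)) {
    cal <- calibrate_psa_distribution(824 / 1217, 1188 / 1217)
    psa_log_mu <- psa_log_mu %||% cal$psa_log_mu
    psa_log_sigma <- psa_log_sigma %||% cal$psa_log_sigma
  }
  stopifnot(
    length(n_target_population) == 1L, n_target_population >= 0,
    n_target_population == floor(n_target_population),
    is.numeric(psa_log_sigma), psa_log_sigma > 0,
    length(expiry_days) == 1L, expiry_days > 0,
    inherits(enrollment_start, "Date"), inherits(data_cutoff, "Date"),
    data_cutoff >= enrollment_start,
    is.numeric(ats_weights), length(ats_weights) > 0,
    !is.null(names(ats_weights)), all(ats_weights >= 0)
  )
  for (p in c("uptake_prob", "temp_exclusion_prob", "perm_exclusion_prob",
              "fh_prob", "test_completion_prob")) {
    assert_prob(get(p), p)
  }
  if (temp_exclusion_prob + perm_exclusion_prob > 1) {
    stop("temp_exclusion_prob + perm_exclusion_prob must not exceed 1",
         call. = FALSE)
  }
  structure(
    list(
      n_target_population = as.integer(n_target_population),
      uptake_prob = uptake_prob,
      temp_exclusion_prob = temp_exclusion_prob,
      perm_exclusion_prob = perm_exclusion_prob,
      fh_prob = fh_prob,
      psa_log_mu = psa_log_mu,
      psa_log_sigma = psa_log_sigma,
      test_completion_prob = test_completion_prob,
      expiry_days = as.integer(expiry_days),
      enrollment_start = enrollment_start,
      data_cutoff = data_cutoff,
      ats_weights = ats_weights,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic screening cohort
#'
#' Draws one participant record per man in the target population. Invited
#' men complete the questionnaire with probability `uptake_prob`; respondents
#' are permanently or temporarily excluded with the configured
#' probabilities; eligible men carry a family-history flag and, with
#' probability `test_completion_prob`, a PSA value drawn from the calibrated
#' log-normal together with a test date inside the authorization window.
#' Eligible men who did not test are left pending (time remains before the
#' authorization expires at the data cutoff) or expired. All sampling is
#' independent across men and reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A tibble with one row per invited man and columns
#'   `participant_id`, `ats`, `answered_questionnaire`, `exclusion_status`
#'   (`"none"`, `"temporary"`, `"permanent"`, or `NA` for non-respondents),
#'   `fh_positive`, `psa_ng_ml`, `questionnaire_date`, `test_date`,
#'   `pathway_state`, `pirads`, `prostate_volume_cc`, `biopsy_result`.
#'   The `data_cutoff` and `expiry_days` used are attached as attributes.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_target_population = 500, seed = 7))
#' table(cohort$exclusion_status, useNA = "ifany")
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created with cohort_config()", call. = FALSE)
  }
  n <- config$n_target_population
  if (!is.null(config$seed)) set.seed(config$seed)

  if (n == 0L) {
    out <- empty_cohort()
  } else {
    ats <- sample(names(config$ats_weights), n, replace = TRUE,
                  prob = config$ats_weights / sum(config$ats_weights))
    answered <- runif(n) < config$uptake_prob

    exclusion <- rep(NA_character_, n)
    u <- runif(n)
    exclusion[answered] <- ifelse(
      u[answered] < config$perm_exclusion_prob, "permanent",
      ifelse(u[answered] < config$perm_exclusion_prob +
               config$temp_exclusion_prob, "temporary", "none")
    )
    eligible <- !is.na(exclusion) & exclusion == "none"

    fh <- rep(NA, n)
    fh[eligible] <- runif(sum(eligible)) < config$fh_prob

    window <- as.integer(config$data_cutoff - config$enrollment_start)
    qdate <- rep(as.Date(NA), n)
    qdate[answered] <- config$enrollment_start +
      sample.int(window + 1L, sum(answered), replace = TRUE) - 1L

    tested <- eligible & runif(n) < config$test_completion_prob
    psa <- rep(NA_real_, n)
    psa[tested] <- rlnorm(sum(tested), config$psa_log_mu, config$psa_log_sigma)
    tdate <- rep(as.Date(NA), n)
    # test occurs within the authorization window, but never past the cutoff
    delay <- sample.int(config$expiry_days, sum(tested), replace = TRUE)
    tdate[tested] <- pmin(qdate[tested] + delay, config$data_cutoff)

    out <- tibble::tibble(
      participant_id = sprintf("P%07d", seq_len(n)),
      ats = ats,
      answered_questionnaire = answered,
      exclusion_status = exclusion,
      fh_positive = fh,
      psa_ng_ml = psa,
      questionnaire_date = qdate,
      test_date = tdate,
      pathway_state = NA_character_,
      pirads = NA_integer_,
      prostate_volume_cc = NA_real_,
      biopsy_result = ifelse(tested, "not_done", NA_character_)
    )
  }
  attr(out, "data_cutoff") <- config$data_cutoff
  attr(out, "expiry_days") <- config$expiry_days
  out
}

empty_cohort <- function() {
  tibble::tibble(
    participant_id = character(),
    ats = character(),
    answered_questionnaire = logical(),
    exclusion_status = character(),
    fh_positive = logical(),
    psa_ng_ml = double(),
    questionnaire_date = as.Date(character()),
    test_date = as.Date(character()),
    pathway_state = character(),
    pirads = integer(),
    prostate_volume_cc = double(),
    biopsy_result = character()
  )
}

#' Write or read a participant table as delimited text
#'
#' Participant tables are exchanged as comma-separated text with a header
#' row, ISO-8601 dates and empty fields for missing values.
#'
#' @param records a participant tibble.
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the participant tibble with column types restored.
#' @export
write_cohort <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::tibble(
    participant_id = as.character(raw$participant_id),
    ats = as.character(raw$ats),
    answered_questionnaire = as.logical(raw$answered_questionnaire),
    exclusion_status = as.character(raw$exclusion_status),
    fh_positive = as.logical(raw$fh_positive),
    psa_ng_ml = as.numeric(raw$psa_ng_ml),
    questionnaire_date = as.Date(raw$questionnaire_date),
    test_date = as.Date(raw$test_date),
    pathway_state = as.character(raw$pathway_state),
    pirads = as.integer(raw$pirads),
    prostate_volume_cc = as.numeric(raw$prostate_volume_cc),
    biopsy_result = as.character(raw$biopsy_result)
  )
}
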