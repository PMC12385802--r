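urology_states <- c("UROLOGY_LOW_RISK_PSA_1YR", "UROLOGY_MRI_INDICATED",
                    "UROLOGY_HIGH_RISK_MRI_BIOPSY", "REFUSED", "EXITED")

terminal_states <- c("UROLOGY_LOW_RISK_PSA_1YR", "REFUSED", "EXITED",
                     "SURVEILLANCE_1YR", "FOLLOWUP_1YR", "CONSIDER_BIOPSY",
                     "BIOPSY_POSITIVE", "BIOPSY_NEGATIVE")

#' Branch probabilities of the specialist pathway
#'
#' Probabilities governing the stochastic part of the second-level pathway.
#' The five urology-visit outcomes must sum to 1; defaults follow the
#' frequencies observed among the pilot's first completed urology visits
#' (91\% no concerning findings, 7\% MRI indicated, ~1\% refusals/exits,
#' no direct high-risk MRI+biopsy indications). The PI-RADS mass defaults
#' to the benign-heavy profile seen in early screening rounds, and prostate
#' volume is log-normal around ~40 cc.
#'
#' @param p_urology_low,p_urology_mri,p_urology_high,p_refuse,p_exit
#'   probabilities of the urology-visit outcomes: routine surveillance with
#'   a 1-year PSA, MRI indicated, direct MRI+biopsy indication, refusal of
#'   the visit, exit from the programme.
#' @param pirads_pmf probability mass over PI-RADS scores 1 to 5.
#' @param volume_log_mu,volume_log_sigma log-normal parameters of
#'   MRI-estimated prostate volume (cc).
#' @param biopsy_positive_prob probability a performed biopsy finds cancer;
#'   default 0.30, the positivity rate assumed for MRI-targeted biopsies.
#' @return A list of class `pathway_probabilities`.
#' @export
pathway_probabilities <- function(p_urology_low = 0.91,
                                  p_urology_mri = 0.07,
                                  p_urology_high = 0.00,
                                  p_refuse = 0.01,
                                  p_exit = 0.01,
                                  pirads_pmf = c(0.35, 0.35, 0.18, 0.09, 0.03),
                                  volume_log_mu = log(40),
                                  volume_log_sigma = 0.35,
                                  biopsy_positive_prob = 0.30) {
  p5 <- c(p_urology_low, p_urology_mri, p_urology_high, p_refuse, p_exit)
  if (any(p5 < 0) || abs(sum(p5) - 1) > 1e-8) {
    stop("the five urology outcome probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (length(pirads_pmf) != 5L || any(pirads_pmf < 0) ||
      abs(sum(pirads_pmf) - 1) > 1e-8) {
    stop("`pirads_pmf` must be 5 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  assert_prob(biopsy_positive_prob, "biopsy_positive_prob")
  stopifnot(volume_log_sigma > 0)
  structure(
    list(p_urology_low = p_urology_low, p_urology_mri = p_urology_mri,
         p_urology_high = p_urology_high, p_refuse = p_refuse,
         p_exit = p_exit, pirads_pmf = pirads_pmf,
         volume_log_mu = volume_log_mu, volume_log_sigma = volume_log_sigma,
         biopsy_positive_prob = biopsy_positive_prob),
    class = "pathway_probabilities"
  )
}

#' MRI decision table: PI-RADS score and PSA density
#'
#' The protocol's biopsy indication rule after multiparametric MRI, with
#' PSA density = PSA / MRI-estimated prostate volume (ng/mL/cc):
#' \itemize{
#'   \item PI-RADS 4 or 5: biopsy indicated;
#'   \item PI-RADS 3, density at or above `density_biopsy` (0.10): biopsy
#'     indicated; below it: close follow-up with PSA at 1 year;
#'   \item PI-RADS 1-2, density below `density_consider` (0.20): back to
#'     surveillance with a 1-year recall;
#'   \item PI-RADS 1-2, density at or above 0.20: consider biopsy despite
#'     the negative MRI (possible MRI-occult disease).
#' }
#'
#' @param pirads integer PI-RADS v2 score(s) in 1..5; vectorized.
#' @param psa_density non-negative PSA density value(s), ng/mL/cc.
#' @param thresholds protocol thresholds, see [protocol_defaults()].
#' @return Character vector over `{"BIOPSY_INDICATED", "FOLLOWUP_1YR",
#'   "SURVEILLANCE_1YR", "CONSIDER_BIOPSY"}`.
#' @export
#' @examples
#' mri_decision(4, 0.05)   # biopsy regardless of density
#' mri_decision(3, 0.10)   # boundary inclusive: biopsy
#' mri_decision(2, 0.25)   # consider biopsy despite negative MRI
mri_decision <- function(pirads, psa_density,
                         thresholds = protocol_defaults()) {
  n <- max(length(pirads), length(psa_density))
  p <- rep_len(pirads, n)
  d <- rep_len(psa_density, n)
  if (any(is.na(p)) || any(p != floor(p)) || any(p < 1) || any(p > 5)) {
    stop("`pirads` must be integers in 1..5", call. = FALSE)
  }
  if (any(is.na(d)) || any(d < 0)) {
    stop("`psa_density` must be non-negative", call. = FALSE)
  }
  out <- rep(NA_character_, n)
  out[p >= 4] <- "BIOPSY_INDICATED"
  out[p == 3 & d >= thresholds$density_biopsy] <- "BIOPSY_INDICATED"
  out[p == 3 & d < thresholds$density_biopsy] <- "FOLLOWUP_1YR"
  out[p <= 2 & d < thresholds$density_consider] <- "SURVEILLANCE_1YR"
  out[p <= 2 & d >= thresholds$density_consider] <- "CONSIDER_BIOPSY"
  out
}

#' Sample urology-visit outcomes
#'
#' Draws the outcome of the specialist consultation (history review, DRE,
#' risk judgement) for men awaiting urology, from the configured outcome
#' probabilities. Reproducible under the session RNG state.
#'
#' @param records participant rows, all in pathway state `AWAITING_UROLOGY`.
#' @param probs a [pathway_probabilities()].
#' @return Character vector of sampled states, one per record, over
#'   `{"UROLOGY_LOW_RISK_PSA_1YR", "UROLOGY_MRI_INDICATED",
#'   "UROLOGY_HIGH_RISK_MRI_BIOPSY", "REFUSED", "EXITED"}`.
#' @export
urology_outcome <- function(records, probs) {
  stopifnot(is.data.frame(records), inherits(probs, "pathway_probabilities"))
  if (nrow(records) == 0L) return(character())
  if (any(is.na(records$pathway_state)) ||
      any(records$pathway_state != "AWAITING_UROLOGY")) {
    stop("all records must be in pathway state AWAITING_UROLOGY",
         call. = FALSE)
  }
  sample(urology_states, nrow(records), replace = TRUE,
         prob = c(probs$p_urology_low, probs$p_urology_mri,
                  probs$p_urology_high, probs$p_refuse, probs$p_exit))
}

#' Run the specialist pathway for referred men
#'
#' Walks every man referred to urology through the second-level pathway:
#' urology visit outcome, MRI with sampled PI-RADS and prostate volume where
#' indicated, the PI-RADS x PSA-density biopsy decision, and a terminal
#' biopsy result flag where a biopsy is indicated. A man with a direct
#' high-risk MRI+biopsy indication undergoes MRI (for targeting) and then
#' biopsy regardless of the MRI decision table. "Consider biopsy" (negative
#' MRI, high density) is kept as its own terminal state and is not
#' auto-converted into a biopsy. PI-RADS scores of 3 or more also produce a
#' urologist-reassessment entry in the event log, mirroring protocol
#' practice.
#'
#' @param records a triaged participant table ([triage_table()]).
#' @param probs a [pathway_probabilities()].
#' @param seed optional integer seed for the pathway draws; if `NULL` the
#'   current RNG state is used.
#' @param thresholds protocol thresholds, see [protocol_defaults()].
#' @return A list with elements
#'   \describe{
#'     \item{records}{the input table with final `pathway_state`, `pirads`,
#'       `prostate_volume_cc` and `biopsy_result` filled in for referred
#'       men;}
#'     \item{events}{event log tibble (`participant_id`, `step`,
#'       `from_state`, `to_state`);}
#'     \item{summary}{named list of counts: referred, urology visits
#'       completed, refusals, MRIs performed, biopsies indicated, biopsies
#'       performed, positive biopsies, and the terminal-state table.}
#'   }
#' @export
run_pathway <- function(records, probs = pathway_probabilities(),
                        seed = NULL, thresholds = protocol_defaults()) {
  stopifnot(is.data.frame(records))
  if (!"risk_category" %in% names(records)) {
    stop("records must be triaged first (see triage_table())", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  idx <- which(!is.na(records$risk_category) &
                 records$risk_category == "REFER_UROLOGY")
  n_ref <- length(idx)
  events <- list()
  log_event <- function(ids, step, from, to) {
    if (length(ids) > 0) {
      events[[length(events) + 1L]] <<- tibble::tibble(
        participant_id = ids, step = step, from_state = from, to_state = to)
    }
  }

  if (n_ref > 0) {
    ref <- records[idx, ]
    ref$pathway_state <- "AWAITING_UROLOGY"
    out1 <- urology_outcome(ref, probs)
    log_event(ref$participant_id, 1L, "AWAITING_UROLOGY", out1)

    state <- out1
    needs_mri <- out1 %in% c("UROLOGY_MRI_INDICATED",
                             "UROLOGY_HIGH_RISK_MRI_BIOPSY")
    n_mri <- sum(needs_mri)
    pirads <- rep(NA_integer_, n_ref)
    volume <- rep(NA_real_, n_ref)
    biopsy <- ifelse(is.na(ref$biopsy_result), "not_done", ref$biopsy_result)

    if (n_mri > 0) {
      pirads[needs_mri] <- sample(1:5, n_mri, replace = TRUE,
                                  prob = probs$pirads_pmf)
      volume[needs_mri] <- rlnorm(n_mri, probs$volume_log_mu,
                                  probs$volume_log_sigma)
      density <- ref$psa_ng_ml[needs_mri] / volume[needs_mri]
      log_event(ref$participant_id[needs_mri], 2L, out1[needs_mri],
                "MRI_DONE")
      decision <- mri_decision(pirads[needs_mri], density, thresholds)
      # a direct high-risk indication proceeds to biopsy whatever the table says
      decision[out1[needs_mri] == "UROLOGY_HIGH_RISK_MRI_BIOPSY"] <-
        "BIOPSY_INDICATED"
      # suspicious scans go back past the urologist before the pathway continues
      reassess <- pirads[needs_mri] >= 3
      log_event(ref$participant_id[needs_mri][reassess], 3L, "MRI_DONE",
                "UROLOGY_REASSESSMENT")
      log_event(ref$participant_id[needs_mri], 4L, "MRI_DONE", decision)
      state[needs_mri] <- decision
    }

    to_biopsy <- state == "BIOPSY_INDICATED"
    if (any(to_biopsy)) {
      pos <- runif(sum(to_biopsy)) < probs$biopsy_positive_prob
      result <- ifelse(pos, "BIOPSY_POSITIVE", "BIOPSY_NEGATIVE")
      log_event(ref$participant_id[to_biopsy], 5L, "BIOPSY_INDICATED", result)
      biopsy[to_biopsy] <- ifelse(pos, "positive", "negative")
      state[to_biopsy] <- result
    }

    records$pathway_state[idx] <- state
    records$pirads[idx] <- pirads
    records$prostate_volume_cc[idx] <- volume
    records$biopsy_result[idx] <- biopsy

    term <- table(factor(state, levels = terminal_states))
    if (sum(term) != n_ref) {
      stop("internal error: pathway states do not partition referred men")
    }
    summary <- list(
      n_referred = n_ref,
      n_urology_visits = sum(out1 != "REFUSED"),
      n_refused = sum(out1 == "REFUSED"),
      n_mri = n_mri,
      n_biopsy_indicated = sum(needs_mri & state %in%
                                 c("BIOPSY_POSITIVE", "BIOPSY_NEGATIVE")),
      n_biopsy = sum(to_biopsy),
      n_biopsy_positive = sum(state == "BIOPSY_POSITIVE"),
      terminal_counts = term
    )
  } else {
    summary <- list(
      n_referred = 0L, n_urology_visits = 0L, n_refused = 0L, n_mri = 0L,
      n_biopsy_indicated = 0L, n_biopsy = 0L, n_biopsy_positive = 0L,
      terminal_counts = table(factor(character(), levels = terminal_states))
    )
  }

  events <- if (length(events) > 0) {
    dplyr::bind_rows(events)
  } else {
    tibble::tibble(participant_id = character(), step = integer(),
                   from_state = character(), to_state = character())
  }
  list(records = records, events = events, summary = summary)
}

#' Write a pathway event log as delimited text
#'
#' @param events event tibble from [run_pathway()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  write.csv(events, path, row.names = FALSE, na = "")
  invisible(path)
}
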