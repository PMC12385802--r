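#' Event counts for one comparison arm
#'
#' Fractional event counts are allowed: utilization figures may be adjusted
#' pro-rata (e.g. scaled to the share of screening episodes completed), so
#' an arm can legitimately carry 16.8 events.
#'
#' @param events non-negative event count, fractional allowed.
#' @param denominator positive number of units at risk (e.g. PSA tests).
#' @return A list of class `arm_counts`.
#' @export
#' @examples
#' arm_counts(261, 1412)
arm_counts <- function(events, denominator) {
  stopifnot(is.numeric(events), is.numeric(denominator),
            length(events) == 1L, length(denominator) == 1L)
  if (denominator <= 0) stop("`denominator` must be positive", call. = FALSE)
  if (events < 0 || events > denominator) {
    stop("`events` must lie in [0, denominator]", call. = FALSE)
  }
  structure(list(events = events, denominator = denominator),
            class = "arm_counts")
}

#' Compare two utilization proportions (Wald interval)
#'
#' Absolute difference of two independent proportions with the unpooled
#' Wald (normal-approximation) confidence interval and no continuity
#' correction:
#' \deqn{\hat p_1 - \hat p_2 \; \pm \; z \sqrt{\hat p_1 (1-\hat p_1)/n_1 +
#'   \hat p_2 (1-\hat p_2)/n_2}.}
#' Percentages are reported half-up to two decimals. The relative reduction
#' of arm 2 versus arm 1 is included when arm 1 has any events.
#'
#' @param arm1,arm2 [arm_counts()] objects (reference arm first, e.g.
#'   standard care vs screening).
#' @param z normal critical value (default 1.96 for a 95\% interval; `z = 0`
#'   collapses the interval onto the point estimate).
#' @return A one-row tibble: `p1_pct`, `p2_pct`, `abs_diff_pct`,
#'   `ci_low_pct`, `ci_high_pct` (all half-up to two decimals) and
#'   `rel_reduction_pct` (nearest integer, `NA` when arm 1 has no events).
#' @export
#' @examples
#' compare_proportions(arm_counts(312, 16933), arm_counts(16.8, 1412))
compare_proportions <- function(arm1, arm2, z = 1.96) {
  stopifnot(inherits(arm1, "arm_counts"), inherits(arm2, "arm_counts"),
            is.numeric(z), length(z) == 1L, z >= 0)
  p1 <- arm1$events / arm1$denominator
  p2 <- arm2$events / arm2$denominator
  diff <- p1 - p2
  se <- sqrt(p1 * (1 - p1) / arm1$denominator +
               p2 * (1 - p2) / arm2$denominator)
  tibble::tibble(
    p1_pct = round_half_up(100 * p1, 2),
    p2_pct = round_half_up(100 * p2, 2),
    abs_diff_pct = round_half_up(100 * diff, 2),
    ci_low_pct = round_half_up(100 * (diff - z * se), 2),
    ci_high_pct = round_half_up(100 * (diff + z * se), 2),
    rel_reduction_pct = if (p1 > 0) round_half_up(100 * (1 - p2 / p1)) else
      NA_real_
  )
}

#' Relative reduction of a proportion
#'
#' `(1 - p2/p1) x 100`, the percent reduction of arm 2 relative to arm 1,
#' rounded half-up to the nearest integer.
#'
#' @inheritParams compare_proportions
#' @return A single percentage.
#' @export
#' @examples
#' relative_reduction(arm_counts(312, 16933), arm_counts(16.8, 1412)) # 35
relative_reduction <- function(arm1, arm2) {
  stopifnot(inherits(arm1, "arm_counts"), inherits(arm2, "arm_counts"))
  p1 <- arm1$events / arm1$denominator
  p2 <- arm2$events / arm2$denominator
  if (p1 <= 0) {
    stop("relative reduction is undefined when arm 1 has no events",
         call. = FALSE)
  }
  round_half_up(100 * (1 - p2 / p1))
}

#' Scale a raw event count by a completion fraction (approximate)
#'
#' When part of a screening cohort has not yet completed the pathway,
#' utilization counts observed so far understate full-cohort utilization.
#' This helper scales a raw count pro-rata, `events / completion_fraction`.
#' It is a crude linear adjustment — it assumes the pending part of the
#' cohort will behave like the completed part — and is intended only to
#' mirror how adjusted comparison inputs are constructed.
#'
#' @param events raw event count observed among completed episodes.
#' @param completion_fraction fraction of episodes completed, in (0, 1].
#' @return The adjusted (possibly fractional) count.
#' @export
adjust_events <- function(events, completion_fraction) {
  stopifnot(is.numeric(events), events >= 0)
  if (!is.numeric(completion_fraction) || completion_fraction <= 0 ||
      completion_fraction > 1) {
    stop("`completion_fraction` must lie in (0, 1]", call. = FALSE)
  }
  events / completion_fraction
}
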