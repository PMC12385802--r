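#' Define a cancer-yield projection scenario
#'
#' One row of the participation-scenario yield model. The number screened
#' can either be derived from an eligible population and a participation
#' rate (floored to a whole man) or supplied directly (as for the observed
#' pilot cohort).
#'
#' @param eligible_population men eligible for invitation (no recent PSA).
#' @param participation_rate fraction of the eligible population screened.
#' @param n_screened number screened, given directly; overrides the
#'   population x rate product.
#' @param incidence_per_100k_yr expected prostate cancer incidence, cases
#'   per 100,000 person-years.
#' @param interval_years length of one screening round, years.
#' @param test_sensitivity sensitivity of the screening episode (default
#'   0.87, the trial-based assumption).
#' @param label optional scenario label.
#' @return A list of class `projection_scenario`.
#' @export
#' @examples
#' projection_scenario(861163, 0.15, incidence_per_100k_yr = 97.6)
projection_scenario <- function(eligible_population = NULL,
                                participation_rate = NULL,
                                n_screened = NULL,
                                incidence_per_100k_yr,
                                interval_years = 2,
                                test_sensitivity = 0.87,
                                label = NULL) {
  if (is.null(n_screened)) {
    if (is.null(eligible_population) || is.null(participation_rate)) {
      stop(paste("supply either `n_screened` or both `eligible_population`",
                 "and `participation_rate`"), call. = FALSE)
    }
    assert_prob(participation_rate, "participation_rate")
    stopifnot(eligible_population >= 0)
    n_screened <- floor(eligible_population * participation_rate)
  }
  assert_prob(test_sensitivity, "test_sensitivity")
  stopifnot(n_screened >= 0, incidence_per_100k_yr >= 0, interval_years >= 0)
  structure(
    list(eligible_population = eligible_population,
         participation_rate = participation_rate,
         n_screened = as.numeric(n_screened),
         incidence_per_100k_yr = incidence_per_100k_yr,
         interval_years = interval_years,
         test_sensitivity = test_sensitivity,
         label = label),
    class = "projection_scenario"
  )
}

#' Project expected cancer yield for one scenario
#'
#' Closed-form expected screen-detected cancers over one round:
#' \deqn{E[\mathrm{cases}] = n_{\mathrm{screened}} \times
#'   \frac{\mathrm{incidence}}{100{,}000} \times \mathrm{interval} \times
#'   \mathrm{sensitivity},}
#' with yield per 1000 = expected cases / screened x 1000. The model is
#' linear in every factor, so yield per 1000 does not depend on the
#' population size. Reported cases and yield are rounded half-up to one
#' decimal; the unrounded expectation is returned alongside.
#'
#' @param scenario a [projection_scenario()].
#' @return A one-row tibble with `label`, `n_screened`, `expected_cases`,
#'   `yield_per_1000` (both half-up to one decimal) and
#'   `expected_cases_exact`.
#' @export
#' @examples
#' project_yield(projection_scenario(861163, 0.15,
#'                                   incidence_per_100k_yr = 97.6))
project_yield <- function(scenario) {
  stopifnot(inherits(scenario, "projection_scenario"))
  s <- scenario
  cases <- s$n_screened * (s$incidence_per_100k_yr / 1e5) *
    s$interval_years * s$test_sensitivity
  yield <- if (s$n_screened > 0) cases / s$n_screened * 1000 else 0
  tibble::tibble(
    label = s$label %||% NA_character_,
    n_screened = s$n_screened,
    expected_cases = round_half_up(cases, 1),
    yield_per_1000 = round_half_up(yield, 1),
    expected_cases_exact = cases
  )
}

#' Project a grid of scenarios
#'
#' Applies [project_yield()] to each scenario in order.
#'
#' @param scenarios list of [projection_scenario()] objects.
#' @return A tibble with one row per scenario (empty for an empty list).
#' @export
scenario_grid <- function(scenarios) {
  stopifnot(is.list(scenarios))
  if (length(scenarios) == 0L) {
    return(tibble::tibble(label = character(), n_screened = double(),
                          expected_cases = double(), yield_per_1000 = double(),
                          expected_cases_exact = double()))
  }
  dplyr::bind_rows(lapply(scenarios, project_yield))
}
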