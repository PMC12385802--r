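#' Calibrate the log-normal PSA distribution from two category fractions
#'
#' Population PSA at a fixed age is well described by a log-normal law. The
#' screening protocol only reports the fractions of men below the two
#' clinical thresholds (1.0 and 3.0 ng/mL), which is exactly enough to pin
#' down the two parameters: writing F for the log-normal CDF, the system
#' \deqn{F(1) = f_1, \quad F(3) = f_3}
#' becomes linear in \eqn{(\mu, \sigma)} after probit transformation,
#' \deqn{\sigma = \log 3 / (\Phi^{-1}(f_3) - \Phi^{-1}(f_1)), \qquad
#'       \mu = -\sigma \, \Phi^{-1}(f_1),}
#' using \eqn{\log 1 = 0}. The solution is unique whenever
#' `0 < frac_below_1 < frac_below_3 < 1`.
#'
#' @param frac_below_1 fraction of men with PSA below 1.0 ng/mL.
#' @param frac_below_3 fraction of men with PSA below 3.0 ng/mL; must exceed
#'   `frac_below_1`.
#' @return A named list with elements `psa_log_mu` and `psa_log_sigma`
#'   (location and scale of log-PSA, PSA in ng/mL).
#' @export
#' @examples
#' # calibration to the Lombardy pilot's FH-negative stratification
#' calibrate_psa_distribution(824 / 1217, 1188 / 1217)
calibrate_psa_distribution <- function(frac_below_1, frac_below_3) {
  assert_prob(frac_below_1, "frac_below_1")
  assert_prob(frac_below_3, "frac_below_3")
  if (frac_below_1 <= 0 || frac_below_3 >= 1 || frac_below_1 >= frac_below_3) {
    stop("calibration requires 0 < frac_below_1 < frac_below_3 < 1",
         call. = FALSE)
  }
  z1 <- qnorm(frac_below_1)
  z3 <- qnorm(frac_below_3)
  sigma <- log(3) / (z3 - z1)
  mu <- -sigma * z1
  list(psa_log_mu = mu, psa_log_sigma = sigma)
}
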