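#' Round half away from zero
#'
#' Commercial ("half-up") rounding: exact halves move away from zero, so
#' 58.35 -> 58.4 at one decimal. Used for every reported percentage so that
#' printed tables match the programme's reporting convention; `base::round()`
#' rounds halves to even and would disagree on boundary values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
#' @examples
#' round_half_up(2.5)       # 3, where round(2.5) is 2
#' round_half_up(58.35, 1)  # 58.4
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  scale <- 10^digits
  # small epsilon guards values like 2.675 whose binary form sits a hair
  # below the decimal half
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# percentage of a count over a denominator, half-up to one decimal;
# 0/0 is reported as 0 (a programme with no activity has zero rates)
pct1 <- function(num, den) {
  if (den == 0) return(0)
  round_half_up(100 * num / den, 1)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
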