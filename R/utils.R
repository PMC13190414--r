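# Time-unit conventions used throughout the package.
# Survival curves are fitted and evaluated on a month axis; one month is
# 365.25/12 days.  Discounting and mortality conversions use a 365-day year
# (the "28-day probability" convention of the background-mortality source).
DAYS_PER_MONTH <- 365.25 / 12
DAYS_PER_YEAR <- 365.25
GIDWANI_YEAR_DAYS <- 365

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Convert an annual probability to a per-cycle probability
#'
#' Converts through the rate scale (Gidwani method): the annual probability
#' is turned into a constant hazard \eqn{r = -\log(1 - p)}, which is then
#' rescaled to the cycle length, \eqn{p_c = 1 - \exp(-r\,d/365)} for a cycle
#' of \eqn{d} days.  Used to put the background (all-cause) annual mortality
#' on the 28-day model cycle.
#'
#' @param annual_prob annual probability, in `[0, 1)`.
#' @param cycle_days cycle length in days (integer, `>= 1`).
#' @return per-cycle probability.
#' @examples
#' annual_to_cycle_prob(0.00804, 28)
#' @export
annual_to_cycle_prob <- function(annual_prob, cycle_days) {
  if (any(annual_prob < 0 | annual_prob >= 1))
    stop_config("annual_prob must be in [0, 1); got %s", annual_prob[1])
  if (any(cycle_days < 1))
    stop_config("cycle_days must be >= 1")
  rate <- -log(1 - annual_prob)
  1 - exp(-rate * cycle_days / GIDWANI_YEAR_DAYS)
}
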