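# Parametric survival distributions.
#
# Seven families are supported, parameterized as the field's survival
# packages print them (shape/scale for the log-logistic, meanlog/sdlog for
# the log-normal, shape/rate for the proportional-hazards Weibull, and the
# three-parameter (mu, sigma, Q) generalized gamma).  Evaluation goes
# through the corresponding stats/flexsurv survival functions.

.family_info <- list(
  exponential = list(params = c("rate"),            positive = c(TRUE)),
  weibull_ph  = list(params = c("shape", "rate"),   positive = c(TRUE, TRUE)),
  gompertz    = list(params = c("shape", "rate"),   positive = c(FALSE, TRUE)),
  loglogistic = list(params = c("shape", "scale"),  positive = c(TRUE, TRUE)),
  lognormal   = list(params = c("meanlog", "sdlog"), positive = c(FALSE, TRUE)),
  gamma       = list(params = c("shape", "rate"),   positive = c(TRUE, TRUE)),
  gengamma    = list(params = c("mu", "sigma", "Q"), positive = c(FALSE, TRUE, FALSE))
)

#' Parametric survival distribution
#'
#' Constructs a validated survival distribution on a month time axis.
#' Families and their parameters (in order):
#' \describe{
#'   \item{exponential}{`rate`; \eqn{S(t) = e^{-rt}}}
#'   \item{weibull_ph}{`shape`, `rate`; \eqn{S(t) = e^{-r t^{k}}}
#'     (proportional-hazards form)}
#'   \item{gompertz}{`shape`, `rate` (flexsurv parameterization)}
#'   \item{loglogistic}{`shape`, `scale`;
#'     \eqn{S(t) = 1/(1 + (t/\sigma)^{k})}; the median equals `scale`}
#'   \item{lognormal}{`meanlog`, `sdlog`;
#'     \eqn{S(t) = 1 - \Phi((\log t - \mu)/\sigma)}}
#'   \item{gamma}{`shape`, `rate`}
#'   \item{gengamma}{`mu`, `sigma`, `Q` (three-parameter generalized gamma)}
#' }
#'
#' @param family one of `"exponential"`, `"weibull_ph"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`, `"gamma"`, `"gengamma"`.
#' @param ... the family's parameters, positionally or by name.
#' @return an object of class `surv_dist`.
#' @examples
#' surv_dist("loglogistic", shape = 1.538, scale = 27.354)
#' surv_dist("weibull_ph", shape = 1.599, rate = 0.007)
#' @export
surv_dist <- function(family, ...) {
  family <- match.arg(family, names(.family_info))
  info <- .family_info[[family]]
  dots <- list(...)
  if (length(dots) != length(info$params))
    stop_config("%s needs %d parameter(s): %s", family,
                length(info$params), paste(info$params, collapse = ", "))
  if (is.null(names(dots)) || all(names(dots) == "")) {
    names(dots) <- info$params
  } else if (!setequal(names(dots), info$params)) {
    stop_config("%s parameters must be named %s", family,
                paste(info$params, collapse = ", "))
  }
  pars <- vapply(info$params, function(p) as.numeric(dots[[p]]), numeric(1))
  bad <- info$positive & !(pars > 0)
  if (any(bad) || any(!is.finite(pars)))
    stop_config("invalid %s parameter(s): %s", family,
                paste(sprintf("%s=%g", info$params, pars), collapse = ", "))
  structure(list(family = family, pars = pars), class = "surv_dist")
}

#' @export
print.surv_dist <- function(x, ...) {
  cat("<surv_dist> ", x$family, "(",
      paste(sprintf("%s = %g", names(x$pars), x$pars), collapse = ", "),
      ")  [time in months]\n", sep = "")
  invisible(x)
}

#' Survival probability
#'
#' Evaluates \eqn{S(t)} for a [surv_dist] at times `t` (months).
#'
#' @param dist a [surv_dist].
#' @param t vector of non-negative times, months.
#' @return vector of survival probabilities in `[0, 1]`.
#' @examples
#' os <- surv_dist("loglogistic", 1.538, 27.354)
#' surv_prob(os, c(0, 27.354))  # 1 and 0.5 (median = scale)
#' @export
surv_prob <- function(dist, t) {
  stopifnot(inherits(dist, "surv_dist"))
  if (any(t < 0)) stop_config("t must be >= 0")
  p <- dist$pars
  switch(dist$family,
    exponential = stats::pexp(t, rate = p[["rate"]], lower.tail = FALSE),
    weibull_ph  = flexsurv::pweibullPH(t, shape = p[["shape"]],
                                       scale = p[["rate"]], lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p[["shape"]],
                                      rate = p[["rate"]], lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p[["shape"]],
                                    scale = p[["scale"]], lower.tail = FALSE),
    lognormal   = stats::plnorm(t, meanlog = p[["meanlog"]],
                                sdlog = p[["sdlog"]], lower.tail = FALSE),
    gamma       = stats::pgamma(t, shape = p[["shape"]],
                                rate = p[["rate"]], lower.tail = FALSE),
    gengamma    = flexsurv::pgengamma(t, mu = p[["mu"]], sigma = p[["sigma"]],
                                      Q = p[["Q"]], lower.tail = FALSE)
  )
}

# quantile (inverse survival), used by the synthetic-data generator
surv_quantile <- function(dist, u) {
  p <- dist$pars
  switch(dist$family,
    exponential = stats::qexp(u, rate = p[["rate"]], lower.tail = FALSE),
    weibull_ph  = flexsurv::qweibullPH(u, shape = p[["shape"]],
                                       scale = p[["rate"]], lower.tail = FALSE),
    gompertz    = flexsurv::qgompertz(u, shape = p[["shape"]],
                                      rate = p[["rate"]], lower.tail = FALSE),
    loglogistic = flexsurv::qllogis(u, shape = p[["shape"]],
                                    scale = p[["scale"]], lower.tail = FALSE),
    lognormal   = stats::qlnorm(u, meanlog = p[["meanlog"]],
                                sdlog = p[["sdlog"]], lower.tail = FALSE),
    gamma       = stats::qgamma(u, shape = p[["shape"]],
                                rate = p[["rate"]], lower.tail = FALSE),
    gengamma    = flexsurv::qgengamma(u, mu = p[["mu"]], sigma = p[["sigma"]],
                                      Q = p[["Q"]], lower.tail = FALSE)
  )
}

#' Interval transition probability from a survival curve
#'
#' The conditional probability of leaving the curve's state during
#' `(t, t + delta]` given occupancy at `t`:
#' \eqn{1 - S(t+\delta)/S(t)}.  When \eqn{S(t) = 0} the state is exhausted
#' and the probability is returned as 1 with a warning.
#'
#' @param dist a [surv_dist].
#' @param t start of the interval, months.
#' @param delta interval width, months (`> 0`).
#' @return probability in `[0, 1]`.
#' @export
interval_trans_prob <- function(dist, t, delta) {
  if (any(delta <= 0)) stop_config("delta must be > 0")
  s0 <- surv_prob(dist, t)
  s1 <- surv_prob(dist, t + delta)
  out <- ifelse(s0 > 0, 1 - s1 / s0, 1)
  if (any(s0 == 0))
    warning("S(t) = 0: absorbing tail, transition probability set to 1")
  clamp01(out)
}
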