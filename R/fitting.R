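# Maximum-likelihood fitting of the parametric families to right-censored
# IPD, and information-criterion model selection.  Fitting is delegated to
# flexsurv::flexsurvreg; results are mapped back onto surv_dist objects.

.flexsurv_dist <- c(exponential = "exp", weibull_ph = "weibullPH",
                    gompertz = "gompertz", loglogistic = "llogis",
                    lognormal = "lnorm", gamma = "gamma", gengamma = "gengamma")

# flexsurv parameter name -> our parameter name, per family
.par_map <- list(
  exponential = c(rate = "rate"),
  weibull_ph  = c(shape = "shape", scale = "rate"),
  gompertz    = c(shape = "shape", rate = "rate"),
  loglogistic = c(shape = "shape", scale = "scale"),
  lognormal   = c(meanlog = "meanlog", sdlog = "sdlog"),
  gamma       = c(shape = "shape", rate = "rate"),
  gengamma    = c(mu = "mu", sigma = "sigma", Q = "Q")
)

#' Fit a parametric survival family to right-censored data
#'
#' Maximizes the right-censored log-likelihood
#' \eqn{\sum_i [\delta_i \log f(t_i) + (1-\delta_i)\log S(t_i)]} and returns
#' the fitted distribution together with its information criteria
#' (AIC \eqn{= -2\ell + 2k}; BIC \eqn{= -2\ell + k\log n}).
#'
#' @param time event/censoring times, months (`>= 0`).
#' @param event event indicator, 1 = event, 0 = censored.
#' @param family a family name accepted by [surv_dist()].
#' @return an object of class `parsurv_fit` with elements `dist`
#'   (a [surv_dist]), `loglik`, `aic`, `bic`, `k`, `n`, `family`.
#' @seealso [fit_parsurv_all()], [select_best_fit()]
#' @export
fit_parsurv <- function(time, event, family) {
  family <- match.arg(family, names(.family_info))
  if (length(time) != length(event)) stop_config("time/event length mismatch")
  if (any(time < 0)) stop_config("times must be >= 0")
  if (!all(event %in% c(0, 1))) stop_config("event must be 0/1")
  if (sum(event) < 2)
    stop("fitting requires at least 2 events", call. = FALSE)
  fs <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                          dist = .flexsurv_dist[[family]]),
    error = function(e) stop(sprintf(
      "parametric fit (%s) failed to converge: %s", family, conditionMessage(e)),
      call. = FALSE))
  est <- stats::setNames(fs$res[, "est"], rownames(fs$res))
  map <- .par_map[[family]]
  pars <- as.list(est[names(map)])
  names(pars) <- unname(map)
  dist <- do.call(surv_dist, c(list(family = family), pars))
  k <- fs$npars
  n <- length(time)
  structure(list(dist = dist, loglik = fs$loglik,
                 aic = -2 * fs$loglik + 2 * k,
                 bic = -2 * fs$loglik + k * log(n),
                 k = k, n = n, family = family),
            class = "parsurv_fit")
}

#' @export
print.parsurv_fit <- function(x, ...) {
  print(x$dist)
  cat(sprintf("  n = %d, logLik = %.3f, AIC = %.3f, BIC = %.3f\n",
              x$n, x$loglik, x$aic, x$bic))
  invisible(x)
}

#' @export
logLik.parsurv_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
AIC.parsurv_fit <- function(object, ..., k = 2) object$aic

#' @export
BIC.parsurv_fit <- function(object, ...) object$bic

#' Fit all (or several) candidate families to one dataset
#'
#' @inheritParams fit_parsurv
#' @param families character vector of family names (default: all seven).
#' @return a named list of `parsurv_fit` objects; families that fail to
#'   converge are dropped with a warning.
#' @export
fit_parsurv_all <- function(time, event,
                            families = names(.family_info)) {
  fits <- list()
  for (f in families) {
    fit <- tryCatch(fit_parsurv(time, event, f), error = function(e) {
      warning(sprintf("%s: %s", f, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(fit)) fits[[f]] <- fit
  }
  if (!length(fits)) stop("no candidate family could be fitted", call. = FALSE)
  fits
}

#' Select the best-fitting family by AIC (BIC tie-break)
#'
#' Returns the fit with the lowest AIC.  Exact AIC ties are broken by the
#' lower BIC.  If the AIC winner and the BIC winner disagree, the
#' disagreement is reported as a message (AIC governs).
#'
#' @param fits a non-empty list of `parsurv_fit` objects fitted to the same
#'   data.
#' @return the selected `parsurv_fit`.
#' @export
select_best_fit <- function(fits) {
  if (!length(fits)) stop_config("empty fit collection")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  bic <- vapply(fits, function(f) f$bic, numeric(1))
  best_aic <- which(aic == min(aic))
  winner <- if (length(best_aic) > 1) best_aic[which.min(bic[best_aic])] else best_aic
  if (which.min(bic) != winner)
    message(sprintf("AIC and BIC disagree (AIC: %s, BIC: %s); AIC governs",
                    names(fits)[winner] %||% winner,
                    names(fits)[which.min(bic)] %||% which.min(bic)))
  fits[[winner]]
}

#' Fit-report table (family x criteria)
#'
#' @param fits list of `parsurv_fit`, e.g. from [fit_parsurv_all()].
#' @param endpoint,arm optional labels attached to every row.
#' @return data.frame with columns arm, endpoint, family, loglik, aic, bic.
#' @export
fit_report <- function(fits, endpoint = NA_character_, arm = NA_character_) {
  data.frame(
    arm = arm, endpoint = endpoint,
    family = vapply(fits, function(f) f$family, character(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    row.names = NULL)
}

#' Read / write IPD as CSV (columns time, event)
#'
#' @param path file path.
#' @return `read_ipd`: data.frame with columns `time` (months) and `event`
#'   (0/1).
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "event") %in% names(d)))
    stop_config("IPD csv must have columns time,event")
  if (any(d$time < 0) || !all(d$event %in% c(0, 1)))
    stop_config("invalid IPD: times must be >= 0 and event 0/1")
  d[c("time", "event")]
}

#' @rdname read_ipd
#' @param ipd data.frame with columns time, event.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(ipd[c("time", "event")], path, row.names = FALSE)
  invisible(path)
}
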