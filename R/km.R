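# Kaplan-Meier estimation and Guyot-style reconstruction of pseudo
# individual-patient data from digitized step-function coordinates plus
# numbers at risk.  The reconstruction inverts the product-limit
# construction interval by interval, adjusting censoring counts until the
# running number at risk matches the published risk table.

#' Kaplan-Meier estimate as a digitized-curve data frame
#'
#' Product-limit estimator (via [survival::survfit()]) returned as a
#' right-continuous step function starting at (0, 1).
#'
#' @param time,event right-censored data (months, 0/1).
#' @return data.frame of class `km_curve` with columns `time`, `survival`,
#'   `n_risk`, `n_event`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop_config("empty data")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  d <- data.frame(time = c(0, fit$time), survival = c(1, fit$surv),
                  n_risk = c(fit$n, fit$n.risk),
                  n_event = c(0, fit$n.event))
  class(d) <- c("km_curve", "data.frame")
  d
}

#' Survival probability of a step function at arbitrary times
#'
#' @param curve data.frame with columns `time`, `survival` (right-continuous
#'   steps).
#' @param t times at which to evaluate.
#' @return survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  sf <- stats::stepfun(curve$time[-1], curve$survival, right = FALSE)
  sf(t)
}

validate_digitized <- function(curve, risk) {
  problems <- character()
  if (curve$time[1] != 0 || abs(curve$survival[1] - 1) > 1e-9)
    problems <- c(problems, "curve must start at (0, 1)")
  if (is.unsorted(curve$time, strictly = TRUE))
    problems <- c(problems, "curve times must be strictly increasing")
  rising <- which(diff(curve$survival) > 1e-9)
  if (length(rising))
    problems <- c(problems, paste("survival rises at curve rows:",
                                  paste(rising + 1, collapse = ",")))
  inc <- which(diff(risk$n_risk) > 0)
  if (length(inc))
    problems <- c(problems, paste("n_risk increases at risk rows:",
                                  paste(inc + 1, collapse = ",")))
  if (any(risk$n_risk < 0)) problems <- c(problems, "negative n_risk")
  if (nrow(risk) < 2) problems <- c(problems, "risk table needs >= 2 rows")
  problems
}

#' Reconstruct pseudo-IPD from a digitized KM curve and a risk table
#'
#' Within each risk-table interval the numbers of events and censorings
#' consistent with the digitized survival drops and the published numbers at
#' risk are solved for iteratively (censorings assumed uniform within the
#' interval), then individual event/censoring times are emitted at the
#' digitized coordinates.  Small digitization jitter (survival rising by
#' less than 0.005) is removed by an isotonic pass with a message; larger
#' inconsistencies are validation errors.
#'
#' @param curve data.frame with columns `time`, `survival`: the digitized
#'   coordinates, first point (0, 1).
#' @param risk data.frame with columns `time`, `n_risk`: numbers at risk.
#' @param total_events optional total event count; when supplied, event
#'   counts are proportionally rescaled in a final pass.
#' @return data.frame with columns `time`, `event`; exactly
#'   `risk$n_risk[1]` rows.
#' @references Guyot P et al. (2012) BMC Med Res Methodol 12:9.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  curve <- as.data.frame(curve)[c("time", "survival")]
  risk <- as.data.frame(risk)[c("time", "n_risk")]
  jitter <- diff(curve$survival) > 1e-12
  if (any(jitter)) {
    if (max(diff(curve$survival)) > 0.005)
      stop_config("digitized survival rises by > 0.005 at rows %s",
                  paste(which(jitter) + 1, collapse = ","))
    message(sprintf("isotonic clamp applied to %d rising digitized point(s)",
                    sum(jitter)))
    curve$survival <- cummin(curve$survival)
  }
  problems <- validate_digitized(curve, risk)
  if (length(problems))
    stop_config("invalid digitized inputs:\n  %s",
                paste(problems, collapse = "\n  "))
  if (max(risk$time) > max(curve$time))
    risk <- risk[risk$time <= max(curve$time), , drop = FALSE]

  t_s <- curve$time; s <- curve$survival
  n_click <- length(t_s)
  # append a sentinel click point at the end of follow-up
  n_int <- nrow(risk)
  lower <- vapply(seq_len(n_int), function(i)
    which(t_s >= risk$time[i])[1], integer(1))
  upper <- c(lower[-1] - 1L, n_click)
  n_risk <- risk$n_risk

  d <- integer(n_click); cen <- integer(n_click)
  n_hat <- integer(n_click + 1); n_hat[1] <- n_risk[1]
  km_hat <- numeric(n_click); last_i <- 1L

  if (n_int > 1) {
    for (i in seq_len(n_int - 1)) {
      if (upper[i] < lower[i]) { n_risk[i + 1] <- min(n_risk[i + 1], n_hat[lower[i]]); next }
      s_lo <- s[lower[i]]; s_hi <- s[lower[i + 1]]
      n_censor <- round(n_hat[lower[i]] * (if (s_lo > 0) s_hi / s_lo else 1) -
                          n_risk[i + 1])
      repeat {
        if (n_censor <= 0) {
          cen[lower[i]:upper[i]] <- 0L
          n_censor <- 0
        } else {
          cen_t <- t_s[lower[i]] +
            seq_len(n_censor) * (t_s[lower[i + 1]] - t_s[lower[i]]) / (n_censor + 1)
          cen[lower[i]:upper[i]] <- graphics::hist(
            cen_t, breaks = t_s[lower[i]:lower[i + 1]], plot = FALSE)$counts
        }
        last <- last_i
        for (k in lower[i]:upper[i]) {
          if (k == 1) { d[k] <- 0L; km_hat[k] <- 1 }
          else {
            d[k] <- if (km_hat[last] > 0)
              round(n_hat[k] * (1 - s[k] / km_hat[last])) else 0L
            d[k] <- max(0L, min(d[k], n_hat[k]))
            km_hat[k] <- km_hat[last] * (1 - d[k] / max(n_hat[k], 1))
          }
          n_hat[k + 1] <- n_hat[k] - d[k] - cen[k]
          if (n_hat[k + 1] < 0) { cen[k] <- cen[k] + n_hat[k + 1]; n_hat[k + 1] <- 0L }
          if (d[k] != 0) last <- k
        }
        diff_risk <- n_hat[lower[i + 1]] - n_risk[i + 1]
        if (diff_risk == 0 || (diff_risk < 0 && n_censor <= 0)) break
        n_censor <- n_censor + diff_risk
      }
      if (n_hat[lower[i + 1]] < n_risk[i + 1]) n_risk[i + 1] <- n_hat[lower[i + 1]]
      last_i <- last
    }
  }
  # final interval: no censoring assumed before end of follow-up
  i <- n_int
  if (upper[i] >= lower[i]) {
    last <- last_i
    for (k in lower[i]:upper[i]) {
      if (k == 1) { d[k] <- 0L; km_hat[k] <- 1 }
      else {
        d[k] <- if (km_hat[last] > 0)
          round(n_hat[k] * (1 - s[k] / km_hat[last])) else 0L
        d[k] <- max(0L, min(d[k], n_hat[k]))
        km_hat[k] <- km_hat[last] * (1 - d[k] / max(n_hat[k], 1))
      }
      cen[k] <- 0L
      n_hat[k + 1] <- n_hat[k] - d[k]
      if (d[k] != 0) last <- k
    }
  }

  if (!is.null(total_events)) {
    tot <- sum(d)
    if (tot > 0 && tot != total_events) {
      scale <- total_events / tot
      d_new <- round(d * scale)
      # keep within availability
      for (k in seq_len(n_click)) {
        avail <- if (k == 1) 0L else n_hat[k]
        d_new[k] <- max(0L, min(d_new[k], avail))
      }
      d <- d_new
    }
  }

  # emit records: events at click times, censorings spread inside intervals
  times <- numeric(0); events <- integer(0)
  for (k in seq_len(n_click)) {
    if (d[k] > 0) { times <- c(times, rep(t_s[k], d[k])); events <- c(events, rep(1L, d[k])) }
    if (cen[k] > 0) {
      upper_t <- if (k < n_click) t_s[k + 1] else t_s[k]
      ct <- t_s[k] + seq_len(cen[k]) * (upper_t - t_s[k]) / (cen[k] + 1)
      times <- c(times, ct); events <- c(events, rep(0L, cen[k]))
    }
  }
  n_left <- n_risk[1] - length(times)
  if (n_left > 0) {  # still at risk at end of follow-up
    times <- c(times, rep(max(t_s), n_left)); events <- c(events, rep(0L, n_left))
  } else if (n_left < 0) {
    keep <- seq_len(n_risk[1])
    ord <- order(times); times <- times[ord][keep]; events <- events[ord][keep]
  }
  out <- data.frame(time = times, event = events)
  out[order(out$time), , drop = FALSE]
}

#' Read digitized-curve / risk-table CSVs
#'
#' @param path CSV path; digitized curves have columns `time,survival`,
#'   risk tables `time,n_risk`.
#' @return data.frame.
#' @export
read_digitized <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "survival") %in% names(d)))
    stop_config("digitized csv must have columns time,survival")
  d
}

#' @rdname read_digitized
#' @export
read_risk_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "n_risk") %in% names(d)))
    stop_config("risk table csv must have columns time,n_risk")
  d
}
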