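# Synthetic-data generation: simulated right-censored IPD from the
# parametric families, and digitized-curve fixtures (step-function
# coordinates + risk tables) for the reconstruction pipeline.  Defaults
# mirror the base-case fitted curves and the trial's per-arm sample size,
# so synthetic runs resemble the base case without claiming trial data.

#' Simulation specification for one arm
#'
#' @param pfs,os generating [surv_dist]s (defaults: the base-case sac-TMT
#'   curves).
#' @param n subjects per arm (default 188, one arm of a 376-patient 1:1
#'   trial).
#' @param cutoff_months administrative censoring time.
#' @param dropout_prob probability of random dropout; dropout times are
#'   uniform on (0, cutoff).
#' @param seed RNG seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(pfs = surv_dist("lognormal", meanlog = 2.20, sdlog = 0.999),
                     os = surv_dist("loglogistic", shape = 1.538, scale = 27.354),
                     n = 188, cutoff_months = 24, dropout_prob = 0.05,
                     seed = 1L) {
  if (n < 2) stop_config("n must be >= 2")
  if (cutoff_months <= 0) stop_config("cutoff must be > 0")
  if (dropout_prob < 0 || dropout_prob > 1) stop_config("dropout_prob in [0,1]")
  structure(list(pfs = pfs, os = os, n = n, cutoff_months = cutoff_months,
                 dropout_prob = dropout_prob, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate right-censored IPD for one arm
#'
#' Event times are drawn by inverse-CDF.  PFS and OS are comonotone (one
#' shared uniform rank per subject) and PFS is additionally capped at OS,
#' so no subject progresses after death.  Each subject is censored at the
#' earlier of the administrative cutoff and (with probability
#' `dropout_prob`) a uniform dropout time.
#'
#' @param spec a [sim_spec()].
#' @return list with data.frames `pfs` and `os`, each with columns `time`,
#'   `event`.
#' @export
simulate_ipd <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  u <- stats::runif(spec$n)
  t_os <- surv_quantile(spec$os, u)
  t_pfs <- pmin(surv_quantile(spec$pfs, u), t_os)
  cens <- rep(spec$cutoff_months, spec$n)
  drop <- stats::runif(spec$n) < spec$dropout_prob
  cens[drop] <- pmin(cens[drop], stats::runif(sum(drop), 0, spec$cutoff_months))
  mk <- function(t) data.frame(time = pmin(t, cens),
                               event = as.integer(t <= cens))
  list(pfs = mk(t_pfs), os = mk(t_os))
}

#' Build a digitized-curve fixture from IPD
#'
#' Computes the KM estimate, samples it on a time grid (emulating manual
#' curve digitization, with optional bounded jitter) and counts the exact
#' numbers at risk at the requested times.
#'
#' @param ipd data.frame with columns `time`, `event`.
#' @param grid_step_months digitization grid step; the grid runs from 0 to
#'   the last observed time.  Use `grid_times` to supply explicit times
#'   instead.
#' @param risk_times times for the number-at-risk table.
#' @param jitter_sd standard deviation of truncated (+/- 2 sd) Gaussian
#'   jitter added to the sampled survival values; 0 for exact sampling.
#' @param grid_times optional explicit digitization times (overrides
#'   `grid_step_months`).
#' @return list with `curve` (data.frame time, survival) and `risk`
#'   (data.frame time, n_risk).
#' @export
make_digitized_fixture <- function(ipd, grid_step_months = 0.5,
                                   risk_times = NULL, jitter_sd = 0,
                                   grid_times = NULL) {
  if (!nrow(ipd)) stop_config("empty data")
  km <- km_estimate(ipd$time, ipd$event)
  tmax <- max(ipd$time)
  tg <- grid_times %||% unique(c(seq(0, tmax, by = grid_step_months), tmax))
  sg <- km_survival_at(km, tg)
  if (jitter_sd > 0) {
    eps <- pmax(pmin(stats::rnorm(length(sg), 0, jitter_sd), 2 * jitter_sd),
                -2 * jitter_sd)
    eps[1] <- 0
    sg <- clamp01(sg + eps)
    sg <- cummin(sg)  # digitizers trace a non-increasing curve
  }
  risk_times <- risk_times %||% seq(0, tmax, length.out = 5)
  risk <- data.frame(time = risk_times,
                     n_risk = vapply(risk_times,
                                     function(t) sum(ipd$time >= t), numeric(1)))
  list(curve = data.frame(time = tg, survival = sg), risk = risk)
}
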