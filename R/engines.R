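# The two cohort engines.  Both produce the same cohort_trace: per-cycle
# occupancy of the three states plus discounted accruals, so that the
# economic layer is engine-agnostic.

# Shared accrual.  Membership over cycle k (interval t_{k-1} -> t_k) is the
# trapezoidal average of the endpoint shares ("half_cycle") or the
# start-of-cycle share ("start"); discounting is continuous-in-cycle at the
# interval midpoint.  One-off AE cost and disutility enter at model entry
# (cycle 0, undiscounted).
finalize_trace <- function(spec, strategy_name, shares, engine,
                           time_months = NULL, log = character()) {
  n <- nrow(shares) - 1
  dm <- cycle_months(spec); dy <- cycle_years(spec)
  tk <- (0:n) * dm
  u <- spec$utilities
  half <- spec$accrual == "half_cycle"
  m_pfs <- if (half) (shares$pfs[1:n] + shares$pfs[2:(n + 1)]) / 2 else shares$pfs[1:n]
  m_pd  <- if (half) (shares$pd[1:n] + shares$pd[2:(n + 1)]) / 2 else shares$pd[1:n]
  disc <- (1 + spec$discount_annual)^(-((1:n) - 0.5) * dm / 12)

  cost_pfs <- pfs_cost_schedule(spec, strategy_name)
  cost_pd <- pd_cycle_cost(spec, strategy_name)
  cost_cycle <- (m_pfs * cost_pfs + m_pd * cost_pd) * disc
  qaly_cycle <- (m_pfs * u$pfs + m_pd * u$pd) * dy * disc
  ly_cycle <- (m_pfs + m_pd) * dy * disc

  ae_cost <- ae_entry_cost(spec, strategy_name)
  ae_dis <- ae_entry_disutility(spec, strategy_name)
  ae_qaly_loss <- if (spec$ae_disutility_once) ae_dis else ae_dis * dy

  trace <- data.frame(
    cycle = 0:n,
    time_months = if (is.null(time_months)) tk else time_months,
    share_pfs = shares$pfs, share_pd = shares$pd, share_dead = shares$dead,
    cost_disc = c(ae_cost, cost_cycle),
    qaly_disc = c(-ae_qaly_loss, qaly_cycle),
    ly_disc = c(0, ly_cycle))
  structure(trace, class = c("cohort_trace", "data.frame"),
            strategy = strategy_name, engine = engine, log = log)
}

#' Totals of a cohort trace
#'
#' @param trace a `cohort_trace`.
#' @return list with `total_cost`, `total_qalys`, `total_lys` (all
#'   discounted).
#' @export
trace_totals <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  list(total_cost = sum(trace$cost_disc),
       total_qalys = sum(trace$qaly_disc),
       total_lys = sum(trace$ly_disc))
}

#' Partitioned survival model occupancy and accrual
#'
#' State shares are read directly off the curves: at each cycle boundary
#' `share_pfs = min(S_PFS, S_OS)`, `share_pd = max(0, S_OS - S_PFS)`,
#' `share_dead = 1 - S_OS`.  Cycles where the fitted PFS curve crosses
#' above the OS curve are capped at OS and counted in the trace's log
#' attribute.
#'
#' @param spec a `cea_spec`.
#' @param strategy_name strategy to run.
#' @return a `cohort_trace`.
#' @export
run_psm <- function(spec, strategy_name) {
  s <- spec$strategies[[strategy_name]]
  if (is.null(s)) stop_config("unknown strategy '%s'", strategy_name)
  n <- n_cycles(spec)
  tk <- (0:n) * cycle_months(spec)
  s_pfs <- surv_prob(s$pfs, tk)
  s_os <- surv_prob(s$os, tk)
  capped <- sum(s_pfs > s_os)
  log <- if (capped > 0)
    sprintf("PSM %s: PFS curve capped at OS in %d cycle(s)", strategy_name, capped)
    else character()
  shares <- data.frame(pfs = pmin(s_pfs, s_os),
                       pd = pmax(0, s_os - s_pfs),
                       dead = 1 - s_os)
  finalize_trace(spec, strategy_name, shares, "psm", log = log)
}

#' Time-dependent Markov transition schedule
#'
#' For cycle `k` over curve-time interval `(t_k, t_k + delta]`:
#' the PFS exit probability is `1 - S_PFS(t_k+delta)/S_PFS(t_k)`;
#' PFS to death is the background per-cycle mortality (capped at the exit
#' probability); PFS to PD takes the remainder.  PD to death closes the OS
#' curve: the deaths required to bring cumulative mortality to
#' `1 - S_OS(t_k+delta)`, net of deaths out of PFS, divided by the running
#' PD occupancy and clamped to `[0, 1]`.  When the PD state cannot absorb
#' the required deaths (notably the first cycles, when PD is still empty),
#' the overflow is allocated to PFS to death beyond the background floor,
#' capped at the total PFS exit probability; this keeps the cohort's death
#' share on the OS curve.  Negative requirements (background deaths
#' exceeding the OS curve's) clamp to zero; clamped and overflow cycles are
#' counted in the log.  The schedule depends on the cohort recursion and is
#' built alongside it.
#'
#' With `grid = "cycle"` the curves are read at integer cycle indices of
#' their month axis (one cycle treated as one month of curve time, the
#' convention of the original analysis); with `"calendar"` at the true
#' cycle length in months.
#'
#' @param spec a `cea_spec`.
#' @param strategy_name strategy to run.
#' @param grid overrides `spec$markov_grid` if given.
#' @return list with elements `schedule` (data.frame of per-cycle
#'   transition probabilities), `shares`, `log`.
#' @export
build_transition_schedule <- function(spec, strategy_name, grid = NULL) {
  s <- spec$strategies[[strategy_name]]
  if (is.null(s)) stop_config("unknown strategy '%s'", strategy_name)
  grid <- match.arg(grid %||% spec$markov_grid, c("cycle", "calendar"))
  n <- n_cycles(spec)
  f <- if (grid == "cycle") 1 else cycle_months(spec)
  p_bg <- annual_to_cycle_prob(spec$bg_annual_mortality, spec$cycle_days)

  occ <- c(pfs = 1, pd = 0, dead = 0)
  shares <- matrix(0, n + 1, 3, dimnames = list(NULL, c("pfs", "pd", "dead")))
  shares[1, ] <- occ
  sched <- matrix(0, n, 5, dimnames = list(NULL, c(
    "p_pfs_pd", "p_pfs_dead", "p_pfs_stay", "p_pd_dead", "p_pd_stay")))
  clamped <- 0L; overflowed <- 0L
  for (k in seq_len(n)) {
    t0 <- (k - 1) * f; t1 <- k * f
    s0 <- surv_prob(s$pfs, t0)
    p_exit <- if (s0 > 0) 1 - surv_prob(s$pfs, t1) / s0 else 1
    p_exit <- clamp01(p_exit)
    p_pfs_dead <- min(p_bg, p_exit)
    # deaths needed this cycle to keep cumulative mortality on the OS curve
    d_k <- (1 - surv_prob(s$os, t1)) - occ[["dead"]]
    need_pd <- d_k - occ[["pfs"]] * p_pfs_dead
    if (need_pd < 0) { clamped <- clamped + 1L; need_pd <- 0 }
    p_pd_dead <- if (occ[["pd"]] > 0) min(need_pd / occ[["pd"]], 1) else 0
    leftover <- need_pd - occ[["pd"]] * p_pd_dead
    if (leftover > 1e-15 && occ[["pfs"]] > 0) {
      overflowed <- overflowed + 1L
      p_pfs_dead <- min(p_exit, p_pfs_dead + leftover / occ[["pfs"]])
    }
    p_pfs_pd <- p_exit - p_pfs_dead
    sched[k, ] <- c(p_pfs_pd, p_pfs_dead, 1 - p_exit, p_pd_dead, 1 - p_pd_dead)
    occ <- c(pfs = occ[["pfs"]] * (1 - p_exit),
             pd = occ[["pfs"]] * p_pfs_pd + occ[["pd"]] * (1 - p_pd_dead),
             dead = occ[["dead"]] + occ[["pfs"]] * p_pfs_dead +
               occ[["pd"]] * p_pd_dead)
    shares[k + 1, ] <- occ
  }
  log <- c(
    if (clamped > 0)
      sprintf("Markov %s: PD->death requirement clamped at 0 in %d cycle(s)",
              strategy_name, clamped),
    if (overflowed > 0)
      sprintf("Markov %s: death overflow routed via PFS in %d cycle(s)",
              strategy_name, overflowed))
  list(schedule = data.frame(cycle = seq_len(n), curve_time = (seq_len(n) - 1) * f,
                             sched),
       shares = as.data.frame(shares), grid = grid, log = log)
}

#' Markov cohort model occupancy and accrual
#'
#' Runs the cohort recursion from (1, 0, 0) over the transition schedule of
#' [build_transition_schedule()] and accrues half-cycle-corrected outcomes,
#' producing the same `cohort_trace` type as [run_psm()].
#'
#' @inheritParams build_transition_schedule
#' @return a `cohort_trace`.
#' @export
run_markov <- function(spec, strategy_name, grid = NULL) {
  ts <- build_transition_schedule(spec, strategy_name, grid)
  finalize_trace(spec, strategy_name, ts$shares, "markov", log = ts$log)
}
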