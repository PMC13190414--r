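# The decision-problem specification: strategies (curves + economics),
# clock, horizon, discounting, thresholds, PSA settings.  The bundled
# base case encodes the published model inputs (2025 USD).

.spec_fields <- c("engine", "cycle_days", "horizon_years", "discount_annual",
                  "wtp", "bg_annual_mortality", "markov_grid", "accrual",
                  "ae_disutility_once", "vial_strategy", "patient", "prices",
                  "vial_strengths", "followup", "utilities", "ae",
                  "strategies", "comparator", "psa", "scenarios")

#' Build a cost-effectiveness model specification
#'
#' All arguments default to the bundled base case; see
#' [base_case_spec()] for the complete default set.  Validation rejects
#' out-of-range values (utilities outside `[0, 1]`, negative prices,
#' discount outside `[0, 0.08]`, unknown strategy fields).
#'
#' @param engine `"psm"`, `"markov"` or `"both"`.
#' @param cycle_days model cycle length in days.
#' @param horizon_years time horizon in years; the trace spans the last
#'   full cycle within the horizon.
#' @param discount_annual annual discount rate for costs and outcomes.
#' @param wtp willingness-to-pay threshold, USD/QALY.
#' @param bg_annual_mortality background (all-cause) annual mortality
#'   probability.
#' @param markov_grid `"cycle"` (transition probabilities read at integer
#'   cycle indices of the month-scaled curves) or `"calendar"` (read at the
#'   true cycle length in months).  See the methods vignette.
#' @param accrual `"half_cycle"` (trapezoidal state membership) or
#'   `"start"` (start-of-cycle membership).
#' @param ae_disutility_once if `TRUE`, the expected grade >= 3 AE
#'   disutility is applied as a one-off absolute QALY decrement at model
#'   entry; if `FALSE`, it is applied for exactly one cycle (scaled by cycle
#'   length).
#' @param vial_strategy `"exact"` (dose-proportional drug cost) or
#'   `"round_up"` (whole vials, no sharing).
#' @param patient list: `weight` (kg), `bsa` (m^2), `crcl` (mL/min).
#' @param prices,vial_strengths,followup,utilities,ae economic inputs; see
#'   [base_case_spec()].
#' @param strategies named list of strategies; each has `label`, `pfs` and
#'   `os` ([surv_dist]), `regimen` (`"sac"` or `"chemo"`), and `pd_mix`
#'   (weights `bsc`, `pem`, `osi` for the progressed-disease treatment mix).
#' @param comparator name of the reference strategy.
#' @param psa list: `n` iterations, `seed`.
#' @param scenarios optional named list of scenario definitions
#'   (`overrides`, `wtp_thresholds`).
#' @return object of class `cea_spec`.
#' @export
model_spec <- function(engine = "both",
                       cycle_days = 28,
                       horizon_years = 10,
                       discount_annual = 0.05,
                       wtp = 41811,
                       bg_annual_mortality = 0.00804,
                       markov_grid = "cycle",
                       accrual = "half_cycle",
                       ae_disutility_once = TRUE,
                       vial_strategy = "exact",
                       patient = list(weight = 65, bsa = 1.72, crcl = 70),
                       prices = .default_prices(),
                       vial_strengths = .default_vials(),
                       followup = .default_followup(),
                       utilities = list(pfs = 0.804, pd = 0.321),
                       ae = .default_ae(),
                       strategies = .default_strategies(),
                       comparator = "chemo",
                       psa = list(n = 1000, seed = 2026),
                       scenarios = list()) {
  spec <- list(engine = match.arg(engine, c("both", "psm", "markov")),
               cycle_days = cycle_days, horizon_years = horizon_years,
               discount_annual = discount_annual, wtp = wtp,
               bg_annual_mortality = bg_annual_mortality,
               markov_grid = match.arg(markov_grid, c("cycle", "calendar")),
               accrual = match.arg(accrual, c("half_cycle", "start")),
               ae_disutility_once = isTRUE(ae_disutility_once),
               vial_strategy = match.arg(vial_strategy, c("exact", "round_up")),
               patient = patient, prices = prices,
               vial_strengths = vial_strengths, followup = followup,
               utilities = utilities, ae = ae, strategies = strategies,
               comparator = comparator, psa = psa, scenarios = scenarios)
  class(spec) <- "cea_spec"
  validate_spec(spec)
  spec
}

.default_prices <- function() list(
  sac_vial = 1315.85, pem_vial = 65.52, carb_vial = 11.06, cis_vial = 1.71,
  osi_tab = 23.18, bsc_cycle = 436.19,
  ae = c(anemia = 448.56, leukopenia = 421.40, neutropenia = 406.56,
         thrombocytopenia = 2937.46))

.default_vials <- function() list(sac = 200, pem = 500, carb = 150, cis = 200)

.default_followup <- function() list(
  cbc = 2.10, biochem = 25.20, urinalysis = 2.52, ct = 11.20, mri = 70.00,
  nursing = 3.64, bed = 2.80, consult = 3.08, injection = 0.81, prep = 4.76,
  ct_every = 2, mri_every = 3)

.default_ae <- function() data.frame(
  name = c("anemia", "leukopenia", "neutropenia", "thrombocytopenia"),
  disutility = c(0.073, 0.200, 0.200, 0.190),
  inc_sac_tmt = c(0.110, 0.280, 0.400, 0.020),
  inc_chemo = c(0.140, 0.220, 0.330, 0.160))

# The chemotherapy arm's progressed-disease mix carries the committed
# calibration of the unprinted subsequent-treatment proportions (see the
# methods vignette); the sac-TMT arm uses best supportive care alone.
.default_strategies <- function() list(
  sac_tmt = list(
    label = "sac-TMT", regimen = "sac",
    pfs = surv_dist("lognormal", meanlog = 2.20, sdlog = 0.999),
    os = surv_dist("loglogistic", shape = 1.538, scale = 27.354),
    pd_mix = c(bsc = 1, pem = 0, osi = 0)),
  chemo = list(
    label = "Chemotherapy", regimen = "chemo",
    pfs = surv_dist("loglogistic", shape = 2.420, scale = 4.590),
    os = surv_dist("weibull_ph", shape = 1.599, rate = 0.007),
    pd_mix = c(bsc = 1, pem = 0, osi = 0.180)))

#' The bundled base-case specification
#'
#' @return a [model_spec()] with every input at its base-case value.
#' @export
base_case_spec <- function() model_spec()

validate_spec <- function(spec) {
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(spec$cycle_days >= 1, "cycle_days must be >= 1")
  chk(spec$horizon_years > 0, "horizon_years must be > 0")
  chk(spec$discount_annual >= 0 && spec$discount_annual <= 0.08,
      "discount_annual must lie in [0, 0.08]")
  chk(spec$wtp > 0, "wtp must be > 0")
  chk(spec$bg_annual_mortality >= 0 && spec$bg_annual_mortality < 1,
      "bg_annual_mortality must be in [0, 1)")
  u <- unlist(spec$utilities)
  chk(all(u >= 0 & u <= 1), "utilities must lie in [0, 1]")
  chk(all(unlist(spec$patient) > 0), "patient characteristics must be > 0")
  chk(all(unlist(spec$prices) >= 0), "prices must be >= 0")
  chk(all(unlist(spec$vial_strengths) > 0), "vial strengths must be > 0")
  ae <- spec$ae
  chk(all(ae$disutility >= 0), "ae disutilities are stored as magnitudes (>= 0)")
  chk(all(ae$inc_sac_tmt >= 0 & ae$inc_sac_tmt <= 1) &&
      all(ae$inc_chemo >= 0 & ae$inc_chemo <= 1),
      "ae incidences must lie in [0, 1]")
  chk(spec$comparator %in% names(spec$strategies),
      "comparator must name a strategy")
  for (nm in names(spec$strategies)) {
    s <- spec$strategies[[nm]]
    chk(inherits(s$pfs, "surv_dist") && inherits(s$os, "surv_dist"),
        sprintf("strategy %s: pfs/os must be surv_dist", nm))
    chk(s$regimen %in% c("sac", "chemo"),
        sprintf("strategy %s: unknown regimen '%s'", nm, s$regimen))
    chk(all(s$pd_mix >= 0) && all(c("bsc", "pem", "osi") %in% names(s$pd_mix)),
        sprintf("strategy %s: pd_mix needs non-negative bsc/pem/osi weights", nm))
  }
  chk(spec$psa$n >= 1, "psa$n must be >= 1")
  if (length(errs))
    stop_config("invalid model spec:\n  %s", paste(errs, collapse = "\n  "))
  invisible(spec)
}

n_cycles <- function(spec)
  as.integer(spec$horizon_years * DAYS_PER_YEAR / spec$cycle_days)

cycle_months <- function(spec) spec$cycle_days / DAYS_PER_MONTH
cycle_years <- function(spec) spec$cycle_days / DAYS_PER_YEAR

#' @export
print.cea_spec <- function(x, ...) {
  cat("<cea_spec>\n")
  cat(sprintf("  engine: %s | cycle: %d days | horizon: %g years (%d cycles)\n",
              x$engine, x$cycle_days, x$horizon_years, n_cycles(x)))
  cat(sprintf("  discount: %g%%/yr | WTP: %s USD/QALY\n",
              100 * x$discount_annual, format(x$wtp, big.mark = ",")))
  cat(sprintf("  strategies: %s (comparator: %s)\n",
              paste(names(x$strategies), collapse = ", "), x$comparator))
  invisible(x)
}

#' Load a model specification from a YAML file
#'
#' The file may set any subset of [model_spec()]'s fields; unset fields take
#' their base-case defaults.  Unknown keys are rejected with their location.
#' Survival curves are written as `{family: ..., <param>: ...}` maps.
#'
#' @param path YAML file path.
#' @return a validated `cea_spec`.
#' @export
load_model_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .spec_fields)
  if (length(unknown))
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (!is.null(raw$strategies)) {
    raw$strategies <- lapply(raw$strategies, function(s) {
      for (ep in c("pfs", "os")) {
        d <- s[[ep]]
        if (is.null(d$family)) stop_config("strategy curve missing 'family'")
        s[[ep]] <- do.call(surv_dist,
                           c(list(family = d$family), d[names(d) != "family"]))
      }
      s$pd_mix <- unlist(s$pd_mix)
      s
    })
  }
  if (!is.null(raw$ae)) raw$ae <- as.data.frame(raw$ae)
  if (!is.null(raw$prices) && !is.null(raw$prices$ae))
    raw$prices$ae <- unlist(raw$prices$ae)
  do.call(model_spec, raw)
}
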