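# Cost and utility accrual: dosing and vial arithmetic, per-cycle state
# costs, one-off adverse-event costs and disutilities, and the ICER.

#' Cost of one drug administration
#'
#' Computes the administered dose from the dosing rule and patient profile,
#' then the acquisition cost.  With `vial_strategy = "round_up"` the number
#' of vials is `ceiling(dose/strength)` (no vial sharing); with `"exact"`
#' the cost is dose-proportional (`dose/strength` units).
#' Carboplatin is dosed by the Calvert formula, AUC x (CrCl + 25).
#'
#' @param dose_mg administered dose in mg.
#' @param vial_mg vial strength in mg.
#' @param unit_price price per vial, USD.
#' @param vial_strategy `"exact"` or `"round_up"`.
#' @return cost per administration, USD.
#' @examples
#' drug_admin_cost(5 * 65, 200, 1315.85, "round_up")  # 2 vials, 2631.70
#' @export
drug_admin_cost <- function(dose_mg, vial_mg, unit_price,
                            vial_strategy = c("exact", "round_up")) {
  vial_strategy <- match.arg(vial_strategy)
  if (dose_mg < 0 || vial_mg <= 0) stop_config("invalid dose/vial strength")
  units <- switch(vial_strategy, exact = dose_mg / vial_mg,
                  round_up = ceiling(dose_mg / vial_mg))
  units * unit_price
}

#' Calvert-formula carboplatin dose
#'
#' @param auc target AUC (mg/mL*min).
#' @param crcl creatinine clearance (mL/min), used as the GFR estimate.
#' @return dose in mg: `auc * (crcl + 25)`.
#' @export
calvert_dose <- function(auc, crcl) auc * (crcl + 25)

# follow-up bundle cost per model cycle, given administrations per cycle.
# Per-cycle: 1 consultation + CBC + biochemistry + urinalysis; CT every
# `ct_every` cycles, MRI every `mri_every` (accrued as per-cycle averages);
# per administration: injection + preparation fees, 1 nursing + 1 bed day.
followup_cycle_cost <- function(fu, admins_per_cycle) {
  fu$consult + fu$cbc + fu$biochem + fu$urinalysis +
    fu$ct / fu$ct_every + fu$mri / fu$mri_every +
    admins_per_cycle * (fu$injection + fu$prep + fu$nursing + fu$bed)
}

# Per-cycle progression-free treatment cost schedule for a strategy.
# sac regimen: 5 mg/kg on days 1 and 15 of each 28-day cycle (2
# administrations per model cycle).  chemo regimen: pemetrexed 500 mg/m^2 +
# carboplatin AUC 5 on day 1 of each 21-day cycle, converted to a daily
# rate and accrued per model cycle; 4 induction cycles (84 days), then
# pemetrexed maintenance.  Drug costs accrue only while progression-free.
pfs_cost_schedule <- function(spec, strategy_name) {
  s <- spec$strategies[[strategy_name]]
  p <- spec$prices; v <- spec$vial_strengths; pt <- spec$patient
  n <- n_cycles(spec)
  if (s$regimen == "sac") {
    per_admin <- drug_admin_cost(5 * pt$weight, v$sac, p$sac_vial,
                                 spec$vial_strategy)
    admins <- 2 * (spec$cycle_days / 28)
    drug <- rep(per_admin * admins, n)
  } else {
    pem <- drug_admin_cost(500 * pt$bsa, v$pem, p$pem_vial, spec$vial_strategy)
    carb <- drug_admin_cost(calvert_dose(5, pt$crcl), v$carb, p$carb_vial,
                            spec$vial_strategy)
    induction_daily <- (pem + carb) / 21
    maint_daily <- pem / 21
    day_end <- seq_len(n) * spec$cycle_days
    induction_days <- pmax(0, pmin(day_end, 84) - (day_end - spec$cycle_days))
    drug <- induction_daily * induction_days +
      maint_daily * (spec$cycle_days - induction_days)
    admins <- spec$cycle_days / 21
  }
  fu <- followup_cycle_cost(spec$followup, admins)
  drug + fu
}

# Progressed-disease cost per model cycle: best supportive care plus the
# strategy's subsequent-treatment mix (pemetrexed maintenance-style dosing
# every 21 days; osimertinib one 80 mg tablet daily).
pd_cycle_cost <- function(spec, strategy_name) {
  s <- spec$strategies[[strategy_name]]
  p <- spec$prices; v <- spec$vial_strengths; pt <- spec$patient
  pem_daily <- drug_admin_cost(500 * pt$bsa, v$pem, p$pem_vial,
                               spec$vial_strategy) / 21
  mix <- s$pd_mix
  mix[["bsc"]] * p$bsc_cycle * (spec$cycle_days / 28) +
    mix[["pem"]] * pem_daily * spec$cycle_days +
    mix[["osi"]] * p$osi_tab * spec$cycle_days
}

ae_incidence <- function(spec, strategy_name) {
  col <- paste0("inc_", strategy_name)
  if (!col %in% names(spec$ae))
    stop_config("no AE incidence column for strategy %s", strategy_name)
  stats::setNames(spec$ae[[col]], spec$ae$name)
}

# expected one-off grade >= 3 AE management cost at model entry
ae_entry_cost <- function(spec, strategy_name) {
  inc <- ae_incidence(spec, strategy_name)
  sum(inc * spec$prices$ae[spec$ae$name])
}

# expected AE disutility (a positive magnitude)
ae_entry_disutility <- function(spec, strategy_name) {
  inc <- ae_incidence(spec, strategy_name)
  sum(inc * spec$ae$disutility)
}

#' Per-cycle state cost
#'
#' @param spec a `cea_spec`.
#' @param state `"pfs"`, `"pd"` or `"dead"`.
#' @param strategy_name a strategy in `spec$strategies`.
#' @param cycle_index 1-based model cycle.
#' @return USD accrued by one patient spending that cycle in the state
#'   (undiscounted; excludes the one-off entry AE cost).
#' @export
state_cycle_cost <- function(spec, state, strategy_name, cycle_index) {
  switch(match.arg(state, c("pfs", "pd", "dead")),
         pfs = pfs_cost_schedule(spec, strategy_name)[cycle_index],
         pd = pd_cycle_cost(spec, strategy_name),
         dead = 0)
}

#' Incremental cost-effectiveness comparison
#'
#' @param a,b lists (or one-row data.frames) with `total_cost` and
#'   `total_qalys`; `a` is the intervention, `b` the comparator.
#' @return list with `delta_cost`, `delta_qalys`, `icer` and a `dominance`
#'   label: `"icer"` (well-defined ratio), `"dominant"` (cheaper and more
#'   effective), `"dominated"` (dearer and less effective), or
#'   `"indifferent"`.
#' @export
icer <- function(a, b) {
  dc <- a$total_cost - b$total_cost
  de <- a$total_qalys - b$total_qalys
  if (de == 0) {
    lab <- if (dc == 0) "indifferent" else if (dc < 0) "dominant" else "dominated"
    return(list(delta_cost = dc, delta_qalys = de, icer = NA_real_,
                dominance = lab))
  }
  lab <- if (dc <= 0 && de > 0) "dominant" else if (dc >= 0 && de < 0)
    "dominated" else "icer"
  list(delta_cost = dc, delta_qalys = de, icer = dc / de, dominance = lab)
}
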