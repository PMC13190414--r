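# Dosing, vial arithmetic, state costs, AE burden, ICER.

spec0 <- base_case_spec()

test_that("administration doses and vial rounding follow the dosing rules", {
  # sac-TMT 5 mg/kg x 65 kg = 325 mg -> 2 x 200 mg vials
  expect_equal(drug_admin_cost(5 * 65, 200, 1315.85, "round_up"), 2631.70)
  # dose-proportional costing
  expect_equal(drug_admin_cost(5 * 65, 200, 1315.85, "exact"),
               325 / 200 * 1315.85)
  # pemetrexed 500 mg/m2 x 1.72 m2 = 860 mg -> 2 x 500 mg vials
  expect_equal(drug_admin_cost(500 * 1.72, 500, 65.52, "round_up"), 131.04)
  # carboplatin via Calvert: AUC 5 x (70 + 25) = 475 mg
  expect_equal(calvert_dose(5, 70), 475)
  expect_error(drug_admin_cost(-1, 200, 10), "invalid")
})

test_that("expected one-off AE burden matches the incidence-weighted sums", {
  expect_equal(psmarkov:::ae_entry_cost(spec0, "sac_tmt"),
               0.11 * 448.56 + 0.28 * 421.40 + 0.40 * 406.56 + 0.02 * 2937.46)
  expect_equal(psmarkov:::ae_entry_cost(spec0, "sac_tmt"), 388.7068)
  expect_equal(psmarkov:::ae_entry_cost(spec0, "chemo"), 759.6648)
  expect_equal(psmarkov:::ae_entry_disutility(spec0, "sac_tmt"), 0.14783)
  expect_equal(psmarkov:::ae_entry_disutility(spec0, "chemo"), 0.15062)
})

test_that("state cycle costs: death is free, PD carries BSC", {
  expect_equal(state_cycle_cost(spec0, "dead", "sac_tmt", 1), 0)
  # sac-TMT PD mix is 100% best supportive care
  expect_equal(state_cycle_cost(spec0, "pd", "sac_tmt", 5), 436.19)
  # PFS cycle cost includes two administrations of drug plus follow-up
  pfs1 <- state_cycle_cost(spec0, "pfs", "sac_tmt", 1)
  expect_gt(pfs1, 2 * 325 / 200 * 1315.85)
  expect_error(state_cycle_cost(spec0, "alive", "sac_tmt", 1))
})

test_that("chemo drug costs switch from induction to maintenance at 84 days", {
  sched <- psmarkov:::pfs_cost_schedule(spec0, "chemo")
  # cycles 1-3 (84 days) carry platinum + pemetrexed; later cycles less
  expect_equal(sched[1], sched[3])
  expect_lt(sched[4], sched[1])
  expect_equal(sched[5], sched[100])
})

test_that("ICER arithmetic and dominance flags", {
  a <- list(total_cost = 100, total_qalys = 1.0)
  b <- list(total_cost = 50, total_qalys = 0.5)
  cmp <- icer(a, b)
  expect_equal(cmp$icer, 100)
  expect_identical(cmp$dominance, "icer")
  expect_identical(icer(a, a)$dominance, "indifferent")
  expect_identical(icer(list(total_cost = 10, total_qalys = 2), b)$dominance,
                   "dominant")
  expect_identical(icer(list(total_cost = 90, total_qalys = 0.1), b)$dominance,
                   "dominated")
  # division at full precision
  expect_equal(icer(list(total_cost = b$total_cost + 64948.58,
                         total_qalys = b$total_qalys + 0.74), b)$icer,
               64948.58 / 0.74)
})

test_that("zero costs collapse the comparison onto dominance logic", {
  sp <- spec0
  for (nm in c("sac_vial", "pem_vial", "carb_vial", "cis_vial", "osi_tab",
               "bsc_cycle")) sp$prices[[nm]] <- 0
  sp$prices$ae[] <- 0
  for (nm in names(sp$followup))
    if (!nm %in% c("ct_every", "mri_every")) sp$followup[[nm]] <- 0
  r <- run_cea(sp, "psm")$results
  row <- r[r$strategy == "sac_tmt", ]
  expect_equal(row$delta_cost, 0)
  expect_identical(row$dominance, "dominant")
})

test_that("doubling the sac-TMT vial price moves only sac drug cost", {
  sp2 <- apply_params(spec0, c(cost.sac_vial = 2 * spec0$prices$sac_vial))
  r1 <- run_cea(spec0, "psm")$results
  r2 <- run_cea(sp2, "psm")$results
  # chemo arm untouched
  expect_equal(r2$total_cost[r2$strategy == "chemo"],
               r1$total_cost[r1$strategy == "chemo"])
  # sac increase equals the baseline discounted drug-acquisition outlay
  inc <- r2$total_cost[r2$strategy == "sac_tmt"] -
    r1$total_cost[r1$strategy == "sac_tmt"]
  sp0 <- apply_params(spec0, c(cost.sac_vial = 0))
  r0 <- run_cea(sp0, "psm")$results
  drug0 <- r1$total_cost[r1$strategy == "sac_tmt"] -
    r0$total_cost[r0$strategy == "sac_tmt"]
  expect_equal(inc, drug0, tolerance = 1e-9)
  # QALYs bit-identical under a pure price change
  expect_identical(r2$total_qalys, r1$total_qalys)
})

test_that("base-case costs are positive with sac-TMT the dearer strategy", {
  r <- run_cea(spec0)$results
  expect_true(all(r$total_cost > 0))
  for (eng in c("psm", "markov")) {
    sub <- r[r$engine == eng, ]
    expect_gt(sub$total_cost[sub$strategy == "sac_tmt"],
              sub$total_cost[sub$strategy == "chemo"])
  }
})
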