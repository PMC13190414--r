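# OWSA, PSA draws, CEAC.

spec0 <- base_case_spec()

test_that("the parameter table is well-formed", {
  tab <- param_table(spec0)
  expect_true(all(tab$low <= tab$base & tab$base <= tab$high))
  expect_true(all(tab$dist %in% c("gamma", "beta", "none")))
  expect_true("discount" %in% tab$name)
  expect_identical(anyDuplicated(tab$name), 0L)
})

test_that("apply_params reaches every parameter and rejects unknowns", {
  tab <- param_table(spec0)
  for (i in seq_len(nrow(tab))) {
    v <- stats::setNames(tab$low[i], tab$name[i])
    sp <- apply_params(spec0, v)
    expect_false(isTRUE(all.equal(sp, spec0)), info = tab$name[i])
  }
  # every priced input except unused cisplatin moves the model output
  active <- setdiff(tab$name[tab$dist != "none"], "cost.cis_vial")
  base_res <- run_cea(spec0, "psm")$results
  for (key in c("cost.sac_vial", "util.pd", "disutil.neutropenia",
                "inc.chemo.thrombocytopenia", "cost.fu.mri")) {
    row <- tab[tab$name == key, ]
    sp <- apply_params(spec0, stats::setNames(row$low, key))
    r <- run_cea(sp, "psm")$results
    expect_false(isTRUE(all.equal(r[c("total_cost", "total_qalys")],
                                  base_res[c("total_cost", "total_qalys")])),
                 info = key)
  }
  expect_error(apply_params(spec0, c(not.a.key = 1)), "unknown parameter")
})

test_that("degenerate and distribution-specific draws behave", {
  set.seed(1)
  expect_equal(psmarkov:::draw_param(5, 10, 10, 10, "gamma"), rep(10, 5))
  g <- psmarkov:::draw_param(2000, 436.19, 348.95, 523.43, "gamma")
  expect_true(all(g > 0))
  expect_equal(mean(g), 436.19, tolerance = 0.02)
  b <- psmarkov:::draw_param(10000, 0.804, 0.536, 0.840, "beta")
  expect_true(all(b > 0 & b < 1))
  expect_lt(abs(mean(b) - 0.804), 0.01)
  # infeasible beta moments fall back to uniform with a warning
  expect_warning(u <- psmarkov:::draw_param(500, 0.5, 0, 4, "beta"),
                 "uniform fallback")
  expect_true(all(u >= 0 & u <= 4))
})

test_that("the PSA is bit-reproducible from its seed", {
  p1 <- run_psa(spec0, n = 20, seed = 123, engine = "psm")
  p2 <- run_psa(spec0, n = 20, seed = 123, engine = "psm")
  expect_identical(p1, p2)
  p3 <- run_psa(spec0, n = 20, seed = 124, engine = "psm")
  expect_false(identical(p1$dcost_psm, p3$dcost_psm))
})

test_that("PSA sample means stay near the deterministic base case", {
  psa <- run_psa(spec0, n = 200, seed = 11, engine = "psm")
  det <- run_cea(spec0, "psm")$results
  dc0 <- det$delta_cost[det$strategy == "sac_tmt"]
  de0 <- det$delta_qalys[det$strategy == "sac_tmt"]
  expect_lt(abs(mean(psa$dcost_psm) - dc0) / dc0, 0.10)
  expect_lt(abs(mean(psa$dqaly_psm) - de0) / de0, 0.10)
  # drawn utilities in [0, 1], drawn costs positive
  expect_true(all(psa$util.pfs > 0 & psa$util.pfs < 1))
  expect_true(all(psa$cost.sac_vial > 0))
})

test_that("the CEAC is the NMB exceedance curve with the right limits", {
  psa <- run_psa(spec0, n = 100, seed = 5, engine = "psm")
  grid <- c(0, 41811, 150000, 1e7)
  cc <- ceac(psa, grid)
  # all draws cost more: probability 0 at wtp 0
  expect_equal(cc$prob_ce[1], 0)
  # all draws gain QALYs here: probability 1 as wtp grows without bound
  expect_equal(cc$prob_ce[4], 1)
  expect_true(all(diff(cc$prob_ce) >= 0))
  # quadrant/NMB consistency at an intermediate threshold
  l <- 90000
  manual <- mean(l * psa$dqaly_psm - psa$dcost_psm > 0)
  expect_equal(ceac(psa, l)$prob_ce, manual)
  expect_error(ceac(psa, numeric(0)), "empty")
})

test_that("OWSA spreads are zero for frozen ranges and sorted descending", {
  tab <- param_table(spec0)
  frozen <- tab[tab$name == "util.pd", ]
  frozen$low <- frozen$high <- frozen$base
  out <- owsa(spec0, "psm", ranges = frozen)
  expect_equal(out$spread, 0)
  sub <- tab[tab$name %in% c("util.pd", "util.pfs", "cost.sac_vial",
                             "cost.fu.cbc"), ]
  out2 <- owsa(spec0, "psm", ranges = sub)
  expect_true(all(diff(out2$spread) <= 0))
})

test_that("discounting is monotone: higher rates shrink totals", {
  costs <- qalys <- numeric(0)
  for (r in c(0, 0.05, 0.08)) {
    sp <- apply_params(spec0, c(discount = r))
    res <- run_cea(sp, "psm")$results
    costs <- c(costs, res$total_cost[res$strategy == "sac_tmt"])
    qalys <- c(qalys, res$total_qalys[res$strategy == "sac_tmt"])
  }
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})
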