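# Product-limit estimation and Guyot-style pseudo-IPD reconstruction.

test_that("KM estimate matches hand computation and an independent oracle", {
  # three events, no censoring
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  km2 <- km_estimate(c(2, 5, 9), c(0, 0, 0))
  expect_true(all(km2$survival == 1))
  # 200 simulated records vs the hand-rolled product-limit oracle
  set.seed(5)
  tt <- rexp(200, 0.1); cc <- runif(200, 0, 25)
  time <- pmin(tt, cc); ev <- as.integer(tt <= cc)
  km3 <- km_estimate(time, ev)
  ora <- naive_km(time, ev)
  expect_equal(km_survival_at(km3, ora$time), ora$survival, tolerance = 1e-12)
})

test_that("fully determined reconstruction recovers events exactly", {
  tt <- c(1, 2, 3, 5, 8)
  km <- km_estimate(tt, rep(1, 5))
  rec <- reconstruct_ipd(km[, c("time", "survival")],
                         data.frame(time = c(0, tt), n_risk = c(5, 5:1)))
  expect_equal(rec$time, tt)
  expect_equal(rec$event, rep(1L, 5))
})

test_that("a flat curve with decreasing risk yields censorings only", {
  curve <- data.frame(time = c(0, 4, 8, 12), survival = c(1, 1, 1, 1))
  risk <- data.frame(time = c(0, 6, 12), n_risk = c(30, 20, 10))
  rec <- reconstruct_ipd(curve, risk)
  expect_identical(nrow(rec), 30L)
  expect_true(all(rec$event == 0))
})

test_that("inconsistent digitized inputs are rejected with locations", {
  curve <- data.frame(time = c(0, 2, 4), survival = c(1, 0.8, 0.9))
  risk <- data.frame(time = c(0, 4), n_risk = c(50, 30))
  expect_error(reconstruct_ipd(curve, risk), "rises")
  curve2 <- data.frame(time = c(0, 2, 4), survival = c(1, 0.8, 0.6))
  risk2 <- data.frame(time = c(0, 4), n_risk = c(50, 60))
  expect_error(reconstruct_ipd(curve2, risk2), "n_risk increases")
})

test_that("small digitization jitter is isotonically clamped with a message", {
  curve <- data.frame(time = c(0, 2, 4, 6),
                      survival = c(1, 0.80, 0.802, 0.60))
  risk <- data.frame(time = c(0, 6), n_risk = c(100, 55))
  expect_message(rec <- reconstruct_ipd(curve, risk), "isotonic")
  expect_identical(nrow(rec), 100L)
})

test_that("round trip preserves the survival function within 0.03", {
  # simulate -> KM -> digitize (with jitter) -> reconstruct -> KM
  ss <- sim_spec(pfs = surv_dist("exponential", rate = 0.15),
                 os = surv_dist("exponential", rate = 0.10),
                 n = 200, cutoff_months = 18, dropout_prob = 0.10, seed = 7)
  ipd <- simulate_ipd(ss)$os
  risk_times <- c(0, 6, 12, 18)
  fix <- make_digitized_fixture(ipd, grid_step_months = 0.25,
                                risk_times = risk_times, jitter_sd = 0.004)
  rec <- reconstruct_ipd(fix$curve, fix$risk)
  expect_identical(nrow(rec), nrow(ipd))   # record count = initial at-risk
  km0 <- km_estimate(ipd$time, ipd$event)
  km1 <- km_estimate(rec$time, rec$event)
  diffs <- abs(km_survival_at(km0, risk_times) -
                 km_survival_at(km1, risk_times))
  expect_true(all(diffs <= 0.03), info = toString(round(diffs, 4)))
  # medians quantized independently to the 0.25-month digitization grid
  med <- function(km) min(km$time[km$survival <= 0.5])
  expect_lt(abs(med(km0) - med(km1)), 2 * 0.25 + 1e-9)
})

test_that("total-event rescaling pass is applied when supplied", {
  set.seed(9)
  tt <- rexp(120, 0.12); cc <- runif(120, 0, 30)
  time <- pmin(tt, cc); ev <- as.integer(tt <= cc)
  fix <- make_digitized_fixture(data.frame(time = time, event = ev),
                                grid_step_months = 0.5,
                                risk_times = c(0, 5, 10, 15))
  rec <- reconstruct_ipd(fix$curve, fix$risk, total_events = sum(ev))
  expect_lt(abs(sum(rec$event) - sum(ev)), 6)
})

test_that("IPD and digitized CSV round trips preserve the data", {
  d <- data.frame(time = c(1.5, 3, 7), event = c(1, 0, 1))
  p <- tempfile(fileext = ".csv")
  write_ipd(d, p)
  expect_equal(read_ipd(p), d)
  curve <- data.frame(time = c(0, 1), survival = c(1, 0.9))
  write.csv(curve, p, row.names = FALSE)
  expect_equal(read_digitized(p), curve)
  risk <- data.frame(time = c(0, 6), n_risk = c(10, 4))
  write.csv(risk, p, row.names = FALSE)
  expect_equal(read_risk_table(p), risk)
  unlink(p)
})
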