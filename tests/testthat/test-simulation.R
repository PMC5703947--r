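test_that("pre-trigger trajectories are identical across regimens", {
  sims <- lapply(c("untreated", "mtd", "metronomic", "adaptive"),
                 function(k) cached_sim(2, k))
  trig <- vapply(sims, function(s) s$trigger_time, numeric(1))
  expect_true(all(trig == trig[1]))
  pre <- lapply(sims, function(s) s$series[s$series$t <= s$trigger_time, 1:5])
  for (k in 2:4) expect_identical(pre[[k]], pre[[1]])
})

test_that("milestones are monotone in the frequency threshold", {
  for (pid in 1:2) for (kind in c("mtd", "adaptive")) {
    m <- milestone_times(cached_sim(pid, kind), c(0.05, 0.5, 0.90))
    m <- m[!is.na(m)]
    if (length(m) > 1) expect_true(all(diff(m) >= 0))
  }
  # a threshold below the initial resistant frequency is crossed at time 0
  expect_equal(unname(milestone_times(cached_sim(2, "untreated"), 0.01)), 0)
})

test_that("untreated runs converge to the untreated ESS", {
  for (pid in 1:2) {
    sim <- cached_sim(pid, "untreated")
    fin <- unlist(tail(sim$series, 1)[, c("x1", "x2", "x3")])
    pres <- sim$ess$present
    expect_equal(unname(fin[pres]), sim$ess$abundances[pres], tolerance = 1e-3)
    expect_true(all(fin[setdiff(1:3, pres)] / sum(fin) < 1e-3))
    expect_true(is.na(sim$milestones$progression))
    expect_identical(sim$terminated, "HORIZON")
  }
})

test_that("a zero inoculum keeps the resistant clone extinct forever", {
  sim <- simulate_patient(table3_patient(1), regimen("mtd"),
                          solver_control(horizon_days = 2000), inoculum = 0)
  expect_true(all(sim$series$x3 == 0))
  expect_true(is.na(sim$milestones$tminus_5pct))
  expect_true(is.na(sim$milestones$tminus_90pct))
})

test_that("milestones are stable under a 10x tolerance tightening", {
  p2 <- table3_patient(2)
  loose <- simulate_patient(p2, regimen("mtd"), solver_control(
    rel_tol = 1e-8, abs_tol = 1e-10, horizon_days = 300))
  tight <- simulate_patient(p2, regimen("mtd"), solver_control(
    rel_tol = 1e-9, abs_tol = 1e-11, horizon_days = 300))
  for (f in c("tminus_5pct", "tminus_90pct")) {
    a <- loose$milestones[[f]]; b <- tight$milestones[[f]]
    expect_lt(abs(a - b) / b, 1e-3)
  }
})

test_that("adaptive switching lands on the hysteresis thresholds without chattering", {
  sim <- cached_sim(1, "adaptive")
  iv <- sim$on_intervals
  expect_gt(nrow(iv), 1)
  expect_true(all(iv[, 2] > iv[, 1]))            # no zero-length pulses
  expect_true(all(diff(as.vector(t(iv))) > 0))   # alternating, ordered
  b <- sim$baseline_psa
  psa_at <- function(t) {
    i <- which.min(abs(sim$series$t - t)); sim$series$psa[i]
  }
  # later on-starts occur at the restart threshold, on-ends at the stop threshold
  starts <- iv[-1, 1]; ends <- iv[iv[, 2] < max(sim$series$t), 2]
  for (t in starts) expect_equal(psa_at(t) / b, 1.0, tolerance = 0.01)
  for (t in ends) expect_equal(psa_at(t) / b, 0.5, tolerance = 0.01)
})

test_that("adaptive therapy delays competitive release on a best responder", {
  mtd <- cached_sim(1, "mtd"); ada <- cached_sim(1, "adaptive")
  expect_gt(ada$milestones$tminus_5pct, mtd$milestones$tminus_5pct)
  expect_gt(ada$milestones$tminus_90pct, mtd$milestones$tminus_90pct)
})

test_that("dose accounting: MTD is exactly 100%, untreated 0%, adaptive far less", {
  for (pid in 1:2) {
    expect_equal(dose_fraction(cached_sim(pid, "mtd")$ledger), 100)
    expect_equal(dose_fraction(cached_sim(pid, "untreated")$ledger), 0)
    expect_lt(dose_fraction(cached_sim(pid, "adaptive")$ledger), 25)
  }
})

test_that("progression needs sustained takeover with PSA above half baseline", {
  sim <- cached_sim(2, "mtd")
  prog <- sim$milestones$progression
  expect_false(is.na(prog))
  expect_gte(prog, sim$milestones$tminus_90pct)
  expect_identical(sim$terminated, "PROGRESSION")
  expect_true(is.na(progression_time(cached_sim(2, "untreated"))))
})

test_that("regimen comparison tabulates one row per policy", {
  cmp <- compare_regimens(table3_patient(2),
                          control = solver_control(horizon_days = 400))
  expect_equal(nrow(cmp), 4)
  expect_identical(cmp$regimen, c("untreated", "mtd", "metronomic", "adaptive"))
  expect_true(all(cmp$trigger_time == cmp$trigger_time[1]))
  expect_equal(cmp$dose_pct[cmp$regimen == "mtd"], 100)
})

test_that("interval monitoring switches only at 4-weekly decision points", {
  sim <- simulate_patient(table3_patient(2),
                          regimen("adaptive", monitoring = "interval"),
                          solver_control(horizon_days = 800))
  iv <- sim$on_intervals
  off <- (as.vector(t(iv)) - sim$trigger_time) %% 28
  expect_true(all(pmin(off, 28 - off) < 1e-6 |
                    abs(as.vector(t(iv)) - 800) < 1e-6))
})
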