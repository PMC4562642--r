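test_that("integrator matches closed-form exponential growth", {
  m <- toy_model_const(r1 = 0.3, r2 = 0.1, s = 0)
  st <- culture_state(N = c(A = 1e5, B = 0), M = 0, V = 1)
  out <- integrate_between_events(st, m, t_end = 5, dt_max = 0.01)
  expect_equal(out$N[["A"]], 1e5 * exp(0.3 * 5), tolerance = 1e-6)
  expect_equal(out$N[["B"]], 0)
  expect_equal(out$M, 0)
  # zero cells: nothing moves
  z <- integrate_between_events(culture_state(N = c(A = 0, B = 0), M = 7, V = 2),
                                toy_model(), 3, dt_max = 0.05)
  expect_equal(z$M, 7)
  expect_equal(sum(z$N), 0)
})

test_that("halving the step leaves the day-16 state unchanged to 1e-4", {
  m <- toy_model()
  s1 <- run_simulation(m, feeding_schedule("linear", D = 1), dt_max = 0.02)
  s2 <- run_simulation(m, feeding_schedule("linear", D = 1), dt_max = 0.01)
  expect_equal(sum(s1$state$N), sum(s2$state$N), tolerance = 1e-4)
  expect_equal(s1$state$M, s2$state$M, tolerance = 1e-4)
  mt1 <- compute_metrics(s1, m); mt2 <- compute_metrics(s2, m)
  for (f in c("fold_total_expansion", "fold_cd34_expansion",
              "volumetric_efficiency", "time_above_fraction", "endpoint_conc"))
    expect_equal(mt1[[f]], mt2[[f]], tolerance = 1e-3)
})

test_that("apply_bolus dilutes without removing factor", {
  st <- culture_state(N = c(A = 1), M = 100, V = 1)
  b <- apply_bolus(st, 1)
  expect_equal(concentration(b), 50)
  expect_equal(b$M, 100)
  expect_equal(apply_bolus(st, 0)$V, 1)
  # sequence of boluses equals one summed bolus
  st2 <- apply_bolus(apply_bolus(apply_bolus(st, 0.3), 0.5), 0.2)
  expect_equal(concentration(st2), concentration(apply_bolus(st, 1)))
  expect_error(apply_bolus(st, -1), ">= 0")
})

test_that("media exchange zeroes the factor amount only", {
  st <- culture_state(N = c(A = 5), M = 500, V = 3)
  e <- apply_media_exchange(st)
  expect_equal(e$M, 0)
  expect_equal(e$V, 3)
  expect_equal(e$N, st$N)
  expect_equal(apply_media_exchange(e)$M, 0)  # no-op on empty media
  # D=0 trajectory: sawtooth with zeros right after days 4, 8, 12
  s <- run_simulation(toy_model(s = 5e-4), feeding_schedule("none_exchange"),
                      dt_max = 0.05)
  tr <- s$trajectory
  for (d in c(4, 8, 12)) {
    rows <- which(abs(tr$time - d) < 1e-9)
    expect_length(rows, 2)                 # pre- and post-event snapshots
    expect_gt(tr$C[rows[1]], 0)
    expect_equal(tr$C[rows[2]], 0)
  }
  expect_equal(s$events$type, rep("exchange", 3))
})

test_that("scheduled_bolus_volume covers all schedule kinds", {
  expect_equal(scheduled_bolus_volume(feeding_schedule("linear", D = 1), 3), 1)
  expect_equal(scheduled_bolus_volume(feeding_schedule("linear", D = 3), 7), 3)
  expect_equal(scheduled_bolus_volume(feeding_schedule("none_exchange"), 2), 0)
  # exponential and logarithmic schedules share the same total budget
  ex <- feeding_schedule("exponential", k = 0.3, fold_volume = 16)
  lg <- feeding_schedule("logarithmic", k = 0.5, fold_volume = 16)
  tot <- function(s) sum(vapply(1:15, function(d) scheduled_bolus_volume(s, d), 0))
  expect_equal(tot(ex), 15)
  expect_equal(tot(lg), 15)
  # exponential increments increase with day
  incs <- vapply(1:15, function(d) scheduled_bolus_volume(ex, d), 0)
  expect_true(all(diff(incs) > 0))
})

test_that("measure_concentration is noiseless, censored, and calibrated", {
  st <- culture_state(N = c(A = 1), M = 85, V = 1)
  expect_equal(measure_concentration(st, measurement_model(cv = 0)), 85)
  low <- culture_state(N = c(A = 1), M = 1, V = 1)
  expect_equal(measure_concentration(low, measurement_model(detection_limit = 5)), 5)
  # Monte-Carlo moment check: mean-preserving multiplicative noise
  set.seed(3)
  mm <- measurement_model(cv = 0.1)
  big <- culture_state(N = c(A = 1), M = 100, V = 1)
  draws <- replicate(1e4, measure_concentration(big, mm))
  expect_equal(mean(draws), 100, tolerance = 0.01)
  expect_equal(sd(draws) / mean(draws), 0.1, tolerance = 0.05)
})

test_that("run_simulation honours the feeding calendar and determinism", {
  m <- toy_model()
  s <- run_simulation(m, feeding_schedule("linear", D = 1), horizon = 16,
                      dt_max = 0.05)
  expect_equal(s$state$V, 16)            # readout before any day-16 feed
  expect_equal(nrow(s$events), 15)
  expect_equal(s$state$V_added, 15)
  # zero secretion: concentration identically zero
  s0 <- run_simulation(toy_model(s = 0), feeding_schedule("none_exchange"),
                       dt_max = 0.05)
  expect_true(all(s0$trajectory$C == 0))
  # determinism: identical seeds give identical everything
  sched <- feeding_schedule("pid", controller = default_pid_config())
  a <- run_simulation(ref_model(), sched, mm = measurement_model(cv = 0.05),
                      dt_max = 0.05, seed = 99)
  b <- run_simulation(ref_model(), sched, mm = measurement_model(cv = 0.05),
                      dt_max = 0.05, seed = 99)
  expect_identical(a$events, b$events)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("mass and volume ledgers reconcile with the event log", {
  for (sched in list(feeding_schedule("linear", D = 1),
                     feeding_schedule("exponential", k = 0.3, fold_volume = 16),
                     feeding_schedule("none_exchange"),
                     feeding_schedule("pid", controller = default_pid_config()))) {
    m <- if (sched$kind == "pid") ref_model() else toy_model()
    s <- run_simulation(m, sched, dt_max = 0.02)
    tr <- s$trajectory
    boluses <- sum(s$events$volume[s$events$type %in% c("bolus", "pid_bolus")])
    expect_equal(s$state$V, m$V0 + boluses, tolerance = 1e-9)
    # M(end) - M(0) + exchanged amount = integral of secretion
    w <- vapply(m$groups, `[[`, 0, "w")
    adj <- as.matrix(tr[, group_ids(m)]) %*% w
    sec <- vapply(adj, function(a) net_secretion_rate(a, m$secretion), 0)
    integral <- sum(diff(tr$time) * (head(sec, -1) + tail(sec, -1)) / 2)
    exch_rows <- which(s$events$type == "exchange")
    removed <- sum(vapply(exch_rows, function(i) {
      t_ev <- s$events$time[i]
      tr$M[which(abs(tr$time - t_ev) < 1e-9)[1]]  # pre-exchange amount
    }, 0))
    expect_equal(s$state$M + removed, integral, tolerance = 1e-3 * integral)
  }
})

test_that("a pointwise-larger feeding schedule gives pointwise lower C", {
  m <- toy_model_const()   # growth decoupled from concentration
  s1 <- run_simulation(m, feeding_schedule("linear", D = 1), dt_max = 0.02)
  s3 <- run_simulation(m, feeding_schedule("linear", D = 3), dt_max = 0.02)
  expect_identical(s1$trajectory$time, s3$trajectory$time)
  expect_true(all(s3$trajectory$C <= s1$trajectory$C + 1e-12))
})

test_that("run_replicates derives disjoint seeds and propagates variability", {
  m <- toy_model()
  # degenerate sampler: replicate equals a single nominal run
  r1 <- run_replicates(m, toy_sampler(0), feeding_schedule("linear", D = 1),
                       n = 1, base_seed = 5, dt_max = 0.05)
  expect_length(r1, 1)
  expect_equal(sum(r1[[1]]$state$N) > 0, TRUE)
  # nondegenerate: no two replicate trajectories identical, seeds disjoint
  rs <- run_replicates(m, toy_sampler(0.5), feeding_schedule("linear", D = 1),
                       n = 6, base_seed = 5, dt_max = 0.1)
  seeds <- vapply(rs, `[[`, 0L, "seed")
  expect_equal(anyDuplicated(seeds), 0L)
  finals <- vapply(rs, function(r) sum(r$state$N), 0)
  expect_equal(anyDuplicated(finals), 0L)
  # ensemble SD positive under a nondegenerate sampler, zero under degenerate
  dz <- run_replicates(m, toy_sampler(0), feeding_schedule("linear", D = 1),
                       n = 3, base_seed = 5, dt_max = 0.1)
  expect_equal(sd(vapply(dz, function(r) sum(r$state$N), 0)), 0)
  expect_gt(sd(finals), 0)
})

test_that("flow-mode PID delivers as constant inflow and saturates mid-segment", {
  cfg <- pid_config(Kp = 0.2, Kd = 0.5, N = 0.5, Ts = 12, setpoint = 85,
                    max_fold_volume = 5, output_mode = "flow")
  s <- run_simulation(ref_model(), feeding_schedule("pid", controller = cfg),
                      dt_max = 0.02)
  expect_equal(s$state$V, 5, tolerance = 1e-6)
  expect_true("controller_off" %in% s$events$type)
  t_off <- s$events$time[s$events$type == "controller_off"][1]
  flows <- s$events[s$events$type == "pid_flow" & s$events$volume > 0, ]
  expect_true(all(flows$time <= t_off + 1e-9))
})
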