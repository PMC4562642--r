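make_table <- function(scheme = "D1",
                       time = c(0, 4, 8, 12),
                       A = c(100, 200, 350, 500),
                       B = c(50, 60, 80, 100),
                       conc = c(0, 40, 90, 150),
                       vol = c(1, 5, 9, 13)) {
  timecourse_table(time, data.frame(A = A, B = B), conc, vol, scheme)
}

test_that("interval_growth_rates follows the percent-per-day formula", {
  tb <- make_table()
  gr <- interval_growth_rates(tb, "A")
  expect_equal(gr$midpoint_day, c(2, 6, 10))
  expect_equal(gr$rate_pct_per_day[1], (200 - 100) / (100 * 4) * 100)  # 25
  # no change -> 0
  tb0 <- make_table(A = c(100, 100, 100, 100))
  expect_equal(interval_growth_rates(tb0, "A")$rate_pct_per_day, rep(0, 3))
  # zero start count: interval skipped with warning
  tbz <- make_table(A = c(100, 0, 200, 300))
  expect_warning(gz <- interval_growth_rates(tbz, "A"), "zero count")
  expect_equal(nrow(gz), 2)
  expect_error(interval_growth_rates(tb, "missing"), "not present")
})

test_that("interval_mean_concentration averages endpoints, exchange-aware", {
  tb <- make_table(conc = c(0, 100, 80, 120))
  mc <- interval_mean_concentration(tb)
  expect_equal(mc$mean_conc_pg_ml[1], 50)
  expect_equal(mc$midpoint_day, c(2, 6, 10))
  tbc <- make_table(conc = rep(80, 4))
  expect_equal(interval_mean_concentration(tbc)$mean_conc_pg_ml, rep(80, 3))
  # pooled across schemes keeps the scheme tag
  pooled <- rbind(interval_mean_concentration(make_table(scheme = "D1")),
                  interval_mean_concentration(make_table(scheme = "D3")))
  expect_setequal(unique(pooled$scheme), c("D1", "D3"))
  # media-exchange table: interval starts at the post-exchange zero
  d0 <- make_table(scheme = "D0", conc = c(50, 60, 70, 80), vol = rep(1, 4))
  m0 <- interval_mean_concentration(d0)
  expect_equal(m0$conc_start, rep(0, 3))
  expect_equal(m0$mean_conc_pg_ml, c(30, 35, 40))
})

test_that("interval_secretion_rates tracks the factor amount ledger", {
  tb <- timecourse_table(c(0, 4), data.frame(A = c(1, 1), B = c(1, 1)),
                         conc_pg_ml = c(0, 100), volume_ml = c(1, 5),
                         scheme = "D1")
  expect_equal(interval_secretion_rates(tb)$rate_pg_per_day, (500 - 0) / 4)
  # constant amount -> 0
  tbc <- make_table(conc = c(10, 10, 10, 10), vol = c(1, 1, 1, 1))
  expect_equal(interval_secretion_rates(tbc)$rate_pg_per_day, rep(0, 3))
  # D0: hand-tracked ledger with post-exchange reset M(t1+) = 0
  d0 <- timecourse_table(c(0, 4, 8), data.frame(A = 1:3, B = 1:3),
                         conc_pg_ml = c(0, 200, 240),
                         volume_ml = c(2, 2, 2), scheme = "D0")
  sr <- interval_secretion_rates(d0)
  expect_equal(sr$rate_pg_per_day, c(400 / 4, 480 / 4))
  # ledger conservation for fed-batch tables
  tb2 <- make_table()
  M <- tb2$conc_pg_ml * tb2$volume_ml
  expect_equal(sum(interval_secretion_rates(tb2)$rate_pg_per_day *
                     interval_secretion_rates(tb2)$dt_days),
               M[length(M)] - M[1])
})

test_that("fit_growth_correlation recovers, interpolates and degenerates", {
  # noiseless exponential round trip within 1%
  cs <- c(0, 25, 60, 110, 180, 260, 350)
  pts <- data.frame(conc = cs, rate_pct = 40 * exp(-0.01 * cs))
  fit <- fit_growth_correlation(pts, kind = "exponential")
  expect_equal(fit$a, 0.40, tolerance = 0.01)
  expect_equal(fit$b, -0.01, tolerance = 0.01)
  # auto picks exponential on a negative dose response, spline otherwise
  expect_equal(fit_growth_correlation(pts, kind = "auto")$kind, "exponential")
  pts_up <- data.frame(conc = cs, rate_pct = 10 + 0.05 * cs)
  expect_equal(fit_growth_correlation(pts_up, kind = "auto")$kind, "spline")
  # two points -> straight line through them
  two <- fit_growth_correlation(data.frame(conc = c(0, 100),
                                           rate_pct = c(10, 30)), "spline")
  expect_equal(evaluate_growth_rate(two, 50), 0.20)
  # all-equal rates -> constant exponential
  flat <- fit_growth_correlation(data.frame(conc = c(0, 50, 100),
                                            rate_pct = c(20, 20, 20)),
                                 "exponential")
  expect_equal(flat$a, 0.20, tolerance = 1e-6)
  expect_equal(flat$b, 0, tolerance = 1e-6)
  expect_error(fit_growth_correlation(pts[1:2, ], "exponential"), ">= 3")
})

test_that("interval-aware exponential fit beats the pointwise fit on drifting C", {
  # observations are path averages over wide intervals; truth a=40, b=-0.01
  c1 <- c(0, 50, 150, 280); c2 <- c(60, 160, 300, 520)
  y <- 40 * (exp(-0.01 * c2) - exp(-0.01 * c1)) / (-0.01 * (c2 - c1))
  fit <- fit_growth_correlation(
    data.frame(conc = (c1 + c2) / 2, rate_pct = y,
               conc_start = c1, conc_end = c2), "exponential")
  expect_equal(fit$a, 0.40, tolerance = 1e-4)
  expect_equal(fit$b, -0.01, tolerance = 1e-4)
  naive <- fit_growth_correlation(
    data.frame(conc = (c1 + c2) / 2, rate_pct = y), "exponential")
  expect_gt(abs(naive$b - -0.01), abs(fit$b - -0.01))
})

test_that("fit_secretion_correlation fits slope through origin and splines", {
  x <- c(1e5, 3e5, 6e5, 1e6)
  exact <- fit_secretion_correlation(
    data.frame(adjusted = x, rate_pg_per_day = 2e-4 * x))
  expect_equal(exact$s, 2e-4, tolerance = 1e-12)
  single <- fit_secretion_correlation(
    data.frame(adjusted = 1e6, rate_pg_per_day = 200))
  expect_equal(single$s, 2e-4)
  # noisy recovery within 10% at CV = 10%, n = 9, fixed seed
  set.seed(11)
  x9 <- seq(1e5, 9e5, length.out = 9)
  noisy <- fit_secretion_correlation(
    data.frame(adjusted = x9,
               rate_pg_per_day = 2e-4 * x9 * exp(rnorm(9, 0, 0.1))))
  expect_equal(noisy$s, 2e-4, tolerance = 0.1)
  expect_error(fit_secretion_correlation(
    data.frame(adjusted = c(0, 0), rate_pg_per_day = c(1, 2))), "all-zero")
  sp <- fit_secretion_correlation(
    data.frame(adjusted = c(0, 1e6), rate_pg_per_day = c(0, 150)), "spline")
  expect_equal(net_secretion_rate(5e5, sp), 75)
})

test_that("expression-weight normalization anchors, merges and averages", {
  setA <- c(proB = 200, hsc = 80, mono = 300)
  setB <- c(proB = 100, nk = 40)
  w <- normalize_expression_weights(setA, setB, "proB")
  expect_equal(w[["nk"]], 80)            # every setB signal doubled
  expect_equal(w[["proB"]], 200)         # present in both: mean of 200, 200
  expect_equal(w[["hsc"]], 80)
  # identical sets unchanged
  expect_equal(normalize_expression_weights(setA, setA, "proB"), setA[names(setA)])
  expect_error(normalize_expression_weights(setA, c(nk = 1), "proB"), "anchor")
  # group weight = mean of member signals (arithmetic oracle)
  gw <- group_expression_weights(w, list(g1 = c("hsc", "proB"), g2 = "nk"))
  expect_equal(gw[["g1"]], mean(c(80, 200)))
  expect_equal(gw[["g2"]], 80)  # nk signal after anchor rescaling
})

test_that("interval rates approach the continuous rate as sampling shrinks", {
  r <- 0.3
  rates <- vapply(c(4, 2, 1, 0.5), function(dt) {
    t <- seq(0, 8, by = dt)
    tb <- timecourse_table(t, data.frame(A = 100 * exp(r * t),
                                         B = rep(1, length(t))),
                           conc_pg_ml = rep(0, length(t)),
                           volume_ml = rep(1, length(t)), scheme = "D1")
    interval_growth_rates(tb, "A")$rate_pct_per_day[1] / 100
  }, 0)
  expect_true(all(diff(abs(rates - r)) < 0))  # monotone approach
  expect_gt(rates[1], r)                      # linear rate overestimates
})
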