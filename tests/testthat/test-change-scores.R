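test_that("residualized change is a least-squares residual", {
  t1 <- c(1, 2, 3, 4)
  expect_equal(as.numeric(residualized_change(t1, 2 * t1)), rep(0, 4))
  # hand-computed residuals of the 4-point regression
  r <- residualized_change(t1, c(2, 1, 4, 5))
  expect_equal(as.numeric(r), c(0.8, -1.4, 0.4, 0.2), tolerance = 1e-9)
  # orthogonality at machine precision
  set.seed(5)
  a <- rnorm(50); b <- 0.6 * a + rnorm(50)
  res <- as.numeric(residualized_change(a, b))
  expect_lt(abs(sum(res)), 1e-10)
  expect_lt(abs(sum(res * a)), 1e-9)
})

test_that("residualized change drops incomplete pairs listwise, in order", {
  t1 <- c(1, 2, NA, 4, 5)
  t2 <- c(2, 4, 5, NA, 9)
  r <- residualized_change(t1, t2)
  expect_equal(attr(r, "n_dropped"), 2L)
  expect_true(all(is.na(r[c(3, 4)])))
  expect_equal(length(r), 5L)
  expect_error(residualized_change(rep(1, 5), 1:5), "zero variance")
})

test_that("person-level OLS slopes match the closed form", {
  expect_equal(person_ols_slope(0:9, 3 + 2 * (0:9)), 2.0)
  expect_equal(person_ols_slope(0:5, rep(4, 6)), 0.0)
  expect_equal(person_ols_slope(0:3, c(10, 9, 7, 6)), -1.4)
  expect_error(person_ols_slope(rep(2, 5), rnorm(5)), "single time")
  expect_true(is.na(person_ols_slope(0:2, c(1, 2, 3), min_obs = 4L)))
})

test_that("slopes are shift-invariant and scale linearly", {
  set.seed(7)
  t <- sort(runif(20, 0, 21)); y <- rnorm(20)
  s <- person_ols_slope(t, y)
  expect_equal(person_ols_slope(t, y + 100), s)
  expect_equal(person_ols_slope(t, 3 * y), 3 * s)
})

test_that("windowed means cover the documented half-open windows", {
  panel <- data.frame(
    participant = rep("p1", 10),
    day = c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4),
    value = c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100))
  first3 <- windowed_ema_mean(panel, "first_k_days", k = 3)
  expect_equal(first3$value, mean(c(10, 20, 30, 40, 50, 60)))
  last2 <- windowed_ema_mean(panel, "last_k_days", k = 2, duration_days = 5)
  expect_equal(last2$value, mean(c(70, 80, 90, 100)))
  whole <- windowed_ema_mean(panel, "first_k_days", k = 5)
  expect_equal(whole$value, mean(panel$value))
  one <- windowed_ema_mean(panel[1, ], "first_k_days", k = 1)
  expect_equal(one$value, 10)
  expect_error(windowed_ema_mean(panel, "first_k_days", k = 0), "k must")
  expect_error(windowed_ema_mean(panel, "last_k_days", k = 9,
                                 duration_days = 5), "duration")
})

test_that("participants absent from a window are counted, not invented", {
  panel <- data.frame(participant = c("a", "a", "b"),
                      day = c(0, 1, 20), value = c(1, 2, 3))
  w <- windowed_ema_mean(panel, "first_k_days", k = 3)
  expect_equal(w$participant, "a")
  expect_equal(attr(w, "n_missing"), 1L)
})

test_that("winsorization follows the type-7 quantile convention", {
  v <- as.numeric(1:100)
  w <- winsorize(v, 0.05, 0.95)
  expect_equal(min(w), quantile(v, 0.05, type = 7, names = FALSE))
  expect_equal(max(w), quantile(v, 0.95, type = 7, names = FALSE))
  expect_equal(min(w), 5.95)
  expect_equal(max(w), 95.05)
  expect_equal(order(v), order(w))
  # no-clip bounds are the identity; constant vectors pass through
  expect_equal(as.numeric(winsorize(v, 0, 1)), v)
  expect_equal(as.numeric(winsorize(rep(3, 10), 0.05, 0.95)), rep(3, 10))
  expect_error(winsorize(v, 0.9, 0.1), "lower_p")
})

test_that("winsorizing twice with the same numeric bounds is a no-op", {
  set.seed(11)
  v <- rt(200, df = 3)
  w1 <- winsorize(v, 0.05, 0.95)
  b <- attr(w1, "bounds")
  w2 <- winsorize(as.numeric(w1), bounds = b)
  expect_equal(as.numeric(w2), as.numeric(w1))
})

test_that("compliance summaries reproduce the percent arithmetic", {
  d <- hmp_design(20)  # 28 days x 4 beeps = 112 scheduled
  # counts chosen to average 89.85 observed beeps
  counts <- c(rep(89L, 3), rep(90L, 17))
  stopifnot(mean(counts) == 89.85)
  panel <- do.call(rbind, lapply(seq_along(counts), function(i) {
    grid <- expand.grid(beep = 0:3, day = 0:27)[seq_len(counts[i]), ]
    data.frame(participant = sprintf("P%02d", i), day = grid$day,
               beep = grid$beep, value = 3)
  }))
  cs <- compliance_summary(panel, d, trend = "ols")
  expect_equal(round(cs$mean_percent, 1), 80.2)
  expect_equal(cs$per_participant$n_scheduled[1], 112)
})

test_that("full compliance gives 100 percent and a zero weekly trend", {
  d <- care_design(10)
  tr <- lowcens_truth(compliance_base = 1, compliance_weekly_decline = 0)
  s <- quiet_sim(d, tr, seed = 13)
  cs <- suppressWarnings(compliance_summary(s$ema, d, trend = "ols"))
  expect_true(all(cs$per_participant$percent == 100))
  expect_equal(cs$weekly_trend, 0, tolerance = 1e-12)
})

test_that("a generated weekly compliance decline is recovered", {
  d <- care_design(500)
  tr <- lowcens_truth(compliance_base = 0.85,
                      compliance_weekly_decline = 0.03)
  s <- quiet_sim(d, tr, seed = 17)
  cs <- suppressWarnings(compliance_summary(s$ema, d, trend = "mixed"))
  expect_equal(cs$weekly_trend, -0.03, tolerance = 0.01 / 0.03)
  expect_lt(cs$trend_p, 0.001)
})

test_that("participant change tables join questionnaire and EMA streams", {
  d <- care_design(40)
  s <- quiet_sim(d, lowcens_truth(), seed = 19)
  ch <- participant_changes(s$waves, s$ema)
  expect_setequal(names(ch), c("participant", "retro_t1", "retro_t2",
                               "retro_change", "ema_slope", "n_ema_obs"))
  expect_equal(nrow(ch), 40)
  expect_equal(mean(ch$retro_change, na.rm = TRUE), 0, tolerance = 1e-9)
  # slopes only where enough observations
  expect_true(all(is.na(ch$ema_slope) | ch$n_ema_obs >= 4))
})
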