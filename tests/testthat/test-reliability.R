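test_that("Cronbach's alpha matches the defining formula and its limits", {
  # 4 persons x 3 items, expected value computed from the formula by hand
  x <- matrix(c(1, 1, 2, 2, 3, 3, 3, 3, 4, 4, 2, 5), nrow = 4, byrow = TRUE)
  expect_equal(as.numeric(cronbach_alpha(x)), 0.8347826, tolerance = 1e-6)
  # two perfectly parallel items
  y <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(as.numeric(cronbach_alpha(y)), 1)
  # independent items have population alpha 0
  set.seed(1)
  z <- cbind(rnorm(1e5), rnorm(1e5))
  expect_lt(abs(as.numeric(cronbach_alpha(z))), 0.02)
})

test_that("alpha errors and listwise handling behave as documented", {
  expect_error(cronbach_alpha(matrix(1:6, ncol = 1)), "2 items")
  expect_error(cronbach_alpha(matrix(1, nrow = 5, ncol = 3)), "zero variance")
  x <- matrix(c(1, 1, 2, 2, 3, 3, 3, 3, 4, 4, 2, 5, NA, 1, 1),
              nrow = 5, byrow = TRUE)
  a <- cronbach_alpha(x)
  expect_equal(attr(a, "n_dropped"), 1L)
  expect_equal(attr(a, "n_units"), 4L)
})

test_that("the Spearman-Brown prophecy reproduces known adjustments", {
  # printed split-half/adjusted pairs from the source trials
  expect_equal(round(spearman_brown_double(0.89), 2), 0.94)
  expect_equal(round(spearman_brown_double(0.50), 2), 0.67)
  expect_equal(round(spearman_brown_double(0.96), 2), 0.98)
  expect_equal(round(spearman_brown_double(0.77), 2), 0.87)
  expect_equal(round(spearman_brown_double(0.61), 2), 0.76)
  expect_equal(spearman_brown_double(0), 0)
  expect_equal(spearman_brown_double(1), 1)
  expect_error(spearman_brown_double(-1), "must be in")
})

test_that("Spearman-Brown is strictly increasing and maps [0,1] to [0,1]", {
  r <- seq(-0.99, 1, by = 0.01)
  v <- spearman_brown_double(r)
  expect_true(all(diff(v) > 0))
  u <- seq(0, 1, by = 0.01)
  expect_true(all(spearman_brown_double(u) >= 0 &
                    spearman_brown_double(u) <= 1))
  expect_true(all(spearman_brown_double(u[u > 0 & u < 1]) >=
                    u[u > 0 & u < 1]))
})

test_that("residualized-change reliability reproduces the printed values", {
  expect_equal(round(residualized_change_reliability(0.89, 0.90, 0.69), 2),
               0.71)
  expect_equal(round(residualized_change_reliability(0.93, 0.94, 0.66), 2),
               0.84)
  expect_equal(round(residualized_change_reliability(0.94, 0.95, 0.55), 2),
               0.90)
  # r12 = 0 reduces to the outcome-wave reliability
  for (a in c(0.2, 0.5, 0.9))
    expect_equal(residualized_change_reliability(a, a, 0), a)
  expect_error(residualized_change_reliability(0.9, 0.9, 1), "r12")
})

test_that("change reliability rises with wave reliability, falls with r12", {
  base <- residualized_change_reliability(0.85, 0.85, 0.6)
  expect_gt(residualized_change_reliability(0.95, 0.85, 0.6), base)
  expect_gt(residualized_change_reliability(0.85, 0.95, 0.6), base)
  expect_lt(residualized_change_reliability(0.85, 0.85, 0.8), base)
  # orientation matters: the outcome-wave alpha carries more weight
  expect_false(isTRUE(all.equal(
    residualized_change_reliability(0.80, 0.95, 0.6),
    residualized_change_reliability(0.95, 0.80, 0.6))))
})

test_that("raw difference-score reliability matches its closed forms", {
  # equal SDs and alphas: (alpha - r) / (1 - r)
  expect_equal(raw_change_reliability(0.8, 0.8, 0.5, 1, 1),
               (0.8 - 0.5) / (1 - 0.5))
  # alpha = r12: no reliable change variance at all
  expect_equal(raw_change_reliability(0.9, 0.9, 0.9, 1, 1), 0)
  # general case, frozen from direct hand substitution
  expect_equal(raw_change_reliability(0.89, 0.90, 0.69, 1.0, 1.2),
               0.6760204, tolerance = 1e-6)
})

test_that("split plans are balanced random partitions within participants", {
  d <- care_design(n_participants = 25)
  s <- quiet_sim(d, lowcens_truth(), seed = 8)
  plan <- make_split_plan(s$ema, seed = 4)
  counts <- table(plan$participant, plan$half)
  expect_true(all(abs(counts[, "A"] - counts[, "B"]) <= 1))
  expect_equal(sort(plan$row), seq_len(nrow(s$ema)))
  # seeded determinism
  expect_identical(as.data.frame(make_split_plan(s$ema, seed = 4)),
                   as.data.frame(plan))
})

test_that("noise-free heterogeneous slopes give a split-half correlation of 1", {
  set.seed(2)
  n <- 12
  panel <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(participant = sprintf("P%02d", i), time = 0:9,
               value = 5 * i + i * (0:9))
  }))
  est <- split_half_reliability(panel, "slope", seed = 1)
  expect_equal(est$value_raw, 1.0, tolerance = 1e-9)
  expect_equal(est$value_sb, 1.0, tolerance = 1e-9)
  # half means of a trending series vary with split composition, so the
  # mean statistic is high but not exactly 1
  est_m <- split_half_reliability(panel, "mean", seed = 1)
  expect_gt(est_m$value_raw, 0.9)
})

test_that("degenerate split-half inputs raise the documented errors", {
  panel <- data.frame(participant = rep(c("a", "b", "c"), each = 6),
                      time = rep(0:5, 3), value = 7)
  expect_error(split_half_reliability(panel, "mean", seed = 1),
               "zero variance")
  few <- data.frame(participant = rep(c("a", "b"), each = 6),
                    time = rep(0:5, 2), value = rnorm(12))
  expect_error(split_half_reliability(few, "slope", seed = 1),
               "fewer than 3")
})

test_that("split-half estimates carry SB >= raw and respect min_obs", {
  d <- care_design(n_participants = 60)
  s <- quiet_sim(d, lowcens_truth(), seed = 21)
  est <- split_half_reliability(s$ema, "slope", seed = 2)
  expect_true(est$value_sb >= est$value_raw)
  expect_lte(est$value_sb, 1)
  # a harsh min_obs excludes low-compliance participants and counts them
  est40 <- split_half_reliability(s$ema, "slope", seed = 2, min_obs = 50L)
  expect_lt(est40$n_units, est$n_units)
  expect_equal(est40$n_units + est40$n_excluded, est$n_units)
})

test_that("MLM slope reliability has the right limits and errors", {
  ss <- c(a = 100, b = 200, c = 400)
  expect_equal(mlm_slope_reliability(list(tau11 = 0.2, sigma2 = 0), ss)$value_raw, 1)
  expect_equal(mlm_slope_reliability(list(tau11 = 0, sigma2 = 9), ss)$value_raw, 0)
  lam <- mlm_slope_reliability(list(tau11 = 0.16, sigma2 = 225), ss)
  expect_equal(lam$value_raw, mean(0.16 / (0.16 + 225 / ss)))
  expect_error(mlm_slope_reliability(list(tau11 = 0.1, sigma2 = 1), c(1, 0)),
               "sum of squares")
})

test_that("multi-split averaging stabilizes the split-half estimate", {
  d <- care_design(n_participants = 80)
  s <- quiet_sim(d, lowcens_truth(), seed = 31)
  single <- vapply(1:6, function(sd)
    split_half_reliability(s$ema, "slope", seed = sd)$value_raw, numeric(1))
  avg <- vapply(c(101L, 201L), function(sd)
    split_half_reliability(s$ema, "slope", seed = sd,
                           n_splits = 10L)$value_raw, numeric(1))
  expect_lt(abs(diff(avg)), max(single) - min(single) + 1e-12)
})
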