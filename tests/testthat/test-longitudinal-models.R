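test_that("a common noise-free trajectory is recovered to 3 decimals", {
  d <- care_design(12)
  tr <- lowcens_truth(sigma2 = 0, tau00 = 0.1, tau11 = 1e-6, tau01 = 0,
                      gamma10 = -0.25, gamma11 = 0,
                      compliance_base = 1, compliance_weekly_decline = 0)
  s <- quiet_sim(d, tr, seed = 23)
  set.seed(1)
  s$ema$value <- s$ema$value + rnorm(nrow(s$ema), sd = 1e-4)
  fit <- quiet_lmm(s$ema, robustness = "none")
  expect_equal(fit$fixed$estimate[fit$fixed$term == "time"], -0.25,
               tolerance = 1e-3 / 0.25)
})

test_that("the group-by-time interaction recovers the generating arm effect", {
  d <- care_design(400)
  tr <- lowcens_truth(gamma11 = -0.2)
  s <- quiet_sim(d, tr, seed = 29)
  ema <- merge(s$ema, s$truth[c("participant", "group")], by = "participant")
  fit <- quiet_lmm(ema, include_group = TRUE, robustness = "none")
  row <- fit$fixed[fit$fixed$term == "time:group", ]
  expect_lt(abs(row$estimate - (-0.2)), 3 * row$se)
  expect_true(all(c(fit$tau00, fit$tau11, fit$sigma2) >= 0))
  expect_lte(abs(fit$tau01), sqrt(fit$tau00 * fit$tau11) + 1e-8)
})

test_that("identical data give identical fits (deterministic optimizer)", {
  d <- care_design(60)
  s <- quiet_sim(d, lowcens_truth(), seed = 31)
  f1 <- quiet_lmm(s$ema, robustness = "winsorized_input")
  f2 <- quiet_lmm(s$ema, robustness = "winsorized_input")
  expect_identical(f1$fixed, f2$fixed)
  expect_identical(f1$sigma2, f2$sigma2)
})

test_that("winsorized-input fits resist heavy-tailed contamination", {
  d <- care_design(40)
  tr <- lowcens_truth(gamma10 = -0.3, gamma11 = 0)
  err_none <- err_wins <- numeric(40)
  for (i in seq_len(40)) {
    s <- quiet_sim(d, tr, seed = 1000 + i)
    set.seed(2000 + i)
    k <- sample(nrow(s$ema), round(0.05 * nrow(s$ema)))
    s$ema$value[k] <- s$ema$value[k] +
      sample(c(-1, 1), length(k), TRUE) * rexp(length(k), rate = 1 / 60)
    fn <- quiet_lmm(s$ema, robustness = "none")
    fw <- quiet_lmm(s$ema, robustness = "winsorized_input")
    err_none[i] <- abs(fn$fixed$estimate[fn$fixed$term == "time"] + 0.3)
    err_wins[i] <- abs(fw$fixed$estimate[fw$fixed$term == "time"] + 0.3)
  }
  expect_lt(median(err_wins), median(err_none))
})

test_that("the growth-model effect size is forced arithmetic", {
  expect_equal(feingold_d(0, 21, 2)$d, 0)
  expect_equal(feingold_d(-0.01, 28, 1.4)$d, -0.2)
  expect_error(feingold_d(0.1, 21, 0), "sd_raw")
  for (b in c(-0.3, -0.01, 0.02, 1))
    expect_equal(sign(feingold_d(b, 21, 5)$d), sign(b))
  # affine invariance: rescaling outcome and standardizer together
  expect_equal(feingold_d(0.05 * 7, 21, 2 * 7)$d, feingold_d(0.05, 21, 2)$d)
})

test_that("the ANCOVA group effect recovers a known shift and flips with coding", {
  set.seed(41)
  n <- 300
  t1 <- rnorm(n, 30, 6)
  grp <- rep(c(0, 1), n / 2)
  t2 <- 0.7 * t1 - 3 * grp + rnorm(n, 0, 4)
  a <- ancova_group_effect(t1, t2, grp)
  expect_lt(abs(a$b - (-3)), 3 * a$se)
  flipped <- ancova_group_effect(t1, t2, 1 - grp)
  expect_equal(flipped$b, -a$b, tolerance = 1e-9)
  expect_equal(abs(flipped$d), abs(a$d), tolerance = 1e-9)
  expect_error(ancova_group_effect(t1, t2, rep(1, n)), "two")
})

test_that("the ANCOVA test holds its type-I error under the null", {
  set.seed(43)
  reject <- 0L
  for (i in 1:200) {
    n <- 100
    t1 <- rnorm(n); t2 <- 0.6 * t1 + rnorm(n)
    grp <- sample(rep(c(0, 1), n / 2))
    if (ancova_group_effect(t1, t2, grp)$p < 0.05) reject <- reject + 1L
  }
  # Binomial(200, 0.05): mean 10, SD ~3.1
  expect_lte(reject, 22L)
})

test_that("pre/post criterion regression has the documented structure", {
  set.seed(47)
  n <- 30
  dep1 <- rnorm(n, 10, 3)
  ch <- data.frame(retro_change = rnorm(n), ema_slope = rnorm(n))
  out <- suppressWarnings(criterion_validity_prepost(dep1, dep1, ch))
  est <- out$estimate[match(c("dep_t1", "retro_change", "ema_slope"),
                            out$term)]
  expect_equal(est, c(1, 0, 0), tolerance = 1e-8)
  # adding a constant to the outcome only shifts the intercept
  dep2 <- 0.8 * dep1 + 0.5 * ch$retro_change + rnorm(n)
  o1 <- criterion_validity_prepost(dep1, dep2, ch)
  o2 <- criterion_validity_prepost(dep1, dep2 + 7, ch)
  expect_equal(o1$estimate[o1$term != "(Intercept)"],
               o2$estimate[o2$term != "(Intercept)"], tolerance = 1e-9)
  expect_equal(o2$estimate[o2$term == "(Intercept)"],
               o1$estimate[o1$term == "(Intercept)"] + 7, tolerance = 1e-9)
})

test_that("pre/post regression recovers generated effects", {
  set.seed(53)
  n <- 500
  dep1 <- rnorm(n, 10, 3)
  ch <- data.frame(retro_change = rnorm(n), ema_slope = rnorm(n))
  dep2 <- 0.6 * dep1 + 0.4 * ch$retro_change - 0.3 * ch$ema_slope + rnorm(n)
  out <- criterion_validity_prepost(dep1, dep2, ch)
  for (spec in list(c("dep_t1", 0.6), c("retro_change", 0.4),
                    c("ema_slope", -0.3))) {
    row <- out[out$term == spec[1], ]
    expect_lt(abs(row$estimate - as.numeric(spec[2])), 3 * row$se)
  }
})

test_that("longitudinal criterion model: null effects and centering algebra", {
  d <- care_design(150)
  tr <- lowcens_truth(dep_effect_retro = 0, dep_effect_ema = 0,
                      dep_slope_noise_sd = 2)
  s <- quiet_sim(d, tr, seed = 59)
  ch <- participant_changes(s$waves, s$ema)
  cv <- suppressWarnings(criterion_validity_longitudinal(s$depression, ch))
  for (term in c("time_c:retro_change", "time_c:ema_slope")) {
    row <- cv$fixed[cv$fixed$term == term, ]
    expect_lt(abs(row$estimate), 3 * row$se)
  }
  # re-centering time changes main effects, not interaction slopes
  cv0 <- suppressWarnings(
    criterion_validity_longitudinal(s$depression, ch, center = "baseline"))
  for (term in c("time_c:retro_change", "time_c:ema_slope")) {
    expect_equal(cv$fixed$estimate[cv$fixed$term == term],
                 cv0$fixed$estimate[cv0$fixed$term == term],
                 tolerance = 1e-4)
  }
})

test_that("paired pre/post effects handle change, no-change and degeneracy", {
  x <- c(4, 7, 9, 12, 3)
  no_change <- paired_prepost_effect(x, x)
  expect_equal(no_change$t, 0)
  expect_equal(no_change$d, 0)
  expect_error(paired_prepost_effect(x, x - 2), "degenerate")
  set.seed(61)
  t1 <- rnorm(89, 30, 6)
  t2 <- t1 - 0.5 * 6 + rnorm(89, 0, 4)
  pp <- paired_prepost_effect(t1, t2)
  # d estimates a 0.5 SD shift; SE of d roughly sqrt(1/n + d^2/2n) ~ 0.11
  expect_lt(abs(pp$d - 0.5), 0.35)
  expect_lt(pp$p, 0.01)
})
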