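# Statistical comparison stages checked against closed-form oracles
# computed inline (independent of the wrapped routines).

test_that("paired t test matches the closed-form computation", {
  x <- c(10, 12, 9, 11, 13); y <- c(8, 11, 9, 10, 9)
  res <- paired_t_test(x, y)
  d <- x - y; n <- length(d)
  t_hand <- mean(d) / (sd(d) / sqrt(n))
  p_hand <- 2 * pt(-abs(t_hand), n - 1)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  # identical vectors
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  # constant nonzero differences -> degenerate flag
  deg <- paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(deg$degenerate)
  expect_error(paired_t_test(1:3, 1:4), "lengths differ")
})

test_that("Pearson r matches the product-moment formula", {
  x <- c(1, 2, 3, 5, 8, 9); y <- c(2, 1, 4, 6, 9, 8)
  res <- pearson_r(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(4 / (1 - r_hand^2))
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(x, rep(1, 6)), "constant")
})

test_that("2x2 chi-squared matches the hand formula and is row-swap invariant", {
  tab <- matrix(c(12, 5, 7, 11), 2)
  res <- chi2_2x2(tab)
  n <- sum(tab)
  hand <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab)) / prod(colSums(tab))
  expect_equal(res$chisq, hand, tolerance = 1e-12)
  expect_equal(res$p, pchisq(hand, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(chi2_2x2(tab[2:1, ])$chisq, res$chisq, tolerance = 1e-12)
  # perfect independence
  expect_equal(chi2_2x2(matrix(c(10, 10, 10, 10), 2))$chisq, 0)
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "degenerate")
})

test_that("dose dichotomization uses a strict threshold", {
  expect_identical(dichotomize_by_dose(c(150, 200, 201), 200),
                   c("low", "low", "high"))
  expect_identical(dichotomize_by_dose(c(300, 250), 200), c("high", "high"))
  d <- c(110, 250, 200, 199.9, 320)
  expect_equal(sum(dichotomize_by_dose(d, 200) == "high"), 2)
})

test_that("Kaplan-Meier estimate matches the hand product-limit", {
  # all events at t = 10
  res <- km_estimate(rep(10, 4), rep(1, 4))
  expect_equal(res$surv[res$time == 10], 0)
  expect_equal(res$median, 10)
  # all censored: S stays 1, median undefined
  res2 <- km_estimate(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(res2$surv == 1))
  expect_true(is.na(res2$median))
  # times (2, 3+, 5): S(2) = 2/3; at t = 5 the last subject at risk fails
  res3 <- km_estimate(c(2, 3, 5), c(1, 0, 1))
  expect_equal(res3$surv[res3$time == 2], 2 / 3, tolerance = 1e-12)
  expect_equal(res3$surv[res3$time == 5], 0, tolerance = 1e-12)
  # restricted mean over [0, 5]: 1 * 2 + (2/3) * 3
  expect_equal(res3$restricted_mean, 2 + 2, tolerance = 1e-9)
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(10)
  t <- sort(sample(1:50, 12))
  res <- km_estimate(t, rep(1, 12))
  emp <- vapply(res$time, function(u) mean(t > u), 0)
  expect_equal(res$surv, emp, tolerance = 1e-12)
})

test_that("log-rank matches a hand O-E tabulation and is time-scale invariant", {
  time <- c(1, 3, 5, 2, 4, 6); event <- rep(1, 6)
  group <- rep(c("A", "B"), each = 3)
  res <- logrank_test(time, event, group)
  # independent tabulation over distinct event times
  oe <- 0; v <- 0
  for (u in sort(unique(time[event == 1]))) {
    n1 <- sum(time >= u & group == "A"); n2 <- sum(time >= u & group == "B")
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & group == "A")
    n <- n1 + n2
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  expect_equal(res$chisq, oe^2 / v, tolerance = 1e-9)
  expect_equal(res$p, pchisq(oe^2 / v, 1, lower.tail = FALSE), tolerance = 1e-9)
  # common time rescaling leaves the statistic unchanged
  res_scaled <- logrank_test(time * 7.3, event, group)
  expect_equal(res_scaled$chisq, res$chisq, tolerance = 1e-12)
  # identical groups -> chi-squared 0
  res0 <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("A", "B"), 3))
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  # separated groups -> large statistic
  sep <- logrank_test(c(1, 2, 3, 50, 60, 70), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_lt(sep$p, 0.05)
  # no events -> degenerate
  expect_true(logrank_test(c(1, 2), c(0, 0), c("A", "B"))$degenerate)
})

test_that("dose-dependent cohorts separate PFS by log-rank with high power", {
  # exponential PFS means 286 vs 92 days; at 45/21 the test is well powered
  p <- cohort_params(phantom = small_spec())
  hits <- vapply(1:25, function(r) {
    co <- make_cohort(66, p, seed = 3000 + r * 101, imaging = FALSE,
                      group_sizes = c(high = 45, low = 21))
    lr <- logrank_test(co$survival$time_days, co$survival$event,
                       co$survival$group)
    lr$p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.8)
})

test_that("run_comparison assembles paired tests, groups and survival", {
  p <- cohort_params(phantom = small_spec())
  co <- make_cohort(16, p, seed = 21, imaging = FALSE, keep_cases = TRUE)
  # paired dose table from the truth blocks (MAA vs microsphere)
  rows <- lapply(seq_len(16), function(i) {
    cs <- co$cases[[i]]
    data.frame(case = i, compartment = c("tumor", "in_target"),
               dose_maa = cs$truth$dose_maa$dose_gy[1:2],
               dose_pet = cs$truth$dose_microsphere$dose_gy[1:2],
               lsf_maa = cs$truth$maa$lsf,
               lsf_pet = cs$truth$microsphere$lsf)
  })
  pd <- do.call(rbind, rows)
  rep <- run_comparison(pd, data.frame(case = co$survival$case,
                                       time_days = co$survival$time_days,
                                       event = co$survival$event))
  expect_named(rep$paired, c("in_target", "tumor"))
  expect_equal(rep$paired$tumor$n, 16)
  # MAA lung shunt is built to exceed the microsphere shunt
  expect_gt(rep$lsf$mean_difference, 0)
  expect_lt(rep$lsf$p, 0.05)
  # bias direction: MAA underestimates tumor dose, overestimates in-target
  expect_lt(rep$paired$tumor$t_test$mean_difference, 0)
  expect_gt(rep$paired$in_target$t_test$mean_difference, 0)
  expect_true(all(rep$groups$group %in% c("high", "low")))
  expect_s3_class(rep$km[[1]]$fit, "survfit")
})
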