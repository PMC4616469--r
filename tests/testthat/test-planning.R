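# Activity planning: inversions, the partition-model plan, BSA method and
# the lung-shunt reduction schedule.

test_that("activity for tumor dose matches the closed form and round-trips", {
  m <- fix_measurements(lsf = 0.05)  # f_tm = 0.95 * 800/1000 = 0.76
  a <- activity_for_tumor_dose(m, 120)
  expect_equal(a, 120 * 0.5 / (49.67 * 0.76), tolerance = 1e-12)
  expect_equal(round(a, 3), 1.589)
  expect_equal(activity_for_tumor_dose(m, 0), 0)
  # round trip at several targets
  for (d in c(50, 120, 300)) {
    rep <- dose_report(activity_for_tumor_dose(m, d), m)
    expect_equal(rep$dose_gy[rep$compartment == "tumor"], d, tolerance = 1e-9)
  }
})

test_that("tolerance activities invert the dose model with an unbounded sentinel", {
  m <- fix_measurements(lsf = 0.05)
  expect_equal(tolerance_activity(m, "lung", 20), 20 * 0.99 / (49.67 * 0.05),
               tolerance = 1e-12)
  expect_gt(tolerance_activity(m, "lung", 30), tolerance_activity(m, "lung", 20))
  m0 <- fix_measurements(lsf = 0)
  expect_identical(tolerance_activity(m0, "lung", 20), Inf)
})

test_that("partition-model plan recommends min(required, tolerances) and flags the cap", {
  m <- fix_measurements(lsf = 0.05)
  plan <- plan_partition_model(m)
  expect_true(plan$feasible)
  expect_identical(plan$limiting_constraint, NA_character_)
  expect_equal(plan$recommended_activity, plan$required_activity)
  expect_equal(plan$reduction_fraction, 0)
  expect_identical(plan$liver_limit_used, "in_target")
  # out-target tolerance at 86% of required -> 14% reduction
  c14 <- planning_constraints(use_out_target_limit = TRUE)
  req <- plan_partition_model(m, c14)$required_activity
  f_out <- 0.95 * 50 / 1000
  limit14 <- 0.86 * req * 49.67 * f_out / compartment_mass(300, "out_target")
  c14 <- planning_constraints(out_target_limit = limit14,
                              use_out_target_limit = TRUE)
  plan14 <- plan_partition_model(m, c14)
  expect_false(plan14$feasible)
  expect_identical(plan14$limiting_constraint, "out_target")
  expect_equal(plan14$reduction_fraction, 0.14, tolerance = 1e-9)
  # LSF above the exclusion threshold
  expect_error(plan_partition_model(fix_measurements(lsf = 0.25)),
               "excluded")
})

test_that("a small in-target volume switches to the out-target limit", {
  m <- partition_measurements(
    tumor = voi_measurement(500, total_counts = 800),
    in_target = voi_measurement(50, total_counts = 150),  # < 10% of liver
    out_target = voi_measurement(300, total_counts = 50),
    lsf = 0.05)
  expect_identical(plan_partition_model(m)$liver_limit_used, "out_target")
})

test_that("plan is invariant to the overall count scale", {
  m1 <- fix_measurements()
  m2 <- partition_measurements(
    voi_measurement(500, total_counts = 800 * 13),
    voi_measurement(1000, total_counts = 150 * 13),
    voi_measurement(300, total_counts = 50 * 13),
    lsf = 0.05)
  p1 <- plan_partition_model(m1); p2 <- plan_partition_model(m2)
  expect_equal(p1$recommended_activity, p2$recommended_activity, tolerance = 1e-12)
  expect_equal(p1$tolerance_activities, p2$tolerance_activities, tolerance = 1e-12)
})

test_that("doses at the recommended activity respect applicable limits (safety property)", {
  cons <- planning_constraints()
  for (m in random_measurements(300, seed = 77)) {
    plan <- plan_partition_model(m, cons)
    rep <- dose_report(plan$recommended_activity, m)
    expect_lte(rep$dose_gy[rep$compartment == "lung"], cons$lung_limit + 1e-9)
    lim <- if (plan$liver_limit_used == "in_target") cons$in_target_limit
           else cons$out_target_limit
    expect_lte(rep$dose_gy[rep$compartment == plan$liver_limit_used],
               lim + 1e-9)
  }
})

test_that("BSA activity matches an independent DuBois evaluation", {
  # hand-coded DuBois formula as the oracle
  dubois <- function(h, w) 0.007184 * w^0.425 * h^0.725
  expect_equal(bsa_activity(170, 70, 100, 1000),
               (dubois(170, 70) - 0.2) + 0.1, tolerance = 1e-12)
  expect_equal(dubois(170, 70), 1.8098, tolerance = 1e-4)
  expect_equal(bsa_activity(170, 70, 100, 1000), 1.7098, tolerance = 1e-4)
  # involvement -> 0 limit and monotonicity
  expect_equal(bsa_activity(170, 70, 1e-9, 1000), dubois(170, 70) - 0.2,
               tolerance = 1e-6)
  a_lo <- bsa_activity(170, 70, 100, 1000)
  a_hi <- bsa_activity(170, 70, 300, 1000)
  expect_gt(a_hi, a_lo)
  expect_error(bsa_activity(170, 70, 1200, 1000), "exceeds")
})

test_that("lung-shunt reduction applies the 0/20/40% bands and excludes at 0.2", {
  expect_equal(lsf_reduction(1.5, 0.05), 1.5)
  expect_equal(lsf_reduction(1.5, 0.12), 1.5 * 0.8)
  expect_equal(lsf_reduction(1.5, 0.18), 1.5 * 0.6)
  expect_equal(lsf_reduction(2, 0.1), 2 * 0.8)   # band edges
  expect_equal(lsf_reduction(2, 0.15), 2 * 0.6)
  expect_error(lsf_reduction(1, 0.22), "excluded")
  expect_error(lsf_reduction(1, 0.20), "excluded")
  # maximum reduction over admissible LSF is 40%
  grid <- seq(0, 0.199, by = 0.001)
  red <- vapply(grid, function(l) 1 - lsf_reduction(1, l), 0)
  expect_equal(max(red), 0.4)
})
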