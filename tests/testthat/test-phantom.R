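# Phantom synthesis: geometry, enforced LSF, acquisition simulation,
# planar projection.

test_that("phantom puts activity where the concentrations say and enforces the LSF", {
  # all concentration in the tumor -> all activity tumor-labeled, LSF 0
  spec <- small_spec(
    activity_concentration = list(
      maa = c(tumor = 2, in_target = 0, out_target = 0, lung = 0),
      microsphere = c(tumor = 2, in_target = 0, out_target = 0, lung = 0)),
    lsf_true = 0)
  ph <- build_phantom(spec, "maa")
  tum <- ph$labels == COMPARTMENTS[["tumor"]]
  expect_equal(sum(ph$values[tum]), sum(ph$values))
  expect_equal(sum(ph$values[ph$labels == COMPARTMENTS[["lung"]]]), 0)
  # lsf_true = 0.06 -> lung voxel-sum fraction exactly 0.06
  ph6 <- build_phantom(small_spec(lsf_true = 0.06), "maa")
  lung <- ph6$labels == COMPARTMENTS[["lung"]]
  expect_equal(sum(ph6$values[lung]) / sum(ph6$values), 0.06, tolerance = 1e-12)
  # per-label voxel sums are the ground-truth activities (bookkeeping)
  conc <- c(tumor = 3.5, in_target = 1, out_target = 1)
  for (nm in names(conc)) {
    sel <- ph6$labels == COMPARTMENTS[[nm]]
    expect_equal(sum(ph6$values[sel]), conc[[nm]] * ph6$voxel_volume * sum(sel),
                 tolerance = 1e-9)
  }
})

test_that("phantom construction is deterministic and validates geometry", {
  spec <- small_spec(lsf_true = 0.06)
  expect_identical(build_phantom(spec, "maa"), build_phantom(spec, "maa"))
  bad <- small_spec(geometry = data.frame(
    label = c("tumor", "in_target"), cx = c(100, 110), cy = c(100, 110),
    cz = c(100, 110), ax = c(40, 40), ay = c(40, 40), az = c(40, 40)))
  expect_error(build_phantom(bad, "maa"), "overlap")
  zero <- small_spec(activity_concentration = list(
    maa = c(tumor = 0, in_target = 0, out_target = 0, lung = 0),
    microsphere = c(tumor = 0, in_target = 0, out_target = 0, lung = 0)),
    lsf_true = 0)
  expect_error(build_phantom(zero, "maa"), "degenerate")
})

test_that("acquisition with no blur, no noise and full coverage is the identity", {
  ph <- build_phantom(small_spec(lsf_true = 0.03), "microsphere")
  out <- simulate_emission_image(ph, 0, 0, 1)
  expect_identical(out$values, ph$values)
  expect_identical(out$labels, ph$labels)
})

test_that("Gaussian blur conserves interior counts within 0.1%", {
  ph <- build_phantom(phantom_spec(lsf_true = 0.06), "maa")
  for (fwhm in c(10, 12)) {
    b <- simulate_emission_image(ph, psf_fwhm = fwhm, noise_scale = 0)
    expect_lt(abs(sum(b$values) - sum(ph$values)) / sum(ph$values), 0.001)
  }
})

test_that("Poisson noise is reproducible and unbiased around the blurred mean", {
  ph <- build_phantom(small_spec(lsf_true = 0.05), "maa")
  a <- simulate_emission_image(ph, 8, 100, 1, seed = 7)
  b <- simulate_emission_image(ph, 8, 100, 1, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, simulate_emission_image(ph, 8, 100, 1, seed = 8)$values))
  # across seeds the total counts match the blurred expectation within MC error
  mu <- sum(gaussian_blur(ph$values, 8, ph$voxel_size)) * 100
  tot <- vapply(1:50, function(s)
    sum(simulate_emission_image(ph, 8, 100, 1, seed = s)$values), 0)
  expect_lt(abs(mean(tot) - mu) / mu, 4 / sqrt(50 * mu) + 1e-3)
})

test_that("partial axial coverage keeps the liver and basal lungs only", {
  ph <- build_phantom(small_spec(lsf_true = 0.06), "microsphere")
  cropped <- simulate_emission_image(ph, 0, 0, coverage = 0.4)
  expect_lt(dim(cropped$values)[3], dim(ph$values)[3])
  # all liver labels survive the crop
  for (nm in c("tumor", "in_target", "out_target"))
    expect_equal(sum(cropped$labels == COMPARTMENTS[[nm]]),
                 sum(ph$labels == COMPARTMENTS[[nm]]))
  # about 40% of lung slices remain
  zs_full <- which(apply(ph$labels == COMPARTMENTS[["lung"]], 3, any))
  zs_crop <- which(apply(cropped$labels == COMPARTMENTS[["lung"]], 3, any))
  expect_equal(length(zs_crop), ceiling(0.4 * length(zs_full)))
})

test_that("planar projection sums along the AP axis with conjugate attenuation", {
  ph <- build_phantom(small_spec(lsf_true = 0.02), "maa")
  pp <- project_planar(ph, 0)
  axis_sum <- apply(ph$values, c(1, 3), sum)
  expect_equal(pp$anterior, axis_sum, tolerance = 1e-12)
  unmirrored <- pp$posterior[rev(seq_len(nrow(pp$posterior))), ]
  expect_equal(unmirrored, axis_sum, tolerance = 1e-12)
  # single voxel of activity a totals a in each view
  vals <- array(0, c(8, 8, 8)); labs <- array(0L, c(8, 8, 8))
  vals[3, 4, 5] <- 2.5; labs[3, 4, 5] <- COMPARTMENTS[["tumor"]]
  one <- activity_volume(vals, labs, c(4, 4, 4))
  p1 <- project_planar(one, 0)
  expect_equal(sum(p1$anterior), 2.5)
  expect_equal(sum(p1$posterior), 2.5)
})

test_that("conjugate geometric mean obeys the thin-source slab identity", {
  # thin source at depth d in a slab of thickness T:
  # sqrt(ant * post) = a * exp(-mu * T / 2) independent of d
  mu <- 0.015
  d <- c(8, 8, 8); vs <- c(4, 4, 4)
  Tmm <- d[2] * vs[2]
  for (iy in c(2, 4, 7)) {
    vals <- array(0, d); labs <- array(0L, d)
    vals[4, iy, 4] <- 3; labs[4, iy, 4] <- COMPARTMENTS[["tumor"]]
    vol <- activity_volume(vals, labs, vs)
    pp <- project_planar(vol, mu)
    gm <- sqrt(sum(pp$anterior) * sum(pp$posterior))
    expect_equal(gm, 3 * exp(-mu * Tmm / 2), tolerance = 1e-9)
  }
})

test_that("planar ROI masks assign lung and liver columns correctly", {
  ph <- build_phantom(small_spec(lsf_true = 0.06), "maa")
  pp <- project_planar(ph, 0)
  lung <- planar_roi(pp, ph$labels, "lung")
  liver <- planar_roi(pp, ph$labels, c("tumor", "in_target", "out_target"))
  expect_equal(lung_shunt_fraction(lung, liver), 0.06, tolerance = 0.005)
})
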