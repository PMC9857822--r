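test_that("lean body mass matches the sex-specific formulas", {
  expect_equal(compute_lbm(patient_physiology(80, 180, "male")),
               64.296, tolerance = 1e-4)
  expect_equal(compute_lbm(patient_physiology(60, 165, "female")),
               44.630, tolerance = 1e-4)
  # homogeneous limit: at vanishing weight (fixed frame) LBM vanishes
  expect_lt(compute_lbm(patient_physiology(1e-3, 180, "male",
                                           override = TRUE)), 1e-2)
})

test_that("physiology sanity bounds and degenerate LBM are rejected", {
  expect_error(patient_physiology(10, 180, "male"), "sanity")
  expect_error(patient_physiology(80, 90, "male"), "sanity")
  expect_silent(patient_physiology(10, 180, "male", override = TRUE))
  # extreme weight/height ratio drives the quadratic term negative
  expect_error(compute_lbm(patient_physiology(150, 120, "male")),
               "validity")
})

test_that("decay factor identities hold", {
  lam <- 0.693 / 6.0067
  expect_identical(decay_factor(lam, 0), 1)
  # one half-life back in time halves the activity (up to the 0.693
  # approximation of ln 2, which is 1.5e-4 relative)
  expect_equal(decay_factor(lam, -6.0067), 0.5000, tolerance = 2e-4)
  # exponential composition
  for (ab in list(c(1.5, 2.25), c(-3, 0.5), c(-0.1, -4))) {
    expect_equal(decay_factor(lam, ab[1]) * decay_factor(lam, ab[2]),
                 decay_factor(lam, sum(ab)))
  }
  expect_error(decay_factor(0, 1), "positive")
})

test_that("actual activity composes the decay cascade", {
  # all four timestamps equal: every factor is 1
  rec <- activity_record(800, 40, 0, 0, 0, 0)
  expect_equal(actual_activity(rec), 760)
  # scan one half-life after a coincident measure/inject/postinjection
  rec2 <- activity_record(800, 40, 0, 0, 0, 6.0067)
  expect_equal(actual_activity(rec2), 380.0, tolerance = 1e-3)
  # zero residual, equal timestamps: the administered dose itself
  rec3 <- activity_record(740, 0, 0, 0, 0, 0)
  expect_equal(actual_activity(rec3), 740)
})

test_that("actual activity accepts POSIXct timestamps", {
  t0 <- as.POSIXct("2022-03-01 09:00:00", tz = "UTC")
  rec <- activity_record(800, 40, t0, t0, t0, t0 + 6.0067 * 3600)
  expect_equal(actual_activity(rec), 380.0, tolerance = 1e-3)
})

test_that("activity record invariants are enforced", {
  expect_error(activity_record(800, 900, 0, 0, 0, 1), "exceeds")
  expect_error(activity_record(800, 40, 1, 0, 1, 2), "administered")
  expect_error(activity_record(800, 40, 0, 1, 0.5, 0.5), "scan")
  # residual back-decay can exceed the measured activity
  rec <- activity_record(100, 95, 0, 10, 10, 10)
  expect_error(actual_activity(rec), "exceeds measured")
})

test_that("SUV conversion applies the lean-body-mass formula voxelwise", {
  phys <- patient_physiology(80, 180, "male")
  rec <- activity_record(800, 40, 0, 0, 0, 0)  # actual = 760 MBq exactly
  av <- voxel_volume(array(5000, c(6, 6, 6)), 4)
  suv <- to_suv_volume(av, phys, rec)
  # 5000 Bq/mL * 64.2963 kg * 1000 / 7.6e8 Bq, computed by hand
  expect_equal(suv$values[1, 1, 1], 5000 * 64.2962963 * 1000 / 7.6e8,
               tolerance = 1e-10)
  expect_s3_class(suv, "suv_volume")
  expect_equal(suv$voxel_size_mm, av$voxel_size_mm)
})

test_that("SUV conversion is linear in concentration and activity", {
  phys <- patient_physiology(80, 180, "male")
  rec <- activity_record(800, 0, 0, 0, 0, 0)
  rec_half <- activity_record(400, 0, 0, 0, 0, 0)
  set.seed(3)
  vals <- array(runif(4^3, 0, 9000), c(4, 4, 4))
  av <- voxel_volume(vals, 4)
  av3 <- voxel_volume(3 * vals, 4)
  s1 <- to_suv_volume(av, phys, rec)
  expect_equal(to_suv_volume(av3, phys, rec)$values, 3 * s1$values)
  # halving the administered activity doubles every SUV
  expect_equal(to_suv_volume(av, phys, rec_half)$values, 2 * s1$values)
  # zero concentration maps to zero SUV
  expect_true(all(to_suv_volume(voxel_volume(array(0, c(4, 4, 4)), 4),
                                phys, rec)$values == 0))
})
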