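test_that("noise-free lesions convert back to their true SUV exactly", {
  cfg <- generator_config(seed = 4, grid_shape = c(32L, 32L, 32L))
  les <- lesion_spec(c(64, 64, 64), 10, true_suv = 10, site = "liver")
  gen <- generate_patient_volume(cfg, list(les))
  suv <- to_suv_volume(gen$volume, gen$physiology, gen$activity_record)
  m <- sphere_voxel_indices(suv, c(64, 64, 64), 10)
  expect_gt(nrow(m), 0)
  expect_equal(unique(suv$values[m[, "idx"]]), 10)
  # background voxels convert back to the background uptake
  far <- suv$values[1, 1, 1]
  expect_equal(far, cfg$background_uptake)
})

test_that("generation is bitwise reproducible under a fixed seed", {
  cfg <- generator_config(seed = 11, grid_shape = c(32L, 32L, 32L),
                          noise_cv = 0.05)
  les <- list(lesion_spec(c(40, 40, 40), 8, 12, "liver"),
              lesion_spec(c(90, 90, 90), 8, 6, "bone"))
  g1 <- generate_patient_volume(cfg, les)
  g2 <- generate_patient_volume(cfg, les)
  expect_identical(g1$volume$values, g2$volume$values)
})

test_that("overlapping spheres are rejected with the offending pair named", {
  cfg <- generator_config(grid_shape = c(32L, 32L, 32L))
  les <- list(lesion_spec(c(40, 40, 40), 10, 12, "liver"),
              lesion_spec(c(52, 40, 40), 10, 6, "bone"))
  expect_error(generate_patient_volume(cfg, les),
               "lesion_001.*lesion_002")
  # a sphere leaving the grid is also rejected
  expect_error(generate_patient_volume(
    cfg, list(lesion_spec(c(5, 40, 40), 10, 12, "liver"))),
    "inside the grid")
})

test_that("two-compartment lesions carry their analytic SUVpeak", {
  cfg <- generator_config(grid_shape = c(32L, 32L, 32L))
  les <- lesion_spec(c(64, 64, 64), 11, true_suv = 12,
                     site = "liver", true_suv_peak = 9)
  gen <- generate_patient_volume(cfg, list(les))
  suv <- to_suv_volume(gen$volume, gen$physiology, gen$activity_record)
  voi <- sphere_voi(c(64, 64, 64), 11)
  expect_equal(suv_max(suv, voi), 12)
  expect_equal(suv_peak(suv, voi), 9, tolerance = 1e-12)
  # unattainable peak targets are rejected
  expect_error(generate_patient_volume(
    cfg, list(lesion_spec(c(64, 64, 64), 11, 12, "liver",
                          true_suv_peak = 13))), "attainable")
})

test_that("truncated-normal calibration recovers the configured mean", {
  set.seed(101)
  draws <- spectsuv:::draw_lesion_pairs(600, "liver", 19)
  tab <- reference_uptake_table()
  liver <- tab[tab$site == "liver", ]
  se <- sd(draws$suv_max) / sqrt(nrow(draws))
  expect_lt(abs(mean(draws$suv_max) - liver$suv_max_mean), 3 * se)
  expect_true(all(draws$suv_max > 0))
  expect_true(all(draws$suv_peak <= draws$suv_max))
})

test_that("phantom measurement respects the deviation band", {
  # zero deviation: measured equals true exactly
  ph0 <- generate_phantom(phantom_spec(measurement_deviation = 0),
                          seed = 5)
  expect_equal(ph0$measured_concentration, ph0$true_concentration)
  # fixed seed: identical draws
  spec <- phantom_spec(measurement_deviation = 0.05)
  expect_identical(generate_phantom(spec, seed = 5),
                   generate_phantom(spec, seed = 5))
  expect_true(all(abs(generate_phantom(spec, seed = 9)$deviation_frac)
                  <= 0.05))
  # invalid concentrations are rejected at spec construction
  bad <- default_nema_spheres()
  bad$true_concentration[2] <- -10
  expect_error(phantom_spec(sphere_specs = bad), "positive")
})

test_that("cohort follow-ups reproduce requested summed-SUVmax changes", {
  co <- generate_cohort(21, 6, outcome_plan = list(
    trajectory_spec(c(1.4, 0.65)), trajectory_spec(0.6),
    trajectory_spec(1.0), trajectory_spec(c(0.85, 1.2)),
    trajectory_spec(0.5, new_lesions = TRUE), trajectory_spec(1.3)))
  sets <- cohort_target_sets(co)
  for (p in seq_along(co$plan)) {
    scans <- sets[[names(sets)[p]]]
    mult <- co$plan[[p]]$multipliers
    base_sum <- scans[[1]]$summed_suv_max
    for (k in seq_along(mult)) {
      if (co$plan[[p]]$new_lesions[k]) next  # new focus alters the sum
      got <- scans[[k + 1]]$summed_suv_max
      expect_lt(abs(got / (base_sum * mult[k]) - 1), 1e-3)
    }
  }
})

test_that("trajectories requesting CR with residual uptake are rejected", {
  expect_error(trajectory_spec(0.5, expect = "CR"), "CR")
  expect_error(trajectory_spec(c(1, 0), new_lesions = c(FALSE, TRUE),
                               expect = c("SD", "CR")), "CR")
  expect_silent(trajectory_spec(0, expect = "CR"))
})

test_that("an empty cohort yields valid empty tables", {
  co <- generate_cohort(1, 0)
  expect_equal(nrow(co$patients), 0)
  expect_equal(nrow(co$scans), 0)
  expect_equal(nrow(co$lesions), 0)
})

test_that("generated ki67 is independent of generated uptake", {
  co <- generate_cohort(33, 200, marker_mode = "bernoulli")
  base <- co$lesions[grepl("_S0$", co$lesions$scan_id), ]
  per_pat <- tapply(base$suv_max, base$patient_id, mean)
  ki <- co$patients$ki67_pct[match(names(per_pat),
                                   co$patients$patient_id)]
  expect_lt(abs(cor(ki, per_pat)), 0.2)
})

test_that("generator config invariants are enforced", {
  expect_error(generator_config(noise_cv = 1), "noise_cv")
  expect_error(generator_config(voxel_size_mm = 0), "positive")
  # grid must hold the 1-cm3 kernel
  expect_error(generator_config(voxel_size_mm = 4,
                                grid_shape = c(2L, 2L, 2L)), "kernel")
})
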