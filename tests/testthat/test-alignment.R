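# Estimator accuracy is exercised on stacks upsampled to the resolution at
# which section alignment operates (finer than the analysis voxel grid).

alignment_template <- function(seed = 1, factor = 4) {
  sc <- make_scene(scene_config(seed = seed))
  list(tmpl = upsample_mask(sc$striatum, factor),
       lm = upsample_mask(sc$landmark, factor))
}

test_that("roll is recovered from per-section midlines", {
  tp <- alignment_template(factor = 2)
  expect_lt(abs(estimate_roll(tp$tmpl)), 0.2)
  for (roll in c(5, -3)) {
    mis <- apply_misalignment(tp$tmpl, section_transform(roll_deg = roll))
    expect_lt(abs(estimate_roll(mis) - roll), 0.5)
  }
  # degenerate midline points are rejected
  pts <- cbind(section = 1, dv_d = 2, ml_d = 3, dv_v = 2, ml_v = 3)
  expect_error(estimate_roll(tp$tmpl, pts), "degenerate")
})

test_that("pitch and yaw are recovered from center-of-mass statistics", {
  tp <- alignment_template()
  py0 <- estimate_pitch_yaw(tp$tmpl, tp$tmpl)
  expect_lt(abs(py0$pitch_deg), 0.5)
  expect_lt(abs(py0$yaw_deg), 0.5)
  mis <- apply_misalignment(tp$tmpl, section_transform(yaw_deg = 4))
  expect_lt(abs(estimate_pitch_yaw(mis, tp$tmpl)$yaw_deg - 4), 1)
  mis <- apply_misalignment(tp$tmpl, section_transform(pitch_deg = 2))
  expect_lt(abs(estimate_pitch_yaw(mis, tp$tmpl)$pitch_deg - 2), 1)
  # a single-hemisphere stack cannot drive the hemisphere statistic
  half <- tp$tmpl$values
  half[, , seq_len(dim(half)[3] / 2)] <- FALSE
  expect_error(estimate_pitch_yaw(binary_mask(half, tp$tmpl$voxel_size_um),
                                  tp$tmpl), "hemispheres")
})

test_that("scales are recovered from moment extents", {
  tp <- alignment_template(factor = 2)
  expect_equal(scale_to_template(tp$tmpl, tp$tmpl)$scales, c(1, 1, 1),
               tolerance = 1e-6)
  mis <- apply_misalignment(tp$tmpl, section_transform(scale_ap = 1.2))
  expect_equal(scale_to_template(mis, tp$tmpl)$scales[1], 1.2,
               tolerance = 0.05 * 1.2)
  mis <- apply_misalignment(tp$tmpl, section_transform(scale_ml = 0.8))
  expect_equal(scale_to_template(mis, tp$tmpl)$scales[3], 0.8,
               tolerance = 0.05 * 0.8)
})

test_that("iterative alignment recovers planted jitter and never hurts Dice", {
  tp <- alignment_template(factor = 2)
  # template against itself: no shifts anywhere
  self <- iterative_com_align(tp$tmpl, tp$tmpl)
  expect_true(all(self$shifts == 0))

  set.seed(42)
  n <- dim(tp$tmpl$values)[1]
  jit <- random_section_jitter(n, 2, weights = apply(tp$tmpl$values, 1, sum))
  mis <- apply_misalignment(tp$tmpl,
                            section_transform(per_section_shifts = jit))
  al <- iterative_com_align(mis, tp$tmpl)
  expect_lte(max(abs(al$shifts + jit)[al$active, ]), 1)

  # a second round never decreases whole-stack Dice
  for (seed in 1:5) {
    set.seed(seed)
    jit <- random_section_jitter(n, 2,
                                 weights = apply(tp$tmpl$values, 1, sum))
    mis <- apply_misalignment(tp$tmpl,
                              section_transform(per_section_shifts = jit))
    one <- iterative_com_align(mis, tp$tmpl, n_rounds = 1)
    two <- iterative_com_align(mis, tp$tmpl, n_rounds = 2)
    expect_gte(two$dice[2] + 1e-9, one$dice[1])
  }
})

test_that("damaged sections are repaired from their neighbors", {
  v <- array(FALSE, dim = c(5, 4, 4))
  v[2, 1:2, 1:2] <- TRUE
  v[4, 1:2, 1:2] <- TRUE
  m <- binary_mask(v, 100)
  rep3 <- repair_damaged_section(m, 3)
  expect_identical(rep3$values[3, , ], v[2, , ])  # identical neighbors

  # neighbors {A, empty}: mean 0.5 is not strictly greater than 0.5
  v2 <- v
  v2[4, , ] <- FALSE
  rep2 <- repair_damaged_section(binary_mask(v2, 100), 3)
  expect_false(any(rep2$values[3, , ]))

  g <- array(0, dim = c(3, 2, 2))
  g[1, , ] <- 0.2
  g[3, , ] <- 0.4
  vol <- projection_volume(g, 100)
  expect_equal(repair_damaged_section(vol, 2)$values[2, 1, 1], 0.3)
  expect_error(repair_damaged_section(m, 1), "flanking")
})

test_that("a full composite misalignment is corrected end to end", {
  tp <- alignment_template(seed = 3)
  set.seed(33)
  n <- dim(tp$tmpl$values)[1]
  jit <- random_section_jitter(n, 1, weights = apply(tp$tmpl$values, 1, sum))
  tr <- section_transform(roll_deg = 3, pitch_deg = 2, yaw_deg = -2,
                          scale_ap = 1.05, scale_dv = 0.95, scale_ml = 1.08,
                          per_section_shifts = jit)
  mis <- apply_misalignment(tp$tmpl, tr)
  mis_lm <- apply_misalignment(tp$lm, tr)
  corr <- correct_misalignment(mis, tp$tmpl, landmark = mis_lm,
                               landmark_template = tp$lm)
  est <- corr$transform
  expect_lt(abs(est$roll_deg - 3), 1)
  expect_lt(abs(est$pitch_deg - 2), 1)
  expect_lt(abs(est$yaw_deg + 2), 1)
  expect_lt(abs(est$scale_ap - 1.05), 0.05)
  expect_lt(abs(est$scale_dv - 0.95), 0.05)
  expect_lt(abs(est$scale_ml - 1.08), 0.05)
  expect_gte(dice_coefficient(corr$stack, tp$tmpl), 0.9)
})
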