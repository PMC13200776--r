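test_that("symmetry ratio normalizes the affected by the healthy side", {
  expect_equal(compute_symmetry_ratio(6, 6), 1)
  expect_equal(compute_symmetry_ratio(0, 8), 0)
  expect_equal(compute_symmetry_ratio(3, 6), 0.5)
  # supranormal movement on the affected side is clipped to symmetric
  expect_equal(compute_symmetry_ratio(9, 6), 1)
  expect_error(compute_symmetry_ratio(-1, 6), "non-negative")
})

test_that("the dead zone treats sub-threshold motion as not evaluable", {
  # neither side moves: no asymmetry to score
  expect_equal(compute_symmetry_ratio(0.1, 0.2), 1)
  # only the affected side is below threshold: complete regional paresis
  expect_equal(compute_symmetry_ratio(0.3, 6), 0)
  # threshold is configurable
  expect_equal(compute_symmetry_ratio(0.3, 6, dead_zone = 0.2), 0.05)
})

test_that("the affected side is the one with smaller weighted amplitude", {
  amps <- data.frame(
    region = rep(c("forehead", "eye", "mouth"), each = 2),
    side = rep(c("left", "right"), 3),
    amplitude = c(2, 8, 2, 8, 2, 8)
  )
  expect_equal(detect_affected_side(amps), "left")
  expect_equal(detect_affected_side(amps, override = "right"), "right")

  # mixed picture: forehead worse left, mouth worse right; the mouth
  # carries five times the forehead weight, so the right side wins
  mixed <- data.frame(
    region = rep(c("forehead", "mouth"), each = 2),
    side = rep(c("left", "right"), 2),
    amplitude = c(1, 8, 8, 1)
  )
  # weighted means: left (0.1*1 + 0.5*8)/0.6 = 6.83, right 1.42
  expect_equal(detect_affected_side(mixed), "right")

  tie <- data.frame(region = c("eye", "eye"), side = c("left", "right"),
                    amplitude = c(5, 5))
  expect_error(detect_affected_side(tie), "ambiguous side")
})

test_that("the DFI is the 10/40/50 weighted composite of region ratios", {
  expect_equal(unname(dfi_weights()), c(0.10, 0.40, 0.50))
  expect_equal(sum(dfi_weights()), 1)

  batt <- make_planted_battery(
    c(forehead = 1, eye = 0.5, mouth = 0.5), affected = "left")
  res <- compute_dfi(batt, affected_side = "left")
  expect_equal(res$dfi_percent, 55, tolerance = 1e-9)
  expect_equal(unname(res$ratios[c("forehead", "eye", "mouth")]),
               c(1, 0.5, 0.5))
  expect_equal(res$affected_side, "left")

  symmetric <- make_planted_battery(c(forehead = 1, eye = 1, mouth = 1))
  expect_equal(compute_dfi(symmetric,
                           affected_side = "left")$dfi_percent, 100)
  paretic <- make_planted_battery(c(forehead = 0, eye = 0, mouth = 0),
                                  affected = "left")
  expect_equal(compute_dfi(paretic, affected_side = "left")$dfi_percent, 0)
})

test_that("an incomplete battery is rejected with the missing regions", {
  face <- make_face("forehead")
  rec <- make_recording("eyebrow_elevation", face)
  expect_error(compute_dfi(list(rec)), "incomplete task battery.*eye.*mouth")
})

test_that("DFI is a convex combination and monotone in each ratio", {
  set.seed(11)
  for (i in 1:10) {
    r <- runif(3)
    batt <- make_planted_battery(
      c(forehead = r[1], eye = r[2], mouth = r[3]), affected = "left")
    dfi <- compute_dfi(batt, affected_side = "left")$dfi_percent
    expect_gte(dfi, 100 * min(r) - 1e-9)
    expect_lte(dfi, 100 * max(r) + 1e-9)

    # raising one region's ratio strictly raises the composite
    j <- sample(3, 1)
    r2 <- r
    r2[j] <- min(1, r[j] + 0.2)
    if (r2[j] > r[j]) {
      batt2 <- make_planted_battery(
        c(forehead = r2[1], eye = r2[2], mouth = r2[3]), affected = "left")
      expect_gt(compute_dfi(batt2, affected_side = "left")$dfi_percent, dfi)
    }
  }
})

test_that("planted severities are recovered exactly without noise", {
  set.seed(12)
  for (i in 1:5) {
    sev <- runif(3, 0.2, 1)  # above the dead zone
    cfg <- simulation_config(severity = sev, affected_side = "left",
                             landmark_noise_sd = 0, seed = 100 + i)
    res <- compute_dfi(simulate_battery(cfg), affected_side = "left")
    expect_equal(res$dfi_percent, 100 * sum(dfi_weights() * sev),
                 tolerance = 1e-6)
  }
})

test_that("mirroring the palsy to the other hemiface leaves the DFI fixed", {
  sev <- c(forehead = 0.8, eye = 0.4, mouth = 0.6)
  left <- compute_dfi(simulate_battery(
    simulation_config(sev, affected_side = "left", seed = 5)),
    affected_side = "left")
  right <- compute_dfi(simulate_battery(
    simulation_config(sev, affected_side = "right", seed = 5)),
    affected_side = "right")
  expect_equal(left$dfi_percent, right$dfi_percent, tolerance = 1e-9)
})

test_that("exercise accuracy is achieved over reference, capped at 100", {
  face <- make_face("mouth")
  rec <- make_recording("show_teeth", face,
                        displacements = list(mouth1L = c(0, 4, 0)))
  expect_equal(exercise_accuracy(rec, 4, "left"), 100)
  expect_equal(exercise_accuracy(rec, 8, "left"), 50)
  still <- make_recording("show_teeth", face)
  expect_equal(exercise_accuracy(still, 4, "left"), 0)
  rec3 <- make_recording("show_teeth", face,
                         displacements = list(mouth1L = c(0, 3, 0)))
  expect_equal(exercise_accuracy(rec3, 4, "left"), 75)
  expect_error(exercise_accuracy(rec, 0, "left"), "positive")
})
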