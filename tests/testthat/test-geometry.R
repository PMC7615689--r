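test_that("training angle grids match the task definitions", {
  expect_equal(build_training_angles(22.5), c(0, 22.5, 45, 67.5, 90))
  a2 <- build_training_angles(2)
  expect_length(a2, 46L)
  expect_equal(a2, seq(0, 90, by = 2))
  expect_equal(build_training_angles(90), c(0, 90))
  expect_equal(build_training_angles(18), c(0, 18, 36, 54, 72, 90))
  # non-divisor nominal spacing snaps to the nearest uniform grid
  a4 <- build_training_angles(6.425)
  expect_length(a4, 15L)
  expect_equal(diff(a4), rep(90 / 14, 14))
  expect_error(build_training_angles(0), "0, 90")
  expect_error(build_training_angles(95), "0, 90")
})

test_that("angle grids always contain the endpoints, sorted and duplicate-free", {
  for (d in c(2, 5, 6.425, 11.25, 13, 18, 22.5, 30, 45, 90)) {
    a <- build_training_angles(d)
    expect_equal(a[1], 0)
    expect_equal(a[length(a)], 90)
    expect_false(is.unsorted(a, strictly = TRUE))
  }
})

test_that("neighbour spacing summary reproduces the design ladder values", {
  s <- neighbour_spacing_summary(c(22.5, 18, 11.25, 6.425, 2))
  expect_lt(abs(s$mean - 5.13), 0.005)
  expect_lt(abs(s$se - 0.55), 0.005)
  expect_true(s$se_defined)
  expect_warning(s2 <- neighbour_spacing_summary(c(10, 5)), "undefined")
  expect_equal(s2$mean, 5)
  expect_equal(s2$se, 0)
  expect_false(s2$se_defined)
  s3 <- neighbour_spacing_summary(c(9, 6, 3))
  expect_equal(s3$mean, 3)
  expect_equal(s3$se, 0)
  expect_error(neighbour_spacing_summary(7), "two delta")
})

test_that("session schedules are balanced and respect the consecutive constraint", {
  specs <- training_task_specs()
  # Train-I: 600 streets over 5 angles, exactly 120 each
  s1 <- schedule_training_session(specs[["Train-I"]], seed = 4)
  expect_equal(nrow(s1), 600L)
  expect_true(all(table(s1$angle) == 120L))
  # Train-V: 600 over 46 angles, counts differ by at most 1
  s5 <- schedule_training_session(specs[["Train-V"]], seed = 4)
  tab <- table(s5$angle)
  expect_length(tab, 46L)
  expect_true(all(tab %in% c(13L, 14L)))
  # constraint across the whole sequence including trial boundaries
  expect_true(all(abs(diff(s1$angle)) >= 22.5 - 1e-9))
  expect_true(all(abs(diff(s5$angle)) >= 22.5 - 1e-9))
  # determinism
  expect_identical(schedule_training_session(specs[["Train-II"]], seed = 9),
                   schedule_training_session(specs[["Train-II"]], seed = 9))
})

test_that("scheduling fails cleanly when the constraint cannot be met", {
  spec <- training_task_spec("toy", 90, n_trials = 2L, streets_per_trial = 3L,
                             min_consecutive_difference = 120)
  expect_error(schedule_training_session(spec, seed = 1), "infeasible")
})

test_that("transfer variants reflect the base curves about the window axes", {
  W <- 16 / 9
  s <- build_transfer_streets("S", window_width = W)
  m <- build_transfer_streets("M", window_width = W)
  l <- build_transfer_streets("L", window_width = W)
  for (k in 1:6) {
    cs <- s[[k]]$centreline; cm <- m[[k]]$centreline; cl <- l[[k]]$centreline
    expect_equal(cm[, 1], W - cs[, 1])
    expect_equal(cm[, 2], cs[, 2])
    expect_equal(cl[, 1], W - cs[, 1])
    expect_equal(cl[, 2], 1 - cs[, 2])
    # involution: flipping the M curves back restores S (to the last ulp;
    # W - (W - x) is not guaranteed bit-exact in IEEE arithmetic)
    expect_equal(W - cm[, 1], cs[, 1], tolerance = 1e-15)
    # reflections are isometries
    expect_equal(arc_length(cm), arc_length(cs))
    expect_equal(arc_length(cl), arc_length(cs))
  }
  expect_equal(transfer_variant("S")$directions, c(1, 1))
  expect_equal(transfer_variant("M")$directions, c(-1, 1))
  expect_equal(transfer_variant("L")$directions, c(-1, -1))
})

test_that("point-to-ideal distance: Heron construction and nearest neighbour", {
  st0 <- straight_street(0, start = c(0, 0))
  expect_equal(point_to_ideal_distance(c(0.1, 0.05), st0), 0.05)
  expect_equal(point_to_ideal_distance(c(0.25, 0), st0), 0)
  st45 <- straight_street(45, start = c(0.2, 0.2))
  on_line <- c(0.2, 0.2) + 0.3 * c(cos(pi / 4), sin(pi / 4))
  expect_equal(point_to_ideal_distance(on_line, st45), 0, tolerance = 1e-12)
  expect_error(point_to_ideal_distance(c(0, 0),
                                       structure(list(start = c(0, 0), end = c(0, 0)),
                                                 class = c("straight_street", "street"))),
               "degenerate")
})

test_that("Heron and nearest-neighbour distances agree on straight streets", {
  # oracle equivalence: the polyline discretisation of the same ideal line
  set.seed(71)
  for (rep in 1:20) {
    ang <- runif(1, 0, 90)
    st <- straight_street(ang, start = c(0.2, 0.2))
    poly <- curved_street(resample_centreline(rbind(st$start, st$end), 5e-4),
                          width = st$width)
    for (j in 1:5) {
      t <- runif(1, 0.05, 0.95)
      offset <- runif(1, 0.005, 0.05) * sample(c(-1, 1), 1)
      theta <- ang * pi / 180
      p <- st$start + t * st$length * c(cos(theta), sin(theta)) +
        offset * c(-sin(theta), cos(theta))
      expect_lt(abs(point_to_ideal_distance(p, st) -
                      point_to_ideal_distance(p, poly, spacing = 5e-4)),
                1e-4)
    }
  }
})
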