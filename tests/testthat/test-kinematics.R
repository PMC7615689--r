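test_that("the control law accumulates and decays velocity linearly", {
  cfg <- kinematics_config()
  s <- cursor_state(c(0.2, 0.2))
  # no keys from rest: nothing moves
  for (i in 1:10) s <- cursor_step(s, c(FALSE, FALSE), cfg)
  expect_equal(s$velocity, c(0, 0))
  expect_equal(s$position, c(0.2, 0.2))
  # holding one key n frames from rest: v = min(n * accel, vmax)
  s <- cursor_state(c(0, 0))
  for (i in 1:50) s <- cursor_step(s, c(TRUE, FALSE), cfg)
  expect_equal(s$velocity[1], 50 * 0.001)
  for (i in 1:400) s <- cursor_step(s, c(TRUE, FALSE), cfg)
  expect_equal(s$velocity[1], 0.3) # capped
  # release: exactly 300 frames back to zero
  n_decay <- 0L
  while (s$velocity[1] > 0) {
    s <- cursor_step(s, c(FALSE, FALSE), cfg)
    n_decay <- n_decay + 1L
  }
  expect_equal(n_decay, 300L)
})

test_that("velocity stays within bounds under arbitrary key sequences", {
  cfg <- kinematics_config()
  set.seed(5)
  s <- cursor_state(c(0, 0))
  for (i in 1:2000) {
    s <- cursor_step(s, runif(2) < 0.7, cfg)
    expect_true(all(s$velocity >= 0 & s$velocity <= cfg$max_velocity))
  }
})

test_that("a passive policy aborts at the frame cap without resets", {
  cfg <- kinematics_config(frame_cap = 200L)
  tr <- simulate_street(never_press, straight_street(45), cfg)
  expect_equal(tr$outcome, "aborted")
  expect_equal(tr$n_resets, 0L)
  expect_true(is.na(tr$onset_frame))
})

test_that("symmetric key alternation tracks the 45-degree ideal line", {
  tr <- simulate_street(both_keys, straight_street(45), kinematics_config())
  expect_equal(tr$outcome, "completed")
  expect_equal(tr$n_resets, 0L)
  expect_lt(street_error(tr), 2e-3)
})

test_that("driving only one axis on a perpendicular street hits the wall", {
  tr <- simulate_street(horizontal_only, straight_street(90),
                        kinematics_config(frame_cap = 500L))
  expect_gte(tr$n_resets, 1L)
})

test_that("completion requires reaching the end zone", {
  cfg <- kinematics_config()
  st <- straight_street(45)
  tr <- simulate_street(both_keys, st, cfg)
  dense <- resample_centreline(street_centreline(st), 0.002)
  cumlen <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  last <- unlist(tr$frames[nrow(tr$frames), c("x", "y")])
  d2 <- (dense[, 1] - last[1])^2 + (dense[, 2] - last[2])^2
  expect_gte(cumlen[which.min(d2)],
             (1 - cfg$end_zone_fraction) * cumlen[length(cumlen)])
})

test_that("simulation is deterministic given the seed", {
  ag <- default_agent()
  pol <- steering_policy(ag, trial_index = 3)
  st <- straight_street(30)
  t1 <- simulate_street(pol, st, seed = 17)
  t2 <- simulate_street(pol, st, seed = 17)
  expect_identical(t1$frames, t2$frames)
  t3 <- simulate_street(pol, st, seed = 18)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("compiled and reference simulators produce identical trajectories", {
  ag <- default_agent()
  cfg <- kinematics_config()
  cases <- list(
    list(street = straight_street(30), dirs = c(1, 1), trial = 5L, flips = 0L),
    list(street = straight_street(75), dirs = c(1, 1), trial = 40L, flips = 0L),
    list(street = build_transfer_streets("M")[[2]], dirs = c(-1, 1),
         trial = 1L, flips = 1L)
  )
  for (cs in cases) {
    pol <- steering_policy(ag, trial_index = cs$trial, n_flips = cs$flips)
    tr_r <- simulate_street(pol, cs$street, cfg, directions = cs$dirs,
                            seed = 99)
    entry <- streetnav:::street_cache_entry(cs$street)
    st <- streetnav:::agent_trial_state(ag, cs$trial, effect_config(),
                                        cs$flips)
    res <- streetnav:::with_seed(99, streetnav:::sim_street_fast(
      entry, cfg, cs$dirs, st$speed, st$sigma, ag$noise_floor, 1, 1,
      record = TRUE))
    expect_equal(tr_r$outcome == "completed", res$completed)
    expect_equal(tr_r$n_resets, res$n_resets)
    expect_equal(nrow(tr_r$frames), nrow(res$frames))
    expect_equal(as.matrix(tr_r$frames[, c("x", "y", "vx", "vy")]),
                 as.matrix(res$frames[, c("x", "y", "vx", "vy")]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    if (res$completed) {
      expect_equal(movement_time(tr_r), res$movement_time)
      expect_equal(street_error(tr_r), res$error, tolerance = 1e-9)
    }
  }
})
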