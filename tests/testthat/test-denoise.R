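test_that("street difficulty profile is the per-angle grand mean", {
  ss <- data.frame(angle = rep(c(0, 45, 90), each = 4),
                   error = rep(0.02, 12))
  prof <- street_difficulty_profile(ss, "error")
  expect_equal(prof$difficulty, rep(0.02, 3))
  ss2 <- data.frame(angle = c(0, 0, 45, 90), error = c(1, 3, 5, 7))
  prof2 <- street_difficulty_profile(ss2, "error")
  expect_equal(prof2$difficulty, c(2, 5, 7))
  expect_error(street_difficulty_profile(ss2, "error",
                                         angles = c(0, 22.5, 45, 90)),
               "missing-angle")
})

test_that("trial difficulty averages the street difficulties", {
  prof <- data.frame(angle = c(0, 90), difficulty = c(1, 3))
  sched <- data.frame(trial = rep(1:2, each = 6),
                      angle = rep(c(0, 90), 6))
  expect_equal(trial_difficulty(sched, prof), c(2, 2))
  sched2 <- data.frame(trial = rep(1, 6), angle = c(0, 0, 0, 0, 90, 90))
  expect_equal(trial_difficulty(sched2, prof), 1 + 2 / 3)
})

test_that("denoising removes exactly the difficulty-predicted component", {
  set.seed(9)
  diff <- runif(40, 1, 3)
  # group performance exactly beta * difficulty + c: denoised means constant
  gm <- 2.5 * diff + 1
  subj <- rbind(gm + 0.1, gm - 0.1, gm)
  den <- denoise_trials(subj, diff)
  expect_equal(colMeans(den), rep(mean(gm), 40))
  # slope zero: output equals input
  gm0 <- rep(2, 40)
  subj0 <- rbind(gm0 + 0.3, gm0 - 0.3)
  den0 <- denoise_trials(subj0, diff, group_means = gm0)
  expect_equal(den0, subj0)
  # orthogonality of the denoised group means to difficulty
  noisy <- rbind(gm + rnorm(40, 0, 0.2), gm + rnorm(40, 0, 0.2),
                 gm + rnorm(40, 0, 0.2))
  dn <- denoise_trials(noisy, diff)
  expect_lt(abs(cor(colMeans(dn), diff)), 1e-10)
})

test_that("denoising loses no data and preserves between-subject variance", {
  set.seed(10)
  subj <- matrix(rnorm(25 * 30, 10), nrow = 25)
  diff <- runif(30, 1, 2)
  den <- denoise_trials(subj, diff)
  expect_equal(dim(den), dim(subj))
  expect_equal(apply(den, 2, var), apply(subj, 2, var))
  # idempotence
  den2 <- denoise_trials(den, diff)
  expect_lt(max(abs(den2 - den)), 1e-10)
})

test_that("degenerate difficulty returns the input with a warning", {
  subj <- matrix(rnorm(40), nrow = 4)
  expect_warning(out <- denoise_trials(subj, rep(1.5, 10)), "constant")
  expect_identical(out, subj)
})

test_that("strict-literal residual mode also removes the learning trend", {
  set.seed(12)
  diff <- runif(50, 1, 3)
  trend <- seq(5, 1, length.out = 50) # learning-related decline
  gm <- trend + 0.5 * diff
  subj <- rbind(gm, gm + 0.2)
  fitted_mode <- denoise_trials(subj, diff)
  resid_mode <- denoise_trials(subj, diff, mode = "residual")
  # fitted mode keeps the learning trend in the group mean
  expect_gt(abs(cor(colMeans(fitted_mode), trend)), 0.9)
  # residual mode subtracts the raw residuals, so the group mean collapses
  # onto the difficulty-predicted line (learning-related variance removed)
  gfit <- lm(colMeans(subj) ~ diff)
  expect_equal(colMeans(resid_mode), unname(fitted(gfit)))
})

test_that("simulated cohorts show the band-shaped difficulty profile", {
  # intermediate angles (10-40, 50-80 degrees) harder than 0, 45 and 90
  spec <- training_task_spec("t", 11.25, n_trials = 40L)
  sch <- schedule_training_session(spec, 3)
  errs <- list()
  for (i in 1:4) {
    ag <- default_agent(seed = i)
    ses <- simulate_training_session(ag, sch, seed = 100 + i)
    errs[[i]] <- ses$streets[ses$streets$completed, ]
  }
  prof <- street_difficulty_profile(do.call(rbind, errs), "error")
  band <- prof$difficulty[prof$angle %in% c(22.5, 33.75, 56.25, 67.5)]
  easy <- prof$difficulty[prof$angle %in% c(0, 45, 90)]
  expect_gt(min(band), max(easy))
})
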