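test_that("population sampling fills the full design deterministically", {
  spec <- population_spec(master_seed = 11L)
  pop <- sample_population(spec)
  expect_equal(nrow(pop), 450L)
  tab <- table(pop$training_task, pop$transfer_variant)
  expect_equal(dim(tab), c(5L, 3L))
  expect_true(all(tab == 30L))
  expect_identical(pop, sample_population(population_spec(master_seed = 11L)))
  pop1 <- sample_population(population_spec(n_per_group = 1L))
  expect_equal(nrow(pop1), 15L)
  expect_error(population_spec(n_per_group = 0L), "positive")
})

test_that("competence is positively rank-correlated with baseline skill", {
  pop <- sample_population(population_spec(master_seed = 3L))
  rho <- cor(pop$competence, pop$baseline_skill, method = "spearman")
  expect_gt(rho, 0.15)
  expect_true(all(pop$competence %in% 1:3))
  expect_true(all(pop$baseline_skill > 0 & pop$baseline_skill <= 1))
  # null world removes the coupling
  pop0 <- sample_population(population_spec(effects = null_effects(),
                                            master_seed = 3L))
  expect_lt(abs(cor(pop0$competence, pop0$baseline_skill,
                    method = "spearman")), 0.12)
})

test_that("a noise-free non-learning agent scores identically on repeated trials", {
  ag <- agent_params(baseline_skill = 0.6, learning_rate = 0,
                     motor_noise_sd = 0, noise_floor = 0)
  sch <- data.frame(trial = rep(1:3, each = 2L), street = rep(1:2, 3L),
                    angle = rep(c(30, 60), 3L))
  ses <- simulate_training_session(ag, sch, seed = 2)
  tr <- ses$trials
  expect_equal(tr$movement_time, rep(tr$movement_time[1], 3))
  expect_equal(tr$error, rep(tr$error[1], 3))
})

test_that("learning produces decreasing error over trials", {
  spec <- training_task_spec("t", 22.5, n_trials = 60L)
  sch <- schedule_training_session(spec, 5)
  ses <- simulate_training_session(default_agent(lr = 0.04), sch, seed = 21)
  slope <- coef(lm(error ~ trial, ses$trials))[["trial"]]
  expect_lt(slope, 0)
})

test_that("higher baseline skill yields shorter movement times", {
  spec <- training_task_spec("t", 22.5, n_trials = 20L)
  sch <- schedule_training_session(spec, 5)
  slow <- agent_params(baseline_skill = 0.35, learning_rate = 0.02)
  fast <- agent_params(baseline_skill = 0.85, learning_rate = 0.02)
  mt_slow <- mean(simulate_training_session(slow, sch, seed = 3)$trials$movement_time)
  mt_fast <- mean(simulate_training_session(fast, sch, seed = 3)$trials$movement_time)
  expect_lt(mt_fast, mt_slow)
})

test_that("transposition leaks learned improvement but not baseline ability", {
  ag <- default_agent()
  eff <- effect_config()
  pre_S <- streetnav:::agent_trial_state(ag, 1L, eff, n_flips = 0L)
  pre_L <- streetnav:::agent_trial_state(ag, 1L, eff, n_flips = 2L)
  expect_equal(pre_S$sigma, pre_L$sigma) # untrained: variants comparable
  post_S <- streetnav:::agent_trial_state(ag, 101L, eff, n_flips = 0L)
  post_M <- streetnav:::agent_trial_state(ag, 101L, eff, n_flips = 1L)
  post_L <- streetnav:::agent_trial_state(ag, 101L, eff, n_flips = 2L)
  expect_lt(post_S$sigma, post_M$sigma)
  expect_lt(post_M$sigma, post_L$sigma)
  expect_lt(post_L$sigma, pre_L$sigma) # some transfer remains
  # null world: no leak at all
  post_L0 <- streetnav:::agent_trial_state(ag, 101L, null_effects(), 2L)
  expect_equal(post_L0$sigma,
               streetnav:::agent_trial_state(ag, 101L, null_effects(), 0L)$sigma)
})

test_that("learning-rate recovery from a handful of agents is unbiased enough", {
  spec <- training_task_spec("t", 11.25, n_trials = 100L)
  sch <- schedule_training_session(spec, 11)
  set.seed(404)
  lr_true <- exp(log(0.02) + 0.35 * rnorm(8))
  rel <- numeric(8)
  for (i in 1:8) {
    ag <- default_agent(lr = lr_true[i])
    ses <- simulate_training_session(ag, sch, seed = 500 + i)
    est <- fit_learning_curve(ses$streets[ses$streets$completed, ])
    rel[i] <- abs(est$rate - lr_true[i]) / lr_true[i]
  }
  expect_lt(median(rel), 0.4)
})
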