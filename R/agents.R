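# Synthetic participant model.
#
# The study measured humans; for simulation we need a generative stand-in.
# Each agent steers towards a look-ahead point on the street centreline with
# zero-mean angular noise whose SD decays exponentially over trials
# (exponential law of practice), and regulates its speed towards a target
# that grows with the same learning curve. Angular noise is additionally
# scaled by a street-angle difficulty term (smallest at 0, 45 and 90 degrees,
# where the required key ratio is trivial, largest in between) and by a
# transposition cost on transfer variants with remapped cursor directions.

#' Agent parameters
#'
#' @param baseline_skill speed-scaling skill in `(0, 1]`; the agent's speed
#'   target is `speed_base * (baseline_skill + asymptote_gain * (1 -
#'   exp(-learning_rate * (t - 1))))` height units/frame on trial `t`.
#' @param learning_rate per-trial exponential learning rate (>= 0), shared by
#'   the speed gain and the decay of steering noise.
#' @param asymptote_gain additional speed fraction gained at asymptote (>= 0).
#' @param motor_noise_sd initial SD of the angular steering noise, degrees.
#' @param noise_floor asymptotic (residual) angular noise SD, degrees.
#' @param competence self-reported bimanual competence, integer 1 (basic) to
#'   3 (expert).
#' @param rng_seed integer seed driving this agent's simulation randomness.
#' @return object of class `agent_params`.
#' @export
agent_params <- function(baseline_skill, learning_rate, asymptote_gain = 0.2,
                         motor_noise_sd = 25, noise_floor = 1,
                         competence = 2L, rng_seed = 1L) {
  stopifnot(baseline_skill > 0, baseline_skill <= 1, learning_rate >= 0,
            asymptote_gain >= 0, motor_noise_sd >= 0, noise_floor >= 0,
            competence %in% 1:3)
  structure(list(baseline_skill = baseline_skill,
                 learning_rate = learning_rate,
                 asymptote_gain = asymptote_gain,
                 motor_noise_sd = motor_noise_sd,
                 noise_floor = noise_floor,
                 competence = as.integer(competence),
                 rng_seed = as.integer(rng_seed)),
            class = "agent_params")
}

#' Policy/effect configuration for the agent model
#'
#' All group-level effects are configuration, never hard-coded, so both a
#' structured ("alternative") world and a flat null world can be simulated:
#' `null_effects()` zeroes every effect.
#'
#' @param speed_base full-skill speed target in height units/frame.
#' @param lookahead look-ahead distance along the centreline (height units).
#' @param difficulty_gain weight of the street-angle difficulty term: the
#'   steering-noise SD is scaled by
#'   `(1 - difficulty_gain) + difficulty_gain * |sin(4 * angle)|`, which at
#'   full weight (1) silences learnable noise on one-hand (0, 90 degree) and
#'   symmetric (45 degree) streets and peaks at 22.5/67.5 degrees; 0 disables
#'   the term.
#' @param remap_cost transposition cost on transfer tasks: the fraction of
#'   the training-related steering-noise reduction that fails to transfer
#'   when cursor directions are remapped,
#'   `min(1, remap_cost * sqrt(n_flips))` (sublinear in the number of
#'   flipped axes: remapping one hand's direction already disrupts the
#'   learned coordination of both). 0 gives full transfer (null world).
#' @param task_lr_mult named multiplier of `learning_rate` per training task.
#' @param competence_lr_gain relative learning-rate shift per competence
#'   level away from the middle level.
#' @param competence_skill_rho rank correlation between competence and
#'   baseline skill in the population.
#' @return object of class `effect_config`.
#' @export
effect_config <- function(speed_base = 0.015, lookahead = 0.05,
                          difficulty_gain = 1.0, remap_cost = 0.35,
                          task_lr_mult = c("Train-I" = 1.5, "Train-II" = 1.0,
                                           "Train-III" = 1.0, "Train-IV" = 0.7,
                                           "Train-V" = 0.7),
                          competence_lr_gain = 0.15,
                          competence_skill_rho = 0.4) {
  structure(list(speed_base = speed_base, lookahead = lookahead,
                 difficulty_gain = difficulty_gain, remap_cost = remap_cost,
                 task_lr_mult = task_lr_mult,
                 competence_lr_gain = competence_lr_gain,
                 competence_skill_rho = competence_skill_rho),
            class = "effect_config")
}

#' Null-world effect configuration
#'
#' Disables all group-level effects (task learning-rate shifts, transposition
#' cost, competence effects) so that downstream group statistics are null.
#' @param ... overrides passed to [effect_config()].
#' @return an [effect_config()].
#' @export
null_effects <- function(...) {
  effect_config(remap_cost = 0,
                task_lr_mult = c("Train-I" = 1, "Train-II" = 1,
                                 "Train-III" = 1, "Train-IV" = 1,
                                 "Train-V" = 1),
                competence_lr_gain = 0, competence_skill_rho = 0, ...)
}

#' Population specification
#'
#' The standard cohort is the full crossing of 5 training tasks x 3 transfer
#' variants with 30 agents per cell (450 agents).
#'
#' @param n_per_group agents per design cell.
#' @param training_tasks training-task names.
#' @param transfer_variants transfer-variant names.
#' @param effects an [effect_config()].
#' @param master_seed integer master seed; all per-agent and per-stage seeds
#'   derive from it.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_per_group = 30L,
                            training_tasks = c("Train-I", "Train-II",
                                               "Train-III", "Train-IV",
                                               "Train-V"),
                            transfer_variants = c("S", "M", "L"),
                            effects = effect_config(),
                            master_seed = 20230L) {
  if (n_per_group < 1L) stop("n_per_group must be positive")
  structure(list(n_per_group = as.integer(n_per_group),
                 training_tasks = training_tasks,
                 transfer_variants = transfer_variants,
                 effects = effects,
                 master_seed = as.integer(master_seed)),
            class = "population_spec")
}

# splittable seed derivation: deterministic 31-bit stream per (label, index)
derive_seed <- function(master_seed, label, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", index))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(master_seed) * 2654435761) %% 2147483647)
}

#' Sample a synthetic population
#'
#' Draws agent parameters for every design cell. Competence (1-3) is coupled
#' to baseline skill through a Gaussian copula with the configured rank
#' correlation; per-task learning-rate multipliers and the competence
#' learning-rate gain are applied from the effect configuration.
#'
#' @param spec a [population_spec()].
#' @return data.frame with one row per agent: `subject_id`, `training_task`,
#'   `transfer_variant`, `competence`, `baseline_skill`, `learning_rate`,
#'   `asymptote_gain`, `motor_noise_sd`, `noise_floor`, `rng_seed`.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  eff <- spec$effects
  cells <- expand.grid(training_task = spec$training_tasks,
                       transfer_variant = spec$transfer_variants,
                       stringsAsFactors = FALSE)
  n_total <- nrow(cells) * spec$n_per_group
  with_seed(derive_seed(spec$master_seed, "population"), {
    rows <- vector("list", nrow(cells))
    sid <- 0L
    for (ci in seq_len(nrow(cells))) {
      n <- spec$n_per_group
      # Gaussian copula between skill and competence
      z_skill <- rnorm(n)
      rho <- eff$competence_skill_rho
      z_comp <- rho * z_skill + sqrt(1 - rho^2) * rnorm(n)
      competence <- cut(z_comp, breaks = c(-Inf, qnorm(1 / 3), qnorm(2 / 3), Inf),
                        labels = FALSE)
      baseline_skill <- pmin(pmax(0.55 + 0.12 * z_skill, 0.25), 0.95)
      lr_mult <- eff$task_lr_mult[[cells$training_task[ci]]]
      learning_rate <- exp(log(0.02) + 0.35 * rnorm(n)) * lr_mult *
        (1 + eff$competence_lr_gain * (competence - 2))
      motor_noise_sd <- pmax(rnorm(n, 25, 5), 10)
      rows[[ci]] <- data.frame(
        subject_id = sid + seq_len(n),
        training_task = cells$training_task[ci],
        transfer_variant = cells$transfer_variant[ci],
        competence = as.integer(competence),
        baseline_skill = baseline_skill,
        learning_rate = learning_rate,
        asymptote_gain = 0.2,
        motor_noise_sd = motor_noise_sd,
        noise_floor = 1,
        rng_seed = vapply(sid + seq_len(n), function(i)
          derive_seed(spec$master_seed, "agent", i), integer(1))
      )
      sid <- sid + n
    }
    do.call(rbind, rows)
  })
}

# per-trial learning state: speed target (hu/frame) and steering-noise SD
# (deg). On transfer tasks with n_flips transposed axes, a configurable
# fraction of the noise reduction acquired in training fails to transfer.
agent_trial_state <- function(agent, trial_index, effects = effect_config(),
                              n_flips = 0L) {
  t <- trial_index - 1
  gain <- 1 - exp(-agent$learning_rate * t)
  sigma <- agent$motor_noise_sd * exp(-agent$learning_rate * t)
  if (n_flips > 0L) {
    leak <- min(1, effects$remap_cost * sqrt(n_flips))
    sigma <- sigma + leak * (agent$motor_noise_sd - sigma)
    gain <- gain * (1 - leak)
  }
  list(
    speed = effects$speed_base *
      min(1, agent$baseline_skill + agent$asymptote_gain * gain),
    sigma = sigma
  )
}

#' Closed-loop steering policy for an agent
#'
#' Returns a policy usable with [simulate_street()]: each frame it aims at a
#' look-ahead point on the centreline, corrupts the ideal heading with
#' zero-mean Gaussian angular noise (SD decaying exponentially with the trial
#' index, scaled by the street-angle difficulty term and the transposition
#' cost), and presses the key(s) whose axis speed is below the corrupted
#' heading's demand. One standard-normal variate is consumed per frame.
#'
#' @param agent an [agent_params()] (or a population row coerced to one).
#' @param trial_index 1-based trial number; drives the learning state.
#' @param n_flips number of transposed cursor axes (0 training/Transfer-S,
#'   1 Transfer-M, 2 Transfer-L).
#' @param effects an [effect_config()].
#' @param look_steps look-ahead expressed in resampled centreline points.
#' @return function `(state, nearest, ctx) -> c(key_h, key_v)`.
#' @export
steering_policy <- function(agent, trial_index, n_flips = 0L,
                            effects = effect_config(),
                            look_steps = 15L) {
  stopifnot(trial_index >= 1)
  st <- agent_trial_state(agent, trial_index, effects, n_flips)
  speed <- st$speed
  sigma_deg <- st$sigma
  dgain <- effects$difficulty_gain
  floor_deg <- agent$noise_floor
  function(state, nearest, ctx) {
    dense <- ctx$dense
    n <- nrow(dense)
    tgt <- min(n, nearest$index + look_steps)
    kx <- (dense[tgt, 1] - state$position[1]) * ctx$directions[1]
    ky <- (dense[tgt, 2] - state$position[2]) * ctx$directions[2]
    # raw heading deliberately unclamped: values outside [0, pi/2] carry the
    # corrective signal when the cursor has drifted across the ideal line
    phi <- atan2(ky, kx)
    i0 <- max(1L, nearest$index - 1L)
    i1 <- min(n, nearest$index + 1L)
    ta <- atan2(abs(dense[i1, 2] - dense[i0, 2]),
                abs(dense[i1, 1] - dense[i0, 1]))
    sigma <- sigma_deg * ((1 - dgain) + dgain * abs(sin(4 * ta))) + floor_deg
    phin <- min(max(phi + rnorm(1) * sigma * pi / 180, 0), pi / 2)
    # zero sub-epsilon demands (cos(pi/2) is ~6e-17, not exactly 0)
    dem_h <- speed * cos(phin); if (dem_h < 1e-9) dem_h <- 0
    dem_v <- speed * sin(phin); if (dem_v < 1e-9) dem_v <- 0
    c(state$velocity[1] < dem_h, state$velocity[2] < dem_v)
  }
}

# coerce a population data.frame row to agent_params
as_agent <- function(row) {
  agent_params(baseline_skill = row$baseline_skill,
               learning_rate = row$learning_rate,
               asymptote_gain = row$asymptote_gain,
               motor_noise_sd = row$motor_noise_sd,
               noise_floor = row$noise_floor,
               competence = row$competence,
               rng_seed = row$rng_seed)
}

#' Fit an exponential learning curve to street-level errors
#'
#' Estimates the per-trial exponential learning rate from simulated (or
#' logged) street scores by least-squares fitting of
#' `error = A * exp(-rate * (trial - 1)) + C` (Levenberg-Marquardt, started
#' from a small grid of initial rates). By default only streets whose angle
#' carries a substantial difficulty weight (`|sin(4 * angle)| >` threshold)
#' enter the fit: one-hand and symmetric streets express mostly floor noise
#' and dilute the learning signal.
#'
#' @param streets data.frame with columns `trial`, `angle`, `error` (e.g.
#'   from [simulate_training_session()]); incomplete streets should be
#'   removed beforehand.
#' @param difficulty_threshold minimum `|sin(4 * angle)|` for inclusion;
#'   set to 0 to use all streets.
#' @param start_rates initial values of the rate tried in the fit.
#' @return list with `rate`, `amplitude`, `floor` and the `fit` object, or
#'   `NULL` if no fit converged.
#' @export
fit_learning_curve <- function(streets, difficulty_threshold = 0.5,
                               start_rates = c(0.01, 0.02, 0.04, 0.08)) {
  stopifnot(all(c("trial", "angle", "error") %in% names(streets)))
  w <- abs(sin(4 * streets$angle * pi / 180))
  d <- streets[w >= difficulty_threshold, ]
  if (nrow(d) < 10L) stop("too few streets above the difficulty threshold")
  best <- NULL
  bsse <- Inf
  for (r0 in start_rates) {
    fit <- tryCatch(
      minpack.lm::nlsLM(error ~ A * exp(-r * (trial - 1)) + C, data = d,
                        start = list(A = max(d$error), r = r0,
                                     C = min(d$error)),
                        lower = c(0, 1e-4, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      s <- sum(stats::residuals(fit)^2)
      if (s < bsse) { bsse <- s; best <- fit }
    }
  }
  if (is.null(best)) return(NULL)
  cf <- coef(best)
  list(rate = unname(cf["r"]), amplitude = unname(cf["A"]),
       floor = unname(cf["C"]), fit = best)
}
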