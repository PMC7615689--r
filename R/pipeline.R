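# Cohort-scale pipeline: generate -> simulate -> score -> denoise -> analyze.
#
# The per-street frame loop runs in compiled code (see src/simulate.cpp); the
# R reference simulator in simulate_street() is kept as the behavioural
# oracle and the two are cross-checked in the test suite.

#' Run configuration
#'
#' Bundles every tunable default of the pipeline. Unknown keys are rejected,
#' so configurations round-trip losslessly through YAML.
#'
#' @param n_per_group agents per design cell.
#' @param n_trials training trials per session.
#' @param streets_per_trial streets per trial (path length).
#' @param n_transfer_trials transfer trials per phase (pre and post).
#' @param street_length,street_width street geometry in height units.
#' @param street_start start point of training streets.
#' @param window_width task-window width in height units.
#' @param spacing centreline resampling spacing.
#' @param n_early,n_late trials averaged for the early/late change score.
#' @param pm_inverted see [performance_index()].
#' @param denoise_mode see [denoise_trials()].
#' @param pilot_n_per_group pilot subjects per cell for constant calibration.
#' @param pilot_seed fixed seed of the synthetic pilot sample.
#' @param master_seed master seed; all stage and agent seeds derive from it.
#' @param kinematics a [kinematics_config()].
#' @param effects an [effect_config()].
#' @return list of class `run_config`.
#' @export
run_config <- function(n_per_group = 30L, n_trials = 100L,
                       streets_per_trial = 6L, n_transfer_trials = 5L,
                       street_length = 0.5, street_width = 0.06,
                       street_start = c(0.2, 0.2), window_width = 16 / 9,
                       spacing = 0.002, n_early = 10L, n_late = 10L,
                       pm_inverted = FALSE,
                       denoise_mode = "fitted",
                       pilot_n_per_group = 5L, pilot_seed = 99202L,
                       master_seed = 20230L,
                       kinematics = kinematics_config(),
                       effects = effect_config()) {
  structure(list(n_per_group = as.integer(n_per_group),
                 n_trials = as.integer(n_trials),
                 streets_per_trial = as.integer(streets_per_trial),
                 n_transfer_trials = as.integer(n_transfer_trials),
                 street_length = street_length, street_width = street_width,
                 street_start = street_start, window_width = window_width,
                 spacing = spacing, n_early = as.integer(n_early),
                 n_late = as.integer(n_late), pm_inverted = pm_inverted,
                 denoise_mode = denoise_mode,
                 pilot_n_per_group = as.integer(pilot_n_per_group),
                 pilot_seed = as.integer(pilot_seed),
                 master_seed = as.integer(master_seed),
                 kinematics = kinematics, effects = effects),
            class = "run_config")
}

# precompute the dense centreline of a street once
street_cache_entry <- function(street, spacing = 0.002) {
  dense <- resample_centreline(street_centreline(street), spacing)
  cumlen <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  list(street = street, dense = dense, cumlen = cumlen,
       straight = inherits(street, "straight_street"),
       width = street$width)
}

# fast one-street simulation via the compiled loop; consumes the current R
# RNG stream (one normal draw per frame)
sim_street_fast <- function(entry, config, directions, speed, sigma_deg,
                            noise_floor_deg, remap_mult, difficulty_gain,
                            look_steps = 15L, window = 40L, record = FALSE) {
  res <- .sim_street_cpp(entry$dense, entry$cumlen, entry$width,
                         entry$straight, directions[1], directions[2],
                         config$accel_per_frame, config$max_velocity,
                         config$end_zone_fraction, config$frame_cap,
                         speed, sigma_deg, noise_floor_deg, remap_mult,
                         difficulty_gain, look_steps, window, record)
  mt <- if (res$completed)
    (res$end_frame - res$onset_frame) / config$frame_rate else NA_real_
  err <- if (res$n_scored > 0) sqrt(res$sum_sq / res$n_scored) else NA_real_
  out <- list(completed = res$completed, n_resets = res$n_resets,
              movement_time = mt, error = err,
              onset_frame = res$onset_frame, end_frame = res$end_frame)
  if (record) {
    fr <- as.data.frame(res$frames[seq_len(res$nrec), , drop = FALSE])
    names(fr) <- c("frame", "x", "y", "vx", "vy", "key_h", "key_v",
                   "reset", "dist")
    out$frames <- fr
  }
  out
}

#' Simulate the training session of one agent
#'
#' Runs every scheduled street through the compiled simulator under the
#' agent's per-trial learning state. Deterministic given `seed`.
#'
#' @param agent one row of a [sample_population()] table (or an
#'   [agent_params()]).
#' @param schedule a [schedule_training_session()] table.
#' @param cache named list of street cache entries keyed by angle (built
#'   internally when `NULL`).
#' @param config a [kinematics_config()].
#' @param effects an [effect_config()].
#' @param seed integer seed for this session.
#' @param run_cfg a [run_config()] supplying street geometry when `cache` is
#'   `NULL`.
#' @return list with `streets` (data.frame: trial, street, angle,
#'   movement_time, error, completed, n_resets) and `trials` (data.frame:
#'   trial, movement_time, error, n_completed), where trial values average
#'   the completed streets of the trial.
#' @export
simulate_training_session <- function(agent, schedule, cache = NULL,
                                      config = kinematics_config(),
                                      effects = effect_config(),
                                      seed = 1L, run_cfg = run_config()) {
  if (is.null(cache)) {
    angles <- sort(unique(schedule$angle))
    cache <- lapply(angles, function(a)
      street_cache_entry(straight_street(a, run_cfg$street_length,
                                         run_cfg$street_width,
                                         run_cfg$street_start),
                         run_cfg$spacing))
    names(cache) <- as.character(angles)
  }
  n <- nrow(schedule)
  mt <- err <- numeric(n)
  done <- logical(n)
  resets <- integer(n)
  trials <- unique(schedule$trial)
  with_seed(seed, {
    i <- 0L
    for (tr in trials) {
      st <- agent_trial_state(agent, tr, effects)
      rows <- which(schedule$trial == tr)
      for (r in rows) {
        i <- i + 1L
        entry <- cache[[as.character(schedule$angle[r])]]
        res <- sim_street_fast(entry, config, c(1, 1), st$speed, st$sigma,
                               agent$noise_floor, 1,
                               effects$difficulty_gain)
        mt[i] <- res$movement_time; err[i] <- res$error
        done[i] <- res$completed; resets[i] <- res$n_resets
      }
    }
  })
  streets <- data.frame(trial = schedule$trial, street = schedule$street,
                        angle = schedule$angle, movement_time = mt,
                        error = err, completed = done, n_resets = resets)
  agg <- function(v) tapply(ifelse(done, v, NA_real_), schedule$trial,
                            mean, na.rm = TRUE)
  trials_df <- data.frame(
    trial = as.integer(names(agg(mt))),
    movement_time = as.numeric(agg(mt)),
    error = as.numeric(agg(err)),
    n_completed = as.integer(tapply(done, schedule$trial, sum)))
  list(streets = streets, trials = trials_df)
}

#' Simulate one transfer phase of one agent
#'
#' Five trials of six curved streets in pseudo-random order, under the
#' transfer variant's movement directions and transposition cost. The `pre`
#' phase uses the agent's untrained state (trial index 1); the `post` phase
#' the state after the training session.
#'
#' @param agent a population row or [agent_params()].
#' @param variant transfer variant name (`"S"`, `"M"`, `"L"`).
#' @param phase `"pre"` or `"post"`.
#' @param cache list of six street cache entries for this variant (built
#'   internally when `NULL`).
#' @param config,effects,run_cfg as in [simulate_training_session()].
#' @param seed integer seed.
#' @return data.frame: phase, trial, movement_time, error, n_completed.
#' @export
simulate_transfer_block <- function(agent, variant, phase = c("pre", "post"),
                                    cache = NULL,
                                    config = kinematics_config(),
                                    effects = effect_config(),
                                    seed = 1L, run_cfg = run_config()) {
  phase <- match.arg(phase)
  tv <- transfer_variant(variant)
  if (is.null(cache)) {
    streets <- build_transfer_streets(tv, length = run_cfg$street_length,
                                      width = run_cfg$street_width,
                                      window_width = run_cfg$window_width)
    cache <- lapply(streets, street_cache_entry, spacing = run_cfg$spacing)
  }
  n_flips <- tv$flip_horizontal + tv$flip_vertical
  trial_index <- if (phase == "pre") 1L else run_cfg$n_trials + 1L
  st <- agent_trial_state(agent, trial_index, effects, n_flips)
  nt <- run_cfg$n_transfer_trials
  out <- vector("list", nt)
  with_seed(seed, {
    for (tr in seq_len(nt)) {
      ord <- sample.int(6L)
      mt <- err <- numeric(6L); done <- logical(6L)
      for (k in seq_len(6L)) {
        res <- sim_street_fast(cache[[ord[k]]], config, tv$directions,
                               st$speed, st$sigma, agent$noise_floor,
                               1, effects$difficulty_gain)
        mt[k] <- res$movement_time; err[k] <- res$error
        done[k] <- res$completed
      }
      out[[tr]] <- data.frame(
        phase = phase, trial = tr,
        movement_time = mean(mt[done]), error = mean(err[done]),
        n_completed = sum(done))
    }
  })
  do.call(rbind, out)
}

#' Simulate a full synthetic cohort
#'
#' Generates the population, one shared street schedule per training task,
#' and simulates every agent's training session and pre/post transfer
#' blocks. All randomness derives from the configuration's master seed.
#'
#' @param run_cfg a [run_config()].
#' @param population optional pre-sampled population table (defaults to
#'   [sample_population()] of the configured design).
#' @return list of class `cohort_sim` with `population`, `schedules` (per
#'   task), `streets` (long per-street score table), `trials` (long
#'   per-trial table), `transfer` (long transfer table) and `n_aborted`.
#' @export
simulate_cohort <- function(run_cfg = run_config(), population = NULL) {
  ms <- run_cfg$master_seed
  eff <- run_cfg$effects
  kin <- run_cfg$kinematics
  if (is.null(population)) {
    spec <- population_spec(n_per_group = run_cfg$n_per_group,
                            effects = eff, master_seed = ms)
    population <- sample_population(spec)
  }
  tasks <- training_task_specs(n_trials = run_cfg$n_trials,
                               streets_per_trial = run_cfg$streets_per_trial)
  tasks <- tasks[names(tasks) %in% unique(population$training_task)]
  schedules <- lapply(seq_along(tasks), function(i)
    schedule_training_session(tasks[[i]], derive_seed(ms, "schedule", i)))
  names(schedules) <- names(tasks)
  caches <- lapply(tasks, function(tk) {
    cache <- lapply(tk$angles, function(a)
      street_cache_entry(straight_street(a, run_cfg$street_length,
                                         run_cfg$street_width,
                                         run_cfg$street_start),
                         run_cfg$spacing))
    names(cache) <- as.character(tk$angles)
    cache
  })
  variants <- unique(population$transfer_variant)
  tcaches <- lapply(variants, function(v) {
    streets <- build_transfer_streets(v, length = run_cfg$street_length,
                                      width = run_cfg$street_width,
                                      window_width = run_cfg$window_width)
    lapply(streets, street_cache_entry, spacing = run_cfg$spacing)
  })
  names(tcaches) <- variants

  n <- nrow(population)
  street_list <- trial_list <- transfer_list <- vector("list", n)
  n_aborted <- 0L
  for (j in seq_len(n)) {
    ag <- population[j, ]
    sid <- ag$subject_id
    tr <- simulate_training_session(
      ag, schedules[[ag$training_task]], caches[[ag$training_task]],
      kin, eff, seed = derive_seed(ms, "train", sid), run_cfg = run_cfg)
    pre <- simulate_transfer_block(
      ag, ag$transfer_variant, "pre", tcaches[[ag$transfer_variant]],
      kin, eff, seed = derive_seed(ms, "pre", sid), run_cfg = run_cfg)
    post <- simulate_transfer_block(
      ag, ag$transfer_variant, "post", tcaches[[ag$transfer_variant]],
      kin, eff, seed = derive_seed(ms, "post", sid), run_cfg = run_cfg)
    n_aborted <- n_aborted + sum(!tr$streets$completed)
    street_list[[j]] <- cbind(subject_id = sid,
                              training_task = ag$training_task,
                              tr$streets)
    trial_list[[j]] <- cbind(subject_id = sid,
                             training_task = ag$training_task,
                             tr$trials)
    tf <- rbind(pre, post)
    transfer_list[[j]] <- cbind(subject_id = sid,
                                transfer_variant = ag$transfer_variant,
                                tf)
  }
  if (n_aborted > 0L)
    warning(n_aborted, " street attempt(s) hit the frame cap and were excluded")
  structure(list(population = population,
                 schedules = schedules,
                 streets = do.call(rbind, street_list),
                 trials = do.call(rbind, trial_list),
                 transfer = do.call(rbind, transfer_list),
                 n_aborted = n_aborted,
                 run_cfg = run_cfg),
            class = "cohort_sim")
}

#' Calibrate PI normalisation constants on a synthetic pilot sample
#'
#' Simulates an independent pilot cohort (by default 5 agents per cell, 75 in
#' total, under a fixed pilot seed) and averages its trial-level error and
#' movement time into the constants `a` and `b`.
#'
#' @param run_cfg a [run_config()]; `pilot_n_per_group` and `pilot_seed`
#'   control the pilot sample.
#' @return a [calibrate_constants()] result.
#' @export
pilot_constants <- function(run_cfg = run_config()) {
  pcfg <- run_cfg
  pcfg$n_per_group <- run_cfg$pilot_n_per_group
  pcfg$master_seed <- run_cfg$pilot_seed
  sim <- simulate_cohort(pcfg)
  ok <- stats::complete.cases(sim$trials[, c("movement_time", "error")])
  calibrate_constants(sim$trials[ok, ])
}

#' Score and denoise a simulated cohort into per-subject results
#'
#' Per training task, computes the street-difficulty profiles (movement time
#' and error separately), the per-trial difficulties from the task's shared
#' schedule, removes the difficulty component from every subject's trial
#' series, recomputes the PI from the denoised values, and assembles one row
#' per subject with early/late training PI, pre/post transfer PI and the
#' change scores.
#'
#' @param sim a [simulate_cohort()] result.
#' @param constants PI normalisation constants; defaults to
#'   [pilot_constants()] under the simulation's configuration.
#' @param denoise logical; apply trial-difficulty denoising to the training
#'   series.
#' @return data.frame of class `cohort_result`: one row per subject with
#'   group labels, competence, `training_pi_mean`, `early`, `late`,
#'   `training_change`, `pre`, `post`, `transfer_change`.
#' @export
cohort_results <- function(sim, constants = NULL, denoise = TRUE) {
  run_cfg <- sim$run_cfg
  if (is.null(constants)) constants <- pilot_constants(run_cfg)
  pop <- sim$population
  res <- vector("list", length(unique(pop$training_task)))
  ti <- 0L
  for (task in unique(pop$training_task)) {
    ti <- ti + 1L
    subj <- pop$subject_id[pop$training_task == task]
    tt <- sim$trials[sim$trials$training_task == task, ]
    trials <- sort(unique(tt$trial))
    mt <- matrix(NA_real_, length(subj), length(trials),
                 dimnames = list(subj, trials))
    er <- mt
    idx <- cbind(match(tt$subject_id, subj), match(tt$trial, trials))
    mt[idx] <- tt$movement_time
    er[idx] <- tt$error
    if (denoise) {
      ss <- sim$streets[sim$streets$training_task == task &
                          sim$streets$completed, ]
      sched <- sim$schedules[[task]]
      prof_mt <- street_difficulty_profile(ss, "movement_time")
      prof_er <- street_difficulty_profile(ss, "error")
      mt <- denoise_trials(mt, trial_difficulty(sched, prof_mt),
                           mode = run_cfg$denoise_mode)
      er <- denoise_trials(er, trial_difficulty(sched, prof_er),
                           mode = run_cfg$denoise_mode)
    }
    pi_mat <- performance_index(mt, pmax(er, 1e-9), constants,
                                pm_inverted = run_cfg$pm_inverted)
    rows <- lapply(seq_along(subj), function(k) {
      sid <- subj[k]
      tf <- sim$transfer[sim$transfer$subject_id == sid, ]
      pre_pi <- performance_index(tf$movement_time[tf$phase == "pre"],
                                  tf$error[tf$phase == "pre"], constants,
                                  pm_inverted = run_cfg$pm_inverted)
      post_pi <- performance_index(tf$movement_time[tf$phase == "post"],
                                   tf$error[tf$phase == "post"], constants,
                                   pm_inverted = run_cfg$pm_inverted)
      cs <- change_scores(pi_mat[k, ], pre_pi, post_pi,
                          n_early = run_cfg$n_early,
                          n_late = run_cfg$n_late)
      data.frame(subject_id = sid, training_task = task,
                 transfer_variant =
                   pop$transfer_variant[pop$subject_id == sid],
                 competence = pop$competence[pop$subject_id == sid],
                 training_pi_mean = mean(pi_mat[k, ]),
                 early = cs$early, late = cs$late,
                 training_change = cs$training_change,
                 pre = cs$pre, post = cs$post,
                 transfer_change = cs$transfer_change)
    })
    res[[ti]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$subject_id), ]
  rownames(out) <- NULL
  class(out) <- c("cohort_result", "data.frame")
  out
}

#' Run the study's statistical analysis on a cohort result
#'
#' Reproduces the analysis structure of the design: validation one-way ANOVA
#' of overall training performance across training tasks (with Bonferroni
#' follow-ups), paired early-vs-late t-test per training task, ANOVA of the
#' training change score across tasks, ANCOVA of post-transfer performance
#' on transfer variant with pre-transfer performance as covariate, and the
#' correlation between training change and transfer change.
#'
#' @param cohort a [cohort_results()] table.
#' @param followup_family Bonferroni family size for the training follow-ups
#'   (default: all pairwise comparisons).
#' @return list with elements `training_validation`, `learning` (per-task
#'   paired tests), `training_change_anova`, `transfer_ancova`,
#'   `correlation`.
#' @export
analyze_cohort <- function(cohort, followup_family = NULL) {
  tasks <- sort(unique(cohort$training_task))
  learning <- lapply(tasks, function(tk) {
    d <- cohort[cohort$training_task == tk, ]
    paired_t(d$late, d$early)
  })
  names(learning) <- tasks
  list(
    training_validation = one_way_anova(cohort$training_pi_mean,
                                        cohort$training_task,
                                        family_size = followup_family),
    learning = learning,
    training_change_anova = one_way_anova(cohort$training_change,
                                          cohort$training_task,
                                          family_size = followup_family),
    transfer_ancova = ancova(cohort, dv = "post",
                             factors = "transfer_variant",
                             covariates = "pre"),
    correlation = training_transfer_correlation(cohort)
  )
}

# stable 31-bit FNV-style hash of a configuration for provenance stamps
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 216613626
  for (ch in utf8ToInt(as.character(s))) {
    h <- ((h + ch) * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Provenance stamp for a pipeline run
#' @param run_cfg a [run_config()].
#' @return list with the configuration hash, master seed, package version and
#'   creation time.
#' @export
provenance_stamp <- function(run_cfg) {
  list(config_hash = config_hash(unclass(run_cfg)),
       master_seed = run_cfg$master_seed,
       package_version =
         as.character(utils::packageVersion("streetnav")),
       r_version = as.character(getRversion()),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the full pipeline
#'
#' Generate the population and schedules, simulate all sessions, calibrate
#' constants on the synthetic pilot, score and denoise, and run the
#' statistical analysis. Deterministic given the configuration's master
#' seed.
#'
#' @param run_cfg a [run_config()].
#' @return list with `sim`, `constants`, `cohort`, `analysis`, `provenance`.
#' @export
run_pipeline <- function(run_cfg = run_config()) {
  sim <- simulate_cohort(run_cfg)
  constants <- pilot_constants(run_cfg)
  cohort <- cohort_results(sim, constants)
  analysis <- analyze_cohort(cohort)
  list(sim = sim, constants = constants, cohort = cohort,
       analysis = analysis, provenance = provenance_stamp(run_cfg))
}
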