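# shared fixtures: a mid-skill agent and a hand-built trajectory object

default_agent <- function(lr = 0.03, seed = 1L, ...) {
  agent_params(baseline_skill = 0.55, learning_rate = lr, rng_seed = seed, ...)
}

# minimal trajectory object for scoring tests: straight 0-degree street at
# the origin, cursor at constant offset d above the ideal line
fake_trajectory <- function(offsets, onset_frame = 1L,
                            street = straight_street(0, start = c(0, 0)),
                            frame_rate = 60) {
  n <- length(offsets)
  frames <- data.frame(
    frame = seq_len(n), x = seq(0.01, 0.4, length.out = n), y = offsets,
    vx = rep(0.005, n), vy = 0, key_h = TRUE, key_v = FALSE,
    reset = FALSE, dist = abs(offsets))
  structure(list(frames = frames, outcome = "completed", n_resets = 0L,
                 onset_frame = onset_frame, end_frame = n,
                 street = street,
                 config = kinematics_config(frame_rate = frame_rate),
                 directions = c(1, 1)),
            class = "trajectory")
}

never_press <- function(state, nearest, ctx) c(FALSE, FALSE)
both_keys <- function(state, nearest, ctx) c(TRUE, TRUE)
horizontal_only <- function(state, nearest, ctx) c(TRUE, FALSE)
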