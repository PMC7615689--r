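# Frame-based simulator of the two-key cursor control law.
#
# One key per hand drives one axis. Holding a key accelerates that axis by a
# fixed amount per display frame; releasing it decelerates by the same
# amount. Axis speeds are clamped to [0, max_velocity]; the control law can
# never reverse along an axis, only the signed direction convention of the
# task (training vs transposed transfer variants) decides where "forwards"
# points.

#' Kinematics configuration
#'
#' @param accel_per_frame acceleration per frame while a key is held (and
#'   deceleration when released), height units/frame.
#' @param max_velocity maximum per-axis speed, height units/frame.
#' @param frame_rate display refresh rate in Hz.
#' @param end_zone_fraction terminal fraction of street arc length that counts
#'   as "street completed".
#' @param frame_cap hard per-street frame budget; reaching it aborts the
#'   street (default 3600 frames = 60 s at 60 Hz).
#' @return object of class `kinematics_config`.
#' @export
kinematics_config <- function(accel_per_frame = 0.001, max_velocity = 0.3,
                              frame_rate = 60, end_zone_fraction = 0.05,
                              frame_cap = 3600L) {
  stopifnot(accel_per_frame > 0, max_velocity > 0, frame_rate > 0,
            end_zone_fraction > 0, end_zone_fraction < 1, frame_cap >= 1L)
  structure(list(accel_per_frame = accel_per_frame,
                 max_velocity = max_velocity,
                 frame_rate = frame_rate,
                 end_zone_fraction = end_zone_fraction,
                 frame_cap = as.integer(frame_cap)),
            class = "kinematics_config")
}

#' Initial cursor state
#' @param position numeric length-2 starting position.
#' @return list with `position`, `velocity` (per-axis, non-negative), `frame`.
#' @export
cursor_state <- function(position) {
  list(position = as.numeric(position), velocity = c(0, 0), frame = 0L)
}

#' Advance the cursor by one frame
#'
#' Per axis: the speed increases by `accel_per_frame` if the key is held and
#' decreases by the same amount if released, clamped to
#' `[0, max_velocity]`; the position then advances by the speed times the
#' signed movement direction of that axis.
#'
#' @param state a cursor state (see [cursor_state()]).
#' @param keys logical length-2: horizontal and vertical key held.
#' @param config a [kinematics_config()].
#' @param directions signed axis directions, e.g. `c(1, 1)` for
#'   rightwards/upwards.
#' @return the updated state.
#' @export
cursor_step <- function(state, keys, config, directions = c(1, 1)) {
  a <- config$accel_per_frame
  v <- state$velocity + ifelse(keys, a, -a)
  v <- pmin(pmax(v, 0), config$max_velocity)
  list(position = state$position + v * directions,
       velocity = v,
       frame = state$frame + 1L)
}

# Nearest point on a dense polyline: index, distance and arc length at the
# nearest vertex. `from` restricts the search window for incremental calls.
.nearest_on_polyline <- function(p, dense, cumlen, from = NULL, window = 40L) {
  if (is.null(from)) {
    idx <- seq_len(nrow(dense))
  } else {
    idx <- max(1L, from - window):min(nrow(dense), from + window)
  }
  d2 <- (dense[idx, 1] - p[1])^2 + (dense[idx, 2] - p[2])^2
  i <- idx[which.min(d2)]
  list(index = i, dist = sqrt(min(d2)), arc = cumlen[i])
}

#' Simulate one street attempt
#'
#' Iterates [cursor_step()] under a control policy until the cursor reaches
#' the street's end zone (outcome `"completed"`), with wall collisions
#' (distance to the centreline exceeding half the street width) resetting the
#' cursor to the street start at zero velocity, or until the frame budget is
#' exhausted (outcome `"aborted"`).
#'
#' This is the reference implementation; cohort-scale simulation uses a
#' compiled equivalent (see [simulate_trial_set()]) that is cross-checked
#' against this one.
#'
#' @param policy function `(state, nearest, ctx) -> logical c(key_h, key_v)`;
#'   `nearest` carries `index`, `dist` and `arc` of the cursor's nearest
#'   centreline point, `ctx` the street context (dense centreline, cumulative
#'   arc lengths, total length, config, directions).
#' @param street a street object.
#' @param config a [kinematics_config()].
#' @param directions signed axis directions.
#' @param seed optional integer; when given, the policy's random draws run
#'   under this seed (restoring the caller's RNG state afterwards).
#' @param spacing centreline resampling spacing (height units).
#' @return object of class `trajectory`: list with `frames` (data.frame:
#'   frame, x, y, vx, vy, key_h, key_v, reset, dist), `outcome`, `n_resets`,
#'   `onset_frame`, `end_frame`, `street`, `config`, `directions`.
#' @export
simulate_street <- function(policy, street, config = kinematics_config(),
                            directions = c(1, 1), seed = NULL,
                            spacing = 0.002) {
  run <- function() {
    dense <- resample_centreline(street_centreline(street), spacing)
    cumlen <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
    total_len <- cumlen[length(cumlen)]
    goal_arc <- (1 - config$end_zone_fraction) * total_len
    half_w <- street$width / 2
    ctx <- list(street = street, dense = dense, cumlen = cumlen,
                total_len = total_len, config = config,
                directions = directions)
    start <- dense[1, ]
    state <- cursor_state(start)
    nn <- .nearest_on_polyline(start, dense, cumlen)
    cap <- config$frame_cap
    rec <- matrix(NA_real_, nrow = cap, ncol = 9)
    outcome <- "aborted"
    n_resets <- 0L
    nrec <- 0L
    for (i in seq_len(cap)) {
      keys <- policy(state, nn, ctx)
      state <- cursor_step(state, keys, config, directions)
      nn <- .nearest_on_polyline(state$position, dense, cumlen,
                                 from = nn$index)
      reset <- nn$dist > half_w
      nrec <- nrec + 1L
      rec[nrec, ] <- c(state$frame, state$position, state$velocity,
                       keys, reset, nn$dist)
      if (reset) {
        n_resets <- n_resets + 1L
        state <- list(position = start, velocity = c(0, 0),
                      frame = state$frame)
        nn <- .nearest_on_polyline(start, dense, cumlen)
      } else if (nn$arc >= goal_arc) {
        outcome <- "completed"
        break
      }
    }
    frames <- as.data.frame(rec[seq_len(nrec), , drop = FALSE])
    names(frames) <- c("frame", "x", "y", "vx", "vy",
                       "key_h", "key_v", "reset", "dist")
    moving <- which(frames$vx > 0 | frames$vy > 0)
    onset <- if (length(moving)) frames$frame[moving[1]] else NA_integer_
    structure(
      list(frames = frames, outcome = outcome, n_resets = n_resets,
           onset_frame = onset,
           end_frame = if (outcome == "completed") frames$frame[nrec] else NA_integer_,
           street = street, config = config, directions = directions),
      class = "trajectory"
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s, %d frames, %d resets\n",
              x$outcome, nrow(x$frames), x$n_resets))
  invisible(x)
}
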