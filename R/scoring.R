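# Dependent variables: movement time, RMS error, and the performance index
# PI = Pm * Pe with Pe = a / error and Pm = movement time / b, where the
# normalisation constants a (error) and b (movement time) are calibrated on a
# pilot sample.

#' Movement time of a completed street attempt
#'
#' Time from cursor movement onset (first frame with nonzero velocity) to
#' street completion, in seconds.
#'
#' @param trajectory a completed trajectory (see [simulate_street()]).
#' @param config the [kinematics_config()] used (defaults to the one stored
#'   in the trajectory).
#' @return movement time in seconds.
#' @export
movement_time <- function(trajectory, config = trajectory$config) {
  if (trajectory$outcome != "completed")
    stop("trajectory not scorable: street was not completed")
  (trajectory$end_frame - trajectory$onset_frame) / config$frame_rate
}

# distances from every frame (onset..end) to the street's ideal line;
# vectorised version of point_to_ideal_distance over a trajectory
.frame_distances <- function(trajectory, street, spacing = 0.002) {
  fr <- trajectory$frames
  fr <- fr[fr$frame >= trajectory$onset_frame, , drop = FALSE]
  if (inherits(street, "straight_street")) {
    a <- sqrt(sum((street$end - street$start)^2))
    if (a <= 0) stop("degenerate street: zero length")
    b <- sqrt((fr$x - street$start[1])^2 + (fr$y - street$start[2])^2)
    cc <- sqrt((fr$x - street$end[1])^2 + (fr$y - street$end[2])^2)
    s <- (a + b + cc) / 2
    area2 <- s * pmax(s - a, 0) * pmax(s - b, 0) * pmax(s - cc, 0)
    2 * sqrt(pmax(area2, 0)) / a
  } else {
    dense <- resample_centreline(street$centreline, spacing)
    vapply(seq_len(nrow(fr)), function(i)
      sqrt(min((dense[, 1] - fr$x[i])^2 + (dense[, 2] - fr$y[i])^2)),
      numeric(1))
  }
}

#' RMS error of a completed street attempt
#'
#' Root mean square of the frame-wise distance between the cursor and the
#' street's ideal line (Heron construction for straight streets, nearest
#' neighbour on a densely resampled centreline for curved ones), over all
#' frames from movement onset to completion — including frames of failed
#' attempts before wall-collision resets.
#'
#' @param trajectory a completed trajectory.
#' @param street the street (defaults to the one stored in the trajectory).
#' @param spacing resampling spacing for curved streets.
#' @return RMS error in height units.
#' @export
street_error <- function(trajectory, street = trajectory$street,
                         spacing = 0.002) {
  if (trajectory$outcome != "completed")
    stop("trajectory not scorable: street was not completed")
  d <- .frame_distances(trajectory, street, spacing)
  sqrt(mean(d^2))
}

#' Normalisation constants from a pilot sample
#'
#' Averages the street-level error and movement time of a pilot score set to
#' obtain the constant error `a` and constant movement time `b` used to
#' normalise the performance index.
#'
#' @param pilot_scores data.frame with columns `error` and `movement_time`
#'   (one row per scored street or trial).
#' @return list with `a` (height units) and `b` (seconds), class
#'   `normalization_constants`.
#' @export
calibrate_constants <- function(pilot_scores) {
  if (is.null(pilot_scores) || nrow(pilot_scores) == 0L)
    stop("empty pilot set")
  stopifnot(all(c("error", "movement_time") %in% names(pilot_scores)))
  structure(list(a = mean(pilot_scores$error),
                 b = mean(pilot_scores$movement_time)),
            class = "normalization_constants")
}

#' Performance index of a trial
#'
#' `PI = Pm * Pe` with `Pm = movement_time / b` and `Pe = a / error`,
#' computed from the trial-level (street-averaged) movement time and error.
#' `pm_inverted = TRUE` switches to `Pm = b / movement_time`, under which
#' faster movement raises the index; the default follows the printed
#' definition.
#'
#' @param movement_time trial-wise movement time, seconds (> 0).
#' @param error trial-wise RMS error, height units (> 0).
#' @param constants a [calibrate_constants()] result (or list with `a`, `b`).
#' @param pm_inverted logical; see above.
#' @return numeric performance index (vectorised over inputs).
#' @export
performance_index <- function(movement_time, error, constants,
                              pm_inverted = FALSE) {
  if (any(movement_time <= 0) || any(error <= 0))
    stop("undefined PI: movement time and error must be positive")
  pm <- if (pm_inverted) constants$b / movement_time
        else movement_time / constants$b
  pe <- constants$a / error
  pm * pe
}

#' Aggregate street scores into a trial score
#'
#' Trial-wise movement time and error are the arithmetic means of the street
#' values composing the trial.
#'
#' @param street_scores data.frame with columns `movement_time` and `error`
#'   (one row per street of the trial).
#' @return list with `movement_time` and `error`.
#' @export
trial_score <- function(street_scores) {
  stopifnot(nrow(street_scores) >= 1L)
  list(movement_time = mean(street_scores$movement_time),
       error = mean(street_scores$error))
}
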