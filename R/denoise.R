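# Trial-difficulty denoising.
#
# Street angles differ systematically in difficulty (0 and 90 degrees need
# one hand only; intermediate angles need asymmetric bimanual ratios), so a
# trial's score partly reflects which streets it happened to contain. To
# avoid confounding learning-related change with trial difficulty, the
# difficulty-predicted component of the group-level trial series is removed
# from every subject's series: a per-angle difficulty profile is averaged
# over all street occurrences, each trial's difficulty is the mean over its
# six streets, the group-level per-trial mean is regressed on trial
# difficulty, and the mean-centred fitted component is subtracted from the
# single-subject data. This loses no data and leaves the between-subject
# variance at every trial untouched.

#' Street-difficulty profile
#'
#' Grand mean of a dependent variable for each street angle, across all
#' street occurrences (within and across subjects) of one training task.
#'
#' @param street_scores data.frame with columns `angle` and the dependent
#'   variable named by `value`.
#' @param value name of the dependent-variable column (e.g. `"error"` or
#'   `"movement_time"`).
#' @param angles optional full angle grid of the task; an error is raised if
#'   any grid angle was never observed.
#' @return data.frame with columns `angle` and `difficulty`, sorted by angle.
#' @export
street_difficulty_profile <- function(street_scores, value = "error",
                                      angles = NULL) {
  stopifnot(all(c("angle", value) %in% names(street_scores)))
  agg <- tapply(street_scores[[value]], street_scores$angle, mean)
  out <- data.frame(angle = as.numeric(names(agg)),
                    difficulty = as.numeric(agg))
  out <- out[order(out$angle), , drop = FALSE]
  if (!is.null(angles)) {
    missing <- setdiff(round(angles, 8), round(out$angle, 8))
    if (length(missing))
      stop("missing-angle error: unobserved street angle(s): ",
           paste(missing, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Per-trial difficulty from a schedule and a difficulty profile
#'
#' The trial difficulty is the average of the street difficulties of the
#' streets composing the trial.
#'
#' @param schedule data.frame with columns `trial` and `angle` (as from
#'   [schedule_training_session()]).
#' @param profile a [street_difficulty_profile()].
#' @return numeric vector, one difficulty per trial, in trial order.
#' @export
trial_difficulty <- function(schedule, profile) {
  d <- profile$difficulty[match(round(schedule$angle, 8),
                                round(profile$angle, 8))]
  if (anyNA(d)) stop("schedule contains angles absent from the profile")
  as.numeric(tapply(d, schedule$trial, mean))
}

#' Remove the trial-difficulty component from subject trial series
#'
#' Fits an ordinary least-squares regression of the group-level per-trial
#' mean on the trial difficulty and subtracts the difficulty-attributable
#' component from every subject's series. In the default `"fitted"` mode the
#' mean-centred fitted values are subtracted, which removes exactly the
#' difficulty-predicted variation while preserving the series mean and all
#' between-subject variance; `"residual"` mode subtracts the raw regression
#' residuals instead (the strict-literal reading of subtracting "raw
#' residuals", which would also remove learning-related variation — provided
#' for comparison only).
#'
#' @param subject_values numeric matrix, subjects in rows, trials in columns
#'   (a single series may be given as a vector).
#' @param difficulty numeric vector of per-trial difficulties.
#' @param group_means optional per-trial group-level means; defaults to the
#'   column means of `subject_values`.
#' @param mode `"fitted"` (default) or `"residual"`; see above.
#' @return matrix (or vector) of the same shape as the input.
#' @export
denoise_trials <- function(subject_values, difficulty, group_means = NULL,
                           mode = c("fitted", "residual")) {
  mode <- match.arg(mode)
  vec <- is.null(dim(subject_values))
  m <- if (vec) matrix(subject_values, nrow = 1L) else as.matrix(subject_values)
  if (ncol(m) != length(difficulty))
    stop("difficulty length must equal the number of trials")
  if (ncol(m) < 3L) stop("need at least 3 trials")
  if (is.null(group_means)) group_means <- colMeans(m)
  if (length(group_means) != ncol(m))
    stop("group_means length must equal the number of trials")
  if (sd(difficulty) == 0) {
    warning("constant trial difficulty; returning input unchanged")
    return(subject_values)
  }
  fit <- lm(group_means ~ difficulty)
  component <- if (mode == "fitted") {
    fitted(fit) - mean(fitted(fit))
  } else {
    as.numeric(residuals(fit))
  }
  out <- sweep(m, 2L, component)
  if (vec) as.numeric(out) else out
}
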