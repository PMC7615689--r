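#' @useDynLib streetnav, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef sd rnorm runif qf pf t.test cor.test aov anova
#' @importFrom utils head tail
NULL

# All geometry lives in "height units": resolution-independent coordinates where
# 1.0 equals the task-window height, origin bottom-left, x rightwards, y upwards.

#' Construct a straight street
#'
#' A straight street is a corridor of a given width around an ideal line that
#' runs from `start` at `angle` degrees (0 = horizontal, 90 = vertical) for
#' `length` height units. Street angles encode the required bimanual key
#' ratio: 0 and 90 degrees need one hand only, 45 degrees needs both hands
#' equally.
#'
#' @param angle street angle in degrees, in `[0, 90]`.
#' @param length street length in height units (> 0).
#' @param width corridor width in height units (> 0).
#' @param start numeric length-2 start point (height units).
#' @return an object of class `c("straight_street", "street")`.
#' @export
straight_street <- function(angle, length = 0.5, width = 0.06,
                            start = c(0.2, 0.2)) {
  stopifnot(is.numeric(angle), length(angle) == 1L)
  if (angle < 0 || angle > 90) stop("street angle must be in [0, 90] degrees")
  if (length <= 0) stop("street length must be > 0")
  if (width <= 0) stop("street width must be > 0")
  theta <- angle * pi / 180
  end <- start + length * c(cos(theta), sin(theta))
  structure(
    list(angle = angle, length = length, width = width,
         start = start, end = end),
    class = c("straight_street", "street")
  )
}

#' Construct a curved street
#'
#' A curved street is a corridor around an ordered centreline polyline.
#'
#' @param centreline numeric matrix with >= 2 rows and 2 columns (x, y in
#'   height units), ordered along the path.
#' @param width corridor width in height units (> 0).
#' @param variant_id integer curve identifier (1-6 in the standard transfer
#'   family).
#' @return an object of class `c("curved_street", "street")`.
#' @export
curved_street <- function(centreline, width = 0.06, variant_id = 1L) {
  centreline <- as.matrix(centreline)
  if (nrow(centreline) < 2L || ncol(centreline) != 2L)
    stop("centreline must be a matrix of >= 2 points (x, y)")
  seg <- diff(centreline)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen <= 0)) stop("centreline points must be strictly ordered (no zero-length segments)")
  if (width <= 0) stop("street width must be > 0")
  structure(
    list(centreline = centreline, width = width,
         variant_id = as.integer(variant_id),
         length = sum(seglen)),
    class = c("curved_street", "street")
  )
}

#' Centreline of a street as a polyline
#'
#' @param street a street object.
#' @return a two-column matrix of centreline points.
#' @export
street_centreline <- function(street) {
  if (inherits(street, "straight_street")) {
    rbind(street$start, street$end)
  } else if (inherits(street, "curved_street")) {
    street$centreline
  } else stop("not a street object")
}

#' Total arc length of a polyline
#' @param xy two-column matrix of points.
#' @return total arc length (height units).
#' @export
arc_length <- function(xy) {
  xy <- as.matrix(xy)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Resample a polyline at (approximately) uniform spacing
#'
#' Densifies a centreline by linear interpolation so that consecutive points
#' are at most `spacing` apart in arc length. Original vertices are kept.
#'
#' @param xy two-column matrix of points.
#' @param spacing maximum arc-length distance between resampled points.
#' @return a two-column matrix.
#' @export
resample_centreline <- function(xy, spacing = 0.002) {
  xy <- as.matrix(xy)
  out <- vector("list", nrow(xy) - 1L)
  for (i in seq_len(nrow(xy) - 1L)) {
    a <- xy[i, ]; b <- xy[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / spacing))
    t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  rbind(do.call(rbind, out), xy[nrow(xy), , drop = FALSE])
}

#' Training street angle grid
#'
#' Builds the inclusive grid of street angles from 0 to 90 degrees for a
#' training task defined by its minimum angular difference between streets.
#' The grid always contains 0 and 90; the spacing is `90 / round(90 / delta)`,
#' the closest even divisor of 90 to the requested minimum difference, so a
#' nominal difference that does not divide 90 evenly (e.g. 6.425) yields the
#' nearest uniform grid (spacing 90/14 = 6.4286).
#'
#' @param min_angular_difference nominal minimum angular difference between
#'   streets, in degrees, in `(0, 90]`.
#' @return sorted numeric vector of angles in degrees, including 0 and 90.
#' @export
#' @examples
#' build_training_angles(22.5) # 0, 22.5, 45, 67.5, 90
#' length(build_training_angles(2)) # 46
build_training_angles <- function(min_angular_difference) {
  d <- min_angular_difference
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0 || d > 90)
    stop("min_angular_difference must be a single value in (0, 90]")
  k <- max(1L, round(90 / d))
  seq(0, 90, length.out = k + 1L)
}

#' Mean and standard error of neighbouring angular-difference spacings
#'
#' Summarises how evenly a descending ladder of minimum angular differences
#' (one per training task) is spaced: the mean and standard error of the
#' successive differences. Used to check that a set of training tasks forms
#' an approximately linear difficulty scale.
#'
#' @param deltas numeric vector (length >= 2) of minimum angular differences,
#'   sorted descending.
#' @return list with `mean`, `se` (sample SD of successive differences divided
#'   by sqrt of their count; 0 with `se_defined = FALSE` when only one
#'   difference exists), and `se_defined`.
#' @export
neighbour_spacing_summary <- function(deltas) {
  if (!is.numeric(deltas) || length(deltas) < 2L)
    stop("need at least two delta values")
  if (is.unsorted(rev(deltas), strictly = FALSE))
    stop("deltas must be sorted descending")
  diffs <- abs(diff(deltas))
  k <- length(diffs)
  if (k == 1L) {
    warning("only one spacing; standard error undefined, returning 0")
    return(list(mean = mean(diffs), se = 0, se_defined = FALSE))
  }
  list(mean = mean(diffs), se = sd(diffs) / sqrt(k), se_defined = TRUE)
}

#' Training-task specification
#'
#' The five standard training tasks (Train-I to Train-V) differ only in their
#' minimum angular difference between streets, which determines the angle
#' grid: 22.5, 18, 11.25, 6.425 and 2 degrees respectively.
#'
#' @param name task label.
#' @param min_angular_difference degrees; see [build_training_angles()].
#' @param n_trials number of training trials (paths) in a session.
#' @param streets_per_trial streets composing one trial.
#' @param min_consecutive_difference minimum angular difference between any
#'   two consecutively scheduled streets (degrees), to avoid street-to-street
#'   carry-over.
#' @return object of class `training_task_spec`.
#' @export
training_task_spec <- function(name, min_angular_difference,
                               n_trials = 100L, streets_per_trial = 6L,
                               min_consecutive_difference = 22.5) {
  angles <- build_training_angles(min_angular_difference)
  stopifnot(n_trials >= 1L, streets_per_trial >= 1L)
  structure(
    list(name = name,
         min_angular_difference = min_angular_difference,
         angles = angles,
         n_trials = as.integer(n_trials),
         streets_per_trial = as.integer(streets_per_trial),
         min_consecutive_difference = min_consecutive_difference),
    class = "training_task_spec"
  )
}

#' The five standard training-task specifications
#'
#' @param n_trials,streets_per_trial session shape passed to each spec.
#' @return named list of [training_task_spec()] objects Train-I .. Train-V.
#' @export
training_task_specs <- function(n_trials = 100L, streets_per_trial = 6L) {
  deltas <- c("Train-I" = 22.5, "Train-II" = 18, "Train-III" = 11.25,
              "Train-IV" = 6.425, "Train-V" = 2)
  out <- lapply(names(deltas), function(nm)
    training_task_spec(nm, deltas[[nm]], n_trials = n_trials,
                       streets_per_trial = streets_per_trial))
  names(out) <- names(deltas)
  out
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Schedule a pseudo-randomised training session
#'
#' Draws a sequence of `n_trials * streets_per_trial` street angles such that
#' (i) every angle of the task's grid is used a maximally balanced number of
#' times (per-angle counts differ by at most 1) and (ii) every pair of
#' consecutive streets — including across trial boundaries — differs by at
#' least `min_consecutive_difference` degrees. The draw is deterministic
#' given `seed` (seeded greedy sampling with restarts).
#'
#' @param spec a [training_task_spec()].
#' @param seed integer seed.
#' @param max_retries maximum greedy restarts before giving up.
#' @return data.frame with columns `trial`, `street` (1-based position within
#'   the trial) and `angle` (degrees).
#' @export
schedule_training_session <- function(spec, seed, max_retries = 10000L) {
  stopifnot(inherits(spec, "training_task_spec"))
  angles <- spec$angles
  min_diff <- spec$min_consecutive_difference
  total <- spec$n_trials * spec$streets_per_trial
  if (total < length(angles))
    stop("session too short to use every street at least once")
  # feasibility: every angle needs at least one partner >= min_diff away
  ok <- vapply(angles, function(a) any(abs(angles - a) >= min_diff - 1e-9),
               logical(1))
  if (!all(ok) || length(angles) < 2L)
    stop("scheduling infeasible: consecutive-difference constraint cannot be met")

  with_seed(seed, {
    k <- length(angles)
    base <- total %/% k
    n_extra <- total - base * k
    for (attempt in seq_len(max_retries)) {
      counts <- rep(base, k)
      if (n_extra > 0L)
        counts[sample.int(k, n_extra)] <- base + 1L
      seqn <- integer(total)
      prev <- NA_real_
      failed <- FALSE
      for (i in seq_len(total)) {
        feas <- which(counts > 0L &
                        (is.na(prev) | abs(angles - prev) >= min_diff - 1e-9))
        if (length(feas) == 0L) { failed <- TRUE; break }
        # weight by squared remaining count: keeps the multiset balanced so
        # the endgame does not strand a single repeated angle
        w <- counts[feas]^2
        pick <- if (length(feas) == 1L) feas else
          feas[sample.int(length(feas), 1L, prob = w)]
        seqn[i] <- pick
        counts[pick] <- counts[pick] - 1L
        prev <- angles[pick]
      }
      if (!failed) {
        return(data.frame(
          trial = rep(seq_len(spec$n_trials), each = spec$streets_per_trial),
          street = rep(seq_len(spec$streets_per_trial), spec$n_trials),
          angle = angles[seqn]
        ))
      }
    }
  })
  stop("scheduling infeasible: no valid sequence found within retry budget")
}

#' Transfer-task variant definitions
#'
#' The three transfer variants differ from the training task in the direction
#' of cursor movement. `S` keeps the trained mapping (rightwards/upwards);
#' `M` transposes the horizontal direction (leftwards/upwards), which mirrors
#' the streets along the vertical axis of the window; `L` transposes both
#' (leftwards/downwards), mirroring along both axes.
#'
#' @param name one of `"S"`, `"M"`, `"L"`.
#' @return object of class `transfer_variant` with logical `flip_horizontal`
#'   (mirror about the vertical axis, i.e. x -> W - x), `flip_vertical`
#'   (mirror about the horizontal axis, y -> 1 - y) and `directions`, the
#'   signed axis directions of cursor movement `c(x, y)`.
#' @export
transfer_variant <- function(name = c("S", "M", "L")) {
  name <- match.arg(name)
  def <- switch(name,
    S = list(flip_horizontal = FALSE, flip_vertical = FALSE,
             directions = c(1, 1)),
    M = list(flip_horizontal = TRUE, flip_vertical = FALSE,
             directions = c(-1, 1)),
    L = list(flip_horizontal = TRUE, flip_vertical = TRUE,
             directions = c(-1, -1))
  )
  structure(c(list(name = name), def), class = "transfer_variant")
}

# Fixed shape family for the six transfer curves: perpendicular deflection of
# a 45-degree chord by two low-frequency sinusoids under a half-sine envelope
# (so the curve meets the chord at both ends). Amplitudes in height units.
.curve_family <- data.frame(
  variant_id = 1:6,
  a1 = c(0.035, -0.031, 0.028, -0.038, 0.024, 0.033),
  a2 = c(0.014, 0.017, -0.020, 0.012, -0.018, -0.011),
  k1 = c(1, 1, 1, 1, 1, 1),
  k2 = c(2, 2, 2, 3, 3, 2),
  p1 = c(0.0, 0.4, 0.9, 0.2, 0.7, 1.3),
  p2 = c(0.5, 1.6, 0.3, 1.1, 2.0, 0.8)
)

#' Build the six curved streets of a transfer variant
#'
#' The base (`S`) family is a fixed set of six smooth curves around a central
#' 45-degree chord; `M` and `L` return the same curves reflected about the
#' vertical axis, or both axes, of the task window. Reflections are
#' isometries, so arc lengths are identical across variants.
#'
#' @param variant a [transfer_variant()] or its name.
#' @param length chord length of each curve (height units).
#' @param width corridor width (height units).
#' @param window_width task-window width in height units (height = 1);
#'   defaults to a 16:9 window.
#' @param n_points centreline points per curve.
#' @return list of six [curved_street()] objects.
#' @export
build_transfer_streets <- function(variant = "S", length = 0.5, width = 0.06,
                                   window_width = 16 / 9, n_points = 121L) {
  if (is.character(variant)) variant <- transfer_variant(variant)
  stopifnot(inherits(variant, "transfer_variant"))
  half <- length / (2 * sqrt(2))
  centre <- c(window_width / 2, 0.5)
  s0 <- centre - half
  t <- seq(0, 1, length.out = n_points)
  u <- c(1, 1) / sqrt(2)   # chord direction (45 degrees)
  nrm <- c(-1, 1) / sqrt(2) # left normal
  streets <- lapply(seq_len(6L), function(i) {
    p <- .curve_family[i, ]
    defl <- sin(pi * t) *
      (p$a1 * sin(2 * pi * p$k1 * t + p$p1) +
         p$a2 * sin(2 * pi * p$k2 * t + p$p2))
    xy <- cbind(s0[1] + t * length * u[1] + defl * nrm[1],
                s0[2] + t * length * u[2] + defl * nrm[2])
    if (variant$flip_horizontal) xy[, 1] <- window_width - xy[, 1]
    if (variant$flip_vertical) xy[, 2] <- 1 - xy[, 2]
    curved_street(xy, width = width, variant_id = i)
  })
  names(streets) <- paste0("curve", seq_len(6L))
  streets
}

#' Distance from a point to a street's ideal line
#'
#' For straight streets the perpendicular distance to the ideal line is
#' computed through the triangle-area (Heron) construction over the line
#' endpoints and the query point. For curved streets it is the nearest
#' neighbour (minimum Euclidean distance) over a densely resampled
#' centreline.
#'
#' @param point numeric length-2 point (height units).
#' @param street a street object.
#' @param spacing resampling spacing for curved streets (height units).
#' @return non-negative distance in height units.
#' @export
point_to_ideal_distance <- function(point, street, spacing = 0.002) {
  stopifnot(is.numeric(point), length(point) == 2L)
  if (inherits(street, "straight_street")) {
    a <- sqrt(sum((street$end - street$start)^2))
    if (a <= 0) stop("degenerate street: zero length")
    b <- sqrt(sum((point - street$start)^2))
    cc <- sqrt(sum((point - street$end)^2))
    s <- (a + b + cc) / 2
    area2 <- s * max(s - a, 0) * max(s - b, 0) * max(s - cc, 0)
    2 * sqrt(max(area2, 0)) / a
  } else if (inherits(street, "curved_street")) {
    dense <- resample_centreline(street$centreline, spacing)
    sqrt(min((dense[, 1] - point[1])^2 + (dense[, 2] - point[2])^2))
  } else stop("not a street object")
}
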