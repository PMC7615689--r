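# Interchange formats: tidy long CSV for trajectories and per-stage tables,
# YAML for configurations, JSON for provenance stamps.

.traj_cols <- c("subject_id", "group", "trial", "street", "frame",
                "x", "y", "vx", "vy", "key_h", "key_v", "reset_flag")

#' Convert a trajectory object into a tidy long table
#'
#' @param trajectory a [simulate_street()] result (with recorded frames).
#' @param subject_id,group,trial,street identifying labels for the rows.
#' @return data.frame with one row per frame.
#' @export
trajectory_table <- function(trajectory, subject_id = 1L, group = "",
                             trial = 1L, street = 1L) {
  fr <- trajectory$frames
  data.frame(subject_id = subject_id, group = group, trial = trial,
             street = street, frame = as.integer(fr$frame),
             x = fr$x, y = fr$y, vx = fr$vx, vy = fr$vy,
             key_h = as.integer(fr$key_h), key_v = as.integer(fr$key_v),
             reset_flag = as.integer(fr$reset))
}

#' Write trajectories to CSV
#'
#' Positions and velocities are serialised with 17 significant digits
#' (shortest exact double representation), so a write/read round trip is
#' bit-lossless.
#'
#' @param trajectories a long table as from [trajectory_table()] (rows from
#'   several streets may be concatenated).
#' @param path output CSV path.
#' @export
write_trajectories <- function(trajectories, path) {
  stopifnot(all(.traj_cols %in% names(trajectories)))
  out <- trajectories[, .traj_cols]
  # %.17g guarantees an exact double round trip through text
  for (cl in c("x", "y", "vx", "vy")) out[[cl]] <- sprintf("%.17g", out[[cl]])
  data.table::fwrite(out, path)
}

#' Read trajectories from CSV
#'
#' @param path CSV path written by [write_trajectories()].
#' @param strict logical; when frames within a (subject, trial, street) block
#'   arrive out of order, `strict = TRUE` raises an error while the default
#'   re-sorts them with a warning.
#' @return data.frame in the canonical column order; an empty table (with a
#'   warning) for an empty file.
#' @export
read_trajectories <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- tryCatch(
    data.table::fread(path),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  df <- as.data.frame(dt)
  for (cl in intersect(c("x", "y", "vx", "vy"), names(df)))
    df[[cl]] <- as.numeric(df[[cl]])
  if (nrow(df) == 0L) {
    warning("empty trajectory file: ", path)
    out <- as.data.frame(matrix(nrow = 0, ncol = length(.traj_cols)))
    names(out) <- .traj_cols
    return(out)
  }
  missing <- setdiff(.traj_cols, names(df))
  if (length(missing))
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  key <- interaction(df$subject_id, df$trial, df$street, drop = TRUE)
  unsorted <- any(tapply(df$frame, key, is.unsorted))
  if (unsorted) {
    if (strict) stop("frames out of order in ", path)
    warning("frames out of order; re-sorting")
    df <- df[order(df$subject_id, df$trial, df$street, df$frame), ]
    rownames(df) <- NULL
  }
  df[, .traj_cols]
}

# flatten a run_config into plain lists for YAML
.cfg_to_list <- function(run_cfg) {
  x <- unclass(run_cfg)
  x$kinematics <- unclass(x$kinematics)
  x$effects <- unclass(x$effects)
  x$effects$task_lr_mult <- as.list(x$effects$task_lr_mult)
  x
}

#' Write a run configuration to YAML
#' @param run_cfg a [run_config()].
#' @param path output YAML path.
#' @export
write_run_config <- function(run_cfg, path) {
  yaml::write_yaml(.cfg_to_list(run_cfg), path, precision = 15L)
}

#' Read a run configuration from YAML
#'
#' Unknown keys (at the top level or inside the kinematics/effects blocks)
#' are rejected; missing keys fall back to package defaults.
#'
#' @param path YAML path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  defaults <- .cfg_to_list(run_config())
  bad <- setdiff(names(x), names(defaults))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  kin <- x$kinematics
  if (!is.null(kin)) {
    badk <- setdiff(names(kin), names(defaults$kinematics))
    if (length(badk)) stop("unknown kinematics key(s): ",
                           paste(badk, collapse = ", "))
  }
  eff <- x$effects
  if (!is.null(eff)) {
    bade <- setdiff(names(eff), names(defaults$effects))
    if (length(bade)) stop("unknown effects key(s): ",
                           paste(bade, collapse = ", "))
  }
  merged <- utils::modifyList(defaults, x)
  kin_args <- merged$kinematics
  eff_args <- merged$effects
  eff_args$task_lr_mult <- unlist(eff_args$task_lr_mult)
  args <- merged[setdiff(names(merged), c("kinematics", "effects"))]
  args$kinematics <- do.call(kinematics_config, kin_args)
  args$effects <- do.call(effect_config, eff_args)
  do.call(run_config, args)
}

#' Write a provenance stamp to JSON
#' @param stamp a [provenance_stamp()].
#' @param path output JSON path.
#' @export
write_provenance <- function(stamp, path) {
  jsonlite::write_json(stamp, path, auto_unbox = TRUE, digits = NA)
}
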