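# Kinematic feature extraction.
#
# A trajectory is an ordered (t, x, y) sequence at a constant time step.
# Speeds are forward differences of position over the step; acceleration is
# the signed derivative of scalar speed (so decelerations are negative and
# MinAcceleration is informative); directional change is the absolute
# turning angle between successive displacement vectors per unit time.
# Per-trajectory features are averaged per (participant, task) to build the
# analysis dataset, after dropping tasks flagged as not correctly
# performed.

traj_dt <- function(trajectory) {
  dt <- diff(trajectory$t)
  if (length(dt) == 0) {
    stop_kinvae("trajectory has fewer than 2 samples",
                "kinvae_degenerate_trajectory")
  }
  if (max(abs(dt - dt[1])) > 1e-8 * max(dt[1], 1e-12) + 1e-12) {
    stop_kinvae("trajectory time steps are not constant",
                "kinvae_degenerate_trajectory")
  }
  dt[1]
}

#' Instantaneous speed series of a trajectory
#'
#' Element k is the Euclidean distance between samples k and k+1 divided by
#' the (constant) time step, in screen units per second.
#'
#' @param trajectory A `kinvae_trajectory` (>= 2 samples, constant step).
#' @return Numeric vector of length `n_samples - 1`.
#' @export
speed_series <- function(trajectory) {
  dt <- traj_dt(trajectory)
  sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2) / dt
}

#' Signed acceleration series from a speed series
#'
#' Forward difference of scalar speed over the time step; negative values
#' are decelerations.
#'
#' @param speeds Numeric speed series (length >= 2).
#' @param dt Time step in seconds.
#' @return Numeric vector of length `length(speeds) - 1`.
#' @export
acceleration_series <- function(speeds, dt) {
  if (length(speeds) < 2) {
    stop_kinvae("need at least 2 speed values",
                "kinvae_degenerate_trajectory")
  }
  check_number(dt, "dt", lower = 0, strict = TRUE)
  diff(speeds) / dt
}

#' Directional-change series of a trajectory
#'
#' For each pair of successive displacement vectors, the absolute turning
#' angle (radians in \[0, pi\]) divided by the time step. Zero-length
#' displacements carry no direction and are skipped.
#'
#' @param trajectory A `kinvae_trajectory` (>= 3 samples).
#' @return Numeric vector of length (number of nonzero displacements - 1).
#' @export
directional_change_series <- function(trajectory) {
  dt <- traj_dt(trajectory)
  dx <- diff(trajectory$x); dy <- diff(trajectory$y)
  keep <- (dx != 0 | dy != 0)
  dx <- dx[keep]; dy <- dy[keep]
  if (length(dx) < 2) {
    stop_kinvae("fewer than 2 nonzero displacements: direction undefined",
                "kinvae_degenerate_trajectory")
  }
  n <- length(dx)
  a <- cbind(dx[-n], dy[-n]); b <- cbind(dx[-1], dy[-1])
  dot <- rowSums(a * b)
  cross <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  abs(atan2(cross, dot)) / dt
}

#' Straightness (STH) of a trajectory
#'
#' Ratio of the start-to-end chord length to the total path length; 1 for a
#' perfectly straight drag, 0 for a path returning to its start.
#'
#' @param trajectory A `kinvae_trajectory` with positive path length.
#' @return A number in \[0, 1\].
#' @export
straightness <- function(trajectory) {
  steps <- sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2)
  path <- sum(steps)
  if (!is.finite(path) || path <= 0) {
    stop_kinvae("zero path length: straightness undefined",
                "kinvae_degenerate_trajectory")
  }
  n <- length(trajectory$x)
  chord <- sqrt((trajectory$x[n] - trajectory$x[1])^2 +
                  (trajectory$y[n] - trajectory$y[1])^2)
  min(chord / path, 1)
}

# Mean of interior local maxima (or minima) of a series, i.e. points where
# the first difference changes sign; falls back to the global extremum when
# the series has no interior extremum (e.g. monotone profiles).
peak_mean <- function(series, type = c("max", "min")) {
  type <- match.arg(type)
  n <- length(series)
  if (n >= 3) {
    d <- diff(series)
    left <- d[-(n - 1)]; right <- d[-1]
    idx <- if (type == "max") which(left > 0 & right < 0) else
      which(left < 0 & right > 0)
    if (length(idx) > 0) return(mean(series[idx + 1]))
  }
  if (type == "max") max(series) else min(series)
}

#' Per-trajectory kinematic features
#'
#' Computes the twelve-feature record for one trajectory: mean/sd of speed,
#' mean of local speed maxima and minima (MaxSpeed/MinSpeed), the same four
#' statistics of signed acceleration, straightness STH, mean and sd of
#' directional change, and path length. Local speed/acceleration extrema
#' are interior sign changes of the series' first difference, falling back
#' to the global extremum for monotone series; set `peaks = "global"` to
#' use global extrema throughout.
#'
#' @param trajectory A `kinvae_trajectory` with >= 3 samples and positive
#'   path length.
#' @param peaks `"local"` (default) or `"global"`.
#' @return Named numeric vector: the 12 features of [feature_names()]
#'   (with `MeanLength` holding this trajectory's path length) plus
#'   `PathLength`.
#' @export
trajectory_features <- function(trajectory, peaks = c("local", "global")) {
  peaks <- match.arg(peaks)
  if (length(trajectory$x) < 3) {
    stop_kinvae("trajectory has fewer than 3 samples",
                "kinvae_degenerate_trajectory")
  }
  dt <- traj_dt(trajectory)
  v <- speed_series(trajectory)
  a <- acceleration_series(v, dt)
  dc <- directional_change_series(trajectory)
  path <- sum(sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2))
  pk <- function(s, type) {
    if (peaks == "local") peak_mean(s, type)
    else if (type == "max") max(s) else min(s)
  }
  out <- c(
    MeanSpeed = mean(v),
    MaxSpeed = pk(v, "max"),
    MinSpeed = pk(v, "min"),
    sdSpeed = stats::sd(v),
    MeanAcceleration = mean(a),
    MaxAcceleration = pk(a, "max"),
    MinAcceleration = pk(a, "min"),
    sdAcceleration = stats::sd(a),
    STH = straightness(trajectory),
    DC = mean(dc),
    sdDC = stats::sd(dc),
    MeanLength = path,
    PathLength = path
  )
  # single-interval degenerate cases: sd of a length-1 series is NA
  out[is.na(out)] <- 0
  out
}

new_feature_dataset <- function(df, stats = NULL) {
  required <- c("participant_id", "group", "task_id", KINVAE_FEATURES)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_kinvae(paste("feature dataset missing column(s):",
                      paste(missing, collapse = ", ")),
                "kinvae_schema_error")
  }
  if (!all(df$group %in% c(0L, 1L))) {
    stop_kinvae("group labels must be 0 or 1", "kinvae_schema_error")
  }
  fm <- as.matrix(df[KINVAE_FEATURES])
  if (anyNA(fm) || any(!is.finite(fm))) {
    stop_kinvae("feature dataset contains missing or non-finite values",
                "kinvae_schema_error")
  }
  rownames(df) <- NULL
  structure(df, class = c("kinvae_features", "data.frame"),
            standardization_stats = stats)
}

#' @export
print.kinvae_features <- function(x, ...) {
  counts <- table(factor(x$group, levels = 0:1))
  cat(sprintf(
    "<kinvae_features> %d rows, %d participants (group 0: %d rows, group 1: %d rows)%s\n",
    nrow(x), length(unique(x$participant_id)), counts[1], counts[2],
    if (is.null(attr(x, "standardization_stats"))) "" else " [standardized]"
  ))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("... (", nrow(x) - 4, " more rows)\n", sep = "")
  invisible(x)
}

feature_matrix <- function(dataset) {
  as.matrix(as.data.frame(dataset)[KINVAE_FEATURES])
}

#' Build the per-task feature dataset from a cohort of trajectories
#'
#' Applies the dataset assembly rules: tasks flagged as not correctly
#' performed are dropped; per-trajectory features of the retained tasks are
#' averaged into one row per (participant, task); `MeanLength` is the mean
#' path length of the task's trajectories and the trajectory count per task
#' is recorded as `nTrajectories` (not a model feature). Degenerate
#' trajectories (< 3 samples or zero path length) are excluded with a
#' warning; participants with no retained task are dropped with a warning.
#'
#' @param cohort A `kinvae_cohort` from [generate_cohort()] (or assembled
#'   from read trajectories).
#' @param peaks Peak statistic convention, see [trajectory_features()].
#' @return A `kinvae_features` dataset, one row per retained
#'   (participant, task).
#' @export
build_dataset <- function(cohort, peaks = "local") {
  stopifnot(inherits(cohort, "kinvae_cohort"))
  if (length(cohort$trajectories) == 0) {
    stop_kinvae("cohort contains no trajectories", "kinvae_schema_error")
  }
  tc <- cohort$task_correct
  correct_map <- stats::setNames(tc$correct,
                                 paste(tc$participant_id, tc$task_id))

  feats <- vector("list", length(cohort$trajectories))
  keys <- character(length(cohort$trajectories))
  n_dropped <- 0L
  for (i in seq_along(cohort$trajectories)) {
    tr <- cohort$trajectories[[i]]
    key <- paste(tr$participant_id, tr$task_id)
    ok <- correct_map[key]
    if (is.na(ok)) {
      stop_kinvae(sprintf("no correctness flag for participant %s task %s",
                          tr$participant_id, tr$task_id),
                  "kinvae_schema_error")
    }
    if (!ok) next
    f <- tryCatch(trajectory_features(tr, peaks = peaks),
                  kinvae_degenerate_trajectory = function(e) NULL)
    if (is.null(f)) {
      n_dropped <- n_dropped + 1L
      next
    }
    feats[[i]] <- f
    keys[i] <- key
  }
  if (n_dropped > 0) {
    warning(sprintf("excluded %d degenerate trajectories", n_dropped))
  }
  used <- !vapply(feats, is.null, logical(1))
  if (!any(used)) {
    stop_kinvae("no usable trajectories after filtering",
                "kinvae_schema_error")
  }
  fm <- do.call(rbind, feats[used])
  key <- keys[used]
  agg <- rowsum(fm, key)
  counts <- as.numeric(table(key)[rownames(agg)])
  agg <- agg / counts

  parts <- sub(" [^ ]+$", "", rownames(agg))
  tasks <- as.integer(sub("^.* ", "", rownames(agg)))
  df <- data.frame(
    participant_id = parts,
    group = as.integer(cohort$labels[parts]),
    task_id = tasks,
    difficulty = (tasks - 1L) %/% 5L + 1L,
    as.data.frame(agg[, KINVAE_FEATURES, drop = FALSE]),
    nTrajectories = counts
  )
  all_parts <- names(cohort$labels)
  lost <- setdiff(all_parts, unique(df$participant_id))
  if (length(lost) > 0) {
    warning(sprintf("participant(s) with no retained task dropped: %s",
                    paste(lost, collapse = ", ")))
  }
  df <- df[order(match(df$participant_id, all_parts), df$task_id), ]
  new_feature_dataset(df)
}

#' Standardize (z-score) the feature columns of a dataset
#'
#' With `stats = NULL`, column means and SDs are computed from the dataset
#' itself and stored on the result; passing the stored stats of a training
#' split standardizes a test split without leakage.
#'
#' @param dataset A `kinvae_features` dataset.
#' @param stats Optional data frame with columns `feature`, `mean`, `sd`
#'   covering all 12 features (as produced by a previous call, retrievable
#'   via `attr(x, "standardization_stats")`).
#' @return A standardized `kinvae_features` dataset carrying the stats used.
#' @export
standardize <- function(dataset, stats = NULL) {
  stopifnot(inherits(dataset, "kinvae_features"))
  x <- feature_matrix(dataset)
  if (is.null(stats)) {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    bad <- names(sd)[!is.finite(sd) | sd <= 0]
    if (length(bad) > 0) {
      stop_kinvae(paste("zero-variance feature column(s):",
                        paste(bad, collapse = ", ")),
                  "kinvae_zero_variance")
    }
    stats <- data.frame(feature = KINVAE_FEATURES, mean = unname(mu),
                        sd = unname(sd))
  } else {
    if (!all(KINVAE_FEATURES %in% stats$feature) || any(stats$sd <= 0)) {
      stop_kinvae("`stats` must cover all 12 features with positive SDs",
                  "kinvae_invalid_config")
    }
    stats <- stats[match(KINVAE_FEATURES, stats$feature), ]
  }
  z <- sweep(sweep(x, 2, stats$mean, "-"), 2, stats$sd, "/")
  df <- as.data.frame(dataset)
  df[KINVAE_FEATURES] <- z
  new_feature_dataset(df, stats = stats)
}
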