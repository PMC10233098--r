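# Synthetic cohort generation.
#
# Two generation paths are provided:
#   * trajectory mode (`generate_cohort`): raw 40 Hz tap-to-lift drag paths
#     built from a minimum-jerk base profile with class-dependent speed
#     jitter and lateral tremor, exercising the feature extractor;
#   * feature mode (`sample_feature_table`): per-task feature rows drawn
#     from a group-conditional multivariate normal whose standardized mean
#     differences equal the configured effect sizes exactly, exercising the
#     model. Feature mode is the canonical input for model validation
#     because its statistical structure is controlled in closed form.

# Raw-unit location/scale of each feature in feature-space mode, chosen to
# resemble drags across a 1280 x 800 screen at 40 Hz (speeds in units/s,
# accelerations in units/s^2, DC in rad/s, lengths in units).
FEATURE_SCALES <- data.frame(
  feature = KINVAE_FEATURES,
  mean = c(600, 1200, 150, 250, 0, 4000, -4000, 2000, 0.92, 8, 12, 600),
  sd   = c(150,  300,  60,  80, 300, 1200, 1200,  600, 0.04, 3,  4, 120)
)

# Group-1 shifts of the two class knobs (log duration, log jitter
# amplitude) per unit of requested standardized effect on MaxSpeed and
# MaxAcceleration. Solved from the generator's empirical sensitivity matrix
# (effect size per unit log-knob, estimated by large-cohort simulation of
# this same generator):
#   d(MaxSpeed ES, MaxAccel ES) / d(logT, logA) = S,  KNOB_GAIN = solve(S).
TRAJ_KNOB_GAIN <- matrix(
  c(-0.176107,  0.001144,
    -0.223950,  0.397578),
  nrow = 2, byrow = TRUE,
  dimnames = list(c("logT", "logA"), c("MaxSpeed", "MaxAcceleration"))
)

default_effect_sizes <- function() {
  es <- stats::setNames(numeric(12), KINVAE_FEATURES)
  es[c("sdSpeed", "MaxAcceleration", "sdAcceleration")] <- 1.5
  es[c("MaxSpeed", "MinAcceleration")] <- -1.5
  es
}

#' Configuration of a synthetic cohort
#'
#' Describes a two-group study: `n_per_group` participants per group, each
#' performing `n_tasks` dragging tasks (organized as `n_tasks / 5`
#' difficulty levels of 5 tasks), with `n_traj_per_task` tap-to-lift
#' trajectories per task sampled at `sample_rate` Hz. `effect_sizes` gives
#' the standardized between-group mean difference (group 1 minus group 0)
#' targeted for each feature; the default places +1.5 on sdSpeed,
#' MaxAcceleration and sdAcceleration and -1.5 on MaxSpeed and
#' MinAcceleration, the qualitative pattern characteristic of ASD-like
#' motion in touchscreen phenotyping.
#'
#' @param n_per_group Participants per group (default 30).
#' @param n_tasks Tasks per participant, multiple of 5 (default 25).
#' @param n_traj_per_task Trajectories per task (default 5).
#' @param sample_rate Sampling rate in Hz (default 40).
#' @param effect_sizes Named numeric vector (subset of [feature_names()])
#'   of standardized between-group differences; unnamed features default
#'   to 0. Pass `NULL` for all-zero effects.
#' @param noise_scale Multiplier on within-group variability (default 1).
#' @param incorrect_task_rate Fraction of tasks flagged as not correctly
#'   performed, in \[0,1\] (default 0).
#' @param latent_rank For feature mode: if non-`NULL`, the within-group
#'   (and, approximately, between-group) variation spans this many latent
#'   directions in feature space, plus small isotropic noise. Must be
#'   between 1 and 12.
#' @param seed Integer master seed (default 1).
#' @return A `kinvae_cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 30, n_tasks = 25, n_traj_per_task = 5,
                          sample_rate = 40,
                          effect_sizes = default_effect_sizes(),
                          noise_scale = 1, incorrect_task_rate = 0,
                          latent_rank = NULL, seed = 1) {
  check_number(n_per_group, "n_per_group", lower = 1)
  if (n_tasks < 5 || n_tasks %% 5 != 0) {
    stop_kinvae("`n_tasks` must be a positive multiple of 5",
                "kinvae_invalid_config")
  }
  check_number(n_traj_per_task, "n_traj_per_task", lower = 1)
  check_number(sample_rate, "sample_rate", lower = 0, strict = TRUE)
  check_number(noise_scale, "noise_scale", lower = 0, strict = TRUE)
  check_number(incorrect_task_rate, "incorrect_task_rate", lower = 0)
  if (incorrect_task_rate > 1) {
    stop_kinvae("`incorrect_task_rate` must be in [0,1]",
                "kinvae_invalid_config")
  }
  es <- stats::setNames(numeric(12), KINVAE_FEATURES)
  if (!is.null(effect_sizes)) {
    if (is.null(names(effect_sizes)) ||
        !all(names(effect_sizes) %in% KINVAE_FEATURES)) {
      stop_kinvae("`effect_sizes` must be named with feature names",
                  "kinvae_invalid_config")
    }
    es[names(effect_sizes)] <- effect_sizes
  }
  if (!is.null(latent_rank)) {
    check_number(latent_rank, "latent_rank", lower = 1)
    if (latent_rank > 12) {
      stop_kinvae("`latent_rank` cannot exceed the 12 features",
                  "kinvae_invalid_config")
    }
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      n_tasks = as.integer(n_tasks),
      n_traj_per_task = as.integer(n_traj_per_task),
      sample_rate = sample_rate,
      effect_sizes = es,
      noise_scale = noise_scale,
      incorrect_task_rate = incorrect_task_rate,
      latent_rank = if (is.null(latent_rank)) NULL else as.integer(latent_rank),
      seed = as.integer(seed)
    ),
    class = "kinvae_cohort_config"
  )
}

# Smooth unit-variance noise: moving-average filtered white noise,
# restandardized. Used for both speed-profile jitter and lateral tremor.
smooth_noise <- function(n, window) {
  if (n <= 0) return(numeric(0))
  w <- max(3L, as.integer(window))
  raw <- stats::rnorm(n + 2L * w)
  sm <- stats::filter(raw, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm[(w + 1L):(w + n)])
  s <- stats::sd(sm)
  if (!is.finite(s) || s == 0) return(rep(0, n))
  (sm - mean(sm)) / s
}

new_trajectory <- function(participant_id, task_id, trajectory_index,
                           t, x, y) {
  structure(
    list(participant_id = participant_id, task_id = task_id,
         trajectory_index = trajectory_index, t = t, x = x, y = y),
    class = "kinvae_trajectory"
  )
}

#' Simulate one tap-to-lift drag trajectory
#'
#' The base path is a minimum-jerk profile along the straight chord from
#' `start` to `target` (position fraction \eqn{10\tau^3 - 15\tau^4 +
#' 6\tau^5}), the profile human point-to-point movements approximate.
#' Class-dependent irregularity enters two ways: multiplicative jitter on
#' the tangential speed profile (smooth noise of relative amplitude
#' `class_params$speed_jitter`) and additive lateral tremor perpendicular
#' to the chord (`class_params$tremor`, screen units). Both vanish at the
#' endpoints, so the path starts exactly at `start` and ends exactly at
#' `target`.
#'
#' @param start,target Numeric length-2 (x, y) screen coordinates.
#' @param duration Movement time in seconds (> 0).
#' @param class_params List with elements `speed_jitter` (>= 0) and
#'   `tremor` (>= 0).
#' @param sample_rate Samples per second (default 40).
#' @param seed Optional integer seed for the jitter/tremor draws.
#' @param participant_id,task_id,trajectory_index Identifiers stored on the
#'   result.
#' @return A `kinvae_trajectory` with `round(duration * sample_rate) + 1`
#'   samples at a constant time step.
#' @export
generate_trajectory <- function(start, target, duration,
                                class_params = list(speed_jitter = 0,
                                                    tremor = 0),
                                sample_rate = 40, seed = NULL,
                                participant_id = "P1", task_id = 1L,
                                trajectory_index = 1L) {
  check_number(duration, "duration", lower = 0, strict = TRUE)
  check_number(sample_rate, "sample_rate", lower = 0, strict = TRUE)
  start <- as.numeric(start); target <- as.numeric(target)
  if (length(start) != 2 || length(target) != 2 ||
      isTRUE(all(start == target))) {
    stop_kinvae("`start` and `target` must be distinct (x, y) points",
                "kinvae_invalid_config")
  }
  jitter <- class_params$speed_jitter %||% 0
  tremor <- class_params$tremor %||% 0

  n <- round(duration * sample_rate) + 1L
  if (n < 3L) {
    stop_kinvae("duration x sample_rate too small: need >= 3 samples",
                "kinvae_invalid_config")
  }
  build <- function() {
    t <- (seq_len(n) - 1L) / sample_rate
    tau <- pmin(t / duration, 1)
    frac <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    chord <- target - start
    dist <- sqrt(sum(chord^2))
    u <- chord / dist
    nrm <- c(-u[2], u[1])

    if (jitter > 0) {
      # modulate the tangential speed profile, then renormalize total
      # progress so the drag still terminates at the target
      base_step <- diff(frac) * dist
      mod <- pmax(1 + jitter * smooth_noise(n - 1L, sample_rate / 8), 0.05)
      step <- base_step * mod
      prog <- c(0, cumsum(step))
      prog <- prog * dist / prog[n]
    } else {
      prog <- frac * dist
    }
    x <- start[1] + prog * u[1]
    y <- start[2] + prog * u[2]
    if (tremor > 0) {
      e <- smooth_noise(n, sample_rate / 6) * tremor
      # pin the tremor to zero at both endpoints
      e <- e - (e[1] + (e[n] - e[1]) * (seq_len(n) - 1) / (n - 1))
      x <- x + e * nrm[1]
      y <- y + e * nrm[2]
    }
    new_trajectory(participant_id, task_id, trajectory_index, t, x, y)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Baseline kinematic knobs shared by both groups; group 1 additionally
# shifts log-duration and log-jitter via TRAJ_KNOB_GAIN.
TRAJ_BASELINE <- list(
  duration = 0.9,       # s, typical drag time across ~550 units
  speed_jitter = 0.25,  # relative amplitude of speed-profile modulation
  tremor = 3,           # screen units of lateral displacement noise
  sd_log_dur_part = 0.12, sd_log_jit_part = 0.25,
  sd_log_dur_traj = 0.08
)

participant_ids <- function(config) {
  c(sprintf("TD%02d", seq_len(config$n_per_group)),
    sprintf("ASD%02d", seq_len(config$n_per_group)))
}

#' Generate a full synthetic cohort of raw trajectories
#'
#' Simulates `2 * n_per_group` participants, each performing `n_tasks`
#' dragging tasks with `n_traj_per_task` trajectories per task. Start
#' points lie near the bottom of a 1280 x 800 canvas and targets near the
#' top. Each participant carries lognormal random effects on movement
#' duration and speed-jitter amplitude; group-1 participants additionally
#' shift these two knobs so that the extracted MaxSpeed and MaxAcceleration
#' effect sizes match `effect_sizes` in expectation (the remaining
#' configured effects — sdSpeed, sdAcceleration, MinAcceleration — arise as
#' correlated consequences of the jitter knob and are realized
#' qualitatively, not exactly).
#'
#' @param config A [cohort_config()].
#' @return A `kinvae_cohort` list with elements `trajectories` (list of
#'   `kinvae_trajectory`), `labels` (named 0/1 integer vector keyed by
#'   participant), `task_correct` (data frame participant_id/task_id/
#'   correct) and the config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "kinvae_cohort_config"))
  bl <- TRAJ_BASELINE
  ids <- participant_ids(config)
  groups <- rep(c(0L, 1L), each = config$n_per_group)
  names(groups) <- ids

  shift <- as.numeric(
    TRAJ_KNOB_GAIN %*%
      config$effect_sizes[c("MaxSpeed", "MaxAcceleration")]
  ) # (d logT, d logA) applied to group 1

  difficulty <- rep(seq_len(config$n_tasks %/% 5L), each = 5L)
  trajectories <- vector("list",
                         length(ids) * config$n_tasks * config$n_traj_per_task)
  correct <- vector("list", length(ids))
  k <- 0L
  for (i in seq_along(ids)) {
    pid <- ids[i]
    g <- groups[[pid]]
    pe <- with_seed(substream_seed(config$seed, "participant", i), {
      list(log_dur = stats::rnorm(1, 0, bl$sd_log_dur_part * config$noise_scale),
           log_jit = stats::rnorm(1, 0, bl$sd_log_jit_part * config$noise_scale))
    })
    dur_p <- bl$duration * exp(pe$log_dur + g * shift[1])
    jit_p <- bl$speed_jitter * exp(pe$log_jit + g * shift[2])

    corr_p <- with_seed(substream_seed(config$seed, "correct", i), {
      stats::runif(config$n_tasks) >= config$incorrect_task_rate
    })
    correct[[i]] <- data.frame(participant_id = pid,
                               task_id = seq_len(config$n_tasks),
                               correct = corr_p)

    for (task in seq_len(config$n_tasks)) {
      geo <- with_seed(substream_seed(config$seed, "task", i, task), {
        list(sx = stats::runif(config$n_traj_per_task, 200, 1080),
             sy = stats::runif(config$n_traj_per_task, 80, 160),
             tx = stats::runif(config$n_traj_per_task, 200, 1080),
             ty = stats::runif(config$n_traj_per_task, 620, 760),
             ld = stats::rnorm(config$n_traj_per_task, 0,
                               bl$sd_log_dur_traj * config$noise_scale))
      })
      dscale <- 1 + 0.04 * (difficulty[task] - 3) # harder tasks: slower
      for (j in seq_len(config$n_traj_per_task)) {
        k <- k + 1L
        trajectories[[k]] <- generate_trajectory(
          start = c(geo$sx[j], geo$sy[j]),
          target = c(geo$tx[j], geo$ty[j]),
          duration = dur_p * dscale * exp(geo$ld[j]),
          class_params = list(speed_jitter = jit_p,
                              tremor = bl$tremor * config$noise_scale),
          sample_rate = config$sample_rate,
          seed = substream_seed(config$seed, "traj", i, task, j),
          participant_id = pid, task_id = task, trajectory_index = j
        )
      }
    }
  }
  structure(
    list(trajectories = trajectories,
         labels = groups,
         task_correct = do.call(rbind, correct),
         config = config),
    class = "kinvae_cohort"
  )
}

#' Sample a feature table directly from the group-conditional model
#'
#' Bypasses trajectory simulation: each participant-task row is drawn from
#' a group-conditional multivariate normal over the 12 features, with
#' standardized between-group mean differences equal to
#' `config$effect_sizes` by construction. Within-group variance splits into
#' a participant random effect (30%) and row-level noise (70%), scaled by
#' `noise_scale`. With `latent_rank = r`, both components are confined to
#' an r-dimensional subspace of feature space (the first direction aligned
#' with the effect-size contrast when one is configured) plus small
#' isotropic noise — the construction used to probe latent-dimension
#' selection.
#'
#' @param config A [cohort_config()].
#' @return A `kinvae_features` dataset of `2 * n_per_group * n_tasks` rows.
#' @export
sample_feature_table <- function(config) {
  stopifnot(inherits(config, "kinvae_cohort_config"))
  p <- 12L
  ids <- participant_ids(config)
  groups <- rep(c(0L, 1L), each = config$n_per_group)
  n_tasks <- config$n_tasks
  es <- config$effect_sizes
  tau2 <- 0.3; omega2 <- 0.7 # participant / row variance split (z-scale)

  if (is.null(config$latent_rank)) {
    sd_z <- rep(sqrt(tau2 + omega2), p) # = 1
    draw_part <- function() stats::rnorm(p, 0, sqrt(tau2))
    draw_row <- function(nr) matrix(stats::rnorm(nr * p, 0, sqrt(omega2)),
                                    nr, p)
  } else {
    r <- config$latent_rank
    psi <- 0.05
    basis <- with_seed(substream_seed(config$seed, "latent-basis"), {
      M <- matrix(stats::rnorm(p * r), p, r)
      if (sqrt(sum(es^2)) > 0) M[, 1] <- es
      qr.Q(qr(M))
    })
    # scale every feature's loading row to put exactly (1 - psi) of its
    # variance in the r-dimensional span, so each feature carries the same
    # signal-to-isotropic-noise ratio
    rn <- pmax(sqrt(rowSums(basis^2)), 1e-8)
    A <- basis / rn * sqrt((1 - psi) / (tau2 + omega2))
    sd_z <- sqrt((tau2 + omega2) * rowSums(A^2) + psi) # = 1 by construction
    draw_part <- function() as.numeric(A %*% stats::rnorm(r, 0, sqrt(tau2)))
    draw_row <- function(nr) {
      matrix(stats::rnorm(nr * r, 0, sqrt(omega2)), nr, r) %*% t(A) +
        matrix(stats::rnorm(nr * p, 0, sqrt(psi)), nr, p)
    }
  }

  delta <- es * sd_z # raw z-scale shift realizing the standardized effects
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- groups[i]
    b_p <- with_seed(substream_seed(config$seed, "feat-part", i), draw_part())
    noise <- with_seed(substream_seed(config$seed, "feat-rows", i),
                       draw_row(n_tasks))
    z <- sweep(noise * config$noise_scale, 2,
               (g - 0.5) * delta + b_p * config$noise_scale, "+")
    x <- sweep(sweep(z, 2, FEATURE_SCALES$sd, "*"), 2,
               FEATURE_SCALES$mean, "+")
    colnames(x) <- KINVAE_FEATURES
    rows[[i]] <- cbind(
      data.frame(participant_id = ids[i], group = g,
                 task_id = seq_len(n_tasks),
                 difficulty = rep(seq_len(n_tasks %/% 5L), each = 5L)),
      as.data.frame(x)
    )
  }
  new_feature_dataset(do.call(rbind, rows))
}
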