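# Plain-text serialization: trajectory CSV, feature CSV, model bundle
# (JSON, full precision) and run reports. Write-then-read round trips
# reproduce values to full double precision.

#' Write / read the trajectory CSV
#'
#' One row per sample, columns participant_id, group, task_id, difficulty,
#' trajectory_index, t, x, y.
#'
#' @param cohort A `kinvae_cohort`.
#' @param path Output file.
#' @return `write_trajectories`: the path, invisibly. `read_trajectories`:
#'   a `kinvae_cohort` (with `task_correct` defaulting to all-correct
#'   unless a flag column is present).
#' @export
write_trajectories <- function(cohort, path) {
  stopifnot(inherits(cohort, "kinvae_cohort"))
  rows <- lapply(cohort$trajectories, function(tr) {
    data.frame(participant_id = tr$participant_id,
               group = as.integer(cohort$labels[tr$participant_id]),
               task_id = tr$task_id,
               difficulty = (tr$task_id - 1L) %/% 5L + 1L,
               trajectory_index = tr$trajectory_index,
               t = tr$t, x = tr$x, y = tr$y)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @param tolerance Relative tolerance on time-step uniformity.
#' @export
read_trajectories <- function(path, tolerance = 1e-6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "group", "task_id", "trajectory_index",
              "t", "x", "y")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop_kinvae(paste("trajectory file missing column(s):",
                      paste(missing, collapse = ", ")),
                "kinvae_schema_error")
  }
  for (col in c("t", "x", "y")) {
    if (!is.numeric(df[[col]])) {
      stop_kinvae(sprintf("non-numeric values in column '%s'", col),
                  "kinvae_schema_error")
    }
  }
  key <- paste(df$participant_id, df$task_id, df$trajectory_index)
  trajectories <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, ][order(df$t[idx]), ]
    dt <- diff(sub$t)
    if (length(dt) > 0 && (max(dt) - min(dt)) > tolerance * max(dt)) {
      stop_kinvae(sprintf("nonuniform time steps for %s", key[idx[1]]),
                  "kinvae_schema_error")
    }
    new_trajectory(sub$participant_id[1], sub$task_id[1],
                   sub$trajectory_index[1], sub$t, sub$x, sub$y)
  })
  names(trajectories) <- NULL
  lab <- unique(df[c("participant_id", "group")])
  labels <- stats::setNames(as.integer(lab$group), lab$participant_id)
  pt <- unique(df[c("participant_id", "task_id")])
  structure(
    list(trajectories = trajectories, labels = labels,
         task_correct = data.frame(participant_id = pt$participant_id,
                                   task_id = pt$task_id, correct = TRUE),
         config = NULL),
    class = "kinvae_cohort"
  )
}

#' Write / read the feature CSV
#'
#' Columns participant_id, group, task_id, difficulty, then the 12 feature
#' names. Reading validates the schema and rejects duplicate
#' (participant, task) keys and non-numeric cells.
#'
#' @param dataset A `kinvae_features` dataset.
#' @param path File path.
#' @export
write_features <- function(dataset, path) {
  stopifnot(inherits(dataset, "kinvae_features"))
  df <- as.data.frame(dataset)
  cols <- c("participant_id", "group", "task_id", "difficulty",
            KINVAE_FEATURES)
  cols <- cols[cols %in% names(df)]
  utils::write.csv(format(df[cols], digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("participant_id", "group", "task_id",
                       KINVAE_FEATURES), names(df))
  if (length(missing) > 0) {
    stop_kinvae(paste("feature file missing column(s):",
                      paste(missing, collapse = ", ")),
                "kinvae_schema_error")
  }
  for (col in KINVAE_FEATURES) {
    if (!is.numeric(df[[col]])) {
      stop_kinvae(sprintf("non-numeric values in feature column '%s'", col),
                  "kinvae_schema_error")
    }
  }
  key <- paste(df$participant_id, df$task_id)
  if (anyDuplicated(key)) {
    stop_kinvae(sprintf("duplicate (participant, task) key: %s",
                        key[anyDuplicated(key)]),
                "kinvae_schema_error")
  }
  if (!"difficulty" %in% names(df)) {
    df$difficulty <- (df$task_id - 1L) %/% 5L + 1L
  }
  new_feature_dataset(df)
}

#' Save / load a trained model bundle
#'
#' A single JSON document holding the network weights (flattened arrays
#' with shapes), the network config, the standardization stats and the
#' loss history, at full double precision.
#'
#' @param model A `kinvae_model`.
#' @param path File path (`.json`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "kinvae_model"))
  flat <- flatten_params(model$params)
  weights <- lapply(flat, function(a) {
    list(dim = if (is.matrix(a)) dim(a) else length(a), data = as.numeric(a))
  })
  bundle <- list(
    format = "kinvae-model-1",
    config = unclass(model$config),
    stats = model$stats,
    weights = weights,
    history = model$history
  )
  jsonlite::write_json(bundle, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(bundle$format, "kinvae-model-1")) {
    stop_kinvae("not a kinvae model bundle", "kinvae_schema_error")
  }
  cfg <- bundle$config
  config <- network_config(
    latent_dim = cfg$latent_dim, encoder_hidden = cfg$encoder_hidden,
    predictor_hidden = cfg$predictor_hidden, activation = cfg$activation,
    predictor_output = cfg$predictor_output, epochs = cfg$epochs,
    batch_size = cfg$batch_size, learning_rate = cfg$learning_rate,
    optimizer = cfg$optimizer, seed = cfg$seed
  )
  params <- init_params(config)
  flat <- flatten_params(params)
  for (nm in names(flat)) {
    w <- bundle$weights[[nm]]
    if (is.null(w)) {
      stop_kinvae(sprintf("model bundle missing weight '%s'", nm),
                  "kinvae_schema_error")
    }
    a <- as.numeric(w$data)
    if (length(w$dim) == 2) a <- matrix(a, w$dim[1], w$dim[2])
    flat[[nm]] <- a
  }
  structure(
    list(params = apply_flat(params, flat), config = config,
         stats = as.data.frame(bundle$stats),
         history = as.data.frame(bundle$history)),
    class = "kinvae_model"
  )
}
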