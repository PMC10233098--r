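# Latent-space analysis downstream of training: projections, PCA-based
# dimension selection, class-conditional diagonal-Gaussian fits,
# density-based assignment, Monte-Carlo single-feature perturbation and
# per-feature assignment-probability response curves.
#
# All analysis uses the encoder mean mu (no sampling noise): the mean is
# the canonical latent representation of an observation, and a
# participant's position is the arithmetic mean of their task positions.

#' Project a dataset into the latent space
#'
#' @param model A `kinvae_model`.
#' @param dataset A `kinvae_features` dataset (standardized with the
#'   model's stats, or raw — raw data are standardized internally).
#' @return A `kinvae_projection`: `task_points` (data frame with
#'   participant_id, group, task_id and latent columns z1..zd),
#'   `participant_points` (one row per participant, exact mean of its task
#'   rows), and `labels`.
#' @export
project_latent <- function(model, dataset) {
  stopifnot(inherits(model, "kinvae_model"),
            inherits(dataset, "kinvae_features"))
  if (is.null(attr(dataset, "standardization_stats"))) {
    dataset <- standardize(dataset, stats = model$stats)
  }
  df <- as.data.frame(dataset)
  mu <- encode(model, feature_matrix(dataset))$mu
  d <- ncol(mu)
  colnames(mu) <- paste0("z", seq_len(d))
  task_points <- cbind(df[c("participant_id", "group", "task_id")],
                       as.data.frame(mu))
  pm <- rowsum(mu, df$participant_id)
  pm <- pm / as.numeric(table(df$participant_id)[rownames(pm)])
  labels <- df$group[match(rownames(pm), df$participant_id)]
  participant_points <- data.frame(participant_id = rownames(pm),
                                   group = labels,
                                   as.data.frame(pm), row.names = NULL)
  structure(list(task_points = task_points,
                 participant_points = participant_points,
                 latent_dim = d),
            class = "kinvae_projection")
}

latent_matrix <- function(points) {
  as.matrix(points[grep("^z[0-9]+$", names(points))])
}

#' PCA explained-variance profile of latent points
#'
#' Eigen-decomposition of the points' covariance; used to pick the number
#' of latent variables worth keeping: train once with a generous latent
#' dimension, then keep the smallest m whose leading components explain at
#' least `threshold` of the variance.
#'
#' @param points Matrix of latent vectors, or a data frame with z columns
#'   (e.g. `participant_points` of a [project_latent()] result).
#' @param threshold Cumulative explained-variance threshold for the
#'   suggested dimension (default 0.95).
#' @return A `kinvae_pca`: `explained_variance_ratios` (nonincreasing,
#'   summing to 1), `loadings`, `cumulative`, and `n_components` (smallest
#'   m with cumulative ratio >= threshold).
#' @export
pca_explained_variance <- function(points, threshold = 0.95) {
  X <- if (is.data.frame(points)) latent_matrix(points) else as.matrix(points)
  if (nrow(X) < 3) {
    stop_kinvae("need at least 3 points for a PCA", "kinvae_degenerate")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ratios <- ev / sum(ev)
  cum <- cumsum(ratios)
  structure(
    list(explained_variance_ratios = ratios,
         loadings = pc$rotation,
         cumulative = cum,
         threshold = threshold,
         n_components = which(cum >= threshold - 1e-12)[1]),
    class = "kinvae_pca"
  )
}

#' Fit a diagonal Gaussian to one class's latent points
#'
#' Maximum-likelihood fit: sample mean and per-dimension variances with
#' the 1/n divisor, floored at 1e-6 to keep densities well-defined for
#' degenerate point sets. The diagonal form mirrors the structure the KL
#' regularization imposes on the latent space.
#'
#' @param points Latent matrix or data frame with z columns (one class).
#' @param label Class label stored on the fit (0 or 1).
#' @return A `kinvae_gaussian` with `mean`, `variances`, `label`, `n`.
#' @export
fit_class_gaussian <- function(points, label = NA) {
  X <- if (is.data.frame(points)) latent_matrix(points) else as.matrix(points)
  n <- nrow(X)
  if (is.null(n) || n < 2) {
    stop_kinvae("need at least 2 points to fit a class Gaussian",
                "kinvae_fit_error")
  }
  mu <- colMeans(X)
  v <- colMeans(sweep(X, 2, mu)^2)
  structure(list(label = label, mean = mu,
                 variances = pmax(v, 1e-6), n = n),
            class = "kinvae_gaussian")
}

gaussian_logpdf <- function(g, point) {
  sum(stats::dnorm(point, mean = g$mean, sd = sqrt(g$variances), log = TRUE))
}

#' Assignment posterior of a latent point under two class Gaussians
#'
#' Evaluates the two diagonal-Gaussian densities at the point (in
#' log-space) and normalizes with equal priors:
#' p_class = pdf_class / (pdf_td + pdf_asd).
#'
#' @param point Latent vector (or matrix of points, one per row).
#' @param g_td,g_asd `kinvae_gaussian` fits for groups 0 and 1.
#' @return Named vector `c(p_td, p_asd)` (or an n x 2 matrix), each pair
#'   summing to 1.
#' @export
assignment_posterior <- function(point, g_td, g_asd) {
  if (length(g_td$mean) != length(g_asd$mean)) {
    stop_kinvae("class Gaussians have mismatched dimensions",
                "kinvae_shape_error")
  }
  one <- function(p) {
    if (length(p) != length(g_td$mean)) {
      stop_kinvae("point dimension does not match the Gaussians",
                  "kinvae_shape_error")
    }
    lp <- c(gaussian_logpdf(g_td, p), gaussian_logpdf(g_asd, p))
    if (all(!is.finite(lp))) {
      stop_kinvae("both class densities vanish at this point",
                  "kinvae_undecidable_point")
    }
    w <- exp(lp - log_sum_exp(lp))
    c(p_td = w[1], p_asd = w[2])
  }
  if (is.matrix(point)) t(apply(point, 1, one)) else one(as.numeric(point))
}

feature_moments <- function(dataset, feature_name,
                            scope = c("dataset", "group", "participant"),
                            participant_id = NULL) {
  scope <- match.arg(scope)
  df <- as.data.frame(dataset)
  v <- df[[feature_name]]
  sel <- switch(scope,
    dataset = rep(TRUE, nrow(df)),
    group = df$group == df$group[df$participant_id == participant_id][1],
    participant = df$participant_id == participant_id
  )
  list(mean = mean(v[sel]), sd = stats::sd(v[sel]))
}

#' Monte-Carlo perturbation of one feature of one participant
#'
#' Resamples feature `feature_name` from a normal with that feature's
#' empirical mean and SD (taken from `stats_scope`: the whole dataset by
#' default, or the participant's group, or the participant alone) while
#' all other features stay fixed. For each of the `n` draws the value is
#' written into every task row of the participant, the rows are
#' re-standardized with the model's stats and encoded, and the
#' participant's mean latent position and its assignment posterior are
#' recorded — measuring how much, and where, that feature can move the
#' participant in the latent space.
#'
#' @param model A `kinvae_model`.
#' @param dataset Raw (unstandardized) `kinvae_features` dataset.
#' @param participant_id Participant to perturb.
#' @param feature_name One of [feature_names()].
#' @param n Number of Monte-Carlo draws (default 100).
#' @param stats_scope `"dataset"` (default), `"group"` or `"participant"`.
#' @param g_td,g_asd Optional `kinvae_gaussian` fits used for posteriors;
#'   fitted from the dataset's own participant projections when omitted.
#' @param seed Optional integer seed.
#' @return A `kinvae_perturbation`: `sampled_values` (n), `latent_positions`
#'   (n x d), `posteriors` (n x 2), `baseline` (unperturbed position) and
#'   `mean_displacement` (mean Euclidean distance from baseline).
#' @export
perturb_feature <- function(model, dataset, participant_id, feature_name,
                            n = 100, stats_scope = "dataset",
                            g_td = NULL, g_asd = NULL, seed = NULL) {
  stopifnot(inherits(model, "kinvae_model"),
            inherits(dataset, "kinvae_features"))
  if (!feature_name %in% KINVAE_FEATURES) {
    stop_kinvae(sprintf("unknown feature '%s'", feature_name),
                "kinvae_feature_error")
  }
  df <- as.data.frame(dataset)
  rows <- which(df$participant_id == participant_id)
  if (length(rows) == 0) {
    stop_kinvae(sprintf("participant '%s' not in dataset", participant_id),
                "kinvae_feature_error")
  }
  if (is.null(g_td) || is.null(g_asd)) {
    proj <- project_latent(model, dataset)
    pp <- proj$participant_points
    g_td <- fit_class_gaussian(pp[pp$group == 0, ], label = 0)
    g_asd <- fit_class_gaussian(pp[pp$group == 1, ], label = 1)
  }
  mom <- feature_moments(dataset, feature_name, stats_scope, participant_id)
  if (!is.finite(mom$sd) || mom$sd < 1e-12) {
    warning(sprintf("feature '%s' has (near-)zero spread in scope '%s'; %s",
                    feature_name, stats_scope,
                    "all draws equal its mean"))
    mom$sd <- 0
  }
  draws <- if (is.null(seed)) stats::rnorm(n, mom$mean, mom$sd) else
    with_seed(seed, stats::rnorm(n, mom$mean, mom$sd))

  sub <- df[rows, , drop = FALSE]
  baseline <- colMeans(encode(
    model, std_matrix(sub, model$stats))$mu)
  positions <- matrix(NA_real_, n, model$config$latent_dim)
  for (i in seq_len(n)) {
    sub_i <- sub
    sub_i[[feature_name]] <- draws[i]
    positions[i, ] <- colMeans(encode(model,
                                      std_matrix(sub_i, model$stats))$mu)
  }
  colnames(positions) <- paste0("z", seq_len(ncol(positions)))
  posteriors <- assignment_posterior(positions, g_td, g_asd)
  structure(
    list(participant_id = participant_id, feature_name = feature_name,
         sampled_values = draws, latent_positions = positions,
         posteriors = posteriors, baseline = baseline,
         mean_displacement = mean(sqrt(rowSums(
           sweep(positions, 2, baseline)^2)))),
    class = "kinvae_perturbation"
  )
}

# standardize a raw sub-data.frame with model stats and return the matrix
std_matrix <- function(df, stats) {
  x <- as.matrix(df[KINVAE_FEATURES])
  sweep(sweep(x, 2, stats$mean[match(KINVAE_FEATURES, stats$feature)], "-"),
        2, stats$sd[match(KINVAE_FEATURES, stats$feature)], "/")
}

#' Mean latent displacement per feature
#'
#' Runs [perturb_feature()] for every feature over (a sample of)
#' participants and summarizes the mean latent displacement per feature —
#' the quantity that separates classification-driving features from
#' marginal ones.
#'
#' @param model,dataset As in [perturb_feature()].
#' @param n Draws per feature and participant.
#' @param participants Participants to include (default: all).
#' @param stats_scope See [perturb_feature()].
#' @param seed Optional integer seed.
#' @return Data frame feature / mean_displacement, plus per-participant
#'   displacement matrix as attribute `per_participant`.
#' @export
perturbation_ranking <- function(model, dataset, n = 100,
                                 participants = NULL,
                                 stats_scope = "dataset", seed = 1) {
  df <- as.data.frame(dataset)
  if (is.null(participants)) participants <- unique(df$participant_id)
  proj <- project_latent(model, dataset)
  pp <- proj$participant_points
  g_td <- fit_class_gaussian(pp[pp$group == 0, ], label = 0)
  g_asd <- fit_class_gaussian(pp[pp$group == 1, ], label = 1)
  disp <- matrix(NA_real_, length(participants), length(KINVAE_FEATURES),
                 dimnames = list(participants, KINVAE_FEATURES))
  for (i in seq_along(participants)) {
    for (f in KINVAE_FEATURES) {
      tr <- perturb_feature(model, dataset, participants[i], f, n = n,
                            stats_scope = stats_scope,
                            g_td = g_td, g_asd = g_asd,
                            seed = substream_seed(seed, "perturb", i, f))
      disp[i, f] <- tr$mean_displacement
    }
  }
  out <- data.frame(feature = KINVAE_FEATURES,
                    mean_displacement = colMeans(disp))
  out <- out[order(-out$mean_displacement), ]
  rownames(out) <- NULL
  attr(out, "per_participant") <- disp
  out
}

#' Assignment-probability response curve of one feature
#'
#' For each grid value v, feature `feature_name` is set to v in every row
#' of the dataset, rows are re-standardized and encoded, each participant
#' is reduced to their mean latent position, and the assignment posterior
#' under the two class Gaussians is computed. The curve reports the mean
#' and SD across participants at each grid point — how the probability of
#' assignment to either group responds to the feature's value.
#'
#' @param model A `kinvae_model`.
#' @param dataset Raw `kinvae_features` dataset.
#' @param g_td,g_asd `kinvae_gaussian` class fits.
#' @param feature_name One of [feature_names()].
#' @param grid Numeric grid of feature values; default spans the feature's
#'   empirical mean +/- 3 SD in `n_grid` points.
#' @param n_grid Grid resolution when `grid` is NULL (default 50).
#' @return A `kinvae_curve` data frame: feature, value, p_td, p_asd,
#'   sd_td, sd_asd.
#' @export
feature_response_curve <- function(model, dataset, g_td, g_asd,
                                   feature_name, grid = NULL, n_grid = 50) {
  if (!feature_name %in% KINVAE_FEATURES) {
    stop_kinvae(sprintf("unknown feature '%s'", feature_name),
                "kinvae_feature_error")
  }
  if (is.null(grid)) {
    mom <- feature_moments(dataset, feature_name, "dataset")
    grid <- seq(mom$mean - 3 * mom$sd, mom$mean + 3 * mom$sd,
                length.out = n_grid)
  }
  if (length(grid) == 0) {
    stop_kinvae("empty feature grid", "kinvae_invalid_config")
  }
  df <- as.data.frame(dataset)
  parts <- unique(df$participant_id)
  res <- matrix(NA_real_, length(grid), 4)
  for (k in seq_along(grid)) {
    df_k <- df
    df_k[[feature_name]] <- grid[k]
    mu <- encode(model, std_matrix(df_k, model$stats))$mu
    pm <- rowsum(mu, df_k$participant_id)
    pm <- pm / as.numeric(table(df_k$participant_id)[rownames(pm)])
    post <- assignment_posterior(pm, g_td, g_asd)
    res[k, ] <- c(colMeans(post), apply(post, 2, stats::sd))
  }
  structure(
    data.frame(feature = feature_name, value = grid,
               p_td = res[, 1], p_asd = res[, 2],
               sd_td = res[, 3], sd_asd = res[, 4]),
    class = c("kinvae_curve", "data.frame")
  )
}

#' Latent density map of a feature's perturbation traces
#'
#' Pools the perturbed latent positions of one feature across participants
#' into a normalized 2-D histogram over a shared grid: the probability for
#' the feature to map an input into each zone of the (2-D) latent space.
#'
#' @param traces List of `kinvae_perturbation` objects for one feature.
#' @param bins Number of bins per axis (default 40).
#' @param limits Optional list with `x` and `y` range vectors; default is
#'   the pooled range of the traces.
#' @return A `kinvae_density`: `x`, `y` (bin centers), `density` matrix
#'   integrating to 1 over the grid, and `feature_name`.
#' @export
feature_density_map <- function(traces, bins = 40, limits = NULL) {
  pts <- do.call(rbind, lapply(traces, function(tr) tr$latent_positions))
  if (ncol(pts) != 2) {
    stop_kinvae("density maps require a 2-D latent space",
                "kinvae_dim_error")
  }
  if (is.null(limits)) {
    pad <- function(r) r + c(-1, 1) * max(diff(r), 1e-6) * 0.05
    limits <- list(x = pad(range(pts[, 1])), y = pad(range(pts[, 2])))
  }
  bx <- seq(limits$x[1], limits$x[2], length.out = bins + 1)
  by <- seq(limits$y[1], limits$y[2], length.out = bins + 1)
  ix <- findInterval(pts[, 1], bx, rightmost.closed = TRUE)
  iy <- findInterval(pts[, 2], by, rightmost.closed = TRUE)
  keep <- ix >= 1 & ix <= bins & iy >= 1 & iy <= bins
  h <- matrix(0, bins, bins)
  for (i in which(keep)) h[ix[i], iy[i]] <- h[ix[i], iy[i]] + 1
  cell <- diff(bx)[1] * diff(by)[1]
  dens <- h / (sum(h) * cell)
  structure(
    list(x = (bx[-1] + bx[-(bins + 1)]) / 2,
         y = (by[-1] + by[-(bins + 1)]) / 2,
         density = dens, cell_area = cell,
         feature_name = traces[[1]]$feature_name),
    class = "kinvae_density"
  )
}

#' Orthogonal Procrustes alignment of two latent configurations
#'
#' Finds the orthogonal transform (rotation, possibly with reflection)
#' that best maps `comparison` onto `reference` after centering both, via
#' the SVD solution of the orthogonal Procrustes problem. Used to check
#' that latent structure is consistent across training seeds up to
#' rotation.
#'
#' @param reference,comparison Matrices (or z-column data frames) of
#'   matched points — same participants, two training runs.
#' @return A `kinvae_alignment`: `rotation` (d x d orthogonal matrix
#'   applied on the right to the centered comparison), `translation`
#'   terms, `rmse` (root-mean-square residual after alignment),
#'   `reference_rms` (RMS radius of the centered reference) and
#'   `relative_residual` = rmse / reference_rms.
#' @export
latent_alignment <- function(reference, comparison) {
  R <- if (is.data.frame(reference)) latent_matrix(reference) else
    as.matrix(reference)
  C <- if (is.data.frame(comparison)) latent_matrix(comparison) else
    as.matrix(comparison)
  if (!all(dim(R) == dim(C))) {
    stop_kinvae("reference and comparison must hold matched point sets",
                "kinvae_pairing_error")
  }
  mr <- colMeans(R); mc <- colMeans(C)
  R0 <- sweep(R, 2, mr); C0 <- sweep(C, 2, mc)
  sv <- svd(crossprod(C0, R0))
  Q <- sv$u %*% t(sv$v)
  aligned <- C0 %*% Q
  rmse <- sqrt(mean(rowSums((aligned - R0)^2)))
  ref_rms <- sqrt(mean(rowSums(R0^2)))
  structure(
    list(rotation = Q, ref_center = mr, comp_center = mc,
         rmse = rmse, reference_rms = ref_rms,
         relative_residual = rmse / ref_rms),
    class = "kinvae_alignment"
  )
}
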