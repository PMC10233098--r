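# Variational autoencoder with supervised predictor head.
#
# Architecture: a tanh encoder trunk feeding two linear heads (latent mean
# mu and log-variance, with sigma = exp(logvar / 2) so the latent SD is
# strictly positive), the reparameterized draw z = mu + sigma * eps, a
# decoder mirroring the encoder with a linear output layer (features are
# z-scored, so the reconstruction is computed directly), and a small
# predictor MLP (tanh hidden layer, softmax output over the two groups).
# The loss is the unweighted sum of mean-squared-error reconstruction,
# the closed-form KL divergence of the latent distribution from N(0, I),
# and binary cross-entropy of the predictor.
#
# No deep-learning framework is used: the forward pass, backpropagation
# and the Adam optimizer are implemented directly in matrix code, which
# keeps every gradient inspectable (see the finite-difference tests).

#' Network and training configuration
#'
#' @param latent_dim Latent dimensionality d (default 10 for the
#'   dimension-selection run; the final analysis model typically uses 2).
#' @param encoder_hidden Integer vector of encoder hidden-layer sizes
#'   (default 32); the decoder mirrors it in reverse.
#' @param predictor_hidden Hidden size of the predictor head (default 16).
#' @param activation Hidden activation, currently `"tanh"`.
#' @param predictor_output `"softmax"` (2-unit, default) or `"sigmoid"`
#'   (single unit); both evaluate binary cross-entropy on the class-1
#'   probability.
#' @param epochs,batch_size,learning_rate Training-loop settings
#'   (defaults 500, 64, 1e-3, Adam).
#' @param optimizer Only `"adam"` is implemented.
#' @param seed Integer seed governing weight initialization, batch order
#'   and reparameterization draws.
#' @return A `kinvae_network_config` list.
#' @export
network_config <- function(latent_dim = 10, encoder_hidden = 32,
                           predictor_hidden = 16, activation = "tanh",
                           predictor_output = c("softmax", "sigmoid"),
                           epochs = 500, batch_size = 64,
                           learning_rate = 1e-3, optimizer = "adam",
                           seed = 1) {
  check_number(latent_dim, "latent_dim", lower = 1)
  if (length(encoder_hidden) < 1 || any(encoder_hidden < 1)) {
    stop_kinvae("`encoder_hidden` sizes must all be >= 1",
                "kinvae_invalid_config")
  }
  check_number(predictor_hidden, "predictor_hidden", lower = 1)
  check_number(epochs, "epochs", lower = 1)
  check_number(batch_size, "batch_size", lower = 1)
  check_number(learning_rate, "learning_rate", lower = 0, strict = TRUE)
  activation <- match.arg(activation, "tanh")
  optimizer <- match.arg(optimizer, "adam")
  structure(
    list(latent_dim = as.integer(latent_dim),
         encoder_hidden = as.integer(encoder_hidden),
         predictor_hidden = as.integer(predictor_hidden),
         activation = activation,
         predictor_output = match.arg(predictor_output),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, optimizer = optimizer,
         seed = as.integer(seed)),
    class = "kinvae_network_config"
  )
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

layer_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(i) {
    list(W = glorot(sizes[i], sizes[i + 1]), b = numeric(sizes[i + 1]))
  })
}

# Stack forward. act_out: apply tanh to the final layer too (encoder
# trunk); otherwise the last layer is linear (decoder, predictor logits).
stack_forward <- function(layers, X, act_out = FALSE) {
  A <- list(X)
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    A[[l + 1]] <- if (l < L || act_out) tanh(Z) else Z
  }
  A
}

# Backward through a stack given cached activations A (from stack_forward)
# and the gradient dOut w.r.t. the stack output. act_out must match the
# forward call. Returns per-layer gradients and the gradient w.r.t. X.
stack_backward <- function(layers, A, dOut, act_out = FALSE) {
  L <- length(layers)
  grads <- vector("list", L)
  dZ <- if (act_out) dOut * (1 - A[[L + 1]]^2) else dOut
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(A[[l]], dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[l]]$W)
    if (l > 1) dZ <- dA * (1 - A[[l]]^2)
  }
  list(grads = grads, dX = dA)
}

init_params <- function(config, n_features = 12L) {
  d <- config$latent_dim
  enc_sizes <- c(n_features, config$encoder_hidden)
  dec_sizes <- c(d, rev(config$encoder_hidden), n_features)
  n_out <- if (config$predictor_output == "softmax") 2L else 1L
  h <- enc_sizes[length(enc_sizes)]
  list(
    enc = layer_init(enc_sizes),
    head_mu = list(W = glorot(h, d), b = numeric(d)),
    head_lv = list(W = glorot(h, d), b = numeric(d)),
    dec = layer_init(dec_sizes),
    pred = layer_init(c(d, config$predictor_hidden, n_out))
  )
}

LV_CLAMP <- 15 # log-variance clamp; inactive in normal training regimes

as_input_matrix <- function(x, n_features = 12L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != n_features) {
    stop_kinvae(sprintf("input has %d columns; expected %d", ncol(x),
                        n_features), "kinvae_shape_error")
  }
  if (any(!is.finite(x))) {
    stop_kinvae("input contains non-finite values", "kinvae_shape_error")
  }
  x
}

encoder_forward <- function(params, X) {
  A <- stack_forward(params$enc, X, act_out = TRUE)
  H <- A[[length(A)]]
  mu <- sweep(H %*% params$head_mu$W, 2, params$head_mu$b, "+")
  lv <- sweep(H %*% params$head_lv$W, 2, params$head_lv$b, "+")
  lv <- pmin(pmax(lv, -LV_CLAMP), LV_CLAMP)
  list(A = A, H = H, mu = mu, lv = lv, sigma = exp(lv / 2))
}

#' Encode standardized feature vectors to latent distribution parameters
#'
#' Deterministic forward pass through the encoder: returns the latent mean
#' and SD of each input row. Inputs must be standardized with the model's
#' stored stats (see [standardize()]); [project_latent()] handles that
#' bookkeeping for whole datasets.
#'
#' @param model A `kinvae_model` from [train_vae()].
#' @param x A 12-vector or matrix with 12 columns (standardized).
#' @return List with `mu` and `sigma`, each an n x d matrix.
#' @export
encode <- function(model, x) {
  X <- as_input_matrix(x)
  ef <- encoder_forward(model$params, X)
  list(mu = ef$mu, sigma = ef$sigma)
}

#' Reparameterized draw of latent variables
#'
#' Draws z = mu + sigma * eps with eps standard normal — the
#' reparameterization that lets gradients flow through the latent sample
#' during training.
#'
#' @param enc List with `mu` and `sigma` (vectors or matrices), e.g. from
#'   [encode()].
#' @param seed Optional integer seed.
#' @return Matrix (or vector) of latent draws, same shape as `mu`.
#' @export
sample_latent <- function(enc, seed = NULL) {
  mu <- enc$mu; sigma <- enc$sigma
  draw <- function() {
    eps <- if (is.null(dim(mu))) stats::rnorm(length(mu)) else
      matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    mu + sigma * eps
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Closed-form KL divergence of the latent distribution from N(0, I)
#'
#' For a diagonal Gaussian with mean mu and SD sigma,
#' \deqn{KL = \tfrac12 \sum_j (\mu_j^2 + \sigma_j^2 - 1 - \ln \sigma_j^2).}
#' Nonnegative, and zero exactly at mu = 0, sigma = 1. For matrix inputs
#' the mean over rows is returned (the batch convention used in training).
#'
#' @param enc List with `mu` and `sigma` (> 0).
#' @return Nonnegative scalar.
#' @export
kl_loss <- function(enc) {
  mu <- enc$mu; sigma <- enc$sigma
  if (any(sigma <= 0)) {
    stop_kinvae("sigma must be strictly positive", "kinvae_domain_error")
  }
  if (is.null(dim(mu))) {
    mu <- matrix(mu, 1); sigma <- matrix(sigma, 1)
  }
  per_row <- 0.5 * rowSums(mu^2 + sigma^2 - 1 - 2 * log(sigma))
  mean(per_row)
}

#' Mean-squared-error reconstruction loss
#'
#' @param x,x_hat Vectors or matrices of equal shape (original and
#'   reconstructed standardized features).
#' @return Mean over all entries of the squared differences.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (length(x) != length(x_hat) ||
      !identical(dim(x) %||% length(x), dim(x_hat) %||% length(x_hat))) {
    stop_kinvae("x and x_hat must have identical shape",
                "kinvae_shape_error")
  }
  mean((x - x_hat)^2)
}

PROB_EPS <- 1e-7

#' Binary cross-entropy of the predictor
#'
#' \eqn{-[y \log p + (1 - y)\log(1 - p)]}, with p clamped to
#' \[1e-7, 1 - 1e-7\] for stability; averaged when given vectors.
#'
#' @param y Binary labels (0/1).
#' @param p Predicted probability of class 1.
#' @return Nonnegative scalar.
#' @export
predictor_loss <- function(y, p) {
  if (!all(y %in% c(0, 1))) {
    stop_kinvae("labels must be 0 or 1", "kinvae_label_error")
  }
  p <- pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Combine the three loss components
#'
#' The full training objective weights reconstruction, KL regularization
#' and prediction error equally: total = recon + kl + pred.
#'
#' @param recon,kl,pred Nonnegative component values.
#' @return A `kinvae_loss` list with the three components and their sum.
#' @export
total_loss <- function(recon, kl, pred) {
  for (v in c(recon, kl, pred)) {
    if (!is.finite(v) || v < 0) {
      stop_kinvae("loss components must be finite and nonnegative",
                  "kinvae_domain_error")
    }
  }
  structure(list(recon = recon, kl = kl, pred = pred,
                 total = recon + kl + pred),
            class = "kinvae_loss")
}

softmax_rows <- function(Z) {
  m <- apply(Z, 1, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

# One full forward pass + loss on a (standardized) batch. eps is the
# reparameterization draw (B x d).
model_forward <- function(params, X, y, eps, config) {
  ef <- encoder_forward(params, X)
  z <- ef$mu + ef$sigma * eps
  dec_A <- stack_forward(params$dec, z)
  x_hat <- dec_A[[length(dec_A)]]
  pred_A <- stack_forward(params$pred, z)
  logits <- pred_A[[length(pred_A)]]
  if (config$predictor_output == "softmax") {
    probs <- softmax_rows(logits)
    p1 <- probs[, 2]
  } else {
    p1 <- 1 / (1 + exp(-logits[, 1]))
    probs <- cbind(1 - p1, p1)
  }
  recon <- reconstruction_loss(X, x_hat)
  kl <- kl_loss(list(mu = ef$mu, sigma = ef$sigma))
  pred <- predictor_loss(y, p1)
  list(ef = ef, z = z, dec_A = dec_A, x_hat = x_hat, pred_A = pred_A,
       probs = probs, p1 = p1,
       loss = total_loss(recon, kl, pred))
}

model_backward <- function(params, fw, X, y, eps, config) {
  B <- nrow(X); P <- ncol(X)
  ef <- fw$ef

  dXhat <- 2 * (fw$x_hat - X) / (B * P)
  dec_bk <- stack_backward(params$dec, fw$dec_A, dXhat)

  if (config$predictor_output == "softmax") {
    Y <- cbind(1 - y, y)
    dLogits <- (fw$probs - Y) / B
  } else {
    dLogits <- matrix((fw$p1 - y) / B, ncol = 1)
  }
  pred_bk <- stack_backward(params$pred, fw$pred_A, dLogits)

  dz <- dec_bk$dX + pred_bk$dX
  dmu <- dz + ef$mu / B
  # through sigma = exp(lv/2): d lv = dz * eps * sigma / 2, plus the KL
  # term 0.5 * (sigma^2 - 1) / B; clamped lv entries pass no gradient
  dlv <- dz * eps * ef$sigma / 2 + 0.5 * (ef$sigma^2 - 1) / B
  dlv[abs(ef$lv) >= LV_CLAMP] <- 0

  g_mu <- list(W = crossprod(ef$H, dmu), b = colSums(dmu))
  g_lv <- list(W = crossprod(ef$H, dlv), b = colSums(dlv))
  dH <- tcrossprod(dmu, params$head_mu$W) + tcrossprod(dlv, params$head_lv$W)
  enc_bk <- stack_backward(params$enc, ef$A, dH, act_out = TRUE)

  list(enc = enc_bk$grads, head_mu = g_mu, head_lv = g_lv,
       dec = dec_bk$grads, pred = pred_bk$grads)
}

# Flatten the nested parameter list into a named list of arrays for the
# optimizer (and for serialization / finite-difference checks).
flatten_params <- function(params) {
  out <- list()
  walk <- function(x, prefix) {
    if (!is.null(x$W)) {
      out[[paste0(prefix, ".W")]] <<- unname(x$W)
      out[[paste0(prefix, ".b")]] <<- unname(x$b)
    } else {
      for (i in seq_along(x)) walk(x[[i]], paste0(prefix, i))
    }
  }
  for (nm in names(params)) walk(params[[nm]], nm)
  out
}

apply_flat <- function(params, flat) {
  walk <- function(x, prefix) {
    if (!is.null(x$W)) {
      x$W <- flat[[paste0(prefix, ".W")]]
      x$b <- flat[[paste0(prefix, ".b")]]
      x
    } else {
      for (i in seq_along(x)) x[[i]] <- walk(x[[i]], paste0(prefix, i))
      x
    }
  }
  for (nm in names(params)) params[[nm]] <- walk(params[[nm]], nm)
  params
}

adam_step <- function(state, flat_g, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(flat_g)) {
    g <- flat_g[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$theta[[nm]] <- state$theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Train the supervised VAE
#'
#' Mini-batch gradient descent (Adam) on the equally weighted sum of
#' reconstruction, KL and predictor losses. If the dataset is not already
#' standardized, column stats are computed and stored on the model; test
#' data must later be standardized with these same stats.
#'
#' @param dataset A `kinvae_features` dataset containing both groups.
#' @param config A [network_config()].
#' @return A `kinvae_model`: network weights, config, standardization
#'   stats, and the per-epoch loss history (`$history`, columns epoch /
#'   recon / kl / pred / total).
#' @export
train_vae <- function(dataset, config = network_config()) {
  stopifnot(inherits(dataset, "kinvae_features"),
            inherits(config, "kinvae_network_config"))
  stats <- attr(dataset, "standardization_stats")
  if (is.null(stats)) {
    dataset <- standardize(dataset)
    stats <- attr(dataset, "standardization_stats")
  }
  X <- feature_matrix(dataset)
  y <- as.numeric(as.data.frame(dataset)$group)
  if (length(unique(y)) < 2) {
    stop_kinvae("training data must contain both groups",
                "kinvae_training_error")
  }
  n <- nrow(X)

  with_seed(substream_seed(config$seed, "train"), {
    params <- init_params(config)
    flat <- flatten_params(params)
    state <- list(theta = flat,
                  m = lapply(flat, function(a) a * 0),
                  v = lapply(flat, function(a) a * 0))
    hist <- matrix(NA_real_, config$epochs, 4,
                   dimnames = list(NULL, c("recon", "kl", "pred", "total")))
    t_step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      acc <- c(recon = 0, kl = 0, pred = 0)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        eps <- matrix(stats::rnorm(length(idx) * config$latent_dim),
                      length(idx), config$latent_dim)
        params <- apply_flat(params, state$theta)
        fw <- model_forward(params, Xb, yb, eps, config)
        if (!is.finite(fw$loss$total)) {
          stop_kinvae(sprintf("training diverged at epoch %d", epoch),
                      "kinvae_divergence")
        }
        gr <- model_backward(params, fw, Xb, yb, eps, config)
        t_step <- t_step + 1L
        state <- adam_step(state, flatten_params(gr),
                           config$learning_rate, t_step)
        w <- length(idx) / n
        acc <- acc + w * c(fw$loss$recon, fw$loss$kl, fw$loss$pred)
      }
      # total must equal recon + kl + pred bit-exactly (sum() accumulates
      # in extended precision and can differ in the last ulp)
      hist[epoch, ] <- c(acc, (acc[[1]] + acc[[2]]) + acc[[3]])
    }
    params <- apply_flat(params, state$theta)
    structure(
      list(params = params, config = config, stats = stats,
           history = data.frame(epoch = seq_len(config$epochs), hist)),
      class = "kinvae_model"
    )
  })
}

#' @export
print.kinvae_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<kinvae_model> d = %d, encoder %s, %d epochs (final loss %.4f = recon %.4f + kl %.4f + pred %.4f)\n",
    x$config$latent_dim, paste(x$config$encoder_hidden, collapse = "-"),
    x$config$epochs, h$total, h$recon, h$kl, h$pred))
  invisible(x)
}

#' Predicted class-1 probability for dataset rows
#'
#' Encodes each row to its latent mean (no sampling noise) and applies the
#' predictor head. Raw datasets are standardized with the model's stats.
#'
#' @param model A `kinvae_model`.
#' @param dataset A `kinvae_features` dataset or a numeric matrix of
#'   standardized features.
#' @return Numeric vector of probabilities of group 1.
#' @export
predict_prob <- function(model, dataset) {
  if (inherits(dataset, "kinvae_features")) {
    if (is.null(attr(dataset, "standardization_stats"))) {
      dataset <- standardize(dataset, stats = model$stats)
    }
    X <- feature_matrix(dataset)
  } else {
    X <- as_input_matrix(dataset)
  }
  ef <- encoder_forward(model$params, X)
  pred_A <- stack_forward(model$params$pred, ef$mu)
  logits <- pred_A[[length(pred_A)]]
  if (model$config$predictor_output == "softmax") {
    softmax_rows(logits)[, 2]
  } else {
    1 / (1 + exp(-logits[, 1]))
  }
}

#' Stratified k-fold cross-validated accuracy
#'
#' Rows (or whole participants, with `by_participant = TRUE`) are split
#' into k folds, stratified by group. For each fold the standardization
#' stats are computed on the training rows only, a fresh model is trained,
#' and held-out rows are classified by arg-max of the predictor output.
#' Row-level splitting matches per-observation evaluation but lets a
#' participant's other tasks inform the fold they are tested in;
#' participant-grouped splitting removes that leakage.
#'
#' @param dataset A raw (unstandardized) `kinvae_features` dataset.
#' @param config A [network_config()].
#' @param k Number of folds (default 10).
#' @param by_participant Group folds by participant instead of by row.
#' @param seed Seed for the fold assignment (default: derived from
#'   `config$seed`).
#' @param keep_models Retain the k trained models (default FALSE).
#' @return A `kinvae_cv` list: `fold_accuracies`, `mean`, `sd`, `k`, the
#'   per-row fold assignment `fold_of_row`, and optionally `models`.
#' @export
kfold_cv <- function(dataset, config = network_config(), k = 10,
                     by_participant = FALSE, seed = NULL,
                     keep_models = FALSE) {
  stopifnot(inherits(dataset, "kinvae_features"))
  if (k < 2) stop_kinvae("k must be >= 2", "kinvae_fold_error")
  df <- as.data.frame(dataset)
  if (is.null(seed)) seed <- substream_seed(config$seed, "folds")

  if (by_participant) {
    units <- unique(df[c("participant_id", "group")])
    unit_of_row <- match(df$participant_id, units$participant_id)
    unit_group <- units$group
  } else {
    unit_of_row <- seq_len(nrow(df))
    unit_group <- df$group
  }
  if (min(table(unit_group)) < k) {
    stop_kinvae("k exceeds the size of the smallest class",
                "kinvae_fold_error")
  }
  fold_of_unit <- integer(length(unit_group))
  with_seed(seed, {
    for (g in unique(unit_group)) {
      idx <- which(unit_group == g)
      fold_of_unit[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold_of_row <- fold_of_unit[unit_of_row]

  accs <- numeric(k)
  models <- if (keep_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    train_rows <- fold_of_row != f
    train_ds <- new_feature_dataset(df[train_rows, , drop = FALSE])
    test_ds <- new_feature_dataset(df[!train_rows, , drop = FALSE])
    train_std <- standardize(train_ds)
    fold_config <- config
    fold_config$seed <- substream_seed(config$seed, "fold-train", f)
    model <- train_vae(train_std, fold_config)
    test_std <- standardize(test_ds, stats = model$stats)
    p <- predict_prob(model, test_std)
    accs[f] <- mean(as.integer(p >= 0.5) == test_ds$group)
    if (keep_models) models[[f]] <- model
  }
  structure(
    list(fold_accuracies = accs, mean = mean(accs), sd = stats::sd(accs),
         k = k, by_participant = by_participant,
         fold_of_row = fold_of_row, models = models),
    class = "kinvae_cv"
  )
}

#' @export
print.kinvae_cv <- function(x, ...) {
  cat(sprintf("<kinvae_cv> %d folds%s: accuracy %.1f%% +/- %.1f%%\n",
              x$k, if (x$by_participant) " (participant-grouped)" else "",
              100 * x$mean, 100 * x$sd))
  invisible(x)
}
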