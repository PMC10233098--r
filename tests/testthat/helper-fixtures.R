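# Shared fixtures, all generated in code.

# A path with hand-checkable geometry: constant step on a line, 40 Hz.
line_trajectory <- function(n = 5, dx = 1, dy = 0, rate = 40) {
  kinvae:::new_trajectory("P1", 1L, 1L,
                          t = (seq_len(n) - 1) / rate,
                          x = (seq_len(n) - 1) * dx,
                          y = (seq_len(n) - 1) * dy)
}

make_trajectory <- function(x, y, rate = 40, id = "P1") {
  kinvae:::new_trajectory(id, 1L, 1L, t = (seq_along(x) - 1) / rate,
                          x = x, y = y)
}

random_trajectory <- function(seed, n = 10, rate = 40) {
  set.seed(seed)
  make_trajectory(cumsum(rnorm(n, 2, 1)), cumsum(rnorm(n, 1, 1)), rate)
}

# Small feature-mode cohort for fast model tests.
small_table <- function(seed = 1, n_per_group = 15, n_tasks = 10, ...) {
  sample_feature_table(cohort_config(n_per_group = n_per_group,
                                     n_tasks = n_tasks, seed = seed, ...))
}

fast_net <- function(d = 2, epochs = 60, seed = 1, ...) {
  network_config(latent_dim = d, epochs = epochs, seed = seed, ...)
}

# Independent brute-force recomputation of all trajectory features, written
# as plain loops from the definitions (the oracle for the extractor).
brute_force_features <- function(tr) {
  n <- length(tr$x)
  dt <- tr$t[2] - tr$t[1]
  v <- numeric(n - 1)
  for (k in 1:(n - 1)) {
    v[k] <- sqrt((tr$x[k + 1] - tr$x[k])^2 + (tr$y[k + 1] - tr$y[k])^2) / dt
  }
  a <- numeric(length(v) - 1)
  for (k in 1:(length(v) - 1)) a[k] <- (v[k + 1] - v[k]) / dt
  # turning angles between successive nonzero displacement vectors
  dirs <- list()
  for (k in 1:(n - 1)) {
    d <- c(tr$x[k + 1] - tr$x[k], tr$y[k + 1] - tr$y[k])
    if (any(d != 0)) dirs[[length(dirs) + 1]] <- d
  }
  dc <- numeric(0)
  if (length(dirs) >= 2) {
    for (k in 1:(length(dirs) - 1)) {
      u <- dirs[[k]]; w <- dirs[[k + 1]]
      ang <- atan2(abs(u[1] * w[2] - u[2] * w[1]), sum(u * w))
      dc <- c(dc, ang / dt)
    }
  }
  path <- 0
  for (k in 1:(n - 1)) {
    path <- path + sqrt((tr$x[k + 1] - tr$x[k])^2 +
                          (tr$y[k + 1] - tr$y[k])^2)
  }
  chord <- sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2)
  local_peaks <- function(s, maxima) {
    out <- numeric(0)
    if (length(s) >= 3) {
      for (k in 2:(length(s) - 1)) {
        if (maxima && s[k] > s[k - 1] && s[k] > s[k + 1]) out <- c(out, s[k])
        if (!maxima && s[k] < s[k - 1] && s[k] < s[k + 1]) out <- c(out, s[k])
      }
    }
    if (length(out) == 0) out <- if (maxima) max(s) else min(s)
    mean(out)
  }
  c(MeanSpeed = mean(v), MaxSpeed = local_peaks(v, TRUE),
    MinSpeed = local_peaks(v, FALSE), sdSpeed = sd(v),
    MeanAcceleration = mean(a), MaxAcceleration = local_peaks(a, TRUE),
    MinAcceleration = local_peaks(a, FALSE), sdAcceleration = sd(a),
    STH = min(chord / path, 1), DC = mean(dc), sdDC = sd(dc),
    MeanLength = path)
}
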