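# Helper: a model object with hand-set weights (no training).
manual_model <- function(config, mutate = identity) {
  params <- kinvae:::with_seed(1, kinvae:::init_params(config))
  params <- mutate(params)
  structure(list(params = params, config = config,
                 stats = data.frame(feature = feature_names(),
                                    mean = 0, sd = 1),
                 history = NULL),
            class = "kinvae_model")
}

zero_params <- function(params) {
  flat <- kinvae:::flatten_params(params)
  kinvae:::apply_flat(params, lapply(flat, function(a) a * 0))
}

test_that("KL divergence matches its closed form and a quadrature oracle", {
  expect_equal(kl_loss(list(mu = rep(0, 5), sigma = rep(1, 5))), 0)
  expect_equal(kl_loss(list(mu = c(1, 0), sigma = c(1, 1))), 0.5)
  expect_error(kl_loss(list(mu = 0, sigma = 0)),
               class = "kinvae_domain_error")

  kl_quad <- function(mu, sd) {
    stats::integrate(function(x) {
      q <- dnorm(x, mu, sd)
      lr <- dnorm(x, mu, sd, log = TRUE) - dnorm(x, 0, 1, log = TRUE)
      q * lr
    }, mu - 12 * sd - 5, mu + 12 * sd + 5, rel.tol = 1e-10)$value
  }
  cases <- list(c(0, 1), c(1, 1), c(-0.7, 0.4), c(2.5, 3), c(0, 0.05))
  for (cs in cases) {
    expect_equal(kl_loss(list(mu = cs[1], sigma = cs[2])),
                 kl_quad(cs[1], cs[2]), tolerance = 1e-6)
  }
})

test_that("reconstruction and predictor losses follow their definitions", {
  expect_equal(reconstruction_loss(rep(0, 12), rep(0, 12)), 0)
  expect_equal(reconstruction_loss(rep(0, 12), rep(1, 12)), 1)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(reconstruction_loss(a, b), reconstruction_loss(b, a))
  expect_error(reconstruction_loss(rep(0, 12), rep(0, 11)),
               class = "kinvae_shape_error")

  expect_lt(predictor_loss(1, 1 - 1e-9), 1e-6)
  expect_equal(predictor_loss(1, 0.5), log(2))
  expect_equal(predictor_loss(0, 0.5), predictor_loss(1, 0.5))
  expect_error(predictor_loss(2, 0.5), class = "kinvae_label_error")
})

test_that("the total loss is the unweighted, order-free sum", {
  l <- total_loss(1.0, 0.5, 0.7)
  expect_equal(l$total, 2.2)
  expect_equal(total_loss(0, 0, 0)$total, 0)
  expect_equal(total_loss(0.5, 0.7, 1.0)$total, l$total)
  expect_error(total_loss(-1, 0, 0), class = "kinvae_domain_error")
})

test_that("an all-zero network encodes everything to mu = 0, sigma = 1", {
  cfg <- network_config(latent_dim = 3)
  m <- manual_model(cfg, zero_params)
  enc <- encode(m, rnorm(12))
  expect_equal(as.numeric(enc$mu), rep(0, 3))
  expect_equal(as.numeric(enc$sigma), rep(1, 3))
  expect_error(encode(m, rnorm(11)), class = "kinvae_shape_error")
})

test_that("the encoder forward pass matches a hand-computed chain", {
  cfg <- network_config(latent_dim = 1, encoder_hidden = 1)
  x <- seq(-0.5, 0.6, length.out = 12)
  w1 <- matrix(seq(0.1, 1.2, by = 0.1), ncol = 1)
  m <- manual_model(cfg, function(p) {
    p$enc[[1]]$W <- w1
    p$enc[[1]]$b <- 0.2
    p$head_mu$W <- matrix(1.5)
    p$head_mu$b <- -0.3
    p$head_lv$W <- matrix(0.8)
    p$head_lv$b <- 0.1
    p
  })
  h <- tanh(sum(w1 * x) + 0.2)
  enc <- encode(m, x)
  expect_equal(as.numeric(enc$mu), 1.5 * h - 0.3, tolerance = 1e-12)
  expect_equal(as.numeric(enc$sigma), exp((0.8 * h + 0.1) / 2),
               tolerance = 1e-12)
  # two identical calls, identical answers
  expect_identical(encode(m, x), enc)
})

test_that("latent sampling is reparameterized correctly", {
  enc <- list(mu = c(2, -1), sigma = c(0, 0))
  expect_equal(sample_latent(enc, seed = 1), c(2, -1))

  enc2 <- list(mu = 0.7, sigma = 1.3)
  draws <- sample_latent(list(mu = matrix(0.7, 1e5, 1),
                              sigma = matrix(1.3, 1e5, 1)), seed = 42)
  se <- 1.3 / sqrt(1e5)
  expect_lt(abs(mean(draws) - 0.7), 3 * se)
  expect_identical(sample_latent(enc2, seed = 9),
                   sample_latent(enc2, seed = 9))
})

test_that("backpropagated gradients agree with finite differences", {
  cfg <- network_config(latent_dim = 2, encoder_hidden = 4,
                        predictor_hidden = 3, seed = 2)
  X <- kinvae:::with_seed(5, matrix(rnorm(36), 3, 12))
  y <- c(0, 1, 1)
  eps <- kinvae:::with_seed(6, matrix(rnorm(6), 3, 2))
  params <- kinvae:::with_seed(7, kinvae:::init_params(cfg))
  flat <- kinvae:::flatten_params(params)

  loss_at <- function(fl) {
    p <- kinvae:::apply_flat(params, fl)
    kinvae:::model_forward(p, X, y, eps, cfg)$loss$total
  }
  fw <- kinvae:::model_forward(params, X, y, eps, cfg)
  grads <- kinvae:::flatten_params(
    kinvae:::model_backward(params, fw, X, y, eps, cfg))

  set.seed(8)
  h <- 1e-5
  for (nm in names(flat)) {
    idx <- sample(length(flat[[nm]]), min(4, length(flat[[nm]])))
    for (i in idx) {
      up <- flat; up[[nm]][i] <- up[[nm]][i] + h
      dn <- flat; dn[[nm]][i] <- dn[[nm]][i] - h
      fd <- (loss_at(up) - loss_at(dn)) / (2 * h)
      g <- grads[[nm]][i]
      expect_lt(abs(fd - g) / max(abs(fd), abs(g), 1e-6), 1e-4)
    }
  }
})

test_that("training reduces the loss, logs exact decompositions, and is deterministic", {
  ft <- small_table(seed = 3)
  cfg <- fast_net(d = 2, epochs = 40, seed = 9)
  m <- train_vae(ft, cfg)
  h <- m$history
  expect_equal(h$total, h$recon + h$kl + h$pred)
  expect_lt(h$total[nrow(h)], h$total[1])
  expect_equal(ncol(encode(m, kinvae:::feature_matrix(standardize(ft)))$mu),
               2)

  m2 <- train_vae(ft, cfg)
  expect_identical(kinvae:::flatten_params(m$params),
                   kinvae:::flatten_params(m2$params))

  ft1 <- as.data.frame(ft)
  ft1 <- kinvae:::new_feature_dataset(ft1[ft1$group == 0, ])
  expect_error(train_vae(ft1, cfg), class = "kinvae_training_error")
})

test_that("the sigmoid predictor variant trains and predicts probabilities", {
  ft <- small_table(seed = 6)
  cfg <- fast_net(d = 2, epochs = 40, seed = 2,
                  predictor_output = "sigmoid")
  m <- train_vae(ft, cfg)
  p <- predict_prob(m, ft)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean((p >= 0.5) == (ft$group == 1)), 0.8)
})

test_that("cross-validation partitions rows once and stratifies by class", {
  ft <- small_table(seed = 8)
  cfg <- fast_net(d = 2, epochs = 15, seed = 4)
  cv <- kfold_cv(ft, cfg, k = 5)
  expect_length(cv$fold_accuracies, 5)
  expect_equal(cv$mean, mean(cv$fold_accuracies))
  expect_equal(cv$sd, sd(cv$fold_accuracies))
  expect_length(cv$fold_of_row, nrow(ft))
  expect_true(all(table(cv$fold_of_row) > 0))
  # stratification: class balance is preserved in every fold
  tab <- table(cv$fold_of_row, ft$group)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))

  cvp <- kfold_cv(ft, cfg, k = 5, by_participant = TRUE)
  split_count <- tapply(cvp$fold_of_row, ft$participant_id,
                        function(f) length(unique(f)))
  expect_true(all(split_count == 1))

  expect_error(kfold_cv(ft, cfg, k = 1), class = "kinvae_fold_error")
  tiny <- kinvae:::new_feature_dataset(
    as.data.frame(ft)[c(1:3, 200:202), ])
  expect_error(kfold_cv(tiny, cfg, k = 5), class = "kinvae_fold_error")
})
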