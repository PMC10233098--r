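# A trained model + dataset pair reused across latent-analysis tests.
latent_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ft <- small_table(seed = 10, n_per_group = 12, n_tasks = 10)
      m <- train_vae(ft, fast_net(d = 2, epochs = 120, seed = 3))
      proj <- project_latent(m, ft)
      pp <- proj$participant_points
      cache <<- list(
        ft = ft, model = m, proj = proj,
        g_td = fit_class_gaussian(pp[pp$group == 0, ], label = 0),
        g_asd = fit_class_gaussian(pp[pp$group == 1, ], label = 1))
    }
    cache
  }
})

test_that("latent projection yields one exact mean point per participant", {
  fx <- latent_fixture()
  proj <- fx$proj
  expect_equal(nrow(proj$participant_points), 24)
  expect_equal(nrow(proj$task_points), nrow(fx$ft))
  for (pid in proj$participant_points$participant_id[c(1, 13)]) {
    tp <- proj$task_points[proj$task_points$participant_id == pid, ]
    pp <- proj$participant_points[
      proj$participant_points$participant_id == pid, ]
    expect_equal(as.numeric(pp[c("z1", "z2")]),
                 unname(colMeans(tp[c("z1", "z2")])), tolerance = 1e-12)
  }
  expect_identical(project_latent(fx$model, fx$ft)$participant_points,
                   proj$participant_points)
})

test_that("PCA ratios are a valid, correctly ordered spectrum", {
  # points in an exact 2-plane of 10-space
  set.seed(1)
  B <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  pts <- matrix(rnorm(400), 200, 2) %*% t(B)
  pca <- pca_explained_variance(pts)
  expect_equal(sum(pca$explained_variance_ratios[1:2]), 1,
               tolerance = 1e-9)
  expect_equal(pca$n_components, 2)

  iso <- matrix(rnorm(1e4 * 10), 1e4, 10)
  pi2 <- pca_explained_variance(iso)
  expect_true(all(abs(pi2$explained_variance_ratios - 0.1) < 0.02))
  expect_equal(sum(pi2$explained_variance_ratios), 1, tolerance = 1e-9)
  expect_true(all(diff(pi2$explained_variance_ratios) <= 1e-12))
  expect_error(pca_explained_variance(iso[1:2, ]),
               class = "kinvae_degenerate")
})

test_that("class Gaussian fitting is the floored maximum-likelihood fit", {
  g <- fit_class_gaussian(matrix(c(0, 0, 2, 2), 2, byrow = TRUE))
  expect_equal(unname(g$mean), c(1, 1))
  expect_equal(unname(g$variances), c(1, 1)) # divide-by-n MLE

  set.seed(2)
  big <- cbind(rnorm(1e4, 3, 2), rnorm(1e4, -1, 0.5))
  gb <- fit_class_gaussian(big)
  expect_lt(abs(gb$mean[1] - 3), 3 * 2 / sqrt(1e4))
  expect_lt(abs(gb$mean[2] + 1), 3 * 0.5 / sqrt(1e4))
  expect_lt(abs(gb$variances[1] - 4), 3 * 4 * sqrt(2 / 1e4))

  flat <- fit_class_gaussian(matrix(1, 5, 2))
  expect_equal(unname(flat$variances), c(1e-6, 1e-6))
  expect_error(fit_class_gaussian(matrix(1, 1, 2)),
               class = "kinvae_fit_error")
})

test_that("assignment posteriors normalize and match direct density evaluation", {
  g0 <- structure(list(label = 0, mean = c(-1, 0), variances = c(1, 2)),
                  class = "kinvae_gaussian")
  g1 <- structure(list(label = 1, mean = c(1, 0), variances = c(1, 2)),
                  class = "kinvae_gaussian")
  expect_equal(unname(assignment_posterior(c(0, 5), g0, g1)), c(0.5, 0.5))

  far <- structure(list(label = 1, mean = c(100, 0), variances = c(1, 1)),
                   class = "kinvae_gaussian")
  p <- assignment_posterior(c(-1, 0), g0, far)
  expect_gte(p[["p_td"]], 1 - 1e-10)

  # brute-force pdf oracle
  pt <- c(0.3, -0.8)
  d0 <- prod(dnorm(pt, g0$mean, sqrt(g0$variances)))
  d1 <- prod(dnorm(pt, g1$mean, sqrt(g1$variances)))
  expect_equal(unname(assignment_posterior(pt, g0, g1)),
               c(d0, d1) / (d0 + d1), tolerance = 1e-12)

  pts <- rbind(c(0, 0), c(2, 1))
  post <- assignment_posterior(pts, g0, g1)
  expect_equal(unname(rowSums(post)), c(1, 1), tolerance = 1e-12)
  expect_error(assignment_posterior(c(1, 2, 3), g0, g1),
               class = "kinvae_shape_error")
})

test_that("feature perturbation traces have the documented structure", {
  fx <- latent_fixture()
  tr <- perturb_feature(fx$model, fx$ft, "TD01", "MaxAcceleration",
                        n = 100, g_td = fx$g_td, g_asd = fx$g_asd,
                        seed = 5)
  expect_length(tr$sampled_values, 100)
  expect_equal(dim(tr$latent_positions), c(100, 2))
  expect_equal(unname(rowSums(tr$posteriors)), rep(1, 100),
               tolerance = 1e-12)
  tr2 <- perturb_feature(fx$model, fx$ft, "TD01", "MaxAcceleration",
                         n = 100, g_td = fx$g_td, g_asd = fx$g_asd,
                         seed = 5)
  expect_identical(tr$latent_positions, tr2$latent_positions)
  expect_error(
    perturb_feature(fx$model, fx$ft, "TD01", "NotAFeature",
                    g_td = fx$g_td, g_asd = fx$g_asd),
    class = "kinvae_feature_error")
  expect_error(
    perturb_feature(fx$model, fx$ft, "nobody", "DC",
                    g_td = fx$g_td, g_asd = fx$g_asd),
    class = "kinvae_feature_error")
})

test_that("a zero-spread feature leaves the participant pinned in place", {
  fx <- latent_fixture()
  df <- as.data.frame(fx$ft)
  df$DC <- df$DC * 0 + 7 # constant column
  flat <- kinvae:::new_feature_dataset(df)
  expect_warning(
    tr <- perturb_feature(fx$model, flat, "TD01", "DC", n = 20,
                          g_td = fx$g_td, g_asd = fx$g_asd, seed = 1),
    "zero spread|near-.?zero"
  )
  expect_equal(max(dist(tr$latent_positions)), 0)
})

test_that("response curves are normalized, sized by the grid, and deterministic", {
  fx <- latent_fixture()
  cv <- feature_response_curve(fx$model, fx$ft, fx$g_td, fx$g_asd,
                               "MaxAcceleration", n_grid = 21)
  expect_equal(nrow(cv), 21)
  expect_equal(cv$p_td + cv$p_asd, rep(1, 21), tolerance = 1e-12)
  expect_true(all(diff(cv$value) > 0))
  expect_error(
    feature_response_curve(fx$model, fx$ft, fx$g_td, fx$g_asd,
                           "MaxAcceleration", grid = numeric(0)),
    class = "kinvae_invalid_config")
})

test_that("density maps integrate to one and track the trace mass", {
  fx <- latent_fixture()
  traces <- lapply(c("TD01", "ASD01"), function(p) {
    perturb_feature(fx$model, fx$ft, p, "sdSpeed", n = 50,
                    g_td = fx$g_td, g_asd = fx$g_asd, seed = 2)
  })
  dm <- feature_density_map(traces, bins = 25)
  expect_equal(sum(dm$density) * dm$cell_area, 1, tolerance = 1e-6)

  # a single repeated position puts all mass in one cell
  one <- traces[[1]]
  one$latent_positions <- matrix(rep(c(0.5, -0.2), each = 10), 10, 2)
  dm1 <- feature_density_map(list(one), bins = 10,
                             limits = list(x = c(-1, 1), y = c(-1, 1)))
  expect_equal(sum(dm1$density > 0), 1)

  # mode location agrees with the trace mean for a unimodal cloud
  set.seed(3)
  uni <- traces[[1]]
  uni$latent_positions <- cbind(rnorm(4000, 1, 0.3), rnorm(4000, -1, 0.3))
  dmu <- feature_density_map(list(uni), bins = 15)
  idx <- which(dmu$density == max(dmu$density), arr.ind = TRUE)
  expect_lt(abs(dmu$x[idx[1]] - 1), 0.3)
  expect_lt(abs(dmu$y[idx[2]] + 1), 0.3)
})

test_that("Procrustes alignment recovers rotations and measures noise", {
  set.seed(4)
  ref <- matrix(rnorm(60), 30, 2)
  theta <- pi / 2
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  al <- latent_alignment(ref, ref %*% R)
  expect_lt(al$rmse, 1e-10)
  expect_equal(al$rotation %*% R, diag(2), tolerance = 1e-10)

  self <- latent_alignment(ref, ref)
  expect_equal(self$rotation, diag(2), tolerance = 1e-12)
  expect_lt(self$rmse, 1e-12)

  noisy <- ref %*% R + matrix(rnorm(60, 0, 0.05), 30, 2)
  aln <- latent_alignment(ref, noisy)
  expect_lt(aln$rmse, 0.15)
  expect_gt(aln$rmse, 0.01)

  expect_error(latent_alignment(ref, ref[1:10, ]),
               class = "kinvae_pairing_error")
})

test_that("alignment agrees with the vegan Procrustes cross-check", {
  set.seed(5)
  ref <- matrix(rnorm(40), 20, 2)
  cmp <- ref %*% matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2, 2) +
    matrix(rnorm(40, 0, 0.02), 20, 2)
  ours <- latent_alignment(ref, cmp)
  vg <- vegan::procrustes(ref, cmp, scale = FALSE)
  expect_equal(ours$rotation, vg$rotation, tolerance = 1e-8)
  expect_equal(ours$rmse^2 * nrow(ref), vg$ss, tolerance = 1e-6)
})
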