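test_that("fit_item_glm matches the normal-equations oracle", {
  g <- vol_grid(c(1, 1, 1))
  ids <- paste0("it", 1:3)
  timing <- fbd_run_timing(ids)
  ib <- item_beta_maps("s", "r", matrix(c(2, -1, 0.5), 3, 1,
                                        dimnames = list(ids, NULL)),
                       1L, g, ids)
  y <- generate_timeseries(ib, timing, tr = 2.5, noise_sd = 0.8, seed = 2)

  fit <- fit_item_glm(y, timing, tr = 2.5, grid = g)
  X <- cbind(infonetscore:::build_design(timing, nrow(y), 2.5), 1)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$betas[, 1]), unname(beta_hat[ids, 1]),
               tolerance = 1e-10)

  res <- y - X %*% beta_hat
  expect_equal(unname(fit$resid_var), sum(res^2) / (nrow(y) - ncol(X)),
               tolerance = 1e-10)
  expect_equal(fit$dof, nrow(y) - ncol(X))
})

test_that("GLM edge cases: null voxel, scale equivariance, rank deficiency", {
  g <- vol_grid(c(2, 1, 1))
  ids <- paste0("it", 1:3)
  timing <- fbd_run_timing(ids)
  ib <- item_beta_maps("s", "r",
                       matrix(c(1, 2, 3, 0, 0, 0), 3, 2,
                              dimnames = list(ids, NULL)), 1:2, g, ids)
  y <- generate_timeseries(ib, timing, tr = 2.5)
  fit <- fit_item_glm(y, timing, tr = 2.5, grid = g)
  expect_equal(unname(fit$betas[, 2]), rep(0, 3))
  expect_equal(unname(fit$resid_var[2]), 0)

  fit3 <- fit_item_glm(3 * y, timing, tr = 2.5, grid = g)
  expect_equal(fit3$betas, 3 * fit$betas, tolerance = 1e-10)

  # duplicated trial type at identical onsets -> collinear regressors
  bad <- rbind(timing,
               within(timing[timing$trial_type == "it1", ],
                      trial_type <- "dup"))
  expect_error(fit_item_glm(y, bad, tr = 2.5, grid = g),
               "rank-deficient.*(dup|it1)")
})

test_that("contrast z is calibrated on null data and detects signal", {
  # closed-form check on a tiny handmade design
  set.seed(8)
  n_t <- 10
  X <- cbind(it1 = rnorm(n_t), it2 = rnorm(n_t))
  y <- 0.7 * X[, 1] + rnorm(n_t)
  Xf <- cbind(X, 1)
  bh <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
  res <- y - Xf %*% bh
  s2 <- sum(res^2) / (n_t - 3)
  cw <- c(0.5, 0.5)
  xtxi <- solve(t(Xf) %*% Xf)[1:2, 1:2]
  t_oracle <- sum(cw * bh[1:2]) / sqrt(s2 * (t(cw) %*% xtxi %*% cw))

  fit <- item_beta_maps("s", "r", matrix(bh[1:2], 2, 1,
                                         dimnames = list(c("it1", "it2"),
                                                         NULL)),
                        1L, vol_grid(c(1, 1, 1)), c("it1", "it2"),
                        resid_var = s2, dof = n_t - 3, xtx_inv = xtxi)
  zm <- contrast_zmap(fit)
  expect_equal(zm$z, qnorm(pt(drop(t_oracle), n_t - 3)), tolerance = 1e-10)

  # null calibration: betas are pure noise with unit xtx_inv
  set.seed(13)
  n_vox <- 1000
  nb <- matrix(rnorm(24 * n_vox), 24, n_vox,
               dimnames = list(sprintf("it%02d", 1:24), NULL))
  fit0 <- item_beta_maps("s", "r", nb, seq_len(n_vox),
                         vol_grid(c(10, 10, 10)), rownames(nb),
                         resid_var = rchisq(n_vox, 100) / 100, dof = 100)
  z0 <- contrast_zmap(fit0)$z
  expect_gt(ks.test(z0, "pnorm")$p.value, 0.01)

  # strong planted activation pushes z far positive
  nb2 <- nb; nb2[, 1] <- nb2[, 1] + 5
  fit2 <- item_beta_maps("s", "r", nb2, seq_len(n_vox),
                         vol_grid(c(10, 10, 10)), rownames(nb),
                         resid_var = rep(1, n_vox), dof = 100)
  expect_gt(contrast_zmap(fit2)$z[1], 10)
})

test_that("zero residual variance with signal clamps with a warning", {
  nb <- matrix(1, 3, 2, dimnames = list(paste0("it", 1:3), NULL))
  fit <- item_beta_maps("s", "r", nb, 1:2, vol_grid(c(2, 1, 1)),
                        rownames(nb), resid_var = c(0, 1), dof = 50)
  expect_warning(zm <- contrast_zmap(fit), "zero residual variance")
  expect_true(is.finite(zm$z[1]))
  expect_gt(zm$z[1], zm$z[2])
  expect_equal(zm$n_clamped, 1L)
})

test_that("robust-range mask implements the top-fraction rule", {
  mk_zmap <- function(z) structure(
    list(z = z, voxels = seq_along(z), grid = vol_grid(c(length(z), 1, 1)),
         name = "images_gt_baseline", n_clamped = 0L),
    class = "contrast_zmap")

  m <- robust_range_mask(mk_zmap(1:100), 0.02)
  expect_identical(which(m), 99:100)

  m5 <- robust_range_mask(mk_zmap(1:10), 0.5)
  expect_identical(which(m5), 6:10)

  expect_warning(m0 <- robust_range_mask(mk_zmap(-(1:10))), "empty")
  expect_false(any(m0))

  # ties at the threshold are all included
  mt <- robust_range_mask(mk_zmap(c(1, 2, 3, 3, 3)), 0.2)
  expect_identical(which(mt), 3:5)

  # invariant to strictly increasing transforms of z
  set.seed(2)
  z <- rnorm(500)
  expect_equal(robust_range_mask(mk_zmap(z), 0.1),
               robust_range_mask(mk_zmap(5 * atan(z)), 0.1),
               ignore_attr = TRUE)
  expect_error(robust_range_mask(mk_zmap(z), 1.2), "top_fraction")
})
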