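# within-category minus between-category mean pattern distance over the
# informational voxels of one subject's run-1 betas
wb_gap <- function(cohort, s = 1L) {
  b <- cohort$subjects[[s]]$runs[[1]]
  gt <- cohort$ground_truth
  dm <- as.matrix(condensed_correlation_dm(
    b$betas[, match(gt$info_voxels, b$voxels)]))
  same <- outer(gt$categories, gt$categories, "==")
  diag(same) <- NA
  mean(dm[same & !is.na(same)]) - mean(dm[!same & !is.na(same)])
}

test_that("cohort generation is deterministic and structured", {
  spec <- cohort_spec(n_subjects_per_group = 1L, n_runs = 2L,
                      grid_dims = c(12L, 12L, 12L), seed = 21)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$subjects[[1]]$runs[[2]]$betas,
                   b$subjects[[1]]$runs[[2]]$betas)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$ground_truth, b$ground_truth)

  gt <- a$ground_truth
  expect_length(intersect(gt$task_voxels, gt$info_voxels), 0)
  expect_setequal(names(gt$categories), a$subjects[[1]]$runs[[1]]$item_ids)
  expect_identical(sort(unique(a$behavior$group)), c("expert", "novice"))
  expect_true(all(a$behavior$fbd_run1 >= 0 & a$behavior$fbd_run1 <= 1))

  # visual clusters cross categories: every cluster spans > 1 category
  spans <- tapply(gt$categories, gt$visual_clusters,
                  function(x) length(unique(x)))
  expect_true(all(spans > 1))
})

test_that("planted category signal scales with expertise", {
  # e = 0: no category structure in the info-blob patterns
  gaps0 <- vapply(1:6, function(s)
    wb_gap(generate_cohort(cohort_spec(n_subjects_per_group = 1L,
                                       expertise = c(0, 1), n_runs = 1L,
                                       grid_dims = c(12L, 12L, 12L),
                                       seed = s))),
    numeric(1))
  expect_lt(abs(mean(gaps0)), 0.02)

  # e = 1, vanishing noise: within < between for every pair
  coh <- generate_cohort(cohort_spec(n_subjects_per_group = 1L,
                                     expertise = c(1, 1),
                                     noise_sd = 1e-6, n_runs = 1L,
                                     grid_dims = c(12L, 12L, 12L),
                                     seed = 3))
  b <- coh$subjects[[1]]$runs[[1]]
  gt <- coh$ground_truth
  dm <- as.matrix(condensed_correlation_dm(
    b$betas[, match(gt$info_voxels, b$voxels)]))
  same <- outer(gt$categories, gt$categories, "==")
  diag(same) <- NA
  expect_lt(max(dm[same & !is.na(same)]), min(dm[!same & !is.na(same)]))

  # monotone in e (averaged over seeds)
  gap_at_e <- function(e) mean(vapply(1:20, function(s)
    wb_gap(generate_cohort(cohort_spec(n_subjects_per_group = 1L,
                                       expertise = c(e, 1), n_runs = 1L,
                                       grid_dims = c(10L, 10L, 10L),
                                       blob_radius = 2, seed = 100 + s))),
    numeric(1)))
  gaps <- vapply(c(0, 0.5, 1), gap_at_e, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("task blobs carry no item information", {
  gaps <- vapply(1:10, function(s) {
    coh <- generate_cohort(cohort_spec(n_subjects_per_group = 1L,
                                       expertise = c(1, 1), n_runs = 1L,
                                       grid_dims = c(12L, 12L, 12L),
                                       seed = 300 + s))
    b <- coh$subjects[[1]]$runs[[1]]
    gt <- coh$ground_truth
    dm <- as.matrix(condensed_correlation_dm(
      b$betas[, match(gt$task_voxels, b$voxels)]))
    same <- outer(gt$categories, gt$categories, "==")
    diag(same) <- NA
    mean(dm[same & !is.na(same)]) - mean(dm[!same & !is.na(same)])
  }, numeric(1))
  # mean gap across seeds is within ~3 SE of zero
  expect_lt(abs(mean(gaps)), 3 * sd(gaps) / sqrt(length(gaps)) + 1e-6)
})

test_that("behavior couples to expertise", {
  coh <- generate_cohort(cohort_spec(n_subjects_per_group = 10L, seed = 77,
                                     grid_dims = c(8L, 8L, 8L),
                                     blob_radius = 2, n_runs = 1L))
  e <- coh$ground_truth$expertise
  expect_gt(cor(e, coh$behavior$fbd_run1), 0.5)
  expect_identical(coh$behavior$group,
                   unname(ifelse(e >= 0.5, "expert", "novice")))
})

test_that("random responder calibrates to chance", {
  acc <- simulate_random_responder(1e4, seed = 4)
  expect_lt(abs(acc - 0.5), 3 * 0.005)
  expect_true(simulate_random_responder(1, seed = 9) %in% c(0, 1))
  accs <- vapply(1:100, function(s) simulate_random_responder(1e3, s),
                 numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.005)
})

test_that("time-series forward model and GLM round trip", {
  g <- vol_grid(c(3, 3, 1))
  ids <- paste0("it", 1:4)
  betas <- matrix(rnorm(4 * 9), 4, 9, dimnames = list(ids, NULL))
  ib <- item_beta_maps("s1", "run1", betas, 1:9, g, ids)
  timing <- fbd_run_timing(ids)

  y <- generate_timeseries(ib, timing, tr = 2.5, noise_sd = 0)
  # noise-free single-beta voxel equals the convolved regressor
  ib1 <- item_beta_maps("s1", "run1",
                        matrix(c(1, 0, 0, 0), 4, 1,
                               dimnames = list(ids, NULL)), 1L, g, ids)
  y1 <- generate_timeseries(ib1, timing, tr = 2.5)
  X <- infonetscore:::build_design(timing, nrow(y1), 2.5)
  expect_equal(as.numeric(y1), as.numeric(X[, "it1"]), tolerance = 1e-12)
  # linearity in the betas
  ib2 <- item_beta_maps("s1", "run1",
                        matrix(c(2, 0, 0, 0), 4, 1,
                               dimnames = list(ids, NULL)), 1L, g, ids)
  expect_equal(as.numeric(generate_timeseries(ib2, timing, tr = 2.5)),
               2 * as.numeric(y1), tolerance = 1e-12)

  fit <- fit_item_glm(y, timing, tr = 2.5, grid = g)
  expect_equal(fit$betas, ib$betas, tolerance = 1e-8)

  expect_error(generate_timeseries(ib, timing, tr = -1), "TR")
  bad <- data.frame(onset = c(0, 2), duration = c(6, 6),
                    trial_type = c("it1", "it2"))
  expect_error(generate_timeseries(ib, bad, tr = 2.5), "overlap")
})

test_that("impossible blob placement errors", {
  expect_error(generate_cohort(cohort_spec(n_subjects_per_group = 1L,
                                           grid_dims = c(5L, 5L, 5L),
                                           blob_radius = 3, seed = 1)),
               "fit|place")
})
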