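mk_zmap <- function(z) structure(
  list(z = z, voxels = seq_along(z), grid = vol_grid(c(length(z), 1, 1)),
       name = "images_gt_baseline", n_clamped = 0L),
  class = "contrast_zmap")

test_that("univariate score averages the robust range", {
  rec <- univariate_score(mk_zmap(1:100), 0.02, "s1", "run1")
  expect_equal(rec$score, 99.5)
  expect_setequal(rec$contributing_voxels, 99:100)

  expect_equal(univariate_score(mk_zmap(rep(3.2, 50)))$score, 3.2)

  expect_warning(rec0 <- univariate_score(mk_zmap(-(1:10))), "empty")
  expect_true(is.na(rec0$score))
  expect_true("missing" %in% rec0$flags)

  # voxel-order permutation leaves the score unchanged
  set.seed(3)
  z <- rnorm(200, 1)
  expect_equal(univariate_score(mk_zmap(z))$score,
               univariate_score(mk_zmap(sample(z)))$score)
})

mk_slr <- function(dms, item_ids) {
  structure(list(centers = seq_along(dms),
                 neighborhoods = as.list(seq_along(dms)),
                 dms = dms, n_dropped = 0L, item_ids = item_ids),
            class = "searchlight_result")
}

test_that("rsa score thresholds Fisher z and flags drops and caps", {
  em <- build_expert_model(seed = 2)
  ids <- em$dm$item_ids

  # all centers equal to the expert DM: rho = 1 -> capped, not dropped
  slr_perfect <- mk_slr(list(em$dm, em$dm), ids)
  rec <- rsa_score(slr_perfect, em)
  expect_true("capped" %in% rec$flags)
  expect_equal(rec$score, atanh(1 - 1e-16))

  # pure-noise DMs essentially never clear z >= 2 (rho >= 0.964)
  set.seed(7)
  noise_dms <- lapply(1:30, function(i)
    dissim_matrix(runif(length(em$dm$values), 0, 2), ids))
  rec0 <- rsa_score(mk_slr(noise_dms, ids), em)
  expect_true(is.na(rec0$score))
  expect_true("dropped" %in% rec0$flags)

  # planted near-expert DMs survive; noise does not
  tight <- lapply(1:5, function(i) {
    v <- em$dm$values + rnorm(length(em$dm$values), 0, 0.001)
    dissim_matrix(pmax(v, 0), ids)
  })
  rec1 <- rsa_score(mk_slr(c(tight, noise_dms), ids), em)
  expect_false(is.na(rec1$score))
  expect_setequal(rec1$contributing_voxels, 1:5)
  expect_gte(rec1$score, 2)

  bad <- mk_slr(list(em$dm), rev(ids))
  expect_error(rsa_score(bad, em), "ordering")
})

test_that("infonet score finds planted category structure", {
  coh <- tiny_cohort(seed = 11)
  cats <- coh$ground_truth$categories

  hi <- infonet_score(coh$subjects[[4]]$runs[[1]], cats,
                      config = fast_infonet_config())
  expect_gte(hi$record$score, 0.8)
  expect_true(hi$record$score <= 1 && hi$record$score >= 0)
  # the winning network's searchlights cover the informational blobs
  best <- hi$networks[[which.max(vapply(hi$networks, `[[`, 0,
                                        "svm_accuracy"))]]
  expect_gt(length(intersect(best$centers,
                             coh$ground_truth$info_voxels)) /
              length(best$centers), 0.5)

  lo <- infonet_score(coh$subjects[[1]]$runs[[1]], cats,
                      config = fast_infonet_config())
  expect_lt(lo$record$score, hi$record$score)

  # determinism under the same config seed
  hi2 <- infonet_score(coh$subjects[[4]]$runs[[1]], cats,
                       config = fast_infonet_config())
  expect_identical(hi$record$score, hi2$record$score)
  expect_identical(hi$record$contributing_voxels,
                   hi2$record$contributing_voxels)
})

test_that("infonet fallback and degenerate paths still score", {
  coh <- tiny_cohort(seed = 13)
  cats <- coh$ground_truth$categories
  b <- coh$subjects[[1]]$runs[[1]]
  # an extreme AU threshold forces the root fallback for a noise subject
  cfg <- fast_infonet_config()
  cfg$au_threshold <- 1 - 1e-12
  res <- infonet_score(b, cats, config = cfg)
  expect_false(is.na(res$record$score))
  expect_true(res$record$score >= 0 && res$record$score <= 1)

  # precomputed zmap with no positive z -> flagged missing
  zneg <- contrast_zmap(b)
  zneg$z <- -abs(zneg$z)
  cfg2 <- fast_infonet_config()
  cfg2$zmap <- zneg
  expect_warning(res2 <- infonet_score(b, cats, config = cfg2), "empty")
  expect_true(is.na(res2$record$score))
  expect_true("missing" %in% res2$record$flags)

  expect_error(infonet_score(b, cats[1:5]), "items do not match")
})

test_that("infonet score is invariant to center enumeration order", {
  coh <- tiny_cohort(seed = 17)
  cats <- coh$ground_truth$categories
  b <- coh$subjects[[4]]$runs[[1]]
  zm <- contrast_zmap(b)
  rr <- robust_range_mask(zm, 0.02)
  centers <- zm$voxels[rr]

  score_with_centers <- function(ctrs) {
    nbh <- sphere_neighborhoods(b$grid, b$voxels, 3, 10, centers = ctrs)
    slr <- searchlight_dms(b, nbh)
    dend <- hierarchical_cluster(slr)
    sup <- multiscale_bootstrap_au(slr, dend,
                                   scales = seq(0.6, 1.4, by = 0.2),
                                   n_boot_per_scale = 40, seed = 5)
    nets <- suppressWarnings(cut_networks(dend, sup))
    accs <- vapply(nets, function(idx) {
      as.numeric(svm_category_accuracy(
        mds_embed(average_dm(slr$dms[idx])), cats))
    }, numeric(1))
    max(accs)
  }
  set.seed(19)
  expect_equal(score_with_centers(centers),
               score_with_centers(rev(centers)))
})
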