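test_that("hierarchical clustering merges duplicates first and is order-invariant", {
  set.seed(51)
  base <- matrix(rnorm(3 * 40), 3, 40)
  stack <- base[c(1, 1, 2, 2, 3, 3), ]
  dend <- hierarchical_cluster(stack)
  first3 <- dend$heights[1:3]
  expect_lt(max(first3), 1e-12)
  expect_true(any(vapply(dend$members, identical, logical(1), c(1L, 2L))))

  # hand agglomeration: two near-duplicates and one outsider -> ((1,2),3)
  s3 <- rbind(base[1, ], base[1, ] + rnorm(40, 0, 0.01), base[2, ])
  d3 <- hierarchical_cluster(s3)
  expect_equal(d3$members[[1]], c(1L, 2L))
  expect_equal(d3$members[[2]], 1:3)

  # permuting observations gives an isomorphic tree
  perm <- c(3, 1, 2)
  dp <- hierarchical_cluster(s3[perm, ])
  sig <- function(ms) sort(vapply(ms, paste, "", collapse = ","))
  expect_identical(sig(lapply(dp$members, function(m) sort(perm[m]))),
                   sig(d3$members))

  expect_error(hierarchical_cluster(matrix(1, 3, 10)), "constant")
  expect_error(hierarchical_cluster(s3[1, , drop = FALSE]), "at least 2")
})

test_that("multiscale bootstrap recovers planted structure and is reproducible", {
  stack <- make_planted_stack(10, 2, noise_sd = 0.6, seed = 61)
  dend <- hierarchical_cluster(stack)
  sup <- multiscale_bootstrap_au(stack, dend, n_boot_per_scale = 60,
                                 seed = 9)
  expect_s3_class(sup, "node_support")
  expect_true(all(sup$bp >= 0 & sup$bp <= 1))
  expect_true(all(sup$au >= 0 & sup$au <= 1))

  members <- attr(sup, "members")
  g1 <- which(vapply(members, identical, logical(1), 1:10))
  g2 <- which(vapply(members, identical, logical(1), 11:20))
  expect_length(g1, 1)
  expect_length(g2, 1)
  expect_gte(sup$au[g1], 0.95)
  expect_gte(sup$au[g2], 0.95)

  sup2 <- multiscale_bootstrap_au(stack, dend, n_boot_per_scale = 60,
                                  seed = 9)
  expect_identical(sup$au, sup2$au)
  expect_identical(attr(sup, "bp_matrix"), attr(sup2, "bp_matrix"))

  # root is flagged and trivially supported
  expect_identical(sup$flag[nrow(sup)], "root")
  expect_equal(sup$bp[nrow(sup)], 1)

})

test_that("AU and BP discriminate graded planted support consistently", {
  # six planted pairs with increasing within-pair noise: true support fades
  set.seed(5)
  p <- 276
  protos <- matrix(rnorm(6 * p), 6, p)
  noises <- c(0.8, 1.4, 2.0, 2.8, 3.6, 5.0)
  stack <- do.call(rbind, lapply(1:6, function(k)
    protos[rep(k, 2), ] + matrix(rnorm(2 * p, 0, noises[k]), 2, p)))
  dend <- hierarchical_cluster(stack)
  sup <- multiscale_bootstrap_au(stack, dend, n_boot_per_scale = 100,
                                 seed = 3)
  members <- attr(sup, "members")
  idx <- vapply(1:6, function(k) {
    w <- which(vapply(members, identical, logical(1), c(2L * k - 1L, 2L * k)))
    if (length(w)) w else NA_integer_
  }, 1L)
  found <- which(!is.na(idx))
  expect_gte(length(found), 4)
  # bootstrap support decreases as the planted pairs get noisier
  expect_lt(cor(sup$bp[idx[found]], noises[found], method = "spearman"),
            -0.8)
  # both measures put planted nodes above the unplanted internal nodes
  planted <- idx[found]
  other <- setdiff(which(sup$flag != "root"), planted)
  expect_gt(mean(sup$au[planted]), mean(sup$au[other]))
  expect_gt(mean(sup$bp[planted]), mean(sup$bp[other]))
})

test_that("single-scale bootstrap reduces to the ordinary bootstrap", {
  stack <- make_planted_stack(5, 2, p = 60, noise_sd = 0.5, seed = 71)
  dend <- hierarchical_cluster(stack)
  sup <- multiscale_bootstrap_au(stack, dend, scales = 1,
                                 n_boot_per_scale = 50, seed = 3)
  nonroot <- sup$flag != "root"
  expect_identical(sup$au[nonroot], sup$bp[nonroot])
  expect_true(all(sup$flag[nonroot] == "degenerate_fit"))
  expect_error(multiscale_bootstrap_au(stack, dend, scales = c(0.8, 1.2),
                                       n_boot_per_scale = 50), "3 scales")
  expect_error(multiscale_bootstrap_au(stack, dend, n_boot_per_scale = 5),
               ">= 20")
})

test_that("cut_networks returns maximal reliable non-root nodes", {
  stack <- make_planted_stack(10, 3, noise_sd = 0.5, seed = 81)
  dend <- hierarchical_cluster(stack)
  sup <- multiscale_bootstrap_au(stack, dend, n_boot_per_scale = 60,
                                 seed = 5)
  nets <- cut_networks(dend, sup)
  expect_identical(sort(vapply(nets, paste, "", collapse = ",")),
                   sort(vapply(list(1:10, 11:20, 21:30), paste, "",
                               collapse = ",")))

  # disjointness and coverage properties
  all_members <- unlist(nets)
  expect_identical(anyDuplicated(all_members), 0L)
  expect_true(all(all_members %in% 1:30))

  # with every non-root AU forced to 1, the maximal nodes are the root's
  # two children (the root itself is never a candidate)
  sup1 <- sup
  sup1$au <- rep(1, nrow(sup1))
  nets1 <- cut_networks(dend, sup1)
  expect_length(nets1, 2)
  expect_setequal(sort(unlist(nets1)), 1:30)

  # nothing qualifies -> root fallback with warning
  sup0 <- sup
  sup0$au <- rep(0, nrow(sup0))
  expect_warning(nets0 <- cut_networks(dend, sup0), "root")
  expect_length(nets0, 1)
  expect_identical(nets0[[1]], 1:30)
  expect_true(attr(nets0, "fallback"))

  expect_error(cut_networks(dend, sup, au_threshold = 1 + 1e-9), "0, 1")
})

test_that("noise yields few high-AU nodes", {
  set.seed(91)
  stack <- matrix(rnorm(40 * 276), 40, 276)
  dend <- hierarchical_cluster(stack)
  sup <- multiscale_bootstrap_au(stack, dend, n_boot_per_scale = 60,
                                 seed = 17)
  nonroot <- sup$flag != "root"
  expect_lte(mean(sup$au[nonroot] >= 0.95), 0.15)
})

test_that("dendrogram exports parse back", {
  stack <- make_planted_stack(4, 2, p = 50, seed = 15)
  dend <- hierarchical_cluster(stack)
  sup <- multiscale_bootstrap_au(stack, dend, n_boot_per_scale = 30,
                                 seed = 2)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_dendrogram_json(dend, sup, jpath)
  nodes <- jsonlite::read_json(jpath)
  expect_length(nodes, length(dend$members))
  expect_equal(unlist(nodes[[1]]$members), dend$members[[1]])

  npath <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(dend, npath)
  skip_if_not_installed("ape")
  tree <- ape::read.tree(npath)
  expect_equal(ape::Ntip(tree), 8)
})
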