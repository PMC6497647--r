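#' Per-subject, per-run neural score record
#'
#' @param subject_id,run_id identifiers.
#' @param method one of `"infonet"`, `"rsa"`, `"univariate"`.
#' @param score scalar score (`NA` when flagged missing/dropped).
#' @param contributing_voxels linear voxel indices behind the score.
#' @param diagnostics named list of per-stage counts.
#' @param flags character vector (e.g. `"missing"`, `"dropped"`,
#'   `"capped"`, `"fallback"`).
#' @return object of class `neural_score_record`.
#' @export
neural_score_record <- function(subject_id, run_id, method, score,
                                contributing_voxels = integer(0),
                                diagnostics = list(), flags = character(0)) {
  stopifnot(method %in% c("infonet", "rsa", "univariate"))
  structure(list(subject_id = subject_id, run_id = run_id, method = method,
                 score = score,
                 contributing_voxels = as.integer(contributing_voxels),
                 diagnostics = diagnostics, flags = flags),
            class = "neural_score_record")
}

#' @export
print.neural_score_record <- function(x, ...) {
  cat(sprintf("<neural_score_record %s %s %s: %s%s>\n",
              x$subject_id, x$run_id, x$method,
              if (is.na(x$score)) "NA" else format(x$score, digits = 4),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.neural_score_record <- function(x, ...) {
  data.frame(subject_id = x$subject_id, run_id = x$run_id, method = x$method,
             score = x$score, n_voxels = length(x$contributing_voxels),
             flags = paste(x$flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Whole-brain univariate neural score
#'
#' Mean contrast z over the robust-range voxels (the top `top_fraction` of
#' positive z for images > fixation baseline). An empty mask yields a
#' missing score.
#'
#' @param zmap a [contrast_zmap].
#' @param top_fraction robust-range fraction (default 0.02).
#' @param subject_id,run_id identifiers for the record.
#' @return a [neural_score_record] with method `"univariate"`.
#' @export
univariate_score <- function(zmap, top_fraction = 0.02,
                             subject_id = NA_character_,
                             run_id = NA_character_) {
  stopifnot(all(is.finite(zmap$z)))
  mask <- robust_range_mask(zmap, top_fraction)
  if (!any(mask)) {
    return(neural_score_record(subject_id, run_id, "univariate", NA_real_,
                               diagnostics = list(n_selected = 0L),
                               flags = "missing"))
  }
  neural_score_record(subject_id, run_id, "univariate",
                      mean(zmap$z[mask]),
                      contributing_voxels = zmap$voxels[mask],
                      diagnostics = list(n_selected = sum(mask),
                                         threshold = attr(mask, "threshold")))
}

#' Searchlight RSA neural score
#'
#' Each searchlight DM is compared with the high-dimensional expert model by
#' Spearman correlation; the Fisher z of each rho is thresholded at
#' `z >= z_threshold` and the surviving z values are averaged. Subjects with
#' no surviving searchlight location are flagged `"dropped"` (score `NA`).
#' A perfect |rho| = 1 would make z infinite; such values are capped at
#' `atanh(1 - 1e-16)` (~18.71) and the record flagged `"capped"`.
#'
#' @param slr a `searchlight_result`.
#' @param expert an [expert_model] over the same items.
#' @param z_threshold Fisher-z selection threshold (default 2).
#' @param subject_id,run_id identifiers.
#' @return a [neural_score_record] with method `"rsa"`.
#' @export
rsa_score <- function(slr, expert, z_threshold = 2.0,
                      subject_id = NA_character_, run_id = NA_character_) {
  stopifnot(inherits(slr, "searchlight_result"),
            inherits(expert, "expert_model"))
  if (!identical(slr$item_ids, expert$dm$item_ids))
    stop("searchlight and expert model item orderings differ")
  rho <- vapply(slr$dms, spearman_dm_similarity, numeric(1L),
                dm_b = expert$dm)
  z <- fisher_z_capped(rho)
  capped <- attr(z, "capped")
  surv <- z >= z_threshold
  flags <- character(0)
  if (any(capped & surv)) flags <- c(flags, "capped")
  if (!any(surv)) {
    return(neural_score_record(subject_id, run_id, "rsa", NA_real_,
                               diagnostics = list(n_centers = length(rho),
                                                  n_surviving = 0L),
                               flags = c(flags, "dropped")))
  }
  neural_score_record(subject_id, run_id, "rsa", mean(z[surv]),
                      contributing_voxels = slr$centers[surv],
                      diagnostics = list(n_centers = length(rho),
                                         n_surviving = sum(surv),
                                         max_z = max(z)),
                      flags = flags)
}

#' Informational-network neural score
#'
#' The full pipeline: univariate robust-range voxel selection; searchlight
#' DMs at the selected centers; multiscale-bootstrap hierarchical clustering
#' into statistically reliable informational networks; per-network average
#' DM, 2-D MDS embedding and radial-SVM classification of the 3-way expert
#' category labels; the score is the maximum SVM accuracy over networks.
#' Ties on accuracy break toward the larger network, then the lower merge
#' height.
#'
#' @param betas an [item_beta_maps] (with residual-variance fields, unless a
#'   precomputed `zmap` is supplied in `config`).
#' @param expert_categories named factor of 3-way category labels over
#'   `betas$item_ids` (the dimensionality-reduced expert model).
#' @param config named list overriding any of: `top_fraction` (0.02),
#'   `radius_voxels` (3), `min_voxels` (10), `scales`
#'   (`seq(0.5, 1.4, 0.1)`), `n_boot_per_scale` (100), `au_threshold`
#'   (0.95), `min_size` (2), `svm_cost` (1), `kernel_width` (0.5),
#'   `eval_mode` ("resubstitution"), `mds_variant` ("classical"), `seed`
#'   (1), `zmap` (precomputed [contrast_zmap]), `mask` (brain mask; default
#'   all beta voxels).
#' @return list with `record` (a [neural_score_record], method `"infonet"`)
#'   and `networks` (per network: `members`, `centers`, `au`, `height`,
#'   `average_dm`, `embedding`, `svm_accuracy`).
#' @export
infonet_score <- function(betas, expert_categories, config = list()) {
  stopifnot(inherits(betas, "item_beta_maps"))
  cfg <- utils::modifyList(list(
    top_fraction = 0.02, radius_voxels = 3, min_voxels = 10L,
    scales = seq(0.5, 1.4, by = 0.1), n_boot_per_scale = 100L,
    au_threshold = 0.95, min_size = 2L,
    svm_cost = 1, kernel_width = 0.5,
    eval_mode = "resubstitution", mds_variant = "classical",
    seed = 1L, zmap = NULL, mask = NULL), config)

  labels <- expert_categories
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), betas$item_ids))
      stop("expert category items do not match the beta-map items")
    labels <- labels[betas$item_ids]
  } else if (length(labels) != length(betas$item_ids)) {
    stop("need one category label per item")
  }

  zmap <- if (is.null(cfg$zmap)) contrast_zmap(betas) else cfg$zmap
  rr <- robust_range_mask(zmap, cfg$top_fraction)
  diag_ <- list(n_voxels = length(zmap$z), n_robust_range = sum(rr))
  empty_record <- function(flags, extra = list()) {
    list(record = neural_score_record(betas$subject_id, betas$run_id,
                                      "infonet", NA_real_,
                                      diagnostics = c(diag_, extra),
                                      flags = flags),
         networks = list())
  }
  if (!any(rr)) return(empty_record("missing"))

  mask <- if (is.null(cfg$mask)) betas$voxels else cfg$mask
  nbh <- sphere_neighborhoods(betas$grid, mask, cfg$radius_voxels,
                              cfg$min_voxels, centers = zmap$voxels[rr])
  if (length(nbh$centers) == 0L)
    return(empty_record("missing", list(n_surviving_centers = 0L)))
  slr <- searchlight_dms(betas, nbh)
  m <- length(slr$centers)
  diag_$n_surviving_centers <- m

  flags <- character(0)
  if (m == 1L) {
    nets <- list(1L)
    attr(nets, "nodes") <- NA_integer_
    attr(nets, "heights") <- 0
    support <- NULL
    flags <- c(flags, "single_center")
  } else {
    dend <- hierarchical_cluster(slr)
    support <- multiscale_bootstrap_au(slr, dend, scales = cfg$scales,
                                       n_boot_per_scale = cfg$n_boot_per_scale,
                                       seed = cfg$seed)
    nets <- withCallingHandlers(
      cut_networks(dend, support, cfg$au_threshold, cfg$min_size),
      warning = function(w) {
        flags <<- c(flags, "fallback")
        invokeRestart("muffleWarning")
      })
  }

  networks <- vector("list", length(nets))
  for (k in seq_along(nets)) {
    idx <- nets[[k]]
    avg <- average_dm(slr$dms[idx])
    emb <- mds_embed(avg, n_dims = 2L, variant = cfg$mds_variant)
    acc <- svm_category_accuracy(emb, labels, cost = cfg$svm_cost,
                                 kernel_width = cfg$kernel_width,
                                 eval_mode = cfg$eval_mode)
    node <- attr(nets, "nodes")[k]
    networks[[k]] <- list(members = idx, centers = slr$centers[idx],
                          au = if (!is.null(support) && !is.na(node))
                                 support$au[node] else NA_real_,
                          height = attr(nets, "heights")[k],
                          average_dm = avg, embedding = emb,
                          svm_accuracy = as.numeric(acc))
  }
  accs <- vapply(networks, `[[`, numeric(1L), "svm_accuracy")
  sizes <- lengths(nets)
  heights <- attr(nets, "heights")
  best <- order(-accs, -sizes, heights)[1L]
  diag_$n_networks <- length(networks)
  diag_$best_network_size <- sizes[best]

  rec <- neural_score_record(betas$subject_id, betas$run_id, "infonet",
                             accs[best],
                             contributing_voxels = networks[[best]]$centers,
                             diagnostics = diag_, flags = flags)
  list(record = rec, networks = networks)
}
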