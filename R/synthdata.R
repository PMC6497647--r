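#' Specification of a synthetic fMRI cohort
#'
#' Describes the stated world the generator emulates: a cohort of subjects
#' whose item-level beta maps contain (i) task-active "blobs" (uniform
#' activation for every stimulus image relative to fixation), (ii)
#' informational blobs whose item patterns encode a 3-category structure
#' with amplitude scaled by each subject's latent expertise `e`, plus an
#' orthogonal visual-similarity structure crossing the categories, and (iii)
#' i.i.d. Gaussian noise. Behavioral accuracies are linear in `e` plus noise.
#'
#' Expertise is continuous in `[0, 1]`; `group` is the thresholded view
#' (expert iff `e >= 0.5`).
#'
#' @param n_subjects_per_group subjects per group (default 10).
#' @param grid_dims voxel grid (default `c(16, 16, 16)`).
#' @param n_items stimuli per run (default 24: three mechanical categories
#'   of 8 — cantilevers, trusses, vertical loads).
#' @param n_runs fMRI runs (default 4).
#' @param expertise optional numeric vector of latent expertise in `[0, 1]`,
#'   one per subject (`2 * n_subjects_per_group`); default: half drawn
#'   uniformly on `[0, 0.5)` (novices) and half on `[0.5, 1]` (experts).
#' @param n_task_blobs,n_info_blobs number of task-only and informational
#'   blobs (defaults 2 and 2).
#' @param blob_radius blob sphere radius in voxels (default 3, matching the
#'   default searchlight radius).
#' @param a_task mean task activation in beta units (default 3).
#' @param w_cat amplitude of the expertise-scaled category pattern
#'   (default 1.2).
#' @param w_vis amplitude of the visual-similarity pattern (default 0.8).
#' @param noise_sd beta noise standard deviation (default 1).
#' @param n_visual_clusters visual clusters crossing the categories
#'   (default 8: each cluster holds one item from every category, so visual
#'   similarity can never proxy mechanical category).
#' @param behav_base,behav_slope FBD accuracy model `clip(base + slope * e +
#'   N(0, 0.05^2), 0, 1)` (defaults 0.45 and 0.40, echoing the observed
#'   novice ~0.54 / expert ~0.75 run-1 scale).
#' @param behav_noise_sd behavioral noise sd (default 0.05).
#' @param glm_dof residual degrees of freedom the betas are pretended to
#'   come from (default 270, the scale of a ~298-volume run).
#' @param missing_rate probability that a subject lacks the SCI / FCI
#'   concept-inventory scores (default 1/3 each, independently).
#' @param seed master integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group = 10L,
                        grid_dims = c(16L, 16L, 16L),
                        n_items = 24L, n_runs = 4L,
                        expertise = NULL,
                        n_task_blobs = 2L, n_info_blobs = 2L,
                        blob_radius = 3,
                        a_task = 3, w_cat = 1.2, w_vis = 0.8,
                        noise_sd = 1,
                        n_visual_clusters = 8L,
                        behav_base = 0.45, behav_slope = 0.40,
                        behav_noise_sd = 0.05,
                        glm_dof = 270L, missing_rate = 1 / 3,
                        seed = 1L) {
  stopifnot(n_subjects_per_group >= 1L, n_items >= 6L, n_runs >= 1L,
            n_task_blobs >= 0L, n_info_blobs >= 1L, blob_radius >= 1,
            noise_sd > 0, n_visual_clusters >= 2L)
  if (!is.null(expertise)) {
    stopifnot(length(expertise) == 2L * n_subjects_per_group,
              all(expertise >= 0 & expertise <= 1))
  }
  if (n_items %% 3L != 0L)
    stop("n_items must be divisible by the 3 mechanical categories")
  structure(as.list(environment()), class = "cohort_spec")
}

# deterministic per-subject/purpose subseed below 2^31
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + (as.numeric(p) %% 104729) + 1) %% 2147483629
  as.integer(s) + 1L
}

#' Generate a seeded synthetic cohort
#'
#' Draws blob locations, category/visual pattern prototypes, per-subject
#' expertise, per-run item beta maps and a behavioral table according to a
#' [cohort_spec]. Fully reproducible: the same spec (including seed) yields
#' bit-identical output.
#'
#' Beta generative model, per voxel `v` and item `i`:
#' `beta[i, v] = a_task * [v in any blob] + w_cat * e * mu[cat(i), v] * [v in
#' info blob] + w_vis * nu[vis(i), v] * [v in info blob] + N(0, noise_sd^2)`,
#' where the `mu` are 3 fixed orthogonal category prototypes and the `nu`
#' orthogonal visual-cluster prototypes (orthogonal to the `mu` as well),
#' each scaled to unit per-voxel RMS within its blob.
#'
#' @param spec a [cohort_spec].
#' @return list with `subjects` (per subject: `subject_id`, `group`, `e`,
#'   `runs` = list of [item_beta_maps]), `behavior` (data.frame), `ground_truth`
#'   (expertise, task/info voxel index sets, item category and visual labels,
#'   blob centers), `expert_model` (an [expert_model]), `mask` (logical
#'   array), `grid`, and the `spec` itself.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- vol_grid(spec$grid_dims)
  mask <- array(TRUE, spec$grid_dims)
  n_sub <- 2L * spec$n_subjects_per_group

  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  set.seed(derive_seed(spec$seed, 101L))
  blobs <- place_blobs(grid,
                       rep(c("task", "info"),
                           c(spec$n_task_blobs, spec$n_info_blobs)),
                       spec$blob_radius)
  task_blobs <- blobs[seq_len(spec$n_task_blobs)]
  info_blobs <- blobs[spec$n_task_blobs + seq_len(spec$n_info_blobs)]
  task_vox <- sort(unique(unlist(lapply(task_blobs, `[[`, "voxels"))))
  info_vox <- sort(unique(unlist(lapply(info_blobs, `[[`, "voxels"))))

  n_cat <- 3L
  per_cat <- spec$n_items %/% n_cat
  categories <- rep(c("cantilever", "truss", "vertical_load"),
                    each = per_cat)
  visual <- assign_visual_clusters(spec$n_items, per_cat, n_cat,
                                   spec$n_visual_clusters)
  item_ids <- sprintf("item%02d", seq_len(spec$n_items))

  # orthonormal prototypes per info blob, unit per-voxel RMS
  protos <- lapply(seq_along(info_blobs), function(b) {
    vox <- info_blobs[[b]]$voxels
    nv <- length(vox)
    k <- n_cat + spec$n_visual_clusters
    if (nv <= k)
      stop("info blob too small for orthogonal prototype construction")
    set.seed(derive_seed(spec$seed, 202L, b))
    q <- qr.Q(qr(matrix(stats::rnorm(nv * k), nv, k))) * sqrt(nv)
    mu <- q[, seq_len(n_cat), drop = FALSE]
    nu <- q[, n_cat + seq_len(spec$n_visual_clusters), drop = FALSE]
    # center prototypes across (item-count-weighted) classes so the
    # item-mean pattern is exactly zero at every voxel: the planted category
    # and visual structure then cannot leak into the images > baseline
    # contrast, only into the pattern geometry
    wc <- rep(1 / n_cat, n_cat)
    mu <- mu - drop(mu %*% wc)
    wv <- tabulate(visual, spec$n_visual_clusters)
    wv <- wv / sum(wv)
    nu <- nu - drop(nu %*% wv)
    list(voxels = vox, mu = mu, nu = nu)
  })

  set.seed(derive_seed(spec$seed, 303L))
  e <- spec$expertise
  if (is.null(e)) {
    e <- c(stats::runif(spec$n_subjects_per_group, 0, 0.5 - 1e-9),
           stats::runif(spec$n_subjects_per_group, 0.5, 1))
  }
  group <- ifelse(e >= 0.5, "expert", "novice")
  subject_ids <- sprintf("sub%02d", seq_len(n_sub))

  all_vox <- which(mask)
  n_vox <- length(all_vox)
  in_any_blob <- logical(n_vox)
  in_any_blob[c(task_vox, info_vox)] <- TRUE

  # fixed (item x voxel) pattern layers, shared across subjects up to e-scaling
  cat_idx <- match(categories, c("cantilever", "truss", "vertical_load"))
  cat_layer <- matrix(0, spec$n_items, n_vox)
  vis_layer <- matrix(0, spec$n_items, n_vox)
  for (pb in protos) {
    cols <- pb$voxels
    cat_layer[, cols] <- cat_layer[, cols] + t(pb$mu[, cat_idx, drop = FALSE])
    vis_layer[, cols] <- vis_layer[, cols] + t(pb$nu[, visual, drop = FALSE])
  }
  base_layer <- spec$a_task * as.numeric(in_any_blob)

  subjects <- vector("list", n_sub)
  behavior <- NULL
  for (s in seq_len(n_sub)) {
    runs <- vector("list", spec$n_runs)
    for (r in seq_len(spec$n_runs)) {
      set.seed(derive_seed(spec$seed, 404L, s, r))
      noise <- matrix(stats::rnorm(spec$n_items * n_vox, 0, spec$noise_sd),
                      spec$n_items, n_vox)
      betas <- sweep(spec$w_cat * e[s] * cat_layer + spec$w_vis * vis_layer,
                     2L, base_layer, "+") + noise
      rownames(betas) <- item_ids
      resid_var <- spec$noise_sd^2 *
        stats::rchisq(n_vox, spec$glm_dof) / spec$glm_dof
      runs[[r]] <- item_beta_maps(subject_ids[s], paste0("run", r),
                                  betas, all_vox, grid, item_ids,
                                  resid_var = resid_var, dof = spec$glm_dof,
                                  xtx_inv = diag(spec$n_items))
    }
    set.seed(derive_seed(spec$seed, 505L, s))
    fbd <- pmin(pmax(spec$behav_base + spec$behav_slope * e[s] +
                       stats::rnorm(spec$n_runs, 0, spec$behav_noise_sd),
                     0), 1)
    sci <- pmin(pmax(0.10 + 0.55 * e[s] +
                       stats::rnorm(1, 0, spec$behav_noise_sd), 0), 1)
    fci <- pmin(pmax(0.25 + 0.60 * e[s] +
                       stats::rnorm(1, 0, spec$behav_noise_sd), 0), 1)
    if (stats::runif(1) < spec$missing_rate) sci <- NA_real_
    if (stats::runif(1) < spec$missing_rate) fci <- NA_real_
    subjects[[s]] <- list(subject_id = subject_ids[s], group = group[s],
                          e = e[s], runs = runs)
    row <- data.frame(subject_id = subject_ids[s], group = group[s],
                      sci_acc = sci, fci_acc = fci)
    for (r in seq_len(spec$n_runs)) row[[paste0("fbd_run", r)]] <- fbd[r]
    behavior <- rbind(behavior, row)
  }

  em <- build_expert_model(n_items = spec$n_items,
                           category_sizes = rep(per_cat, n_cat),
                           seed = derive_seed(spec$seed, 606L))

  list(subjects = subjects,
       behavior = behavior,
       ground_truth = list(
         expertise = stats::setNames(e, subject_ids),
         task_voxels = task_vox, info_voxels = info_vox,
         categories = stats::setNames(categories, item_ids),
         visual_clusters = stats::setNames(visual, item_ids),
         blob_centers = vapply(blobs, `[[`, integer(1L), "center")),
       expert_model = em,
       mask = mask, grid = grid, spec = spec)
}

# Visual-cluster assignment crossing the mechanical categories.
#
# Default 24-item design (8 clusters of 3): each cluster holds 2 items of one
# category and 1 of another, arranged so that same-cluster pairs split into
# 8 within-category and 16 between-category pairs — nearly the marginal
# within/between ratio (84:192). Visual similarity then (i) links every item
# to at least one item of a different category and (ii) leaves the expected
# within-minus-between category distance at zero when no category signal is
# planted (e = 0). Other configurations fall back to striping clusters
# across categories (every cluster spans several categories, but the e = 0
# distance gap is then slightly negative for between pairs).
assign_visual_clusters <- function(n_items, per_cat, n_cat, n_clusters) {
  if (n_items == 24L && per_cat == 8L && n_cat == 3L && n_clusters == 8L) {
    # per cluster: (major category x2, minor category x1)
    major <- c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L)
    minor <- c(3L, 3L, 2L, 3L, 3L, 1L, 1L, 2L)
    visual <- integer(24L)
    used <- integer(3L)  # items consumed per category
    item_of <- function(cat, k) (cat - 1L) * per_cat + k
    for (cl in 1:8) {
      for (rep_ in 1:2) {
        used[major[cl]] <- used[major[cl]] + 1L
        visual[item_of(major[cl], used[major[cl]])] <- cl
      }
      used[minor[cl]] <- used[minor[cl]] + 1L
      visual[item_of(minor[cl], used[minor[cl]])] <- cl
    }
    return(visual)
  }
  (rep(seq_len(per_cat), times = n_cat) - 1L) %% n_clusters + 1L
}

# Place spherical blobs fully inside the grid, one per entry of `types`.
# Blobs of different types must not share voxels (task activation and
# informational patterns live in separate tissue); same-type blobs may abut
# or overlap, which only changes effective blob volume.
place_blobs <- function(grid, types, radius, max_tries = 200L,
                        max_restarts = 50L) {
  offs <- sphere_offsets(radius)
  d <- grid$dims
  if (any(d < 2 * floor(radius) + 1))
    stop("blobs of this radius cannot fit inside the mask/grid")
  for (restart in seq_len(max_restarts)) {
    blobs <- list()
    occupied <- sapply(unique(types), function(t) integer(0),
                       simplify = FALSE)
    tries <- 0L
    while (length(blobs) < length(types) && tries <= max_tries) {
      tries <- tries + 1L
      ty <- types[length(blobs) + 1L]
      ctr <- vapply(d, function(k)
        sample(seq.int(floor(radius) + 1L, k - floor(radius)), 1L),
        integer(1L))
      vox <- coords_to_index(sweep(offs, 2L, ctr, "+"), grid)
      other <- unlist(occupied[setdiff(names(occupied), ty)])
      if (length(intersect(vox, other)) > 0L) next
      blobs[[length(blobs) + 1L]] <-
        list(center = coords_to_index(matrix(ctr, 1L), grid),
             voxels = sort(vox))
      occupied[[ty]] <- c(occupied[[ty]], vox)
    }
    if (length(blobs) == length(types)) return(blobs)
    # dead end: earlier blobs boxed the rest out; restart the placement
  }
  stop("could not place non-overlapping blobs inside the mask")
}

#' Accuracy of a uniformly random two-alternative responder
#'
#' Simulates a responder who answers a balanced two-alternative
#' forced-choice correctness judgment uniformly at random; each trial is
#' correct with probability 1/2 (chance = 50 percent accuracy).
#'
#' @param n_trials number of trials (`>= 1`).
#' @param seed integer seed.
#' @return mean accuracy in `[0, 1]`.
#' @export
simulate_random_responder <- function(n_trials, seed = 1L) {
  stopifnot(n_trials >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  mean(stats::rbinom(n_trials, 1L, 0.5))
}

#' Forward-simulate a 4-D time series from item beta maps
#'
#' Voxel time course = sum over items of `beta[i, v]` times the 6-second
#' boxcar at that item's onset convolved with the canonical double-gamma
#' HRF, plus white noise. The simplified forward model of the 6-second
#' stimulus-consideration window; TR defaults to 2.5 s.
#'
#' @param betas an [item_beta_maps].
#' @param timing data.frame(`onset`, `duration`, `trial_type`) with one row
#'   per item trial (`trial_type` = item id); events must not overlap within
#'   the modeled window.
#' @param tr repetition time in seconds (> 0; default 2.5).
#' @param noise_sd white-noise sd (default 0).
#' @param n_vols number of volumes (default: covers the last event + 30 s).
#' @param seed integer seed for the noise.
#' @return time x voxel matrix with attributes `tr` and `voxels`.
#' @export
generate_timeseries <- function(betas, timing, tr = 2.5, noise_sd = 0,
                                n_vols = NULL, seed = 1L) {
  stopifnot(inherits(betas, "item_beta_maps"))
  if (tr <= 0) stop("TR must be positive")
  o <- order(timing$onset)
  ends <- timing$onset[o] + timing$duration[o]
  if (any(ends[-length(ends)] > timing$onset[o][-1L] + 1e-9))
    stop("timing events overlap within the modeled window")
  if (is.null(n_vols)) n_vols <- ceiling((max(ends) + 30) / tr)
  X <- build_design(timing, n_vols, tr)
  item_X <- X[, betas$item_ids, drop = FALSE]
  y <- item_X %*% betas$betas
  if (noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    y <- y + matrix(stats::rnorm(length(y), 0, noise_sd), nrow(y), ncol(y))
  }
  attr(y, "tr") <- tr
  attr(y, "voxels") <- betas$voxels
  y
}

#' Event timing table for one synthetic run
#'
#' One 6-second consideration event per item, separated by enough fixation
#' for unconfounded estimation, plus one pooled response-period regressor.
#'
#' @param item_ids item identifiers, in presentation order.
#' @param trial_spacing seconds between consecutive trial onsets
#'   (default 15.5 + 15.5, trial plus inter-trial fixation).
#' @param consideration_dur modeled stimulus window (default 6 s).
#' @param include_response add 4-s response events (default TRUE).
#' @return data.frame(`onset`, `duration`, `trial_type`).
#' @export
fbd_run_timing <- function(item_ids, trial_spacing = 31,
                           consideration_dur = 6, include_response = TRUE) {
  onsets <- (seq_along(item_ids) - 1L) * trial_spacing
  timing <- data.frame(onset = onsets, duration = consideration_dur,
                       trial_type = item_ids)
  if (include_response) {
    timing <- rbind(timing,
                    data.frame(onset = onsets + consideration_dur + 4,
                               duration = 4, trial_type = "response"))
  }
  timing[order(timing$onset), ]
}
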