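#' Pipeline configuration
#'
#' Validated bundle of every tunable in the simulate -> score -> validate ->
#' localize pipeline. Unknown keys are rejected; the full configuration is
#' serialized into every output's provenance block.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # simulate
    n_subjects_per_group = 10L, grid_dims = c(16L, 16L, 16L),
    n_items = 24L, n_runs = 4L, expertise = NULL,
    n_task_blobs = 2L, n_info_blobs = 2L, blob_radius = 3,
    a_task = 3, w_cat = 1.2, w_vis = 0.8, noise_sd = 1,
    behav_base = 0.45, behav_slope = 0.40,
    # score
    methods = c("infonet", "rsa", "univariate"),
    runs = NULL,                      # NULL = all runs
    top_fraction = 0.02, radius_voxels = 3, min_voxels = 10L,
    z_threshold = 2.0,
    scales = seq(0.5, 1.4, by = 0.1), n_boot_per_scale = 100L,
    au_threshold = 0.95, min_size = 2L,
    svm_cost = 1, kernel_width = 0.5, eval_mode = "resubstitution",
    mds_variant = "classical",
    # io
    out_dir = NULL, write_volumes = FALSE,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  if (!all(cfg$methods %in% c("infonet", "rsa", "univariate")))
    stop("methods must be among infonet, rsa, univariate")
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  h <- 0
  for (v in utf8ToInt(as.character(s))) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full synthetic pipeline
#'
#' Generates a cohort from the configuration, computes the requested neural
#' scores for every subject and run, validates the run-1 scores against the
#' behavioral table (mixed model per method, Welch group test), builds
#' group localization maps, and (when `out_dir` is set) writes scores TSV,
#' validation JSON, localization volumes and a provenance log. Deterministic
#' under the configuration seed.
#'
#' @param config a [pipeline_config].
#' @return list with `cohort`, `scores` (data.frame), `records`,
#'   `validation`, `localization`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- cohort_spec(
    n_subjects_per_group = config$n_subjects_per_group,
    grid_dims = config$grid_dims, n_items = config$n_items,
    n_runs = config$n_runs, expertise = config$expertise,
    n_task_blobs = config$n_task_blobs, n_info_blobs = config$n_info_blobs,
    blob_radius = config$blob_radius, a_task = config$a_task,
    w_cat = config$w_cat, w_vis = config$w_vis, noise_sd = config$noise_sd,
    behav_base = config$behav_base, behav_slope = config$behav_slope,
    seed = config$seed)
  cohort <- generate_cohort(spec)
  runs <- if (is.null(config$runs)) seq_len(spec$n_runs)
          else as.integer(config$runs)

  records <- list()
  for (sub in cohort$subjects) {
    for (r in runs) {
      betas <- sub$runs[[r]]
      zmap <- contrast_zmap(betas)
      sl_cache <- NULL
      if (any(c("rsa") %in% config$methods)) {
        nbh <- sphere_neighborhoods(betas$grid, betas$voxels,
                                    config$radius_voxels, config$min_voxels)
        sl_cache <- searchlight_dms(betas, nbh)
      }
      for (method in config$methods) {
        rec <- switch(method,
          univariate = univariate_score(zmap, config$top_fraction,
                                        sub$subject_id, betas$run_id),
          rsa = rsa_score(sl_cache, cohort$expert_model, config$z_threshold,
                          sub$subject_id, betas$run_id),
          infonet = infonet_score(betas,
                                  cohort$ground_truth$categories,
                                  config = list(
                                    top_fraction = config$top_fraction,
                                    radius_voxels = config$radius_voxels,
                                    min_voxels = config$min_voxels,
                                    scales = config$scales,
                                    n_boot_per_scale = config$n_boot_per_scale,
                                    au_threshold = config$au_threshold,
                                    min_size = config$min_size,
                                    svm_cost = config$svm_cost,
                                    kernel_width = config$kernel_width,
                                    eval_mode = config$eval_mode,
                                    mds_variant = config$mds_variant,
                                    zmap = zmap,
                                    seed = derive_seed(config$seed, 909L,
                                                       match(sub$subject_id,
                                                             cohort$behavior$subject_id),
                                                       r)))$record)
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  scores <- do.call(rbind, lapply(records, as.data.frame))

  run1 <- scores[scores$run_id == "run1", ]
  blong <- behavior_long(cohort$behavior)
  validation <- list()
  for (method in config$methods) {
    sm <- run1[run1$method == method & !is.na(run1$score), ]
    val <- list(n_scored = nrow(sm),
                n_dropped = sum(run1$method == method) - nrow(sm))
    grp <- cohort$behavior$group[match(sm$subject_id,
                                       cohort$behavior$subject_id)]
    if (length(unique(grp)) == 2L && min(table(grp)) >= 2L) {
      wt <- tryCatch(
        welch_t(sm$score[grp == "expert"], sm$score[grp == "novice"]),
        error = function(e) NULL)  # e.g. degenerate zero-variance groups
      if (!is.null(wt))
        val$group_t <- wt[c("t", "df", "p", "mean_a", "mean_b")]
    }
    if (nrow(sm) >= 4L && stats::sd(sm$score) > 0) {
      mm <- fit_score_model(sm, blong)
      val$mixed_model <- mm[c("beta", "beta_std", "se", "p", "loglik",
                              "n_obs", "converged")]
    }
    validation[[method]] <- val
  }

  localization <- list()
  groups <- stats::setNames(cohort$behavior$group,
                            cohort$behavior$subject_id)
  for (method in config$methods) {
    recs <- Filter(function(r) r$method == method && r$run_id == "run1" &&
                     length(r$contributing_voxels) > 0, records)
    if (length(recs) == 0L) next
    contrib <- stats::setNames(lapply(recs, `[[`, "contributing_voxels"),
                               vapply(recs, `[[`, "", "subject_id"))
    localization[[method]] <-
      group_localization(contrib, groups[names(contrib)], cohort$grid)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("infonetscore")),
    config = unclass(config), config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC"),
    counts = list(
      n_subjects = length(cohort$subjects),
      n_records = length(records),
      n_dropped_rsa = sum(scores$method == "rsa" & is.na(scores$score))))

  result <- list(cohort = cohort, scores = scores, records = records,
                 validation = validation, localization = localization,
                 provenance = provenance)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$scores,
                     file.path(config$out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(validation = result$validation, provenance = result$provenance),
    file.path(config$out_dir, "validation.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  if (isTRUE(config$write_volumes)) {
    for (method in names(result$localization)) {
      loc <- result$localization[[method]]
      write_nifti(loc$category * 1.0,
                  file.path(config$out_dir,
                            sprintf("localization_%s_category.nii.gz",
                                    method)),
                  loc$grid$voxel_size_mm)
    }
  }
  jsonlite::write_json(result$provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}
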