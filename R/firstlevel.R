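#' Item-level beta maps for one subject and run
#'
#' Container for the per-stimulus activity patterns feeding every neural
#' score: one regression coefficient per item per in-mask voxel, together
#' with the per-voxel residual variance, the residual degrees of freedom, and
#' the unscaled coefficient covariance `(X'X)^-1` of the item regressors
#' needed to turn contrasts into t/z statistics.
#'
#' @param subject_id,run_id identifiers.
#' @param betas numeric item x voxel matrix.
#' @param voxels linear voxel indices (into `grid`) for the columns.
#' @param grid a [vol_grid].
#' @param item_ids character, one per row of `betas`.
#' @param resid_var per-voxel residual variance (same length as `voxels`).
#' @param dof residual degrees of freedom.
#' @param xtx_inv unscaled covariance of the item coefficients (items x
#'   items); the identity for synthetic betas with i.i.d. unit-design noise.
#' @return An object of class `item_beta_maps`.
#' @export
item_beta_maps <- function(subject_id, run_id, betas, voxels, grid, item_ids,
                           resid_var = NULL, dof = NA_real_,
                           xtx_inv = NULL) {
  betas <- as.matrix(betas)
  stopifnot(inherits(grid, "vol_grid"),
            nrow(betas) == length(item_ids),
            ncol(betas) == length(voxels),
            all(is.finite(betas)))
  if (is.null(xtx_inv)) xtx_inv <- diag(length(item_ids))
  structure(list(subject_id = subject_id, run_id = run_id,
                 betas = betas, voxels = as.integer(voxels), grid = grid,
                 item_ids = as.character(item_ids),
                 resid_var = resid_var, dof = dof, xtx_inv = xtx_inv),
            class = "item_beta_maps")
}

#' @export
print.item_beta_maps <- function(x, ...) {
  cat(sprintf("<item_beta_maps: sub %s run %s, %d items x %d voxels>\n",
              x$subject_id, x$run_id, nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

#' Canonical double-gamma haemodynamic response function
#'
#' The community-default HRF: a gamma density peaking at 6 s minus an
#' undershoot gamma peaking at 16 s scaled by 1/6, normalized to unit peak.
#'
#' @param t time in seconds (vector).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(stats::dgamma(5, shape = 6, rate = 1) -
            stats::dgamma(5, shape = 16, rate = 1) / 6)
}

# Boxcar-convolved HRF regressors sampled at the TR grid.
# timing: data.frame(onset, duration, trial_type); one column per level of
# trial_type, in level order.
build_design <- function(timing, n_vols, tr, dt = 0.1) {
  types <- unique(as.character(timing$trial_type))
  t_fine <- seq(0, (n_vols - 1) * tr + 32, by = dt)
  hrf <- hrf_double_gamma(seq(0, 32, by = dt))
  X <- matrix(0, n_vols, length(types), dimnames = list(NULL, types))
  scan_t <- (seq_len(n_vols) - 1) * tr
  for (j in seq_along(types)) {
    rows <- timing[timing$trial_type == types[j], , drop = FALSE]
    box <- numeric(length(t_fine))
    for (k in seq_len(nrow(rows))) {
      on <- rows$onset[k]
      box[t_fine >= on & t_fine < on + rows$duration[k]] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(t_fine)] * dt
    X[, j] <- stats::approx(t_fine, conv, xout = scan_t, rule = 2)$y
  }
  X
}

#' Fit the item-level GLM to a 4-D time series
#'
#' Ordinary least squares of every voxel's time course on one HRF-convolved
#' boxcar regressor per stimulus item (plus any additional trial types in
#' the timing table, e.g. a response-period regressor, which are modeled and
#' then discarded) and an intercept. Between-trial fixation is the unmodeled
#' baseline.
#'
#' @param series numeric 4-D array (x, y, z, time) or time x voxel matrix.
#' @param timing data.frame with columns `onset`, `duration`, `trial_type`
#'   (seconds; `trial_type` values naming items, or `"response"` for the
#'   discarded response regressor).
#' @param tr repetition time in seconds (default 2.5).
#' @param mask logical array / linear indices of voxels to fit (default all).
#' @param grid a [vol_grid]; inferred from array dims if omitted.
#' @param item_ids which trial types are items (default: all except
#'   `"response"`).
#' @param subject_id,run_id identifiers stored in the result.
#' @return An [item_beta_maps] carrying item betas, per-voxel residual
#'   variance, residual dof and the item block of `(X'X)^-1`.
#' @export
fit_item_glm <- function(series, timing, tr = 2.5, mask = NULL, grid = NULL,
                         item_ids = NULL, subject_id = "sub01",
                         run_id = "run1") {
  if (tr <= 0) stop("TR must be positive")
  if (is.array(series) && length(dim(series)) == 4L) {
    d <- dim(series)
    if (is.null(grid)) grid <- vol_grid(d[1:3])
    vox <- if (is.null(mask)) seq_len(prod(d[1:3]))
           else if (is.logical(mask)) which(mask) else as.integer(mask)
    Y <- t(matrix(series, prod(d[1:3]), d[4L])[vox, , drop = FALSE])
  } else {
    Y <- as.matrix(series)
    if (is.null(grid)) grid <- vol_grid(c(ncol(Y), 1L, 1L))
    vox <- if (is.null(mask)) seq_len(ncol(Y))
           else if (is.logical(mask)) which(mask) else as.integer(mask)
    Y <- Y[, vox, drop = FALSE]
  }
  n_vols <- nrow(Y)
  X <- build_design(timing, n_vols, tr)
  if (is.null(item_ids)) item_ids <- setdiff(colnames(X), "response")
  X <- cbind(X, intercept = 1)
  if (ncol(X) > n_vols - 2L)
    stop("design has too many regressors for the number of time points")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  coefs <- qr.coef(qrX, Y)
  resid <- Y - X %*% coefs
  dof <- n_vols - ncol(X)
  resid_var <- colSums(resid^2) / dof
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  item_beta_maps(subject_id, run_id,
                 betas = coefs[item_ids, , drop = FALSE],
                 voxels = vox, grid = grid, item_ids = item_ids,
                 resid_var = resid_var, dof = dof,
                 xtx_inv = xtx_inv[item_ids, item_ids, drop = FALSE])
}

#' Whole-brain contrast z-map from an item-level fit
#'
#' Per voxel, the contrast t statistic `t = c'beta / sqrt(sigma^2 c'(X'X)^-1 c)`
#' is converted to a z value by probability matching through the t
#' distribution at the fit's residual dof. The default contrast is the mean
#' of all item regressors against the implicit fixation baseline.
#'
#' @param fit an [item_beta_maps] with `resid_var`, `dof` and `xtx_inv` set
#'   (as produced by [fit_item_glm()] or the synthetic generator).
#' @param contrast_weights numeric, one weight per item regressor (default
#'   `1/n_items` each).
#' @param name contrast label.
#' @return An object of class `contrast_zmap`: list with `z` (per in-mask
#'   voxel), `voxels`, `grid`, `name`, `n_clamped`.
#' @export
contrast_zmap <- function(fit, contrast_weights = NULL,
                          name = "images_gt_baseline") {
  stopifnot(inherits(fit, "item_beta_maps"))
  if (is.null(fit$resid_var) || is.na(fit$dof)) {
    # beta-maps-only route (e.g. volumes read back from disk): fall back to
    # a one-sample t of the item betas against zero per voxel; the item
    # spread then stands in for the GLM residual variance
    warning(paste("no residual-variance information;",
                  "using across-item variance for the contrast"))
    n <- nrow(fit$betas)
    fit$resid_var <- apply(fit$betas, 2L, stats::var)
    fit$dof <- n - 1L
    fit$xtx_inv <- diag(n)
  }
  n_items <- nrow(fit$betas)
  cw <- if (is.null(contrast_weights)) rep(1 / n_items, n_items)
        else as.numeric(contrast_weights)
  if (length(cw) != n_items)
    stop("need one contrast weight per item regressor")
  eff <- drop(crossprod(cw, fit$betas))
  cvar <- drop(crossprod(cw, fit$xtx_inv %*% cw))
  se <- sqrt(fit$resid_var * cvar)
  t_stat <- eff / se
  zero_se <- se == 0
  if (any(zero_se & eff != 0)) {
    warning(sprintf(
      "%d voxel(s) with zero residual variance and nonzero contrast; z clamped",
      sum(zero_se & eff != 0)))
  }
  t_stat[zero_se] <- sign(eff[zero_se]) * Inf
  z <- t_to_z(t_stat, fit$dof)
  zcap <- stats::qnorm(1e-300, lower.tail = FALSE)
  n_clamped <- sum(!is.finite(z) | abs(z) > zcap)
  z <- pmin(pmax(z, -zcap), zcap)
  structure(list(z = z, voxels = fit$voxels, grid = fit$grid, name = name,
                 n_clamped = n_clamped),
            class = "contrast_zmap")
}

# t -> z by matching tail probabilities on the log scale (stable far out)
t_to_z <- function(t_stat, dof) {
  z <- numeric(length(t_stat))
  neg <- t_stat < 0 & is.finite(t_stat)
  pos <- t_stat >= 0 & is.finite(t_stat)
  z[neg] <- stats::qnorm(stats::pt(t_stat[neg], dof, log.p = TRUE),
                         log.p = TRUE)
  z[pos] <- -stats::qnorm(stats::pt(t_stat[pos], dof, lower.tail = FALSE,
                                    log.p = TRUE), log.p = TRUE)
  z[!is.finite(t_stat)] <- t_stat[!is.finite(t_stat)]
  z
}

#' Robust-range voxel selection: top fraction of positive contrast z
#'
#' Selects the voxels whose z value is at least the `k`-th largest positive z,
#' with `k = ceiling(top_fraction * n_positive)`; ties at the threshold are
#' all included. Returns an empty mask (with a warning) when no voxel has
#' positive z.
#'
#' @param zmap a [contrast_zmap].
#' @param top_fraction fraction of positive-z voxels to keep, in (0, 1);
#'   default 0.02 (the top 2 percent).
#' @return logical vector over `zmap$voxels`, with attribute `threshold`.
#' @export
robust_range_mask <- function(zmap, top_fraction = 0.02) {
  stopifnot(inherits(zmap, "contrast_zmap"))
  if (!(top_fraction > 0 && top_fraction < 1))
    stop("top_fraction must lie in (0, 1)")
  z <- zmap$z
  pos <- z[z > 0]
  if (length(pos) == 0L) {
    warning("no voxel with positive z; robust-range mask is empty")
    out <- rep(FALSE, length(z))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  k <- ceiling(top_fraction * length(pos))
  thr <- sort(pos, decreasing = TRUE)[k]
  out <- z >= thr
  attr(out, "threshold") <- thr
  out
}
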