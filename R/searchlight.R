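#' Spherical searchlight neighborhoods
#'
#' For every requested center voxel, collects the in-mask voxels whose
#' Euclidean distance (in voxel-index units; the acquisition uses isotropic
#' voxels) from the center is at most `radius_voxels`. Centers whose
#' neighborhood retains fewer than `min_voxels` members (near mask edges) are
#' dropped.
#'
#' The default radius of 3 voxels yields 123-voxel interior spheres, the
#' ~100-voxel searchlight volume conventional in this literature.
#'
#' @param grid a [vol_grid].
#' @param mask logical array of `grid$dims` (or linear indices) defining the
#'   brain; must select at least one voxel.
#' @param radius_voxels sphere radius in voxel units, `>= 1`.
#' @param min_voxels minimum retained neighborhood size (default 10).
#' @param centers optional linear indices at which to place searchlights;
#'   default: every in-mask voxel.
#' @return list with `centers` (linear indices) and `neighborhoods` (list of
#'   linear-index vectors, one per retained center; each contains its
#'   center).
#' @export
sphere_neighborhoods <- function(grid, mask, radius_voxels = 3,
                                 min_voxels = 10L, centers = NULL) {
  stopifnot(radius_voxels >= 1)
  mask_idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(mask_idx) == 0L) stop("mask is empty")
  if (is.null(centers)) centers <- mask_idx
  if (!all(centers %in% mask_idx)) stop("centers must lie inside the mask")

  in_mask <- logical(prod(grid$dims))
  in_mask[mask_idx] <- TRUE
  offs <- sphere_offsets(radius_voxels)
  d <- grid$dims
  cxyz <- voxel_coords(centers, grid)
  keep <- vector("list", length(centers))
  for (k in seq_along(centers)) {
    pts <- sweep(offs, 2L, cxyz[k, ], "+")
    ok <- pts[, 1L] >= 1L & pts[, 1L] <= d[1L] &
          pts[, 2L] >= 1L & pts[, 2L] <= d[2L] &
          pts[, 3L] >= 1L & pts[, 3L] <= d[3L]
    idx <- coords_to_index(pts[ok, , drop = FALSE], grid)
    keep[[k]] <- idx[in_mask[idx]]
  }
  sizes <- lengths(keep)
  retained <- sizes >= min_voxels
  list(centers = centers[retained], neighborhoods = keep[retained])
}

# integer offsets (dx, dy, dz) with Euclidean norm <= radius, center first
sphere_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, ]
  g <- g[order(g$dx^2 + g$dy^2 + g$dz^2), ]  # center row first
  as.matrix(g)
}

#' Per-center searchlight dissimilarity matrices
#'
#' Computes the condensed correlation-distance matrix of the item patterns
#' restricted to each searchlight neighborhood. Centers whose voxel submatrix
#' leaves any item with zero pattern variance are dropped (their count is
#' recorded in the `n_dropped` field).
#'
#' @param betas an [item_beta_maps] object.
#' @param neighborhoods result of [sphere_neighborhoods()] (fields `centers`,
#'   `neighborhoods`, linear voxel indices into `betas$grid`).
#' @return An object of class `searchlight_result`: list with `centers`,
#'   `neighborhoods`, `dms` (list of [dissim_matrix]), `n_dropped`,
#'   `item_ids`.
#' @export
searchlight_dms <- function(betas, neighborhoods) {
  stopifnot(inherits(betas, "item_beta_maps"))
  if (length(neighborhoods$centers) == 0L)
    stop("no searchlight centers to evaluate (all below min_voxels?)")
  vox_pos <- match(unlist(neighborhoods$neighborhoods), betas$voxels)
  if (anyNA(vox_pos))
    stop("neighborhoods reference voxels absent from the beta maps")
  centers <- neighborhoods$centers
  nbh <- neighborhoods$neighborhoods
  dms <- vector("list", length(centers))
  ok <- logical(length(centers))
  for (k in seq_along(centers)) {
    cols <- match(nbh[[k]], betas$voxels)
    sub <- betas$betas[, cols, drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0 | !is.finite(sds))) next
    dms[[k]] <- condensed_correlation_dm(sub)
    ok[k] <- TRUE
  }
  if (!any(ok))
    stop("all searchlight centers dropped (zero-variance item patterns)")
  structure(list(centers = centers[ok],
                 neighborhoods = nbh[ok],
                 dms = dms[ok],
                 n_dropped = sum(!ok),
                 item_ids = betas$item_ids),
            class = "searchlight_result")
}

#' @export
print.searchlight_result <- function(x, ...) {
  cat(sprintf("<searchlight_result: %d centers (%d dropped), %d items>\n",
              length(x$centers), x$n_dropped, length(x$item_ids)))
  invisible(x)
}

# stack the condensed DMs into an m x p matrix for clustering
dm_stack <- function(slr) {
  do.call(rbind, lapply(slr$dms, function(d) d$values))
}
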