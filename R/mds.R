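#' Multidimensional scaling embedding of a dissimilarity matrix
#'
#' Projects the items of a DM into `n_dims` coordinates. The default is
#' classical (Torgerson) scaling — double-centering of squared distances and
#' the top eigenvectors — which is exact for Euclidean-realizable DMs and
#' fully deterministic. The `"nonmetric"` variant polishes the classical
#' solution by Kruskal stress minimization (fixed iteration cap and
#' tolerance, so equally deterministic).
#'
#' @param dm a [dissim_matrix].
#' @param n_dims embedding dimension (default 2).
#' @param variant `"classical"` (default) or `"nonmetric"`.
#' @param maxit,tol iteration cap and convergence tolerance for the
#'   nonmetric variant.
#' @return item x `n_dims` coordinate matrix (row names = item ids). If the
#'   DM admits fewer than `n_dims` positive eigenvalues, missing columns are
#'   zero-padded with a warning.
#' @export
mds_embed <- function(dm, n_dims = 2L, variant = c("classical", "nonmetric"),
                      maxit = 50L, tol = 1e-6) {
  stopifnot(inherits(dm, "dissim_matrix"), n_dims >= 1L)
  variant <- match.arg(variant)
  m <- as.matrix(dm)
  fit <- stats::cmdscale(m, k = min(n_dims, dm$n_items - 1L), eig = TRUE)
  pts <- fit$points
  # cmdscale keeps numerically-tiny eigendirections; treat eigenvalues below
  # a relative floor as nonpositive so degenerate DMs pad with exact zeros
  eig <- fit$eig[seq_len(ncol(pts))]
  keep <- eig > max(fit$eig) * 1e-8
  pts <- pts[, keep, drop = FALSE]
  if (ncol(pts) < n_dims) {
    warning(sprintf(
      "only %d positive eigenvalue(s); padding %d zero coordinate(s)",
      ncol(pts), n_dims - ncol(pts)))
    pts <- cbind(pts, matrix(0, nrow(pts), n_dims - ncol(pts)))
  }
  if (variant == "nonmetric") {
    # all-equal distances (or degenerate inits) break isoMDS; the classical
    # solution is already the best symmetric answer there
    if (stats::sd(dm$values) > 0 && all(dm$values > 0)) {
      fitn <- MASS::isoMDS(m, y = pts, k = n_dims, maxit = maxit,
                           tol = tol, trace = FALSE)
      pts <- fitn$points
    }
  }
  rownames(pts) <- dm$item_ids
  colnames(pts) <- paste0("dim", seq_len(n_dims))
  pts
}
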