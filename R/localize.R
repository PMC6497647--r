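#' Group localization map of contributing voxels
#'
#' Projects the per-subject contributing-voxel sets behind a neural score
#' onto the shared grid and labels every voxel by which group(s) it served:
#' 0 = none, 1 = expert only, 2 = novice only, 3 = both. Per-group subject
#' counts are kept alongside, so the category layer is recomputable from the
#' counts.
#'
#' @param contributing named list of linear voxel-index vectors, one per
#'   subject.
#' @param groups character vector (`"expert"` / `"novice"`) aligned with
#'   `contributing` (or named by subject).
#' @param grid the common [vol_grid].
#' @return list of class `group_localization_map`: `category` (integer 3-D
#'   array), `count_expert`, `count_novice` (integer arrays), `grid`,
#'   `histogram` (table of total per-voxel subject counts > 0).
#' @export
group_localization <- function(contributing, groups, grid) {
  stopifnot(inherits(grid, "vol_grid"),
            length(contributing) == length(groups))
  if (!is.null(names(groups)) && !is.null(names(contributing)))
    groups <- groups[names(contributing)]
  if (!all(groups %in% c("expert", "novice")))
    stop("groups must be 'expert' or 'novice'")
  n_vox <- prod(grid$dims)
  bad <- vapply(contributing, function(v) any(v < 1L | v > n_vox), logical(1))
  if (any(bad)) stop("contributing voxels fall outside the common grid")
  ce <- integer(n_vox); cn <- integer(n_vox)
  for (i in seq_along(contributing)) {
    v <- unique(contributing[[i]])
    if (groups[i] == "expert") ce[v] <- ce[v] + 1L else cn[v] <- cn[v] + 1L
  }
  category <- integer(n_vox)
  category[ce > 0L & cn == 0L] <- 1L
  category[ce == 0L & cn > 0L] <- 2L
  category[ce > 0L & cn > 0L] <- 3L
  total <- ce + cn
  structure(list(category = array(category, grid$dims),
                 count_expert = array(ce, grid$dims),
                 count_novice = array(cn, grid$dims),
                 grid = grid,
                 histogram = table(total[total > 0L])),
            class = "group_localization_map")
}

#' @export
print.group_localization_map <- function(x, ...) {
  cat(sprintf(
    "<group_localization_map: %d expert-only, %d novice-only, %d shared voxels>\n",
    sum(x$category == 1L), sum(x$category == 2L), sum(x$category == 3L)))
  invisible(x)
}

#' Vertex count of a subdivided-icosahedron standard mesh
#'
#' A triangulated icosahedron with `ld` linear divisions per edge has
#' `10 * ld^2 + 2` vertices per hemisphere (V - E + F Euler arithmetic with
#' V = 12, E = 30, F = 20); the standard two-hemisphere cortical mesh at
#' `ld = 32` therefore has 20,484 nodes.
#'
#' @param linear_divisions subdivisions per icosahedron edge (`>= 1`).
#' @param n_hemispheres meshes counted (default 2).
#' @return integer vertex count.
#' @export
standard_mesh_vertex_count <- function(linear_divisions, n_hemispheres = 2L) {
  stopifnot(linear_divisions >= 1L, n_hemispheres >= 1L)
  ld <- as.integer(linear_divisions)
  as.integer(n_hemispheres) * (10L * ld * ld + 2L)
}
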