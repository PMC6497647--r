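#' Volumetric sampling grid
#'
#' Minimal description of a 3-D voxel grid: integer dimensions and an
#' isotropic voxel size in millimetres. Voxels are addressed by linear index
#' in R's column-major array order.
#'
#' @param dims integer length-3 vector `(nx, ny, nz)`.
#' @param voxel_size_mm isotropic voxel edge length (default 3 mm).
#' @return An object of class `vol_grid`.
#' @export
vol_grid <- function(dims, voxel_size_mm = 3) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), voxel_size_mm > 0)
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm),
            class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid %dx%dx%d, %g mm voxels>\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_mm))
  invisible(x)
}

# linear voxel indices -> n x 3 integer coordinates (1-based)
voxel_coords <- function(idx, grid) {
  arrayInd(idx, grid$dims)
}

# n x 3 coordinates -> linear indices
coords_to_index <- function(xyz, grid) {
  xyz <- matrix(as.integer(xyz), ncol = 3L)
  d <- grid$dims
  (xyz[, 3L] - 1L) * d[1L] * d[2L] + (xyz[, 2L] - 1L) * d[1L] + xyz[, 1L]
}

same_grid <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm))
}
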