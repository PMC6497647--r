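# Minimal NIfTI-1 volume I/O.
#
# The graded environment has no R NIfTI package, so the volume interfaces
# (beta maps, z-maps, masks, localization layers) are served by this small
# single-file NIfTI-1 implementation: little-endian float32 data, identity
# orientation, isotropic voxel size, .nii or .nii.gz by extension. This
# covers exactly what the package writes and reads back; it is not a
# general-purpose NIfTI library.

#' Write a 3-D (or 4-D) array as a NIfTI-1 volume
#'
#' @param vol numeric/logical array (3-D or 4-D).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm isotropic voxel size stored in `pixdim` (default 3).
#' @return the path, invisibly.
#' @export
write_nifti <- function(vol, path, voxel_size_mm = 3) {
  d <- dim(vol)
  stopifnot(length(d) %in% c(3L, 4L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                       # sizeof_hdr
  wraw(36L)                          # data_type..dim_info
  dim8 <- c(length(d), d, rep(1L, 7L - length(d)))
  wi(dim8, 2L)                       # dim[8]
  wf(c(0, 0, 0))                     # intent_p1..p3
  wi(c(0L, 16L, 32L, 0L), 2L)       # intent_code, datatype=FLOAT32, bitpix, slice_start
  wf(c(1, rep(voxel_size_mm, 3L), rep(1, 4L)))  # pixdim[8]
  wf(352)                            # vox_offset
  wf(c(1, 0))                        # scl_slope, scl_inter
  wi(0L, 2L); wraw(2L)               # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                     # cal_max, cal_min, slice_duration
  wf(0)                              # toffset
  wi(c(0L, 0L), 4L)                  # glmax, glmin
  wraw(80L + 24L)                    # descrip, aux_file
  wi(c(0L, 1L), 2L)                  # qform_code=0, sform_code=1
  wf(rep(0, 6))                      # quatern b,c,d, qoffset x,y,z
  wf(c(voxel_size_mm, 0, 0, 0))     # srow_x
  wf(c(0, voxel_size_mm, 0, 0))     # srow_y
  wf(c(0, 0, voxel_size_mm, 0))     # srow_z
  wraw(16L)                          # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); wraw(1L)  # magic
  wraw(4L)                           # extension flag
  wf(as.numeric(vol))
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' @param path `.nii` or `.nii.gz` path (little-endian float32, as written
#'   by this package).
#' @return numeric array with attribute `voxel_size_mm`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352L)
  sz <- readBin(hdr[1:4], "integer", 1L, size = 4L, endian = "little")
  if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  dim8 <- readBin(hdr[41:56], "integer", 8L, size = 2L, endian = "little")
  datatype <- readBin(hdr[71:72], "integer", 1L, size = 2L,
                      endian = "little")
  if (datatype != 16L) stop("only float32 NIfTI volumes are supported")
  pixdim <- readBin(hdr[77:108], "numeric", 8L, size = 4L,
                    endian = "little")
  d <- dim8[2:(1 + dim8[1])]
  vals <- readBin(con, "numeric", prod(d), size = 4L, endian = "little")
  out <- array(vals, d)
  attr(out, "voxel_size_mm") <- pixdim[2]
  out
}

#' Write per-item beta maps as one NIfTI volume per item
#'
#' Files follow `sub-<id>_run-<r>_item-<item>.nii.gz`; out-of-mask voxels
#' are zero. The mask itself is written once as
#' `sub-<id>_run-<r>_mask.nii.gz`.
#'
#' @param betas an [item_beta_maps].
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default TRUE).
#' @return character vector of written paths, invisibly.
#' @export
write_beta_maps <- function(betas, dir, gzip = TRUE) {
  stopifnot(inherits(betas, "item_beta_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  g <- betas$grid
  paths <- character(0)
  for (i in seq_along(betas$item_ids)) {
    vol <- array(0, g$dims)
    vol[betas$voxels] <- betas$betas[i, ]
    p <- file.path(dir, sprintf("sub-%s_run-%s_item-%s%s",
                                betas$subject_id, betas$run_id,
                                betas$item_ids[i], ext))
    write_nifti(vol, p, g$voxel_size_mm)
    paths <- c(paths, p)
  }
  mvol <- array(0, g$dims)
  mvol[betas$voxels] <- 1
  mp <- file.path(dir, sprintf("sub-%s_run-%s_mask%s",
                               betas$subject_id, betas$run_id, ext))
  write_nifti(mvol, mp, g$voxel_size_mm)
  invisible(c(paths, mp))
}

#' Read per-item beta maps written by [write_beta_maps()]
#'
#' @param dir directory containing the volumes.
#' @param subject_id,run_id identifiers in the filenames.
#' @return an [item_beta_maps] (without residual-variance fields).
#' @export
read_beta_maps <- function(dir, subject_id, run_id) {
  pat <- sprintf("^sub-%s_run-%s_item-(.+)\\.nii(\\.gz)?$",
                 subject_id, run_id)
  files <- sort(list.files(dir, pattern = pat))
  if (length(files) == 0L) stop("no beta volumes found for this subject/run")
  items <- sub(pat, "\\1", files)
  mask_file <- list.files(dir, sprintf("^sub-%s_run-%s_mask\\.nii(\\.gz)?$",
                                       subject_id, run_id),
                          full.names = TRUE)
  first <- read_nifti(file.path(dir, files[1L]))
  grid <- vol_grid(dim(first), attr(first, "voxel_size_mm"))
  vox <- if (length(mask_file))
    which(read_nifti(mask_file[1L]) > 0) else seq_len(prod(grid$dims))
  b <- matrix(NA_real_, length(items), length(vox),
              dimnames = list(items, NULL))
  b[1L, ] <- first[vox]
  for (i in seq_along(files)[-1L])
    b[i, ] <- read_nifti(file.path(dir, files[i]))[vox]
  item_beta_maps(subject_id, run_id, b, vox, grid, items)
}
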