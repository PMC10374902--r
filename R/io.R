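#' Construct a 4D BOLD volume container
#'
#' @param data 4D numeric array (X, Y, Z, T); a 3D array is promoted to a
#'   single-volume 4D array with a warning.
#' @param affine invertible 4x4 voxel-to-world transform.
#' @param tr_seconds repetition time in seconds.
#' @return an object of class `bold_volume`.
#' @export
bold_volume <- function(data, affine = diag(4), tr_seconds = 1) {
  if (length(dim(data)) == 3) {
    warnf("3D volume promoted to 4D with T = 1")
    dim(data) <- c(dim(data), 1L)
  }
  if (length(dim(data)) != 4) stopf("data must be a 3D or 4D array")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < .Machine$double.eps) stopf("affine is singular")
  if (tr_seconds <= 0) stopf("tr_seconds must be positive")
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "bold_volume")
}

#' @export
print.bold_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_volume: %dx%dx%d voxels, %d volumes, TR = %gs\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' Read a NIfTI file as a BOLD volume
#'
#' @param path NIfTI-1/2 file (.nii or .nii.gz).
#' @return a [bold_volume()]; 3D files are promoted to T = 1 with a warning.
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  pd <- RNifti::pixdim(im)
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  bold_volume(array(as.numeric(im), dim(im)), affine = aff, tr_seconds = tr)
}

#' Write a BOLD volume as NIfTI
#'
#' Round-trips data at float32 precision and the affine exactly.
#'
#' @param vol a [bold_volume()].
#' @param path output path (.nii or .nii.gz).
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "bold_volume"))
  im <- RNifti::asNifti(vol$data)
  sp <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  RNifti::pixdim(im) <- c(sp, vol$tr_seconds)
  im <- RNifti::`sform<-`(im, structure(vol$affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a 3D mask aligned to a volume
#'
#' @param path NIfTI file holding a 3D binary mask.
#' @param reference optional [bold_volume()] the mask must align with; the
#'   grids must match and the affines agree to 1e-4.
#' @return logical 3D array.
#' @export
read_mask <- function(path, reference = NULL) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) == 4 && d[4] == 1) { im <- im[, , , 1]; d <- dim(im) }
  if (length(d) != 3) stopf("mask file must be 3D, got %s dims", length(d))
  if (!is.null(reference)) {
    rd <- dim(reference$data)[1:3]
    if (!all(d == rd))
      stopf("mask grid %s does not match data grid %s",
            paste(d, collapse = "x"), paste(rd, collapse = "x"))
    aff <- unclass(RNifti::xform(im)); attributes(aff) <- list(dim = c(4L, 4L))
    if (max(abs(aff - reference$affine)) > 1e-4)
      stopf("mask affine differs from data affine by more than 1e-4")
  }
  array(as.numeric(im) != 0, d)
}

# write a logical 3D mask with a given affine
write_mask <- function(mask, affine, path) {
  im <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(im) <- sp
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Extract in-mask time series in canonical voxel order
#'
#' Voxels are ordered by ascending flattened index with x fastest (R's
#' column-major layout), so the ordering is a property of the grid, not of
#' the file: equal masks always yield identical matrices.
#'
#' @param vol a [bold_volume()].
#' @param mask 3D logical/binary array on the same grid.
#' @return list with `series` (T x V matrix) and `voxels`, a data.frame with
#'   0-based voxel indices i, j, k and world-mm coordinates per row.
#' @export
extract_roi_series <- function(vol, mask) {
  stopifnot(inherits(vol, "bold_volume"))
  dims <- dim(vol$data)
  if (!all(dim(mask) == dims[1:3]))
    stopf("mask grid %s does not match data grid %s",
          paste(dim(mask), collapse = "x"), paste(dims[1:3], collapse = "x"))
  idx <- which(mask != 0)
  if (length(idx) == 0) stopf("mask is empty")
  flat <- matrix(vol$data, prod(dims[1:3]), dims[4])
  series <- t(flat[idx, , drop = FALSE])
  ijk1 <- arrayInd(idx, dims[1:3])
  world <- t(vol$affine %*% rbind(t(ijk1 - 1), 1))[, 1:3, drop = FALSE]
  voxels <- data.frame(row = seq_along(idx),
                       i = ijk1[, 1] - 1L, j = ijk1[, 2] - 1L, k = ijk1[, 3] - 1L,
                       x_mm = world[, 1], y_mm = world[, 2], z_mm = world[, 3])
  list(series = series, voxels = voxels)
}

#' Put per-voxel values back into a 3D map
#'
#' Inverse of the spatial part of [extract_roi_series()]: values are placed
#' at the mask's canonical voxel order, elsewhere `NA`.
#'
#' @param values numeric vector, one value per in-mask voxel.
#' @param mask 3D logical array.
#' @return 3D numeric array.
#' @export
embed_in_mask <- function(values, mask) {
  idx <- which(mask != 0)
  if (length(values) != length(idx))
    stopf("%d values for %d in-mask voxels", length(values), length(idx))
  out <- array(NA_real_, dim(mask))
  out[idx] <- values
  out
}
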