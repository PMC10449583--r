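#' 3D image volume
#'
#' A minimal container for a 3D scalar grid together with its voxel size and
#' a grid-to-world affine. Voxel indices are 1-based in R; the affine maps
#' 0-based voxel indices to world millimetres (the NIfTI convention), so
#' `world = affine %*% c(i - 1, j - 1, k - 1, 1)`.
#'
#' @param data numeric 3D array.
#' @param voxel_size positive length-3 numeric vector, in mm.
#' @param affine 4x4 grid-to-world matrix; defaults to a scaling by
#'   `voxel_size` centred at the origin.
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive numbers", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat("<dwi_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.dwi_volume <- function(x) dim(x$data)

#' Read / write a volume as NIfTI-1
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] keeping
#' the `dwi_volume` voxel size and affine in the sform.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `dwi_volume` (or a plain 4D array with
#'   attributes for 4D files); `write_volume` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  vox <- RNifti::pixdim(img)[seq_len(min(3L, length(dm)))]
  aff <- structure(RNifti::xform(img), code = NULL)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dm) == 3L) return(dwi_volume(arr, voxel_size = vox, affine = aff))
  structure(arr, voxel_size = vox, affine = aff)
}

#' @rdname read_volume
#' @param vol a `dwi_volume`, or a 3D/4D numeric array.
#' @param voxel_size,affine used when `vol` is a bare array.
#' @export
write_volume <- function(vol, path, voxel_size = c(1, 1, 1), affine = NULL) {
  if (inherits(vol, "dwi_volume")) {
    arr <- vol$data; voxel_size <- vol$voxel_size; affine <- vol$affine
  } else {
    arr <- as.array(vol)
    if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  }
  storage.mode(arr) <- "double"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

affines_match <- function(a, b, tol = 1e-4) {
  all(abs(as.matrix(a) - as.matrix(b)) <= tol)
}
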