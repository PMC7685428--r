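#' Construct a 3D volume on a voxel lattice
#'
#' A `volume_grid` couples a 3D numeric array with a 4x4 voxel-to-world
#' affine (mm). Voxel indices are 0-based in the affine convention (the
#' world position of array element `[i, j, k]` is
#' `affine %*% c(i - 1, j - 1, k - 1, 1)`), matching the NIfTI standard.
#'
#' @param values 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix; defaults to isotropic
#'   `voxel_size_mm` with the world origin at the lattice center.
#' @param voxel_size_mm voxel edge length(s) in mm used when `affine` is
#'   not supplied (length 1 or 3).
#' @return a `volume_grid`.
#' @export
volume_grid <- function(values, affine = NULL, voxel_size_mm = 1) {
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (!all(is.finite(values))) stop("volume values must be finite")
  if (is.null(affine)) affine <- centered_affine(dim(values), voxel_size_mm)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine must be invertible")
  structure(list(values = values, affine = affine), class = "volume_grid")
}

#' Default centered affine for a lattice
#'
#' @param dim lattice dimensions (length 3).
#' @param voxel_size_mm voxel sizes, length 1 or 3.
#' @return 4x4 affine placing the world origin at the lattice center.
#' @export
centered_affine <- function(dim, voxel_size_mm = 1) {
  vs <- rep_len(as.numeric(voxel_size_mm), 3)
  if (any(vs <= 0)) stop("voxel_size_mm must be positive")
  a <- diag(4)
  diag(a)[1:3] <- vs
  a[1:3, 4] <- -vs * (dim - 1) / 2
  a
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid %s, voxel %s mm, values in [%.3g, %.3g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(voxel_sizes(x$affine), 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Voxel edge lengths implied by an affine
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @return length-3 vector of column norms (mm per voxel step).
#' @export
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Map voxel lattice indices to world mm
#'
#' @param ijk matrix (n x 3) of 1-based lattice indices.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk - 1, 1)   # affine convention is 0-based
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

stopifnot_same_grid <- function(volumes) {
  d0 <- dim(volumes[[1]]$values)
  a0 <- volumes[[1]]$affine
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!identical(dim(v$values), d0))
      stop("volume ", names(volumes)[i] %||% i, " has shape ",
           paste(dim(v$values), collapse = "x"), ", expected ",
           paste(d0, collapse = "x"))
    if (max(abs(v$affine - a0)) > 1e-6)
      stop("volume ", names(volumes)[i] %||% i, " has a mismatched affine")
  }
  invisible(TRUE)
}

#' Write a volume to NIfTI
#'
#' @param v a `volume_grid` (or plain 3D array plus `affine`).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype, e.g. "float" or "uint8".
#' @return the path, invisibly.
#' @export
write_volume <- function(v, path, datatype = "float") {
  img <- RNifti::asNifti(v$values, datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file.
#' @return a `volume_grid` with the image's xform as affine.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(unclass(RNifti::xform(img))[1:4, 1:4]), 4, 4)
  volume_grid(as.array(img), affine = aff)
}
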