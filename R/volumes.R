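#' Image volume: a 3D scalar array with a voxel-to-world affine
#'
#' The basic carrier for lesion masks, disconnection probability maps and
#' statistic maps. Voxel indices are 0-based throughout the package; the
#' affine maps 0-based voxel indices to world coordinates in millimetres.
#'
#' @param data 3D numeric array (at least one voxel per axis).
#' @param affine 4x4 numeric matrix, invertible, mapping (i, j, k, 1) voxel
#'   indices to homogeneous world-mm coordinates.
#' @return An object of class \code{image_volume} with fields \code{data}
#'   and \code{affine}.
#' @export
image_volume <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1)) stop("each axis must have at least one voxel")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("`affine` must be 4x4")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps)
    stop("affine is not invertible")
  structure(list(data = data, affine = affine), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel volume ", format(voxel_volume(x)), " mm^3\n", sep = "")
  invisible(x)
}

#' Voxel volume in cubic millimetres
#'
#' @param vol an \code{image_volume}.
#' @return \code{|det(affine[1:3, 1:3])|} in mm^3.
#' @export
voxel_volume <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' Binary lesion mask for one subject
#'
#' @param volume an \code{image_volume} whose data are strictly 0/1.
#' @param subject_id identifier for the subject.
#' @return An object of class \code{lesion_mask}.
#' @export
lesion_mask <- function(volume, subject_id = "subject") {
  stopifnot(inherits(volume, "image_volume"))
  v <- volume$data
  if (!all(v %in% c(0, 1))) stop("lesion mask must be strictly binary (0/1)")
  if (sum(v) == 0) warning("lesion mask for ", subject_id, " is empty")
  structure(list(volume = volume, subject_id = subject_id),
            class = "lesion_mask")
}

#' Read a single 3D NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @return An \code{image_volume}; integer-coded data are preserved exactly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) > 3) {
    if (prod(dm[-(1:3)]) > 1)
      stop("4D input not supported; supply a single 3D volume: ", path)
    dm <- dm[1:3]
  }
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  image_volume(array(as.vector(img), dim = dm), affine)
}

#' Write an image volume as NIfTI
#'
#' Masks and other small-integer volumes are stored as unsigned 8-bit,
#' everything else as 32-bit float.
#'
#' @param vol an \code{image_volume}.
#' @param path output path (.nii or .nii.gz); parent directory must exist.
#' @param datatype "auto", "uint8" or "float".
#' @return Invisibly, \code{path}.
#' @export
write_volume <- function(vol, path, datatype = c("auto", "uint8", "float")) {
  stopifnot(inherits(vol, "image_volume"))
  datatype <- match.arg(datatype)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (datatype == "auto") {
    v <- vol$data
    datatype <- if (all(v == as.integer(v)) && all(v >= 0) && all(v <= 255))
      "uint8" else "float"
  }
  im <- RNifti::asNifti(vol$data)
  # pixdim must carry the scale or RNifti's xform drops it on write
  RNifti::pixdim(im) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  im <- RNifti::`sform<-`(im, structure(vol$affine, code = 2L))
  im <- RNifti::`qform<-`(im, structure(vol$affine, code = 2L))
  RNifti::writeNifti(im, path, datatype = datatype)
  if (!file.exists(path)) stop("failed to write ", path)
  invisible(path)
}

#' Map world-mm points to 0-based voxel indices
#'
#' Applies the inverse affine and rounds half away from zero, so the mapping
#' is reproducible bit-exactly across platforms. Indices may fall outside the
#' grid; callers check bounds.
#'
#' @param points numeric 3-vector or n x 3 matrix of world-mm coordinates.
#' @param vol an \code{image_volume} (or a bare 4x4 affine).
#' @return Integer matrix n x 3 (or 3-vector) of 0-based indices.
#' @export
world_to_voxel <- function(points, vol) {
  affine <- if (inherits(vol, "image_volume")) vol$affine else as.matrix(vol)
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  ijk <- t(solve(affine) %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
  out <- matrix(as.integer(round_half_away(ijk)), ncol = 3)
  if (vec) out[1, ] else out
}

#' Map 0-based voxel indices to world-mm coordinates
#'
#' @param ijk integer 3-vector or n x 3 matrix of 0-based voxel indices.
#' @param vol an \code{image_volume} (or a bare 4x4 affine).
#' @return Numeric n x 3 matrix (or 3-vector) of world-mm coordinates.
#' @export
voxel_to_world <- function(ijk, vol) {
  affine <- if (inherits(vol, "image_volume")) vol$affine else as.matrix(vol)
  vec <- is.null(dim(ijk))
  p <- if (vec) matrix(ijk, 1, 3) else as.matrix(ijk)
  out <- t(affine %*% rbind(t(p), 1))[, 1:3, drop = FALSE]
  if (vec) out[1, ] else out
}

# all volumes of one analysis must share shape and affine (within tol)
check_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid shape mismatch: ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  if (max(abs(a$affine - b$affine)) > tol)
    stop("grid affine mismatch beyond tolerance ", tol)
  invisible(TRUE)
}

#' Resample a lesion mask through an affine transform onto a target grid
#'
#' Pull-back nearest-neighbour resampling: each target voxel centre is mapped
#' through the inverse of \code{transform} into the source volume's world
#' space and takes the value of the nearest source voxel. The output is
#' strictly binary; masks are never interpolated.
#'
#' @param mask a \code{lesion_mask}.
#' @param transform 4x4 world-to-world affine (source world -> target world).
#' @param target an \code{image_volume} defining the output grid.
#' @return A \code{lesion_mask} on the target grid (with a warning if empty).
#' @export
apply_affine_to_mask <- function(mask, transform, target) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(target, "image_volume"))
  transform <- as.matrix(transform)
  if (abs(det(transform)) < .Machine$double.eps)
    stop("transform is not invertible")
  src <- mask$volume
  dmt <- dim(target$data)
  # target voxel index -> source voxel index (continuous), one 4x4 composite
  M <- solve(src$affine) %*% solve(transform) %*% target$affine
  idx_t <- as.matrix(expand.grid(i = 0:(dmt[1] - 1), j = 0:(dmt[2] - 1),
                                 k = 0:(dmt[3] - 1)))
  ijk_s <- t(M %*% rbind(t(idx_t), 1))[, 1:3, drop = FALSE]
  ijk_s <- round_half_away(ijk_s)
  dms <- dim(src$data)
  ok <- ijk_s[, 1] >= 0 & ijk_s[, 1] < dms[1] &
        ijk_s[, 2] >= 0 & ijk_s[, 2] < dms[2] &
        ijk_s[, 3] >= 0 & ijk_s[, 3] < dms[3]
  out <- numeric(prod(dmt))
  lin_s <- 1 + ijk_s[ok, 1] + dms[1] * (ijk_s[ok, 2] + dms[2] * ijk_s[ok, 3])
  out[ok] <- as.numeric(src$data[lin_s] != 0)
  vol <- image_volume(array(out, dim = dmt), target$affine)
  lesion_mask(vol, mask$subject_id)
}

#' Summarise a lesion mask
#'
#' @param mask a \code{lesion_mask}.
#' @return List with \code{n_voxels}, \code{volume_mm3} (voxel count times
#'   voxel volume) and \code{n_components} (26-connectivity, matching the
#'   cluster-extraction convention).
#' @export
lesion_summary <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  v <- mask$volume$data
  n_vox <- sum(v != 0)
  if (n_vox == 0)
    return(list(n_voxels = 0L, volume_mm3 = 0, n_components = 0L))
  lab <- label_components(v != 0, connectivity = 26)
  list(n_voxels = as.integer(n_vox),
       volume_mm3 = n_vox * voxel_volume(mask$volume),
       n_components = as.integer(max(lab)))
}
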