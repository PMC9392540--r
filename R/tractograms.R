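#' Tractogram: a set of streamlines in world-mm coordinates
#'
#' Streamlines are n x 3 numeric matrices of ordered points in world
#' millimetres; format-specific coordinate conventions (TRK voxel-mm) are
#' normalised at read time so downstream code never sees them.
#'
#' @param streamlines list of n_i x 3 numeric matrices, each with >= 2 finite
#'   points.
#' @param control_id identifier of the normative control.
#' @param space template-space label; all tractograms of one analysis must
#'   share it with the analysis grid.
#' @return An object of class \code{tractogram}.
#' @export
tractogram <- function(streamlines, control_id = "control", space = "MNI152") {
  if (!is.list(streamlines) || length(streamlines) < 1)
    stop("a tractogram needs at least one streamline")
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3 || nrow(s) < 2) stop("each streamline needs >= 2 3D points")
    if (!all(is.finite(s))) stop("streamline contains non-finite coordinates")
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines, control_id = control_id,
                 space = space), class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat("<tractogram> ", length(x$streamlines), " streamlines, control ",
      x$control_id, ", space ", x$space, "\n", sep = "")
  invisible(x)
}

#' Default resampling step for a grid
#'
#' Half the smallest voxel edge: dense enough that a resampled streamline
#' cannot step over a voxel it crosses.
#'
#' @param grid an \code{image_volume}.
#' @return Step size in mm.
#' @export
default_step <- function(grid) {
  0.5 * min(sqrt(colSums(grid$affine[1:3, 1:3]^2)))
}

#' Resample a streamline at a maximum step length
#'
#' Every original vertex is kept and each segment is subdivided into equal
#' parts no longer than \code{step}, so the operation is idempotent and the
#' output points all lie on the original polyline.
#'
#' @param points n x 3 matrix of world-mm points.
#' @param step maximum spacing in mm (> 0).
#' @return m x 3 matrix, consecutive points at most \code{step} apart.
#' @export
resample_streamline <- function(points, step) {
  stopifnot(is.finite(step), step > 0)
  p <- as.matrix(points)
  if (!all(is.finite(p))) stop("streamline contains non-finite coordinates")
  n <- nrow(p)
  if (n < 2) return(p)
  a <- p[-n, , drop = FALSE]
  b <- p[-1, , drop = FALSE]
  seglen <- sqrt(rowSums((b - a)^2))
  # small epsilon so a segment of exactly `step` is not split by fp noise
  nseg <- pmax(1L, as.integer(ceiling(seglen / step - 1e-9)))
  segidx <- rep(seq_len(n - 1L), nseg)
  tt <- sequence(nseg) / rep(nseg, nseg)
  out <- a[segidx, , drop = FALSE] +
    (b - a)[segidx, , drop = FALSE] * tt
  rbind(p[1, , drop = FALSE], out)
}

# per-streamline unique in-grid voxel linear indices (1-based) after
# dense resampling; the shared primitive behind selection and visitation
streamline_voxels <- function(points, grid, step) {
  rp <- resample_streamline(points, step)
  ijk <- world_to_voxel(rp, grid)
  dm <- dim(grid$data)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < dm[1] &
        ijk[, 2] >= 0 & ijk[, 2] < dm[2] &
        ijk[, 3] >= 0 & ijk[, 3] < dm[3]
  unique(1 + ijk[ok, 1] + dm[1] * (ijk[ok, 2] + dm[2] * ijk[ok, 3]))
}

#' Select the streamlines that pass through a lesion mask
#'
#' A streamline is selected iff, after dense resampling at \code{step}, at
#' least one of its points falls in a nonzero mask voxel. With the default
#' step (half the voxel edge) the test is exact for the phantom geometry.
#'
#' @param t a \code{tractogram}.
#' @param mask a \code{lesion_mask} on the analysis grid.
#' @param step resampling step in mm; default half the smallest voxel edge.
#' @return A \code{tractogram} containing the selected subset (possibly with
#'   zero streamlines, returned as a bare list-of-streamlines tractogram
#'   structure).
#' @export
streamlines_through_mask <- function(t, mask, step = NULL) {
  stopifnot(inherits(t, "tractogram"), inherits(mask, "lesion_mask"))
  grid <- mask$volume
  step <- step %||% default_step(grid)
  inmask <- as.vector(grid$data != 0)
  sel <- vapply(t$streamlines, function(s) {
    any(inmask[streamline_voxels(s, grid, step)])
  }, logical(1))
  out <- t
  out$streamlines <- t$streamlines[sel]
  attr(out, "selected") <- sel
  out
}

#' Binary visitation map of a set of streamlines
#'
#' A voxel is 1 iff any densely resampled point of any streamline maps to it.
#'
#' @param streamlines a \code{tractogram} or bare list of streamline matrices
#'   (may be empty).
#' @param grid an \code{image_volume} defining the output grid.
#' @param step resampling step in mm; default half the smallest voxel edge.
#' @return List of class \code{visitation_map}: \code{volume} (binary
#'   \code{image_volume}) and \code{control_id}.
#' @export
visitation_map <- function(streamlines, grid, step = NULL) {
  control_id <- "control"
  if (inherits(streamlines, "tractogram")) {
    control_id <- streamlines$control_id
    streamlines <- streamlines$streamlines
  }
  step <- step %||% default_step(grid)
  out <- numeric(prod(dim(grid$data)))
  if (length(streamlines)) {
    vox <- unlist(lapply(streamlines, streamline_voxels,
                         grid = grid, step = step))
    out[unique(vox)] <- 1
  }
  structure(list(volume = image_volume(array(out, dim(grid$data)),
                                       grid$affine),
                 control_id = control_id),
            class = "visitation_map")
}

## ---- TCK (MRtrix tracks) ----------------------------------------------

#' Write a tractogram as a TCK (MRtrix tracks) file
#'
#' Points are written in world mm (scanner space), Float32 little-endian,
#' streamlines separated by NaN triplets, file terminated by an Inf triplet.
#'
#' @param t a \code{tractogram}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_tck <- function(t, path) {
  stopifnot(inherits(t, "tractogram"))
  fixed <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                  length(t$streamlines), "\n")
  # the offset in "file: . N" counts its own bytes; iterate to a fixed point
  off <- nchar(fixed, type = "bytes") + nchar("file: . \nEND\n") + 1
  repeat {
    hdr <- paste0(fixed, "file: . ", off, "\nEND\n")
    if (nchar(hdr, type = "bytes") == off) break
    off <- nchar(hdr, type = "bytes")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

read_tck <- function(path, control_id, space) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 14 ||
      rawToChar(raw[1:13]) != "mrtrix tracks")
    stop("not a TCK file (bad magic): ", path)
  # header is newline-separated "key: value" lines up to END
  end_pat <- charToRaw("\nEND\n")
  end_at <- NA
  for (i in seq_len(length(raw) - 4)) {
    if (all(raw[i:(i + 4)] == end_pat)) { end_at <- i; break }
  }
  if (is.na(end_at)) stop("truncated TCK header: ", path)
  hdr <- strsplit(rawToChar(raw[1:(end_at - 1)]), "\n")[[1]]
  kv <- regmatches(hdr, regexec("^([^:]+): *(.*)$", hdr))
  keys <- vapply(kv, function(x) if (length(x)) x[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(x) if (length(x)) x[3] else NA_character_,
                 character(1))
  dt <- vals[match("datatype", keys)]
  if (is.na(dt) || dt != "Float32LE")
    stop("unsupported TCK datatype: ", dt)
  off_field <- vals[match("file", keys)]
  off <- as.integer(sub("^\\. *", "", off_field))
  if (is.na(off) || off > length(raw)) stop("bad TCK file offset: ", path)
  vals <- readBin(raw[(off + 1):length(raw)], "numeric",
                  n = (length(raw) - off) %/% 4, size = 4, endian = "little")
  if (length(vals) %% 3 != 0) stop("truncated TCK point data: ", path)
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  inf_rows <- which(is.infinite(pts[, 1]))
  if (length(inf_rows)) pts <- pts[seq_len(inf_rows[1] - 1), , drop = FALSE]
  breaks <- is.nan(pts[, 1])
  grp <- cumsum(c(TRUE, breaks[-length(breaks)]))
  keep <- !breaks
  sls <- split.data.frame(pts[keep, , drop = FALSE], grp[keep])
  sls <- lapply(unname(sls), as.matrix)
  sls <- sls[vapply(sls, nrow, integer(1)) > 0]
  tractogram(sls, control_id = control_id, space = space)
}

## ---- TRK (TrackVis) ---------------------------------------------------

#' Write a tractogram as a TRK (TrackVis) file
#'
#' TRK stores points in corner-origin voxel-mm coordinates of a reference
#' grid; world-mm points are converted using the grid affine, which is also
#' embedded in the header (vox_to_ras, version 2).
#'
#' @param t a \code{tractogram}.
#' @param path output path.
#' @param grid \code{image_volume} supplying the reference affine and shape.
#' @return Invisibly, \code{path}.
#' @export
write_trk <- function(t, path, grid) {
  stopifnot(inherits(t, "tractogram"), inherits(grid, "image_volume"))
  vs <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  inv <- solve(grid$affine)
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, width) {
    r <- raw(width)
    b <- charToRaw(s)
    r[seq_along(b)] <- b
    writeBin(r, con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(dim(grid$data)), con, size = 2, endian = "little")
  writeBin(as.numeric(vs), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")      # origin
  writeBin(0L, con, size = 2, endian = "little")              # n_scalars
  writeBin(raw(200), con)                                     # scalar names
  writeBin(0L, con, size = 2, endian = "little")              # n_properties
  writeBin(raw(200), con)                                     # property names
  writeBin(as.numeric(t(grid$affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)                                     # reserved
  wchar("RAS", 4)                                             # voxel_order
  writeBin(raw(4), con)                                       # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4, endian = "little")
  writeBin(raw(2), con)                                       # pad1
  writeBin(raw(6), con)                                       # invert/swap
  writeBin(length(t$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")              # version
  writeBin(1000L, con, size = 4, endian = "little")           # hdr_size
  for (s in t$streamlines) {
    vox <- t(inv %*% rbind(t(s), 1))[, 1:3, drop = FALSE]
    voxmm <- sweep(vox + 0.5, 2, vs, `*`)
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_trk <- function(path, control_id, space) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 1000) stop("truncated TRK file: ", path)
  if (rawToChar(raw[1:5]) != "TRACK") stop("not a TRK file (bad magic): ", path)
  rd <- function(from, what, n, size) {
    readBin(raw[(from + 1):(from + n * size)], what, n = n, size = size,
            endian = "little")
  }
  voxel_size <- rd(12, "numeric", 3, 4)
  n_scalars <- rd(36, "integer", 1, 2)
  n_properties <- rd(238, "integer", 1, 2)
  vox_to_ras <- matrix(rd(440, "numeric", 16, 4), 4, 4, byrow = TRUE)
  version <- rd(992, "integer", 1, 4)
  hdr_size <- rd(996, "integer", 1, 4)
  if (hdr_size != 1000) stop("bad TRK header size: ", hdr_size)
  if (version < 2 || abs(det(vox_to_ras)) < 1e-12)
    stop("TRK file lacks a usable vox_to_ras affine (version ", version, ")")
  if (any(voxel_size <= 0)) stop("bad TRK voxel size")
  # voxmm -> world: divide by voxel size, shift corner->centre, apply affine
  pos <- 1000
  sls <- list()
  while (pos + 4 <= length(raw)) {
    npts <- rd(pos, "integer", 1, 4)
    pos <- pos + 4
    need <- npts * (3 + n_scalars) * 4
    if (npts <= 0 || pos + need > length(raw))
      stop("truncated TRK streamline data: ", path)
    vals <- rd(pos, "numeric", npts * (3 + n_scalars), 4)
    pos <- pos + need + n_properties * 4
    m <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2, voxel_size, `/`) - 0.5
    sls[[length(sls) + 1]] <- t(vox_to_ras %*% rbind(t(vox), 1))[, 1:3,
                                                                 drop = FALSE]
  }
  tractogram(sls, control_id = control_id, space = space)
}

#' Read a tractogram (TRK or TCK)
#'
#' The format is detected from the magic bytes; all points are returned in
#' world mm regardless of the on-disk convention.
#'
#' @param path path to a .trk or .tck file.
#' @param control_id identifier to attach (default: file stem).
#' @param space template-space label to attach.
#' @return A \code{tractogram}.
#' @export
read_tractogram <- function(path, control_id = NULL, space = "MNI152") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 6) stop("empty or unreadable tractogram file: ", path)
  control_id <- control_id %||% sub("\\.(trk|tck)$", "", basename(path))
  magic <- rawToChar(readBin(path, "raw", 6)[1:5])
  if (magic == "TRACK") read_trk(path, control_id, space)
  else if (substr(magic, 1, 5) == "mrtri") read_tck(path, control_id, space)
  else stop("unknown tractogram magic bytes in ", path)
}
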