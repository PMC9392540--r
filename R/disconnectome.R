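#' Per-subject voxel-wise disconnection probability map
#'
#' For each voxel, the fraction of normative controls in whom at least one
#' streamline passing through the subject's lesion visits that voxel. Values
#' are stored as proportions in [0, 1]; every value is an exact multiple of
#' 1/N where N is the number of controls.
#'
#' @name disconnectome_map
NULL

new_disconnectome_map <- function(volume, subject_id, n_controls) {
  structure(list(volume = volume, subject_id = subject_id,
                 n_controls = as.integer(n_controls)),
            class = "disconnectome_map")
}

#' @export
print.disconnectome_map <- function(x, ...) {
  cat("<disconnectome_map> subject ", x$subject_id, ", ", x$n_controls,
      " controls, ", sum(x$volume$data > 0), " nonzero voxels\n", sep = "")
  invisible(x)
}

# Precompute, per control, each streamline's unique in-grid voxel indices.
# Shared across subjects in a batch; results are identical to recomputing
# per subject because selection and visitation reduce to these index sets.
control_voxel_cache <- function(control, grid, step) {
  lapply(control$streamlines, streamline_voxels, grid = grid, step = step)
}

disconnectome_from_caches <- function(lesion, caches, grid, step) {
  nvox <- prod(dim(grid$data))
  inmask <- as.vector(lesion$volume$data != 0)
  if (!any(inmask)) stop("lesion mask is empty for ", lesion$subject_id)
  counts <- numeric(nvox)
  any_hit <- FALSE
  for (cache in caches) {
    sel <- vapply(cache, function(v) any(inmask[v]), logical(1))
    if (any(sel)) {
      any_hit <- TRUE
      visited <- unique(unlist(cache[sel], use.names = FALSE))
      counts[visited] <- counts[visited] + 1
    }
  }
  if (!any_hit)
    warning("no streamline of any control intersects the lesion of subject ",
            lesion$subject_id)
  vol <- image_volume(array(counts / length(caches), dim(grid$data)),
                      grid$affine)
  new_disconnectome_map(vol, lesion$subject_id, length(caches))
}

#' Disconnectome map for one subject
#'
#' Implements the percentage-overlap construction: per control, streamlines
#' intersecting the lesion are selected, their binary visitation map is
#' computed, and the per-voxel average over controls is returned.
#'
#' @param lesion a nonempty \code{lesion_mask} on the analysis grid.
#' @param controls list of \code{tractogram}s (>= 1), pre-normalised to the
#'   analysis grid's template space.
#' @param grid \code{image_volume} defining the analysis grid (defaults to
#'   the lesion's grid).
#' @param step streamline resampling step in mm; default half the smallest
#'   voxel edge.
#' @return A \code{disconnectome_map}.
#' @export
disconnectome_for_subject <- function(lesion, controls, grid = NULL,
                                      step = NULL) {
  stopifnot(inherits(lesion, "lesion_mask"))
  if (length(controls) < 1) stop("at least one control tractogram is required")
  grid <- grid %||% lesion$volume
  check_same_grid(lesion$volume, grid)
  step <- step %||% default_step(grid)
  caches <- lapply(controls, control_voxel_cache, grid = grid, step = step)
  disconnectome_from_caches(lesion, caches, grid, step)
}

#' Disconnectome maps for a cohort of subjects
#'
#' Per-control visitation geometry is computed once and reused across
#' subjects; results are identical to subject-by-subject calls. Subjects
#' whose computation fails are recorded and the batch continues.
#'
#' @param lesions list of \code{lesion_mask} (>= 1).
#' @param controls list of \code{tractogram}s.
#' @param grid analysis grid (\code{image_volume}); defaults to the first
#'   lesion's grid.
#' @param step resampling step in mm.
#' @return List with \code{maps} (order-preserving; \code{NULL} for failed
#'   subjects) and \code{errors} (named list of error messages).
#' @export
disconnectome_batch <- function(lesions, controls, grid = NULL, step = NULL) {
  if (length(lesions) < 1) stop("at least one subject is required")
  if (length(controls) < 1) stop("at least one control tractogram is required")
  grid <- grid %||% lesions[[1]]$volume
  step <- step %||% default_step(grid)
  caches <- lapply(controls, control_voxel_cache, grid = grid, step = step)
  errors <- list()
  maps <- vector("list", length(lesions))
  for (i in seq_along(lesions)) {
    res <- tryCatch(
      {
        check_same_grid(lesions[[i]]$volume, grid)
        disconnectome_from_caches(lesions[[i]], caches, grid, step)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[lesions[[i]]$subject_id]] <- conditionMessage(res)
    } else {
      maps[[i]] <- res
    }
  }
  list(maps = maps, errors = errors)
}

#' Threshold a disconnectome map to a binary volume
#'
#' Inclusive boundary: a voxel is kept iff its proportion is >= \code{tau}.
#'
#' @param d a \code{disconnectome_map}.
#' @param tau proportion in [0, 1].
#' @return Binary \code{image_volume}.
#' @export
threshold_map <- function(d, tau) {
  stopifnot(inherits(d, "disconnectome_map"), tau >= 0, tau <= 1)
  image_volume(array(as.numeric(d$volume$data >= tau), dim(d$volume$data)),
               d$volume$affine)
}
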