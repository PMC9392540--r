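# 3D connected components with selectable neighbourhood.

#' Neighbour offsets for a 3D connectivity scheme
#'
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full cube).
#' @return Integer matrix (n_offsets x 3).
#' @export
neighbor_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Label connected components of a 3D logical array
#'
#' Breadth-first labelling; label ids are assigned in order of the first
#' (column-major) foreground voxel of each component.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape: 0 background, 1..K components.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("`mask` must be a 3D array")
  dm <- dim(mask)
  fg <- mask != 0
  labels <- array(0L, dm)
  offs <- neighbor_offsets(connectivity)
  n_off <- nrow(offs)
  todo <- which(fg)
  next_label <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    next_label <- next_label + 1L
    labels[seed] <- next_label
    frontier <- seed
    while (length(frontier)) {
      co <- arrayInd(frontier, dm)
      # all neighbours of the whole frontier at once
      ni <- rep(co[, 1], each = n_off) + offs[, 1]
      nj <- rep(co[, 2], each = n_off) + offs[, 2]
      nk <- rep(co[, 3], each = n_off) + offs[, 3]
      ok <- ni >= 1 & ni <= dm[1] & nj >= 1 & nj <= dm[2] &
            nk >= 1 & nk <= dm[3]
      lin <- unique(ni[ok] + dm[1] * ((nj[ok] - 1) + dm[2] * (nk[ok] - 1)))
      lin <- lin[fg[lin] & labels[lin] == 0L]
      labels[lin] <- next_label
      frontier <- lin
    }
  }
  labels
}
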