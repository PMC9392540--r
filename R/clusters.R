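#' Extract suprathreshold clusters from a statistic (bootstrap-ratio) map
#'
#' Voxels strictly above the threshold (or strictly below its negative, for
#' the negative tail) are partitioned into connected components; components
#' smaller than \code{min_size_vox} are dropped. The table follows the
#' cluster-report schema: size in voxels and mm^3, most extreme statistic,
#' and its peak location in 0-based voxel indices and world mm.
#'
#' @param bsr_vol \code{image_volume} of pseudo-z values.
#' @param threshold finite threshold (default 3, applied strictly:
#'   a voxel exactly at the threshold is excluded).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_size_vox minimum cluster size in voxels (default 1: no filter).
#' @param tail "positive" (stat > threshold) or "negative"
#'   (stat < -threshold).
#' @return List with \code{table} (data.frame sorted by size descending:
#'   cluster_id, size_vox, size_mm3, max_bsr, peak_i/j/k, peak_x/y/z_mm)
#'   and \code{labels} (integer \code{image_volume}: 0 background,
#'   cluster_id elsewhere). No suprathreshold voxel gives an empty table.
#' @export
extract_clusters <- function(bsr_vol, threshold = 3, connectivity = 26,
                             min_size_vox = 1, tail = c("positive", "negative")) {
  stopifnot(inherits(bsr_vol, "image_volume"), is.finite(threshold),
            min_size_vox >= 1)
  tail <- match.arg(tail)
  stat <- bsr_vol$data
  supra <- if (tail == "positive") stat > threshold else stat < -threshold
  dm <- dim(stat)
  empty <- list(
    table = data.frame(cluster_id = integer(), size_vox = integer(),
                       size_mm3 = numeric(), max_bsr = numeric(),
                       peak_i = integer(), peak_j = integer(),
                       peak_k = integer(), peak_x_mm = numeric(),
                       peak_y_mm = numeric(), peak_z_mm = numeric()),
    labels = image_volume(array(0L, dm), bsr_vol$affine))
  if (!any(supra)) return(empty)
  lab <- label_components(supra, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size_vox)
  if (!length(keep)) return(empty)
  vv <- voxel_volume(bsr_vol)
  rows <- lapply(keep, function(id) {
    lin <- which(lab == id)
    vals <- stat[lin]
    peak_at <- lin[which.max(abs(vals))]
    ijk <- arrayInd(peak_at, dm) - 1L
    data.frame(size_vox = length(lin), size_mm3 = length(lin) * vv,
               max_bsr = vals[which.max(abs(vals))],
               peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3],
               min_lin = min(lin), old_id = id)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$size_vox, tab$min_lin)
  tab <- tab[ord, , drop = FALSE]
  tab$cluster_id <- seq_len(nrow(tab))
  world <- voxel_to_world(as.matrix(tab[, c("peak_i", "peak_j", "peak_k")]),
                          bsr_vol)
  tab$peak_x_mm <- world[, 1]; tab$peak_y_mm <- world[, 2]
  tab$peak_z_mm <- world[, 3]
  relabel <- integer(max(lab))
  relabel[tab$old_id] <- tab$cluster_id
  new_lab <- array(0L, dm)
  fg <- lab > 0
  mapped <- relabel[lab[fg]]
  new_lab[fg] <- ifelse(is.na(mapped) | mapped == 0, 0L, mapped)
  rownames(tab) <- NULL
  list(table = tab[, c("cluster_id", "size_vox", "size_mm3", "max_bsr",
                       "peak_i", "peak_j", "peak_k",
                       "peak_x_mm", "peak_y_mm", "peak_z_mm")],
       labels = image_volume(new_lab, bsr_vol$affine))
}

#' Mean disconnection per subject within each cluster
#'
#' @param maps list of \code{disconnectome_map}, one per subject.
#' @param labels integer label \code{image_volume} from
#'   \code{\link{extract_clusters}}.
#' @return Numeric matrix subjects x clusters of mean disconnection
#'   proportions (columns named \code{cluster_<id>}).
#' @export
cluster_disconnectivity <- function(maps, labels) {
  stopifnot(inherits(labels, "image_volume"))
  ids <- sort(unique(labels$data[labels$data > 0]))
  if (!length(ids)) stop("label volume contains no cluster")
  lin <- lapply(ids, function(id) which(labels$data == id))
  out <- t(vapply(maps, function(m) {
    check_same_grid(m$volume, labels)
    vapply(lin, function(ix) mean(m$volume$data[ix]), numeric(1))
  }, numeric(length(ids))))
  out <- matrix(out, nrow = length(maps))
  colnames(out) <- paste0("cluster_", ids)
  out
}

#' Pearson correlations between cluster disconnectivity and a test battery
#'
#' Each cell correlates one predictor column (cluster disconnectivity, plus
#' any extra columns such as MoCA and PLS brain scores) with one battery
#' measure over pairwise-complete subjects. Cells with fewer than 3 complete
#' pairs, or with a constant column among the complete pairs, are set
#' missing with a reason.
#'
#' @param cv subjects x clusters matrix from
#'   \code{\link{cluster_disconnectivity}}.
#' @param battery data.frame of battery measures (missing values allowed).
#' @param extra optional data.frame of additional predictor columns aligned
#'   with \code{cv} rows (e.g. \code{moca}, \code{brain_score}).
#' @return List with matrices \code{r}, \code{n} (complete pairs per cell)
#'   and \code{reason} (character, "" where the cell is defined).
#' @export
correlate_with_battery <- function(cv, battery, extra = NULL) {
  preds <- as.data.frame(cv)
  if (!is.null(extra)) preds <- cbind(preds, as.data.frame(extra))
  battery <- as.data.frame(battery)
  if (nrow(preds) != nrow(battery))
    stop("predictors and battery must cover the same subjects")
  r <- matrix(NA_real_, ncol(preds), ncol(battery),
              dimnames = list(names(preds), names(battery)))
  n <- matrix(0L, ncol(preds), ncol(battery), dimnames = dimnames(r))
  reason <- matrix("", ncol(preds), ncol(battery), dimnames = dimnames(r))
  for (i in seq_len(ncol(preds))) {
    for (j in seq_len(ncol(battery))) {
      x <- preds[[i]]; y <- battery[[j]]
      ok <- is.finite(x) & is.finite(y)
      n[i, j] <- sum(ok)
      if (sum(ok) < 3) {
        reason[i, j] <- "fewer than 3 complete pairs"
      } else if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        reason[i, j] <- "constant column: correlation undefined"
      } else {
        r[i, j] <- stats::cor(x[ok], y[ok])
      }
    }
  }
  list(r = r, n = n, reason = reason)
}
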