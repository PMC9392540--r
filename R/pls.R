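#' Nonrotated behavioral PLS linking disconnectome maps to behavior
#'
#' Latent variables are defined by a-priori contrasts on the behavioral block
#' (not by SVD rotation). Both blocks are column z-scored, so with identity
#' contrasts each salience map is exactly the vector of mass-univariate
#' Pearson correlations between one behavioral variable and every voxel.
#' Significance of latent-variable strength comes from row permutations of
#' the behavioral block; voxel-level reliability from subject bootstrap
#' resampling, summarised as bootstrap ratios (pseudo-z).
#'
#' @name pls_brain_behavior
NULL

#' Build the analysis mask from a stack of disconnectome maps
#'
#' A voxel enters the analysis iff it is nonzero in at least one subject and
#' has nonzero variance across subjects (constant columns are unusable by a
#' correlation-scale PLS).
#'
#' @param maps list of \code{disconnectome_map} (>= 2 subjects).
#' @return Sorted integer vector of 1-based voxel linear indices.
#' @export
build_analysis_mask <- function(maps) {
  if (length(maps) < 2) stop("need >= 2 subjects to build an analysis mask")
  x <- vapply(maps, function(m) as.vector(m$volume$data),
              numeric(prod(dim(maps[[1]]$volume$data))))
  x <- t(x)  # subjects x voxels
  nonzero <- colSums(x != 0) > 0
  mu <- colMeans(x)
  v <- colSums((x - rep(mu, each = nrow(x)))^2)
  keep <- nonzero & v > 1e-12 * pmax(1, abs(mu))
  idx <- which(keep)
  if (!length(idx)) stop("analysis mask is empty: no voxel varies across subjects")
  sort(idx)
}

#' Stack disconnectome maps into a subjects x voxels matrix
#'
#' @param maps list of \code{disconnectome_map}, rows in list order.
#' @param mask_index voxel linear indices from \code{build_analysis_mask}.
#' @return Numeric matrix (subjects x length(mask_index)).
#' @export
brain_matrix <- function(maps, mask_index) {
  t(vapply(maps, function(m) as.vector(m$volume$data)[mask_index],
           numeric(length(mask_index))))
}

#' Column z-scoring (mean 0, sample SD 1)
#'
#' @param M numeric matrix with no constant column.
#' @return Matrix of the same shape; SD uses denominator n - 1.
#' @export
zscore_columns <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (n < 2) stop("need >= 2 rows to z-score")
  mu <- colMeans(M)
  Mc <- M - rep(mu, each = n)
  s <- sqrt(colSums(Mc^2) / (n - 1))
  if (any(s <= 1e-12 * pmax(1, abs(mu))))
    stop("constant column cannot be z-scored (columns: ",
         paste(which(s <= 1e-12 * pmax(1, abs(mu))), collapse = ", "), ")")
  Mc / rep(s, each = n)
}

# z-score allowing constant columns, which are set to all-zero (used inside
# bootstrap resamples where sparse voxels can be constant by chance)
zscore_columns_safe <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  Mc <- M - rep(mu, each = n)
  s <- sqrt(colSums(Mc^2) / (n - 1))
  const <- s <= 1e-12 * pmax(1, abs(mu))
  s[const] <- 1
  Z <- Mc / rep(s, each = n)
  Z[, const] <- 0
  Z
}

normalize_contrasts <- function(C, b) {
  if (is.character(C) && length(C) == 1 && C == "identity") C <- diag(b)
  C <- as.matrix(C)
  if (nrow(C) != b) stop("contrast matrix must have one row per behavior variable")
  nrm <- sqrt(colSums(C^2))
  if (any(nrm == 0)) stop("zero contrast column")
  sweep(C, 2, nrm, `/`)
}

#' Nonrotated (contrast-driven) PLS: saliences, strengths, brain scores
#'
#' With Xz, Yz the column-z-scored blocks, the cross-block matrix is
#' R = t(Yz) Xz / (n - 1); for each unit-normalised contrast c the salience
#' is v = t(R) c, its strength s = ||v||, and subject brain scores are
#' Xz v / s.
#'
#' @param X subjects x voxels brain matrix (no constant column).
#' @param Y subjects x b behavior matrix (no constant column, no missing).
#' @param C b x k contrast matrix, or \code{"identity"}.
#' @return List of class \code{pls_result} with \code{salience} (voxels x k),
#'   \code{strength} (k), \code{brain_scores} (subjects x k) and the
#'   normalised \code{contrasts}.
#' @export
nonrotated_pls <- function(X, Y, C = "identity") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of subjects")
  if (n < 3) stop("need at least 3 subjects")
  Cn <- normalize_contrasts(C, ncol(Y))
  Xz <- zscore_columns(X)
  Yz <- zscore_columns(Y)
  R <- crossprod(Yz, Xz) / (n - 1)          # b x voxels
  V <- crossprod(R, Cn)                     # voxels x k
  s <- sqrt(colSums(V^2))
  scores <- matrix(0, n, ncol(Cn))
  pos <- s > 0
  if (any(pos))
    scores[, pos] <- Xz %*% sweep(V[, pos, drop = FALSE], 2, s[pos], `/`)
  structure(list(salience = V, strength = s, brain_scores = scores,
                 contrasts = Cn, n = n),
            class = "pls_result")
}

#' Permutation test of latent-variable strength
#'
#' Rows of Y are permuted jointly (X fixed), Y is re-z-scored, and the
#' latent-variable strengths are recomputed. The p-value uses the add-one
#' smoothing p = (1 + #\{s_perm >= s_obs\}) / (1 + n_perm), so p is never 0.
#'
#' @param X,Y,C as in \code{\link{nonrotated_pls}}.
#' @param n_perm number of permutations (>= 1); the study default is 1000.
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @return List with \code{perm_p} (length k), \code{s_obs}, \code{n_perm},
#'   \code{seed}.
#' @export
permutation_test <- function(X, Y, C = "identity", n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  obs <- nonrotated_pls(X, Y, C)
  n <- obs$n
  Xz <- zscore_columns(as.matrix(X))
  Yz <- zscore_columns(as.matrix(Y))  # permuting rows commutes with z-scoring
  Cn <- obs$contrasts
  count <- numeric(length(obs$strength))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      Yp <- Yz[sample.int(n), , drop = FALSE]
      V <- crossprod(crossprod(Yp, Xz) / (n - 1), Cn)
      sp <- sqrt(colSums(V^2))
      count <- count + (sp >= obs$strength)
    }
  })
  list(perm_p = (1 + count) / (1 + n_perm), s_obs = obs$strength,
       n_perm = n_perm, seed = seed)
}

#' Bootstrap standard errors and bootstrap-ratio (pseudo-z) maps
#'
#' Subjects are resampled with replacement (the same resample applied to the
#' rows of X and Y); within each resample both blocks are re-z-scored and the
#' saliences recomputed. A resample in which a behavior column is constant
#' (e.g. all-female) is redrawn and the redraw logged; a brain column
#' constant within a resample is given z-score zero for that resample.
#' The bootstrap ratio is the observed salience divided by the elementwise
#' bootstrap SD (denominator n_boot - 1); voxels with zero SE get ratio 0
#' and are flagged.
#'
#' @param X,Y,C as in \code{\link{nonrotated_pls}}.
#' @param n_boot number of resamples (>= 2); the study default is 1000.
#' @param seed integer seed.
#' @return List with \code{boot_se} (voxels x k), \code{bsr} (voxels x k),
#'   \code{zero_se} (logical voxels x k), \code{n_redraws}, \code{n_boot},
#'   \code{seed}.
#' @export
bootstrap_ratios <- function(X, Y, C = "identity", n_boot = 1000, seed = 1) {
  stopifnot(n_boot >= 2)
  obs <- nonrotated_pls(X, Y, C)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  Cn <- obs$contrasts
  k <- ncol(Cn)
  nv <- ncol(X)
  sum_v <- matrix(0, nv, k)
  sum_v2 <- matrix(0, nv, k)
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      attempts <- 0L
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) >= 3) {
          Yb <- Y[idx, , drop = FALSE]
          sdY <- apply(Yb, 2, stats::sd)
          if (all(sdY > 0)) break
        }
        n_redraws <- n_redraws + 1L
        attempts <- attempts + 1L
        if (attempts > 1000)
          stop("could not draw a usable bootstrap resample after 1000 attempts")
      }
      Xbz <- zscore_columns_safe(X[idx, , drop = FALSE])
      Ybz <- zscore_columns(Y[idx, , drop = FALSE])
      V <- crossprod(crossprod(Ybz, Xbz) / (n - 1), Cn)
      sum_v <- sum_v + V
      sum_v2 <- sum_v2 + V^2
    }
  })
  var_v <- (sum_v2 - sum_v^2 / n_boot) / (n_boot - 1)
  boot_se <- sqrt(pmax(var_v, 0))
  zero_se <- boot_se <= 0
  bsr <- matrix(0, nv, k)
  bsr[!zero_se] <- obs$salience[!zero_se] / boot_se[!zero_se]
  list(boot_se = boot_se, bsr = bsr, zero_se = zero_se,
       n_redraws = n_redraws, n_boot = n_boot, seed = seed)
}

#' Full brain-behavior PLS on a cohort of disconnectome maps
#'
#' Convenience wrapper: builds the analysis mask, stacks the brain matrix,
#' drops (and logs) subjects with missing behavioral values, and runs the
#' contrast-driven PLS with permutation and bootstrap inference.
#'
#' @param maps list of \code{disconnectome_map}, one per subject, aligned
#'   with the rows of \code{behavior}.
#' @param behavior data.frame of behavioral variables (default columns
#'   \code{female}, \code{age}, \code{moca}).
#' @param columns behavioral columns to enter, in contrast order.
#' @param C contrast matrix or \code{"identity"}.
#' @param n_perm,n_boot resample counts (study default 1000 each).
#' @param seed master seed; permutation and bootstrap use independent
#'   sub-seeds derived from it.
#' @return A \code{pls_result} list: salience, strength, perm_p, boot_se,
#'   bsr, brain_scores, mask_index, grid, subjects used, seeds and counts.
#' @export
pls_brain_behavior <- function(maps, behavior,
                               columns = c("female", "age", "moca"),
                               C = "identity", n_perm = 1000, n_boot = 1000,
                               seed = 1) {
  stopifnot(length(maps) == nrow(behavior))
  Y_all <- as.matrix(behavior[, columns, drop = FALSE])
  complete <- stats::complete.cases(Y_all)
  if (!all(complete))
    message("dropping ", sum(!complete),
            " subject(s) with missing behavioral values")
  maps <- maps[complete]
  Y <- Y_all[complete, , drop = FALSE]
  mask_index <- build_analysis_mask(maps)
  X <- brain_matrix(maps, mask_index)
  fit <- nonrotated_pls(X, Y, C)
  perm <- permutation_test(X, Y, C, n_perm = n_perm,
                           seed = derive_seed(seed, "perm"))
  boot <- bootstrap_ratios(X, Y, C, n_boot = n_boot,
                           seed = derive_seed(seed, "boot"))
  structure(list(salience = fit$salience, strength = fit$strength,
                 brain_scores = fit$brain_scores, contrasts = fit$contrasts,
                 perm_p = perm$perm_p, boot_se = boot$boot_se,
                 bsr = boot$bsr, zero_se = boot$zero_se,
                 n_redraws = boot$n_redraws,
                 mask_index = mask_index, grid = maps[[1]]$volume,
                 columns = columns, subjects_used = which(complete),
                 n = nrow(Y), n_perm = n_perm, n_boot = n_boot, seed = seed),
            class = "pls_result")
}

#' Scatter a masked voxel vector back into a full volume
#'
#' @param v numeric vector of length \code{length(mask_index)} (a salience
#'   or bootstrap-ratio map).
#' @param mask_index voxel linear indices the vector is aligned with.
#' @param grid \code{image_volume} defining shape and affine.
#' @return \code{image_volume} with \code{v} at the mask voxels, 0 elsewhere.
#' @export
salience_to_volume <- function(v, mask_index, grid) {
  if (length(v) != length(mask_index))
    stop("vector length (", length(v), ") != mask size (",
         length(mask_index), ")")
  out <- numeric(prod(dim(grid$data)))
  out[mask_index] <- v
  image_volume(array(out, dim(grid$data)), grid$affine)
}
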