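# Shared fixtures and independent oracles used across the suite.

make_grid <- function(shape = c(8, 8, 8), voxel = 2) {
  image_volume(array(0, shape), diag(c(rep(voxel, 3), 1)))
}

# lesion mask with 1s at the given 0-based ijk rows
mask_at <- function(grid, ijk, subject_id = "sub") {
  a <- array(0, dim(grid$data))
  ijk <- matrix(ijk, ncol = 3)
  a[ijk + 1] <- 1
  lesion_mask(image_volume(a, grid$affine), subject_id)
}

# --- independent connected-components oracle: iterative min-label
# relaxation over the foreground until a fixed point, then renumbering
oracle_label <- function(mask, connectivity) {
  dm <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  lab <- array(0, dm)
  lab[mask != 0] <- which(mask != 0)
  repeat {
    changed <- FALSE
    for (lin in which(mask != 0)) {
      co <- arrayInd(lin, dm)
      best <- lab[lin]
      for (o in seq_len(nrow(offs))) {
        p <- co + offs[o, ]
        if (all(p >= 1) && all(p <= dm) && mask[p[1], p[2], p[3]] != 0)
          best <- min(best, lab[p[1], p[2], p[3]])
      }
      if (best < lab[lin]) { lab[lin] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  ids <- sort(unique(lab[lab > 0]))
  out <- array(0L, dm)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# same partition up to label permutation
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  tab <- table(a[fg], b[fg])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# --- brute-force disconnectome oracle: per control, per streamline,
# per segment point; own interpolation and own voxel mapping
oracle_disconnectome <- function(lesion, controls, grid, step) {
  dm <- dim(grid$data)
  inv <- solve(grid$affine)
  point_to_idx <- function(p) {
    v <- (inv %*% c(p, 1))[1:3]
    as.integer(sign(v) * floor(abs(v) + 0.5))
  }
  sl_voxels <- function(s) {
    vox <- list()
    pts <- list(s[1, ])
    for (seg in seq_len(nrow(s) - 1)) {
      a <- s[seg, ]; b <- s[seg + 1, ]
      len <- sqrt(sum((b - a)^2))
      m <- max(1, ceiling(len / step - 1e-9))
      for (q in seq_len(m)) pts[[length(pts) + 1]] <- a + (b - a) * q / m
    }
    hits <- character()
    for (p in pts) {
      ijk <- point_to_idx(p)
      if (all(ijk >= 0) && all(ijk < dm))
        hits <- c(hits, paste(ijk, collapse = ","))
    }
    unique(hits)
  }
  counts <- array(0, dm)
  for (ctl in controls) {
    visited <- character()
    for (s in ctl$streamlines) {
      vx <- sl_voxels(s)
      in_lesion <- FALSE
      for (key in vx) {
        ijk <- as.integer(strsplit(key, ",")[[1]])
        if (lesion$volume$data[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] != 0)
          in_lesion <- TRUE
      }
      if (in_lesion) visited <- union(visited, vx)
    }
    for (key in visited) {
      ijk <- as.integer(strsplit(key, ",")[[1]])
      counts[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] <-
        counts[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] + 1
    }
  }
  counts / length(controls)
}

# --- normal-equations OLS oracle
oracle_ols <- function(X, y) {
  X <- as.matrix(X)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  tss <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  Fval <- ((tss - rss) / (ncol(X) - 1)) / (rss / df)
  list(beta = as.vector(beta), se = as.vector(se), t = as.vector(tval),
       p = as.vector(2 * stats::pt(abs(tval), df, lower.tail = FALSE)),
       F = Fval, df = df, rss = rss)
}

# small phantom spec for fast end-to-end tests
tiny_spec <- function(n_controls = 5) {
  phantom_spec(grid_shape = c(16, 16, 16), voxel_size = 2,
               bundles = list(
                 list(name = "target",
                      points = rbind(c(8, 10, 14), c(16, 12, 18),
                                     c(24, 10, 14)),
                      radius = 3, n_streamlines = 8),
                 list(name = "background",
                      points = rbind(c(10, 22, 10), c(16, 22, 16),
                                     c(22, 22, 22)),
                      radius = 3, n_streamlines = 8)),
               n_controls = n_controls,
               jitter_control = 0.5, jitter_streamline = 0.4)
}
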