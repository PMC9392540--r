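# Synthetic phantom cohort: normative tube-bundle tractograms, spherical
# lesions, and behavior with a planted disconnection -> cognition effect.
# Everything is deterministic given one master seed (hierarchical sub-seeds
# per component), and the generator emits its own ground truth so recovery
# tests have an oracle.

#' Phantom specification for the synthetic normative tractograms
#'
#' Each bundle is a tube around a control-point polyline: streamlines are
#' deterministic parallel tube samples (golden-angle spiral over the tube
#' cross-section), and randomness enters only through rigid control-level
#' and streamline-level jitter offsets. With zero jitter, every control is
#' identical.
#'
#' @param grid_shape integer 3-vector of voxel counts (default 32^3).
#' @param voxel_size isotropic voxel edge in mm (default 2).
#' @param bundles list of bundles, each \code{list(name, points (n x 3
#'   world-mm matrix), radius (mm), n_streamlines)}.
#' @param n_controls number of normative controls (default 20).
#' @param jitter_control SD in mm of the rigid per-control bundle offset
#'   (default 0.5, calibrated so the planted effect stays spatially
#'   recoverable at the study scale).
#' @param jitter_streamline SD in mm of the rigid per-streamline offset
#'   (default 0.4).
#' @return List of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32), voxel_size = 2,
                         bundles = default_bundles(),
                         n_controls = 20,
                         jitter_control = 0.5, jitter_streamline = 0.4) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4), voxel_size > 0,
            n_controls >= 1, jitter_control >= 0, jitter_streamline >= 0)
  for (b in bundles) {
    stopifnot(!is.null(b$name), nrow(b$points) >= 2, b$n_streamlines >= 1)
    if (b$radius <= voxel_size / 2)
      stop("bundle ", b$name, ": tube radius must exceed half a voxel edge")
    margin <- b$radius + 3 * (jitter_control + jitter_streamline)
    lo <- -0.5 * voxel_size + margin
    hi <- (grid_shape - 0.5) * voxel_size - margin
    if (any(t(b$points) < lo) || any(t(b$points) > hi))
      stop("bundle ", b$name, " does not fit inside the grid at 3 jitter SD")
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 bundles = bundles, n_controls = as.integer(n_controls),
                 jitter_control = jitter_control,
                 jitter_streamline = jitter_streamline),
            class = "phantom_spec")
}

#' Default two-bundle phantom geometry
#'
#' A curved "target" bundle (the planted effect's substrate) and a separate
#' diagonal "background" bundle, both comfortably inside the default
#' 32^3 x 2 mm grid.
#' @return List of two bundle specifications.
#' @export
default_bundles <- function() {
  list(
    list(name = "target",
         points = rbind(c(12, 18, 26), c(22, 20, 33), c(32, 22, 38),
                        c(42, 20, 33), c(52, 18, 26)),
         radius = 4, n_streamlines = 30),
    list(name = "background",
         points = rbind(c(16, 44, 14), c(28, 46, 26), c(40, 44, 38),
                        c(50, 42, 48)),
         radius = 4, n_streamlines = 30)
  )
}

#' Effect specification for the planted brain-behavior coupling
#'
#' The cognitive score is \code{clip(round(baseline - beta * d_i + eps), 0,
#' 30)} with \code{d_i} the subject's true mean disconnection of the target
#' footprint and \code{eps ~ N(0, noise_sd)}; battery subtests load
#' negatively on \code{d_i} with independent noise and are observed in a
#' subsample.
#'
#' @param target_bundle name of the bundle carrying the effect.
#' @param beta score points lost per unit mean target disconnection.
#' @param noise_sd residual SD of the cognitive score.
#' @param baseline intercept of the cognitive score (0-30 scale).
#' @param battery_loadings named vector: points of each subtest lost per
#'   unit disconnection.
#' @param battery_noise_sd residual SD of each subtest.
#' @param battery_baseline subtest intercept.
#' @param subsample_fraction fraction of subjects with battery data.
#' @return List of class \code{effect_spec}.
#' @export
effect_spec <- function(target_bundle = "target", beta = 10, noise_sd = 1.5,
                        baseline = 28,
                        battery_loadings = c(fluency_phonetic = 12,
                                             fluency_semantic = 12,
                                             attention_span = 8,
                                             working_memory = 8,
                                             psychomotor_speed = 10,
                                             spatial_memory = 6),
                        battery_noise_sd = 4, battery_baseline = 50,
                        subsample_fraction = 0.8) {
  stopifnot(beta >= 0, noise_sd >= 0, baseline >= 0, baseline <= 30,
            subsample_fraction >= 0, subsample_fraction <= 1)
  structure(list(target_bundle = target_bundle, beta = beta,
                 noise_sd = noise_sd, baseline = baseline,
                 battery_loadings = battery_loadings,
                 battery_noise_sd = battery_noise_sd,
                 battery_baseline = battery_baseline,
                 subsample_fraction = subsample_fraction),
            class = "effect_spec")
}

#' Analysis grid implied by a phantom spec
#'
#' @param spec a \code{phantom_spec}.
#' @return Empty \code{image_volume} with diagonal voxel-size affine.
#' @export
phantom_grid <- function(spec) {
  image_volume(array(0, spec$grid_shape),
               diag(c(rep(spec$voxel_size, 3), 1)))
}

# orthonormal frame perpendicular to direction v
perp_frame <- function(v) {
  v <- v / sqrt(sum(v^2))
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * v) * v
  u <- u / sqrt(sum(u^2))
  w <- c(v[2] * u[3] - v[3] * u[2],
         v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  cbind(u, w)
}

# deterministic tube-sample offsets: golden-angle spiral over the disk
tube_offsets <- function(bundle) {
  m <- bundle$n_streamlines
  frame <- perp_frame(bundle$points[nrow(bundle$points), ] - bundle$points[1, ])
  q <- seq_len(m)
  rho <- bundle$radius * sqrt((q - 0.5) / m)
  theta <- q * 2.399963229728653  # golden angle
  cbind(rho * cos(theta), rho * sin(theta)) %*% t(frame)
}

#' Generate the normative control tractograms and bundle footprints
#'
#' @param spec a \code{phantom_spec}.
#' @param seed integer seed; output is bit-reproducible.
#' @return List with \code{controls} (list of \code{tractogram}),
#'   \code{footprints} (named list of binary \code{image_volume}: voxels
#'   within the noise-free tube of each bundle) and \code{grid}.
#' @export
make_controls <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- phantom_grid(spec)
  extent_lo <- -0.5 * spec$voxel_size
  extent_hi <- (spec$grid_shape - 0.5) * spec$voxel_size
  centerlines <- lapply(spec$bundles, function(b)
    resample_streamline(b$points, spec$voxel_size))
  offsets <- lapply(spec$bundles, tube_offsets)
  controls <- with_seed(seed, {
    lapply(seq_len(spec$n_controls), function(ci) {
      sls <- list()
      for (bi in seq_along(spec$bundles)) {
        b <- spec$bundles[[bi]]
        ctrl_off <- stats::rnorm(3, sd = spec$jitter_control)
        for (q in seq_len(b$n_streamlines)) {
          sl_off <- stats::rnorm(3, sd = spec$jitter_streamline)
          pts <- centerlines[[bi]] +
            rep(offsets[[bi]][q, ] + ctrl_off + sl_off,
                each = nrow(centerlines[[bi]]))
          if (any(t(pts) < extent_lo) || any(t(pts) > extent_hi))
            stop("bundle ", b$name, " escaped the grid in control ", ci)
          sls[[length(sls) + 1]] <- pts
        }
      }
      tractogram(sls, control_id = sprintf("ctrl%02d", ci), space = "MNI152")
    })
  })
  footprints <- lapply(spec$bundles, function(b)
    bundle_footprint(b, grid))
  names(footprints) <- vapply(spec$bundles, `[[`, character(1), "name")
  list(controls = controls, footprints = footprints, grid = grid)
}

# footprint = visitation map of the noise-free bundle (the deterministic
# tube-sample streamlines with zero jitter); deterministic given the spec
bundle_footprint <- function(bundle, grid) {
  centerline <- resample_streamline(bundle$points,
                                    min(sqrt(colSums(grid$affine[1:3, 1:3]^2))))
  offs <- tube_offsets(bundle)
  sls <- lapply(seq_len(bundle$n_streamlines), function(q)
    centerline + rep(offs[q, ], each = nrow(centerline)))
  visitation_map(sls, grid)$volume
}

voxel_centers <- function(grid) {
  dm <- dim(grid$data)
  idx <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                               k = 0:(dm[3] - 1)))
  voxel_to_world(idx, grid)
}

#' Generate spherical lesion masks for a synthetic cohort
#'
#' Each subject gets 1-3 spheres with log-uniform radii. A fixed fraction of
#' subjects is "on target": their first sphere is centred on a random point
#' of the target bundle's centerline (plus a small offset); all other
#' spheres are placed uniformly in the grid interior. All masks are
#' nonempty (the minimum radius always covers a voxel centre on a 2 mm
#' grid).
#'
#' @param spec a \code{phantom_spec}.
#' @param n_subjects number of subjects (0 allowed: empty list).
#' @param on_target_fraction fraction of subjects whose lesion hits the
#'   target bundle (default 0.35).
#' @param radius_range min/max sphere radius in mm (default 2-10).
#' @param seed integer seed.
#' @param target_bundle name of the targeted bundle.
#' @return List with \code{lesions} (list of \code{lesion_mask}) and
#'   \code{on_target} (logical vector, the ground-truth assignment).
#' @export
make_lesions <- function(spec, n_subjects = 102, on_target_fraction = 0.35,
                         radius_range = c(2, 10), seed = 1,
                         target_bundle = "target") {
  stopifnot(inherits(spec, "phantom_spec"),
            on_target_fraction >= 0, on_target_fraction <= 1,
            radius_range[1] >= spec$voxel_size * 0.87,  # sqrt(3)/2 edge
            radius_range[2] >= radius_range[1])
  grid <- phantom_grid(spec)
  if (radius_range[2] >= min(spec$grid_shape) * spec$voxel_size / 2)
    stop("maximum lesion radius exceeds the grid")
  if (n_subjects == 0) return(list(lesions = list(), on_target = logical()))
  bnames <- vapply(spec$bundles, `[[`, character(1), "name")
  tb <- spec$bundles[[match(target_bundle, bnames)]]
  centerline <- resample_streamline(tb$points, 0.5)
  centers <- voxel_centers(grid)
  dm <- dim(grid$data)
  hi <- (spec$grid_shape - 1) * spec$voxel_size
  with_seed(seed, {
    k <- round(on_target_fraction * n_subjects)
    on_target <- logical(n_subjects)
    on_target[sample.int(n_subjects, k)] <- TRUE
    lesions <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      n_spheres <- sample(1:3, 1)
      radii <- exp(stats::runif(n_spheres, log(radius_range[1]),
                                log(radius_range[2])))
      mask <- rep(FALSE, nrow(centers))
      for (s in seq_len(n_spheres)) {
        if (s == 1 && on_target[i]) {
          ctr <- centerline[sample.int(nrow(centerline), 1), ] +
            stats::rnorm(3, sd = 1.5)
        } else {
          ctr <- stats::runif(3, 0, hi)
        }
        ctr <- pmin(pmax(ctr, radii[s] - spec$voxel_size / 2),
                    hi - radii[s] + spec$voxel_size / 2)
        d2 <- (centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2 +
          (centers[, 3] - ctr[3])^2
        mask <- mask | d2 <= radii[s]^2
      }
      vol <- image_volume(array(as.numeric(mask), dm), grid$affine)
      lesions[[i]] <- lesion_mask(vol, sprintf("sub%03d", i))
    }
    list(lesions = lesions, on_target = on_target)
  })
}

#' Generate the behavioral table with the planted effect
#'
#' Demographics are moment-matched to the study cohort (age N(66.3, 12.3)
#' truncated to 24-87; 25.5\% female; phase groups drawn with the cohort's
#' acute/subacute/chronic proportions via simulated onset intervals at the
#' 7/180-day thresholds). The cognitive score decreases with each subject's
#' true mean target disconnection; battery subtests are observed in a
#' random subsample.
#'
#' @param maps list of \code{disconnectome_map}, one per subject.
#' @param truth ground-truth list (needs \code{footprint_index}).
#' @param eff an \code{effect_spec}.
#' @param seed integer seed.
#' @return data.frame with subject_id, female, age, moca, group,
#'   onset_days and the battery columns (NA outside the subsample), plus
#'   attribute \code{"d"} (true mean target disconnection per subject).
#' @export
make_behavior <- function(maps, truth, eff, seed = 1) {
  stopifnot(inherits(eff, "effect_spec"))
  d <- vapply(maps, function(m) mean(m$volume$data[truth$footprint_index]),
              numeric(1))
  n <- length(d)
  with_seed(seed, {
    age <- round(pmin(87, pmax(24, stats::rnorm(n, 66.3, 12.3))), 1)
    female <- stats::rbinom(n, 1, 0.255)
    grp <- sample(c("acute", "subacute", "chronic"), n, replace = TRUE,
                  prob = c(20, 25, 57) / 102)
    onset_days <- ifelse(grp == "acute", sample(1:6, n, replace = TRUE),
                  ifelse(grp == "subacute", sample(7:180, n, replace = TRUE),
                         sample(181:1399, n, replace = TRUE)))
    moca <- pmin(30, pmax(0, round(eff$baseline - eff$beta * d +
                                     stats::rnorm(n, 0, eff$noise_sd))))
    tab <- data.frame(subject_id = vapply(maps, `[[`, character(1),
                                          "subject_id"),
                      female = female, age = age, moca = moca,
                      group = grp, onset_days = onset_days,
                      stringsAsFactors = FALSE)
    n_batt <- round(eff$subsample_fraction * n)
    has_batt <- logical(n)
    has_batt[sample.int(n, n_batt)] <- TRUE
    for (s in names(eff$battery_loadings)) {
      val <- round(eff$battery_baseline - eff$battery_loadings[[s]] * d +
                     stats::rnorm(n, 0, eff$battery_noise_sd), 2)
      val[!has_batt] <- NA_real_
      tab[[s]] <- val
    }
    attr(tab, "d") <- d
    tab
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs the whole generator: controls, lesions, per-subject disconnectome
#' maps, and behavior, and assembles the cohort table (behavior plus lesion
#' summaries). Fully deterministic from the master seed.
#'
#' @param seed master seed.
#' @param spec a \code{phantom_spec}.
#' @param eff an \code{effect_spec}.
#' @param n_subjects cohort size (study-shaped default 102).
#' @param on_target_fraction,radius_range lesion-placement parameters.
#' @param step streamline resampling step (default half a voxel edge).
#' @return List of class \code{synthetic_cohort}: grid, controls,
#'   footprints, lesions, maps, truth, cohort (data.frame), and the
#'   parameters used.
#' @export
simulate_cohort <- function(seed = 1, spec = phantom_spec(),
                            eff = effect_spec(), n_subjects = 102,
                            on_target_fraction = 0.35,
                            radius_range = c(2, 10), step = NULL) {
  ctl <- make_controls(spec, derive_seed(seed, "controls"))
  les <- make_lesions(spec, n_subjects, on_target_fraction, radius_range,
                      derive_seed(seed, "lesions"), eff$target_bundle)
  grid <- ctl$grid
  step <- step %||% default_step(grid)
  batch <- suppressWarnings(
    disconnectome_batch(les$lesions, ctl$controls, grid, step))
  if (length(batch$errors))
    stop("disconnectome failed for subject(s): ",
         paste(names(batch$errors), collapse = ", "))
  fp <- ctl$footprints[[eff$target_bundle]]
  truth <- list(footprint = fp, footprint_index = which(fp$data != 0),
                on_target = les$on_target, seed = seed)
  behavior <- make_behavior(batch$maps, truth, eff,
                            derive_seed(seed, "behavior"))
  truth$d <- attr(behavior, "d")
  sums <- lapply(les$lesions, lesion_summary)
  cohort <- cbind(behavior,
                  lesion_volume = vapply(sums, `[[`, numeric(1), "volume_mm3"),
                  lesion_voxels = vapply(sums, `[[`, numeric(1), "n_voxels"),
                  n_lesions = vapply(sums, `[[`, numeric(1), "n_components"))
  structure(list(grid = grid, controls = ctl$controls,
                 footprints = ctl$footprints, lesions = les$lesions,
                 maps = batch$maps, truth = truth, cohort = cohort,
                 spec = spec, eff = eff, seed = seed, step = step,
                 n_subjects = n_subjects,
                 on_target_fraction = on_target_fraction,
                 radius_range = radius_range),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Lesions as uncompressed NIfTI (uint8), controls as TCK, behavior as TSV,
#' ground truth and parameters as JSON, plus a manifest with MD5 hashes of
#' every file. A fresh run from the recorded seed reproduces all files
#' bit-exactly. On any failure, files written so far are removed.
#'
#' @param dir output directory (created if needed).
#' @param cohort a \code{synthetic_cohort}.
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(dir, cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  res <- tryCatch({
    dir.create(file.path(dir, "lesions"), showWarnings = FALSE)
    dir.create(file.path(dir, "controls"), showWarnings = FALSE)
    for (l in cohort$lesions) {
      p <- file.path(dir, "lesions", paste0(l$subject_id, "_lesion.nii"))
      write_volume(l$volume, p, datatype = "uint8")
      written <- c(written, p)
    }
    for (ctl in cohort$controls) {
      p <- file.path(dir, "controls", paste0(ctl$control_id, ".tck"))
      write_tck(ctl, p)
      written <- c(written, p)
    }
    p <- file.path(dir, "behavior.tsv")
    utils::write.table(cohort$cohort, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, p)
    p <- file.path(dir, "target_footprint.nii")
    write_volume(cohort$truth$footprint, p, datatype = "uint8")
    written <- c(written, p)
    gt <- list(seed = cohort$seed, d = cohort$truth$d,
               on_target = cohort$truth$on_target,
               footprint_index = cohort$truth$footprint_index,
               grid_shape = dim(cohort$grid$data),
               affine = cohort$grid$affine,
               step = cohort$step,
               n_subjects = cohort$n_subjects,
               on_target_fraction = cohort$on_target_fraction,
               radius_range = cohort$radius_range,
               effect = unclass(cohort$eff),
               phantom = unclass(cohort$spec))
    p <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(gt, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p)
    files <- sort(c(file.path("lesions",
                              vapply(cohort$lesions, function(l)
                                paste0(l$subject_id, "_lesion.nii"),
                                character(1))),
                    file.path("controls",
                              vapply(cohort$controls, function(ctl)
                                paste0(ctl$control_id, ".tck"), character(1))),
                    "behavior.tsv", "target_footprint.nii",
                    "ground_truth.json"))
    hashes <- unname(tools::md5sum(file.path(dir, files)))
    manifest <- list(seed = cohort$seed, n_subjects = cohort$n_subjects,
                     n_controls = length(cohort$controls),
                     files = as.list(stats::setNames(hashes, files)))
    p <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, p)
    manifest
  }, error = function(e) {
    unlink(written)
    stop("write_cohort failed (partial output removed): ",
         conditionMessage(e))
  })
  invisible(res)
}

#' Verify a written cohort against its manifest
#'
#' @param dir cohort directory containing \code{manifest.json}.
#' @return List with \code{ok} (logical) and \code{bad_files}.
#' @export
check_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  files <- names(manifest$files)
  actual <- unname(tools::md5sum(file.path(dir, files)))
  expected <- unlist(manifest$files)
  bad <- files[is.na(actual) | actual != expected]
  list(ok = length(bad) == 0, bad_files = bad)
}

#' Load a written cohort from disk
#'
#' Re-reads lesions, controls, behavior and ground truth as written by
#' \code{\link{write_cohort}} (disconnectome maps are recomputed
#' downstream, not stored).
#'
#' @param dir cohort directory.
#' @return List with lesions, controls, cohort table, truth and grid.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  files <- names(manifest$files)
  lesion_files <- sort(grep("^lesions/", files, value = TRUE))
  control_files <- sort(grep("^controls/", files, value = TRUE))
  lesions <- lapply(lesion_files, function(f) {
    vol <- read_volume(file.path(dir, f))
    lesion_mask(vol, sub("_lesion\\.nii$", "", basename(f)))
  })
  controls <- lapply(control_files, function(f)
    read_tractogram(file.path(dir, f)))
  cohort <- utils::read.table(file.path(dir, "behavior.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  fp <- read_volume(file.path(dir, "target_footprint.nii"))
  truth <- list(footprint = fp, footprint_index = which(fp$data != 0),
                d = gt$d, on_target = gt$on_target, seed = gt$seed)
  grid <- image_volume(array(0, dim(fp$data)), fp$affine)
  list(lesions = lesions, controls = controls, cohort = cohort,
       truth = truth, grid = grid, step = gt$step, manifest = manifest)
}
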