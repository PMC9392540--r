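test_that("controls are deterministic given the seed and degenerate without jitter", {
  spec <- tiny_spec(n_controls = 3)
  a <- make_controls(spec, seed = 7)
  b <- make_controls(spec, seed = 7)
  expect_identical(a$controls, b$controls)
  c2 <- make_controls(spec, seed = 8)
  expect_false(identical(a$controls[[1]]$streamlines,
                         c2$controls[[1]]$streamlines))

  # zero jitter: all controls identical, so disconnectomes are binary
  frozen <- phantom_spec(grid_shape = c(16, 16, 16), voxel_size = 2,
                         bundles = tiny_spec()$bundles, n_controls = 3,
                         jitter_control = 0, jitter_streamline = 0)
  fc <- make_controls(frozen, seed = 1)
  expect_identical(fc$controls[[1]]$streamlines,
                   fc$controls[[2]]$streamlines)
  les <- make_lesions(frozen, 1, on_target_fraction = 1,
                      radius_range = c(2, 4), seed = 2)
  d <- suppressWarnings(
    disconnectome_for_subject(les$lesions[[1]], fc$controls, fc$grid))
  expect_true(all(d$volume$data %in% c(0, 1)))
})

test_that("every control's bundle visitation overlaps the noise-free footprint", {
  spec <- tiny_spec(n_controls = 8)
  ctl <- make_controls(spec, seed = 9)
  fp <- ctl$footprints$target$data != 0
  n_target <- spec$bundles[[1]]$n_streamlines
  for (t in ctl$controls) {
    vm <- visitation_map(t$streamlines[seq_len(n_target)], ctl$grid)
    v <- vm$volume$data != 0
    dice <- 2 * sum(v & fp) / (sum(v) + sum(fp))
    expect_gt(dice, 0.5)
  }
})

test_that("phantom validation rejects bad geometry", {
  expect_error(phantom_spec(bundles = list(list(
    name = "thin", points = rbind(c(10, 10, 10), c(40, 10, 10)),
    radius = 0.5, n_streamlines = 3))), "radius")
  expect_error(phantom_spec(bundles = list(list(
    name = "out", points = rbind(c(0, 0, 0), c(70, 70, 70)),
    radius = 4, n_streamlines = 3))), "out")
})

test_that("lesion placement respects the on-target fraction", {
  spec <- tiny_spec(n_controls = 2)
  expect_length(make_lesions(spec, 0, seed = 1)$lesions, 0)

  les <- make_lesions(spec, 20, on_target_fraction = 1,
                      radius_range = c(3, 6), seed = 3)
  ctl <- make_controls(spec, seed = 4)
  for (l in les$lesions) {
    expect_gt(sum(l$volume$data), 0)
    # with radius >= tube radius, the lesion intersects target streamlines
    sel <- vapply(ctl$controls, function(t) {
      n_target <- spec$bundles[[1]]$n_streamlines
      sub <- t
      sub$streamlines <- t$streamlines[seq_len(n_target)]
      length(streamlines_through_mask(sub, l)$streamlines) > 0
    }, logical(1))
    expect_true(all(sel))
  }

  # off-target lesions leave target disconnection near background level
  off <- make_lesions(spec, 20, on_target_fraction = 0,
                      radius_range = c(2, 4), seed = 5)
  batch <- suppressWarnings(
    disconnectome_batch(off$lesions, ctl$controls, ctl$grid))
  fp_idx <- which(ctl$footprints$target$data != 0)
  d <- vapply(batch$maps, function(m) mean(m$volume$data[fp_idx]),
              numeric(1))
  expect_lt(mean(d), 0.15)
})

test_that("behavior generation plants a negative disconnection-cognition coupling", {
  spec <- tiny_spec(n_controls = 4)
  sim <- simulate_cohort(seed = 11, spec = spec, n_subjects = 40,
                         on_target_fraction = 0.5, radius_range = c(2, 5))
  d <- sim$truth$d
  expect_lt(cor(sim$cohort$moca, d), -0.4)
  expect_true(all(sim$cohort$moca >= 0 & sim$cohort$moca <= 30))
  expect_true(all(sim$cohort$moca == round(sim$cohort$moca)))
  # battery present for the stated subsample only
  n_batt <- sum(!is.na(sim$cohort$fluency_phonetic))
  expect_equal(n_batt, round(0.8 * 40))
  # group labels respect the onset-interval thresholds
  with(sim$cohort, {
    expect_true(all(onset_days[group == "acute"] < 7))
    expect_true(all(onset_days[group == "subacute"] %in% 7:180))
    expect_true(all(onset_days[group == "chronic"] > 180))
  })

  # beta = 0 decouples cognition from disconnection
  null_eff <- effect_spec(beta = 0)
  sim0 <- simulate_cohort(seed = 11, spec = spec, eff = null_eff,
                          n_subjects = 40, on_target_fraction = 0.5,
                          radius_range = c(2, 5))
  expect_lt(abs(cor(sim0$cohort$moca, sim0$truth$d)), 0.45)

  # zero noise, large beta: deterministic decreasing step function
  det_eff <- effect_spec(beta = 20, noise_sd = 0)
  simd <- simulate_cohort(seed = 12, spec = spec, n_subjects = 20,
                          eff = det_eff, on_target_fraction = 0.5,
                          radius_range = c(2, 5))
  expect_equal(simd$cohort$moca,
               pmin(30, pmax(0, round(28 - 20 * simd$truth$d))))
})

test_that("written cohorts are reproducible, complete and tamper-evident", {
  spec <- tiny_spec(n_controls = 3)
  sim <- simulate_cohort(seed = 13, spec = spec, n_subjects = 5,
                         on_target_fraction = 0.5, radius_range = c(2, 4))
  d1 <- file.path(withr::local_tempdir(), "c1")
  d2 <- file.path(withr::local_tempdir(), "c2")
  m1 <- write_cohort(d1, sim)
  sim2 <- simulate_cohort(seed = 13, spec = spec, n_subjects = 5,
                          on_target_fraction = 0.5, radius_range = c(2, 4))
  m2 <- write_cohort(d2, sim2)
  expect_identical(m1$files, m2$files)  # bit-identical regeneration

  # manifest covers one lesion per subject plus controls and tables
  expect_equal(sum(grepl("^lesions/", names(m1$files))), 5)
  expect_equal(sum(grepl("^controls/", names(m1$files))), 3)
  expect_true(check_cohort(d1)$ok)

  # round-trip load preserves the cohort table and lesions
  back <- read_cohort(d1)
  expect_equal(back$cohort$moca, sim$cohort$moca)
  expect_equal(length(back$lesions), 5)
  expect_equal(back$lesions[[2]]$volume$data,
               sim$lesions[[2]]$volume$data)
  expect_equal(back$truth$d, sim$truth$d, tolerance = 1e-12)

  # tampering is detected
  tsv <- file.path(d1, "behavior.tsv")
  writeLines(c(readLines(tsv), "tampered"), tsv)
  chk <- check_cohort(d1)
  expect_false(chk$ok)
  expect_equal(chk$bad_files, "behavior.tsv")
})
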