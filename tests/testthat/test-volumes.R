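test_that("NIfTI round-trip preserves data and affine", {
  dir <- withr::local_tempdir()
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, 4, 8)
  vol <- image_volume(array(1, c(4, 4, 4)), aff)
  p <- file.path(dir, "ones.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_equal(back$data, vol$data)
  expect_equal(back$affine, aff, tolerance = 1e-5)

  # integer mask: nonzero count preserved exactly through uint8 storage
  a <- array(0, c(6, 5, 4))
  a[sample.int(120, 17)] <- 1
  m <- image_volume(a, aff)
  p2 <- file.path(dir, "mask.nii")
  write_volume(m, p2, datatype = "uint8")
  expect_identical(sum(read_volume(p2)$data != 0), 17L)

  # float probability map at stored (float32) precision
  set.seed(1)
  pm <- image_volume(array(runif(64), c(4, 4, 4)), aff)
  p3 <- file.path(dir, "prob.nii")
  write_volume(pm, p3, datatype = "float")
  expect_lt(max(abs(read_volume(p3)$data - pm$data)), 1e-6)
})

test_that("read_volume rejects missing files and 4D input", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "exist")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "v4d.nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), p)
  expect_error(read_volume(p), "4D")
  expect_error(write_volume(image_volume(array(0, c(2, 2, 2))),
                            file.path(dir, "no/such/dir/x.nii")),
               "directory")
})

test_that("voxel volume is the affine block determinant", {
  vol <- image_volume(array(0, c(3, 3, 3)), diag(c(2, 2, 2, 1)))
  expect_equal(voxel_volume(vol), 8)
  expect_error(image_volume(array(0, c(3, 3, 3)), matrix(0, 4, 4)),
               "invertible")
})

test_that("world_to_voxel rounds half away from zero", {
  id <- image_volume(array(0, c(4, 4, 4)), diag(4))
  expect_equal(world_to_voxel(c(0, 0, 0), id), c(0L, 0L, 0L))
  expect_equal(world_to_voxel(c(-1, -1, -1), id), c(-1L, -1L, -1L))
  g2 <- image_volume(array(0, c(4, 4, 4)), diag(c(2, 2, 2, 1)))
  # 3.9 / 2 = 1.95 -> 2
  expect_equal(world_to_voxel(c(3.9, 0, 0), g2), c(2L, 0L, 0L))
  # half-away-from-zero on both sides
  expect_equal(world_to_voxel(c(1, -1, 3), g2), c(1L, -1L, 2L))
  # inverse of voxel_to_world on a lattice
  ijk <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  expect_equal(world_to_voxel(voxel_to_world(ijk, g2), g2),
               matrix(as.integer(ijk), ncol = 3))
})

test_that("mask resampling is nearest-neighbour and binary", {
  g <- make_grid(c(8, 8, 8), 2)
  m <- mask_at(g, rbind(c(2, 3, 4), c(3, 3, 4)))
  # identity transform on the same grid is the identity
  out <- apply_affine_to_mask(m, diag(4), g)
  expect_equal(out$volume$data, m$volume$data)

  # translation by one voxel width shifts indices by one
  tr <- diag(4); tr[1, 4] <- 2
  sh <- apply_affine_to_mask(m, tr, g)
  expect_equal(which(sh$volume$data != 0) - 1, which(m$volume$data != 0))

  # 2x downsampling of a 2x2x2-voxel cube leaves one voxel
  cube <- mask_at(g, as.matrix(expand.grid(0:1, 0:1, 0:1)))
  coarse <- image_volume(array(0, c(4, 4, 4)), diag(c(4, 4, 4, 1)))
  down <- suppressWarnings(apply_affine_to_mask(cube, diag(4), coarse))
  expect_equal(sum(down$volume$data), 1)
  expect_true(all(down$volume$data %in% c(0, 1)))

  # transform pushing the mask off-grid yields an empty mask with a warning
  far <- diag(4); far[1, 4] <- 1000
  expect_warning(apply_affine_to_mask(m, far, g), "empty")
})

test_that("lesion_summary counts voxels, volume and 26-connected components", {
  g <- make_grid(c(8, 8, 8), 2)
  m5 <- mask_at(g, rbind(c(1, 1, 1), c(1, 2, 1), c(1, 3, 1), c(5, 5, 5),
                         c(5, 5, 6)))
  s <- lesion_summary(m5)
  expect_equal(s$n_voxels, 5L)
  expect_equal(s$volume_mm3, 40)
  expect_equal(s$n_components, 2L)

  # diagonal-touching pair is one component under 26-connectivity
  diagpair <- mask_at(g, rbind(c(2, 2, 2), c(3, 3, 3)))
  expect_equal(lesion_summary(diagpair)$n_components, 1L)

  # duplicating a mask into disjoint space doubles the voxel count
  dup <- mask_at(g, rbind(c(1, 1, 1), c(1, 2, 1), c(6, 6, 6), c(6, 7, 6)))
  expect_equal(lesion_summary(dup)$n_voxels,
               2L * lesion_summary(mask_at(g, rbind(c(1, 1, 1),
                                                    c(1, 2, 1))))$n_voxels)

  empty <- suppressWarnings(lesion_mask(image_volume(array(0, c(4, 4, 4))),
                                        "e"))
  expect_equal(lesion_summary(empty),
               list(n_voxels = 0L, volume_mm3 = 0, n_components = 0L))
  expect_error(lesion_mask(image_volume(array(0.5, c(2, 2, 2))), "x"),
               "binary")
})
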