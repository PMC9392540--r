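test_that("column z-scoring has mean 0 and sample SD 1", {
  expect_equal(as.vector(zscore_columns(matrix(1:3))), c(-1, 0, 1))
  set.seed(6)
  M <- matrix(rnorm(200, 5, 3), 20, 10)
  Z <- zscore_columns(M)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-12)
  # idempotence
  expect_equal(zscore_columns(Z), Z, tolerance = 1e-12)
  expect_error(zscore_columns(cbind(1:5, rep(2, 5))), "constant")
})

test_that("analysis mask keeps voxels that are nonzero and variable", {
  g <- make_grid(c(4, 4, 4), 2)
  mk <- function(a) {
    vol <- image_volume(array(a, c(4, 4, 4)), g$affine)
    structure(list(volume = vol, subject_id = "s", n_controls = 2L),
              class = "disconnectome_map")
  }
  same <- array(0, c(4, 4, 4)); same[1:5] <- 0.5
  expect_error(build_analysis_mask(list(mk(same), mk(same))), "empty")
  b <- same; b[7] <- 0.5
  expect_equal(build_analysis_mask(list(mk(same), mk(b))), 7L)
  # oracle: brute-force variance scan on a random stack
  set.seed(7)
  maps <- lapply(1:6, function(i)
    mk(round(array(runif(64), c(4, 4, 4)) * 2) / 4))
  got <- build_analysis_mask(maps)
  X <- sapply(maps, function(m) as.vector(m$volume$data))
  want <- which(apply(X, 1, function(r) any(r != 0) && var(r) > 0))
  expect_equal(got, want)
})

test_that("identity contrasts make saliences equal mass-univariate correlations", {
  set.seed(8)
  n <- 40
  X <- matrix(rnorm(n * 120), n)
  Y <- cbind(female = rbinom(n, 1, 0.3), age = rnorm(n, 66, 12),
             moca = sample(15:30, n, replace = TRUE))
  fit <- nonrotated_pls(X, Y, "identity")
  for (k in 1:3) {
    r_oracle <- as.vector(cor(Y[, k], X))
    expect_lt(max(abs(fit$salience[, k] - r_oracle)), 1e-10)
  }
  expect_equal(fit$strength, sqrt(colSums(fit$salience^2)))
})

test_that("replicated-behavior construction gives the closed-form solution", {
  set.seed(9)
  y <- rnorm(12)
  X <- matrix(rep(y, 10), ncol = 10)
  fit <- nonrotated_pls(X, matrix(y), matrix(1))
  expect_equal(as.vector(fit$salience), rep(1, 10), tolerance = 1e-12)
  expect_equal(fit$strength, sqrt(10), tolerance = 1e-12)
  expect_equal(cor(fit$brain_scores[, 1], y), 1, tolerance = 1e-12)
})

test_that("behavior scaling does not change PLS outputs", {
  set.seed(10)
  X <- matrix(rnorm(30 * 50), 30)
  Y <- cbind(a = rnorm(30), b = rnorm(30, 100, 20))
  f1 <- nonrotated_pls(X, Y)
  Y2 <- Y; Y2[, 2] <- Y2[, 2] * 1000
  f2 <- nonrotated_pls(X, Y2)
  expect_equal(f1$salience, f2$salience, tolerance = 1e-12)
  expect_equal(f1$brain_scores, f2$brain_scores, tolerance = 1e-12)
})

test_that("permutation p-values behave at the extremes and are deterministic", {
  set.seed(11)
  n <- 30
  y <- rnorm(n)
  X <- matrix(rep(y, 40), ncol = 40) + matrix(rnorm(n * 40, 0, 0.01), n)
  Y <- cbind(effect = y, noise = rnorm(n))
  p <- permutation_test(X, Y, n_perm = 1000, seed = 5)
  expect_equal(p$perm_p[1], 1 / 1001)  # no permutation beats a huge effect

  p1 <- permutation_test(X, Y, n_perm = 1, seed = 5)
  expect_true(p1$perm_p[2] %in% c(1 / 2, 1))

  pa <- permutation_test(X, Y, n_perm = 200, seed = 9)
  pb <- permutation_test(X, Y, n_perm = 200, seed = 9)
  expect_identical(pa$perm_p, pb$perm_p)
  expect_false(identical(pa$perm_p,
                         permutation_test(X, Y, n_perm = 200,
                                          seed = 10)$perm_p))
})

test_that("bootstrap ratios flag degenerate SEs and recover a planted effect", {
  set.seed(12)
  n <- 30
  y <- rnorm(n)
  X <- cbind(matrix(rep(y, 5), ncol = 5) + matrix(rnorm(n * 5, 0, 0.05), n),
             matrix(rnorm(n * 45), n))
  Y <- cbind(effect = y, noise = rnorm(n))
  b <- bootstrap_ratios(X, Y, n_boot = 200, seed = 13)
  expect_true(all(b$bsr[1:5, 1] > 3))        # true footprint reliable
  expect_equal(dim(b$boot_se), c(50L, 2L))
  expect_identical(b$bsr,
                   bootstrap_ratios(X, Y, n_boot = 200, seed = 13)$bsr)

  # two identical degenerate draws: SE 0, ratio flagged as 0
  X1 <- matrix(rnorm(8), 4, 2)
  Y1 <- matrix(rnorm(4))
  found <- FALSE
  for (s in 1:200) {
    bb <- try(bootstrap_ratios(X1, Y1, n_boot = 2, seed = s), silent = TRUE)
    if (!inherits(bb, "try-error") && any(bb$zero_se)) {
      expect_true(all(bb$bsr[bb$zero_se] == 0))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("null bootstrap-ratio tails are near the nominal normal rate", {
  set.seed(14)
  n <- 60
  X <- matrix(rnorm(n * 800), n)
  Y <- cbind(a = rnorm(n), b = rnorm(n))
  b <- bootstrap_ratios(X, Y, n_boot = 200, seed = 15)
  rate <- mean(abs(b$bsr) > 3)
  # nominal two-sided N(0,1) tail beyond 3 is ~0.0027; allow generous
  # binomial + bootstrap-approximation slack on 1600 voxel-contrast cells
  expect_lt(rate, 0.02)
})

test_that("salience_to_volume scatters onto the mask and round-trips", {
  g <- make_grid(c(4, 4, 4), 2)
  mask_index <- c(3L, 17L, 42L)
  v <- salience_to_volume(c(1, 2, 3), mask_index, g)
  expect_equal(as.vector(v$data[mask_index]), c(1, 2, 3))
  expect_equal(sum(v$data != 0), 3)
  expect_equal(as.vector(v$data)[mask_index], c(1, 2, 3))
  expect_error(salience_to_volume(1:2, mask_index, g), "length")
  z <- salience_to_volume(rep(0, 3), mask_index, g)
  expect_equal(sum(z$data != 0), 0)
})

test_that("full PLS wrapper drops incomplete subjects and is reproducible", {
  spec <- tiny_spec(n_controls = 4)
  sim <- simulate_cohort(seed = 5, spec = spec, n_subjects = 14,
                         on_target_fraction = 0.5, radius_range = c(2, 5))
  beh <- sim$cohort
  beh$moca[3] <- NA
  expect_message(
    fit <- pls_brain_behavior(sim$maps, beh, n_perm = 50, n_boot = 50,
                              seed = 2),
    "dropping 1")
  expect_equal(fit$n, 13)
  fit2 <- suppressMessages(
    pls_brain_behavior(sim$maps, beh, n_perm = 50, n_boot = 50, seed = 2))
  expect_identical(fit$perm_p, fit2$perm_p)
  expect_identical(fit$bsr, fit2$bsr)
})
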