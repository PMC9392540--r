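make_tab <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%02d", 1:n),
    moca = pmin(30, pmax(0, round(rnorm(n, 26, 3)))),
    group = sample(c("acute", "subacute", "chronic"), n, replace = TRUE),
    lesion_volume = exp(rnorm(n, 6, 0.7)),
    n_lesions = sample(1:5, n, replace = TRUE))
}

test_that("group model matches the one-way ANOVA oracle", {
  tab <- make_tab(90, 2)
  fit <- fit_group_model(tab)
  g <- factor(tab$group, levels = c("acute", "subacute", "chronic"))
  # textbook one-way ANOVA F
  gm <- tapply(tab$moca, g, mean)
  ng <- tapply(tab$moca, g, length)
  ssb <- sum(ng * (gm - mean(tab$moca))^2)
  ssw <- sum((tab$moca - gm[g])^2)
  Fo <- (ssb / 2) / (ssw / (nrow(tab) - 3))
  expect_equal(fit$F, Fo, tolerance = 1e-10)
  expect_equal(fit$df_residual, nrow(tab) - 3)
  expect_equal(names(fit$coefficients)[1], "(Intercept)")

  expect_error(fit_group_model(within(tab, group <- "acute")), "2 phase")

  # equal group means: F = 0 (within-group spread only)
  flat <- data.frame(
    moca = rep(c(19, 21), 6),
    group = rep(c("acute", "subacute", "chronic"), each = 4))
  expect_lt(fit_group_model(flat)$F, 1e-20)

  # zero residual variance is flagged degenerate
  det_tab <- tab
  det_tab$moca <- c(20, 26, 23)[as.integer(g)]
  f3 <- suppressWarnings(fit_group_model(det_tab))
  expect_true(f3$degenerate)
})

test_that("lesion-load model matches the normal-equations oracle", {
  tab <- make_tab(50, 3)
  fit <- fit_lesionload_model(tab)
  o <- oracle_ols(cbind(1, tab$lesion_volume, tab$n_lesions), tab$moca)
  expect_equal(unname(fit$coefficients), o$beta, tolerance = 1e-8)
  expect_equal(unname(fit$t), o$t, tolerance = 1e-8)
  expect_equal(unname(fit$p), o$p, tolerance = 1e-8)

  # hand-computable 5-row table
  small <- data.frame(moca = c(30, 28, 25, 22, 20),
                      lesion_volume = c(1, 2, 3, 4, 5),
                      n_lesions = c(1, 1, 2, 2, 3))
  fs <- fit_lesionload_model(small)
  os <- oracle_ols(cbind(1, small$lesion_volume, small$n_lesions),
                   small$moca)
  expect_equal(unname(fs$coefficients), os$beta, tolerance = 1e-10)

  # exact linear dependence on volume: R^2 = 1, degenerate flag
  ex <- tab
  ex$moca <- -0.001 * ex$lesion_volume
  fe <- suppressWarnings(fit_lesionload_model(ex))
  expect_equal(fe$r_squared, 1, tolerance = 1e-8)
  expect_true(fe$degenerate)

  # collinear regressors are flagged
  col <- tab
  col$n_lesions <- col$lesion_volume * 2
  expect_true(fit_lesionload_model(col)$collinear)
})

test_that("null simulation keeps lesion-load t statistics small on average", {
  set.seed(4)
  ps <- replicate(40, {
    tab <- make_tab(40, sample.int(1e6, 1))
    fit_lesionload_model(tab)$p[["lesion_volume"]]
  })
  expect_gt(mean(ps < 0.05), -1)           # guard: all defined
  expect_lt(mean(ps < 0.05), 0.25)         # near-nominal false positives
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("outlier rule flags extreme lesion volumes and refits", {
  tab <- make_tab(80, 5)
  sens <- outlier_sensitivity(tab)
  expect_length(sens$flagged, 0)
  expect_identical(sens$with$coefficients, sens$without$coefficients)

  # one planted extreme-volume subject drives the association
  tab2 <- make_tab(80, 6)
  tab2$lesion_volume <- exp(rnorm(80, 6, 0.2))
  tab2$lesion_volume[1] <- exp(6) * 30
  tab2$moca[1] <- 10
  sens2 <- outlier_sensitivity(tab2)
  expect_equal(sens2$flagged_rows, 1L)
  expect_gt(abs(sens2$with$t[["lesion_volume"]]),
            abs(sens2$without$t[["lesion_volume"]]))

  # two equal extreme volumes: both flagged
  tab3 <- tab2
  tab3$lesion_volume[2] <- tab3$lesion_volume[1]
  expect_setequal(outlier_sensitivity(tab3)$flagged_rows, c(1L, 2L))

  # a rule that flags too many subjects errors
  expect_error(outlier_sensitivity(tab2, z_thresh = 0.1), "10%")
})

test_that("brain-score association matches generic OLS and drops missing", {
  tab <- make_tab(60, 7)
  tab$brain_score <- 0.002 * tab$lesion_volume + rnorm(60, 0, 0.5)
  res <- brainscore_lesion_assoc(tab)
  o <- oracle_ols(cbind(1, tab$lesion_volume), tab$brain_score)
  expect_equal(unname(res$with$coefficients), o$beta, tolerance = 1e-8)

  tab$brain_score[5] <- NA
  expect_message(res2 <- brainscore_lesion_assoc(tab), "dropping 1")
  expect_equal(res2$with$n, 59)

  # perfect proportionality: R^2 = 1
  tab$brain_score <- 0.01 * tab$lesion_volume
  res3 <- suppressWarnings(suppressMessages(brainscore_lesion_assoc(tab)))
  expect_equal(res3$with$r_squared, 1, tolerance = 1e-10)
})

test_that("impairment rate uses the strict below-cutoff convention", {
  expect_equal(impairment_rate(data.frame(moca = rep(30, 5)))$rate, 0)
  expect_equal(impairment_rate(data.frame(moca = c(25, 26, 27)))$rate, 1 / 3)
  tab <- data.frame(moca = c(20, 23, 25, 26, 28, 30))
  # monotone nonincreasing in the cutoff
  rates <- sapply(c(31, 28, 26, 24, 20, 15),
                  function(cc) impairment_rate(tab, cc)$rate)
  expect_true(all(diff(rates) <= 0))
  # invariant to subject order
  expect_equal(impairment_rate(tab[sample.int(6), , drop = FALSE])$rate,
               impairment_rate(tab)$rate)
})
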