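# Auxiliary cohort-level linear models and summaries: phase-group effect on
# MoCA, lesion-load effect, outlier-sensitivity refits, brain-score vs
# lesion-size association, and the impairment rate at the conventional
# MoCA cutoff.

linear_fit <- function(fit, label, n) {
  sm <- summary(fit)
  co <- stats::coef(sm)
  # overall F of the model (single-factor model: the group-factor F)
  fstat <- sm$fstatistic
  degenerate <- !is.null(fstat) && !is.finite(fstat[1])
  rss <- sum(stats::residuals(fit)^2)
  if (rss <= .Machine$double.eps * sum(fit$model[[1]]^2)) degenerate <- TRUE
  structure(list(
    label = label,
    coefficients = co[, "Estimate"],
    se = co[, "Std. Error"],
    t = co[, "t value"],
    p = co[, "Pr(>|t|)"],
    F = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    F_p = if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    r_squared = sm$r.squared,
    df_residual = fit$df.residual,
    n = n,
    degenerate = degenerate,
    lm = fit), class = "lesion_fit")
}

#' @export
print.lesion_fit <- function(x, ...) {
  cat("<lesion_fit> ", x$label, " (n = ", x$n, ")\n", sep = "")
  print(cbind(estimate = x$coefficients, se = x$se, t = x$t, p = x$p))
  if (is.finite(x$F))
    cat("F =", format(x$F, digits = 4), ", p =", format(x$F_p, digits = 3),
        ", R^2 =", format(x$r_squared, digits = 3), "\n")
  if (x$degenerate) cat("NOTE: degenerate fit (zero residual variance)\n")
  invisible(x)
}

check_cohort_table <- function(tab, need) {
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  invisible(TRUE)
}

#' Phase-group effect on MoCA
#'
#' OLS of MoCA on the 3-level recovery-phase factor (acute < 7 days,
#' subacute 7-180 days, chronic > 180 days since stroke), reference level
#' acute; the overall F-test for the group factor is reported. Empty groups
#' are dropped with a message.
#'
#' @param tab cohort data.frame with columns \code{moca} and \code{group}.
#' @return A \code{lesion_fit}.
#' @export
fit_group_model <- function(tab) {
  check_cohort_table(tab, c("moca", "group"))
  lv <- c("acute", "subacute", "chronic")
  g <- factor(as.character(tab$group), levels = lv)
  if (any(is.na(g))) stop("unknown group label(s): ",
                          paste(unique(tab$group[is.na(g)]), collapse = ", "))
  present <- lv[lv %in% unique(as.character(g))]
  if (length(present) < 2) stop("need at least 2 phase groups")
  if (length(present) < 3)
    message("dropping empty group(s): ",
            paste(setdiff(lv, present), collapse = ", "))
  g <- factor(as.character(g), levels = present)
  d <- data.frame(moca = tab$moca, group = g)
  if (nrow(d) <= length(present)) stop("too few subjects for the group model")
  linear_fit(stats::lm(moca ~ group, data = d), "moca ~ group", nrow(d))
}

#' Lesion-load effect on MoCA
#'
#' OLS of MoCA on total lesion volume and number of lesions, with
#' per-coefficient t statistics and p-values. Near-collinear regressors are
#' flagged via the design-matrix condition number.
#'
#' @param tab cohort data.frame with columns \code{moca},
#'   \code{lesion_volume} and \code{n_lesions}.
#' @return A \code{lesion_fit} (field \code{collinear} set if the condition
#'   number exceeds 1e8).
#' @export
fit_lesionload_model <- function(tab) {
  check_cohort_table(tab, c("moca", "lesion_volume", "n_lesions"))
  d <- data.frame(moca = tab$moca, lesion_volume = tab$lesion_volume,
                  n_lesions = tab$n_lesions)
  if (nrow(d) <= 3) stop("need more than 3 subjects")
  fit <- stats::lm(moca ~ lesion_volume + n_lesions, data = d)
  out <- linear_fit(fit, "moca ~ lesion_volume + n_lesions", nrow(d))
  out$collinear <- kappa(stats::model.matrix(fit), exact = TRUE) > 1e8
  out
}

#' Flag extreme-lesion subjects and refit with and without them
#'
#' The paper-style sensitivity check made explicit: subjects whose
#' log-lesion-volume z-score exceeds \code{z_thresh} are flagged (all of
#' them, not "exactly one") and the lesion-load model is fit both with and
#' without them.
#'
#' @param tab cohort data.frame (see \code{\link{fit_lesionload_model}}).
#' @param z_thresh flagging threshold on the log-volume z-score (default 4).
#' @return List with \code{flagged} (subject ids or row indices),
#'   \code{with} and \code{without} fits (identical when nothing is
#'   flagged). Errors if the rule flags more than 10\% of subjects.
#' @export
outlier_sensitivity <- function(tab, z_thresh = 4) {
  check_cohort_table(tab, c("moca", "lesion_volume", "n_lesions"))
  lv <- log(tab$lesion_volume)
  z <- (lv - mean(lv)) / stats::sd(lv)
  flagged <- which(!is.na(z) & z > z_thresh)
  if (length(flagged) > 0.1 * nrow(tab))
    stop("outlier rule flags more than 10% of subjects (",
         length(flagged), "/", nrow(tab), ")")
  ids <- if ("subject_id" %in% names(tab)) tab$subject_id[flagged] else flagged
  with_fit <- fit_lesionload_model(tab)
  without_fit <- if (length(flagged))
    fit_lesionload_model(tab[-flagged, , drop = FALSE]) else with_fit
  list(flagged = ids, flagged_rows = flagged,
       with = with_fit, without = without_fit)
}

#' Association between PLS brain scores and lesion volume
#'
#' OLS of the subject brain score on total lesion volume, reported both for
#' the full sample and with extreme-lesion subjects (log-volume z > 4)
#' removed. Subjects with missing brain scores are dropped with a message.
#'
#' @param tab cohort data.frame with columns \code{brain_score} and
#'   \code{lesion_volume}.
#' @return List with \code{with}, \code{without} fits and \code{flagged}.
#' @export
brainscore_lesion_assoc <- function(tab) {
  check_cohort_table(tab, c("brain_score", "lesion_volume"))
  ok <- is.finite(tab$brain_score) & is.finite(tab$lesion_volume)
  if (!all(ok)) message("dropping ", sum(!ok),
                        " subject(s) with missing brain score")
  d <- tab[ok, , drop = FALSE]
  if (nrow(d) <= 2) stop("too few subjects with brain scores")
  fit1 <- linear_fit(stats::lm(brain_score ~ lesion_volume, data = d),
                     "brain_score ~ lesion_volume", nrow(d))
  lv <- log(d$lesion_volume)
  z <- (lv - mean(lv)) / stats::sd(lv)
  flagged <- which(!is.na(z) & z > 4)
  fit2 <- if (length(flagged))
    linear_fit(stats::lm(brain_score ~ lesion_volume,
                         data = d[-flagged, , drop = FALSE]),
               "brain_score ~ lesion_volume (outliers removed)",
               nrow(d) - length(flagged))
  else fit1
  list(with = fit1, without = fit2, flagged = flagged)
}

#' Proportion of subjects below the cognitive-impairment cutoff
#'
#' The conventional MoCA rule: a subject is counted as impaired iff the
#' score is strictly below the cutoff (at the default 26, a score of 25
#' counts, 26 does not).
#'
#' @param tab cohort data.frame with column \code{moca}.
#' @param cutoff impairment cutoff (default 26).
#' @return List with \code{rate}, \code{n_impaired}, \code{n}.
#' @export
impairment_rate <- function(tab, cutoff = 26) {
  check_cohort_table(tab, "moca")
  m <- tab$moca[is.finite(tab$moca)]
  list(rate = mean(m < cutoff), n_impaired = sum(m < cutoff), n = length(m))
}
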