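#' Paired t-test on tumor vs healthy margin scores
#'
#' Tests whether the per-patient difference `pms_tumor - pms_healthy` has
#' mean zero, with the usual paired t statistic
#' `t = mean(d) / (sd(d) / sqrt(n))` (sample SD, `n - 1` denominator) and a
#' two-sided p-value on `n - 1` degrees of freedom. Degenerate inputs where
#' every difference is identical are reported rather than erroring: p = 0
#' with infinite t for a nonzero common difference, t = 0 and p = 1 when all
#' differences are zero, both flagged `degenerate`.
#'
#' @param pairs data frame with one row per patient and numeric columns
#'   `pms_tumor` and `pms_healthy`.
#' @return A `pms_ttest`: list with `t`, `df`, `p`, `mean_diff`, `n`,
#'   `degenerate`.
#' @export
#' @examples
#' paired_t_test(tibble::tibble(pms_tumor = c(1, 2, 3), pms_healthy = c(2, 4, 9)))
paired_t_test <- function(pairs) {
  if (!all(c("pms_tumor", "pms_healthy") %in% names(pairs))) {
    stop_pms("pairs must have columns pms_tumor and pms_healthy", "stats")
  }
  x <- pairs$pms_tumor; y <- pairs$pms_healthy
  n <- length(x)
  if (n < 2L) stop_pms("paired t-test needs at least 2 pairs", "stats")
  d <- x - y
  out <- list(mean_diff = mean(d), n = n, df = n - 1L, degenerate = FALSE)
  if (sd(d) == 0) {
    out$degenerate <- TRUE
    if (mean(d) == 0) {
      out$t <- 0; out$p <- 1
    } else {
      out$t <- sign(mean(d)) * Inf; out$p <- 0
    }
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    out$t <- unname(tt$statistic)
    out$p <- tt$p.value
  }
  structure(out, class = "pms_ttest")
}

#' @export
print.pms_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4g, df = %d, p = %.4g, mean diff = %.4g px%s\n",
              x$t, x$df, x$p, x$mean_diff,
              if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' @export
tidy.pms_ttest <- function(x, ...) {
  tibble::tibble(estimate = x$mean_diff, statistic = x$t, p.value = x$p,
                 parameter = x$df, n = x$n, degenerate = x$degenerate,
                 method = "paired t-test", alternative = "two.sided")
}

#' @export
glance.pms_ttest <- function(x, ...) tidy(x)

#' ROC analysis of margin scores
#'
#' Cancer is the positive class and is predicted by LOW scores (the tumor
#' group sits below the healthy group), so at a cutoff `t` sensitivity is the
#' fraction of cancer scores strictly below `t` and specificity the fraction
#' of healthy scores at or above `t`. Candidate cutoffs are the midpoints
#' between adjacent distinct pooled scores plus infinite sentinels, and the
#' area under the curve is the trapezoidal integral of sensitivity against
#' `1 - specificity` — which equals the Mann-Whitney estimate of
#' P(healthy > cancer) with ties counted half.
#'
#' @param scores_cancer,scores_healthy numeric vectors of margin scores, px.
#' @return A `pms_roc`: list with a `curve` tibble (`threshold`, `sens`,
#'   `spec`), `auc`, and the Youden-optimal `threshold`, `sens`, `spec`.
#' @export
#' @examples
#' roc_curve(c(0.4, 0.5, 0.7, 1.1), c(1.0, 1.3, 0.9, 1.6))$auc
roc_curve <- function(scores_cancer, scores_healthy) {
  if (length(scores_cancer) == 0L || length(scores_healthy) == 0L) {
    stop_pms("both score vectors must be non-empty", "stats")
  }
  pooled <- sort(unique(c(scores_cancer, scores_healthy)))
  mids <- if (length(pooled) > 1L) (head(pooled, -1) + tail(pooled, -1)) / 2 else numeric(0)
  thresholds <- c(-Inf, mids, Inf)
  sens <- vapply(thresholds, function(t) mean(scores_cancer < t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(scores_healthy >= t), numeric(1))

  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (head(sens[ord], -1) + tail(sens[ord], -1)) / 2)

  j <- sens + spec - 1
  best <- which(j == max(j))[1L]  # thresholds ascending: ties toward smallest
  structure(list(
    curve = tibble::tibble(threshold = thresholds, sens = sens, spec = spec),
    auc = auc,
    youden_threshold = thresholds[best],
    youden_sens = sens[best],
    youden_spec = spec[best],
    n_cancer = length(scores_cancer),
    n_healthy = length(scores_healthy)
  ), class = "pms_roc")
}

#' @export
print.pms_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d cancer vs %d healthy)\n", x$auc,
              x$n_cancer, x$n_healthy))
  cat(sprintf("Youden threshold = %.4g px (sens %.3f, spec %.3f)\n",
              x$youden_threshold, x$youden_sens, x$youden_spec))
  invisible(x)
}

#' @export
tidy.pms_roc <- function(x, ...) x$curve

#' @export
glance.pms_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, youden_threshold = x$youden_threshold,
                 youden_sens = x$youden_sens, youden_spec = x$youden_spec,
                 n_cancer = x$n_cancer, n_healthy = x$n_healthy)
}

#' Youden-optimal operating point
#'
#' Returns the cutoff maximizing Youden's J = sens + spec - 1, ties broken
#' toward the smallest threshold. With perfectly separated groups the
#' midpoint of the separating gap is returned (it is the only candidate
#' reaching J = 1).
#'
#' @param roc a `pms_roc` from [roc_curve()].
#' @return A list `threshold`, `sens`, `spec`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "pms_roc"))
  list(threshold = roc$youden_threshold, sens = roc$youden_sens,
       spec = roc$youden_spec)
}

#' Full study summary for a paired cohort
#'
#' Mirrors the structure of a paired margin-score study report: group
#' mean +/- sample SD for each arm, the paired t-test, the ROC analysis with
#' AUROC and Youden operating point, and the confusion table of
#' [classify_pms()] at the chosen threshold.
#'
#' @param pairs data frame with columns `pms_tumor`, `pms_healthy` (e.g. from
#'   [score_cohort()] or [score_manifest()]).
#' @param threshold decision threshold in px; default `NULL` uses the cohort's
#'   own Youden-optimal cutoff.
#' @return A `pms_cohort_report` list: `groups` tibble, `ttest`, `roc`,
#'   `threshold`, `confusion` tibble.
#' @export
cohort_report <- function(pairs, threshold = NULL) {
  pairs <- pairs[stats::complete.cases(pairs[, c("pms_tumor", "pms_healthy")]), ]
  if (nrow(pairs) < 2L) stop_pms("cohort_report needs at least 2 complete pairs", "stats")
  groups <- tibble::tibble(
    group = c("tumor", "healthy"),
    n = nrow(pairs),
    mean_pms = c(mean(pairs$pms_tumor), mean(pairs$pms_healthy)),
    sd_pms = c(sd(pairs$pms_tumor), sd(pairs$pms_healthy)),
    median_pms = c(stats::median(pairs$pms_tumor), stats::median(pairs$pms_healthy))
  )
  ttest <- paired_t_test(pairs)
  roc <- roc_curve(pairs$pms_tumor, pairs$pms_healthy)
  threshold <- threshold %||% roc$youden_threshold
  # a fully non-discriminating cohort has no usable cutoff (Youden J = 0
  # everywhere, tie-broken to -Inf); report without a confusion table
  confusion <- NULL
  if (is.finite(threshold) && threshold > 0) {
    scores <- c(pairs$pms_tumor, pairs$pms_healthy)
    actual <- rep(c("cancer", "healthy"), each = nrow(pairs))
    predicted <- classify_pms(scores, threshold)
    confusion <- dplyr::count(tibble::tibble(actual = actual, predicted = predicted),
                              .data$actual, .data$predicted)
  }
  structure(list(groups = groups, ttest = ttest, roc = roc,
                 threshold = threshold, confusion = confusion,
                 pairs = tibble::as_tibble(pairs)),
            class = "pms_cohort_report")
}

#' @export
print.pms_cohort_report <- function(x, ...) {
  cat("Paired margin-score study\n")
  cat(sprintf("  tumor   PMS: %.4f +/- %.4f px\n", x$groups$mean_pms[1], x$groups$sd_pms[1]))
  cat(sprintf("  healthy PMS: %.4f +/- %.4f px\n", x$groups$mean_pms[2], x$groups$sd_pms[2]))
  cat("  "); print(x$ttest)
  cat("  "); print(x$roc)
  cat(sprintf("  classification threshold: %.4g px\n", x$threshold))
  invisible(x)
}

#' @export
glance.pms_cohort_report <- function(x, ...) {
  tibble::tibble(
    n = x$groups$n[1],
    mean_tumor = x$groups$mean_pms[1], sd_tumor = x$groups$sd_pms[1],
    mean_healthy = x$groups$mean_pms[2], sd_healthy = x$groups$sd_pms[2],
    t = x$ttest$t, p = x$ttest$p, auc = x$roc$auc,
    youden_threshold = x$roc$youden_threshold,
    youden_sens = x$roc$youden_sens, youden_spec = x$roc$youden_spec,
    threshold = x$threshold
  )
}

#' @export
tidy.pms_cohort_report <- function(x, ...) x$groups
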