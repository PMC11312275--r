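# ggplot2 views of the main result types.

#' Plot a grayscale image
#'
#' @param object a [gray_image()].
#' @param ... unused.
#' @return A ggplot raster plot in image coordinates (row 0 on top).
#' @export
autoplot.gray_image <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(0:(nrow(object) - 1), times = ncol(object)),
    col = rep(0:(ncol(object) - 1), each = nrow(object)),
    intensity = as.vector(unclass(object))
  )
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white") +
    scale_y_reverse() +
    coord_fixed() +
    labs(x = "col (px)", y = "row (px)", fill = "gray") +
    theme_minimal()
}

#' Plot a fitted average boundary line over the border points
#'
#' Shows the parameterized border `(u, v)`, the fitted average boundary
#' line, and the residuals that define the margin score.
#'
#' @param object a `smooth_boundary` from [fit_average_boundary()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.smooth_boundary <- function(object, ...) {
  ug <- seq(min(object$u), max(object$u), length.out = 200)
  fit_df <- tibble::tibble(u = ug, v = predict(object, ug))
  pts <- tibble::tibble(u = object$u, v = object$v, vhat = object$fitted)
  ggplot(pts, aes(x = .data$u, y = .data$v)) +
    geom_segment(aes(xend = .data$u, yend = .data$vhat),
                 color = "grey60", linewidth = 0.3) +
    geom_point(size = 0.8) +
    geom_line(data = fit_df, color = "red") +
    labs(x = "u along principal axis (px)", y = "v offset (px)",
         title = sprintf("Average boundary line (PMS = %.3f px)",
                         sqrt(mean(object$residuals^2)))) +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object a `pms_roc` from [roc_curve()].
#' @param ... unused.
#' @return A ggplot of sensitivity vs 1 - specificity with the Youden point
#'   marked.
#' @export
autoplot.pms_roc <- function(object, ...) {
  df <- object$curve
  df <- df[order(1 - df$spec, df$sens), ]
  yp <- tibble::tibble(fpr = 1 - object$youden_spec, sens = object$youden_sens)
  ggplot(df, aes(x = 1 - .data$spec, y = .data$sens)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey70") +
    geom_step() +
    geom_point(data = yp, aes(x = .data$fpr, y = .data$sens),
               color = "red", size = 2) +
    coord_fixed() +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("ROC curve, AUC = %.4f", object$auc),
         subtitle = sprintf("Youden threshold %.4g px (sens %.2f, spec %.2f)",
                            object$youden_threshold, object$youden_sens,
                            object$youden_spec)) +
    theme_minimal()
}

#' Plot a cohort report
#'
#' Box/whisker plot of the two groups' margin scores with the classification
#' threshold overlaid.
#'
#' @param object a `pms_cohort_report` from [cohort_report()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pms_cohort_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$pairs[, c("pms_tumor", "pms_healthy")],
                              dplyr::everything(),
                              names_to = "group", names_prefix = "pms_",
                              values_to = "pms")
  ggplot(long, aes(x = .data$group, y = .data$pms, fill = .data$group)) +
    geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    geom_jitter(width = 0.15, size = 0.8, alpha = 0.7) +
    geom_hline(yintercept = object$threshold, linetype = "dashed", color = "red") +
    scale_fill_manual(values = c(tumor = "#d62728", healthy = "#1f77b4"),
                      guide = "none") +
    labs(x = NULL, y = "PMS (px)",
         title = "Margin scores by group",
         subtitle = sprintf("dashed line: threshold %.4g px", object$threshold)) +
    theme_minimal()
}
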