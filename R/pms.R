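#' Fit the average boundary line
#'
#' The "average boundary line" is a deliberately stiff least-squares cubic
#' B-spline of the perpendicular offset `v` on the arc-length coordinate `u`,
#' with interior knots spread evenly at approximately `knot_spacing`. Its job
#' is to absorb organ-scale curvature while leaving pixel-scale nodularity in
#' the residuals; `knot_spacing` is therefore the critical stiffness
#' parameter of the whole score. If the border has fewer points than spline
#' coefficients, the knot count is reduced until the fit is solvable and the
#' count actually used is recorded.
#'
#' @param curve a parameterized `border_curve` (see [parameterize_border()]).
#' @param knot_spacing target interior knot spacing in px; defaults to a
#'   quarter of the border's `u`-range (matching the default "ROI width / 4"
#'   rule for a border spanning its ROI). The `u`-range must be at least
#'   twice `knot_spacing`.
#' @return A `smooth_boundary`: list with the fitted model, `knots` (interior
#'   knot positions), `knots_used`, `residuals` (`v - vhat(u)`, px), and the
#'   data the fit was computed on.
#' @export
fit_average_boundary <- function(curve, knot_spacing = NULL) {
  stopifnot(inherits(curve, "border_curve"))
  if (!all(c("u", "v") %in% names(curve))) {
    stop_pms("curve must be parameterized first (see parameterize_border())", "baseline")
  }
  u <- curve$u; v <- curve$v
  u_range <- diff(range(u))
  knot_spacing <- knot_spacing %||% (u_range / 4)
  if (!is_scalar_number(knot_spacing) || knot_spacing <= 0) {
    stop_pms("knot_spacing must be a positive number", "baseline")
  }
  n_interior <- as.integer(ceiling(u_range / knot_spacing)) - 1L
  if (u_range < 2 * knot_spacing || n_interior < 1L) {
    stop_pms(sprintf(
      "border too short for baseline fit (u-range %.1f px < 2 x knot_spacing %.1f px)",
      u_range, knot_spacing), "baseline")
  }
  # reduce flexibility if there are fewer points than coefficients
  while (n_interior > 1L && length(u) < n_interior + 4L) {
    n_interior <- n_interior - 1L
  }
  knots <- min(u) + seq_len(n_interior) * (u_range / (n_interior + 1L))
  basis <- splines::bs(u, knots = knots, degree = 3L, intercept = TRUE,
                       Boundary.knots = range(u))
  fit <- lm(v ~ basis - 1)
  structure(list(model = fit, basis_knots = knots, boundary_knots = range(u),
                 knots_used = n_interior, knot_spacing = knot_spacing,
                 residuals = unname(stats::residuals(fit)),
                 fitted = unname(stats::fitted(fit)), u = u, v = v,
                 curve = curve),
            class = "smooth_boundary")
}

#' Evaluate the fitted average boundary line
#'
#' @param object a `smooth_boundary`.
#' @param newdata optional numeric vector of `u` values (defaults to the
#'   fitted points).
#' @param ... unused.
#' @return Numeric vector `vhat(u)`.
#' @export
predict.smooth_boundary <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  basis <- splines::bs(newdata, knots = object$basis_knots, degree = 3L,
                       intercept = TRUE, Boundary.knots = object$boundary_knots)
  beta <- coef(object$model)
  beta[is.na(beta)] <- 0  # rank-deficient columns contribute nothing
  drop(basis %*% beta)
}

#' @export
print.smooth_boundary <- function(x, ...) {
  cat(sprintf("<smooth_boundary, %d points, %d interior knots, residual RMS %.4f px>\n",
              length(x$residuals), x$knots_used, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Compute the pancreatic margin score from a fitted boundary
#'
#' The PMS is the root-mean-square deviation of the detected border from the
#' average boundary line, in pixels: `sqrt(mean(residuals^2))`. Low scores
#' mean a smooth margin (tumor-like, desmoplastic), high scores a nodular
#' margin (healthy parenchyma).
#'
#' @param boundary a `smooth_boundary` from [fit_average_boundary()].
#' @param roi_label optional `"tumor"` or `"healthy"` label carried through.
#' @param params optional list of all parameters that influenced the score;
#'   hashed into `params_fingerprint`.
#' @param spacing_mm optional pixel spacing `c(row_mm, col_mm)`; when present
#'   (and isotropic) the score is also reported in millimeters.
#' @return A `pms_result`: list with `pms` (px), `n_points`, `roi_label`,
#'   `knots_used`, `params_fingerprint`, and `pms_mm` (NA without spacing).
#' @export
compute_pms <- function(boundary, roi_label = NA_character_, params = list(),
                        spacing_mm = NULL) {
  stopifnot(inherits(boundary, "smooth_boundary"))
  res <- boundary$residuals
  if (length(res) == 0L) stop_pms("boundary has no residuals", "pms")
  pms <- sqrt(mean(res^2))
  pms_mm <- if (!is.null(spacing_mm)) pms * mean(spacing_mm) else NA_real_
  structure(list(pms = pms, pms_mm = pms_mm, n_points = length(res),
                 roi_label = roi_label, knots_used = boundary$knots_used,
                 params_fingerprint = params_fingerprint(params)),
            class = "pms_result")
}

#' @export
print.pms_result <- function(x, ...) {
  cat(sprintf("<pms_result: PMS %.4f px%s, %d border points, %d knots [%s]>\n",
              x$pms, if (is.na(x$pms_mm)) "" else sprintf(" (%.4f mm)", x$pms_mm),
              x$n_points, x$knots_used,
              if (is.na(x$roi_label)) "unlabeled" else x$roi_label))
  invisible(x)
}

#' @export
tidy.pms_result <- function(x, ...) {
  tibble::tibble(roi_label = x$roi_label, pms = x$pms, pms_mm = x$pms_mm,
                 n_points = x$n_points, knots_used = x$knots_used,
                 params_fingerprint = x$params_fingerprint)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0(stage, ": ", conditionMessage(e)),
          class = c("pmscore_error_stage", "pmscore_error"),
          stage = stage, parent = e)
  })
}

#' Score one region of interest
#'
#' Runs the full measurement chain — crop, Canny edge detection, border
#' extraction, principal-axis parameterization, average-boundary-line fit,
#' RMS residual — and returns the margin score. Failures at any stage are
#' re-raised with the stage name attached.
#'
#' @param image a [gray_image()].
#' @param roi an [roi_box()]; its `label` is carried into the result.
#' @param canny a [canny_params()].
#' @param knot_spacing interior knot spacing of the average boundary line in
#'   px; defaults to a quarter of the ROI width.
#' @param refine enable sub-pixel border refinement (see [extract_border()]);
#'   off by default.
#' @return A `pms_result` (see [compute_pms()]).
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(64, 64), seed = 3))
#' score_roi(ph$image, roi_box(12, 12, 40, 40, label = "healthy"))
score_roi <- function(image, roi, canny = canny_params(), knot_spacing = NULL,
                      refine = FALSE) {
  stopifnot(inherits(image, "gray_image"), inherits(roi, "roi_box"))
  knot_spacing <- knot_spacing %||% (roi$width / 4)
  roi_img <- run_stage("crop", crop(image, roi))
  edges <- run_stage("canny_edges", {
    e <- canny_edges(roi_img, canny)
    if (e$no_edges) stop_pms("no edges", "canny")
    e
  })
  curve <- run_stage("extract_border", extract_border(edges, refine = refine))
  curve <- run_stage("parameterize_border", parameterize_border(curve))
  boundary <- run_stage("fit_average_boundary",
                        fit_average_boundary(curve, knot_spacing))
  compute_pms(boundary, roi_label = roi$label,
              params = list(canny = unclass(canny), knot_spacing = knot_spacing,
                            roi_shape = c(roi$height, roi$width),
                            refine = refine),
              spacing_mm = image_spacing(image))
}

#' Classify a margin score against a threshold
#'
#' Low scores indicate a smooth, tumor-like margin: the prediction is
#' `"cancer"` when `pms < threshold` and `"healthy"` otherwise (a score equal
#' to the threshold is called healthy). The shipped default threshold,
#' 0.6855 px, is a single-center, single-scanner operating point and not a
#' calibrated constant; recalibrate per study with [youden_threshold()].
#'
#' @param pms numeric vector of margin scores, px.
#' @param threshold decision threshold, px (> 0).
#' @return Character vector of `"cancer"` / `"healthy"`.
#' @export
#' @examples
#' classify_pms(c(0.50, 1.27, 0.6855))
classify_pms <- function(pms, threshold = 0.6855) {
  if (!is_scalar_number(threshold) || threshold <= 0) {
    stop_pms("threshold must be a positive number", "classify")
  }
  if (any(pms < 0, na.rm = TRUE)) stop_pms("pms must be non-negative", "classify")
  ifelse(pms < threshold, "cancer", "healthy")
}

#' Score every patient of a phantom cohort in memory
#'
#' Applies [score_roi()] with a centered ROI to both arms of each patient of
#' a [make_cohort()] result.
#'
#' @param cohort a [make_cohort()] tibble.
#' @param roi_shape `c(height, width)` of the centered ROI; defaults to the
#'   phantom shape minus an 8-px margin.
#' @inheritParams score_roi
#' @return A paired tibble: `patient_id`, `pms_tumor`, `pms_healthy`,
#'   `true_rms_tumor`, `true_rms_healthy`.
#' @export
score_cohort <- function(cohort, roi_shape = NULL, canny = canny_params(),
                         knot_spacing = NULL) {
  centered <- function(img, label) {
    shp <- dim(img)
    rs <- roi_shape %||% pmax(c(8, 8), shp - 8)
    roi_box(floor((shp[1] - rs[1]) / 2), floor((shp[2] - rs[2]) / 2),
            rs[1], rs[2], label = label)
  }
  one <- function(ph, label) {
    score_roi(ph$image, centered(ph$image, label), canny = canny,
              knot_spacing = knot_spacing)$pms
  }
  tibble::tibble(
    patient_id = cohort$patient_id,
    pms_tumor = purrr::map_dbl(cohort$phantom_tumor, one, label = "tumor"),
    pms_healthy = purrr::map_dbl(cohort$phantom_healthy, one, label = "healthy"),
    true_rms_tumor = cohort$true_rms_tumor,
    true_rms_healthy = cohort$true_rms_healthy
  )
}

#' Score a paired manifest of images on disk
#'
#' Batch analog of per-patient annotation: for every manifest row both ROIs
#' are scored. A row whose scoring fails is flagged in the `error` column and
#' the remaining rows are still scored.
#'
#' @param manifest result of [load_manifest()] (or a compatible tibble).
#' @inheritParams score_roi
#' @return Tibble `patient_id`, `pms_tumor`, `pms_healthy`, `error`.
#' @export
score_manifest <- function(manifest, canny = canny_params(), knot_spacing = NULL) {
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    out <- tibble::tibble(patient_id = manifest$patient_id[i],
                          pms_tumor = NA_real_, pms_healthy = NA_real_,
                          error = NA_character_)
    tryCatch({
      img <- load_image(manifest$image_path[i])
      out$pms_tumor <- score_roi(img, manifest$roi_tumor[[i]], canny,
                                 knot_spacing)$pms
      out$pms_healthy <- score_roi(img, manifest$roi_healthy[[i]], canny,
                                   knot_spacing)$pms
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  dplyr::bind_rows(rows)
}
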