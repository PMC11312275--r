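#' Specify a synthetic two-phase phantom
#'
#' A phantom is a CT-like two-level image: a bright "parenchyma" phase and a
#' darker "fat" phase separated by a border whose geometry is known exactly.
#' The border is a smooth base curve (straight line at a given angle, or a
#' circular arc) plus a band-limited perturbation — a sum of sinusoids with
#' wavelengths drawn inside `band` and uniform random phases, scaled so the
#' perturbation's RMS amplitude equals `perturbation_rms`. The step image is
#' rasterized with area-weighted anti-aliasing, blurred with a Gaussian
#' point-spread function, and degraded with additive Gaussian noise. The true
#' border and its realized roughness are recorded before any degradation, so
#' every downstream stage has an exact ground-truth oracle.
#'
#' The perturbation is band-limited (not white) on purpose: its wavelengths
#' can then be placed above the edge detector's resolution and below the
#' baseline spline's flexibility, which makes comparison of the measured
#' margin score against the true roughness well-posed.
#'
#' @param shape `c(rows, cols)` in pixels, each at least 16.
#' @param base_curve either `list(type = "line", angle = <degrees>)` — angle 0
#'   is a horizontal border — or `list(type = "arc", radius = <px>)` for a
#'   circular arc bulging through the image center.
#' @param perturbation_rms target RMS amplitude of the border perturbation, px.
#' @param band `c(min_wavelength, max_wavelength)` of the perturbation, px;
#'   the minimum is 2 px (Nyquist).
#' @param contrast `c(inside, outside)` gray levels of the two phases. The
#'   defaults (110 vs 20 on an 8-bit scale) mimic the contrast ordering of
#'   unenhanced parenchyma against surrounding fat; radiometric realism is a
#'   non-goal.
#' @param blur_sigma Gaussian point-spread sigma, px.
#' @param noise_sigma additive Gaussian noise sigma, gray levels.
#' @param seed integer; fully determines the phantom.
#'
#' @return A `phantom_spec` object.
#' @seealso [make_phantom()], [make_cohort()]
#' @export
phantom_spec <- function(shape = c(64, 64),
                         base_curve = list(type = "line", angle = 0),
                         perturbation_rms = 1,
                         band = c(4, 12),
                         contrast = c(inside = 110, outside = 20),
                         blur_sigma = 1,
                         noise_sigma = 2,
                         seed = 1L) {
  if (length(shape) != 2L || any(shape < 16)) {
    stop_pms("phantom shape must be c(rows, cols) with both >= 16", "phantom")
  }
  if (!is.list(base_curve) || !base_curve$type %in% c("line", "arc")) {
    stop_pms("base_curve$type must be 'line' or 'arc'", "phantom")
  }
  if (base_curve$type == "arc" &&
      (!is_scalar_number(base_curve$radius) || base_curve$radius <= 0)) {
    stop_pms("arc base_curve needs a positive radius", "phantom")
  }
  if (!is_scalar_number(perturbation_rms) || perturbation_rms < 0) {
    stop_pms("perturbation_rms must be a non-negative number", "phantom")
  }
  if (length(band) != 2L || band[1] < 2 || band[2] < band[1]) {
    stop_pms("band must be c(min_wavelength, max_wavelength) with min >= 2 px", "phantom")
  }
  if (length(contrast) != 2L || contrast[1] == contrast[2]) {
    stop_pms("contrast must be two distinct gray levels c(inside, outside)", "phantom")
  }
  if (!is_scalar_number(blur_sigma) || blur_sigma < 0) {
    stop_pms("blur_sigma must be >= 0", "phantom")
  }
  if (!is_scalar_number(noise_sigma) || noise_sigma < 0) {
    stop_pms("noise_sigma must be >= 0", "phantom")
  }
  structure(list(shape = as.integer(shape), base_curve = base_curve,
                 perturbation_rms = perturbation_rms, band = as.numeric(band),
                 contrast = as.numeric(contrast), blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  bc <- if (x$base_curve$type == "line") {
    sprintf("line @ %g deg", x$base_curve$angle %||% 0)
  } else {
    sprintf("arc R=%g px", x$base_curve$radius)
  }
  cat(sprintf("<phantom_spec %dx%d, %s, rms %g px, band [%g, %g] px, blur %g, noise %g, seed %d>\n",
              x$shape[1], x$shape[2], bc, x$perturbation_rms, x$band[1], x$band[2],
              x$blur_sigma, x$noise_sigma, x$seed))
  invisible(x)
}

# Draw the band-limited perturbation as a function of arc length u.
# Wavelengths uniform in band, phases uniform in [0, 2pi), equal amplitudes
# scaled so the analytic RMS sqrt(sum(a^2)/2) equals the requested value.
draw_perturbation <- function(rms, band, n_components = 12L) {
  lambda <- runif(n_components, band[1], band[2])
  phase <- runif(n_components, 0, 2 * pi)
  amp <- rep(rms * sqrt(2 / n_components), n_components)
  function(u) {
    out <- numeric(length(u))
    for (k in seq_len(n_components)) {
      out <- out + amp[k] * sin(2 * pi * u / lambda[k] + phase[k])
    }
    out
  }
}

# Border geometry as (u, v) curvilinear coordinates: u runs along the base
# curve, v is the signed offset toward the "inside" phase. Returns functions
# mapping pixel coordinates to (u, v) and border samples to (row, col).
phantom_geometry <- function(spec) {
  rows <- spec$shape[1]; cols <- spec$shape[2]
  cr <- (rows - 1) / 2; cc <- (cols - 1) / 2
  if (spec$base_curve$type == "line") {
    th <- (spec$base_curve$angle %||% 0) * pi / 180
    d <- c(sin(th), cos(th))    # along-border direction (row, col)
    n <- c(cos(th), -sin(th))   # normal, toward the inside phase
    list(
      uv = function(r, c) {
        dr <- r - cr; dc <- c - cc
        list(u = dr * d[1] + dc * d[2], v = dr * n[1] + dc * n[2])
      },
      point = function(u, off) {
        list(row = cr + u * d[1] + off * n[1], col = cc + u * d[2] + off * n[2])
      },
      u_halfspan = sqrt(rows^2 + cols^2) / 2
    )
  } else {
    R <- spec$base_curve$radius
    # Arc center placed below the image so the arc passes through the
    # image center bulging upward; inside = within the disc.
    Or <- cr + R; Oc <- cc
    list(
      uv = function(r, c) {
        dr <- r - Or; dc <- c - Oc
        rho <- sqrt(dr^2 + dc^2)
        alpha <- atan2(dc, -dr)
        list(u = R * alpha, v = R - rho)
      },
      point = function(u, off) {
        alpha <- u / R
        rho <- R - off
        list(row = Or - rho * cos(alpha), col = Oc + rho * sin(alpha))
      },
      u_halfspan = min(R * pi, R * asin(min(1, (sqrt(rows^2 + cols^2) / 2) / R)) + 2)
    )
  }
}

#' Generate a phantom image with known ground truth
#'
#' Rasterizes the two-phase step across the perturbed border (pixel value
#' proportional to the area covered by each phase, via 4x4 subpixel
#' sampling), applies Gaussian blur and additive noise, and returns the exact
#' border polyline together with the realized RMS of the perturbation about
#' the base curve. Truth is computed before degradation and does not depend
#' on `blur_sigma` or `noise_sigma`.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom` with elements `image` (a
#'   [gray_image()]), `truth` (list with `border_points`, a tibble of dense
#'   sub-pixel border samples `(u, row, col)`, and `true_rms`), and `spec`.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 7))
#' ph$truth$true_rms
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  border_len <- 2 * geom$u_halfspan
  if (spec$perturbation_rms > 0 && border_len < 2 * spec$band[2]) {
    stop_pms(sprintf(
      "band max wavelength %g px infeasible for border length %.1f px (minimum border length %g px)",
      spec$band[2], border_len, 2 * spec$band[2]), "phantom")
  }
  with_local_seed(spec$seed, {
    f_raw <- if (spec$perturbation_rms > 0) {
      draw_perturbation(spec$perturbation_rms, spec$band)
    } else {
      function(u) numeric(length(u))
    }

    rows <- spec$shape[1]; cols <- spec$shape[2]
    # ground truth at 0.25 px arc-length resolution, clipped to the image;
    # the raw sinusoid sum is rescaled so the REALIZED RMS of the visible
    # border equals the requested amplitude (the analytic sum-of-squares
    # scaling fluctuates over finite windows because of slow beats between
    # nearby wavelengths)
    u_dense <- seq(-geom$u_halfspan, geom$u_halfspan, by = 0.25)
    off_raw <- f_raw(u_dense)
    pt0 <- geom$point(u_dense, off_raw)
    keep <- pt0$row >= 0 & pt0$row <= rows - 1 & pt0$col >= 0 & pt0$col <= cols - 1
    if (!any(keep)) stop_pms("border does not intersect the image", "phantom")
    raw_rms <- sqrt(mean(off_raw[keep]^2))
    scale <- if (raw_rms > 0) spec$perturbation_rms / raw_rms else 0
    f <- function(u) scale * f_raw(u)
    off <- scale * off_raw
    pt <- geom$point(u_dense, off)
    keep <- pt$row >= 0 & pt$row <= rows - 1 & pt$col >= 0 & pt$col <= cols - 1
    truth <- list(
      border_points = tibble::tibble(u = u_dense[keep], row = pt$row[keep],
                                     col = pt$col[keep]),
      true_rms = sqrt(mean(off[keep]^2))
    )

    # anti-aliased rasterization: 4x4 subsamples per pixel
    s <- 4L
    offs <- (seq_len(s) - 0.5) / s - 0.5
    px <- matrix(0, rows, cols)
    rr <- matrix(rep(0:(rows - 1), cols), rows, cols)
    cc <- matrix(rep(0:(cols - 1), each = rows), rows, cols)
    for (dr in offs) {
      for (dc in offs) {
        uv <- geom$uv(rr + dr, cc + dc)
        inside <- uv$v < f(uv$u)
        px <- px + inside / (s * s)
      }
    }
    img <- spec$contrast[2] + (spec$contrast[1] - spec$contrast[2]) * px
    if (spec$blur_sigma > 0) img <- gaussian_blur_matrix(img, spec$blur_sigma)
    if (spec$noise_sigma > 0) img <- img + rnorm(length(img), sd = spec$noise_sigma)

    structure(list(image = gray_image(img), truth = truth, spec = spec),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d px, true_rms %.4f px>\n",
              nrow(x$image), ncol(x$image), x$truth$true_rms))
  invisible(x)
}

#' Generate a paired phantom cohort
#'
#' Emulates a paired study design: each "patient" contributes one phantom
#' drawn from the tumor-arm template (smooth margin, low roughness) and one
#' from the healthy-arm template (nodular margin). Per-patient seeds are
#' derived from `seed` so any single pair can be regenerated in isolation:
#' tumor-arm seed `seed + i`, healthy-arm seed `seed + n_patients + i`.
#'
#' @param n_patients number of pairs, at least 2.
#' @param tumor_spec,healthy_spec [phantom_spec()] templates for the two arms
#'   (their `seed` fields are overridden per patient).
#' @param seed integer master seed.
#' @return A tibble with one row per patient: `patient_id`, `seed_tumor`,
#'   `seed_healthy`, `true_rms_tumor`, `true_rms_healthy`, and list-columns
#'   `phantom_tumor`, `phantom_healthy` holding the full [make_phantom()]
#'   results.
#' @export
make_cohort <- function(n_patients, tumor_spec, healthy_spec, seed = 1L) {
  if (!is_scalar_number(n_patients) || n_patients < 2) {
    stop_pms("n_patients must be at least 2", "cohort")
  }
  n_patients <- as.integer(n_patients)
  one_arm <- function(template, seeds) {
    purrr::map(seeds, function(s) {
      sp <- template
      sp$seed <- as.integer(s)
      make_phantom(sp)
    })
  }
  seeds_t <- seed + seq_len(n_patients)
  seeds_h <- seed + n_patients + seq_len(n_patients)
  ph_t <- one_arm(tumor_spec, seeds_t)
  ph_h <- one_arm(healthy_spec, seeds_h)
  tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    seed_tumor = as.integer(seeds_t),
    seed_healthy = as.integer(seeds_h),
    true_rms_tumor = purrr::map_dbl(ph_t, ~ .x$truth$true_rms),
    true_rms_healthy = purrr::map_dbl(ph_h, ~ .x$truth$true_rms),
    phantom_tumor = ph_t,
    phantom_healthy = ph_h
  )
}

#' Write a phantom cohort to disk as images plus a manifest
#'
#' Each patient's two phantoms are placed side by side in one composite image
#' (tumor arm left, healthy arm right) written as 16-bit TIFF, with one ROI
#' box centered on each half, and a manifest CSV with columns `patient_id`,
#' `image_path`, `roi_tumor`, `roi_healthy`, `true_rms_tumor`,
#' `true_rms_healthy`, `seed` is written alongside. The manifest can be read
#' back with [load_manifest()] and scored with [score_manifest()].
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @param roi_shape `c(height, width)` of the ROI boxes; defaults to the
#'   phantom shape minus an 8-px margin.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, roi_shape = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  shp_t <- dim(cohort$phantom_tumor[[1]]$image)
  shp_h <- dim(cohort$phantom_healthy[[1]]$image)
  if (shp_t[1] != shp_h[1]) stop_pms("both arms must share the same image height", "cohort")
  roi_shape <- roi_shape %||% pmax(c(8, 8), pmin(shp_t, shp_h) - 8)
  center_roi <- function(shape, roi_shape, col_offset, label) {
    roi_box(floor((shape[1] - roi_shape[1]) / 2),
            col_offset + floor((shape[2] - roi_shape[2]) / 2),
            roi_shape[1], roi_shape[2], label = label)
  }
  rows <- purrr::pmap(cohort, function(patient_id, phantom_tumor, phantom_healthy,
                                       true_rms_tumor, true_rms_healthy,
                                       seed_tumor, ...) {
    composite <- gray_image(cbind(unclass(phantom_tumor$image),
                                  unclass(phantom_healthy$image)))
    img_name <- paste0(patient_id, ".tif")
    write_image(composite, file.path(dir, img_name))
    tibble::tibble(
      patient_id = patient_id,
      image_path = img_name,
      roi_tumor = format_roi(center_roi(shp_t, roi_shape, 0L, "tumor")),
      roi_healthy = format_roi(center_roi(shp_h, roi_shape, shp_t[2], "healthy")),
      true_rms_tumor = true_rms_tumor,
      true_rms_healthy = true_rms_healthy,
      seed = seed_tumor
    )
  })
  manifest <- dplyr::bind_rows(rows)
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  invisible(manifest_path)
}
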