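# Canny edge detection on small ROI images: separable Gaussian smoothing,
# Sobel gradients, 4-direction non-maximum suppression and quantile-based
# hysteresis linking. Implemented in-package; hysteresis linking runs on the
# pixel adjacency graph via igraph.

# 1D convolution along rows then columns with replicate (edge-clamp) padding.
conv_sep <- function(x, krow, kcol) {
  pad_conv <- function(m, k) {
    r <- (length(k) - 1L) / 2L
    n <- nrow(m)
    padded <- m[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[(i - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  x <- pad_conv(x, krow)
  t(pad_conv(t(x), kcol))
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur_matrix <- function(x, sigma) {
  k <- gaussian_kernel(sigma)
  conv_sep(x, k, k)
}

# Sobel derivatives: smoothing kernel (1,2,1)/4 across, difference
# (-1,0,1)/2 along the derivative axis.
sobel_gradients <- function(x) {
  diffk <- c(-1, 0, 1) / 2
  smook <- c(1, 2, 1) / 4
  list(gr = conv_sep(x, diffk, smook),   # d/drow
       gc = conv_sep(x, smook, diffk))   # d/dcol
}

#' Canny detector parameters
#'
#' The source images have no standardized intensity calibration, so both
#' hysteresis thresholds are scale-free: the high threshold is a quantile of
#' this ROI's nonzero gradient magnitudes and the low threshold a fraction of
#' the high one. An affine intensity rescaling therefore leaves the edge map
#' unchanged.
#'
#' @param sigma Gaussian smoothing sigma in px (> 0).
#' @param high_quantile quantile of nonzero gradient magnitudes used as the
#'   high hysteresis threshold, in (0, 1).
#' @param low_fraction low threshold as a fraction of the high one, in (0, 1].
#' @return A `canny_params` object.
#' @export
canny_params <- function(sigma = 1.0, high_quantile = 0.98, low_fraction = 0.4) {
  if (!is_scalar_number(sigma) || sigma <= 0) stop_pms("sigma must be > 0", "canny")
  if (!is_scalar_number(high_quantile) || high_quantile <= 0 || high_quantile >= 1) {
    stop_pms("high_quantile must be in (0, 1)", "canny")
  }
  if (!is_scalar_number(low_fraction) || low_fraction <= 0 || low_fraction > 1) {
    stop_pms("low_fraction must be in (0, 1]", "canny")
  }
  structure(list(sigma = sigma, high_quantile = high_quantile,
                 low_fraction = low_fraction), class = "canny_params")
}

# Non-maximum suppression along the true gradient direction, comparing each
# pixel against bilinearly interpolated magnitudes one step to either side
# (interpolation avoids the chain breaks that pure 4-direction quantization
# produces at high-curvature border turns). On exact two-pixel plateaus the
# >=/> asymmetry keeps the first pixel along the positive direction, so
# ideal step edges yield a single 1-px line.
nms_mask <- function(mag, gr, gc) {
  n <- nrow(mag); m <- ncol(mag)
  padded <- matrix(0, n + 2L, m + 2L)
  padded[2:(n + 1L), 2:(m + 1L)] <- mag
  at <- function(dr, dc) padded[(2L + dr):(n + 1L + dr), (2L + dc):(m + 1L + dc)]

  case_c <- abs(gc) >= abs(gr)  # gradient closer to the column axis
  t_c <- ifelse(gc != 0, gr / gc, 0)
  a_c <- pmin(abs(t_c), 1)
  up_c <- t_c >= 0
  n1_c <- (1 - a_c) * at(0L, 1L) + a_c * ifelse(up_c, at(1L, 1L), at(-1L, 1L))
  n2_c <- (1 - a_c) * at(0L, -1L) + a_c * ifelse(up_c, at(-1L, -1L), at(1L, -1L))

  t_r <- ifelse(gr != 0, gc / gr, 0)
  a_r <- pmin(abs(t_r), 1)
  up_r <- t_r >= 0
  n1_r <- (1 - a_r) * at(1L, 0L) + a_r * ifelse(up_r, at(1L, 1L), at(1L, -1L))
  n2_r <- (1 - a_r) * at(-1L, 0L) + a_r * ifelse(up_r, at(-1L, -1L), at(-1L, 1L))

  keep <- ifelse(case_c,
                 (mag >= n1_c) & (mag > n2_c),
                 (mag >= n1_r) & (mag > n2_r))
  n1 <- ifelse(case_c, n1_c, n1_r)
  n2 <- ifelse(case_c, n2_c, n2_r)

  # quadratic sub-pixel offset along the gradient: vertex of the parabola
  # through (-1, n2), (0, mag), (+1, n1), clamped to half a pixel
  denom <- n1 + n2 - 2 * mag
  delta <- ifelse(denom < 0, pmin(pmax(0.5 * (n2 - n1) / denom, -0.5), 0.5), 0)
  # the "+1" sample sits one pixel along the major axis (t is the minor
  # component), so the offset displaces (delta * t, delta) or transposed
  step_r <- ifelse(case_c, t_c, 1)
  step_c <- ifelse(case_c, 1, t_r)
  list(keep = keep & (mag > 0),
       offset_row = delta * step_r,
       offset_col = delta * step_c)
}

# Pixel adjacency graph of a logical mask via igraph. 8-adjacent pixels are
# joined with weight-1 edges; with `bridge = TRUE`, pixels up to Chebyshev
# distance 4 are additionally joined with "bridge" edges so that the small
# chain breaks non-maximum suppression leaves at high-curvature border
# turns do not sever the border.
mask_components <- function(mask, bridge = FALSE) {
  idx <- which(mask)
  if (length(idx) == 0L) return(list(idx = idx, membership = integer(0)))
  n <- nrow(mask)
  r <- ((idx - 1L) %% n) + 1L
  c <- ((idx - 1L) %/% n) + 1L
  pos <- stats::setNames(seq_along(idx), paste(r, c))
  half_offsets <- function(radius) {
    out <- list()
    for (dr in 0:radius) for (dc in -radius:radius) {
      d <- max(abs(dr), abs(dc))
      if (d >= 1 && (dr > 0 || (dr == 0 && dc > 0))) {
        out[[length(out) + 1L]] <- c(dr, dc, d)
      }
    }
    out
  }
  collect <- function(offsets) {
    edges <- list(); dist <- list()
    for (off in offsets) {
      key <- paste(r + off[1], c + off[2])
      hit <- !is.na(match(key, names(pos)))
      if (any(hit)) {
        edges[[length(edges) + 1L]] <- cbind(seq_along(idx)[hit], pos[key[hit]])
        dist[[length(dist) + 1L]] <- rep(off[3], sum(hit))
      }
    }
    list(e = if (length(edges)) do.call(rbind, edges) else matrix(integer(0), 0, 2),
         d = unlist(dist))
  }
  radius <- if (bridge) 4L else 1L
  all_off <- half_offsets(radius)
  got <- collect(all_off)
  g <- igraph::graph_from_edgelist(got$e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  # two edge weightings: `geom` approximates geometric path length and is
  # used to pick the mutually farthest endpoints; `weight` makes bridges far
  # more expensive than any plausible 8-connected detour, so the shortest
  # path between those endpoints only crosses a bridge where the chain is
  # genuinely broken
  igraph::E(g)$geom <- got$d
  igraph::E(g)$weight <- ifelse(got$d == 1, 1, got$d * 10)
  list(idx = idx, membership = igraph::components(g)$membership, graph = g,
       row = r, col = c)
}

#' Detect edges in a region of interest
#'
#' Standard Canny pipeline: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the gradient direction (against bilinearly interpolated
#' neighbor magnitudes), then hysteresis
#' linking — weak candidate pixels (above the low threshold) are kept only in
#' 8-connected components that contain at least one strong pixel (above the
#' high threshold). A constant ROI yields an empty edge map flagged
#' `no_edges`, not an error.
#'
#' @param roi_image a [gray_image()], at least 8 x 8.
#' @param params a [canny_params()].
#' @return An `edge_map`: list with `mask` (logical matrix),
#'   `gradient_magnitude`, the thresholds used, sub-pixel offset fields
#'   (`offset_row`, `offset_col`, used by [extract_border()]'s optional
#'   refinement), and a `no_edges` flag.
#' @export
canny_edges <- function(roi_image, params = canny_params()) {
  stopifnot(inherits(roi_image, "gray_image"), inherits(params, "canny_params"))
  if (nrow(roi_image) < 8 || ncol(roi_image) < 8) {
    stop_pms("ROI must be at least 8 x 8 for edge detection", "canny")
  }
  x <- gaussian_blur_matrix(unclass(roi_image), params$sigma)
  g <- sobel_gradients(x)
  mag <- sqrt(g$gr^2 + g$gc^2)

  empty <- function() {
    structure(list(mask = matrix(FALSE, nrow(mag), ncol(mag)),
                   gradient_magnitude = mag, high = NA_real_, low = NA_real_,
                   no_edges = TRUE, params = params), class = "edge_map")
  }
  nz <- mag[mag > 0]
  if (length(nz) == 0L) return(empty())
  high <- stats::quantile(nz, params$high_quantile, names = FALSE)
  low <- params$low_fraction * high
  if (high <= 0) return(empty())

  nms <- nms_mask(mag, g$gr, g$gc)
  weak <- nms$keep & (mag >= low)
  strong <- nms$keep & (mag >= high)
  if (!any(strong)) return(empty())

  comp <- mask_components(weak)
  strong_members <- unique(comp$membership[match(which(strong), comp$idx)])
  mask <- matrix(FALSE, nrow(mag), ncol(mag))
  mask[comp$idx[comp$membership %in% strong_members]] <- TRUE

  structure(list(mask = mask, gradient_magnitude = mag, high = high, low = low,
                 offset_row = nms$offset_row, offset_col = nms$offset_col,
                 no_edges = FALSE, params = params), class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map %dx%d, %d edge px%s>\n", nrow(x$mask), ncol(x$mask),
              sum(x$mask), if (x$no_edges) ", no edges" else ""))
  invisible(x)
}
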