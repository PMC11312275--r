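# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# A border_curve from raw coordinates (bypasses edge detection).
curve_from_points <- function(row, col, u = NULL, v = NULL) {
  df <- tibble::tibble(row = row, col = col)
  if (!is.null(u)) {
    df$u <- u
    df$v <- v
  }
  structure(df, class = c("border_curve", "tbl_df", "tbl", "data.frame"))
}

# An edge_map from a logical mask (bypasses the Canny stages).
edge_map_from_mask <- function(mask) {
  structure(list(mask = mask,
                 gradient_magnitude = matrix(1, nrow(mask), ncol(mask)),
                 offset_row = matrix(0, nrow(mask), ncol(mask)),
                 offset_col = matrix(0, nrow(mask), ncol(mask)),
                 high = 1, low = 0.4, no_edges = !any(mask),
                 params = canny_params()),
            class = "edge_map")
}

# Default phantom used across tests: straight border, modest roughness.
test_phantom <- function(rms = 1, seed = 1, shape = c(64, 64), angle = 0,
                         band = c(4, 12), blur = 0.3, noise = 2) {
  make_phantom(phantom_spec(shape = shape,
                            base_curve = list(type = "line", angle = angle),
                            perturbation_rms = rms, band = band,
                            blur_sigma = blur, noise_sigma = noise,
                            seed = seed))
}

# Centered ROI of a given shape inside an image.
centered_roi <- function(image, height, width, label = NA_character_) {
  roi_box(floor((nrow(image) - height) / 2), floor((ncol(image) - width) / 2),
          height, width, label = label)
}

# Rotate a gray_image counter-clockwise by k * 90 degrees.
rotate_image <- function(image, k = 1) {
  m <- unclass(image)
  for (i in seq_len(k %% 4)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  gray_image(m)
}

# Brute-force Mann-Whitney AUC: P(healthy > cancer) + 0.5 P(tie).
brute_auc <- function(cancer, healthy) {
  tot <- 0
  for (x in cancer) for (y in healthy) {
    tot <- tot + (y > x) + 0.5 * (y == x)
  }
  tot / (length(cancer) * length(healthy))
}

# Closed-form paired t-test oracle.
brute_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1))
}
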