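# Border selection and 1D parameterization. The edge map usually contains
# one dominant chain of pixels plus clutter; the organ border is taken to be
# the graph-geodesic between the two mutually farthest pixels of the largest
# 8-connected component.

#' Extract the border curve from an edge map
#'
#' Builds the 8-connectivity graph of edge pixels, takes its largest
#' connected component, and returns the longest geodesic path — found by the
#' double-BFS diameter sweep (farthest pixel from a fixed start, then
#' farthest pixel from that one, then the shortest path between the two).
#' All ties are broken toward the lexicographically smallest `(row, col)`
#' pixel so the output is deterministic.
#'
#' @param edges an `edge_map` from [canny_edges()].
#' @param refine if `TRUE`, displace each pixel by its quadratic sub-pixel
#'   offset along the gradient (off by default: the score is defined on
#'   integer pixel centers, giving a quantization floor of about
#'   1/sqrt(12) = 0.29 px).
#' @return A `border_curve`: tibble of ordered `(row, col)` pixel coordinates
#'   (0-based), consecutive points 8-adjacent, no repeats.
#' @export
extract_border <- function(edges, refine = FALSE) {
  stopifnot(inherits(edges, "edge_map"))
  if (edges$no_edges || !any(edges$mask)) stop_pms("no edges", "border")
  comp <- mask_components(edges$mask, bridge = TRUE)
  # 0-based coordinates, lexicographic (row, col) order for tie-breaking
  r0 <- comp$row - 1L
  c0 <- comp$col - 1L
  lex <- order(r0, c0)

  sizes <- tabulate(comp$membership)
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1L) {
    # tie: the component containing the lexicographically smallest pixel
    memb_lex <- comp$membership[lex]
    comp_id <- memb_lex[memb_lex %in% cand][1L]
  } else {
    comp_id <- cand
  }
  if (best_size < 10L) stop_pms("border too short", "border")

  members <- which(comp$membership == comp_id)
  geom_w <- igraph::E(comp$graph)$geom
  farthest <- function(from) {
    d <- igraph::distances(comp$graph, v = from, to = members,
                           weights = geom_w)[1L, ]
    dmax <- max(d[is.finite(d)])
    hits <- members[which(d == dmax)]
    hits[order(r0[hits], c0[hits])][1L]
  }
  start <- members[order(r0[members], c0[members])][1L]
  a <- farthest(start)
  b <- farthest(a)
  ends <- c(a, b)[order(r0[c(a, b)], c0[c(a, b)])]
  path <- igraph::shortest_paths(comp$graph, from = ends[1L], to = ends[2L])$vpath[[1L]]
  path <- as.integer(path)

  pr <- r0[path]; pc <- c0[path]
  # where a bridge edge jumped a chain break, insert linearly interpolated
  # pixels so consecutive points stay 8-adjacent
  steps <- pmax(abs(diff(pr)), abs(diff(pc)))
  if (any(steps > 1L)) {
    outr <- outc <- vector("list", length(pr))
    for (i in seq_along(pr)) { outr[[i]] <- pr[i]; outc[[i]] <- pc[i] }
    for (j in which(steps > 1L)) {
      k <- steps[j]
      frac <- seq_len(k - 1L) / k
      outr[[j]] <- c(pr[j], as.integer(round(pr[j] + frac * (pr[j + 1L] - pr[j]))))
      outc[[j]] <- c(pc[j], as.integer(round(pc[j] + frac * (pc[j + 1L] - pc[j]))))
    }
    pr <- unlist(outr); pc <- unlist(outc)
    dup <- c(FALSE, diff(pr) == 0L & diff(pc) == 0L)
    pr <- pr[!dup]; pc <- pc[!dup]
  }

  row_out <- as.numeric(pr); col_out <- as.numeric(pc)
  if (refine) {
    lin <- pr + 1L + nrow(edges$mask) * pc  # (row, col) 0-based -> R index
    on_mask <- edges$mask[lin]
    row_out <- row_out + ifelse(on_mask, edges$offset_row[lin], 0)
    col_out <- col_out + ifelse(on_mask, edges$offset_col[lin], 0)
  }
  structure(tibble::tibble(row = row_out, col = col_out),
            class = c("border_curve", "tbl_df", "tbl", "data.frame"))
}

#' @export
print.border_curve <- function(x, ...) {
  param <- if ("u" %in% names(x)) " (parameterized)" else ""
  cat(sprintf("<border_curve, %d points%s>\n", nrow(x), param))
  NextMethod()
}

#' Parameterize a border along its principal axis
#'
#' Expresses the border as a 1D signal: `u` is the signed projection of each
#' point onto the leading principal axis of the point cloud (relative to the
#' centroid) and `v` the perpendicular offset. This turns "deviation of the
#' border from the average boundary line" into an ordinary 1D regression
#' problem. The axis is oriented so `u` increases along the path. A border
#' that folds over its own axis — more than 10% of points falling over 1 px
#' behind the running maximum of `u` along the path — is rejected as not
#' single-valued (e.g. a closed or hook-shaped contour); single-pixel
#' stagger on steep segments is tolerated, and points sharing one `u` are
#' collapsed by averaging `v`.
#'
#' @param curve a `border_curve` from [extract_border()] with at least 10
#'   points.
#' @return The curve with `u` and `v` columns, sorted by strictly increasing
#'   `u`; attributes `centroid` and `axis` record the frame.
#' @export
parameterize_border <- function(curve) {
  stopifnot(inherits(curve, "border_curve"))
  if (nrow(curve) < 10L) stop_pms("border too short", "border")
  pts <- cbind(curve$row, curve$col)
  centroid <- colMeans(pts)
  centered <- sweep(pts, 2, centroid)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  axis <- ev$vectors[, 1L]
  u <- drop(centered %*% axis)
  if (u[length(u)] < u[1L]) {
    axis <- -axis
    u <- -u
  }
  normal <- c(-axis[2L], axis[1L])
  v <- drop(centered %*% normal)

  # fold-over: points whose u falls more than 1 px behind the running
  # maximum along the path. Pixel jitter on steep border segments backtracks
  # by at most one pixel and is tolerated; a closed or hook-shaped contour
  # doubles back over many pixels and is rejected.
  fold_frac <- mean(cummax(u) - u > 1)
  if (fold_frac > 0.10) {
    stop_pms(sprintf(
      "border not single-valued along principal axis (fold-over %.0f%%)",
      100 * fold_frac), "border")
  }

  out <- tibble::tibble(row = curve$row, col = curve$col, u = u, v = v)
  out <- dplyr::arrange(out, .data$u)
  out <- dplyr::summarise(dplyr::group_by(out, .data$u),
                          row = mean(.data$row), col = mean(.data$col),
                          v = mean(.data$v), .groups = "drop")
  out <- dplyr::select(out, "row", "col", "u", "v")
  structure(out, class = c("border_curve", "tbl_df", "tbl", "data.frame"),
            centroid = centroid, axis = axis)
}
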