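#' Run configuration
#'
#' Bundles every tunable of a scoring run: the ROI box size, the Canny
#' parameters, the baseline stiffness, the decision threshold and the master
#' seed. Round-trips losslessly through a flat `key = value` text file so a
#' run can be reproduced exactly from its config.
#'
#' @param roi_shape `c(height, width)` of the ROI boxes, px.
#' @param sigma,high_quantile,low_fraction Canny parameters, see
#'   [canny_params()].
#' @param knot_spacing interior knot spacing of the average boundary line,
#'   px; `NA` means "ROI width / 4".
#' @param threshold classification threshold, px.
#' @param seed integer master seed.
#' @param out_dir output directory for artifacts.
#' @param log_level one of `"quiet"`, `"info"`, `"debug"`.
#' @return A `run_config` object.
#' @export
run_config <- function(roi_shape = c(40, 40), sigma = 1.0, high_quantile = 0.98,
                       low_fraction = 0.4, knot_spacing = NA_real_,
                       threshold = 0.6855, seed = 1L, out_dir = ".",
                       log_level = "info") {
  canny <- canny_params(sigma, high_quantile, low_fraction)  # validates
  if (length(roi_shape) != 2L || any(roi_shape < 8)) {
    stop_pms("roi_shape must be c(height, width), both >= 8", "config")
  }
  if (!is.na(knot_spacing) && (!is_scalar_number(knot_spacing) || knot_spacing <= 0)) {
    stop_pms("knot_spacing must be positive (or NA for ROI width / 4)", "config")
  }
  if (!is_scalar_number(threshold) || threshold <= 0) {
    stop_pms("threshold must be positive", "config")
  }
  if (!log_level %in% c("quiet", "info", "debug")) {
    stop_pms("log_level must be quiet, info or debug", "config")
  }
  structure(list(roi_shape = as.integer(roi_shape), sigma = sigma,
                 high_quantile = high_quantile, low_fraction = low_fraction,
                 knot_spacing = as.numeric(knot_spacing), threshold = threshold,
                 seed = as.integer(seed), out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(unclass(x))) {
    cat(sprintf("  %s = %s\n", k, paste(x[[k]], collapse = ",")))
  }
  invisible(x)
}

#' Write a run configuration to a flat key = value file
#'
#' Lines are `key = value`; `#` starts a comment; vector values are
#' comma-separated.
#'
#' @param config a [run_config()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(unclass(config)), function(k) {
    sprintf("%s = %s", k, paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(c("# margin-score run configuration", lines), path)
  invisible(path)
}

#' Read a run configuration from a flat key = value file
#'
#' @param path config file written by [write_run_config()] (or by hand).
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_pms(sprintf("config file not found: %s", path), "config")
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop_pms(sprintf("cannot parse config line: '%s'", lines[bad][1]), "config")
  vals <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, 1L, FUN.VALUE = ""))
  num <- function(k, default) {
    if (is.null(vals[[k]])) return(default)
    suppressWarnings(as.numeric(strsplit(vals[[k]], ",")[[1]]))
  }
  chr <- function(k, default) if (is.null(vals[[k]])) default else vals[[k]]
  run_config(
    roi_shape = num("roi_shape", c(40, 40)),
    sigma = num("sigma", 1.0),
    high_quantile = num("high_quantile", 0.98),
    low_fraction = num("low_fraction", 0.4),
    knot_spacing = num("knot_spacing", NA_real_),
    threshold = num("threshold", 0.6855),
    seed = num("seed", 1L),
    out_dir = chr("out_dir", "."),
    log_level = chr("log_level", "info")
  )
}

config_canny <- function(config) {
  canny_params(config$sigma, config$high_quantile, config$low_fraction)
}
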