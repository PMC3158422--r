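#' Run configuration
#'
#' Bundles every tunable of the workflow so a run is fully described by one
#' object: the shape model (radius overrides, hydrogen policy, amplitude,
#' analytic-volume order, quadrupole scale), the filter binning (bin sizes,
#' volume type, ST threshold), the screening policy (unknown keys, volume
#' bound), and the seed. Round-trips losslessly through a YAML file.
#'
#' @param radii Named list/vector of element radius overrides (A).
#' @param default_radius Fallback radius for unlisted elements (A).
#' @param include_hydrogens Hydrogen policy for the shape model.
#' @param amplitude Gaussian amplitude p.
#' @param max_order Analytic-volume inclusion-exclusion order.
#' @param quad_scale `"normalized"` or `"volume"`, see [quadrupoles()].
#' @param vol_binsize,q_binsize,volume_type,st_threshold See
#'   [bin_config()].
#' @param unknown_key Unknown-key policy, see [apply_single()].
#' @param use_volume_bound Apply the volume-only ST bound before the
#'   quadrupole cascade.
#' @param seed Integer seed for randomized commands (`NULL` means "must be
#'   supplied on the command line").
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(radii = NULL, default_radius = 1.70,
                       include_hydrogens = FALSE,
                       amplitude = 2 * sqrt(2), max_order = 3,
                       quad_scale = c("normalized", "volume"),
                       vol_binsize = 5.0,
                       q_binsize = c(x = 2.5, y = 0.5, z = 0.1),
                       volume_type = c("mp", "an", "so"),
                       st_threshold = 0.80,
                       unknown_key = c("pass", "reject"),
                       use_volume_bound = TRUE, seed = NULL,
                       log_level = c("info", "quiet", "debug")) {
  cfg <- list(
    radii = if (is.null(radii)) NULL else as.list(radii),
    default_radius = default_radius,
    include_hydrogens = isTRUE(include_hydrogens),
    amplitude = amplitude, max_order = as.integer(max_order),
    quad_scale = match.arg(quad_scale),
    vol_binsize = vol_binsize,
    q_binsize = as.list(q_binsize[c("x", "y", "z")]),
    volume_type = match.arg(volume_type),
    st_threshold = st_threshold,
    unknown_key = match.arg(unknown_key),
    use_volume_bound = isTRUE(use_volume_bound),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    log_level = match.arg(log_level)
  )
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$q_binsize)) raw$q_binsize <- unlist(raw$q_binsize)
  if (!is.null(raw$radii)) raw$radii <- unlist(raw$radii)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
config_radius_table <- function(config) {
  radius_table(radii = if (is.null(config$radii)) NULL else
    unlist(config$radii), default = config$default_radius)
}

#' @rdname run_config
#' @export
config_bin_config <- function(config) {
  bin_config(vol_binsize = config$vol_binsize,
             q_binsize = unlist(config$q_binsize),
             volume_type = config$volume_type,
             st_threshold = config$st_threshold)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

cfg_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) {
    message(...)
  }
}
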