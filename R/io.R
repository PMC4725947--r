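sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a FLIM stack as multi-page TIFF with JSON sidecar
#'
#' One TIFF page per time bin, plus a `<path>.json` sidecar holding the time
#' axis, channel and metadata. Counts up to 65535 are stored as 16-bit
#' unsigned pages (lossless); larger counts promote the file to 32 bits with
#' a `bit_depth` flag in the sidecar.
#'
#' @param stack A [flim_stack()].
#' @param path Output TIFF path.
#' @return `write_flim_stack` invisibly returns `path`; `read_flim_stack`
#'   returns a [flim_stack()] identical to the one written.
#' @export
write_flim_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  cts <- stack$counts
  if (any(cts != round(cts)))
    stop("stack counts must be integers for storage", call. = FALSE)
  mx <- max(cts)
  bits <- if (mx > 65535) 32L else 16L
  scale <- if (bits == 16L) 65535 else mx
  pages <- lapply(seq_len(stack$axis$n_bins),
                  function(b) stack$counts[, , b] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  side <- list(
    n_bins = stack$axis$n_bins, bin_width_ps = stack$axis$bin_width,
    period_ns = stack$axis$period, channel = stack$channel,
    height = stack$height, width = stack$width,
    bit_depth = bits, scale = scale, metadata = stack$metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_flim_stack
#' @export
read_flim_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("format error: missing JSON sidecar ", sp, call. = FALSE)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("n_bins", "bin_width_ps", "period_ns", "channel", "scale"))
    if (is.null(side[[f]]))
      stop("format error: sidecar lacks field '", f, "'", call. = FALSE)
  axis <- time_axis(side$n_bins, side$bin_width_ps, side$period_ns)
  pages <- if (side$bit_depth == 16L)
    tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  else
    lapply(tiff::readTIFF(path, all = TRUE), function(m) round(m * side$scale))
  if (length(pages) != axis$n_bins)
    stop(sprintf("format error: sidecar n_bins=%d but TIFF has %d pages",
                 axis$n_bins, length(pages)), call. = FALSE)
  cube <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), axis$n_bins))
  for (b in seq_along(pages)) cube[, , b] <- pages[[b]]
  if (any(cube < 0))
    stop("format error: negative counts in field 'counts'", call. = FALSE)
  md <- side$metadata
  flim_stack(cube, axis, channel = side$channel,
             metadata = if (is.null(md)) list() else as.list(md))
}

#' Write / read an ROI mask as a PNG label image
#'
#' Labels are stored in an 8-bit grey PNG (max label 255).
#'
#' @param mask A [roi_mask()].
#' @param path PNG path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  if (max(mask$labels) > 255) stop("labels exceed 8-bit range", call. = FALSE)
  png::writePNG(mask$labels / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  roi_mask(matrix(as.integer(round(m * 255)), nrow(m)))
}

#' Write parameter maps as 32-bit float TIFFs and a pseudocolour PNG
#'
#' Each numeric map goes to `<dir>/<name>.tif` (values normalised by a per-map
#' scale recorded in a JSON sidecar); the rendered average-lifetime map goes
#' to `<dir>/tau_avg.png`.
#'
#' @param maps A `parameter_maps` object from [fit_image()].
#' @param dir Output directory (created if needed).
#' @param value_range Colour range (ns) for the rendered map.
#' @return Invisibly, the written file paths.
#' @export
write_parameter_maps <- function(maps, dir, value_range = c(0.5, 2)) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  scales <- list()
  for (nm in c("tau1", "tau2", "tau_avg", "tau_avg_int", "ratio",
               "chi2_reduced", "photons", "kernel")) {
    m <- maps[[nm]]
    m[!is.finite(m)] <- 0
    sc <- max(m, 1)
    p <- file.path(dir, paste0(nm, ".tif"))
    tiff::writeTIFF(m / sc, p, bits.per.sample = 32L)
    scales[[nm]] <- sc
    written <- c(written, p)
  }
  jsonlite::write_json(scales, file.path(dir, "map_scales.json"),
                       auto_unbox = TRUE, digits = NA)
  pp <- file.path(dir, "tau_avg.png")
  png::writePNG(render_lifetime_map(maps, value_range), pp)
  invisible(c(written, pp))
}

# fixed, documented column orders for the CSV surface
table_columns <- list(
  experiment = c("channel", "concentration", "day", "replicate", "tau1",
                 "tau2", "tau_avg_amp", "tau_avg_int", "ratio", "a1", "a2",
                 "background", "shift", "chi2_reduced", "runs_test_p",
                 "converged", "n_photons", "true_tau1", "true_tau2",
                 "true_ratio"),
  summary = c("concentration", "parameter", "mean", "sem", "n", "flagged"),
  posthoc = c("group1", "group2", "mean_diff", "t", "df", "p", "significance"),
  percent_change = c("parameter", "percent_change", "p_control_vs_treated"))

#' Write result tables as CSV
#'
#' Writes each table in a named list to `<out_dir>/<name>.csv` with a fixed
#' column order (known schemas first, extras appended) and locale-independent
#' numeric formatting. Empty tables produce header-only files.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_tables <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(results))
  for (i in seq_along(results)) {
    nm <- names(results)[i]
    df <- as.data.frame(results[[i]])
    schema <- table_columns[[nm]]
    if (!is.null(schema)) {
      ord <- c(intersect(schema, names(df)), setdiff(names(df), schema))
      df <- df[, ord, drop = FALSE]
    }
    paths[i] <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(df, paths[i], row.names = FALSE)
  }
  invisible(paths)
}

#' Run configuration
#'
#' Declarative description of a pipeline run: time axis, IRF specification
#' (parametric or CSV profile), fit options, binning threshold, experiment
#' design and seed. Serialisable to YAML; a run is reproducible from the
#' config plus its seed alone.
#'
#' @param seed Root RNG seed; all stage seeds derive from it.
#' @param axis,irf_fwhm,irf_center Time axis and parametric IRF (ns).
#' @param irf_csv Optional path to a measured IRF profile (overrides the
#'   parametric spec).
#' @param min_photons Adaptive-binning photon floor.
#' @param channel,concentrations,n_days,rois_per_day,photons_per_roi,background
#'   Experiment design (see [simulate_experiment()]).
#' @param fit [fit_options()].
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, axis = time_axis(), irf_fwhm = 0.181,
                       irf_center = 0.6, irf_csv = NULL, min_photons = 1000L,
                       channel = "NADH",
                       concentrations = c(0, 50, 100, 250, 500, 1000),
                       n_days = 5L, rois_per_day = 15L, photons_per_roi = 5e5,
                       background = 2, fit = fit_options(), out_dir = ".") {
  structure(list(seed = as.integer(seed),
                 axis = list(n_bins = axis$n_bins, bin_width = axis$bin_width,
                             period = axis$period),
                 irf = list(fwhm = irf_fwhm, center = irf_center,
                            csv = irf_csv),
                 min_photons = as.integer(min_photons),
                 experiment = list(channel = channel,
                                   concentrations = concentrations,
                                   n_days = as.integer(n_days),
                                   rois_per_day = as.integer(rois_per_day),
                                   photons_per_roi = photons_per_roi,
                                   background = background),
                 fit = unclass(fit), out_dir = out_dir),
            class = "run_config")
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
  needed <- c("seed", "axis", "irf", "experiment")
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stop("config error: missing field(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  fo <- do.call(fit_options, raw$fit %||% list())
  run_config(seed = raw$seed,
             axis = time_axis(raw$axis$n_bins, raw$axis$bin_width,
                              raw$axis$period),
             irf_fwhm = raw$irf$fwhm %||% 0.181,
             irf_center = raw$irf$center %||% 0.6,
             irf_csv = raw$irf$csv,
             min_photons = raw$min_photons %||% 1000L,
             channel = raw$experiment$channel %||% "NADH",
             concentrations = raw$experiment$concentrations,
             n_days = raw$experiment$n_days,
             rois_per_day = raw$experiment$rois_per_day,
             photons_per_roi = raw$experiment$photons_per_roi,
             background = raw$experiment$background %||% 2,
             fit = fo, out_dir = raw$out_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_axis <- function(config)
  time_axis(config$axis$n_bins, config$axis$bin_width, config$axis$period)

config_irf <- function(config, axis = config_axis(config)) {
  if (!is.null(config$irf$csv)) read_irf_csv(config$irf$csv, axis)
  else gaussian_irf(axis, config$irf$fwhm, config$irf$center)
}

#' Write a run manifest
#'
#' Records what is needed to re-run a stage: the config (and its MD5 hash),
#' the seed, the package version and MD5 checksums of the listed output
#' files. Written atomically (temp file + rename). Timestamps are the only
#' non-deterministic field.
#'
#' @param config A [run_config()].
#' @param files Character vector of output files to checksum.
#' @param path Manifest JSON path.
#' @param stage Stage name recorded in the manifest.
#' @return Invisibly, `path`.
#' @export
write_run_manifest <- function(config, files, path, stage = "run") {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  hash_cfg <- config
  hash_cfg$out_dir <- NULL   # hash the scientific config, not output paths
  write_run_config(hash_cfg, tmp)
  files <- files[file.exists(files)]
  sums <- as.list(tools::md5sum(files))
  names(sums) <- basename(files)
  manifest <- list(
    stage = stage,
    config = unclass(config),
    config_hash = unname(tools::md5sum(tmp)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("flimetry")),
    checksums = sums,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  tmp2 <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp2, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp2, path)
  invisible(path)
}
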