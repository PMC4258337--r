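## Image/mask/config I/O and the dispatching entry point behind the CLI.
## Conventions stated once, used everywhere: masks are single-channel PNG
## with 0 = background and 255 = foreground; coordinates are row-major with
## the origin at the top-left.

#' Load a color image
#'
#' Reads PNG, JPEG or TIFF into an [rgb_image()] with channels scaled to
#' `[0, 1]` (8-bit by 255, 16-bit by 65535; the underlying readers
#' normalize by the file's bit depth). Grayscale images are rejected:
#' tongue extraction is color-based. An alpha channel, if present, is
#' dropped.
#'
#' @param path file path; format chosen by extension.
#' @return an [rgb_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop_tongueseg(sprintf("cannot read '%s'", path), "tongueseg_io_error")
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              jpg = , jpeg = jpeg::readJPEG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop_tongueseg(sprintf("unsupported image format '.%s'", ext),
                             "tongueseg_io_error"))
  if (length(dim(x)) != 3L || dim(x)[3] < 3L)
    stop_tongueseg("grayscale images are rejected: tongue extraction is color-based",
                   "tongueseg_io_error")
  rgb_image(x[, , 1:3, drop = FALSE])
}

#' Write / read a binary mask as single-channel PNG
#'
#' Foreground is stored as 255, background as 0; reading thresholds at
#' 0.5, so a write/read round trip is exact.
#'
#' @param mask logical matrix.
#' @param path PNG file path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   logical matrix.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop_tongueseg(sprintf("cannot read '%s'", path), "tongueseg_io_error")
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}

#' Write an image as RGB PNG
#'
#' @param img an [rgb_image()].
#' @param path PNG file path.
#' @export
write_image <- function(img, path) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' Export HSI planes for inspection
#'
#' Writes hue, saturation and intensity as three single-channel 16-bit
#' TIFFs (`<prefix>_hue.tif`, `<prefix>_sat.tif`, `<prefix>_int.tif`).
#' Hue is stored as its degree value (0-359 in 16-bit counts); undefined
#' hue is stored as 65535. Saturation and intensity are scaled to the full
#' 16-bit range.
#'
#' @param hsi an `hsi_image`.
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
write_hsi <- function(hsi, prefix) {
  hue <- hsi$h
  hue[is.na(hue)] <- 65535
  hue[hue != 65535] <- floor(hue[hue != 65535])
  paths <- paste0(prefix, c("_hue.tif", "_sat.tif", "_int.tif"))
  tiff::writeTIFF(hue / 65535, paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(hsi$s, paths[2], bits.per.sample = 16L)
  tiff::writeTIFF(hsi$i, paths[3], bits.per.sample = 16L)
  invisible(paths)
}

#' Run configuration
#'
#' Bundles a method name with its parameter block; round-trips losslessly
#' through YAML via [save_config()] / [load_config()].
#'
#' @param method `"morph"`, `"sequential"` or `"greedy"`.
#' @param params matching parameter object ([morph_params()],
#'   [seq_params()] or [fusion_params()]); defaults used when `NULL`.
#' @param log_level `"quiet"` or `"debug"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(method = "greedy", params = NULL, log_level = "quiet") {
  params <- params %||% switch(method,
                               morph = morph_params(),
                               sequential = seq_params(),
                               greedy = fusion_params(),
                               stop_tongueseg(sprintf("unknown method '%s'", method),
                                              "tongueseg_config_error"))
  if (!log_level %in% c("quiet", "debug"))
    stop_tongueseg("`log_level` must be 'quiet' or 'debug'", "tongueseg_config_error")
  structure(list(method = method, params = params, log_level = log_level),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(list(method = config$method,
                        log_level = config$log_level,
                        params = unclass(config$params)), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_tongueseg(sprintf("cannot read '%s'", path), "tongueseg_io_error")
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) stop_tongueseg(conditionMessage(e),
                                                   "tongueseg_config_error"))
  ctor <- switch(y$method %||% "",
                 morph = morph_params, sequential = seq_params,
                 greedy = fusion_params,
                 stop_tongueseg("config must name a method", "tongueseg_config_error"))
  p <- y$params %||% list()
  if (!is.null(p$yellow_band)) p$yellow_band <- as.numeric(p$yellow_band)
  if (!is.null(p$seed)) p$seed <- as.integer(p$seed)
  run_config(y$method, do.call(ctor, p), y$log_level %||% "quiet")
}

#' Segment an image file according to a configuration
#'
#' Loads the image, dispatches to the configured segmenter, and writes the
#' mask PNG. Returns an integer status instead of raising: 0 on success,
#' 2 on I/O error, 3 on configuration error, 4 on seed failure, 5 when
#' thresholding finds no foreground. With `log_level = "debug"`, logs the
#' parameters and (for the greedy method) acceptance/rejection counters to
#' standard error.
#'
#' @param config a [run_config()].
#' @param in_path input image path.
#' @param out_path output mask PNG path.
#' @return integer exit status, invisibly.
#' @export
run <- function(config, in_path, out_path) {
  status_of <- function(e) {
    if (inherits(e, "tongueseg_io_error")) 2L
    else if (inherits(e, "tongueseg_seed_failure")) 4L
    else if (inherits(e, "tongueseg_no_foreground")) 5L
    else 3L
  }
  debug <- identical(config$log_level, "debug")
  res <- tryCatch({
    img <- load_image(in_path)
    if (debug) {
      message(sprintf("method=%s image=%dx%d", config$method,
                      dim(img)[1], dim(img)[2]))
      message(paste(utils::capture.output(utils::str(unclass(config$params))),
                    collapse = "\n"))
    }
    mask <- segmenter_for(config$method)(img, config$params)
    if (debug && !is.null(attr(mask, "accepted")))
      message(sprintf("accepted=%d rejected=%d",
                      attr(mask, "accepted"), attr(mask, "rejected")))
    write_mask(matrix(as.logical(mask), nrow(mask), ncol(mask)), out_path)
    0L
  }, tongueseg_error = function(e) {
    message("error: ", conditionMessage(e))
    status_of(e)
  })
  invisible(res)
}
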