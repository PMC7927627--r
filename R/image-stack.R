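#' Calibrated multichannel 2D image
#'
#' The raw input container of every pipeline stage: one 2D intensity grid per
#' named channel, plus the pixel calibration in micrometres per pixel. Pixel
#' (0, 0) is the top-left corner, x runs rightward (columns), y downward
#' (rows); matrices are stored `[y + 1, x + 1]`. Intensities are arbitrary
#' nonnegative counts.
#'
#' @param channels named list of numeric matrices, all of identical dimension.
#' @param pixel_size calibration in µm per pixel (> 0).
#' @return an object of class `image_stack`.
#' @examples
#' img <- image_stack(list(DAPI = matrix(0, 32, 32)), pixel_size = 0.624)
#' dim(img)
#' @export
image_stack <- function(channels, pixel_size) {
  if (!is.list(channels) || length(channels) == 0L)
    stopf("channels must be a nonempty named list of matrices")
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stopf("channel names must be unique and nonempty")
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1L]]), logical(1L))))
    stopf("all channels must share dimensions")
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be a positive number (µm/px)")
  structure(list(channels = lapply(channels, function(m) {
    storage.mode(m) <- "double"; m
  }), pixel_size = pixel_size), class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1L]])

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_stack> %d x %d px (%.3g x %.3g µm), %.4g µm/px\n",
              d[2L], d[1L], d[2L] * x$pixel_size, d[1L] * x$pixel_size,
              x$pixel_size))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of an image stack
#' @param image an [image_stack()].
#' @param channel channel name.
#' @return numeric matrix `[y, x]`.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "image_stack"))
  if (!channel %in% names(image$channels))
    stopf("channel '%s' not present (have: %s)", channel,
          paste(names(image$channels), collapse = ", "))
  image$channels[[channel]]
}

channel_names <- function(image) names(image$channels)

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a multichannel TIFF with calibration sidecar
#'
#' Planes are stored as 16-bit TIFF (the usual microscopy bit depth), one
#' plane per channel in channel order, each channel scaled by its maximum
#' on write (quantization step: channel max / 65535); the scale factors,
#' channel names and pixel size are recorded in a JSON sidecar
#' (`<path>.json` next to the TIFF) and undone on read. Writing then
#' re-reading then writing again is byte-identical.
#'
#' @param image an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @seealso [read_image()]
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image_stack"))
  scales <- vapply(image$channels, function(m) {
    mx <- suppressWarnings(max(m, na.rm = TRUE))
    if (!is.finite(mx) || mx <= 0) 1 else mx
  }, numeric(1L))
  planes <- Map(function(m, s) round(m / s * 65535) / 65535,
                image$channels, scales)
  suppressWarnings(tiff::writeTIFF(unname(planes), path,
                                   bits.per.sample = 16L,
                                   compression = "none", reduce = FALSE))
  meta <- list(pixel_size = image$pixel_size,
               channels = as.list(names(image$channels)),
               intensity_scale = as.list(unname(scales)))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             sidecar_path(path))
  invisible(path)
}

#' Read a multichannel TIFF into an image stack
#'
#' Calibration and channel names are taken from the JSON sidecar written by
#' [write_image()] when present. For foreign TIFFs without a sidecar the
#' calibration must be supplied via `pixel_size_override`; channels are then
#' named `ch1`, `ch2`, ... in storage order.
#'
#' @param path TIFF file (>= 1 plane).
#' @param pixel_size_override optional µm/px, takes precedence over metadata.
#' @return an [image_stack()].
#' @export
read_image <- function(path, pixel_size_override = NULL) {
  if (!file.exists(path)) stopf("cannot read image: '%s' does not exist", path)
  planes <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # collapse degenerate samples
    p
  })
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp))
    meta <- jsonlite::fromJSON(paste(readLines(sp, warn = FALSE),
                                     collapse = ""))
  px <- pixel_size_override %||% meta$pixel_size
  if (is.null(px))
    stopf("'%s' has no pixel calibration; supply pixel_size_override", path)
  nm <- unlist(meta$channels) %||% paste0("ch", seq_along(planes))
  if (length(nm) != length(planes))
    stopf("metadata lists %d channels but TIFF has %d planes",
          length(nm), length(planes))
  scl <- unlist(meta$intensity_scale) %||% rep(1, length(planes))
  planes <- Map(function(m, s) m * s, planes, scl)
  names(planes) <- nm
  image_stack(planes, pixel_size = px)
}

#' Write an integer label image as TIFF
#' @param labels integer matrix (background 0).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, path) {
  storage.mode(labels) <- "double"
  write_image(image_stack(list(labels = labels), pixel_size = 1), path)
}

#' Read a label image written by [write_label_image()]
#' @param path TIFF path.
#' @return integer matrix.
#' @export
read_label_image <- function(path) {
  m <- get_channel(read_image(path, pixel_size_override = 1), "labels")
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}
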