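#' Multi-channel microscopy field
#'
#' Container for a single imaged field: a named list of co-registered
#' channel arrays (2D matrices, or 3D arrays for z-stacks) plus the physical
#' pixel size. Typical channels are `DAPI` (nuclear stain), `Cy3` and `Cy5`
#' (FISH/smiFISH probes). All coordinates used by the package are 1-based
#' pixel indices with `x` indexing rows and `y` indexing columns.
#'
#' @param channels Named list of numeric matrices or 3D arrays, all with
#'   identical dimensions and non-negative intensities.
#' @param pixel_size Physical size of one pixel in micrometers (single
#'   number for square pixels).
#' @param z_step z-spacing in micrometers for 3D stacks (e.g. 0.45 for the
#'   confocal stacks this package targets), `NULL` for 2D fields.
#' @return An object of class `image_stack`.
#' @examples
#' img <- image_stack(list(DAPI = matrix(0, 32, 32)))
#' dim(img)
#' @export
image_stack <- function(channels, pixel_size = 1, z_step = NULL) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    abort_input("'channels' must be a non-empty named list of arrays")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    abort_input("every channel must be a matrix or array")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    abort_input("all channels must share the same dimensions")
  }
  nd <- length(dims[[1]])
  if (!nd %in% c(2L, 3L)) abort_input("channels must be 2D or 3D")
  if (nd == 3L && is.null(z_step)) {
    abort_input("3D stacks require 'z_step' (micrometers between planes)")
  }
  for (nm in names(channels)) {
    if (any(channels[[nm]] < 0, na.rm = TRUE)) {
      abort_input("channel '%s' contains negative intensities", nm)
    }
    storage.mode(channels[[nm]]) <- "double"
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    abort_input("'pixel_size' must be a single positive number")
  }
  structure(
    list(channels = channels, pixel_size = pixel_size, z_step = z_step),
    class = "image_stack"
  )
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_stack> %s px, %d channel(s): %s, pixel size %g um%s\n",
    paste(d, collapse = " x "), length(x$channels),
    paste(names(x$channels), collapse = ", "), x$pixel_size,
    if (is.null(x$z_step)) "" else sprintf(", z-step %g um", x$z_step)
  ))
  invisible(x)
}

#' Extract one channel of a field
#'
#' @param img An [image_stack()].
#' @param channel Channel name.
#' @param project For 3D stacks, maximum-intensity project to 2D before
#'   returning (the package analyzes projected stacks).
#' @return A numeric matrix (or 3D array when `project = FALSE`).
#' @export
get_channel <- function(img, channel, project = TRUE) {
  stopifnot(inherits(img, "image_stack"))
  if (!channel %in% names(img$channels)) {
    abort_input("channel '%s' not present (have: %s)", channel,
                paste(names(img$channels), collapse = ", "))
  }
  x <- img$channels[[channel]]
  if (length(dim(x)) == 3L && isTRUE(project)) {
    x <- apply(x, c(1, 2), max)
  }
  x
}

#' Write / read a field as multi-page TIFF
#'
#' Channels are stored as consecutive 32-bit float pages in the order of
#' `names(img$channels)`; a JSON sidecar (`<path>.json`) records the channel
#' order, pixel size and z-step so the stack round-trips losslessly.
#'
#' @param img An [image_stack()] (2D channels).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(img, path) {
  stopifnot(inherits(img, "image_stack"))
  planes <- lapply(img$channels, function(m) {
    if (length(dim(m)) == 3L) m <- apply(m, c(1, 2), max)
    m
  })
  # TIFF pages are stored in [0, 1]; the common intensity scale goes to
  # the sidecar so the stack round-trips on its original scale
  scale <- max(1, vapply(planes, max, numeric(1)))
  tiff::writeTIFF(lapply(planes, function(m) m / scale), path,
                  bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  meta <- list(channels = names(img$channels),
               pixel_size = img$pixel_size,
               z_step = img$z_step,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort_input("missing channel sidecar '%s'", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (length(pages) != length(meta$channels)) {
    abort_input("TIFF '%s' has %d pages but sidecar lists %d channels",
                path, length(pages), length(meta$channels))
  }
  scale <- meta$intensity_scale %||% 1
  channels <- setNames(lapply(pages, function(p) p * scale), meta$channels)
  image_stack(channels, pixel_size = meta$pixel_size,
              z_step = meta$z_step %||% NULL)
}
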