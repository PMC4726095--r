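#' Image stack container
#'
#' An `image_stack` is the carrier object for every image sequence in the
#' package: an ordered list of 2D grayscale frames (numeric matrices, image
#' rows = transverse axis, columns = flow axis) together with the physical
#' acquisition metadata needed to convert pixel displacements into
#' velocities.
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param pixel_pitch physical size of one pixel, micrometres per pixel.
#' @param frame_rate acquisition rate in frames per second.
#'
#' @return An object of class `xpiv_stack`.
#' @export
image_stack <- function(frames, pixel_pitch, frame_rate) {
  if (!is.list(frames) || length(frames) == 0L)
    stopf("`frames` must be a non-empty list of matrices")
  dims <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), dims), logical(1))
  if (!all(ok)) stopf("all frames must be matrices with identical dimensions")
  if (pixel_pitch <= 0 || frame_rate <= 0)
    stopf("pixel_pitch and frame_rate must be positive")
  structure(
    list(frames = frames, pixel_pitch = pixel_pitch, frame_rate = frame_rate),
    class = "xpiv_stack"
  )
}

#' @export
length.xpiv_stack <- function(x) length(x$frames)

#' @export
print.xpiv_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<xpiv_stack> %d frames of %d x %d px, %.4f um/px, %g fps (%.3f s)\n",
    length(x$frames), d[1], d[2], x$pixel_pitch, x$frame_rate,
    length(x$frames) / x$frame_rate
  ))
  invisible(x)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path path to a multi-page TIFF file.
#' @param pixel_pitch,frame_rate acquisition metadata; if `NULL`, read from a
#'   JSON sidecar `<path>.json` written by [write_stack()].
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_pitch = NULL, frame_rate = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if ((is.null(pixel_pitch) || is.null(frame_rate)) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_pitch <- pixel_pitch %||% meta$pixel_pitch
    frame_rate <- frame_rate %||% meta$frame_rate
  }
  if (is.null(pixel_pitch) || is.null(frame_rate))
    stopf("pixel_pitch and frame_rate must be given or present in %s", sidecar)
  image_stack(pages, pixel_pitch, frame_rate)
}

#' Write an image stack to a multi-page 16-bit TIFF with a JSON sidecar
#'
#' Frames are clipped to [0, 1] before quantization. The sidecar records the
#' acquisition metadata plus any extra provenance fields supplied.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param meta named list of extra sidecar fields (e.g. seed, config hash).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, meta = list()) {
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  sidecar <- c(
    list(pixel_pitch = stack$pixel_pitch, frame_rate = stack$frame_rate,
         n_frames = length(stack$frames)),
    meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
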