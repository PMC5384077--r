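#' Image sequence container
#'
#' Bundles an ordered stack of grayscale frames with the acquisition
#' constants needed downstream: the pixel size on the object plane and the
#' frame interval. Frames are numeric matrices in \code{[0, 1]} indexed
#' \code{[row, col]}; the stack is stored as an \code{H x W x T} array.
#'
#' @param frames a list of equally sized numeric matrices, or a 3-d array
#'   with time along the third dimension.
#' @param pixel_size_um pixel size on the object plane (micrometres/pixel).
#' @param frame_rate_hz acquisition rate (frames per second).
#' @param source free-text identifier of the originating acquisition.
#' @return an object of class \code{image_sequence}.
#' @export
image_sequence <- function(frames, pixel_size_um = 1.25, frame_rate_hz = 50,
                           source = "unknown") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must share identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3) stop("frames must form an H x W x T array")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be positive")
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) {
    stop("frame_rate_hz must be positive")
  }
  structure(
    list(
      frames = frames,
      pixel_size_um = pixel_size_um,
      frame_interval_s = 1 / frame_rate_hz,
      source = source
    ),
    class = "image_sequence"
  )
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "image_sequence: %d frames of %d x %d px, %.3g um/px, %.3g ms/frame (%s)\n",
    d[3], d[2], d[1], x$pixel_size_um, 1000 * x$frame_interval_s, x$source
  ))
  invisible(x)
}

n_frames <- function(seq) dim(seq$frames)[3]

#' Read / write multi-page TIFF stacks
#'
#' Thin wrappers around \pkg{tiff} that preserve the acquisition constants
#' via function arguments (TIFF tags are not relied upon).
#'
#' @param path file path.
#' @param pixel_size_um,frame_rate_hz acquisition constants attached to the
#'   returned sequence.
#' @return \code{read_sequence_tiff} returns an \code{image_sequence};
#'   \code{write_sequence_tiff} returns \code{path} invisibly.
#' @export
read_sequence_tiff <- function(path, pixel_size_um = 1.25, frame_rate_hz = 50) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse RGB written by other tools
    p
  })
  image_sequence(pages, pixel_size_um, frame_rate_hz, source = basename(path))
}

#' @param seq an \code{image_sequence}.
#' @rdname read_sequence_tiff
#' @export
write_sequence_tiff <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  nf <- n_frames(seq)
  pages <- lapply(seq_len(nf), function(t) clamp(seq$frames[, , t], 0, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
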