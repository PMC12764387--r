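#' Time-lapse movie container
#'
#' A movie is a `H x W x T` numeric array of nonnegative intensities with
#' acquisition metadata: frame rate (frames/s) and pixel size (um/pixel).
#' Frames are stored along the third dimension so that `frames[, , t]` is
#' one image, rows being the image y axis (increasing downwards) and
#' columns the x axis.
#'
#' @param frames numeric `H x W x T` array, `T >= 2`, finite, >= 0.
#' @param frame_rate frames per second, > 0.
#' @param pixel_size pixel size in micrometres, > 0.
#' @return object of class `cw_movie`.
#' @export
cw_movie <- function(frames, frame_rate, pixel_size) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3] < 2L) stop("a movie needs at least 2 frames")
  if (!all(is.finite(frames))) stop("frames must be finite")
  if (min(frames) < 0) stop("frames must be nonnegative")
  stopifnot(is.numeric(frame_rate), frame_rate > 0,
            is.numeric(pixel_size), pixel_size > 0)
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size),
            class = "cw_movie")
}

#' @export
print.cw_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cw_movie> %d x %d px, %d frames @ %g fps, %g um/px\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie a `cw_movie`.
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Movie TIFF I/O
#'
#' Movies are written as multi-page 32-bit float TIFF with intensities
#' rescaled to [0, 1]; the scale factor plus `frame_rate` and
#' `pixel_size_um` metadata go to a JSON sidecar (`<path>.json`), from
#' which `read_movie_tiff` restores the original intensities.
#'
#' @param movie a `cw_movie`.
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `read_movie_tiff` returns a `cw_movie`; `write_movie_tiff`
#'   returns `path` invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "cw_movie"))
  scale <- max(movie$frames)
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(n_frames(movie)),
                  function(t) movie$frames[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(frame_rate = movie$frame_rate, pixel_size_um = movie$pixel_size,
         intensity_scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  cw_movie(frames * meta$intensity_scale, meta$frame_rate, meta$pixel_size_um)
}
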