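#' Frame stacks and regions of interest
#'
#' A frame stack is an ordered sequence of same-sized 2-D grayscale frames
#' (integer intensities 0--255) with a frame rate, the raw material of motion
#' energy analysis. It is stored as a `height x width x n_frames` array.
#'
#' @param frames a `height x width x n` numeric array, or a list of equally
#'   sized matrices, with intensities in 0--255.
#' @param frame_rate frames per second (> 0).
#' @return An object of class `frame_stack`: a list with elements `frames`
#'   (integer array), `frame_rate`, `height`, `width`, `n_frames`.
#' @examples
#' fs <- frame_stack(array(128L, dim = c(4, 6, 3)), frame_rate = 25)
#' fs$n_frames
#' @export
frame_stack <- function(frames, frame_rate) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share identical dimensions", call. = FALSE)
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a height x width x n array or list of matrices",
         call. = FALSE)
  if (dim(frames)[3L] < 2L)
    stop("a frame stack needs at least 2 frames", call. = FALSE)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("'frame_rate' must be a single positive number", call. = FALSE)
  storage.mode(frames) <- "integer"
  structure(
    list(frames = frames, frame_rate = frame_rate,
         height = dim(frames)[1L], width = dim(frames)[2L],
         n_frames = dim(frames)[3L]),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames, %dx%d px, %g fps (%.1f s)\n",
              x$n_frames, x$width, x$height, x$frame_rate,
              x$n_frames / x$frame_rate))
  invisible(x)
}

#' Rectangular region of interest covering one interactant
#'
#' Pixel bounds are 0-based and half-open, `[x0, x1) x [y0, y1)`, with x
#' running along image columns and y along rows. Each person in the camera
#' view gets one ROI so that a single recording yields two separate movement
#' series.
#'
#' @param label role identifier, conventionally `"patient"` or `"clinician"`.
#' @param x0,y0,x1,y1 integer pixel bounds, 0-based, half-open.
#' @return An object of class `roi`.
#' @examples
#' roi("patient", 0, 0, 320, 720)
#' @export
roi <- function(label, x0, y0, x1, y1) {
  b <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (any(b != floor(b)) || any(b < 0))
    stop("ROI bounds must be nonnegative integers", call. = FALSE)
  if (!(x0 < x1 && y0 < y1))
    stop("ROI must satisfy x0 < x1 and y0 < y1", call. = FALSE)
  structure(list(label = as.character(label),
                 x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s: [%d,%d) x [%d,%d), %d px\n",
              x$label, x$x0, x$x1, x$y0, x$y1, roi_area(x)))
  invisible(x)
}

roi_area <- function(r) (r$x1 - r$x0) * (r$y1 - r$y0)

roi_overlaps <- function(a, b) {
  a$x0 < b$x1 && b$x0 < a$x1 && a$y0 < b$y1 && b$y0 < a$y1
}

check_roi_bounds <- function(r, fs) {
  if (r$x1 > fs$width || r$y1 > fs$height)
    stop(sprintf("ROI '%s' exceeds frame bounds (%dx%d)",
                 r$label, fs$width, fs$height), call. = FALSE)
  invisible(TRUE)
}

# ROI as R (1-based) row/col index vectors into a frame matrix
roi_index <- function(r) {
  list(rows = (r$y0 + 1L):r$y1, cols = (r$x0 + 1L):r$x1)
}

# ITU-R BT.601 luminance, the standard weighting for video material
luminance <- function(rgb) {
  0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
}

#' Read a frame stack from a directory of image frames
#'
#' Reads an alphabetically ordered directory of PNG or TIFF frames into a
#' [frame_stack()]. Color frames are converted to grayscale by ITU-R BT.601
#' luminance (0.299 R + 0.587 G + 0.114 B) and scaled to integer 0--255.
#' Video containers (MP4/AVI) are not decoded directly; extract frames to
#' images first (e.g. `ffmpeg -i in.mp4 frames/f%06d.png`) and point this
#' function at the directory.
#'
#' @param path directory containing the frames.
#' @param frame_rate frames per second; required because image directories
#'   carry no timing metadata.
#' @param pattern regular expression selecting the frame files.
#' @return A [frame_stack()].
#' @export
read_frames <- function(path, frame_rate,
                        pattern = "\\.(png|tif|tiff)$") {
  if (missing(frame_rate))
    stop("'frame_rate' must be supplied for image directories", call. = FALSE)
  if (!dir.exists(path)) {
    if (file.exists(path) && grepl("\\.(mp4|avi|mov|mkv)$", path,
                                   ignore.case = TRUE))
      stop("video containers are not decoded directly; extract frames to a ",
           "PNG directory first (e.g. with ffmpeg) and pass that directory",
           call. = FALSE)
    stop("'path' must be an existing directory of image frames", call. = FALSE)
  }
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) < 2L)
    stop("need at least 2 frame images in ", path, call. = FALSE)
  read1 <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3L] >= 3L) img <- luminance(img) else img <- img[, , 1L]
    }
    round(img * 255)
  }
  frames <- lapply(files, read1)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L)
    stop("frames in ", path, " have mixed dimensions", call. = FALSE)
  frame_stack(frames, frame_rate)
}
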