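#' Motion-energy series
#'
#' A motion-energy series records, for each frame transition t -> t+1, the
#' number of pixels inside one person's ROI whose grayscale intensity changed
#' by more than the noise threshold. It is the elementary movement signal of
#' motion energy analysis (MEA): `values[t]` describes the transition from
#' frame t to frame t+1 (0-based), so a stack of n frames yields n-1 values.
#'
#' @param values nonnegative numeric vector, one entry per frame transition.
#' @param frame_rate frames per second.
#' @param label role identifier (`"patient"` / `"clinician"`).
#' @param threshold intensity-change cut-off used to produce the series
#'   (`NA` when unknown, e.g. simulated series).
#' @return An object of class `mes`: a numeric vector with attributes
#'   `frame_rate`, `label`, `threshold`.
#' @export
motion_energy_series <- function(values, frame_rate, label = "person",
                                 threshold = NA_real_) {
  if (length(values) < 1L || any(!is.finite(values)) || any(values < 0))
    stop("'values' must be a nonempty, finite, nonnegative vector",
         call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("'frame_rate' must be positive", call. = FALSE)
  structure(as.numeric(values), frame_rate = frame_rate,
            label = as.character(label), threshold = threshold,
            class = "mes")
}

#' @export
print.mes <- function(x, ...) {
  cat(sprintf("<mes> '%s': %d transitions at %g fps (%.1f s), moving %.1f%%\n",
              attr(x, "label"), length(x), attr(x, "frame_rate"),
              length(x) / attr(x, "frame_rate"),
              100 * mean(unclass(x) > 0)))
  invisible(x)
}

#' @export
plot.mes <- function(x, ...) {
  fr <- attr(x, "frame_rate")
  graphics::plot((seq_along(x) - 1) / fr, unclass(x), type = "l",
                 xlab = "time (s)", ylab = "motion energy (changed pixels)",
                 main = attr(x, "label"), ...)
  invisible(x)
}

frame_rate_of <- function(x, frame_rate = NULL) {
  fr <- attr(x, "frame_rate")
  if (!is.null(frame_rate)) return(frame_rate)
  if (is.null(fr)) stop("supply 'frame_rate' for plain numeric series",
                        call. = FALSE)
  fr
}

#' Compute motion energy inside a region of interest
#'
#' For every frame transition, counts pixels in `roi` whose absolute
#' grayscale change is strictly greater than `threshold`. The strict
#' comparison means a change of exactly `threshold` does *not* count as
#' movement; with the default threshold 3, a pixel must change by 4 or more.
#'
#' @param frames a [frame_stack()].
#' @param roi a [roi()] lying within the frame bounds.
#' @param threshold nonnegative intensity-change cut-off (default 3, the
#'   value a 99%-quantile calibration of typical camera noise yields).
#' @return A [motion_energy_series()] of length `n_frames - 1`.
#' @seealso [calibrate_threshold()] to derive `threshold` from a static
#'   background region.
#' @examples
#' a <- array(100L, dim = c(8, 8, 3)); a[1, 1, 2] <- 110L
#' motion_energy(frame_stack(a, 25), roi("p", 0, 0, 8, 8))
#' @export
motion_energy <- function(frames, roi, threshold = 3) {
  stopifnot(inherits(frames, "frame_stack"), inherits(roi, "roi"))
  if (threshold < 0) stop("'threshold' must be >= 0", call. = FALSE)
  check_roi_bounds(roi, frames)
  ix <- roi_index(roi)
  sub <- frames$frames[ix$rows, ix$cols, , drop = FALSE]
  n <- dim(sub)[3L]
  m <- matrix(sub, ncol = n)                      # pixels x frames
  d <- abs(m[, -1L, drop = FALSE] - m[, -n, drop = FALSE])
  counts <- colSums(d > threshold)
  motion_energy_series(counts, frames$frame_rate, label = roi$label,
                       threshold = threshold)
}

#' Calibrate the motion-energy noise threshold from a static background
#'
#' Pools the absolute frame-to-frame intensity changes of all pixels in a
#' background region where no movement takes place, over all transitions,
#' takes the requested empirical quantile (default 99%), and rounds it up to
#' the next integer. Used with the strict comparison of [motion_energy()],
#' the returned threshold excludes at least that quantile of pure noise.
#'
#' @param frames a [frame_stack()] showing only static background in `roi`.
#' @param roi the background [roi()].
#' @param quantile probability in (0, 1); default 0.99.
#' @return Integer threshold (0 for a perfectly constant background).
#' @export
calibrate_threshold <- function(frames, roi, quantile = 0.99) {
  stopifnot(inherits(frames, "frame_stack"), inherits(roi, "roi"))
  if (quantile <= 0 || quantile >= 1)
    stop("'quantile' must lie in (0, 1)", call. = FALSE)
  check_roi_bounds(roi, frames)
  ix <- roi_index(roi)
  sub <- frames$frames[ix$rows, ix$cols, , drop = FALSE]
  n <- dim(sub)[3L]
  m <- matrix(sub, ncol = n)
  d <- abs(m[, -1L, drop = FALSE] - m[, -n, drop = FALSE])
  as.integer(ceiling(stats::quantile(d, probs = quantile, names = FALSE)))
}

#' Gross body movement
#'
#' The fraction of frame transitions during which a person moved at all,
#' i.e. the motion-energy value was positive. Reported as a proportion in
#' `[0, 1]` (a person moving 40% of the time scores 0.40).
#'
#' @param series a [motion_energy_series()] or numeric vector.
#' @return Proportion of transitions with nonzero motion energy.
#' @export
gross_body_movement <- function(series) {
  v <- unclass(series)
  if (length(v) == 0L) stop("empty series", call. = FALSE)
  mean(v > 0)
}

#' Moving-median smoothing of a motion-energy series
#'
#' Spike artifacts (compression glitches, brief occlusions) are damped with a
#' centered moving median before synchrony analysis. The kernel spans
#' `width_s` seconds, rounded to the nearest odd number of frames; edges use
#' the shrinking-window median. Set `width_s = 0` to disable.
#'
#' @param series a [motion_energy_series()] or numeric vector.
#' @param width_s kernel width in seconds (default 0.5).
#' @param frame_rate frames per second (taken from the series when present).
#' @return Smoothed series of the same class and length.
#' @export
smooth_series <- function(series, width_s = 0.5, frame_rate = NULL) {
  if (width_s == 0) return(series)
  fr <- frame_rate_of(series, frame_rate)
  k <- max(1L, round(width_s * fr))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(series)
  v <- unclass(series)
  out <- stats::runmed(v, k, endrule = "median")
  attributes(out) <- attributes(series)
  out
}

#' Write / read a motion-energy series as delimited text
#'
#' The series is written as a two-column CSV (`frame_transition_index`,
#' `value`, 0-based indices) with a JSON sidecar (`<path>.json`) holding the
#' label, frame rate and threshold, so a round trip is lossless.
#'
#' @param series a [motion_energy_series()].
#' @param path CSV file path.
#' @return `write_series` returns `path` invisibly; `read_series` returns a
#'   [motion_energy_series()].
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "mes"))
  utils::write.csv(
    data.frame(frame_transition_index = seq_along(series) - 1L,
               value = as.numeric(series)),
    path, row.names = FALSE)
  meta <- list(label = attr(series, "label"),
               frame_rate = attr(series, "frame_rate"),
               threshold_used = attr(series, "threshold"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_series
#' @param frame_rate,label fallbacks when no JSON sidecar is present.
#' @export
read_series <- function(path, frame_rate = NULL, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!"value" %in% names(df)) {
    if (ncol(df) == 1L) names(df) <- "value"
    else stop("series file needs a 'value' column", call. = FALSE)
  }
  threshold <- NA_real_
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(frame_rate)) frame_rate <- meta$frame_rate
    if (is.null(label)) label <- meta$label
    if (!is.null(meta$threshold_used)) threshold <- meta$threshold_used
  }
  if (is.null(frame_rate))
    stop("no frame rate: supply 'frame_rate' or provide the JSON sidecar",
         call. = FALSE)
  motion_energy_series(df$value, frame_rate,
                       label = if (is.null(label)) "person" else label,
                       threshold = threshold)
}
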