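#' Windowed cross-lagged correlation (WCLC) of two movement series
#'
#' Slides a window of `window_s` seconds along the two motion-energy series
#' and computes the Pearson correlation at every lag up to `max_lag_s`
#' seconds (default 5 s, the latency up to which movements are considered
#' synchronous), producing a correlation surface over (window start, lag).
#'
#' Lag convention: at lag `l` the *leader's* window starts at grid position
#' `t` and the follower's window `|l|` frames later. Positive `l` means the
#' clinician's window is the later one, i.e. the **patient leads**; negative
#' `l` means the clinician leads. For `l >= 0` this is
#' `cor(patient[t : t+W], clinician[t+l : t+l+W])`; anchoring the earlier
#' window at `t` for both signs makes the surface exactly mirror-symmetric
#' under exchanging the two series (`r(t, l) -> r(t, -l)`).
#'
#' Cells whose shifted window would run past the series end, or in which
#' either window has zero variance (no movement), are undefined and marked
#' invalid.
#'
#' @param patient,clinician [motion_energy_series()] (or numeric vectors) of
#'   equal length and frame rate.
#' @param window_s window width in seconds (default 5).
#' @param step_s spacing of window starts in seconds (default 1).
#' @param max_lag_s maximum lag in seconds (default 5).
#' @param frame_rate frames per second; taken from the series when present.
#' @return An object of class `wclc`: list with `r` (matrix, window starts x
#'   lags, `NA` = invalid), `starts` (0-based start frames), `lags` (frames),
#'   `window` (frames), `step` (frames), `frame_rate`, `n` (series length).
#' @examples
#' set.seed(1)
#' x <- abs(rnorm(400)); y <- c(rep(0, 25), x[1:375])   # y trails x by 1 s
#' m <- wclc(x, y, frame_rate = 25)
#' m$lags[which.max(m$r[8, ])]                           # ~ +25 frames
#' @export
wclc <- function(patient, clinician, window_s = 5, step_s = 1,
                 max_lag_s = 5, frame_rate = NULL) {
  fr <- frame_rate_of(patient, frame_rate)
  fr2 <- attr(clinician, "frame_rate")
  if (!is.null(fr2) && !is.null(attr(patient, "frame_rate")) && fr2 != fr)
    stop("mismatched frame rates", call. = FALSE)
  x <- as.numeric(patient)
  y <- as.numeric(clinician)
  if (length(x) != length(y))
    stop("series must have equal length", call. = FALSE)
  n <- length(x)
  W <- max(2L, as.integer(round(window_s * fr)))
  step <- max(1L, as.integer(round(step_s * fr)))
  L <- as.integer(round(max_lag_s * fr))
  if (n < W + L)
    stop(sprintf("series too short: need >= %d frames (window + max lag)",
                 W + L), call. = FALSE)
  starts <- seq.int(0L, n - W, by = step)          # 0-based start frames
  lags <- seq.int(-L, L)
  r <- matrix(NA_real_, nrow = length(starts), ncol = length(lags),
              dimnames = list(starts, lags))

  cx <- c(0, cumsum(x)); cxx <- c(0, cumsum(x * x))
  cy <- c(0, cumsum(y)); cyy <- c(0, cumsum(y * y))
  for (j in seq_along(lags)) {
    l <- lags[j]; al <- abs(l)
    a <- max(0L, -l)                               # leader-window offset of x
    b <- max(0L, l)                                # ... of y
    ok <- starts <= n - W - al
    if (!any(ok)) next
    t0 <- starts[ok]
    # cross-products aligned on the pair index
    np <- n - al
    z <- x[(a + 1L):(a + np)] * y[(b + 1L):(b + np)]
    cz <- c(0, cumsum(z))
    sx <- cx[t0 + a + W + 1L] - cx[t0 + a + 1L]
    sxx <- cxx[t0 + a + W + 1L] - cxx[t0 + a + 1L]
    sy <- cy[t0 + b + W + 1L] - cy[t0 + b + 1L]
    syy <- cyy[t0 + b + W + 1L] - cyy[t0 + b + 1L]
    sxy <- cz[t0 + W + 1L] - cz[t0 + 1L]
    vx <- W * sxx - sx * sx
    vy <- W * syy - sy * sy
    # zero-variance windows are undefined; tolerance guards cumsum round-off
    epsx <- 1e-9 * pmax(W * sxx, 1)
    epsy <- 1e-9 * pmax(W * syy, 1)
    val <- vx > epsx & vy > epsy
    rj <- rep(NA_real_, length(t0))
    rj[val] <- pmin(1, pmax(-1, (W * sxy[val] - sx[val] * sy[val]) /
                                  sqrt(vx[val] * vy[val])))
    r[ok, j] <- rj
  }
  structure(list(r = r, starts = starts, lags = lags, window = W,
                 step = step, max_lag = L, frame_rate = fr, n = n),
            class = "wclc")
}

#' @export
print.wclc <- function(x, ...) {
  cat(sprintf(
    "<wclc> %d window starts x %d lags (window %d, step %d, max lag %d frames at %g fps)\n",
    length(x$starts), length(x$lags), x$window, x$step, x$max_lag,
    x$frame_rate))
  cat(sprintf("  defined cells: %d of %d\n", sum(!is.na(x$r)),
              length(x$r)))
  invisible(x)
}

#' @export
as.matrix.wclc <- function(x, ...) x$r

#' Plot a WCLC surface
#'
#' Displays squared correlation over window start (x, seconds) and lag
#' (y, seconds); positive lags are patient-led. Detected synchrony intervals
#' can be overlaid.
#'
#' @param x a [wclc()] object.
#' @param intervals optional interval data frame from [peak_picking()].
#' @param ... passed to [graphics::image()].
#' @export
plot.wclc <- function(x, intervals = NULL, ...) {
  r2 <- x$r^2
  graphics::image(x$starts / x$frame_rate, x$lags / x$frame_rate, r2,
                  xlab = "window start (s)", ylab = "lag (s)  [+ = patient leads]",
                  main = expression(WCLC ~ R^2), ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(intervals) && nrow(intervals)) {
    sgn <- ifelse(intervals$leader == "patient", 1,
                  ifelse(intervals$leader == "clinician", -1, 0))
    graphics::segments(intervals$start_frame / x$frame_rate,
                       sgn * intervals$lag_seconds,
                       intervals$end_frame / x$frame_rate,
                       sgn * intervals$lag_seconds,
                       lwd = 3)
  }
  invisible(x)
}
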