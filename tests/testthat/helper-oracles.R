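# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately use naive two-pass formulas / explicit loops,
# not the package's vectorized paths.

# naive per-window Pearson over the same index ranges as wclc()
brute_wclc <- function(x, y, W, step, L) {
  n <- length(x)
  starts <- seq(0, n - W, by = step)
  lags <- -L:L
  r <- matrix(NA_real_, length(starts), length(lags))
  for (i in seq_along(starts)) for (j in seq_along(lags)) {
    t0 <- starts[i]; l <- lags[j]
    a <- max(0, -l); b <- max(0, l)
    if (t0 > n - W - abs(l)) next
    xs <- x[(t0 + a + 1):(t0 + a + W)]
    ys <- y[(t0 + b + 1):(t0 + b + W)]
    if (max(xs) == min(xs) || max(ys) == min(ys)) next
    r[i, j] <- stats::cor(xs, ys)
  }
  r
}

# per-pixel loop tally of supra-threshold changes inside an ROI
brute_motion_energy <- function(frames, r, threshold) {
  n <- dim(frames)[3]
  out <- integer(n - 1)
  for (t in 1:(n - 1)) {
    cnt <- 0L
    for (yy in (r$y0 + 1):r$y1) for (xx in (r$x0 + 1):r$x1) {
      if (abs(frames[yy, xx, t + 1] - frames[yy, xx, t]) > threshold)
        cnt <- cnt + 1L
    }
    out[t] <- cnt
  }
  out
}

# hand-built wclc object for peak-picking tests
fake_wclc <- function(r, starts, lags, window, step, frame_rate, n = NULL) {
  if (is.null(n)) n <- max(starts) + window + max(abs(lags))
  structure(list(r = r, starts = starts, lags = lags, window = window,
                 step = step, max_lag = max(abs(lags)),
                 frame_rate = frame_rate, n = n),
            class = "wclc")
}

# hand-built interval table
make_intervals <- function(start, end, leader, lag_s, r2, n, frame_rate = 25) {
  structure(data.frame(start_frame = as.integer(start),
                       end_frame = as.integer(end),
                       leader = leader, lag_seconds = lag_s,
                       peak_r2 = r2,
                       n_windows = rep(1L, length(start))),
            n = n, frame_rate = frame_rate,
            class = c("sync_intervals", "data.frame"))
}

# small frame stack from a list of matrices
fs_of <- function(..., fr = 25) frame_stack(list(...), frame_rate = fr)
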