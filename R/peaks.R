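#' Peak-picking: from a WCLC surface to synchrony intervals
#'
#' For each window start, the candidate peak is the lag that maximizes the
#' squared correlation among cells that (a) are local maxima along the lag
#' axis, (b) reach `r2_cutoff`, and (c) — in the default `"positive"` mode —
#' have a positive correlation (in-phase movement). Maximal runs of
#' consecutive window starts whose candidate peaks share the same lag *sign*
#' are merged into one synchrony interval spanning the union of the
#' contributing windows. The interval lag is the R²-weighted mean of the
#' absolute peak lags; the leader follows the lag sign (positive = patient
#' leads, negative = clinician leads, all-zero = tie).
#'
#' Local maxima are strict against both lag-neighbors; plateaus of equal
#' values count once, at the plateau center. Ties between candidate lags are
#' broken toward the smaller absolute lag, then toward the positive lag.
#'
#' @param m a [wclc()] object.
#' @param r2_cutoff minimum squared correlation for a peak (default 0.25,
#'   chosen to suppress spurious correlation between movement series).
#' @param mode `"positive"` (only r > 0 counts as synchrony, the default) or
#'   `"absolute"` (anti-phase movement counts too).
#' @return A data frame of class `sync_intervals` with columns `start_frame`,
#'   `end_frame` (half-open, frame coordinates), `leader`
#'   (`patient`/`clinician`/`tie`), `lag_seconds` (nonnegative), `peak_r2`,
#'   `n_windows`; attributes `n` (series length) and `frame_rate`.
#' @export
peak_picking <- function(m, r2_cutoff = 0.25, mode = c("positive", "absolute")) {
  stopifnot(inherits(m, "wclc"))
  mode <- match.arg(mode)
  if (r2_cutoff <= 0 || r2_cutoff >= 1)
    stop("'r2_cutoff' must lie in (0, 1)", call. = FALSE)
  r <- m$r
  if (mode == "positive") r[!is.na(r) & r < 0] <- NA_real_
  r2 <- r * r
  nr <- nrow(r2)
  peak_lag <- rep(NA_integer_, nr)
  peak_r2 <- rep(NA_real_, nr)
  for (i in seq_len(nr)) {
    cand <- lag_local_maxima(r2[i, ])
    cand <- cand[r2[i, cand] >= r2_cutoff]
    if (!length(cand)) next
    v <- r2[i, cand]
    al <- abs(m$lags[cand])
    # max R2; ties -> smaller |lag|; then positive lag
    o <- order(-v, al, -sign(m$lags[cand]))
    peak_lag[i] <- m$lags[cand[o[1L]]]
    peak_r2[i] <- v[o[1L]]
  }

  # runs: break where a window has no valid peak or the lag sign flips
  has <- !is.na(peak_lag)
  sgn <- ifelse(has, sign(peak_lag), NA_integer_)
  brk <- logical(nr)
  brk[1L] <- TRUE
  if (nr > 1L) for (i in 2:nr) {
    brk[i] <- has[i] != has[i - 1L] ||
      (has[i] && sgn[i] != sgn[i - 1L])
  }
  run_id <- cumsum(brk)

  out <- list()
  for (g in split(seq_len(nr), run_id)) {
    if (!has[g[1L]]) next
    t0 <- m$starts[g]
    w <- peak_r2[g]
    lag_s <- sum(w * abs(peak_lag[g])) / sum(w) / m$frame_rate
    s <- sgn[g[1L]]
    out[[length(out) + 1L]] <- data.frame(
      start_frame = t0[1L],
      end_frame = t0[length(t0)] + m$window,
      leader = if (s > 0) "patient" else if (s < 0) "clinician" else "tie",
      lag_seconds = lag_s,
      peak_r2 = max(w),
      n_windows = length(g))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start_frame = integer(), end_frame = integer(),
               leader = character(), lag_seconds = numeric(),
               peak_r2 = numeric(), n_windows = integer())
  structure(res, n = m$n, frame_rate = m$frame_rate,
            r2_cutoff = r2_cutoff,
            class = c("sync_intervals", "data.frame"))
}

# indices of strict local maxima along a lag profile, plateaus -> center.
# NA (invalid/excluded) cells act as -Inf neighbors.
lag_local_maxima <- function(v) {
  w <- ifelse(is.na(v), -Inf, v)
  rl <- rle(w)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  k <- length(rl$values)
  prev <- c(-Inf, rl$values[-k])
  nxt <- c(rl$values[-1L], -Inf)
  is_max <- is.finite(rl$values) & rl$values > prev & rl$values > nxt
  centers <- starts + (rl$lengths - 1L) %/% 2L
  centers[is_max]
}

#' Attribute frames to patient-led / clinician-led synchrony
#'
#' Expands a set of synchrony intervals into a per-frame attribution. Every
#' frame covered by at least one interval is attributed to exactly one side;
#' where patient-led and clinician-led intervals overlap, the interval with
#' the higher peak R² wins (ties: earlier start, then patient). Tie-leader
#' (zero-lag) frames later contribute half a frame to each side, so
#' total = patient-led + clinician-led holds exactly.
#'
#' @param intervals a `sync_intervals` data frame from [peak_picking()].
#' @param n_frames length of the motion-energy series (number of transitions).
#' @return Character vector of length `n_frames` with values `"patient"`,
#'   `"clinician"`, `"tie"`, `"none"`.
#' @export
attribute_frames <- function(intervals, n_frames) {
  if (n_frames <= 0) stop("'n_frames' must be positive", call. = FALSE)
  att <- rep("none", n_frames)
  if (!nrow(intervals)) return(att)
  if (any(intervals$start_frame < 0) || any(intervals$end_frame > n_frames))
    stop("interval outside series bounds", call. = FALSE)
  lead_rank <- c(patient = 1L, clinician = 2L, tie = 3L)
  o <- order(-intervals$peak_r2, intervals$start_frame,
             lead_rank[intervals$leader])
  best <- rep(NA_integer_, n_frames)               # winning interval per frame
  for (i in rev(o)) {                              # strongest painted last
    span <- (intervals$start_frame[i] + 1L):intervals$end_frame[i]
    best[span] <- i
  }
  covered <- !is.na(best)
  att[covered] <- intervals$leader[best[covered]]
  att
}
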