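#' Per-dyad synchrony profile
#'
#' Summarizes a dyad's synchrony intervals into the measures analyzed at the
#' cohort level. Movement synchrony (MS) is the proportion of the interaction
#' spent in synchrony (40% -> .40), split by leader into patient-led and
#' clinician-led MS via the frame attribution, so that
#' `ms_total = ms_patient_led + ms_clinician_led` holds exactly. The leading
#' variable is patient-led minus clinician-led MS (positive = the patient
#' initiated more synchrony). Mean time-lags are unweighted means of the
#' interval lags (each interval one observation), overall and per leader
#' class; they are `NA` when no interval of that class exists.
#'
#' @param intervals a `sync_intervals` data frame from [peak_picking()].
#' @param n_frames series length (number of frame transitions).
#' @param frame_rate frames per second (taken from `intervals` if present).
#' @return An object of class `sync_profile`: named list with `ms_total`,
#'   `ms_patient_led`, `ms_clinician_led`, `leading`, `lag_mean`,
#'   `lag_mean_patient_led`, `lag_mean_clinician_led`, `n_intervals`.
#' @examples
#' # a patient-led interval covering 40% of 100 frames
#' iv <- structure(data.frame(start_frame = 0L, end_frame = 40L,
#'                            leader = "patient", lag_seconds = 1,
#'                            peak_r2 = .5, n_windows = 1L),
#'                 class = c("sync_intervals", "data.frame"))
#' summarize_intervals(iv, 100, 25)$ms_patient_led
#' @export
summarize_intervals <- function(intervals, n_frames,
                                frame_rate = attr(intervals, "frame_rate")) {
  if (is.null(n_frames) || n_frames <= 0)
    stop("'n_frames' must be positive", call. = FALSE)
  att <- attribute_frames(intervals, n_frames)
  n_pat <- sum(att == "patient") + 0.5 * sum(att == "tie")
  n_clin <- sum(att == "clinician") + 0.5 * sum(att == "tie")
  ms_pat <- n_pat / n_frames
  ms_clin <- n_clin / n_frames
  lag_of <- function(cls) {
    v <- intervals$lag_seconds[intervals$leader == cls]
    if (length(v)) mean(v) else NA_real_
  }
  structure(list(
    ms_total = ms_pat + ms_clin,
    ms_patient_led = ms_pat,
    ms_clinician_led = ms_clin,
    leading = ms_pat - ms_clin,
    lag_mean = if (nrow(intervals)) mean(intervals$lag_seconds) else NA_real_,
    lag_mean_patient_led = lag_of("patient"),
    lag_mean_clinician_led = lag_of("clinician"),
    n_intervals = nrow(intervals)),
    class = "sync_profile")
}

#' @export
print.sync_profile <- function(x, ...) {
  cat("Movement synchrony profile\n")
  cat(sprintf("  total MS        : %.3f\n", x$ms_total))
  cat(sprintf("  patient-led MS  : %.3f\n", x$ms_patient_led))
  cat(sprintf("  clinician-led MS: %.3f\n", x$ms_clinician_led))
  cat(sprintf("  leading         : %+.3f\n", x$leading))
  cat(sprintf("  mean time-lag   : %s s (pat %s / clin %s)\n",
              fmt_na(x$lag_mean), fmt_na(x$lag_mean_patient_led),
              fmt_na(x$lag_mean_clinician_led)))
  cat(sprintf("  intervals       : %d\n", x$n_intervals))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)

#' Assemble per-dyad profiles into a cohort table fragment
#'
#' @param profiles named list (names = dyad ids) of [summarize_intervals()]
#'   profiles, or a list of `dyad_synchrony` fits.
#' @param gross a two-column matrix/data frame (`gross_move_patient`,
#'   `gross_move_clinician`) or `NULL`.
#' @param segment_s optional vector of segment lengths in seconds.
#' @return A data frame, one row per dyad, with the schema the statistics
#'   layer expects.
#' @export
profile_table <- function(profiles, gross = NULL, segment_s = NULL) {
  ids <- names(profiles)
  if (is.null(ids) || anyDuplicated(ids))
    stop("'profiles' must be a named list with unique dyad ids",
         call. = FALSE)
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    if (inherits(p, "dyad_synchrony")) p <- p$profile
    data.frame(dyad_id = ids[i],
               ms_total = p$ms_total,
               ms_patient_led = p$ms_patient_led,
               ms_clinician_led = p$ms_clinician_led,
               leading = p$leading,
               lag_mean = p$lag_mean,
               lag_mean_patient_led = p$lag_mean_patient_led,
               lag_mean_clinician_led = p$lag_mean_clinician_led,
               n_intervals = p$n_intervals)
  })
  out <- do.call(rbind, rows)
  if (!is.null(gross)) {
    gross <- as.data.frame(gross)
    stopifnot(nrow(gross) == nrow(out))
    out$gross_move_patient <- gross[[1L]]
    out$gross_move_clinician <- gross[[2L]]
  }
  if (!is.null(segment_s)) out$segment_s <- segment_s
  # re-check the defining identities on every assembled table
  stopifnot(all(abs(out$ms_total -
                      (out$ms_patient_led + out$ms_clinician_led)) < 1e-12),
            all(abs(out$leading -
                      (out$ms_patient_led - out$ms_clinician_led)) < 1e-12))
  out
}
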