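#' Movement synchrony analysis of one dyad
#'
#' The central fitting function: takes the two motion-energy series of a
#' dyad, optionally smooths them, computes the windowed cross-lagged
#' correlation surface, picks synchrony intervals, and summarizes them into
#' the per-dyad synchrony profile. Returns a classed object with `print`,
#' `summary`, `coef` and `plot` methods.
#'
#' @param patient,clinician [motion_energy_series()] (or numeric vectors) of
#'   equal length and frame rate.
#' @param frame_rate frames per second; taken from the series when present.
#' @param window_s,step_s,max_lag_s WCLC geometry in seconds (defaults 5, 1, 5).
#' @param r2_cutoff squared-correlation cut-off for peaks (default 0.25).
#' @param smooth_s moving-median pre-smoothing width in seconds (default 0:
#'   off; the pipeline applies 0.5 s at the MEA stage).
#' @param mode `"positive"` or `"absolute"`, see [peak_picking()].
#' @return An object of class `dyad_synchrony` with elements `wclc`
#'   (the [wclc()] surface), `intervals`, `profile`, `gross`
#'   (per-person gross body movement), `n_frames`, `frame_rate`, `call`.
#' @examples
#' sim <- simulate_dyad(sim_config(duration_s = 120, seed = 42))
#' fit <- dyad_synchrony(sim$patient, sim$clinician)
#' fit
#' coef(fit)
#' @export
dyad_synchrony <- function(patient, clinician, frame_rate = NULL,
                           window_s = 5, step_s = 1, max_lag_s = 5,
                           r2_cutoff = 0.25, smooth_s = 0,
                           mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  fr <- frame_rate_of(patient, frame_rate)
  if (smooth_s > 0) {
    patient <- smooth_series(patient, smooth_s, fr)
    clinician <- smooth_series(clinician, smooth_s, fr)
  }
  m <- wclc(patient, clinician, window_s = window_s, step_s = step_s,
            max_lag_s = max_lag_s, frame_rate = fr)
  iv <- peak_picking(m, r2_cutoff = r2_cutoff, mode = mode)
  prof <- summarize_intervals(iv, m$n, fr)
  structure(list(
    wclc = m, intervals = iv, profile = prof,
    gross = c(patient = gross_body_movement(patient),
              clinician = gross_body_movement(clinician)),
    n_frames = m$n, frame_rate = fr,
    params = list(window_s = window_s, step_s = step_s,
                  max_lag_s = max_lag_s, r2_cutoff = r2_cutoff,
                  smooth_s = smooth_s, mode = mode),
    call = match.call()),
    class = "dyad_synchrony")
}

#' @export
print.dyad_synchrony <- function(x, ...) {
  cat("Dyadic movement synchrony fit\n")
  cat(sprintf("  %d frame transitions at %g fps (%.1f s), %d synchrony intervals\n",
              x$n_frames, x$frame_rate, x$n_frames / x$frame_rate,
              nrow(x$intervals)))
  print(x$profile)
  invisible(x)
}

#' @export
summary.dyad_synchrony <- function(object, ...) {
  structure(list(fit = object), class = "summary.dyad_synchrony")
}

#' @export
print.summary.dyad_synchrony <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  gross movement  : patient %.2f, clinician %.2f\n",
              f$gross["patient"], f$gross["clinician"]))
  cat(sprintf("  WCLC: window %gs, step %gs, max lag %gs, R2 cutoff %.2f, mode %s\n",
              f$params$window_s, f$params$step_s, f$params$max_lag_s,
              f$params$r2_cutoff, f$params$mode))
  if (nrow(f$intervals)) {
    cat("  intervals:\n")
    iv <- f$intervals
    iv$start_s <- round(iv$start_frame / f$frame_rate, 2)
    iv$end_s <- round(iv$end_frame / f$frame_rate, 2)
    print(utils::head(iv[, c("start_s", "end_s", "leader", "lag_seconds",
                             "peak_r2")], 20), row.names = FALSE)
    if (nrow(iv) > 20) cat(sprintf("  ... and %d more\n", nrow(iv) - 20))
  }
  invisible(x)
}

#' @export
coef.dyad_synchrony <- function(object, ...) {
  p <- object$profile
  c(ms_total = p$ms_total, ms_patient_led = p$ms_patient_led,
    ms_clinician_led = p$ms_clinician_led, leading = p$leading,
    lag_mean = p$lag_mean, lag_mean_patient_led = p$lag_mean_patient_led,
    lag_mean_clinician_led = p$lag_mean_clinician_led)
}

#' @export
plot.dyad_synchrony <- function(x, ...) {
  plot(x$wclc, intervals = x$intervals, ...)
}

#' Write synchrony intervals as CSV
#'
#' Columns: `dyad_id, start_s, end_s, leader, lag_s, peak_r2`.
#'
#' @param fit a [dyad_synchrony()] fit (or a `sync_intervals` data frame
#'   carrying a `frame_rate` attribute).
#' @param path output CSV path.
#' @param dyad_id identifier written into the first column.
#' @export
write_intervals <- function(fit, path, dyad_id = "dyad") {
  if (inherits(fit, "dyad_synchrony")) {
    iv <- fit$intervals; fr <- fit$frame_rate
  } else {
    iv <- fit; fr <- attr(fit, "frame_rate")
  }
  out <- data.frame(dyad_id = rep(dyad_id, nrow(iv)),
                    start_s = iv$start_frame / fr,
                    end_s = iv$end_frame / fr,
                    leader = iv$leader,
                    lag_s = iv$lag_seconds,
                    peak_r2 = iv$peak_r2)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
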