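#' Configuration for the coupled-dyad simulator
#'
#' Defines the movement structure the synchrony pipeline assumes: each person
#' emits movement bouts (an on/off semi-Markov process; during "on", the
#' energy trace is smoothed positive noise under an on/off ramp envelope),
#' and with probability `coupling` a bout is echoed by the other person —
#' the follower's trace is a scaled, noise-perturbed copy of the leader's,
#' starting `lag` seconds later. The designated leader of a coupled bout is
#' the patient with probability `leader_share`.
#'
#' @param duration_s interaction length in seconds (default 600, a 10-minute
#'   interview segment).
#' @param frame_rate frames per second (default 25).
#' @param epoch_rate_per_min expected number of movement epochs per minute
#'   (default 6; epoch onsets follow the previous epoch's end after an
#'   exponential gap, so the realized rate is slightly lower).
#' @param bout_len_meanlog,bout_len_sdlog lognormal bout-length parameters
#'   in seconds (defaults `log(3)` and 0.4: median 3 s).
#' @param bout_len_range_s truncation bounds for bout lengths (default 1--10 s).
#' @param coupling probability that an epoch is coupled (default 0.5).
#' @param leader_share probability the patient leads a coupled epoch
#'   (default 0.5).
#' @param lag_range_s follower-delay bounds in seconds, within (0, 5]
#'   (default 0.5--2.5); the lag is drawn uniformly.
#' @param amplitude energy scale of a bout, in changed-pixel units
#'   (default 50).
#' @param noise_level follower-copy noise as a fraction of `amplitude`
#'   (default 0.15, keeping in-window R² comfortably above the 0.25 cutoff).
#' @param follower_scale_range uniform bounds of the follower's amplitude
#'   scaling (default 0.7--1).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 600, frame_rate = 25,
                       epoch_rate_per_min = 6,
                       bout_len_meanlog = log(3), bout_len_sdlog = 0.4,
                       bout_len_range_s = c(1, 10),
                       coupling = 0.5, leader_share = 0.5,
                       lag_range_s = c(0.5, 2.5),
                       amplitude = 50, noise_level = 0.15,
                       follower_scale_range = c(0.7, 1),
                       seed = NULL) {
  cfg <- list(duration_s = duration_s, frame_rate = frame_rate,
              epoch_rate_per_min = epoch_rate_per_min,
              bout_len_meanlog = bout_len_meanlog,
              bout_len_sdlog = bout_len_sdlog,
              bout_len_range_s = bout_len_range_s,
              coupling = coupling, leader_share = leader_share,
              lag_range_s = lag_range_s, amplitude = amplitude,
              noise_level = noise_level,
              follower_scale_range = follower_scale_range, seed = seed)
  with(cfg, {
    stopifnot(duration_s > 0, frame_rate > 0, epoch_rate_per_min > 0,
              coupling >= 0, coupling <= 1,
              leader_share >= 0, leader_share <= 1,
              lag_range_s[1] > 0, lag_range_s[2] <= 5,
              lag_range_s[1] <= lag_range_s[2],
              amplitude > 0, noise_level >= 0)
  })
  structure(cfg, class = "sim_config")
}

# smoothed positive bout trace of nL frames: |N(0,1)| moving-averaged over
# ~0.3 s, plus a floor, under half-cosine on/off ramps
bout_trace <- function(nL, amplitude, frame_rate) {
  k <- max(1L, round(0.3 * frame_rate))
  z <- abs(stats::rnorm(nL + 2L * k))
  sm <- stats::filter(z, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  core <- as.numeric(sm[(k + 1L):(k + nL)])
  core[is.na(core)] <- mean(core, na.rm = TRUE)
  ramp <- min(nL %/% 2L, max(2L, round(0.5 * frame_rate)))
  env <- rep(1, nL)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[seq_len(ramp)] <- up
    env[(nL - ramp + 1L):nL] <- rev(up)
  }
  amplitude * env * (0.35 + core)
}

#' Simulate one dyad with known coupling ground truth
#'
#' Generates the two motion-energy series of a dyad under [sim_config()],
#' together with the ground-truth table of coupled epochs (onset, end,
#' leader, lag). Epochs never overlap: the next onset follows the previous
#' epoch's end after an exponential gap. Seeded runs are reproducible.
#'
#' @param config a [sim_config()].
#' @return List with `patient` and `clinician`
#'   ([motion_energy_series()]), `truth` (data frame: `start_s`, `end_s`,
#'   `leader`, `lag_s`, `coupled`; only coupled epochs carry a lag), and
#'   `config`.
#' @examples
#' sim <- simulate_dyad(sim_config(duration_s = 120, coupling = 1,
#'                                 leader_share = 1, seed = 7))
#' head(sim$truth)
#' @export
simulate_dyad <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fr <- config$frame_rate
  n <- as.integer(round(config$duration_s * fr))
  if (n < 2L * fr) stop("duration too short", call. = FALSE)
  pat <- numeric(n)
  clin <- numeric(n)
  truth <- list()
  cursor <- 0
  gap_rate <- config$epoch_rate_per_min / 60
  repeat {
    onset <- cursor + stats::rexp(1, gap_rate)
    L <- exp(stats::rnorm(1, config$bout_len_meanlog, config$bout_len_sdlog))
    L <- min(max(L, config$bout_len_range_s[1]), config$bout_len_range_s[2])
    coupled <- stats::runif(1) < config$coupling
    leader <- if (stats::runif(1) < config$leader_share) "patient" else
      "clinician"
    lag <- if (coupled)
      stats::runif(1, config$lag_range_s[1], config$lag_range_s[2]) else
        NA_real_
    end <- onset + L + if (coupled) lag else 0
    if (end >= config$duration_s - 0.2) break
    i0 <- as.integer(round(onset * fr))
    nL <- max(2L, as.integer(round(L * fr)))
    if (i0 + nL > n) break
    trace <- bout_trace(nL, config$amplitude, fr)
    if (leader == "patient") pat[(i0 + 1L):(i0 + nL)] <-
        pat[(i0 + 1L):(i0 + nL)] + trace
    else clin[(i0 + 1L):(i0 + nL)] <- clin[(i0 + 1L):(i0 + nL)] + trace
    if (coupled) {
      j0 <- i0 + as.integer(round(lag * fr))
      nF <- min(nL, n - j0)
      if (nF >= 2L) {
        sc <- stats::runif(1, config$follower_scale_range[1],
                           config$follower_scale_range[2])
        echo <- pmax(0, sc * trace[seq_len(nF)] +
                       stats::rnorm(nF, 0, config$noise_level *
                                      config$amplitude))
        if (leader == "patient") clin[(j0 + 1L):(j0 + nF)] <-
            clin[(j0 + 1L):(j0 + nF)] + echo
        else pat[(j0 + 1L):(j0 + nF)] <- pat[(j0 + 1L):(j0 + nF)] + echo
      }
    }
    truth[[length(truth) + 1L]] <- data.frame(
      start_s = onset, end_s = end, leader = leader, lag_s = lag,
      coupled = coupled)
    cursor <- end
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(start_s = numeric(), end_s = numeric(), leader = character(),
               lag_s = numeric(), coupled = logical())
  list(patient = motion_energy_series(pat, fr, "patient"),
       clinician = motion_energy_series(clin, fr, "clinician"),
       truth = truth, config = config)
}

#' Render a dyad's movement series into a synthetic two-ROI video
#'
#' Builds a [frame_stack()] in which each person's ROI holds a random
#' texture; at each frame transition, a number of ROI pixels proportional to
#' that person's series value jump by 16 intensity units (well above the
#' noise threshold), while the whole image carries ±1 sub-threshold jitter.
#' Running [motion_energy()] on the result therefore recovers each series up
#' to rounding.
#'
#' @param patient,clinician [motion_energy_series()] of equal length/rate.
#' @param layout list with `width`, `height`, `patient` and `clinician`
#'   ([roi()]s, disjoint). Default: two side-by-side 40x60 ROIs in a
#'   120x80 image.
#' @return A [frame_stack()] with attributes `scale_patient`,
#'   `scale_clinician` (series value per flipped pixel).
#' @export
render_video <- function(patient, clinician, layout = NULL) {
  if (length(patient) != length(clinician))
    stop("series must have equal length", call. = FALSE)
  fr <- frame_rate_of(patient)
  if (is.null(layout))
    layout <- list(width = 120L, height = 80L,
                   patient = roi("patient", 10, 10, 50, 70),
                   clinician = roi("clinician", 70, 10, 110, 70))
  if (roi_overlaps(layout$patient, layout$clinician))
    stop("ROIs overlap", call. = FALSE)
  n <- length(patient) + 1L
  h <- layout$height; w <- layout$width
  base <- matrix(rep(seq(90L, 160L, length.out = w), each = h), h, w)
  base <- round(base)
  frames <- array(0L, dim = c(h, w, n))
  cur <- base
  # textured ROIs so unchanged pixels are still non-uniform
  seed_tex <- function(r) {
    ix <- roi_index(r)
    cur[ix$rows, ix$cols] <<- sample(100:156, roi_area(r), replace = TRUE)
  }
  seed_tex(layout$patient); seed_tex(layout$clinician)
  scales <- numeric(2)
  series <- list(as.numeric(patient), as.numeric(clinician))
  rois <- list(layout$patient, layout$clinician)
  for (k in 1:2) {
    mx <- max(series[[k]])
    scales[k] <- if (mx > 0) max(1, mx / (0.8 * roi_area(rois[[k]]))) else 1
  }
  jitter <- function() matrix(sample(c(-1L, 0L, 1L), h * w, replace = TRUE),
                              h, w)
  frames[, , 1L] <- cur + jitter()
  for (t in seq_len(n - 1L)) {
    for (k in 1:2) {
      kk <- round(series[[k]][t] / scales[k])
      if (kk > 0) {
        ix <- roi_index(rois[[k]])
        area <- roi_area(rois[[k]])
        pick <- sample.int(area, min(kk, area))
        sub <- cur[ix$rows, ix$cols]
        sub[pick] <- ifelse(sub[pick] < 128L, sub[pick] + 16L,
                            sub[pick] - 16L)
        cur[ix$rows, ix$cols] <- sub
      }
    }
    frames[, , t + 1L] <- cur + jitter()
  }
  fs <- frame_stack(frames, fr)
  attr(fs, "scale_patient") <- scales[1]
  attr(fs, "scale_clinician") <- scales[2]
  fs
}

#' Circular-shift surrogate of a dyad (pseudosynchrony control)
#'
#' Destroys genuine coupling while preserving each series' marginal bout
#' structure by rotating the clinician series by a random offset of at least
#' twice the maximum lag. The synchrony a surrogate pair still shows is the
#' chance (pseudosynchrony) level.
#'
#' @param patient,clinician [motion_energy_series()] of equal length.
#' @param seed optional integer seed.
#' @param max_lag_s maximum synchrony lag in seconds (default 5).
#' @return List with `patient` (unchanged) and `clinician` (rotated), plus
#'   `offset` (frames).
#' @export
shuffle_surrogate <- function(patient, clinician, seed = NULL,
                              max_lag_s = 5) {
  if (!is.null(seed)) set.seed(seed)
  fr <- frame_rate_of(patient)
  n <- length(clinician)
  L <- as.integer(round(max_lag_s * fr))
  if (n < 4L * L) stop("series shorter than 4x the maximum lag",
                       call. = FALSE)
  offset <- sample(seq.int(2L * L, n - 2L * L), 1L)
  v <- as.numeric(clinician)
  rot <- c(v[(offset + 1L):n], v[seq_len(offset)])
  clin2 <- motion_energy_series(rot, fr, attr(clinician, "label"))
  list(patient = patient, clinician = clin2, offset = offset)
}

# derive a per-dyad seed from the cohort seed (kept < 2^31)
dyad_seed <- function(seed, i) as.integer((seed + 7919 * i) %% 2147483647L)

#' Simulate a cohort of dyads with a planted severity effect
#'
#' Generates `n_dyads` dyads whose patient-led synchrony depends on a latent
#' depression severity `d ~ N(0, 1)`: the probability that an epoch is a
#' patient-led coupled epoch follows a logistic link with slope
#' `effect_size` in `d` (negative slope = higher severity, less patient-led
#' synchrony), while the clinician-led epoch probability stays constant, so
#' no clinician-led association is planted. HAMD and BDI-II are noisy linear
#' readouts of `d` rescaled to their instrument ranges; interpersonal scales
#' load on `d` more weakly; medication is more likely at high severity; age
#' and gender are drawn from demographic marginals.
#'
#' @param n_dyads number of dyads (>= 10; the study scale is 114).
#' @param effect_size logistic slope of severity on the patient-led epoch
#'   probability (default -0.8; 0 plants no effect).
#' @param seed integer seed for the whole cohort; each dyad uses a derived
#'   stream so cohorts are reproducible dyad-by-dyad.
#' @param segment_s per-dyad interaction length in seconds (default 120).
#' @param base_config [sim_config()] supplying the movement parameters;
#'   its coupling/leader_share are replaced by the severity-dependent pair.
#' @return List with `cohort` (data frame: `dyad_id`, latent `severity`,
#'   `hamd`, `bdi`, `iip`, `tdeq_dep`, `tdeq_selfcrit`, `age`, `gender`
#'   (1 = female), `medication`, true `p_patient_led`, `p_clinician_led`),
#'   `dyads` (list of [simulate_dyad()] results) and `seed`.
#' @export
simulate_cohort <- function(n_dyads = 114, effect_size = -0.8, seed = 1,
                            segment_s = 120, base_config = sim_config()) {
  if (n_dyads < 10) stop("need at least 10 dyads", call. = FALSE)
  set.seed(seed)
  d <- stats::rnorm(n_dyads)
  q_clin <- base_config$coupling * (1 - base_config$leader_share)
  p_base <- base_config$coupling * base_config$leader_share
  p_pat <- 2 * p_base * stats::plogis(effect_size * d)
  c_i <- p_pat + q_clin
  if (any(c_i > 0.95)) {
    warning("coupling probabilities clipped to 0.95")
    c_i <- pmin(c_i, 0.95)
  }
  share_i <- ifelse(c_i > 0, p_pat / c_i, 0)
  readout <- function(center, sdev, loading, lo, hi, digits = 0) {
    raw <- center + sdev * (loading * d +
                              sqrt(1 - loading^2) * stats::rnorm(n_dyads))
    round(pmin(hi, pmax(lo, raw)), digits)
  }
  hamd <- readout(14.3, 8.6, 0.85, 0, 52)
  bdi <- readout(20.5, 13.6, 0.80, 0, 63)
  iip <- readout(1.54, 0.54, 0.55, 0, 4, 2)
  tdeq_dep <- readout(3.9, 1.5, 0.60, 1, 7, 1)
  tdeq_selfcrit <- readout(4.4, 1.4, 0.65, 1, 7, 1)
  age <- round(pmin(75, pmax(18, stats::rnorm(n_dyads, 40, 13))))
  gender <- stats::rbinom(n_dyads, 1, 0.7)
  medication <- stats::rbinom(n_dyads, 1, stats::plogis(-0.6 + 0.9 * d))
  dyads <- vector("list", n_dyads)
  for (i in seq_len(n_dyads)) {
    cfg <- base_config
    cfg$duration_s <- segment_s
    cfg$coupling <- c_i[i]
    cfg$leader_share <- share_i[i]
    cfg$seed <- dyad_seed(seed, i)
    dyads[[i]] <- simulate_dyad(cfg)
  }
  cohort <- data.frame(
    dyad_id = sprintf("dyad%03d", seq_len(n_dyads)),
    severity = d, hamd = hamd, bdi = bdi, iip = iip,
    tdeq_dep = tdeq_dep, tdeq_selfcrit = tdeq_selfcrit,
    age = age, gender = gender, medication = medication,
    p_patient_led = p_pat, p_clinician_led = q_clin)
  list(cohort = cohort, dyads = dyads, seed = seed)
}

#' Run the synchrony pipeline over a simulated cohort
#'
#' Fits [dyad_synchrony()] to every dyad of a [simulate_cohort()] result and
#' returns the cohort table joined with the recovered synchrony profiles and
#' gross movement.
#'
#' @param sim a [simulate_cohort()] result.
#' @param ... passed to [dyad_synchrony()].
#' @return The cohort data frame with the [profile_table()] columns appended.
#' @export
profile_cohort <- function(sim, ...) {
  fits <- lapply(sim$dyads, function(d)
    dyad_synchrony(d$patient, d$clinician, ...))
  names(fits) <- sim$cohort$dyad_id
  gross <- t(vapply(fits, function(f) f$gross, numeric(2)))
  pt <- profile_table(fits, gross = gross)
  stopifnot(identical(pt$dyad_id, sim$cohort$dyad_id))
  cbind(sim$cohort, pt[, -1L])
}
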