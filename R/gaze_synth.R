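#' Gaze dynamics profile for the synthetic simulator
#'
#' Parameterises the alternating fixation-saccade renewal process that the
#' simulator samples at tracker rate. Defaults reflect naturalistic viewing:
#' fixations of mean 300 ms (the naturalistic range spans roughly 150-550 ms)
#' and ballistic saccades of mean 60 ms (range about 30-120 ms). The implied
#' saccade rate is `1000 / (fixation mean + saccade mean)` per second; group
#' profiles that differ in movement dynamics are obtained by shortening
#' fixations (higher rate) and enlarging saccade amplitude.
#'
#' @param fixation_mean,fixation_sd fixation duration, ms.
#' @param saccade_amp_mean,saccade_amp_sd saccade amplitude, px.
#' @param saccade_dur_mean,saccade_dur_sd saccade duration, ms (clamped to
#'   30-120 ms when sampled).
#' @param fixation_jitter SD of within-fixation positional drift, px.
#' @param dropout_rate fraction of samples marked invalid in contiguous
#'   blink bursts, in `[0, 0.3]`.
#' @return An object of class `gaze_profile`.
#' @export
gaze_profile <- function(fixation_mean = 300, fixation_sd = 80,
                         saccade_amp_mean = 250, saccade_amp_sd = 80,
                         saccade_dur_mean = 60, saccade_dur_sd = 15,
                         fixation_jitter = 3, dropout_rate = 0.05) {
  stopifnot(fixation_mean > 0, fixation_sd > 0, saccade_amp_mean > 0,
            saccade_amp_sd > 0, saccade_dur_mean > 0, saccade_dur_sd > 0,
            fixation_jitter >= 0, dropout_rate >= 0, dropout_rate <= 0.3)
  structure(list(fixation_mean = fixation_mean, fixation_sd = fixation_sd,
                 saccade_amp_mean = saccade_amp_mean,
                 saccade_amp_sd = saccade_amp_sd,
                 saccade_dur_mean = saccade_dur_mean,
                 saccade_dur_sd = saccade_dur_sd,
                 fixation_jitter = fixation_jitter,
                 dropout_rate = dropout_rate),
            class = "gaze_profile")
}

#' @export
print.gaze_profile <- function(x, ...) {
  rate <- 1000 / (x$fixation_mean + x$saccade_dur_mean)
  cat(sprintf(paste0("<gaze_profile> fixation %g±%g ms, saccade %g±%g px over ",
                     "%g±%g ms (~%.2f saccades/s), jitter %g px, dropout %g\n"),
              x$fixation_mean, x$fixation_sd, x$saccade_amp_mean,
              x$saccade_amp_sd, x$saccade_dur_mean, x$saccade_dur_sd,
              rate, x$fixation_jitter, x$dropout_rate))
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Simulate one gaze recording
#'
#' Samples an alternating fixation-saccade renewal process at `rate_hz`:
#' fixations are stationary clusters with Gaussian positional jitter;
#' saccades are straight, constant-velocity displacements toward a target
#' drawn by jumping `amplitude` pixels in a uniform direction (reflected into
#' the screen). A fraction `dropout_rate` of samples is flagged invalid in
#' contiguous blink bursts. Coordinates are clamped to the screen and the
#' process is fully determined by `seed` (or by the current RNG state when
#' `seed = NULL`).
#'
#' @param profile a [gaze_profile()].
#' @param duration_s recording duration, seconds.
#' @param rate_hz sampling rate, Hz (default 250).
#' @param screen screen dimensions px, default `c(1280, 1024)`.
#' @param seed integer seed or `NULL`.
#' @param dyn_scale individual velocity-scale multiplier applied to the
#'   movement dynamics (saccade amplitude and fixation drift) — a global
#'   movement-vigor factor.
#' @param participant_id,stimulus_id identifiers for the recording.
#' @return A [gaze_recording()] of `duration_s * rate_hz` samples.
#' @export
generate_recording <- function(profile, duration_s, rate_hz = 250,
                               screen = c(1280L, 1024L), seed = NULL,
                               dyn_scale = 1,
                               participant_id = "sim", stimulus_id = "s0") {
  stopifnot(inherits(profile, "gaze_profile"), duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration_s * rate_hz))
  dt <- 1000 / rate_hz
  x <- numeric(n); y <- numeric(n)
  pos <- c(stats::runif(1, 0.2, 0.8) * screen[1],
           stats::runif(1, 0.2, 0.8) * screen[2])
  i <- 1L
  fixating <- TRUE
  while (i <= n) {
    if (fixating) {
      dur <- max(2 * dt, stats::rnorm(1, profile$fixation_mean, profile$fixation_sd))
      len <- min(n - i + 1L, max(1L, as.integer(round(dur / dt))))
      idx <- i:(i + len - 1L)
      jit <- dyn_scale * profile$fixation_jitter
      x[idx] <- pos[1] + stats::rnorm(len, 0, jit)
      y[idx] <- pos[2] + stats::rnorm(len, 0, jit)
      i <- i + len
    } else {
      amp <- dyn_scale * max(10, stats::rnorm(1, profile$saccade_amp_mean,
                                              profile$saccade_amp_sd))
      ang <- stats::runif(1, 0, 2 * pi)
      target <- pos + amp * c(cos(ang), sin(ang))
      # reflect off-screen targets back inside
      target[1] <- abs(target[1]); target[2] <- abs(target[2])
      if (target[1] > screen[1]) target[1] <- 2 * screen[1] - target[1]
      if (target[2] > screen[2]) target[2] <- 2 * screen[2] - target[2]
      target <- pmin(pmax(target, 0), screen)
      dur <- rtrunc_norm(1, profile$saccade_dur_mean, profile$saccade_dur_sd, 30, 120)
      len <- min(n - i + 1L, max(1L, as.integer(round(dur / dt))))
      frac <- seq_len(len) / len
      idx <- i:(i + len - 1L)
      x[idx] <- pos[1] + frac * (target[1] - pos[1])
      y[idx] <- pos[2] + frac * (target[2] - pos[2])
      pos <- target
      i <- i + len
    }
    fixating <- !fixating
  }
  x <- pmin(pmax(x, 0), screen[1])
  y <- pmin(pmax(y, 0), screen[2])

  valid <- rep(TRUE, n)
  if (profile$dropout_rate > 0) {
    target_invalid <- round(profile$dropout_rate * n)
    burst <- as.integer(round(100 / dt))          # ~100 ms blinks
    n_bursts <- max(1L, as.integer(round(target_invalid / burst)))
    starts <- sort(sample.int(max(1L, n - burst), n_bursts))
    for (s in starts) valid[s:min(n, s + burst - 1L)] <- FALSE
  }
  gaze_recording(data.frame(t = (seq_len(n) - 1L) * dt, x = x, y = y,
                            valid = valid),
                 participant_id = participant_id, stimulus_id = stimulus_id,
                 screen = screen, sampling_rate = rate_hz)
}

#' Specification of a synthetic screening cohort
#'
#' Mirrors the structure of a screen-based screening study: `n_asd`
#' children diagnosed with ASD and `n_td` non-ASD children (defaults 29 and
#' 30), each contributing `recordings_per_participant` recordings of
#' `duration_s` seconds at 250 Hz on a 1280x1024 display. Every participant
#' draws an individual velocity scale (a log-normal multiplier on the
#' movement dynamics, so both groups have the same vigor spread and a null
#' cohort with identical profiles carries no group signal). ASD participants
#' additionally receive a CARS severity score from a monotone link in log
#' velocity scale mapped onto `[30, 45]` (above the scale's autism cutoff of
#' 30) plus Gaussian noise; non-ASD participants score the scale minimum of
#' 15.
#'
#' @param n_asd,n_td group sizes.
#' @param profile_asd,profile_td group [gaze_profile()]s; the default ASD
#'   profile has shorter fixations (higher saccade rate) and larger saccade
#'   amplitude. Pass `profile_asd = profile_td` for a null cohort with no
#'   group signal.
#' @param scale_sigma SD of log individual velocity scale.
#' @param cars_noise_sd SD of the Gaussian noise added to the CARS link, in
#'   CARS points (the link spans 15 points; 1.5 is 10 percent of the range).
#' @param recordings_per_participant,duration_s,rate_hz,screen capture setup.
#' @param seed integer seed governing the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_asd = 29L, n_td = 30L,
                        profile_asd = gaze_profile(fixation_mean = 210,
                                                   fixation_sd = 30,
                                                   saccade_amp_mean = 300,
                                                   saccade_amp_sd = 50,
                                                   fixation_jitter = 10),
                        profile_td = gaze_profile(fixation_mean = 330,
                                                  fixation_sd = 30,
                                                  saccade_amp_mean = 180,
                                                  saccade_amp_sd = 40,
                                                  fixation_jitter = 10),
                        scale_sigma = 0.5,
                        cars_noise_sd = 1.5,
                        recordings_per_participant = 1L,
                        duration_s = 10, rate_hz = 250,
                        screen = c(1280L, 1024L), seed = 1L) {
  stopifnot(n_asd >= 1L, n_td >= 1L,
            inherits(profile_asd, "gaze_profile"),
            inherits(profile_td, "gaze_profile"))
  structure(list(n_asd = as.integer(n_asd), n_td = as.integer(n_td),
                 profile_asd = profile_asd, profile_td = profile_td,
                 scale_sigma = scale_sigma, cars_noise_sd = cars_noise_sd,
                 recordings_per_participant = as.integer(recordings_per_participant),
                 duration_s = duration_s, rate_hz = rate_hz,
                 screen = as.numeric(screen), seed = as.integer(seed)),
            class = "cohort_spec")
}

# Monotone CARS link: affine in log velocity scale, mapped onto [30, 45].
# log(scale) ~ N(0, sigma); +/- 2.5 sigma covers essentially all draws.
cars_link <- function(log_scale, sigma) {
  z <- pmin(pmax(log_scale / (2.5 * sigma), -1), 1)   # [-1, 1]
  30 + 7.5 * (z + 1)                                   # [30, 45]
}

#' Generate a synthetic screening cohort
#'
#' Draws participants, severity scores and recordings per [cohort_spec()].
#' Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `manifest` (a [cohort_manifest()] without image
#'   inventory) and `recordings` (named list of [gaze_recording()]s), plus
#'   `scales` (the per-participant velocity scale factors).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ids <- c(sprintf("asd%02d", seq_len(spec$n_asd)),
           sprintf("td%02d", seq_len(spec$n_td)))
  groups <- rep(c("ASD", "non-ASD"), c(spec$n_asd, spec$n_td))
  log_scale <- stats::rnorm(length(ids), 0, spec$scale_sigma)
  cars <- ifelse(groups == "ASD",
                 pmin(pmax(cars_link(log_scale, spec$scale_sigma) +
                             stats::rnorm(length(ids), 0, spec$cars_noise_sd),
                           30), 45),
                 15)
  participants <- data.frame(participant_id = ids, group = groups,
                             cars = cars, stringsAsFactors = FALSE)
  recordings <- list()
  for (i in seq_along(ids)) {
    prof <- if (groups[i] == "ASD") spec$profile_asd else spec$profile_td
    for (r in seq_len(spec$recordings_per_participant)) {
      rec <- generate_recording(prof, spec$duration_s, spec$rate_hz,
                                spec$screen, seed = NULL,
                                dyn_scale = exp(log_scale[i]),
                                participant_id = ids[i],
                                stimulus_id = sprintf("s%d", r))
      recordings[[paste(ids[i], r, sep = "_")]] <- rec
    }
  }
  list(manifest = cohort_manifest(participants),
       recordings = recordings,
       scales = stats::setNames(exp(log_scale), ids))
}
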