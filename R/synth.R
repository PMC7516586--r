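# Synthetic saccadic velocity series.
#
# Emulates a 1024 ms, 1000 Hz eye-movement velocity recording from a
# jumping-point trial: a saccadic-latency period of fixational
# micro-movement plus a weakly unstable (locally divergent) preparatory
# oscillation, one ballistic saccade (raised-cosine velocity pulse with
# main-sequence-like velocity saturation, i.e. a plateau for large, fast
# saccades), then fixation with tremor, drift and sparse microsaccades.
# Micro-movement is attenuated in a window around the saccade
# (peri-saccadic suppression), and white measurement noise is added
# everywhere. All draws come from R's RNG; a fixed seed gives bit-identical
# output.

#' Configuration for the synthetic saccadic-signal generator
#'
#' Defaults model a jumping-point trial at 1000 Hz: saccadic latency drawn
#' from a truncated normal (mean 170 ms, SD 25 ms, clipped to 100-250 ms),
#' saccade duration uniform on 30-80 ms, saccade amplitude uniform on
#' 12-30 deg with peak velocity `2 * amplitude / duration` capped at
#' 500 deg/s (velocity saturation: capped pulses acquire a plateau, as real
#' large saccades do). Fixational micro-movement combines a stochastic
#' 80 Hz tremor band, a slow drift random walk and sparse microsaccade
#' pulses, and is attenuated in a peri-saccadic suppression window.
#'
#' @param rate_hz Sampling rate (default 1000).
#' @param duration_ms Series length (default 1024).
#' @param latency_mean_ms,latency_sd_ms,latency_bounds_ms Truncated-normal
#'   saccadic-latency distribution (ms).
#' @param saccade_duration_ms Uniform range of saccade duration (ms).
#' @param saccade_amplitude_deg Uniform range of saccade amplitude (deg).
#' @param saccade_peak_max Peak-velocity cap (deg/s, default 500).
#' @param latency_fluct_sd Innovation SD (deg/s) of the weakly unstable
#'   oscillatory AR(2) preparatory process active during latency; its
#'   poles sit just outside the unit circle so nearby trajectories diverge
#'   locally. 0 silences it.
#' @param latency_fluct_sat Soft-saturation amplitude (deg/s) bounding the
#'   preparatory process.
#' @param tremor_innov_sd Innovation SD (deg/s) of the stochastic tremor
#'   band (stable AR(2) resonant at `tremor_freq_hz`); realised tremor SD
#'   is roughly 6x the innovation SD at the defaults.
#' @param tremor_freq_hz Tremor band centre frequency (default 80 Hz).
#' @param drift_sd Innovation SD of the drift random walk (deg/s per
#'   sample).
#' @param microsaccade_rate_hz Mean microsaccade rate during fixation
#'   (1/s).
#' @param microsaccade_peak Peak-velocity range of microsaccades (deg/s).
#' @param suppression_pre_ms,suppression_post_ms Extent of the
#'   peri-saccadic micro-movement suppression window before saccade onset
#'   and after saccade end (ms).
#' @param suppression_ramp_ms Cosine ramp length at the window edges (ms).
#' @param suppression_floor Micro-movement gain inside the window
#'   (default 0.1; 1 disables suppression).
#' @param noise_sd Additive white measurement-noise SD (deg/s), applied
#'   everywhere.
#' @param n_participants,n_sessions,n_points Dataset geometry for
#'   [generate_dataset()].
#' @param excluded_sessions Data frame with columns `participant`,
#'   `session` to drop (emulating rejected recordings), or NULL.
#' @param seed Master seed; per-series seeds are derived from it.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(rate_hz = 1000,
                         duration_ms = 1024,
                         latency_mean_ms = 170,
                         latency_sd_ms = 25,
                         latency_bounds_ms = c(100, 250),
                         saccade_duration_ms = c(30, 80),
                         saccade_amplitude_deg = c(12, 30),
                         saccade_peak_max = 500,
                         latency_fluct_sd = 2.5,
                         latency_fluct_sat = 8,
                         tremor_innov_sd = 1.5,
                         tremor_freq_hz = 80,
                         drift_sd = 0.35,
                         microsaccade_rate_hz = 1.5,
                         microsaccade_peak = c(15, 40),
                         suppression_pre_ms = 60,
                         suppression_post_ms = 40,
                         suppression_ramp_ms = 30,
                         suppression_floor = 0.1,
                         noise_sd = 3,
                         n_participants = 24L,
                         n_sessions = 2L,
                         n_points = 29L,
                         excluded_sessions = NULL,
                         seed = 1L) {
  cfg <- list(rate_hz = rate_hz, duration_ms = duration_ms,
              latency_mean_ms = latency_mean_ms,
              latency_sd_ms = latency_sd_ms,
              latency_bounds_ms = latency_bounds_ms,
              saccade_duration_ms = saccade_duration_ms,
              saccade_amplitude_deg = saccade_amplitude_deg,
              saccade_peak_max = saccade_peak_max,
              latency_fluct_sd = latency_fluct_sd,
              latency_fluct_sat = latency_fluct_sat,
              tremor_innov_sd = tremor_innov_sd,
              tremor_freq_hz = tremor_freq_hz,
              drift_sd = drift_sd,
              microsaccade_rate_hz = microsaccade_rate_hz,
              microsaccade_peak = microsaccade_peak,
              suppression_pre_ms = suppression_pre_ms,
              suppression_post_ms = suppression_post_ms,
              suppression_ramp_ms = suppression_ramp_ms,
              suppression_floor = suppression_floor,
              noise_sd = noise_sd,
              n_participants = as.integer(n_participants),
              n_sessions = as.integer(n_sessions),
              n_points = as.integer(n_points),
              excluded_sessions = excluded_sessions,
              seed = as.integer(seed))
  stopifnot(cfg$rate_hz > 0, cfg$duration_ms > 0,
            cfg$latency_bounds_ms[1] <= cfg$latency_bounds_ms[2],
            cfg$latency_bounds_ms[2] + cfg$saccade_duration_ms[2] <
              cfg$duration_ms,
            cfg$suppression_floor >= 0, cfg$suppression_floor <= 1,
            all(unlist(cfg[c("latency_fluct_sd", "tremor_innov_sd",
                             "drift_sd", "microsaccade_rate_hz",
                             "noise_sd")]) >= 0))
  class(cfg) <- "synth_config"
  cfg
}

rtruncnorm1 <- function(mean, sd, bounds) {
  if (sd == 0) return(min(max(mean, bounds[1]), bounds[2]))
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= bounds[1] && x <= bounds[2]) return(x)
  }
  min(max(mean, bounds[1]), bounds[2]) # pathological config: clip
}

runif_range <- function(range) {
  if (range[1] == range[2]) range[1] else stats::runif(1, range[1], range[2])
}

# Raised-cosine velocity pulse with unit peak over `len` samples.
raised_cosine <- function(len) {
  0.5 * (1 - cos(2 * pi * (seq_len(len) - 0.5) / len))
}

# AR(2) resonant at freq_hz: pole_radius < 1 gives a stable stochastic
# oscillation band (tremor); pole_radius > 1 a weakly unstable, locally
# divergent one, bounded by tanh soft saturation.
ar2_band <- function(n, innov_sd, rate_hz, freq_hz, pole_radius, sat = Inf) {
  if (n < 1L) return(numeric(0))
  if (innov_sd == 0) return(numeric(n))
  theta <- 2 * pi * freq_hz / rate_hz
  a1 <- 2 * pole_radius * cos(theta)
  a2 <- -pole_radius^2
  x <- numeric(n + 2L)
  e <- stats::rnorm(n, 0, innov_sd)
  for (i in seq_len(n)) {
    raw <- a1 * x[i + 1L] + a2 * x[i] + e[i]
    x[i + 2L] <- if (is.finite(sat)) sat * tanh(raw / sat) else raw
  }
  x[-(1:2)]
}

cosine_ramp <- function(n) 0.5 * (1 - cos(pi * seq_len(n) / n))

#' Generate one synthetic eye-movement velocity series
#'
#' Layout per trial: samples in `[0, latency)` ms hold fixational
#' micro-movement plus the locally divergent preparatory oscillation; the
#' saccade occupies `[latency, latency + duration)` ms as a signed
#' raised-cosine velocity pulse, clipped at the peak-velocity cap (velocity
#' saturation); fixational micro-movement (stochastic tremor band + drift
#' random walk + sparse microsaccades) fills the remainder. Micro-movement
#' is attenuated inside the peri-saccadic suppression window, the
#' preparatory process tapers out over the last 40 ms before saccade onset,
#' and white measurement noise is added everywhere. With all noise
#' amplitudes zero the velocity is exactly 0 outside the saccade window.
#'
#' @param config A [synth_config()].
#' @param participant,session,point Identity fields for the series.
#' @param seed Seed for this series; `NULL` uses the current RNG state.
#' @return A tibble with columns `participant`, `session`, `point`,
#'   `time_ms` (0-based sample time) and `velocity` (deg/s), plus an
#'   `events` attribute (one-row tibble: latency_ms, saccade_onset_ms,
#'   saccade_duration_ms, amplitude_deg, peak_velocity).
#' @export
generate_series <- function(config = synth_config(), participant = 1L,
                            session = 1L, point = 1L, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- round(config$duration_ms * config$rate_hz / 1000)
  dt_ms <- 1000 / config$rate_hz

  latency_ms <- rtruncnorm1(config$latency_mean_ms, config$latency_sd_ms,
                            config$latency_bounds_ms)
  sac_dur_ms <- runif_range(config$saccade_duration_ms)
  amp <- runif_range(config$saccade_amplitude_deg)
  peak <- min(2 * amp / (sac_dur_ms / 1000), config$saccade_peak_max)
  sign_sac <- if (stats::runif(1) < 0.5) -1 else 1

  i_lat_end <- round(latency_ms / dt_ms)
  i_sac_len <- max(1L, round(sac_dur_ms / dt_ms))
  i_sac_end <- min(n, i_lat_end + i_sac_len)

  # fixational micro-movement over the whole trial
  micro <- ar2_band(n, config$tremor_innov_sd, config$rate_hz,
                    config$tremor_freq_hz, pole_radius = 0.97)
  if (config$drift_sd > 0) {
    micro <- micro + cumsum(stats::rnorm(n, 0, config$drift_sd))
  }
  if (config$microsaccade_rate_hz > 0) {
    n_ms <- stats::rpois(1, config$microsaccade_rate_hz * n / config$rate_hz)
    for (j in seq_len(n_ms)) {
      len <- min(n, max(1L, round(stats::runif(1, 10, 20) / dt_ms)))
      start <- sample.int(max(1L, n - len + 1L), 1L)
      pk <- runif_range(config$microsaccade_peak) *
        (if (stats::runif(1) < 0.5) -1 else 1)
      idx <- start:(start + len - 1L)
      micro[idx] <- micro[idx] + pk * raised_cosine(len)
    }
  }

  # peri-saccadic suppression envelope
  if (config$suppression_floor < 1) {
    env <- rep(1, n)
    floor_g <- config$suppression_floor
    ramp <- max(1L, round(config$suppression_ramp_ms / dt_ms))
    a <- max(1L, i_lat_end - round(config$suppression_pre_ms / dt_ms))
    b <- min(n, i_sac_end + round(config$suppression_post_ms / dt_ms))
    env[a:b] <- floor_g
    if (a > 1L) {
      ra <- max(1L, a - ramp):(a - 1L)
      env[ra] <- 1 - (1 - floor_g) * cosine_ramp(length(ra))
    }
    if (b < n) {
      rb <- (b + 1L):min(n, b + ramp)
      env[rb] <- floor_g + (1 - floor_g) * cosine_ramp(length(rb))
    }
    micro <- micro * env
  }

  v <- micro
  # preparatory (latency) component, tapering out 40 ms before onset
  if (i_lat_end > 0L) {
    prep <- ar2_band(i_lat_end, config$latency_fluct_sd, config$rate_hz,
                     freq_hz = 30, pole_radius = 1.01,
                     sat = config$latency_fluct_sat)
    taper_len <- min(i_lat_end, round(40 / dt_ms))
    if (taper_len > 1L) {
      idx <- (i_lat_end - taper_len + 1L):i_lat_end
      prep[idx] <- prep[idx] * rev(cosine_ramp(taper_len))
    }
    v[seq_len(i_lat_end)] <- v[seq_len(i_lat_end)] + prep
  }
  # saccade pulse: raised cosine clipped at the cap (velocity saturation)
  pulse <- pmin(2 * amp / (sac_dur_ms / 1000) *
                  raised_cosine(i_sac_end - i_lat_end),
                config$saccade_peak_max)
  v[(i_lat_end + 1L):i_sac_end] <- v[(i_lat_end + 1L):i_sac_end] +
    sign_sac * pulse
  # measurement noise
  if (config$noise_sd > 0) v <- v + stats::rnorm(n, 0, config$noise_sd)

  out <- tibble::tibble(participant = participant, session = session,
                        point = point,
                        time_ms = (seq_len(n) - 1) * dt_ms,
                        velocity = v)
  attr(out, "events") <- tibble::tibble(
    participant = participant, session = session, point = point,
    latency_ms = latency_ms, saccade_onset_ms = i_lat_end * dt_ms,
    saccade_duration_ms = (i_sac_end - i_lat_end) * dt_ms,
    amplitude_deg = amp, peak_velocity = sign_sac * peak)
  out
}

#' Generate a full synthetic dataset
#'
#' One series per participant x session x point, minus any excluded
#' sessions, with per-series seeds derived deterministically from the
#' master seed. At the study geometry (24 participants, 2 sessions, 29
#' points, 4 excluded sessions) this yields 44 x 29 = 1276 series.
#'
#' @param config A [synth_config()].
#' @return A long tibble of samples (one row per sample, all series
#'   stacked), with an `events` attribute collecting per-series ground
#'   truth.
#' @export
#' @examples
#' d <- generate_dataset(synth_config(n_participants = 2, n_sessions = 1,
#'                                    n_points = 2, seed = 7))
#' dplyr::count(d, participant, session, point)
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  grid <- tidyr::expand_grid(participant = seq_len(config$n_participants),
                             session = seq_len(config$n_sessions),
                             point = seq_len(config$n_points))
  if (!is.null(config$excluded_sessions)) {
    grid <- dplyr::anti_join(grid, config$excluded_sessions,
                             by = c("participant", "session"))
  }
  series <- purrr::pmap(grid, function(participant, session, point) {
    # per-series seed derived from the master seed; kept within 32-bit range
    s <- (config$seed * 7919L +
            participant * 104729L + session * 15485863L + point * 797L) %%
      2147483629L
    generate_series(config, participant, session, point, seed = s)
  })
  out <- dplyr::bind_rows(series)
  attr(out, "events") <- dplyr::bind_rows(purrr::map(series, attr, "events"))
  out
}

#' Two-point differentiation of a position series
#'
#' The standard first-difference conversion of eye position to velocity:
#' `v_i = (x_{i+1} - x_i) / dt`, giving N - 1 velocity samples from N
#' positions. A central-difference option (`(x_{i+1} - x_{i-1}) / 2dt`,
#' N - 2 samples) is provided for comparison.
#'
#' @param positions Numeric vector of positions (deg), length >= 2.
#' @param dt Sampling interval in seconds (default 0.001).
#' @param stencil `"forward"` (default) or `"central"`.
#' @return Numeric vector of velocities (deg/s).
#' @export
#' @examples
#' differentiate_positions(c(0, 1, 2, 3), dt = 0.001) # 1000 deg/s ramp
differentiate_positions <- function(positions, dt = 0.001,
                                    stencil = c("forward", "central")) {
  stencil <- match.arg(stencil)
  if (!is.numeric(positions) || length(positions) < 2L) {
    stop("`positions` needs at least 2 samples.", call. = FALSE)
  }
  if (stencil == "forward") {
    diff(positions) / dt
  } else {
    if (length(positions) < 3L) {
      stop("Central differences need at least 3 samples.", call. = FALSE)
    }
    n <- length(positions)
    (positions[3:n] - positions[1:(n - 2)]) / (2 * dt)
  }
}
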