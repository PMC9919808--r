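#' Simulation configuration for a chest-worn tri-axial accelerometer
#'
#' Describes the acquisition regime of a low-power chest-mounted MEMS
#' accelerometer: about 10 samples per second, readings clipped to a
#' programmable full-scale range of +/- 2 g, additive Gaussian sensor noise
#' and occasional single-sample spikes ("jumping values") on a random axis.
#'
#' @param sampling_rate_hz samples per second; positive. Default 10.
#' @param accel_range_g full-scale range in g; all generated samples are
#'   clipped to `[-accel_range_g, accel_range_g]`. Default 2.
#' @param noise_sd_g standard deviation of per-axis Gaussian sensor noise, in
#'   g. Default 0.05.
#' @param spike_prob probability that any one sample carries an isolated
#'   spike on a random axis. Default 0.01.
#' @param spike_magnitude_g absolute size of a spike, in g (sign is random).
#'   Default 1.5.
#' @param seed integer seed; every stochastic part of the simulator is a
#'   deterministic function of (script, config, seed).
#' @return an object of class `sim_config` (a named list).
#' @examples
#' sim_config(noise_sd_g = 0, spike_prob = 0)
#' @export
sim_config <- function(sampling_rate_hz = 10, accel_range_g = 2,
                       noise_sd_g = 0.05, spike_prob = 0.01,
                       spike_magnitude_g = 1.5, seed = 1L) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("sampling_rate_hz must be positive", class = "harcascade_invalid_config")
  }
  if (!is.numeric(accel_range_g) || accel_range_g <= 0) {
    abort("accel_range_g must be positive", class = "harcascade_invalid_config")
  }
  if (!is.numeric(noise_sd_g) || noise_sd_g < 0) {
    abort("noise_sd_g must be non-negative", class = "harcascade_invalid_config")
  }
  if (!is.numeric(spike_prob) || spike_prob < 0 || spike_prob > 1) {
    abort("spike_prob must be in [0, 1]", class = "harcascade_invalid_config")
  }
  if (!is.numeric(spike_magnitude_g) || spike_magnitude_g <= 0) {
    abort("spike_magnitude_g must be positive", class = "harcascade_invalid_config")
  }
  structure(
    list(sampling_rate_hz = sampling_rate_hz, accel_range_g = accel_range_g,
         noise_sd_g = noise_sd_g, spike_prob = spike_prob,
         spike_magnitude_g = spike_magnitude_g, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' One scripted activity segment
#'
#' A segment is a stretch of one activity with its signal parameters. The
#' device sits on the chest: when the torso is upright gravity loads mainly
#' the vertical (x) axis; lying down rotates the gravity vector towards the
#' out-of-chest (z) or lateral (y) axis. At rest the acceleration vector has
#' magnitude 1 g.
#'
#' Per-activity parameters (all optional, defaults in parentheses):
#' \describe{
#'   \item{sit}{`tilt_deg` (15): recline of the torso from upright.
#'     `azimuth_deg` (0): direction of the tilt, 0 = backwards (towards z),
#'     90 = sideways (towards y).}
#'   \item{walk}{`tilt_deg` (10), `azimuth_deg` (0), `gait_hz` (2): step
#'     frequency; `amp_vertical_g` (0.35), `amp_lateral_g` (0.15),
#'     `amp_forward_g` (0.1): oscillation amplitudes. The lateral sway runs
#'     at half the step frequency (left/right alternation).}
#'   \item{sleep}{`tilt_deg` (90), `azimuth_deg` (0): supine; 90 gives a
#'     lateral (side-lying) posture.}
#'   \item{cough}{`base`: a named list of posture parameters for the
#'     underlying activity (defaults to the sit posture) plus optionally
#'     `gait_hz`/amplitudes to cough while walking; `burst_amp_g` (0.6):
#'     extra amplitude of a cough burst over the base signal;
#'     `burst_len` (3:5) and `gap_len` (2:3): burst and inter-burst
#'     durations in samples, drawn uniformly.}
#'   \item{fall}{`impact_g` (1.9): peak magnitude at impact;
#'     `prefix_frac` (0.2): leading fraction of the segment spent upright;
#'     `freefall_frac` (0.1): fraction in free fall (magnitude collapses
#'     towards ~0.15 g); the remainder is spent lying still after a
#'     two-sample impact.}
#' }
#'
#' @param activity one of `activity_levels()`.
#' @param duration_s positive duration in seconds.
#' @param params named list of per-activity parameters (see Details).
#' @return an object of class `activity_segment`.
#' @examples
#' activity_segment("walk", 10, params = list(gait_hz = 1.8))
#' @export
activity_segment <- function(activity, duration_s, params = list()) {
  activity <- as.character(activity)
  check_activity_labels(activity)
  if (length(activity) != 1) abort("one activity per segment",
                                   class = "harcascade_invalid_config")
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    abort("duration_s must be a positive number",
          class = "harcascade_invalid_config")
  }
  structure(list(activity = activity, duration_s = duration_s,
                 params = as.list(params)),
            class = "activity_segment")
}

# gravity unit vector for a torso tilted `tilt_deg` from upright,
# in direction `azimuth_deg` (0 = backwards/supine, 90 = lateral)
gravity_vector <- function(tilt_deg, azimuth_deg = 0) {
  t <- tilt_deg * pi / 180
  a <- azimuth_deg * pi / 180
  c(x = cos(t), y = sin(t) * sin(a), z = sin(t) * cos(a))
}

seg_defaults <- function(activity) {
  switch(activity,
    sit   = list(tilt_deg = 15, azimuth_deg = 0),
    walk  = list(tilt_deg = 10, azimuth_deg = 0, gait_hz = 2,
                 amp_vertical_g = 0.35, amp_lateral_g = 0.15,
                 amp_forward_g = 0.1),
    sleep = list(tilt_deg = 90, azimuth_deg = 0),
    cough = list(base = list(tilt_deg = 15, azimuth_deg = 0),
                 burst_amp_g = 0.6, burst_len = 3:5, gap_len = 2:3),
    # an uncontrolled fall ends roughly horizontal but rarely in the neat
    # supine posture of sleeping, hence the default lying azimuth offset
    fall  = list(impact_g = 1.9, prefix_frac = 0.2, freefall_frac = 0.1,
                 tilt_deg = 5, azimuth_deg = 0,
                 lying_tilt_deg = 90, lying_azimuth_deg = 30)
  )
}

# clean (noise-free) n x 3 signal for one segment; RNG state is consumed
# only for stochastic signal structure (cough burst layout, fall direction)
clean_signal <- function(activity, n, p) {
  if (activity %in% c("sit", "sleep")) {
    g <- gravity_vector(p$tilt_deg, p$azimuth_deg)
    return(matrix(g, nrow = n, ncol = 3, byrow = TRUE))
  }
  if (activity == "walk") {
    g <- gravity_vector(p$tilt_deg, p$azimuth_deg)
    ph <- 2 * pi * p$gait_hz * (seq_len(n) - 1) / p$rate
    cbind(g[1] + p$amp_vertical_g * sin(ph),
          g[2] + p$amp_lateral_g * sin(ph / 2),
          g[3] + p$amp_forward_g * sin(ph + pi / 2))
  } else if (activity == "cough") {
    base_p <- utils::modifyList(seg_defaults(
      if (!is.null(p$base$gait_hz)) "walk" else "sit"), as.list(p$base))
    base_p$rate <- p$rate
    base_act <- if (!is.null(p$base$gait_hz)) "walk" else "sit"
    sig <- clean_signal(base_act, n, base_p)
    # burst trains: alternating-sign jolts on the vertical and out-of-chest
    # axes, a few samples long, separated by short quiet gaps
    i <- 1L
    while (i <= n) {
      blen <- if (length(p$burst_len) > 1) sample(p$burst_len, 1) else p$burst_len
      glen <- if (length(p$gap_len) > 1) sample(p$gap_len, 1) else p$gap_len
      idx <- i:min(i + blen - 1L, n)
      jolt <- p$burst_amp_g * (-1)^(seq_along(idx)) * runif(length(idx), 0.7, 1)
      sig[idx, 1] <- sig[idx, 1] + jolt
      sig[idx, 3] <- sig[idx, 3] + 0.5 * jolt * sign(runif(1) - 0.5)
      i <- i + blen + glen
    }
    sig
  } else { # fall
    g_up <- gravity_vector(p$tilt_deg, p$azimuth_deg)
    g_ly <- gravity_vector(p$lying_tilt_deg, p$lying_azimuth_deg)
    n_pre <- max(1L, round(p$prefix_frac * n))
    n_ff <- max(1L, round(p$freefall_frac * n))
    n_imp <- min(2L, max(0L, n - n_pre - n_ff))
    n_ly <- max(0L, n - n_pre - n_ff - n_imp)
    dir <- g_ly / sqrt(sum(g_ly^2))
    rbind(
      matrix(g_up, nrow = n_pre, ncol = 3, byrow = TRUE),
      matrix(0.15 * g_up, nrow = n_ff, ncol = 3, byrow = TRUE),
      if (n_imp > 0) matrix(p$impact_g * dir, nrow = n_imp, ncol = 3,
                            byrow = TRUE),
      matrix(g_ly, nrow = n_ly, ncol = 3, byrow = TRUE)
    )[seq_len(n), , drop = FALSE]
  }
}

sim_segment_impl <- function(segment, config) {
  n <- round(segment$duration_s * config$sampling_rate_hz)
  if (n < 1) abort("segment too short for the sampling rate",
                   class = "harcascade_invalid_config")
  p <- utils::modifyList(seg_defaults(segment$activity), segment$params)
  p$rate <- config$sampling_rate_hz
  sig <- clean_signal(segment$activity, n, p)
  if (config$noise_sd_g > 0) {
    sig <- sig + matrix(rnorm(3 * n, sd = config$noise_sd_g), ncol = 3)
  }
  if (config$spike_prob > 0) {
    hit <- which(runif(n) < config$spike_prob)
    for (i in hit) {
      ax <- sample(3, 1)
      sig[i, ax] <- sig[i, ax] +
        sign(runif(1) - 0.5) * config$spike_magnitude_g
    }
  }
  sig <- pmin(pmax(sig, -config$accel_range_g), config$accel_range_g)
  tibble(t = (seq_len(n) - 1) / config$sampling_rate_hz,
         x = sig[, 1], y = sig[, 2], z = sig[, 3],
         label = segment$activity)
}

new_accel_stream <- function(df, config) {
  structure(df, config = config,
            class = c("accel_stream", class(tibble())))
}

#' Simulate one activity segment
#'
#' Generates a labelled tri-axial acceleration stream for a single scripted
#' activity. The clean per-activity signal model is: static gravity posture
#' (sit/sleep), gravity plus gait oscillation (walk), posture plus short
#' high-amplitude burst trains (cough), and an upright-to-lying transition
#' with a free-fall dip and an impact spike (fall). Gaussian noise and
#' isolated spikes are then added and samples are clipped to the sensor
#' range.
#'
#' @param segment an [activity_segment()].
#' @param config a [sim_config()]; `config$seed` makes the output
#'   reproducible.
#' @return a tibble of class `accel_stream` with columns `t` (seconds),
#'   `x`, `y`, `z` (g) and `label`; `round(duration_s * sampling_rate_hz)`
#'   rows with ideal, strictly increasing timestamps.
#' @examples
#' simulate_segment(activity_segment("sit", 5),
#'                  sim_config(noise_sd_g = 0, spike_prob = 0))
#' @export
simulate_segment <- function(segment, config = sim_config()) {
  stopifnot(inherits(segment, "activity_segment"),
            inherits(config, "sim_config"))
  new_accel_stream(
    withr::with_seed(config$seed, sim_segment_impl(segment, config)),
    config
  )
}

#' Simulate a scripted scenario of consecutive activities
#'
#' Concatenates per-segment streams with continuous timestamps. The label
#' sequence is a deterministic function of the script; the sample values are
#' a deterministic function of (script, config, seed).
#'
#' @param segments a list of [activity_segment()] objects (a "script").
#' @inheritParams simulate_segment
#' @return an `accel_stream` tibble covering the whole script.
#' @examples
#' script <- list(activity_segment("sit", 10), activity_segment("walk", 10))
#' simulate_scenario(script, sim_config(seed = 42))
#' @export
simulate_scenario <- function(segments, config = sim_config()) {
  if (length(segments) < 1) {
    abort("the script must contain at least one segment",
          class = "harcascade_invalid_input")
  }
  stopifnot(all(vapply(segments, inherits, TRUE, "activity_segment")))
  out <- withr::with_seed(config$seed, {
    purrr::map(segments, sim_segment_impl, config = config)
  })
  df <- bind_rows(out)
  df$t <- (seq_len(nrow(df)) - 1) / config$sampling_rate_hz
  new_accel_stream(df, config)
}

#' Build a balanced, deliberately confusable benchmark stream
#'
#' Emulates the conditions under which a single five-class model struggles:
#' sit and sleep postures are drawn from tilt ranges that nearly touch
#' (recline up to 40 degrees vs lying tilts from 50 degrees), and cough
#' bursts are superimposed on sit, walk and sleep base postures while the
#' samples stay labelled `cough` (a cough during any normal activity is
#' still a cough). Falls are many short upright-to-lying events. The result
#' is exactly `n_per_class` samples per activity.
#'
#' @param config a [sim_config()].
#' @param n_per_class samples per class; at least 50.
#' @param seed integer seed for the benchmark draw (overrides `config$seed`).
#' @return an `accel_stream` tibble with `5 * n_per_class` rows.
#' @examples
#' bench <- make_confusable_benchmark(sim_config(), n_per_class = 50, seed = 7)
#' table(bench$label)
#' @export
make_confusable_benchmark <- function(config = sim_config(), n_per_class,
                                      seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_per_class) || n_per_class < 50) {
    abort("n_per_class must be at least 50",
          class = "harcascade_invalid_config")
  }
  n_per_class <- as.integer(n_per_class)
  rate <- config$sampling_rate_hz
  chunk_s <- 10
  df <- withr::with_seed(as.integer(seed), {
    gen_class <- function(activity) {
      rows <- list()
      got <- 0L
      while (got < n_per_class) {
        # frail-care posture continuum: semi-recumbent sitting, variably
        # propped sleeping and post-fall lying overlap in tilt, which is
        # exactly what confuses a single five-class model
        params <- switch(activity,
          sit   = list(tilt_deg = runif(1, 20, 70),
                       azimuth_deg = runif(1, -20, 20)),
          sleep = list(tilt_deg = runif(1, 40, 90),
                       azimuth_deg = runif(1, 0, 90)),
          walk  = list(tilt_deg = runif(1, 0, 20),
                       gait_hz = runif(1, 1.6, 2.4),
                       amp_vertical_g = runif(1, 0.25, 0.45)),
          cough = {
            base_act <- sample(c("sit", "walk", "sleep"), 1)
            base <- switch(base_act,
              sit   = list(tilt_deg = runif(1, 20, 70)),
              walk  = list(tilt_deg = runif(1, 0, 20), gait_hz = 2,
                           amp_vertical_g = 0.35, amp_lateral_g = 0.15,
                           amp_forward_g = 0.1),
              sleep = list(tilt_deg = runif(1, 40, 90),
                           azimuth_deg = runif(1, 0, 90)))
            list(base = base, burst_len = 2:3, gap_len = 2:4)
          },
          fall  = list(tilt_deg = runif(1, 10, 40),
                       lying_tilt_deg = runif(1, 60, 90),
                       lying_azimuth_deg = runif(1, 0, 90),
                       prefix_frac = 0.1, freefall_frac = 0.1)
        )
        # a fall is a short event that ends lying on the floor and stays
        # there; postures run in longer stretches
        dur <- if (activity == "fall") 4 else chunk_s
        seg <- activity_segment(activity, dur, params)
        rows[[length(rows) + 1L]] <- sim_segment_impl(seg, config)
        got <- got + nrow(rows[[length(rows)]])
      }
      utils::head(bind_rows(rows), n_per_class)
    }
    bind_rows(purrr::map(activity_levels(), gen_class))
  })
  df$t <- (seq_len(nrow(df)) - 1) / rate
  new_accel_stream(df, config)
}
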