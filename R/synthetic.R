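#' Simulation configuration for synthetic sEMG recordings
#'
#' Describes the synthetic acquisition protocol emulated by [gen_recording()]:
#' four sEMG channels sampled at 1000 Hz, band-limited to 20--460 Hz, plus a
#' knee-goniometer angle trace in degrees. Each movement class has its own
#' kinematic template (angle range in degrees and cycle rate in Hz); the sEMG
#' channels are band-limited Gaussian carriers amplitude-modulated by
#' rectified functions of the angle and its angular velocity, with
#' channel-specific gains mimicking the four recorded muscles (vastus
#' medialis, semitendinosus, biceps femoris, rectus femoris).
#'
#' @param fs Sampling frequency in Hz.
#' @param duration_s Trial duration in seconds.
#' @param n_channels Number of sEMG channels.
#' @param band Pass band of the carrier in Hz, `c(low, high)` with
#'   `0 < low < high < fs/2`.
#' @param angle_range Named list of `c(min, max)` knee angles in degrees, one
#'   entry per movement class. All values must lie in the physiological
#'   interval \[0, 120\] degrees.
#' @param cycle_rate Named numeric vector of movement cycle rates in Hz.
#' @param envelope_gain `n_channels` x 2 matrix of per-channel activation
#'   weights; column 1 multiplies normalized angular speed, column 2 the
#'   normalized angle.
#' @param class_pattern 3 x `n_channels` muscle recruitment matrix: row k+1
#'   scales each channel's envelope for the class with code k. The defaults
#'   encode that knee extension recruits the quadriceps channels (vm, rf),
#'   knee flexion the hamstring channels (st, bf), and gait all four
#'   cyclically -- the agonist/antagonist structure that makes movements
#'   distinguishable from any single window.
#' @param noise_floor Relative amplitude of the always-on activation floor.
#' @param class_separation Per-class overall activation scale: class with
#'   integer code `k` has its envelopes multiplied by `class_separation^k`,
#'   so the three movements differ in mean rectified sEMG amplitude (dynamic
#'   gait versus slower postural movements recruit muscle to different
#'   degrees). Set to 1 to disable.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   recordings.
#' @return An object of class `sim_config`.
#' @seealso [gen_recording()], [gen_dataset()]
#' @export
sim_config <- function(fs = 1000,
                       duration_s = 30,
                       n_channels = 4,
                       band = c(20, 460),
                       angle_range = list(
                         walking = c(5, 65),
                         sitting_knee_extension = c(10, 90),
                         standing_knee_flexion = c(5, 70)
                       ),
                       cycle_rate = c(
                         walking = 1.0,
                         sitting_knee_extension = 0.5,
                         standing_knee_flexion = 0.4
                       ),
                       envelope_gain = default_envelope_gain(n_channels),
                       class_pattern = default_class_pattern(n_channels),
                       noise_floor = 0.05,
                       class_separation = 1.25,
                       seed = 1L) {
  if (length(band) != 2 || !(0 < band[1] && band[1] < band[2] && band[2] < fs / 2)) {
    stopf("invalid band: need 0 < low < high < fs/2, got [%s, %s] at fs = %s",
          band[1], band[2], fs)
  }
  if (duration_s <= 0) stopf("duration_s must be positive")
  if (duration_s * fs < 256) stopf("recording must cover at least one 256-sample window")
  if (n_channels < 1) stopf("need at least one channel")
  lv <- movement_classes()
  if (!all(lv %in% names(angle_range))) stopf("angle_range must name all three classes")
  if (!all(lv %in% names(cycle_rate))) stopf("cycle_rate must name all three classes")
  for (cl in lv) {
    r <- angle_range[[cl]]
    if (length(r) != 2 || r[1] >= r[2] || r[1] < 0 || r[2] > 120) {
      stopf("angle_range for %s must be c(min, max) within [0, 120] degrees", cl)
    }
  }
  envelope_gain <- as.matrix(envelope_gain)
  if (nrow(envelope_gain) != n_channels || ncol(envelope_gain) != 2) {
    stopf("envelope_gain must be an n_channels x 2 matrix")
  }
  if (class_separation <= 0) stopf("class_separation must be positive")
  class_pattern <- as.matrix(class_pattern)
  if (nrow(class_pattern) != 3 || ncol(class_pattern) != n_channels) {
    stopf("class_pattern must be a 3 x n_channels matrix")
  }
  structure(list(
    fs = fs, duration_s = duration_s, n_channels = n_channels, band = band,
    angle_range = angle_range, cycle_rate = cycle_rate,
    envelope_gain = envelope_gain, class_pattern = class_pattern,
    noise_floor = noise_floor, class_separation = class_separation,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# default per-channel (velocity, angle) activation weights for the four
# muscles vm, st, bf, rf: a dominant tonic component tracking the joint angle
# (load increases with flexion) plus a smaller phasic component tracking
# angular speed, so the angle trace is strongly encoded in every channel
default_envelope_gain <- function(n_channels = 4) {
  g <- matrix(c(
    0.18, 0.95,  # vastus medialis
    0.12, 0.75,  # semitendinosus
    0.10, 0.85,  # biceps femoris
    0.20, 0.90   # rectus femoris
  ), ncol = 2, byrow = TRUE)
  colnames(g) <- c("velocity", "angle")
  rownames(g) <- c("vm", "st", "bf", "rf")
  if (n_channels == 4) return(g)
  g[rep_len(seq_len(4), n_channels), , drop = FALSE]
}

# per-movement muscle recruitment: rows = walking, sitting w/ knee extension,
# standing w/ knee flexion; columns = vm, st, bf, rf
default_class_pattern <- function(n_channels = 4) {
  p <- matrix(c(
    0.90, 0.75, 0.75, 0.90,  # walking: co-activation over the gait cycle
    1.20, 0.45, 0.45, 1.10,  # extension: quadriceps dominant
    0.45, 1.10, 1.20, 0.50   # flexion: hamstrings dominant
  ), nrow = 3, byrow = TRUE)
  rownames(p) <- movement_classes()
  p[, rep_len(seq_len(4), n_channels), drop = FALSE]
}

# class-specific knee angle template; assumes the RNG is already seeded
angle_template <- function(cls_code, n, cfg) {
  lv <- movement_classes()
  cl <- lv[cls_code + 1L]
  tt <- (seq_len(n) - 1) / cfg$fs
  f <- cfg$cycle_rate[[cl]] * runif(1, 0.95, 1.05)
  phase <- runif(1, 0, 2 * pi)
  r <- cfg$angle_range[[cl]]
  u <- switch(cl,
    # periodic flexion-extension at the gait rate
    walking = sin(pi * f * tt + phase)^2,
    # seated: smooth repeated extension cycles from flexed toward straight
    sitting_knee_extension = 1 - (0.5 - 0.5 * cos(2 * pi * f * tt + phase)),
    # standing: smooth repeated flexion cycles from straight toward flexed
    standing_knee_flexion = 0.5 - 0.5 * cos(2 * pi * f * tt + phase)
  )
  pmin(pmax(r[1] + (r[2] - r[1]) * u, 0), 120)
}

# zero-phase band-limited unit-variance Gaussian carrier
band_carrier <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sd(x)
}

#' Generate one synthetic sEMG + knee-angle recording
#'
#' Builds the class kinematic template (walking: periodic flexion--extension;
#' sitting with knee extension: repeated extension ramps from a flexed seated
#' posture; standing with knee flexion: repeated flexion dips from a straight
#' leg), then modulates per-channel band-limited Gaussian carriers by
#' `gain_c * |d(angle)/dt|/100 + bias_c * angle/120 + noise_floor`. No
#' transition-phase samples between postures are generated. The same
#' configuration yields a bit-identical recording.
#'
#' @param cls Movement class: one of [movement_classes()] or its 0-based
#'   integer code.
#' @param cfg A [sim_config()].
#' @param subject_id Identifier stored in the recording.
#' @return An object of class `emg_recording`; see [recording()].
#' @export
#' @examples
#' rec <- gen_recording("walking", sim_config(duration_s = 2, seed = 7))
#' dim(rec$emg)
#' range(rec$angle)
gen_recording <- function(cls, cfg = sim_config(), subject_id = "synthetic") {
  stopifnot(inherits(cfg, "sim_config"))
  code <- as_class_code(cls)
  n <- round(cfg$duration_s * cfg$fs)
  with_seed(cfg$seed, {
    angle <- angle_template(code, n, cfg)
    # normalized angular speed (deg/s scaled by a typical 100 deg/s) and angle
    vel <- c(0, diff(angle)) * cfg$fs / 100
    a_norm <- angle / 120
    emg <- matrix(0, n, cfg$n_channels)
    amp <- cfg$class_separation^code
    for (ch in seq_len(cfg$n_channels)) {
      env <- amp * cfg$class_pattern[code + 1L, ch] *
        (cfg$envelope_gain[ch, 1] * abs(vel) +
         cfg$envelope_gain[ch, 2] * a_norm + cfg$noise_floor)
      emg[, ch] <- env * band_carrier(n, cfg$fs, cfg$band)
    }
    recording(emg, angle, fs = cfg$fs, cls = code,
              subject_id = subject_id, cohort = "synthetic")
  })
}

#' Generate a balanced synthetic dataset
#'
#' Produces `n_trials_per_class` recordings for each of the three movement
#' classes. Per-trial seeds are derived deterministically from `cfg$seed`, so
#' the same configuration always yields the identical dataset while trials
#' differ from one another (cycle-rate jitter, phase, carrier noise).
#'
#' @param n_trials_per_class Number of trials per movement class (>= 1).
#' @param cfg A [sim_config()]; its `seed` field anchors all per-trial seeds.
#' @return List of `3 * n_trials_per_class` `emg_recording` objects, grouped
#'   by class in the order of [movement_classes()].
#' @export
gen_dataset <- function(n_trials_per_class, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_trials_per_class < 1) stopf("n_trials_per_class must be >= 1")
  out <- vector("list", 3L * n_trials_per_class)
  i <- 0L
  for (code in 0:2) {
    for (trial in seq_len(n_trials_per_class)) {
      i <- i + 1L
      cfg_i <- cfg
      cfg_i$seed <- (cfg$seed + 7919L * (i - 1L)) %% .Machine$integer.max
      out[[i]] <- gen_recording(code, cfg_i,
                                subject_id = sprintf("sim_%s_t%02d",
                                                     movement_classes()[code + 1L],
                                                     trial))
    }
  }
  out
}
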