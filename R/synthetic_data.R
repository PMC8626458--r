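#' Configuration for the synthetic accelerometer dataset generator
#'
#' Defaults emulate the structure of the public waist-worn fall repositories
#' this framework targets: cohorts aged 18-75 years, heights 149-193 cm,
#' weights 41.5-102 kg, tri-axial signals in g at a fixed sampling rate,
#' trials of a few seconds to a few minutes, fall trials exhibiting a
#' free-fall valley followed by an impact peak, and ADL trials spanning
#' basic / standard / sporting / near-fall energy levels.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param seed Integer seed fixing every generated value.
#' @param age_range,height_range,weight_range Uniform sampling ranges
#'   (years, cm, kg). Uniform (not normal) sampling guarantees coverage of
#'   the range extremes exercised by the sorted 80/20 splits.
#' @param female_fraction Fraction of female subjects in [0, 1]; the female
#'   head-count is the rounded fraction of `n_subjects`.
#' @param trials_per_subject_per_category Trials generated per subject for
#'   each of the five activity categories.
#' @param sampling_rate Hz.
#' @param trial_duration Seconds per trial (>= 2 s for a full observation
#'   window).
#' @param amplitude_coupling Dimensionless gain linking a subject's
#'   height x weight product to event peak amplitude: the event amplitude is
#'   scaled by `1 + 0.5 * amplitude_coupling * (hw / hw_ref - 1)` where
#'   `hw_ref` is the product of the range midpoints. At 0 the subject's
#'   build has no effect on the signal; at 1 the heaviest/tallest subjects
#'   produce markedly larger impact and sporting peaks. The free-fall valley
#'   is never scaled (free fall is mass-independent).
#' @param noise_sd Per-axis Gaussian noise standard deviation in g.
#' @param age_effect When TRUE, event transition times are lengthened for
#'   older subjects (up to ~25% across the adult age span), mimicking slower
#'   reaction; off by default.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 10, seed = 1,
                             age_range = c(18, 75),
                             height_range = c(149, 193),
                             weight_range = c(41.5, 102),
                             female_fraction = 0.5,
                             trials_per_subject_per_category = 2,
                             sampling_rate = 50, trial_duration = 10,
                             amplitude_coupling = 1, noise_sd = 0.03,
                             age_effect = FALSE) {
  stopifnot(n_subjects >= 1,
            diff(age_range) > 0, diff(height_range) > 0,
            diff(weight_range) > 0,
            female_fraction >= 0, female_fraction <= 1,
            trials_per_subject_per_category >= 1,
            sampling_rate > 0, trial_duration > 0, noise_sd >= 0)
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 age_range = age_range, height_range = height_range,
                 weight_range = weight_range,
                 female_fraction = female_fraction,
                 trials_per_subject_per_category =
                   trials_per_subject_per_category,
                 sampling_rate = sampling_rate,
                 trial_duration = trial_duration,
                 amplitude_coupling = amplitude_coupling,
                 noise_sd = noise_sd, age_effect = age_effect),
            class = "generator_config")
}

#' Default synthetic activity taxonomy
#'
#' Two activities per category; the `intensity` column scales the category
#' waveform amplitude (a `standing` trial with intensity 0 is the pure 1-g
#' gravity signal).
#'
#' @return Activities data frame with an extra `intensity` column.
#' @export
default_activities <- function() {
  data.frame(
    code = c("standing", "sit_down", "walking", "stairs",
             "jumping", "running", "stumble", "slip_recovery",
             "forward_fall", "lateral_fall"),
    description = c("quiet standing", "sitting down on a chair",
                    "level walking", "climbing stairs",
                    "repeated vertical jumps", "jogging",
                    "trip with recovery", "slip with recovery",
                    "forward fall with impact", "lateral fall with impact"),
    klass = c(rep("ADL", 8), rep("FALL", 2)),
    category = c("basic", "basic", "standard", "standard",
                 "sporting", "sporting", "near_fall", "near_fall",
                 "fall", "fall"),
    intensity = c(0, 1, 1, 0.8, 1, 0.8, 1, 0.9, 1, 1),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic subject cohort
#'
#' Characteristics are drawn uniformly within the configured ranges;
#' deterministic given the config seed. The first `round(female_fraction *
#' n_subjects)` subjects are female.
#'
#' @param cfg A [generator_config()].
#' @return Subjects data frame (see [fds_dataset()]).
#' @export
generate_subjects <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  n_f <- round(cfg$female_fraction * n)
  height <- stats::runif(n, cfg$height_range[1], cfg$height_range[2])
  weight <- stats::runif(n, cfg$weight_range[1], cfg$weight_range[2])
  age <- round(stats::runif(n, cfg$age_range[1], cfg$age_range[2]))
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             sex = c(rep("female", n_f), rep("male", n - n_f)),
             age = age, height_cm = height, weight_kg = weight,
             bmi = compute_bmi(weight, height),
             stringsAsFactors = FALSE)
}

# Subject-build gain on event amplitudes. Normalised against the product of
# the configured range midpoints so it is independent of the sampled cohort.
amplitude_gain <- function(subject, cfg) {
  hw <- subject$height_cm * subject$weight_kg
  hw_ref <- mean(cfg$height_range) * mean(cfg$weight_range)
  1 + 0.5 * cfg$amplitude_coupling * (hw / hw_ref - 1)
}

gauss_bump <- function(t, center, width) exp(-0.5 * ((t - center) / width)^2)

# Deterministic waveform kernels: magnitude profile m(t) and tilt angle
# theta(t) away from the vertical; the acceleration vector is m(t) times the
# unit direction (sin(theta), small lateral, cos(theta)). Category contracts:
#   fall      SMV valley < 0.6 g, impact peak > 2 g, near-1 g rest after.
#   basic     SMV within [0.7, 1.5] g throughout.
#   standard  oscillation stronger than basic, no impact.
#   sporting  periodic peaks > 2 g with no preceding sub-0.6 g valley.
#   near_fall valley < 0.8 g, peak well below a fall impact, return to rest.
kernel_signal <- function(category, intensity, gain, t, dur, phase,
                          event_center, width_scale) {
  n <- length(t)
  env <- gauss_bump(t, dur / 2, dur / 4)
  theta <- numeric(n)
  if (category == "basic") {
    m <- 1 + 0.15 * intensity * env * sin(2 * pi * 0.8 * t + phase)
    theta <- 0.15 * intensity * env * gauss_bump(t, dur / 2, dur / 8)
  } else if (category == "standard") {
    m <- 1 + 0.35 * intensity * env * sin(2 * pi * 1.5 * t + phase)
    theta <- 0.20 * intensity * env * abs(sin(2 * pi * 0.5 * t + phase))
  } else if (category == "sporting") {
    osc <- sin(2 * pi * 1.2 * t + phase)
    m <- 1 + env * intensity * (1.8 * gain * abs(osc)^5 + 0.25 * osc)
    theta <- 0.25 * intensity * env * abs(sin(2 * pi * 1.2 * t + phase))
  } else if (category == "near_fall") {
    tc <- event_center
    m <- 1 - 0.35 * intensity * gauss_bump(t, tc, 0.10 * width_scale) +
      0.7 * gain * intensity * gauss_bump(t, tc + 0.25, 0.06 * width_scale)
    theta <- (25 * pi / 180) * gauss_bump(t, tc + 0.20, 0.15 * width_scale)
  } else if (category == "fall") {
    tc <- event_center
    m <- 1 - 0.75 * gauss_bump(t, tc, 0.08 * width_scale) +
      2.2 * gain * gauss_bump(t, tc + 0.30, 0.04 * width_scale)
    theta <- (pi / 2) / (1 + exp(-(t - (tc + 0.30)) /
                                   (0.15 * width_scale)))
  } else {
    stop(sprintf("no waveform kernel for activity category '%s'", category))
  }
  ux <- sin(theta)
  uz <- cos(theta)
  cbind(ax_g = m * ux, ay_g = rep(0, n), az_g = m * uz)
}

#' Generate one synthetic trial
#'
#' @param subject One-row subjects data frame (or list with the same
#'   fields).
#' @param activity One-row activities data frame with an `intensity` column
#'   (see [default_activities()]).
#' @param cfg A [generator_config()].
#' @param trial_seed Integer seed for this trial's random phase, event
#'   timing jitter and axis noise.
#' @return A trial list as returned by [get_trial()] (without an id when
#'   none is supplied).
#' @export
generate_trial <- function(subject, activity, cfg, trial_seed) {
  set.seed(as.integer(trial_seed))
  r <- cfg$sampling_rate
  dur <- cfg$trial_duration
  n <- max(2L, round(dur * r))
  t <- (seq_len(n) - 1) / r
  gain <- amplitude_gain(subject, cfg)
  width_scale <- 1
  if (isTRUE(cfg$age_effect))
    width_scale <- 1 + 0.25 * max(0, subject$age - 20) / 55
  phase <- stats::runif(1, 0, 2 * pi)
  event_center <- 0.4 * dur + stats::runif(1, -0.05, 0.05) * dur
  sig <- kernel_signal(activity$category, activity$intensity, gain, t, dur,
                       phase, event_center, width_scale)
  if (cfg$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(3L * n, 0, cfg$noise_sd), ncol = 3)
  dimnames(sig) <- list(NULL, c("ax_g", "ay_g", "az_g"))
  list(trial_id = NA_character_, subject_id = subject$subject_id,
       activity_code = activity$code, sampling_rate = r, samples = sig)
}

#' Generate a complete labelled synthetic dataset
#'
#' Per subject, `trials_per_subject_per_category` trials are generated for
#' each of the five activity categories, cycling through that category's
#' activities. Per-trial seeds are derived deterministically from the config
#' seed, so the whole dataset is a pure function of the configuration.
#'
#' @param cfg A [generator_config()].
#' @param name Dataset name.
#' @return A validated `fds_dataset`.
#' @export
generate_dataset <- function(cfg, name = "synthetic") {
  subjects <- generate_subjects(cfg)
  activities <- default_activities()
  cats <- ALL_CATEGORIES
  trials <- list()
  signals <- list()
  k <- 0L
  for (si in seq_len(nrow(subjects))) {
    subj <- subjects[si, ]
    for (cat in cats) {
      acts <- activities[activities$category == cat, ]
      for (j in seq_len(cfg$trials_per_subject_per_category)) {
        k <- k + 1L
        act <- acts[((j - 1L) %% nrow(acts)) + 1L, ]
        tseed <- (as.double(cfg$seed) * 7919 + k * 104729) %% 2147483647
        tr <- generate_trial(subj, act, cfg, tseed)
        id <- sprintf("T%04d", k)
        trials[[k]] <- data.frame(trial_id = id,
                                  subject_id = subj$subject_id,
                                  activity_code = act$code,
                                  sampling_rate = cfg$sampling_rate,
                                  stringsAsFactors = FALSE)
        signals[[id]] <- tr$samples
      }
    }
  }
  fds_dataset(name, subjects, activities[, setdiff(names(activities),
                                                   "intensity")],
              do.call(rbind, trials), signals)
}
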