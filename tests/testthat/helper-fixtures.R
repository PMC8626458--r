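# Shared fixtures, built in code at test time.

# Minimal hand-built dataset: 2 subjects, one fall + one ADL activity,
# deterministic ramp signals.
tiny_dataset <- function() {
  subjects <- data.frame(
    subject_id = c("S01", "S02"), sex = c("female", "male"),
    age = c(25, 60), height_cm = c(160, 180), weight_kg = c(55, 80),
    stringsAsFactors = FALSE)
  activities <- data.frame(
    code = c("walk", "fall_fwd"),
    description = c("walking", "forward fall"),
    klass = c("ADL", "FALL"), category = c("standard", "fall"),
    stringsAsFactors = FALSE)
  sig <- function(n, amp) cbind(ax_g = seq(0, amp, length.out = n),
                                ay_g = rep(0, n), az_g = rep(1, n))
  trials <- data.frame(
    trial_id = c("T1", "T2", "T3"),
    subject_id = c("S01", "S01", "S02"),
    activity_code = c("walk", "fall_fwd", "fall_fwd"),
    sampling_rate = c(20, 20, 20), stringsAsFactors = FALSE)
  fds_dataset("tiny", subjects, activities, trials,
              list(T1 = sig(60, 0.3), T2 = sig(60, 2.5),
                   T3 = sig(80, 3.0)))
}

# Synthetic dataset under the default study conditions, memoised per seed
# so several tests can share one generation.
default_synthetic <- local({
  cache <- list()
  function(seed = 1, ...) {
    key <- paste(seed, paste(c(...), collapse = "_"))
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_dataset(generator_config(seed = seed, ...))
    cache[[key]]
  }
})

# Trial wrapper around a raw sample matrix.
as_trial <- function(samples, rate = 20)
  list(trial_id = "T", subject_id = "S", activity_code = "A",
       sampling_rate = rate, samples = samples)

# Wide-margin two-cluster toy: ADL cluster at -mu, FALL cluster at +mu in
# every coordinate, spread sd; linearly separable with margin >> spread.
separable_toy <- function(n_per = 20, d = 12, mu = 5, sd = 0.3,
                          seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * d, -mu, sd), n_per),
             matrix(stats::rnorm(n_per * d, +mu, sd), n_per))
  y <- factor(rep(c("ADL", "FALL"), each = n_per),
              levels = c("ADL", "FALL"))
  idx <- sample(2 * n_per)
  list(x = x[idx, ], y = y[idx])
}

# Random 3-D rotation matrix (proper, det = +1).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Random observation window for oracle checks.
random_window <- function(seed, n = 30, rate = 10) {
  set.seed(seed)
  m <- cbind(stats::rnorm(n, 0, 1), stats::rnorm(n, 0, 1),
             stats::rnorm(n, 1, 1))
  colnames(m) <- c("ax_g", "ay_g", "az_g")
  extract_window(as_trial(m, rate))
}
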