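#' Body-mass index from weight and height
#'
#' BMI is the subject's weight in kilograms divided by the squared height
#' expressed in metres.
#'
#' @param weight_kg Body weight in kilograms (positive).
#' @param height_cm Body height in centimetres (positive).
#' @return BMI in kg/m². Vectorised over both arguments.
#' @examples
#' compute_bmi(100, 200)  # 25
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (!all(is.finite(weight_kg)) || !all(is.finite(height_cm)))
    stop("compute_bmi: weight and height must be finite")
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("compute_bmi: weight and height must be strictly positive")
  weight_kg / (height_cm / 100)^2
}

ADL_CATEGORIES <- c("basic", "standard", "sporting", "near_fall")
ALL_CATEGORIES <- c(ADL_CATEGORIES, "fall")

#' Assemble a fall-detection dataset
#'
#' A dataset couples three metadata tables (subjects, activities, trials)
#' with one tri-axial acceleration signal per trial. Units are g throughout;
#' adapters for repositories storing m/s² or raw ADC counts must convert
#' before constructing the dataset.
#'
#' @param name Dataset name.
#' @param subjects Data frame with columns `subject_id`, `sex`
#'   (\code{"female"}/\code{"male"}), `age` (years), `height_cm`,
#'   `weight_kg`, and optionally `bmi` (recomputed when absent).
#' @param activities Data frame with columns `code`, `description`, `klass`
#'   (\code{"ADL"}/\code{"FALL"}) and `category` (one of basic, standard,
#'   sporting, near_fall, fall).
#' @param trials Data frame with columns `trial_id`, `subject_id`,
#'   `activity_code`, `sampling_rate` (Hz).
#' @param signals Named list (names = trial ids) of numeric matrices with
#'   columns `ax_g`, `ay_g`, `az_g`, one row per sample.
#' @param validate Run [validate_dataset()] before returning.
#' @return An object of class `fds_dataset`.
#' @export
fds_dataset <- function(name, subjects, activities, trials, signals,
                        validate = TRUE) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  activities <- as.data.frame(activities, stringsAsFactors = FALSE)
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  if (is.null(subjects$bmi))
    subjects$bmi <- compute_bmi(subjects$weight_kg, subjects$height_cm)
  ds <- structure(
    list(name = name, subjects = subjects, activities = activities,
         trials = trials, signals = signals),
    class = "fds_dataset")
  if (validate) validate_dataset(ds)
  ds
}

#' Validate a dataset against the structural invariants
#'
#' Checks reference integrity (every trial resolves to a subject and an
#' activity), subject plausibility (positive height/weight, binary sex, BMI
#' consistent with height and weight to 1e-9 relative tolerance), the
#' ADL/fall taxonomy (`klass == "FALL"` exactly when `category == "fall"`),
#' signal sanity (at least two finite samples per trial) and, optionally,
#' per-trial duration bounds.
#'
#' @param ds An `fds_dataset`.
#' @param duration_bounds Optional numeric length-2 vector (seconds); when
#'   given, every trial duration (samples / rate) must lie inside it.
#' @return `ds`, invisibly. Throws a descriptive error naming the offending
#'   record otherwise.
#' @export
validate_dataset <- function(ds, duration_bounds = NULL) {
  s <- ds$subjects; a <- ds$activities; tr <- ds$trials
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("dataset '%s': %s table lacks columns: %s",
                   ds$name, what, paste(miss, collapse = ", ")))
  }
  need(s, c("subject_id", "sex", "age", "height_cm", "weight_kg"), "subjects")
  need(a, c("code", "klass", "category"), "activities")
  need(tr, c("trial_id", "subject_id", "activity_code", "sampling_rate"),
       "trials")

  if (anyDuplicated(s$subject_id))
    stop("duplicated subject_id in subjects table")
  if (!all(s$sex %in% c("female", "male")))
    stop("subject sex must be 'female' or 'male'")
  if (any(!is.finite(s$age)) || any(s$age < 0))
    stop("subject age must be a non-negative number of years")
  if (any(s$height_cm <= 0) || any(s$weight_kg <= 0))
    stop("subject height and weight must be strictly positive")
  if (!is.null(s$bmi)) {
    expect <- compute_bmi(s$weight_kg, s$height_cm)
    bad <- abs(s$bmi - expect) > 1e-9 * pmax(1, abs(expect))
    if (any(bad))
      stop(sprintf("subject %s: stored BMI inconsistent with height/weight",
                   s$subject_id[which(bad)[1]]))
  }

  if (anyDuplicated(a$code)) stop("duplicated activity code")
  if (!all(a$klass %in% c("ADL", "FALL")))
    stop("activity klass must be 'ADL' or 'FALL'")
  if (!all(a$category %in% ALL_CATEGORIES))
    stop("unknown activity category")
  mism <- (a$klass == "FALL") != (a$category == "fall")
  if (any(mism))
    stop(sprintf("activity %s: klass/category mismatch (FALL <=> fall)",
                 a$code[which(mism)[1]]))

  if (anyDuplicated(tr$trial_id)) stop("duplicated trial_id")
  bad_sub <- !(tr$subject_id %in% s$subject_id)
  if (any(bad_sub))
    stop(sprintf("trial %s references unknown subject %s",
                 tr$trial_id[which(bad_sub)[1]],
                 tr$subject_id[which(bad_sub)[1]]))
  bad_act <- !(tr$activity_code %in% a$code)
  if (any(bad_act))
    stop(sprintf("trial %s references unknown activity %s",
                 tr$trial_id[which(bad_act)[1]],
                 tr$activity_code[which(bad_act)[1]]))
  if (any(tr$sampling_rate <= 0))
    stop("trial sampling_rate must be positive")

  for (id in tr$trial_id) {
    sig <- ds$signals[[id]]
    if (is.null(sig))
      stop(sprintf("trial %s has no signal", id))
    if (nrow(sig) < 2)
      stop(sprintf("trial %s: fewer than 2 samples", id))
    if (!all(is.finite(sig)))
      stop(sprintf("trial %s: non-finite acceleration value", id))
    if (!is.null(duration_bounds)) {
      dur <- nrow(sig) / tr$sampling_rate[tr$trial_id == id]
      if (dur < duration_bounds[1] || dur > duration_bounds[2])
        stop(sprintf("trial %s: duration %.3f s outside declared bounds", id,
                     dur))
    }
  }

  kl <- a$klass[match(tr$activity_code, a$code)]
  if (!any(kl == "FALL") || !any(kl == "ADL"))
    stop(sprintf("dataset '%s' must contain at least one fall and one ADL trial",
                 ds$name))
  invisible(ds)
}

#' Retrieve one trial with its signal
#'
#' @param ds An `fds_dataset`.
#' @param trial_id Trial identifier.
#' @return List with `trial_id`, `subject_id`, `activity_code`,
#'   `sampling_rate` and `samples` (N x 3 matrix in g).
#' @export
get_trial <- function(ds, trial_id) {
  i <- match(trial_id, ds$trials$trial_id)
  if (is.na(i)) stop(sprintf("unknown trial '%s'", trial_id))
  list(trial_id = trial_id,
       subject_id = ds$trials$subject_id[i],
       activity_code = ds$trials$activity_code[i],
       sampling_rate = ds$trials$sampling_rate[i],
       samples = ds$signals[[trial_id]])
}

#' Per-trial class labels
#'
#' @param ds An `fds_dataset`.
#' @return Factor with levels `ADL`, `FALL`, one element per trial, in trial
#'   table order, named by trial id.
#' @export
trial_labels <- function(ds) {
  kl <- ds$activities$klass[match(ds$trials$activity_code,
                                  ds$activities$code)]
  stats::setNames(factor(kl, levels = c("ADL", "FALL")), ds$trials$trial_id)
}

#' Summarise a dataset
#'
#' @param ds An `fds_dataset`.
#' @return List with `n_subjects`, `n_trials`, `n_adl`, `n_fall` and
#'   `per_category` (named integer vector of trial counts by activity
#'   category).
#' @export
summarize_dataset <- function(ds) {
  cat <- ds$activities$category[match(ds$trials$activity_code,
                                      ds$activities$code)]
  per <- table(factor(cat, levels = ALL_CATEGORIES))
  n_fall <- sum(cat == "fall")
  list(n_subjects = nrow(ds$subjects),
       n_trials = nrow(ds$trials),
       n_adl = nrow(ds$trials) - n_fall,
       n_fall = n_fall,
       per_category = stats::setNames(as.integer(per), names(per)))
}

#' Write a dataset as a CSV manifest directory
#'
#' Layout: `subjects.csv`, `activities.csv`, `trials.csv` and one
#' `signals/<trial_id>.csv` per trial with columns
#' `time_s, ax_g, ay_g, az_g` (comma-separated, dot decimal, header row).
#'
#' @param ds An `fds_dataset`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  wr <- function(df, f)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
  wr(ds$subjects, "subjects.csv")
  wr(ds$activities, "activities.csv")
  wr(ds$trials, "trials.csv")
  for (i in seq_len(nrow(ds$trials))) {
    id <- ds$trials$trial_id[i]
    sig <- ds$signals[[id]]
    time_s <- (seq_len(nrow(sig)) - 1) / ds$trials$sampling_rate[i]
    out <- data.frame(time_s = time_s, ax_g = sig[, 1], ay_g = sig[, 2],
                      az_g = sig[, 3])
    utils::write.csv(format(out, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     file.path(dir, "signals", paste0(id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a dataset from a CSV manifest directory
#'
#' Inverse of [write_dataset()]. The time column of each signal CSV must be
#' strictly increasing; when a sampling rate is declared in `trials.csv` the
#' median time step must agree with it within 1%.
#'
#' @param dir Manifest directory.
#' @param name Dataset name (defaults to the directory basename).
#' @param validate Run [validate_dataset()] on the result.
#' @return An `fds_dataset`.
#' @export
read_dataset <- function(dir, name = basename(normalizePath(dir)),
                         validate = TRUE) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("manifest file missing: %s", p))
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  subjects <- rd("subjects.csv")
  activities <- rd("activities.csv")
  trials <- rd("trials.csv")
  trials$trial_id <- as.character(trials$trial_id)
  signals <- vector("list", nrow(trials))
  names(signals) <- trials$trial_id
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    p <- file.path(dir, "signals", paste0(id, ".csv"))
    if (!file.exists(p))
      stop(sprintf("trial %s: signal file missing (%s)", id, p))
    sig <- utils::read.csv(p)
    need <- c("time_s", "ax_g", "ay_g", "az_g")
    if (!all(need %in% names(sig)))
      stop(sprintf("trial %s: signal CSV must have columns %s", id,
                   paste(need, collapse = ",")))
    if (any(diff(sig$time_s) <= 0))
      stop(sprintf("trial %s: non-monotonic time column", id))
    if (!all(is.finite(as.matrix(sig[, c("ax_g", "ay_g", "az_g")]))))
      stop(sprintf("trial %s: non-finite acceleration value", id))
    rate <- trials$sampling_rate[i]
    if (is.finite(rate) && nrow(sig) > 1) {
      emp <- 1 / stats::median(diff(sig$time_s))
      if (abs(emp - rate) > 0.01 * rate)
        stop(sprintf(
          "trial %s: time column implies %.2f Hz but %.2f Hz declared",
          id, emp, rate))
    }
    m <- as.matrix(sig[, c("ax_g", "ay_g", "az_g")])
    dimnames(m) <- list(NULL, c("ax_g", "ay_g", "az_g"))
    signals[[id]] <- m
  }
  fds_dataset(name, subjects, activities, trials, signals,
              validate = validate)
}

#' @export
print.fds_dataset <- function(x, ...) {
  sm <- summarize_dataset(x)
  cat(sprintf("<fds_dataset '%s': %d subjects, %d trials (%d ADL / %d fall)>\n",
              x$name, sm$n_subjects, sm$n_trials, sm$n_adl, sm$n_fall))
  invisible(x)
}
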