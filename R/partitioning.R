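#' @title Train/test partition plans
#' @description A split plan assigns trial ids to train and test roles over
#'   one or more folds, produced by one of the partition protocols below.
#'   Every constructor records its parameters in `metadata` and the plan can
#'   be audited with [audit_split_plan()].
#' @name split-plans
NULL

new_split_plan <- function(strategy, folds, metadata) {
  structure(list(strategy = strategy, folds = folds, metadata = metadata),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan '%s': %d fold(s)>\n", x$strategy,
              length(x$folds)))
  invisible(x)
}

subject_of <- function(ds, ids)
  ds$trials$subject_id[match(ids, ds$trials$trial_id)]

#' Audit a split plan
#'
#' Asserts, for every fold: train/test disjointness; both sides are subsets
#' of the dataset's trials; for subject-wise strategies no subject appears
#' on both sides; for cross-validation plans the test folds tile all
#' eligible trials exactly once.
#'
#' @param plan A `split_plan`.
#' @param ds The `fds_dataset` the plan was built from.
#' @return `TRUE` invisibly; throws on any violation.
#' @export
audit_split_plan <- function(plan, ds) {
  all_ids <- ds$trials$trial_id
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    if (length(intersect(f$train, f$test)))
      stop(sprintf("fold %d: train and test overlap", i))
    if (!all(c(f$train, f$test) %in% all_ids))
      stop(sprintf("fold %d: unknown trial id", i))
    if (isTRUE(plan$metadata$subject_wise)) {
      both <- intersect(subject_of(ds, f$train), subject_of(ds, f$test))
      if (length(both))
        stop(sprintf("fold %d: subject %s on both sides", i, both[1]))
    }
  }
  if (isTRUE(plan$metadata$cv)) {
    tested <- unlist(lapply(plan$folds, `[[`, "test"))
    if (anyDuplicated(tested))
      stop("a trial appears in more than one test fold")
    eligible <- plan$metadata$eligible %||% all_ids
    if (!setequal(tested, eligible))
      stop("test folds do not cover the eligible trials")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round-robin assignment of each (subject, activity) group's shuffled
# trials across k folds, with a rotating start so fold sizes stay balanced.
fair_fold_assignment <- function(ids, groups, k, seed) {
  set.seed(seed)
  fold <- integer(length(ids))
  names(fold) <- ids
  start <- 0L
  for (g in split(ids, groups)) {
    g <- sample(g)
    fold[g] <- ((start + seq_along(g) - 1L) %% k) + 1L
    start <- (start + 1L) %% k
  }
  fold
}

#' Fair fivefold split
#'
#' The baseline protocol: trials are distributed so that samples of all
#' activity types and all experimental subjects are present in every fold
#' where group sizes permit. Trials within each (subject, activity) group
#' are dealt round-robin, in seeded random order, across the five folds; a
#' group with fewer than `k` trials simply reaches fewer test folds.
#'
#' @param ds An `fds_dataset`.
#' @param seed Integer seed.
#' @param k Number of folds (default 5).
#' @return A `split_plan` with `k` folds.
#' @export
fair_fivefold <- function(ds, seed = 1, k = 5) {
  ids <- ds$trials$trial_id
  groups <- paste(ds$trials$subject_id, ds$trials$activity_code)
  fold <- fair_fold_assignment(ids, groups, k, seed)
  folds <- lapply(seq_len(k), function(i)
    list(train = ids[fold != i], test = ids[fold == i]))
  new_split_plan("fair", folds,
                 list(cv = TRUE, subject_wise = FALSE, seed = seed, k = k))
}

#' Random subject-wise fivefold split
#'
#' Subjects (not trials) are partitioned at random into `k` folds; each
#' fold's test set contains every trial of its subjects, so no subject ever
#' contributes to both sides.
#'
#' @inheritParams fair_fivefold
#' @return A `split_plan` with `k` folds.
#' @export
subjectwise_random_fivefold <- function(ds, seed = 1, k = 5) {
  subs <- ds$subjects$subject_id
  if (length(subs) < k)
    stop(sprintf("subject-wise %d-fold needs at least %d subjects", k, k))
  set.seed(seed)
  subs <- sample(subs)
  sizes <- rep(length(subs) %/% k, k) +
    (seq_len(k) <= length(subs) %% k)
  grp <- rep(seq_len(k), sizes)
  folds <- lapply(seq_len(k), function(i) {
    test_subs <- subs[grp == i]
    test <- ds$trials$trial_id[ds$trials$subject_id %in% test_subs]
    list(train = setdiff(ds$trials$trial_id, test), test = test)
  })
  new_split_plan("random_subjectwise", folds,
                 list(cv = TRUE, subject_wise = TRUE, seed = seed, k = k))
}

round_half_up <- function(x) floor(x + 0.5)

#' Characteristic-sorted 80/20 split
#'
#' Subjects are sorted by a physical attribute (ties broken by subject id);
#' the M subjects at the chosen extreme form the training cohort, where M is
#' the integer closest to 80% of the cohort size (round half up: 38 -> 30,
#' 17 -> 14). The remaining subjects' trials form the test set.
#'
#' @param ds An `fds_dataset`.
#' @param attribute One of `"weight"`, `"height"`, `"bmi"`, `"age"`.
#' @param train_side `"highest"` or `"lowest"`: which extreme trains.
#' @param train_fraction Training share of subjects (default 0.8).
#' @return A single-fold `split_plan`.
#' @export
characteristic_split <- function(ds,
                                 attribute = c("weight", "height", "bmi",
                                               "age"),
                                 train_side = c("highest", "lowest"),
                                 train_fraction = 0.8) {
  attribute <- match.arg(attribute)
  train_side <- match.arg(train_side)
  col <- switch(attribute, weight = "weight_kg", height = "height_cm",
                bmi = "bmi", age = "age")
  s <- ds$subjects
  ord <- order(s[[col]], s$subject_id)
  n <- nrow(s)
  m <- round_half_up(train_fraction * n)
  if (m <= 0 || m >= n)
    stop(sprintf("characteristic_split: training share of %d from %d subjects is degenerate",
                 m, n))
  sorted <- s$subject_id[ord]
  train_subs <- if (train_side == "lowest") sorted[seq_len(m)]
                else sorted[(n - m + 1):n]
  test <- ds$trials$trial_id[!(ds$trials$subject_id %in% train_subs)]
  train <- setdiff(ds$trials$trial_id, test)
  new_split_plan(
    sprintf("%s_%s", attribute, train_side),
    list(list(train = train, test = test)),
    list(cv = FALSE, subject_wise = TRUE, attribute = attribute,
         train_side = train_side, m = m, n_subjects = n))
}

#' Gender split
#'
#' Training uses every trial of one sex, testing every trial of the other;
#' the 80/20 rule is deliberately not kept.
#'
#' @param ds An `fds_dataset`.
#' @param train_sex `"female"` or `"male"`.
#' @return A single-fold `split_plan`.
#' @export
gender_split <- function(ds, train_sex = c("male", "female")) {
  train_sex <- match.arg(train_sex)
  s <- ds$subjects
  if (!all(c("female", "male") %in% s$sex))
    stop("gender_split: both sexes must be present in the cohort")
  train_subs <- s$subject_id[s$sex == train_sex]
  train <- ds$trials$trial_id[ds$trials$subject_id %in% train_subs]
  test <- setdiff(ds$trials$trial_id, train)
  new_split_plan(sprintf("gender_train_%s", train_sex),
                 list(list(train = train, test = test)),
                 list(cv = FALSE, subject_wise = TRUE,
                      train_sex = train_sex))
}

#' Age-threshold split
#'
#' Subjects strictly younger than the threshold form one side and subjects
#' at or above the threshold the other ("older" includes the boundary).
#' A test side without fall trials is legitimate: downstream sensitivity is
#' then the "n.c." sentinel, not an error.
#'
#' @param ds An `fds_dataset`.
#' @param threshold Age threshold in years (default 50).
#' @param train_side `"younger"` or `"older"`: which side trains.
#' @return A single-fold `split_plan`.
#' @export
age_threshold_split <- function(ds, threshold = 50,
                                train_side = c("younger", "older")) {
  train_side <- match.arg(train_side)
  s <- ds$subjects
  younger <- s$subject_id[s$age < threshold]
  older <- s$subject_id[s$age >= threshold]
  if (!length(younger) || !length(older))
    stop(sprintf("age_threshold_split: no subjects on one side of %d years",
                 threshold))
  train_subs <- if (train_side == "younger") younger else older
  train <- ds$trials$trial_id[ds$trials$subject_id %in% train_subs]
  test <- setdiff(ds$trials$trial_id, train)
  new_split_plan(sprintf("age_%d_train_%s", threshold, train_side),
                 list(list(train = train, test = test)),
                 list(cv = FALSE, subject_wise = TRUE,
                      threshold = threshold, train_side = train_side,
                      boundary = "older side includes the threshold age"))
}

#' Activity-category holdout split
#'
#' All ADL trials of the held-out categories are excluded from training and
#' used exclusively for testing, so test specificity is measured over the
#' held-out categories alone. Fall trials are distributed between the two
#' sides with the fair round-robin machinery (per-subject fall groups over
#' `k` folds), so both sides contain falls from all subjects and
#' sensitivity stays computable on every fold.
#'
#' @param ds An `fds_dataset`.
#' @param test_categories Character vector of ADL categories (subset of
#'   basic, standard, sporting, near_fall) to hold out for testing.
#' @param seed Integer seed for the fall assignment.
#' @param k Number of folds for the fall distribution (default 5).
#' @param fair_subjects Keep the per-subject fair fall distribution
#'   (default); `FALSE` pools falls and deals them round-robin ignoring
#'   subjects.
#' @return A `split_plan` with `k` folds.
#' @export
category_holdout <- function(ds, test_categories, seed = 1, k = 5,
                             fair_subjects = TRUE) {
  if (!length(test_categories))
    stop("category_holdout: test_categories must be non-empty")
  if (!all(test_categories %in% ADL_CATEGORIES))
    stop("category_holdout: test_categories must be ADL sub-categories")
  cat <- ds$activities$category[match(ds$trials$activity_code,
                                      ds$activities$code)]
  present <- unique(cat[cat != "fall"])
  if (!all(test_categories %in% present))
    stop("category_holdout: a requested category has no trials")
  if (all(present %in% test_categories))
    stop("category_holdout: holding out every ADL category leaves no ADLs to train on")

  adl_test <- ds$trials$trial_id[cat %in% test_categories]
  adl_train <- ds$trials$trial_id[cat != "fall" &
                                    !(cat %in% test_categories)]
  fall_ids <- ds$trials$trial_id[cat == "fall"]
  fall_groups <- if (fair_subjects) subject_of(ds, fall_ids)
                 else rep("all", length(fall_ids))
  fold <- fair_fold_assignment(fall_ids, fall_groups, k, seed)
  folds <- lapply(seq_len(k), function(i)
    list(train = c(adl_train, fall_ids[fold != i]),
         test = c(adl_test, fall_ids[fold == i])))
  new_split_plan(
    sprintf("holdout_%s", paste(test_categories, collapse = "+")),
    folds,
    list(cv = FALSE, subject_wise = FALSE,
         test_categories = test_categories, seed = seed, k = k,
         fair_subjects = fair_subjects,
         note = "fall trials dealt fair-style across folds"))
}

#' Serialise a split plan to CSV
#'
#' Writes one `(fold, role, trial_id)` row per assignment plus a plain-text
#' metadata sidecar, enabling exact re-runs.
#'
#' @param plan A `split_plan`.
#' @param path CSV path; metadata goes to `<path>.meta.txt`.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  rows <- do.call(rbind, lapply(seq_along(plan$folds), function(i) {
    f <- plan$folds[[i]]
    rbind(data.frame(fold = i, role = "train", trial_id = f$train),
          data.frame(fold = i, role = "test", trial_id = f$test))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  meta <- c(sprintf("strategy: %s", plan$strategy),
            sprintf("%s: %s", names(plan$metadata),
                    vapply(plan$metadata, function(x)
                      paste(format(x), collapse = ","), "")))
  writeLines(meta, paste0(path, ".meta.txt"))
  invisible(path)
}
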