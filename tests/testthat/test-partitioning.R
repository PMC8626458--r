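# Small, cheap datasets for partition-protocol properties.
part_ds <- function(n_subjects, seed = 1, trials_per = 1)
  generate_dataset(generator_config(
    n_subjects = n_subjects, seed = seed,
    trials_per_subject_per_category = trials_per,
    trial_duration = 2, sampling_rate = 20))

test_that("every protocol passes the audit on cohorts of 5 to 50 subjects", {
  for (n in c(5, 8, 17, 38, 50)) {
    ds <- part_ds(n, seed = n)
    plans <- list(
      fair_fivefold(ds, seed = 1),
      subjectwise_random_fivefold(ds, seed = 1),
      characteristic_split(ds, "weight", "highest"),
      characteristic_split(ds, "bmi", "lowest"),
      gender_split(ds, "male"),
      category_holdout(ds, "sporting", seed = 1))
    for (p in plans) expect_true(audit_split_plan(p, ds))
  }
})

test_that("the 80% training cohort is the integer closest to 0.8 n", {
  expect_equal(characteristic_split(part_ds(38), "weight",
                                    "highest")$metadata$m, 30)
  expect_equal(characteristic_split(part_ds(17), "weight",
                                    "lowest")$metadata$m, 14)
  expect_equal(characteristic_split(part_ds(5), "age",
                                    "highest")$metadata$m, 4)
})

test_that("fair folds are balanced and tile the dataset", {
  ds <- default_synthetic(seed = 1)  # 10 subjects x 2 x 5 = 100 trials
  plan <- fair_fivefold(ds, seed = 3)
  sizes <- vapply(plan$folds, function(f) length(f$test), 0L)
  expect_equal(sizes, rep(20L, 5))
  tested <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_setequal(tested, ds$trials$trial_id)
  expect_equal(anyDuplicated(tested), 0L)
  # every subject appears in every training side
  for (f in plan$folds)
    expect_setequal(unique(ds$trials$subject_id[
      ds$trials$trial_id %in% f$train]), ds$subjects$subject_id)
})

test_that("a 3-trial group reaches exactly 3 distinct test folds", {
  ds <- part_ds(3, seed = 2, trials_per = 6)  # 3 trials per activity code
  plan <- fair_fivefold(ds, seed = 1)
  grp <- ds$trials$trial_id[ds$trials$subject_id == "S001" &
                              ds$trials$activity_code == "standing"]
  expect_equal(length(grp), 3)
  folds_hit <- vapply(grp, function(id)
    which(vapply(plan$folds, function(f) id %in% f$test, TRUE)), 0L)
  expect_equal(length(unique(folds_hit)), 3)
})

test_that("subject-wise folds partition subjects, not trials", {
  ds <- part_ds(38, seed = 4)
  plan <- subjectwise_random_fivefold(ds, seed = 9)
  counts <- vapply(plan$folds, function(f)
    length(unique(ds$trials$subject_id[ds$trials$trial_id %in% f$test])),
    0L)
  expect_true(all(counts %in% c(7L, 8L)))
  expect_equal(sum(counts), 38L)
  for (f in plan$folds) {
    test_subs <- unique(ds$trials$subject_id[ds$trials$trial_id %in%
                                               f$test])
    # all trials of a test subject are in this fold's test side
    expect_setequal(f$test,
                    ds$trials$trial_id[ds$trials$subject_id %in%
                                         test_subs])
  }
  expect_error(subjectwise_random_fivefold(part_ds(4), 1),
               "at least 5 subjects")
})

test_that("characteristic splits are sorted and complementary", {
  ds <- part_ds(17, seed = 5)
  hi <- characteristic_split(ds, "weight", "highest")
  lo <- characteristic_split(ds, "weight", "lowest")
  w <- setNames(ds$subjects$weight_kg, ds$subjects$subject_id)
  train_w <- w[unique(ds$trials$subject_id[ds$trials$trial_id %in%
                                             hi$folds[[1]]$train])]
  test_w <- w[unique(ds$trials$subject_id[ds$trials$trial_id %in%
                                            hi$folds[[1]]$test])]
  expect_gte(min(train_w), max(test_w))
  # inverted side tests the opposite extreme: the two test cohorts are
  # disjoint and each complements the other direction's training cohort
  expect_length(intersect(hi$folds[[1]]$test, lo$folds[[1]]$test), 0)
  expect_setequal(lo$folds[[1]]$test,
                  setdiff(ds$trials$trial_id, lo$folds[[1]]$train))
  lo_test_w <- w[unique(ds$trials$subject_id[ds$trials$trial_id %in%
                                               lo$folds[[1]]$test])]
  expect_gte(min(lo_test_w), max(test_w))  # lo tests the heavy extreme
  expect_error(characteristic_split(part_ds(1), "weight"), "degenerate")
})

test_that("gender split swaps sides exactly and needs both sexes", {
  ds <- part_ds(10, seed = 6)
  m <- gender_split(ds, "male")
  f <- gender_split(ds, "female")
  expect_setequal(m$folds[[1]]$train, f$folds[[1]]$test)
  expect_setequal(m$folds[[1]]$test, f$folds[[1]]$train)
  expect_setequal(c(m$folds[[1]]$train, m$folds[[1]]$test),
                  ds$trials$trial_id)
  ds_male <- generate_dataset(generator_config(
    n_subjects = 5, seed = 1, female_fraction = 0,
    trial_duration = 2, sampling_rate = 20,
    trials_per_subject_per_category = 1))
  expect_error(gender_split(ds_male, "male"), "both sexes")
})

test_that("age threshold puts the boundary age on the older side", {
  ds <- part_ds(20, seed = 7)
  plan <- age_threshold_split(ds, threshold = 50, train_side = "younger")
  ages <- setNames(ds$subjects$age, ds$subjects$subject_id)
  test_ages <- ages[unique(ds$trials$subject_id[
    ds$trials$trial_id %in% plan$folds[[1]]$test])]
  expect_true(all(test_ages >= 50))
  expect_error(age_threshold_split(ds, threshold = 5), "one side")
})

test_that("category holdout trains without the held-out ADLs", {
  ds <- default_synthetic(seed = 1)
  plan <- category_holdout(ds, "sporting", seed = 2)
  cat <- ds$activities$category[match(ds$trials$activity_code,
                                      ds$activities$code)]
  sporting <- ds$trials$trial_id[cat == "sporting"]
  fall_ids <- ds$trials$trial_id[cat == "fall"]
  for (f in plan$folds) {
    expect_length(intersect(f$train, sporting), 0)
    expect_setequal(intersect(f$test, sporting), sporting)
    # each fall trial on exactly one side
    expect_setequal(c(intersect(f$train, fall_ids),
                      intersect(f$test, fall_ids)), fall_ids)
  }
  expect_error(category_holdout(ds, c("basic", "standard", "sporting",
                                      "near_fall")), "every ADL")
  expect_error(category_holdout(ds, "fall"), "sub-categories")
})

test_that("plans are deterministic and serialisable", {
  ds <- part_ds(8, seed = 8)
  p1 <- fair_fivefold(ds, seed = 42)
  p2 <- fair_fivefold(ds, seed = 42)
  expect_identical(p1$folds, p2$folds)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "plan.csv")
  write_split_plan(p1, path)
  rows <- utils::read.csv(path)
  expect_setequal(rows$trial_id[rows$fold == 1 & rows$role == "test"],
                  p1$folds[[1]]$test)
})
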