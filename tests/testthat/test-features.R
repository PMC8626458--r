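test_that("SMV is the Euclidean norm of the acceleration triple", {
  expect_equal(smv(1, 0, 0), 1.0)
  expect_equal(smv(0.6, 0.8, 0), 1.0)
  expect_equal(smv(1, 2, 2), 3.0)
  m <- cbind(c(1, 0.6), c(0, 0.8), c(0, 0))
  expect_equal(smv(m), c(1, 1))
})

make_peaked_trial <- function(n, peak_at, rate) {
  m <- cbind(rep(0, n), rep(0, n), rep(1, n))
  m[peak_at, 3] <- 5
  as_trial(m, rate)
}

test_that("the observation window spans 1 s either side of the peak", {
  w <- extract_window(make_peaked_trial(4000, peak_at = 1001, rate = 200))
  expect_equal(w$peak_index, 1001)
  expect_equal(w$indices, 801:1201)
  expect_equal(nrow(w$samples), 401)
})

test_that("edge peaks shift the window instead of truncating it", {
  w <- extract_window(make_peaked_trial(300, peak_at = 6, rate = 20))
  expect_equal(w$indices, 1:41)
  expect_true(w$peak_index %in% w$indices)
  w2 <- extract_window(make_peaked_trial(300, peak_at = 298, rate = 20))
  expect_equal(w2$indices, 260:300)
})

test_that("trials shorter than 2 s are used whole", {
  w <- extract_window(make_peaked_trial(98, peak_at = 40, rate = 50))
  expect_equal(w$indices, 1:98)
})

test_that("ties in the SMV maximum break to the earliest index", {
  m <- cbind(rep(0, 100), rep(0, 100), rep(1, 100))
  m[c(30, 60), 3] <- 4
  w <- extract_window(as_trial(m, 10))
  expect_equal(w$peak_index, 30)
})

test_that("a constant gravity window has the closed-form feature vector", {
  m <- cbind(rep(0, 50), rep(0, 50), rep(1, 50))
  colnames(m) <- c("ax_g", "ay_g", "az_g")
  f <- feature_vector(list(samples = m, sampling_rate = 25))
  expect_equal(unname(f[c("mean_smv", "max_smv", "min_smv", "sma")]),
               c(1, 1, 1, 1))
  expect_equal(unname(f[c("std_smv", "mad_smv", "rot_angle", "horiz_mag",
                          "max_pair_diff", "skew_smv", "dft_energy",
                          "mean_autocorr")]),
               rep(0, 8))
})

test_that("max pairwise vector difference matches a brute-force oracle", {
  for (seed in 1:50) {
    w <- random_window(seed)
    A <- w$samples
    best <- 0
    for (i in seq_len(nrow(A) - 1))
      for (j in (i + 1):nrow(A))
        best <- max(best, sqrt(sum((A[i, ] - A[j, ])^2)))
    expect_equal(unname(feature_vector(w)["max_pair_diff"]), best,
                 tolerance = 1e-9)
  }
})

test_that("spectral energy satisfies Parseval with the DC term removed", {
  for (seed in 1:50) {
    w <- random_window(seed)
    A <- w$samples
    td <- sum(apply(A, 2, function(x) sum((x - mean(x))^2)))
    expect_equal(unname(feature_vector(w)["dft_energy"]), td,
                 tolerance = 1e-9)
  }
})

test_that("feature bounds hold on arbitrary windows", {
  for (seed in 1:25) {
    f <- feature_vector(random_window(seed))
    expect_true(all(is.finite(f)))
    expect_lte(f[["min_smv"]], f[["mean_smv"]])
    expect_lte(f[["mean_smv"]], f[["max_smv"]])
    expect_gte(f[["std_smv"]], 0)
    expect_gte(f[["mad_smv"]], 0)
    expect_gte(f[["rot_angle"]], 0)
    expect_lte(f[["rot_angle"]], pi)
    expect_gte(f[["dft_energy"]], 0)
  }
})

test_that("a rigid rotation changes only the axis-dependent features", {
  invariant <- c("mean_smv", "std_smv", "mad_smv", "rot_angle",
                 "max_pair_diff", "max_smv", "min_smv", "skew_smv",
                 "dft_energy", "mean_autocorr")
  axis_dep <- c("horiz_mag", "sma")
  changed <- c(horiz_mag = FALSE, sma = FALSE)
  for (seed in 1:10) {
    w <- random_window(seed)
    R <- random_rotation(seed + 100)
    wr <- list(samples = w$samples %*% t(R),
               sampling_rate = w$sampling_rate)
    f0 <- feature_vector(w)
    f1 <- feature_vector(wr)
    expect_equal(f0[invariant], f1[invariant], tolerance = 1e-9)
    changed <- changed | abs(f0[axis_dep] - f1[axis_dep]) > 1e-6
  }
  expect_true(all(changed))
})

test_that("uniform scaling acts linearly, quadratically or not at all", {
  c_ <- 2.5
  linear <- c("mean_smv", "std_smv", "mad_smv", "horiz_mag",
              "max_pair_diff", "max_smv", "min_smv", "sma")
  quadratic <- "dft_energy"
  invariant <- c("rot_angle", "skew_smv", "mean_autocorr")
  for (seed in 1:10) {
    w <- random_window(seed)
    ws <- list(samples = w$samples * c_, sampling_rate = w$sampling_rate)
    f0 <- feature_vector(w)
    f1 <- feature_vector(ws)
    expect_equal(f1[linear], c_ * f0[linear], tolerance = 1e-9)
    expect_equal(f1[quadratic], c_^2 * f0[quadratic], tolerance = 1e-9)
    expect_equal(f1[invariant], f0[invariant], tolerance = 1e-9)
  }
})

test_that("fall windows sit below basic windows in the valley feature", {
  ds <- default_synthetic(seed = 4)
  ft <- featurize_dataset(ds)
  fall <- ft[ft$category == "fall", ]
  basic <- ft[ft$category == "basic", ]
  expect_lt(mean(fall$min_smv), mean(basic$min_smv))
  expect_gt(mean(fall$max_smv), mean(basic$max_smv))
})

test_that("z-scoring centres and scales with the population convention", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  st <- fit_standardization(x)
  z <- apply_standardization(x, st)
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)

  set.seed(9)
  m <- matrix(rnorm(60), 20)
  st <- fit_standardization(m)
  zm <- apply_standardization(m, st)
  expect_equal(colMeans(zm), rep(0, 3), tolerance = 1e-9)
  expect_equal(sqrt(colMeans(zm^2)), rep(1, 3), tolerance = 1e-9)
})

test_that("zero-variance columns are flagged and map to zero", {
  m <- cbind(a = rep(4, 5), b = 1:5)
  expect_warning(st <- fit_standardization(m), "zero-variance")
  z <- apply_standardization(m, st)
  expect_equal(z[, "a"], rep(0, 5))
})
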