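test_that("differential entropy matches its Gaussian closed form", {
  # a window whose sample variance is exactly 1/(2*pi*e) has DE = 0
  x <- withr::with_seed(1, rnorm(200))
  x <- (x - mean(x)) / sd(x) * sqrt(1 / (2 * pi * exp(1)))
  expect_equal(differential_entropy(x), 0, tolerance = 1e-12)

  # scaling by s adds log(s)
  expect_equal(differential_entropy(2 * x) - differential_entropy(x),
               log(2), tolerance = 1e-12)

  # degenerate window hits the variance floor instead of -Inf
  expect_true(is.finite(differential_entropy(rep(1, 100))))
})

test_that("mean DE of simulated Gaussian windows tracks 0.5*log(2*pi*e*s^2)", {
  for (s in c(0.5, 1, 2)) {
    de <- withr::with_seed(42, replicate(100, differential_entropy(rnorm(200, sd = s))))
    expect_lt(abs(mean(de) - 0.5 * log(2 * pi * exp(1) * s^2)), 0.1)
  }
})

test_that("extract_de_features produces the windows x channels x bands tensor", {
  fs <- 200
  sig <- withr::with_seed(3, matrix(rnorm(62 * fs * 10), 62))
  ds <- extract_de_features(sig, fs, sprintf("C%02d", 1:62))
  expect_equal(dim(ds$features), c(10, 62, 5))
  expect_identical(ds$band_names, de_bands()$name)
  expect_true(all(is.finite(ds$features)))
})

test_that("recordings at other rates are resampled to 200 Hz", {
  fs <- 400
  sig <- matrix(sin(2 * pi * 10 * seq_len(fs * 4) / fs), 1)
  ds <- extract_de_features(sig, fs, "CZ",
                            bands = data.frame(name = "alpha",
                                               low_hz = 8, high_hz = 13))
  expect_equal(dim(ds$features), c(4, 1, 1))
  # the 10 Hz tone lives in the alpha band: DE must reflect its power
  broadband <- extract_de_features(sig, fs, "CZ",
                                   bands = data.frame(name = "gamma",
                                                      low_hz = 31,
                                                      high_hz = 50))
  expect_gt(mean(ds$features), mean(broadband$features))
})

test_that("a window longer than the recording is an error", {
  expect_error(extract_de_features(matrix(rnorm(100), 1), 200, "CZ"),
               "longer than")
})

test_that("hemisphere split drops the midline and preserves samples", {
  m <- default_montage()
  chs <- c(m$left, m$right, m$midline)
  ds <- withr::with_seed(4, feature_dataset(
    array(rnorm(6 * 62 * 2), c(6, 62, 2)), rep(1:3, 2), rep("S01", 6),
    rep("ses1", 6), sample(chs), c("beta", "gamma")))
  halves <- split_hemispheres(ds, m)
  expect_identical(halves$left$channel_names, m$left)
  expect_identical(halves$right$channel_names, m$right)
  expect_identical(halves$left$labels, ds$labels)
  expect_length(intersect(halves$left$channel_names,
                          halves$right$channel_names), 0)
  expect_length(intersect(c(halves$left$channel_names,
                            halves$right$channel_names), m$midline), 0)
  # 62 = 27 + 27 + 8
  expect_equal(dim(halves$left$features)[2] + dim(halves$right$features)[2] +
                 length(m$midline), 62)
})

test_that("hemisphere split composes with sub-montage selection", {
  toy <- montage_config(left = c("L1", "L2"), right = c("R1", "R2"))
  ds <- random_dataset(ch = 4)
  ds$channel_names <- c("L1", "L2", "R1", "R2")
  halves <- split_hemispheres(ds, toy)
  expect_equal(dim(halves$left$features)[2], 2)
  # splitting the left output with a sub-montage equals direct selection
  sub <- montage_config(left = "L2", right = "L1")
  again <- split_hemispheres(halves$left, sub)
  expect_equal(again$left$features[, 1, ], ds$features[, 2, ])

  expect_error(split_hemispheres(ds, montage_config("L1", "R9")),
               "absent.*R9")
})

test_that("flatten_bands is channel-major, band-minor", {
  ds <- random_dataset(n = 5, ch = 3, bands = 2)
  mat <- flatten_bands(ds)
  expect_equal(dim(mat), c(5, 6))
  expect_identical(colnames(mat)[1:2], c("CH1.alpha", "CH1.beta"))
  expect_equal(mat[, 3], ds$features[, 2, 1])

  sub <- flatten_bands(ds, "beta")
  expect_equal(dim(sub), c(5, 3))
  expect_equal(sub[, 2], ds$features[, 2, 2])

  expect_error(flatten_bands(ds, "theta"), "unknown band")

  # 27 channels x 5 bands -> the canonical 135-dimensional vector
  big <- generate_population(synthetic_spec(
    n_subjects = 2, n_sessions = 1, samples_per_class_per_session = 2,
    seed = 1))$left
  expect_equal(ncol(flatten_bands(big)), 135)
  expect_equal(ncol(flatten_bands(big, c("beta", "gamma"))), 54)
})

test_that("per-block normalization is blockwise, idempotent and equivariant", {
  ds <- random_dataset(n = 40, ch = 3, bands = 2, seed = 9)
  # give the two subjects different offsets
  ds$features[ds$subject_id == "S02", , ] <-
    ds$features[ds$subject_id == "S02", , ] + 5
  nm <- normalize_per_block(ds, scope = "subject")
  for (s in c("S01", "S02")) {
    block <- matrix(nm$features[nm$subject_id == s, , ], ncol = 6)
    expect_lt(max(abs(colMeans(block))), 1e-12)
    expect_lt(max(abs(apply(block, 2, sd) - 1)), 1e-9)
  }
  # idempotence
  again <- normalize_per_block(nm, scope = "subject")
  expect_lt(max(abs(again$features - nm$features)), 1e-9)

  # permutation equivariance
  perm <- withr::with_seed(11, sample(40))
  nm_perm <- normalize_per_block(subset_samples(ds, perm), scope = "subject")
  expect_equal(nm_perm$features[order(perm), , ], nm$features)
})

test_that("normalization never mixes statistics across blocks", {
  ds <- random_dataset(n = 40, ch = 3, bands = 2, seed = 10)
  base <- normalize_per_block(ds, scope = "subject")
  pert <- ds
  pert$features[pert$subject_id == "S02", , ] <-
    pert$features[pert$subject_id == "S02", , ] * 3 + 1
  pert_norm <- normalize_per_block(pert, scope = "subject")
  s1 <- ds$subject_id == "S01"
  expect_identical(pert_norm$features[s1, , ], base$features[s1, , ])
})

test_that("single-sample blocks are rejected", {
  ds <- random_dataset(n = 5, ch = 2, bands = 1)
  ds$subject_id <- c("A", "A", "A", "A", "B")
  expect_error(normalize_per_block(ds, scope = "subject"), "single sample")
})
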