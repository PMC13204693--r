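test_that("perplexity matches softmax arithmetic and its identities", {
  # uniform logits: exactly log(C + 1)
  expect_equal(perplexity(c(0, 0, 0, 0), n_classes = 3), log(4),
               tolerance = 1e-12)
  # discriminator certain of the target class: near-zero perplexity
  expect_equal(perplexity(c(0, 0, 0, 10)), oracle_perplexity(c(0, 0, 0, 10)),
               tolerance = 1e-12)
  expect_lt(perplexity(c(0, 0, 0, 10)), 1.4e-4)
  # shift invariance
  z <- withr::with_seed(1, rnorm(5))
  expect_equal(perplexity(z), perplexity(z + 100), tolerance = 1e-9)
  expect_equal(perplexity(z), perplexity(z - 300), tolerance = 1e-9)
  # vectorized over rows, against the independent oracle
  zm <- withr::with_seed(2, matrix(rnorm(12), 3))
  expect_equal(perplexity(zm), apply(zm, 1, oracle_perplexity),
               tolerance = 1e-12)
  expect_error(perplexity(c(0, 0, 0), n_classes = 3), "C \\+ 1")
  expect_error(perplexity(c(0, NA, 0, 0)), "finite")
})

test_that("perplexity is monotone decreasing in the target logit", {
  others <- c(1, -0.5, 0.3)
  p <- vapply(seq(-3, 3, 0.5),
              function(zt) perplexity(c(others, zt)), numeric(1))
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0))
})

test_that("hemisphere weights normalize and guard degeneracy", {
  w <- hemisphere_weights(1, 3)
  expect_equal(c(w$left, w$right), c(0.25, 0.75))
  w <- hemisphere_weights(2, 2)
  expect_equal(c(w$left, w$right), c(0.5, 0.5))
  w <- hemisphere_weights(0, 0)
  expect_equal(c(w$left, w$right), c(0.5, 0.5))
  expect_error(hemisphere_weights(-1, 1), "nonnegative")

  pl <- withr::with_seed(3, runif(100, 0, 5))
  pr <- withr::with_seed(4, runif(100, 0, 5))
  pl[7] <- pr[7] <- 0  # exercise the guard inside a vector
  w <- hemisphere_weights(pl, pr)
  expect_lt(max(abs(w$left + w$right - 1)), 1e-12)
  expect_true(all(w$left >= 0 & w$left <= 1))
})

test_that("fusion is the stated convex combination", {
  f <- fuse_predictions(0.6, c(0.5, 0.3, 0.2), 0.4, c(0.1, 0.8, 0.1))
  expect_equal(as.numeric(f$probs), c(0.34, 0.50, 0.16))
  expect_equal(f$label, 2L)

  pl <- c(0.2, 0.5, 0.3)
  f <- fuse_predictions(1, pl, 0, c(1, 0, 0))
  expect_equal(as.numeric(f$probs), pl)

  # identical branches: fused equals either branch for any weights
  f <- fuse_predictions(0.123, pl, 0.877, pl)
  expect_equal(as.numeric(f$probs), pl)

  expect_error(fuse_predictions(0.7, pl, 0.7, pl), "sum to 1")

  # probability simplex is preserved for random inputs
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- oracle_softmax(rnorm(4)); b <- oracle_softmax(rnorm(4))
      wl <- runif(1)
      f <- fuse_predictions(wl, a, 1 - wl, b)
      expect_equal(sum(f$probs), 1, tolerance = 1e-9)
      expect_true(all(f$probs >= 0))
    }
  })
})

test_that("the worked fixture reproduces its hand-computed oracle", {
  fx <- toy_worked_fixture()
  expect_silent(validate_feature_dataset(fx$left))
  expect_silent(validate_feature_dataset(fx$right))
  expect_identical(fx$left$labels, fx$right$labels)

  # independent recomputation, plain arithmetic only
  p_l <- apply(fx$disc_left, 1, oracle_perplexity)
  p_r <- apply(fx$disc_right, 1, oracle_perplexity)
  w_l <- p_l / (p_l + p_r)
  fused <- fx$probs_left * w_l + fx$probs_right * (1 - w_l)
  expect_equal(fx$expected$perplexity_left, p_l, tolerance = 1e-12)
  expect_equal(fx$expected$perplexity_right, p_r, tolerance = 1e-12)
  expect_equal(fx$expected$weight_left, w_l, tolerance = 1e-12)
  expect_equal(as.matrix(fx$expected[paste0("prob.", 1:3)]), fused,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fx$expected$predicted, max.col(fused, ties.method = "first"))

  # the package path agrees with the fixture
  expect_equal(perplexity(fx$disc_left), fx$expected$perplexity_left)
  w <- hemisphere_weights(perplexity(fx$disc_left), perplexity(fx$disc_right))
  expect_equal(w$left, fx$expected$weight_left)

  # deterministic: two calls agree exactly
  expect_identical(toy_worked_fixture(), fx)
})

test_that("bihada variants honor their fusion contracts", {
  pop <- generate_population(synthetic_spec(
    n_subjects = 2, n_sessions = 1, samples_per_class_per_session = 8,
    d_channels = 4, n_bands = 2, seed = 3))
  is <- which(pop$left$subject_id == "S01")
  it <- which(pop$left$subject_id == "S02")
  args <- list(subset_samples(pop$left, is), subset_samples(pop$right, is),
               subset_samples(pop$left, it), subset_samples(pop$right, it))
  tl <- args[[3]]; tr <- args[[4]]

  fit <- do.call(bihada, c(args, list(epochs = 4, batch_size = 8, seed = 2)))
  fr <- predict(fit, tl, tr)
  expect_s3_class(fr, "fusion_result")
  expect_lt(max(abs(fr$weight_left + fr$weight_right - 1)), 1e-12)
  probs <- as.matrix(fr[paste0("prob.", 1:3)])
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-9)
  expect_identical(fr$predicted, max.col(probs, ties.method = "first"))

  # no_perplexity: fixed equal weights whatever the discriminators say
  fit_np <- do.call(bihada, c(args, list(epochs = 4, batch_size = 8, seed = 2,
                                         variant = "no_perplexity")))
  fr_np <- predict(fit_np, tl, tr)
  expect_true(all(fr_np$weight_left == 0.5 & fr_np$weight_right == 0.5))

  # left_only: predictions equal the left branch classifier alone
  fit_l <- do.call(bihada, c(args, list(epochs = 4, batch_size = 8, seed = 2,
                                        variant = "left_only")))
  fr_l <- predict(fit_l, tl, tr)
  solo <- predict(fit_l$left, flatten_bands(tl))
  expect_identical(fr_l$predicted, solo)
  expect_true(all(fr_l$weight_left == 1))

  # binary_discriminator: two-output discriminators in both branches
  fit_bd <- do.call(bihada, c(args, list(epochs = 2, batch_size = 8, seed = 2,
                                         variant = "binary_discriminator")))
  expect_equal(fit_bd$left$model$n_domain_out, 2)

  # shared_extractor: one parameter set behind both hemispheres
  fit_sc <- do.call(bihada, c(args, list(epochs = 2, batch_size = 8, seed = 2,
                                         variant = "shared_extractor")))
  expect_identical(fit_sc$left$model$params$f1, fit_sc$right$model$params$f1)
  expect_identical(fit_sc$left$model$params$bn2, fit_sc$right$model$params$bn2)
  # heads remain hemisphere-specific
  expect_false(identical(fit_sc$left$model$params$y2,
                         fit_sc$right$model$params$y2))
})

test_that("per-batch weighting equals per-sample on constant batches", {
  pop <- generate_population(synthetic_spec(
    n_subjects = 2, n_sessions = 1, samples_per_class_per_session = 8,
    d_channels = 4, n_bands = 2, seed = 4))
  is <- which(pop$left$subject_id == "S01")
  it <- which(pop$left$subject_id == "S02")
  fit <- bihada(subset_samples(pop$left, is), subset_samples(pop$right, is),
                subset_samples(pop$left, it), subset_samples(pop$right, it),
                epochs = 3, batch_size = 8, seed = 6)
  # a batch of identical samples: batch-mean perplexity = per-sample value
  xl <- flatten_bands(subset_samples(pop$left, it))[rep(1L, 8), ]
  xr <- flatten_bands(subset_samples(pop$right, it))[rep(1L, 8), ]
  a <- predict(fit, xl, xr, weighting = "per_sample")
  b <- predict(fit, xl, xr, weighting = "per_batch", batch_size = 8)
  expect_equal(a, b)
})

test_that("left and right branches train independently by default", {
  pop <- generate_population(synthetic_spec(
    n_subjects = 2, n_sessions = 1, samples_per_class_per_session = 6,
    d_channels = 3, n_bands = 2, seed = 8))
  is <- which(pop$left$subject_id == "S01")
  it <- which(pop$left$subject_id == "S02")
  sl <- subset_samples(pop$left, is); sr <- subset_samples(pop$right, is)
  tl <- subset_samples(pop$left, it); tr <- subset_samples(pop$right, it)
  fit1 <- bihada(sl, sr, tl, tr, epochs = 3, batch_size = 8, seed = 9)
  # perturb only the right-hemisphere data
  sr2 <- sr; sr2$features <- sr2$features + 0.5
  fit2 <- bihada(sl, sr2, tl, tr, epochs = 3, batch_size = 8, seed = 9)
  expect_identical(fit1$left$model$params, fit2$left$model$params)
  expect_false(identical(fit1$right$model$params, fit2$right$model$params))
})
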