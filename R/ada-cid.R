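#' Domain-class labels for the class-informed discriminator
#'
#' Source samples carry their emotion label `y_i` in `1..C`; every target
#' sample carries the extra target-domain class `C + 1`.  With
#' `binary = TRUE` the labels collapse to the conventional two-class
#' source/target scheme (source = 1, target = 2).
#'
#' @param domain character vector of `"source"` / `"target"`.
#' @param y integer labels in `1..C` for source samples; ignored (may be
#'   `NA`) for target samples.
#' @param n_classes number of emotion classes `C`.
#' @param binary collapse to binary domain labels.
#' @return integer vector of domain-class labels.
#' @examples
#' domain_class_label("source", 2, n_classes = 3)  # 2
#' domain_class_label("target", NA, n_classes = 3) # 4
#' @export
domain_class_label <- function(domain, y = NULL, n_classes, binary = FALSE) {
  domain <- match.arg(domain, c("source", "target"), several.ok = TRUE)
  n <- length(domain)
  if (is.null(y)) y <- rep(NA_integer_, n)
  if (length(y) != n) stop("`y` must have one entry per sample")
  is_src <- domain == "source"
  if (any(is_src & is.na(y)))
    stop("source samples must provide a class label")
  if (any(is_src & (y < 1L | y > n_classes), na.rm = TRUE))
    stop("source labels must lie in 1..", n_classes)
  if (binary) return(ifelse(is_src, 1L, 2L))
  out <- ifelse(is_src, as.integer(y), n_classes + 1L)
  as.integer(out)
}

#' Classification loss (mean source cross-entropy)
#'
#' Mean negative log-probability of the true class over the source batch.
#'
#' @param log_probs matrix `[n x C]` of class log-probabilities.
#' @param y integer labels in `1..C`.
#' @return scalar loss.
#' @export
classification_loss <- function(log_probs, y) {
  if (!is.matrix(log_probs)) log_probs <- matrix(log_probs, nrow = 1L)
  n <- nrow(log_probs)
  if (n == 0L) stop("empty batch")
  if (length(y) != n) stop("labels must match the batch size")
  if (any(y < 1L | y > ncol(log_probs))) stop("label out of range")
  -mean(log_probs[cbind(seq_len(n), y)])
}

#' Discriminator loss (mean domain-class cross-entropy)
#'
#' Mean cross-entropy over the `C + 1` domain classes on a combined
#' source+target batch, with labels built by [domain_class_label()].  Source
#' samples must never carry the target-domain label.
#'
#' @param log_probs matrix `[n x (C+1)]` of domain-class log-probabilities
#'   (2 columns in the binary variant).
#' @param dci integer domain-class labels.
#' @param domain optional character vector `"source"`/`"target"`; when given,
#'   the bookkeeping invariant (no source sample labeled as target class)
#'   is enforced.
#' @return scalar loss (before the lambda weight).
#' @export
discriminator_loss <- function(log_probs, dci, domain = NULL) {
  if (!is.matrix(log_probs)) log_probs <- matrix(log_probs, nrow = 1L)
  n <- nrow(log_probs)
  if (n == 0L) stop("empty batch")
  if (length(dci) != n) stop("labels must match the batch size")
  if (any(dci < 1L | dci > ncol(log_probs))) stop("domain-class label out of range")
  if (!is.null(domain) && any(domain == "source" & dci == ncol(log_probs)))
    stop("a source sample carries the target-domain label")
  -mean(log_probs[cbind(seq_len(n), dci)])
}

#' Total branch loss
#'
#' `cls + lambda * adv`, with the `1/n_s` and `1/(n_s + n_t)` averaging
#' already inside the two terms.
#'
#' @param cls classification loss.
#' @param adv discriminator loss (unweighted).
#' @param lambda nonnegative weight balancing the two terms; values in
#'   `[0.5, 1]` are the recommended operating range.
#' @return scalar total loss.
#' @export
total_loss <- function(cls, adv, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  cls + lambda * adv
}

# shared training loop for one branch; assumes RNG already seeded.
# Draws one source batch and one target batch per step (the shorter stream is
# cycled); steps_per_epoch = ceil(max(ns, nt) / batch_size).  When
# source_only = TRUE the discriminator pass is skipped but the extractor still
# sees the mixed batch, so the run is RNG- and BN-identical to lambda = 0.
.fit_branch <- function(xs, ys, xt, n_classes, lambda, learning_rate,
                        batch_size, epochs, variant, verbose = FALSE,
                        model = NULL, external_model = FALSE) {
  ns <- nrow(xs); nt <- if (is.null(xt)) 0L else nrow(xt)
  binary <- identical(variant, "binary_discriminator")
  source_only <- identical(variant, "source_only")
  if (is.null(model))
    model <- build_branch(ncol(xs), n_classes,
                          seed = sample.int(.Machine$integer.max, 1L),
                          n_domain_out = if (binary) 2L else n_classes + 1L)
  opt <- .adam_init(model$params)
  steps <- max(1L, ceiling(max(ns, nt) / batch_size))
  trace <- data.frame(epoch = seq_len(epochs), loss_cls = NA_real_,
                      loss_adv = NA_real_, loss_total = NA_real_)
  for (ep in seq_len(epochs)) {
    src_ord <- sample.int(ns)
    tgt_ord <- if (nt > 0L) sample.int(nt) else integer()
    ep_cls <- ep_adv <- 0
    for (st in seq_len(steps)) {
      si <- src_ord[((st - 1L) * batch_size + seq_len(batch_size) - 1L) %% ns + 1L]
      bs_x <- xs[si, , drop = FALSE]; bs_y <- ys[si]
      bt_x <- if (nt > 0L) {
        ti <- tgt_ord[((st - 1L) * batch_size + seq_len(batch_size) - 1L) %% nt + 1L]
        xt[ti, , drop = FALSE]
      } else NULL
      if (source_only || nt == 0L) {
        g <- .source_only_grads(model, bs_x, bs_y, bt_x)
      } else {
        # class-informed branches reverse only the target rows' adversarial
        # gradient (target deception); the binary DANN ablation reverses the
        # whole combined batch, its classic formulation
        g <- nn_branch_grads(model, bs_x, bs_y, bt_x, lambda, binary = binary,
                             reversal = if (binary) "all" else "target_only")
      }
      if (!is.finite(g$loss_cls) || !is.finite(g$loss_adv))
        stop("non-finite loss at epoch ", ep, ", step ", st,
             " (cls = ", g$loss_cls, ", adv = ", g$loss_adv, ")")
      model$state <- g$state
      upd <- .adam_step(model$params, g$grads, opt, learning_rate)
      model$params <- upd$params
      opt <- upd$opt
      ep_cls <- ep_cls + g$loss_cls
      ep_adv <- ep_adv + g$loss_adv
    }
    trace$loss_cls[ep] <- ep_cls / steps
    trace$loss_adv[ep] <- ep_adv / steps
    trace$loss_total[ep] <- total_loss(ep_cls / steps, ep_adv / steps,
                                       if (source_only) 0 else lambda)
    if (verbose && (ep %% 10L == 0L || ep == epochs))
      message(sprintf("epoch %3d  cls %.4f  adv %.4f", ep,
                      trace$loss_cls[ep], trace$loss_adv[ep]))
  }
  list(model = model, trace = trace)
}

# classifier-only gradients; the extractor still forwards the mixed batch so
# BN statistics match a lambda = 0 adversarial run exactly
.source_only_grads <- function(model, xs, ys, xt) {
  ns <- nrow(xs); nt <- if (is.null(xt)) 0L else nrow(xt)
  x_all <- if (nt > 0L) rbind(xs, xt) else xs
  ext <- .extractor_forward(model, x_all, training = TRUE)
  p <- model$params
  hy <- .head_forward(ext$features[seq_len(ns), , drop = FALSE], p$y1, p$y2)
  logp_y <- .row_logsoftmax(hy$logits)
  loss_cls <- -mean(logp_y[cbind(seq_len(ns), ys)])
  onehot <- matrix(0, ns, model$n_classes)
  onehot[cbind(seq_len(ns), ys)] <- 1
  gy <- .head_backward((.row_softmax(hy$logits) - onehot) / ns,
                       p$y1, p$y2, hy$cache)
  dfeat <- matrix(0, ns + nt, ncol(ext$features))
  dfeat[seq_len(ns), ] <- gy$dfeat
  gf <- .extractor_backward(model, ext$cache, dfeat)
  zero <- function(l) lapply(l, function(v) v * 0)
  grads <- c(gf, list(y1 = gy$l1, y2 = gy$l2,
                      d1 = zero(p$d1), d2 = zero(p$d2)))
  list(loss_cls = loss_cls, loss_adv = 0, grads = grads, state = ext$state)
}

#' Fit a single-branch adversarial domain adaptation model
#'
#' Trains one ADA-CiD branch: an MLP feature extractor shared by an emotion
#' classifier (supervised on labeled source samples only) and a class-informed
#' domain discriminator over `C + 1` classes (the C source emotion classes
#' plus a target-domain class), connected through a gradient reversal layer.
#' Each optimizer step draws one source and one target batch, forwards the
#' concatenation through the extractor, and takes a single Adam step on all
#' parameters; target labels are never used.
#'
#' @param x source feature matrix `[n_s x d]`, or a [feature_dataset()]
#'   (flattened with [flatten_bands()]).
#' @param y integer source labels in `1..C` (taken from `x$labels` when `x`
#'   is a `feature_dataset`).
#' @param x_target unlabeled target feature matrix (labels, if any, are
#'   ignored); may be `NULL`, which degenerates to source-only training with
#'   a warning.
#' @param n_classes number of emotion classes; default `max(y)`.
#' @param lambda adversarial loss weight (default 1; the useful range is
#'   0.5-1).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param batch_size per-domain batch size (default 32).
#' @param epochs training epochs (default 200).
#' @param seed integer seed controlling initialization and batch order.
#' @param variant `"full"` (class-informed discriminator),
#'   `"binary_discriminator"` (conventional 2-class domain discriminator) or
#'   `"source_only"` (no adversarial term; baseline).
#' @param band_subset for `feature_dataset` inputs, bands to keep.
#' @param verbose print per-epoch losses.
#' @return an object of class `ada_cid`: list with `model` (the
#'   [build_branch()] parameters), `trace` (per-epoch loss data.frame),
#'   `n_classes` and `config`.
#' @seealso [predict.ada_cid()], [bihada()] for the two-hemisphere model.
#' @export
ada_cid <- function(x, y = NULL, x_target = NULL, n_classes = NULL,
                    lambda = 1, learning_rate = 0.01, batch_size = 32,
                    epochs = 200, seed = 1,
                    variant = c("full", "binary_discriminator", "source_only"),
                    band_subset = NULL, verbose = FALSE) {
  variant <- match.arg(variant)
  if (inherits(x, "feature_dataset")) {
    if (is.null(y)) y <- x$labels
    x <- flatten_bands(x, band_subset)
  }
  if (inherits(x_target, "feature_dataset"))
    x_target <- flatten_bands(x_target, band_subset)
  y <- as.integer(y)
  if (anyNA(y)) stop("source labels must be fully observed")
  n_classes <- n_classes %||% max(y)
  if (n_classes < 2L) stop("need at least two classes")
  if (any(y < 1L | y > n_classes)) stop("labels must lie in 1..n_classes")
  if (batch_size < 1L || epochs < 1L) stop("batch_size and epochs must be >= 1")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (is.null(x_target) || nrow(x_target) == 0L) {
    warning("no target samples: training degenerates to source-only")
    x_target <- NULL
  }
  fit <- withr::with_seed(seed,
    .fit_branch(x, y, x_target, n_classes, lambda, learning_rate,
                batch_size, epochs, variant, verbose))
  structure(
    list(model = fit$model, trace = fit$trace, n_classes = n_classes,
         config = list(lambda = lambda, learning_rate = learning_rate,
                       batch_size = batch_size, epochs = epochs, seed = seed,
                       variant = variant)),
    class = "ada_cid")
}

#' Predict from a fitted single-branch model
#'
#' Evaluation-mode forward pass (batch normalization uses running estimates,
#' so repeated calls are deterministic).
#'
#' @param object an [ada_cid()] fit.
#' @param newdata feature matrix or [feature_dataset()].
#' @param type `"class"` (argmax labels, lowest index wins ties), `"prob"`,
#'   `"log_prob"`, `"domain"` (discriminator log-probabilities over the
#'   `C + 1` domain classes) or `"all"`.
#' @param band_subset bands to keep for `feature_dataset` inputs.
#' @param ... unused.
#' @return depends on `type`; for `"all"`, a list with `class_log_probs` and
#'   `domain_log_probs`.
#' @export
predict.ada_cid <- function(object, newdata,
                            type = c("class", "prob", "log_prob", "domain", "all"),
                            band_subset = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_dataset"))
    newdata <- flatten_bands(newdata, band_subset)
  fwd <- branch_forward(object$model, newdata, training = FALSE)
  switch(type,
    class = max.col(fwd$class_log_probs, ties.method = "first"),
    prob = exp(fwd$class_log_probs),
    log_prob = fwd$class_log_probs,
    domain = fwd$domain_log_probs,
    all = fwd[c("class_log_probs", "domain_log_probs")])
}

#' @export
print.ada_cid <- function(x, ...) {
  cat(sprintf("ADA-CiD branch (%s): %d classes, d_in = %d\n",
              x$config$variant, x$n_classes, x$model$d_in))
  cat(sprintf("  lambda = %g, lr = %g, batch = %d, epochs = %d, seed = %d\n",
              x$config$lambda, x$config$learning_rate, x$config$batch_size,
              x$config$epochs, x$config$seed))
  tr <- utils::tail(x$trace, 1L)
  cat(sprintf("  final losses: cls %.4f, adv %.4f, total %.4f\n",
              tr$loss_cls, tr$loss_adv, tr$loss_total))
  invisible(x)
}

#' @export
summary.ada_cid <- function(object, ...) {
  print(object)
  cat("\nLoss trace (every 10th epoch):\n")
  tr <- object$trace
  print(tr[tr$epoch %% 10L == 0L | tr$epoch == 1L | tr$epoch == nrow(tr), ],
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.ada_cid <- function(object, ...) object$model$params

#' @export
plot.ada_cid <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$epoch, cbind(tr$loss_cls, tr$loss_adv, tr$loss_total),
                    type = "l", lty = 1, col = c("steelblue", "firebrick", "black"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("classification", "adversarial", "total"),
                   lty = 1, col = c("steelblue", "firebrick", "black"),
                   bty = "n")
  invisible(x)
}
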