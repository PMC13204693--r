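#' Discriminator-derived perplexity of a target sample
#'
#' The negative log-softmax mass the class-informed discriminator assigns to
#' the target-domain class (`C + 1`):
#' `P(z) = -log( exp(z[C+1]) / sum_i exp(z[i]) )`, computed with a stable
#' log-sum-exp.  A high value means the discriminator cannot confidently call
#' the sample "target" -- i.e. the branch's target features sit close to the
#' source class structure, signalling good alignment; a near-zero value means
#' the discriminator is certain of the target domain, signalling poor
#' alignment.  Shift-invariant in `z`.
#'
#' @param z numeric vector of `C + 1` discriminator outputs (logits or
#'   log-probabilities), or a matrix with one such row per sample.
#' @param n_classes optionally, `C`; checked against `length(z) - 1` when
#'   given.
#' @return nonnegative perplexity value(s), one per row.
#' @examples
#' perplexity(c(0, 0, 0, 0))   # uniform: log(4)
#' perplexity(c(0, 0, 0, 10))  # certain target: ~ 0
#' @export
perplexity <- function(z, n_classes = NULL) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (!all(is.finite(z))) stop("discriminator outputs must be finite")
  if (!is.null(n_classes) && ncol(z) != n_classes + 1L)
    stop("expected vectors of length C + 1 = ", n_classes + 1L,
         ", got ", ncol(z))
  if (ncol(z) < 2L) stop("discriminator output must have at least 2 classes")
  dt <- ncol(z)  # target-domain class is the last component
  as.numeric(.row_logsumexp(z) - z[, dt])
}

#' Hemisphere fusion weights from branch perplexities
#'
#' `W_h = P_h / (P_l + P_r)`, so the hemisphere whose discriminator is more
#' confused about the target domain (better aligned) receives the larger
#' weight.  When `P_l + P_r` is below `eps` both weights fall back to 1/2.
#'
#' @param p_left,p_right nonnegative perplexities (vectors allowed).
#' @param eps degeneracy guard (default 1e-12).
#' @return list with numeric `left` and `right`, summing to 1 elementwise.
#' @examples
#' hemisphere_weights(1, 3)  # 0.25 / 0.75
#' @export
hemisphere_weights <- function(p_left, p_right, eps = 1e-12) {
  if (any(p_left < 0) || any(p_right < 0))
    stop("perplexities must be nonnegative")
  tot <- p_left + p_right
  wl <- ifelse(tot < eps, 0.5, p_left / tot)
  list(left = wl, right = 1 - wl)
}

#' Fuse the two hemisphere classifiers
#'
#' Convex combination of the branch class-probability vectors:
#' `W_l * probs_l + W_r * probs_r`.  The predicted label is the argmax of the
#' fused distribution (lowest index wins ties).
#'
#' @param w_left,w_right weights summing to 1 (scalars or per-sample
#'   vectors).
#' @param probs_left,probs_right class-probability matrices `[n x C]` (rows
#'   summing to 1); log-probabilities must be exponentiated first.
#' @param tol tolerance on the weight-sum check.
#' @return list with `probs` (fused `[n x C]` matrix) and `label` (integer
#'   argmax per sample).
#' @export
fuse_predictions <- function(w_left, probs_left, w_right, probs_right,
                             tol = 1e-9) {
  if (!is.matrix(probs_left)) probs_left <- matrix(probs_left, nrow = 1L)
  if (!is.matrix(probs_right)) probs_right <- matrix(probs_right, nrow = 1L)
  if (any(abs(w_left + w_right - 1) > tol))
    stop("fusion weights must sum to 1")
  fused <- probs_left * w_left + probs_right * w_right
  list(probs = fused, label = max.col(fused, ties.method = "first"))
}

#' Fit the bi-hemispheric adversarial domain adaptation model
#'
#' Trains one [ada_cid()] branch per hemisphere on sample-aligned left/right
#' feature sets, then fuses the two classifiers at prediction time with
#' perplexity-derived weights (see [perplexity()], [hemisphere_weights()]).
#'
#' Variants: `"full"` is the complete model; `"binary_discriminator"` swaps
#' the class-informed discriminator for a conventional 2-class one;
#' `"no_perplexity"` fixes the fusion weights at (1/2, 1/2);
#' `"shared_extractor"` trains a single extractor fed by both hemispheres
#' (which must then have equal input dimension) while keeping separate
#' classifier/discriminator heads; `"left_only"` / `"right_only"` train and
#' use a single branch.
#'
#' @param source_left,source_right labeled source hemispheres:
#'   [feature_dataset()]s or feature matrices, sample-aligned.
#' @param target_left,target_right unlabeled target hemispheres,
#'   sample-aligned with each other.
#' @param y source labels (taken from `source_left$labels` if omitted).
#' @param lambda,learning_rate,batch_size,epochs,seed training
#'   hyperparameters, as in [ada_cid()].
#' @param variant model variant, see Details.
#' @param weighting default fusion mode for [predict.bihada()]:
#'   `"per_sample"` (weights from each sample's own perplexities) or
#'   `"per_batch"` (weights from batch-mean perplexities over consecutive
#'   32-sample batches).
#' @param band_subset bands to keep for `feature_dataset` inputs.
#' @param verbose print per-epoch losses.
#' @return an object of class `bihada` with fields `left`, `right`
#'   (branch fits), `n_classes` and `config`.
#' @export
bihada <- function(source_left, source_right, target_left, target_right,
                   y = NULL, lambda = 1, learning_rate = 0.01,
                   batch_size = 32, epochs = 200, seed = 1,
                   variant = c("full", "binary_discriminator", "no_perplexity",
                               "shared_extractor", "left_only", "right_only"),
                   weighting = c("per_sample", "per_batch"),
                   band_subset = NULL, verbose = FALSE) {
  variant <- match.arg(variant)
  weighting <- match.arg(weighting)

  get_y <- function(obj) if (inherits(obj, "feature_dataset")) obj$labels else NULL
  flat <- function(obj) {
    if (inherits(obj, "feature_dataset")) flatten_bands(obj, band_subset)
    else as.matrix(obj)
  }
  if (inherits(source_left, "feature_dataset") &&
      inherits(source_right, "feature_dataset")) {
    if (!identical(source_left$labels, source_right$labels) ||
        !identical(source_left$subject_id, source_right$subject_id))
      stop("left and right source datasets are not sample-aligned")
  }
  y <- y %||% get_y(source_left)
  xs_l <- flat(source_left); xs_r <- flat(source_right)
  xt_l <- flat(target_left); xt_r <- flat(target_right)
  if (nrow(xs_l) != nrow(xs_r) || nrow(xt_l) != nrow(xt_r))
    stop("left and right hemispheres must have equal sample counts")
  y <- as.integer(y)
  n_classes <- max(y)

  branch_variant <- if (variant == "binary_discriminator")
    "binary_discriminator" else "full"

  if (variant == "shared_extractor") {
    if (ncol(xs_l) != ncol(xs_r))
      stop("shared_extractor requires equal left/right input dimensions")
    fit <- withr::with_seed(seed,
      .fit_shared(xs_l, xs_r, y, xt_l, xt_r, n_classes, lambda,
                  learning_rate, batch_size, epochs, verbose))
    left_fit <- fit$left; right_fit <- fit$right
  } else {
    do_left <- variant != "right_only"
    do_right <- variant != "left_only"
    left_fit <- if (do_left)
      structure(list(
        model = NULL, trace = NULL, n_classes = n_classes,
        config = list(lambda = lambda, variant = branch_variant)),
        class = "ada_cid") else NULL
    # independent branches: each gets its own deterministic sub-seed
    if (do_left) {
      f <- withr::with_seed(seed,
        .fit_branch(xs_l, y, xt_l, n_classes, lambda, learning_rate,
                    batch_size, epochs, branch_variant, verbose))
      left_fit$model <- f$model; left_fit$trace <- f$trace
    }
    right_fit <- NULL
    if (do_right) {
      f <- withr::with_seed(seed + 1L,
        .fit_branch(xs_r, y, xt_r, n_classes, lambda, learning_rate,
                    batch_size, epochs, branch_variant, verbose))
      right_fit <- structure(list(
        model = f$model, trace = f$trace, n_classes = n_classes,
        config = list(lambda = lambda, variant = branch_variant)),
        class = "ada_cid")
    }
  }

  structure(
    list(left = left_fit, right = right_fit, n_classes = n_classes,
         config = list(lambda = lambda, learning_rate = learning_rate,
                       batch_size = batch_size, epochs = epochs, seed = seed,
                       variant = variant, weighting = weighting,
                       band_subset = band_subset)),
    class = "bihada")
}

# joint training with a single shared extractor and per-hemisphere heads;
# per step each hemisphere's mixed batch passes through the shared extractor
# and the extractor gradients are summed before one Adam step.
.fit_shared <- function(xs_l, xs_r, y, xt_l, xt_r, n_classes, lambda,
                        learning_rate, batch_size, epochs, verbose) {
  ns <- nrow(xs_l); nt <- nrow(xt_l)
  seed_draw <- sample.int(.Machine$integer.max, 1L)
  left <- build_branch(ncol(xs_l), n_classes, seed = seed_draw)
  right <- build_branch(ncol(xs_r), n_classes,
                        seed = sample.int(.Machine$integer.max, 1L))
  # tie the extractors: right shares left's extractor parameters/state
  right$params[c("f1", "f2", "bn1", "bn2")] <-
    left$params[c("f1", "f2", "bn1", "bn2")]
  right$state <- left$state
  opt_l <- .adam_init(left$params)
  opt_r <- .adam_init(right$params[c("y1", "y2", "d1", "d2")])
  steps <- max(1L, ceiling(max(ns, nt) / batch_size))
  trace <- data.frame(epoch = seq_len(epochs), loss_cls = NA_real_,
                      loss_adv = NA_real_, loss_total = NA_real_)
  for (ep in seq_len(epochs)) {
    src_ord <- sample.int(ns); tgt_ord <- if (nt > 0L) sample.int(nt) else integer()
    ep_cls <- ep_adv <- 0
    for (st in seq_len(steps)) {
      si <- src_ord[((st - 1L) * batch_size + seq_len(batch_size) - 1L) %% ns + 1L]
      ti <- if (nt > 0L)
        tgt_ord[((st - 1L) * batch_size + seq_len(batch_size) - 1L) %% nt + 1L]
      else integer()
      gl <- nn_branch_grads(left, xs_l[si, , drop = FALSE], y[si],
                            if (nt) xt_l[ti, , drop = FALSE] else NULL, lambda)
      left$state <- gl$state
      right$state <- gl$state
      gr <- nn_branch_grads(right, xs_r[si, , drop = FALSE], y[si],
                            if (nt) xt_r[ti, , drop = FALSE] else NULL, lambda)
      right$state <- gr$state
      left$state <- gr$state
      # sum extractor gradients from both hemispheres
      ext_names <- c("f1", "f2", "bn1", "bn2")
      g_ext <- gl$grads[ext_names]
      for (nm in ext_names) for (el in names(g_ext[[nm]]))
        g_ext[[nm]][[el]] <- g_ext[[nm]][[el]] + gr$grads[[nm]][[el]]
      upd <- .adam_step(left$params, c(g_ext, gl$grads[c("y1", "y2", "d1", "d2")]),
                        opt_l, learning_rate)
      left$params <- upd$params; opt_l <- upd$opt
      updr <- .adam_step(right$params[c("y1", "y2", "d1", "d2")],
                         gr$grads[c("y1", "y2", "d1", "d2")],
                         opt_r, learning_rate)
      right$params[c("y1", "y2", "d1", "d2")] <- updr$params
      opt_r <- updr$opt
      right$params[ext_names] <- left$params[ext_names]
      ep_cls <- ep_cls + (gl$loss_cls + gr$loss_cls) / 2
      ep_adv <- ep_adv + (gl$loss_adv + gr$loss_adv) / 2
    }
    right$state <- left$state
    trace$loss_cls[ep] <- ep_cls / steps
    trace$loss_adv[ep] <- ep_adv / steps
    trace$loss_total[ep] <- total_loss(ep_cls / steps, ep_adv / steps, lambda)
    if (verbose && ep %% 10L == 0L)
      message(sprintf("epoch %3d  cls %.4f  adv %.4f", ep,
                      trace$loss_cls[ep], trace$loss_adv[ep]))
  }
  mk <- function(m) structure(list(model = m, trace = trace,
                                   n_classes = n_classes,
                                   config = list(lambda = lambda,
                                                 variant = "shared_extractor")),
                              class = "ada_cid")
  list(left = mk(left), right = mk(right))
}

#' Predict with perplexity-weighted hemisphere fusion
#'
#' Runs both branch networks on sample-aligned left/right feature matrices,
#' computes each branch's discriminator perplexity, derives the hemisphere
#' weights, and fuses the two class distributions.
#'
#' @param object a fitted [bihada()] model.
#' @param left,right hemisphere feature matrices or [feature_dataset()]s,
#'   sample-aligned.
#' @param weighting `"per_sample"` or `"per_batch"` (weights from batch-mean
#'   perplexities applied to consecutive batches of `batch_size` samples);
#'   defaults to the mode chosen at fit time.
#' @param batch_size batch size for `"per_batch"` weighting (default 32).
#' @param ... unused.
#' @return a `fusion_result` data.frame with one row per sample: columns
#'   `perplexity_left`, `perplexity_right`, `weight_left`, `weight_right`,
#'   `prob.<k>` for each class, and `predicted`.
#' @export
predict.bihada <- function(object, left, right, weighting = NULL,
                           batch_size = 32, ...) {
  weighting <- weighting %||% object$config$weighting
  weighting <- match.arg(weighting, c("per_sample", "per_batch"))
  bs <- object$config$band_subset
  if (inherits(left, "feature_dataset")) left <- flatten_bands(left, bs)
  if (inherits(right, "feature_dataset")) right <- flatten_bands(right, bs)

  variant <- object$config$variant
  if (variant %in% c("left_only", "right_only")) {
    br <- if (variant == "left_only") object$left else object$right
    x <- if (variant == "left_only") left else right
    fwd <- predict(br, x, type = "all")
    probs <- exp(fwd$class_log_probs)
    p <- perplexity(fwd$domain_log_probs)
    out <- data.frame(perplexity_left = if (variant == "left_only") p else NA,
                      perplexity_right = if (variant == "right_only") p else NA,
                      weight_left = as.numeric(variant == "left_only"),
                      weight_right = as.numeric(variant == "right_only"))
    return(.finish_fusion(out, probs,
                          max.col(probs, ties.method = "first")))
  }

  if (nrow(left) != nrow(right))
    stop("left and right inputs must be sample-aligned")
  fl <- predict(object$left, left, type = "all")
  fr <- predict(object$right, right, type = "all")
  p_l <- perplexity(fl$domain_log_probs)
  p_r <- perplexity(fr$domain_log_probs)

  if (variant == "no_perplexity") {
    w_l <- rep(0.5, length(p_l)); w_r <- rep(0.5, length(p_r))
  } else if (weighting == "per_sample") {
    w <- hemisphere_weights(p_l, p_r)
    w_l <- w$left; w_r <- w$right
  } else {
    n <- length(p_l)
    grp <- (seq_len(n) - 1L) %/% batch_size
    ml <- tapply(p_l, grp, mean)[as.character(grp)]
    mr <- tapply(p_r, grp, mean)[as.character(grp)]
    w <- hemisphere_weights(as.numeric(ml), as.numeric(mr))
    w_l <- w$left; w_r <- w$right
  }
  fused <- fuse_predictions(w_l, exp(fl$class_log_probs),
                            w_r, exp(fr$class_log_probs))
  out <- data.frame(perplexity_left = p_l, perplexity_right = p_r,
                    weight_left = w_l, weight_right = w_r)
  .finish_fusion(out, fused$probs, fused$label)
}

.finish_fusion <- function(meta, probs, label) {
  colnames(probs) <- paste0("prob.", seq_len(ncol(probs)))
  out <- cbind(meta, as.data.frame(probs))
  out$predicted <- label
  class(out) <- c("fusion_result", "data.frame")
  out
}

#' @export
print.bihada <- function(x, ...) {
  cat(sprintf("BiHADA model (%s): %d classes, weighting = %s\n",
              x$config$variant, x$n_classes, x$config$weighting))
  cat(sprintf("  lambda = %g, lr = %g, batch = %d, epochs = %d, seed = %d\n",
              x$config$lambda, x$config$learning_rate, x$config$batch_size,
              x$config$epochs, x$config$seed))
  for (h in c("left", "right"))
    if (!is.null(x[[h]]) && !is.null(x[[h]]$trace)) {
      tr <- utils::tail(x[[h]]$trace, 1L)
      cat(sprintf("  %-5s branch final losses: cls %.4f, adv %.4f\n",
                  h, tr$loss_cls, tr$loss_adv))
    }
  invisible(x)
}

#' @export
summary.bihada <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.bihada <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, sum(!vapply(x[c("left", "right")], is.null,
                                               logical(1)))))
  on.exit(graphics::par(op))
  for (h in c("left", "right"))
    if (!is.null(x[[h]]) && !is.null(x[[h]]$trace))
      plot(x[[h]], main = paste(h, "branch"), ...)
  invisible(x)
}
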