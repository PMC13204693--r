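# Neural-network substrate for the adversarial branches.
#
# A branch is three blocks, all plain MLPs on row-major sample matrices:
#   extractor      d_in -> h1 -> h2, each linear layer followed by batch
#                  normalization and LeakyReLU (so the final h2-dimensional
#                  representation is itself BN+LeakyReLU processed);
#   classifier     h2 -> head_hidden -> C          (log-softmax output);
#   discriminator  h2 -> head_hidden -> C+1        (log-softmax output;
#                  2 outputs in the binary-discriminator variant).
#
# Forward/backward passes are written out explicitly; the gradient reversal
# layer is realized in nn_branch_grads() by negating the adversarial
# feature-gradient before it is backpropagated through the extractor.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1
.LRELU_SLOPE <- 0.01

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
.init_linear <- function(d_in, d_out) {
  lim <- 1 / sqrt(d_in)
  list(W = matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out),
       b = stats::runif(d_out, -lim, lim))
}

#' Build an adversarial branch model
#'
#' Constructs one hemisphere branch: feature extractor
#' (`d_in -> hidden[1] -> hidden[2]`, each linear layer followed by batch
#' normalization and LeakyReLU), emotion classifier
#' (`hidden[2] -> head_hidden -> n_classes`) and class-informed domain
#' discriminator (`hidden[2] -> head_hidden -> n_classes + 1`; the extra
#' output is the target-domain class).  Both heads emit log-probabilities
#' (log-softmax).  Initialization is a uniform fan-in scheme, deterministic
#' given `seed`.
#'
#' @param d_in input dimension (135 for 27 channels x 5 bands).
#' @param n_classes number of emotion classes `C` (>= 2).
#' @param seed integer seed for parameter initialization.
#' @param hidden extractor layer widths, default `c(128, 64)`.
#' @param head_hidden hidden width of both heads, default 32.
#' @param n_domain_out number of discriminator outputs; default
#'   `n_classes + 1` (class-informed), 2 for a binary domain discriminator.
#' @return an object of class `branch_model` holding parameter matrices and
#'   batch-normalization running statistics.
#' @export
build_branch <- function(d_in, n_classes, seed = 1, hidden = c(128L, 64L),
                         head_hidden = 32L, n_domain_out = n_classes + 1L) {
  if (!.is_count(d_in)) stop("d_in must be a positive integer")
  if (!.is_count(n_classes) || n_classes < 2) stop("n_classes must be >= 2")
  withr::with_seed(seed, {
    params <- list(
      f1 = .init_linear(d_in, hidden[1L]),
      f2 = .init_linear(hidden[1L], hidden[2L]),
      y1 = .init_linear(hidden[2L], head_hidden),
      y2 = .init_linear(head_hidden, n_classes),
      d1 = .init_linear(hidden[2L], head_hidden),
      d2 = .init_linear(head_hidden, n_domain_out))
    params$bn1 <- list(gamma = rep(1, hidden[1L]), beta = rep(0, hidden[1L]))
    params$bn2 <- list(gamma = rep(1, hidden[2L]), beta = rep(0, hidden[2L]))
    structure(
      list(params = params,
           state = list(
             bn1 = list(mean = rep(0, hidden[1L]), var = rep(1, hidden[1L])),
             bn2 = list(mean = rep(0, hidden[2L]), var = rep(1, hidden[2L]))),
           d_in = d_in, n_classes = n_classes, n_domain_out = n_domain_out,
           hidden = hidden, head_hidden = head_hidden),
      class = "branch_model")
  })
}

#' @export
print.branch_model <- function(x, ...) {
  cat(sprintf(
    "<branch_model> extractor %d->%d->%d, classifier ->%d->%d, discriminator ->%d->%d\n",
    x$d_in, x$hidden[1], x$hidden[2], x$head_hidden, x$n_classes,
    x$head_hidden, x$n_domain_out))
  invisible(x)
}

# ---- layer forward/backward -------------------------------------------------

.bn_forward <- function(x, bn, state, training) {
  n <- nrow(x)
  if (training && n > 1L) {
    mu <- colMeans(x)
    xc <- .addrow(x, -mu)
    v <- colMeans(xc^2)
    new_state <- list(
      mean = (1 - .BN_MOMENTUM) * state$mean + .BN_MOMENTUM * mu,
      var = (1 - .BN_MOMENTUM) * state$var + .BN_MOMENTUM * v * n / (n - 1L))
  } else {
    mu <- state$mean
    v <- state$var
    xc <- .addrow(x, -mu)
    new_state <- state
  }
  inv_sd <- 1 / sqrt(v + .BN_EPS)
  xhat <- .mulrow(xc, inv_sd)
  list(out = .addrow(.mulrow(xhat, bn$gamma), bn$beta),
       cache = list(xhat = xhat, inv_sd = inv_sd, batch_stats = training && n > 1L),
       state = new_state)
}

.bn_backward <- function(dout, bn, cache) {
  n <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- .mulrow(dout, bn$gamma)
  if (cache$batch_stats) {
    # backprop through the batch mean/variance
    dx <- .mulrow(
      dxhat - rep(colMeans(dxhat), each = n) -
        cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n),
      cache$inv_sd)
  } else {
    dx <- .mulrow(dxhat, cache$inv_sd)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.lrelu <- function(x) pmax(x, 0) + .LRELU_SLOPE * pmin(x, 0)
.lrelu_grad <- function(x) .LRELU_SLOPE + (1 - .LRELU_SLOPE) * (x > 0)

# extractor forward; returns features and caches needed for backprop
.extractor_forward <- function(model, x, training) {
  p <- model$params
  a1 <- .addrow(x %*% p$f1$W, p$f1$b)
  bn1 <- .bn_forward(a1, p$bn1, model$state$bn1, training)
  h1 <- .lrelu(bn1$out)
  a2 <- .addrow(h1 %*% p$f2$W, p$f2$b)
  bn2 <- .bn_forward(a2, p$bn2, model$state$bn2, training)
  h2 <- .lrelu(bn2$out)
  list(features = h2,
       cache = list(x = x, bn1 = bn1$cache, pre1 = bn1$out, h1 = h1,
                    bn2 = bn2$cache, pre2 = bn2$out),
       state = list(bn1 = bn1$state, bn2 = bn2$state))
}

# backprop dfeat through the extractor; returns parameter gradients
.extractor_backward <- function(model, cache, dfeat) {
  p <- model$params
  d2 <- dfeat * .lrelu_grad(cache$pre2)
  bn2 <- .bn_backward(d2, p$bn2, cache$bn2)
  da2 <- bn2$dx
  dW2 <- crossprod(cache$h1, da2); db2 <- colSums(da2)
  dh1 <- tcrossprod(da2, p$f2$W) * .lrelu_grad(cache$pre1)
  bn1 <- .bn_backward(dh1, p$bn1, cache$bn1)
  da1 <- bn1$dx
  dW1 <- crossprod(cache$x, da1); db1 <- colSums(da1)
  list(f1 = list(W = dW1, b = db1), f2 = list(W = dW2, b = db2),
       bn1 = list(gamma = bn1$dgamma, beta = bn1$dbeta),
       bn2 = list(gamma = bn2$dgamma, beta = bn2$dbeta))
}

# head forward: linear -> LeakyReLU -> linear; returns logits + cache
.head_forward <- function(feat, l1, l2) {
  a <- .addrow(feat %*% l1$W, l1$b)
  h <- .lrelu(a)
  logits <- .addrow(h %*% l2$W, l2$b)
  list(logits = logits, cache = list(feat = feat, a = a, h = h))
}

# backprop dlogits through a head; returns grads + dfeat
.head_backward <- function(dlogits, l1, l2, cache) {
  dW2 <- crossprod(cache$h, dlogits); db2 <- colSums(dlogits)
  dh <- tcrossprod(dlogits, l2$W) * .lrelu_grad(cache$a)
  dW1 <- crossprod(cache$feat, dh); db1 <- colSums(dh)
  dfeat <- tcrossprod(dh, l1$W)
  list(l1 = list(W = dW1, b = db1), l2 = list(W = dW2, b = db2),
       dfeat = dfeat)
}

# ---- full branch forward (inference) ---------------------------------------

#' Forward pass of a branch model
#'
#' Runs the extractor and both heads.  In evaluation mode (the default) batch
#' normalization uses the running estimates, so the output is a deterministic
#' function of parameters and input.
#'
#' @param model a [build_branch()] model.
#' @param x feature matrix `[n x d_in]`.
#' @param training use batch statistics in batch normalization (`TRUE` only
#'   inside the training loop).
#' @return list with `class_log_probs` (`n x C`), `domain_log_probs`
#'   (`n x n_domain_out`) and `features` (`n x hidden[2]`); both heads'
#'   outputs are normalized log-probabilities.
#' @export
branch_forward <- function(model, x, training = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$d_in)
    stop("input has ", ncol(x), " columns but the model expects ", model$d_in)
  ext <- .extractor_forward(model, x, training)
  p <- model$params
  hy <- .head_forward(ext$features, p$y1, p$y2)
  hd <- .head_forward(ext$features, p$d1, p$d2)
  list(class_log_probs = .row_logsoftmax(hy$logits),
       domain_log_probs = .row_logsoftmax(hd$logits),
       features = ext$features)
}

#' Gradient reversal (forward contract)
#'
#' The gradient reversal layer is the identity in the forward pass; during
#' backpropagation the upstream gradient is multiplied by `-coeff` before it
#' reaches the feature extractor.  The backward contract is realized inside
#' [nn_branch_grads()]; this function documents and exposes the forward
#' contract and records `coeff` as an attribute.
#'
#' @param x a feature batch.
#' @param coeff nonnegative reversal coefficient (the package fixes 1; the
#'   adversarial strength is carried by the loss weight lambda).
#' @return `x`, unchanged, with attribute `grl_coeff`.
#' @export
gradient_reversal <- function(x, coeff = 1) {
  if (coeff < 0) stop("coeff must be nonnegative")
  attr(x, "grl_coeff") <- coeff
  x
}

# ---- joint loss + gradient computation -------------------------------------

#' Losses and parameter gradients for one adversarial training step
#'
#' The computational core of the training loop, exposed so the adversarial
#' gradient path can be verified independently (finite differences).  The
#' source and target batches are concatenated and passed through the
#' extractor once (batch normalization sees the mixed batch); the classifier
#' sees only source rows, the discriminator all rows with domain-class labels
#' `y_i` (source) / `C+1` (target).  The extractor receives the
#' classification gradient plus `-grl_coeff` times the adversarial gradient
#' (gradient reversal).
#'
#' @param model a [build_branch()] model.
#' @param xs source feature matrix, `ys` source labels in `1..C`.
#' @param ys integer source labels.
#' @param xt target feature matrix (may have zero rows).
#' @param lambda adversarial loss weight (>= 0).
#' @param binary if `TRUE`, use binary source/target domain labels (the
#'   model's discriminator must then have 2 outputs).
#' @param grl_coeff gradient-reversal coefficient (default 1).
#' @param reversal `"target_only"` (the default for the class-informed
#'   discriminator): only the target rows' adversarial gradient is reversed
#'   into the extractor, so the extractor learns to make target features
#'   deceive the discriminator while the source rows' class-structured
#'   discriminator loss trains the discriminator alone; `"all"`: classic
#'   domain-adversarial reversal of the whole combined batch (used for the
#'   binary-discriminator ablation).
#' @param training batch-normalization mode (default `TRUE`).
#' @return list: `loss_cls` (mean source cross-entropy), `loss_adv` (mean
#'   domain cross-entropy over the combined batch, before the lambda weight),
#'   `grads` (per-parameter gradients of `loss_cls + lambda * loss_adv` with
#'   the reversal applied on the extractor), `grads_f_adv` (the adversarial
#'   part of the extractor gradient alone, reversal applied), and `state`
#'   (updated batch-norm running statistics).
#' @export
nn_branch_grads <- function(model, xs, ys, xt, lambda, binary = FALSE,
                            grl_coeff = 1,
                            reversal = c("target_only", "all"),
                            training = TRUE) {
  reversal <- match.arg(reversal)
  ns <- nrow(xs); nt <- if (is.null(xt)) 0L else nrow(xt)
  if (ns == 0L) stop("empty source batch")
  C <- model$n_classes
  if (any(ys < 1L | ys > C)) stop("source labels must lie in 1..C")
  x_all <- if (nt > 0L) rbind(xs, xt) else xs
  ext <- .extractor_forward(model, x_all, training)
  p <- model$params

  # classifier on source rows
  hy <- .head_forward(ext$features[seq_len(ns), , drop = FALSE], p$y1, p$y2)
  logp_y <- .row_logsoftmax(hy$logits)
  loss_cls <- -mean(logp_y[cbind(seq_len(ns), ys)])
  onehot_y <- matrix(0, ns, C); onehot_y[cbind(seq_len(ns), ys)] <- 1
  dlogits_y <- (.row_softmax(hy$logits) - onehot_y) / ns
  gy <- .head_backward(dlogits_y, p$y1, p$y2, hy$cache)

  # discriminator on all rows with domain-class labels
  dci <- domain_class_label(
    domain = rep(c("source", "target"), c(ns, nt)),
    y = c(ys, rep(NA_integer_, nt)), n_classes = C, binary = binary)
  hd <- .head_forward(ext$features, p$d1, p$d2)
  nd <- model$n_domain_out
  if (ncol(hd$logits) != nd || max(dci) > nd)
    stop("discriminator output width does not match the domain labels")
  logp_d <- .row_logsoftmax(hd$logits)
  loss_adv <- -mean(logp_d[cbind(seq_len(ns + nt), dci)])
  onehot_d <- matrix(0, ns + nt, nd)
  onehot_d[cbind(seq_len(ns + nt), dci)] <- 1
  dlogits_d <- lambda * (.row_softmax(hd$logits) - onehot_d) / (ns + nt)
  gd <- .head_backward(dlogits_d, p$d1, p$d2, hd$cache)

  # assemble feature gradient: classification (source rows) plus the
  # reversed adversarial gradient (gradient reversal layer)
  dfeat_adv <- gd$dfeat
  if (reversal == "target_only" && nt > 0L)
    dfeat_adv[seq_len(ns), ] <- 0
  dfeat_cls <- matrix(0, ns + nt, ncol(ext$features))
  dfeat_cls[seq_len(ns), ] <- gy$dfeat
  dfeat <- dfeat_cls - grl_coeff * dfeat_adv
  gf <- .extractor_backward(model, ext$cache, dfeat)
  gf_adv <- .extractor_backward(model, ext$cache, -grl_coeff * dfeat_adv)

  grads <- c(gf, list(y1 = gy$l1, y2 = gy$l2, d1 = gd$l1, d2 = gd$l2))
  list(loss_cls = loss_cls, loss_adv = loss_adv,
       grads = grads, grads_f_adv = gf_adv, state = ext$state)
}

# ---- Adam optimizer ---------------------------------------------------------

.adam_init <- function(params) {
  zero_like <- function(x) rapply(x, function(v) v * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# flat iteration over the nested parameter list; names like "f1.W"
.walk_params <- function(params, fn) {
  for (blk in names(params)) for (el in names(params[[blk]]))
    params[[blk]][[el]] <- fn(blk, el, params[[blk]][[el]])
  params
}

.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (blk in names(grads)) for (el in names(grads[[blk]])) {
    g <- grads[[blk]][[el]]
    opt$m[[blk]][[el]] <- beta1 * opt$m[[blk]][[el]] + (1 - beta1) * g
    opt$v[[blk]][[el]] <- beta2 * opt$v[[blk]][[el]] + (1 - beta2) * g^2
    mhat <- opt$m[[blk]][[el]] / bc1
    vhat <- opt$v[[blk]][[el]] / bc2
    params[[blk]][[el]] <- params[[blk]][[el]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
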